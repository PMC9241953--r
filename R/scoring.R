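#' @title Normalization chain and interactor classification
#' @name scoring
#' @description The scoring procedure applied to a validated count table:
#'   divide each protein's summed peptide count by its length, divide by the
#'   bait's length-normalized value within each assay, pool the log2 values
#'   of all assays as separate observations, fit the mixture, and call
#'   proteins in-complex when their posterior under the high component
#'   exceeds 0.5 and their summed raw counts reach 5.
NULL

#' Length-normalize a count table
#'
#' Divides each (protein, assay) summed peptide count by the protein's
#' length in amino acids, correcting for longer proteins yielding more
#' detectable peptides. Zero counts map to zero.
#'
#' @param table a [count_table()].
#' @param pseudocount value added to every raw count before division
#'   (default 0; a small pseudocount lets zero cells survive the later log2
#'   step, at the cost of biasing low counts).
#' @return data.frame with columns `protein_id`, `assay_id`, `value`.
#' @export
length_normalize <- function(table, pseudocount = 0) {
  stopifnot(inherits(table, "count_table"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  counts <- table$counts
  len <- table$lengths[counts$protein_id]
  data.frame(protein_id = counts$protein_id,
             assay_id = counts$assay_id,
             value = (counts$raw_count + pseudocount) / as.numeric(len),
             stringsAsFactors = FALSE)
}

#' Bait-normalize length-normalized values
#'
#' Within each assay, divides every protein's length-normalized value by the
#' bait's, making values comparable across pulldowns of differing recovery
#' efficiency. The bait maps to exactly 1 in every assay by construction.
#'
#' @param values data.frame from [length_normalize()].
#' @param bait_id bait protein identifier; its value must be positive in
#'   every assay.
#' @return data.frame of the same shape, values now in bait units.
#' @export
bait_normalize <- function(values, bait_id) {
  .require_columns(values, c("protein_id", "assay_id", "value"),
                   "normalized values")
  bait_rows <- values[values$protein_id == bait_id, , drop = FALSE]
  assays <- unique(values$assay_id)
  bait_val <- bait_rows$value[match(assays, bait_rows$assay_id)]
  if (anyNA(bait_val) || any(bait_val <= 0)) {
    stop("bait '", bait_id, "' must have a positive value in every assay",
         call. = FALSE)
  }
  names(bait_val) <- assays
  values$value <- values$value / bait_val[values$assay_id]
  values
}

#' Pool assays and move to the log2 scale
#'
#' Merges the bait-normalized values of all assays into one observation set
#' for mixture training, each (protein, assay) cell a separate observation.
#' Bait cells (identically 1, log2 = 0 by construction) and zero cells
#' (log2 undefined) are excluded and recorded with a reason, so the final
#' observation count is auditable:
#' `n_obs = (proteins - 1) * assays - zero cells among non-bait`.
#'
#' @param values bait-normalized data.frame from [bait_normalize()].
#' @param bait_id bait identifier to exclude.
#' @param min_obs minimum observations required to attempt a mixture fit
#'   (default 10).
#' @return An object of class `observation_set`: list with `entries`
#'   (data.frame `protein_id`, `assay_id`, `log2_value`) and `excluded`
#'   (data.frame `protein_id`, `assay_id`, `reason`).
#' @export
merge_and_log2 <- function(values, bait_id, min_obs = 10L) {
  .require_columns(values, c("protein_id", "assay_id", "value"),
                   "normalized values")
  is_bait <- values$protein_id == bait_id
  is_zero <- !is_bait & values$value == 0
  keep <- !is_bait & !is_zero
  excluded <- data.frame(
    protein_id = values$protein_id[!keep],
    assay_id = values$assay_id[!keep],
    reason = ifelse(is_bait[!keep], "bait", "zero-count"),
    stringsAsFactors = FALSE)
  entries <- data.frame(
    protein_id = values$protein_id[keep],
    assay_id = values$assay_id[keep],
    log2_value = log2(values$value[keep]),
    stringsAsFactors = FALSE)
  if (any(!is.finite(entries$log2_value))) {
    stop("non-finite log2 values encountered; check input counts",
         call. = FALSE)
  }
  if (nrow(entries) < min_obs) {
    stop("only ", nrow(entries), " observations remain after exclusions; ",
         "at least ", min_obs, " are needed to fit a mixture", call. = FALSE)
  }
  structure(list(entries = entries, excluded = excluded),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("Pooled log2 observation set: ", nrow(x$entries), " observations from ",
      length(unique(x$entries$protein_id)), " proteins (",
      nrow(x$excluded), " cells excluded)\n", sep = "")
  invisible(x)
}

#' Call proteins in or out of the bait complex
#'
#' For each non-bait protein, the per-protein score is the arithmetic mean
#' of its pooled log2 observations (only assays in which it was detected;
#' no imputation), and the posterior is the high-component membership
#' probability of that score under the fitted mixture. A protein is called
#' in-complex when its posterior strictly exceeds `posterior_threshold` and
#' its raw counts summed over all assays reach `count_threshold`; the strict
#' inequality and the count floor both follow the calling rule the scores
#' are defined by. Proteins never detected (all-zero counts) receive
#' posterior 0 and a negative verdict. The bait itself is reported first
#' with a sentinel posterior of 1 and `is_bait = TRUE`.
#'
#' @param obs an `observation_set` from [merge_and_log2()].
#' @param fit a converged `gmm_fit` trained on `obs`.
#' @param table the [count_table()] the observations came from (source of
#'   raw count totals and of proteins excluded from training).
#' @param posterior_threshold posterior cutoff, strict (default 0.5).
#' @param count_threshold minimum summed raw count, inclusive (default 5).
#' @return data.frame with columns `protein_id`, `total_raw_count`,
#'   `mean_log2_score`, `posterior`, `is_interactor`, `is_bait`.
#' @export
classify <- function(obs, fit, table, posterior_threshold = 0.5,
                     count_threshold = 5L) {
  stopifnot(inherits(obs, "observation_set"), inherits(fit, "gmm_fit"),
            inherits(table, "count_table"))
  if (!isTRUE(fit$converged)) {
    stop("mixture fit did not converge; refit with more iterations or ",
         "a looser tolerance before classifying", call. = FALSE)
  }
  if (posterior_threshold <= 0 || posterior_threshold >= 1) {
    stop("posterior_threshold must lie in (0, 1)", call. = FALSE)
  }
  if (count_threshold < 0) stop("count_threshold must be >= 0", call. = FALSE)

  totals <- tapply(table$counts$raw_count, table$counts$protein_id, sum)
  proteins <- sort(names(totals))
  prey <- setdiff(proteins, table$bait_id)

  means <- tapply(obs$entries$log2_value, obs$entries$protein_id, mean)
  hi <- select_high_component(fit)

  score <- as.numeric(means[prey])          # NA for all-zero proteins
  posterior <- numeric(length(prey))
  observed <- !is.na(score)
  if (any(observed)) {
    posterior[observed] <- gmm_posterior(fit, score[observed])[, hi]
  }
  calls <- data.frame(
    protein_id = prey,
    total_raw_count = as.integer(totals[prey]),
    mean_log2_score = score,
    posterior = posterior,
    stringsAsFactors = FALSE)
  calls$is_interactor <- calls$posterior > posterior_threshold &
    calls$total_raw_count >= count_threshold
  calls$is_bait <- FALSE

  bait_row <- data.frame(
    protein_id = table$bait_id,
    total_raw_count = as.integer(totals[table$bait_id]),
    mean_log2_score = 0,
    posterior = 1,
    is_interactor = TRUE,
    is_bait = TRUE,
    stringsAsFactors = FALSE)
  rbind(bait_row, calls)
}

#' Sort differentially expressed transcripts by cell-cycle peak phase
#'
#' Companion filter for expression data collected alongside the pulldowns:
#' retains transcripts whose absolute log2 fold change strictly exceeds
#' `lfc_threshold` (and, when `padj_threshold` is set, whose adjusted P
#' value is at most that cutoff), then partitions them by annotated peak
#' expression phase into G1, S/M/C, or noncyclical groups. Transcripts
#' passing the filter but missing from the annotation fall into the
#' noncyclical group with a warning.
#'
#' @param de data.frame with columns `transcript_id`, `log2_change`, and
#'   optionally `adjusted_p` (in `[0, 1]` or NA).
#' @param annotation data.frame with columns `transcript_id`, `peak_phase`
#'   (values `G1`, `SMC`, `NONCYCLICAL`); one phase per transcript.
#' @param lfc_threshold strict absolute log2-fold-change cutoff
#'   (default 1.5).
#' @param padj_threshold inclusive adjusted-P cutoff (default 0.1);
#'   `NULL` disables the significance filter. Transcripts with missing
#'   adjusted P are dropped when the filter is active.
#' @return named list of character vectors `G1`, `SMC`, `NONCYCLICAL`;
#'   disjoint, union equal to the retained transcript set.
#' @export
phase_sort <- function(de, annotation, lfc_threshold = 1.5,
                       padj_threshold = 0.1) {
  .require_columns(de, c("transcript_id", "log2_change"), "DE table")
  .require_columns(annotation, c("transcript_id", "peak_phase"),
                   "phase annotation")
  phases <- c("G1", "SMC", "NONCYCLICAL")
  ann_id <- .trim(annotation$transcript_id)
  ann_phase <- toupper(.trim(annotation$peak_phase))
  if (!all(ann_phase %in% phases)) {
    stop("peak_phase values must be one of: ", paste(phases, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann_id)) {
    stop("phase annotation maps a transcript to more than one phase",
         call. = FALSE)
  }
  if (!is.null(de$adjusted_p)) {
    bad_p <- !is.na(de$adjusted_p) & (de$adjusted_p < 0 | de$adjusted_p > 1)
    if (any(bad_p)) stop("adjusted_p outside [0, 1]", call. = FALSE)
  }

  keep <- abs(de$log2_change) > lfc_threshold
  if (!is.null(padj_threshold)) {
    padj <- if (is.null(de$adjusted_p)) rep(NA_real_, nrow(de)) else de$adjusted_p
    keep <- keep & !is.na(padj) & padj <= padj_threshold
  }
  ids <- .trim(de$transcript_id[keep])

  phase <- ann_phase[match(ids, ann_id)]
  unann <- is.na(phase)
  if (any(unann)) {
    warning(sum(unann), " retained transcript(s) missing from the phase ",
            "annotation; assigned to NONCYCLICAL", call. = FALSE)
    phase[unann] <- "NONCYCLICAL"
  }
  stats::setNames(lapply(phases, function(p) ids[phase == p]), phases)
}
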