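#' @title End-to-end scoring pipeline
#' @name pipeline
#' @description Orchestrates read -> length-normalize -> bait-normalize ->
#'   pool/log2 -> mixture fit -> classify -> write, with a machine-readable
#'   run record that suffices to replay the run.
NULL

#' Run the full interactor-scoring pipeline
#'
#' Executes the stages in fixed order on a count table (given as an object
#' or as file paths), writes the ranked calls, the exclusion log, a fit
#' summary, and a YAML run record capturing every parameter and the seed.
#' The same configuration and seed always produce byte-identical outputs.
#'
#' @param table a [count_table()], or `NULL` to read from files.
#' @param counts_path,format,lengths_path,bait_id file inputs used when
#'   `table` is `NULL`; see [read_count_table()].
#' @param output_dir directory for artifacts (created if needed); `NULL`
#'   skips writing and returns the calls only.
#' @param k,tol,max_iter,var_floor,n_restarts,seed,init mixture-fit
#'   controls, see [fit_gmm()].
#' @param select_k_by_bic if `TRUE`, choose k over `1:3` by BIC instead of
#'   fixing it (default `FALSE`).
#' @param posterior_threshold,count_threshold calling rule, see
#'   [classify()].
#' @param pseudocount added to raw counts before length normalization
#'   (default 0: zero cells are excluded from training rather than
#'   pseudocounted).
#' @param min_obs minimum pooled observations, see [merge_and_log2()].
#' @param verbose print stage progress (default `FALSE`).
#' @return list of class `apmix_run`: `calls` (ordered as written), `fit`,
#'   `observations`, `record` (the run-record list).
#' @examples
#' truth <- simulate_pulldown(sim_config(seed = 1))
#' run <- run_pipeline(table = truth$table, output_dir = NULL)
#' head(run$calls)
#' @export
run_pipeline <- function(table = NULL, counts_path = NULL,
                         format = c("long", "wide", "peptide"),
                         lengths_path = NULL, bait_id = NULL,
                         output_dir = NULL,
                         k = 2L, tol = 1e-8, max_iter = 2000L,
                         var_floor = 1e-6, n_restarts = 5L, seed = 0L,
                         init = "quantile", select_k_by_bic = FALSE,
                         posterior_threshold = 0.5, count_threshold = 5L,
                         pseudocount = 0, min_obs = 10L, verbose = FALSE) {
  format <- match.arg(format)
  say <- function(...) if (verbose) message("[apmix] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  if (is.null(table)) {
    if (is.null(counts_path) || is.null(lengths_path) || is.null(bait_id)) {
      stop("either `table` or all of counts_path, lengths_path, bait_id ",
           "must be given", call. = FALSE)
    }
    say("reading ", counts_path, " (", format, " dialect)")
    table <- stage("read", read_count_table(counts_path, format,
                                            lengths = read_lengths(lengths_path),
                                            bait_id = bait_id))
  }
  stopifnot(inherits(table, "count_table"))

  say("length-normalizing ", length(table$lengths), " proteins")
  ln <- stage("length_normalize", length_normalize(table, pseudocount))
  bn <- stage("bait_normalize", bait_normalize(ln, table$bait_id))
  obs <- stage("merge_and_log2", merge_and_log2(bn, table$bait_id, min_obs))
  say(nrow(obs$entries), " pooled observations (",
      nrow(obs$excluded), " excluded)")

  fit <- stage("fit_gmm", {
    if (select_k_by_bic) {
      select_k_bic(obs$entries$log2_value, k_values = 1:3, tol = tol,
                   max_iter = max_iter, var_floor = var_floor,
                   n_restarts = n_restarts, seed = seed, init = init)
    } else {
      fit_gmm(obs$entries$log2_value, k = k, tol = tol, max_iter = max_iter,
              var_floor = var_floor, n_restarts = n_restarts, seed = seed,
              init = init)
    }
  })
  say("mixture fit: k = ", fit$k, ", means ",
      paste(round(fit$means, 3), collapse = " / "))

  calls <- stage("classify",
                 classify(obs, fit, table, posterior_threshold,
                          count_threshold))

  record <- list(
    pipeline = "apmix score",
    version = as.character(utils::packageVersion("apmix")),
    parameters = list(
      bait_id = table$bait_id,
      format = format,
      counts_path = if (is.null(counts_path)) NA else counts_path,
      lengths_path = if (is.null(lengths_path)) NA else lengths_path,
      k = fit$k, tol = tol, max_iter = max_iter, var_floor = var_floor,
      n_restarts = n_restarts, seed = as.integer(seed), init = init,
      select_k_by_bic = select_k_by_bic,
      posterior_threshold = posterior_threshold,
      count_threshold = as.integer(count_threshold),
      pseudocount = pseudocount, min_obs = as.integer(min_obs)),
    data = list(
      n_proteins = length(table$lengths),
      n_assays = length(table$assays),
      n_observations = nrow(obs$entries),
      n_excluded_bait = sum(obs$excluded$reason == "bait"),
      n_excluded_zero = sum(obs$excluded$reason == "zero-count")),
    fit = list(
      weights = fit$weights, means = fit$means, variances = fit$variances,
      log_likelihood = fit$log_likelihood, n_iter = fit$n_iter,
      converged = fit$converged),
    results = list(
      n_interactors = sum(calls$is_interactor & !calls$is_bait)))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    calls <- write_calls(calls, file.path(output_dir, "calls.tsv"))
    utils::write.table(obs$excluded, file.path(output_dir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(gmm_summary_text(fit),
               file.path(output_dir, "fit_summary.txt"))
    yaml::write_yaml(record, file.path(output_dir, "run_record.yaml"),
                     precision = 15L)
    say("artifacts written to ", output_dir)
  } else {
    ord <- order(-calls$posterior, -calls$total_raw_count, calls$protein_id,
                 method = "radix")
    calls <- calls[ord, , drop = FALSE]
  }
  structure(list(calls = calls, fit = fit, observations = obs,
                 record = record),
            class = "apmix_run")
}

#' Replay a pipeline run from its run record
#'
#' Re-executes [run_pipeline()] using only the parameters stored in a
#' `run_record.yaml`, reproducing the calls file exactly. Requires the
#' original run to have been file-based (the record stores input paths,
#' not data).
#'
#' @param record_path path to a `run_record.yaml`.
#' @param output_dir where to write the replayed artifacts (`NULL` to skip).
#' @return the replayed `apmix_run`.
#' @export
replay_run <- function(record_path, output_dir = NULL) {
  rec <- yaml::read_yaml(record_path)
  p <- rec$parameters
  if (is.null(p$counts_path) || is.na(p$counts_path)) {
    stop("run record has no input paths; only file-based runs can be ",
         "replayed", call. = FALSE)
  }
  run_pipeline(counts_path = p$counts_path, format = p$format,
               lengths_path = p$lengths_path, bait_id = p$bait_id,
               output_dir = output_dir, k = p$k, tol = p$tol,
               max_iter = p$max_iter, var_floor = p$var_floor,
               n_restarts = p$n_restarts, seed = p$seed, init = p$init,
               select_k_by_bic = isTRUE(p$select_k_by_bic),
               posterior_threshold = p$posterior_threshold,
               count_threshold = p$count_threshold,
               pseudocount = p$pseudocount, min_obs = p$min_obs)
}

#' Run the transcript phase-sorting filter from files
#'
#' Reads a differential-expression table (`transcript_id`, `log2_change`,
#' optional `adjusted_p`) and a phase annotation (`transcript_id`,
#' `peak_phase`), applies [phase_sort()], and writes a three-column summary
#' (`transcript_id`, `group`, `log2_change`) plus per-group counts.
#'
#' @param de_path,annotation_path tab-separated input files.
#' @param output_path summary output (`NULL` to skip writing).
#' @param lfc_threshold,padj_threshold see [phase_sort()].
#' @return list with `groups` (as from [phase_sort()]) and `summary`
#'   (the written data.frame).
#' @export
run_phase_sort <- function(de_path, annotation_path, output_path = NULL,
                           lfc_threshold = 1.5, padj_threshold = 0.1) {
  de <- .read_tsv(de_path)
  ann <- .read_tsv(annotation_path)
  groups <- phase_sort(de, ann, lfc_threshold, padj_threshold)
  ids <- unlist(groups, use.names = FALSE)
  grp <- rep(names(groups), lengths(groups))
  summary <- data.frame(
    transcript_id = ids,
    group = grp,
    log2_change = de$log2_change[match(ids, .trim(de$transcript_id))],
    stringsAsFactors = FALSE)
  if (!is.null(output_path)) {
    utils::write.table(summary, output_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(groups = groups, summary = summary)
}

#' @export
print.apmix_run <- function(x, ...) {
  n_int <- sum(x$calls$is_interactor & !x$calls$is_bait)
  cat("apmix run: ", nrow(x$calls) - 1L, " preys scored, ", n_int,
      " called in complex with ", x$record$parameters$bait_id, "\n", sep = "")
  invisible(x)
}
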