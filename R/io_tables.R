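#' @title Count-table I/O and validation
#' @name io_tables
#' @description Readers and writers for the tab-separated tables an AP-MS
#'   scoring run touches: per-assay peptide/spectral counts, protein lengths,
#'   and the final interactor calls. All readers validate strictly and fail
#'   loudly; no format sniffing is performed.
NULL

.trim <- function(x) sub("^\\s+", "", sub("\\s+$", "", as.character(x)))

.read_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.check_counts <- function(count, what = "count") {
  bad <- which(!is.finite(count) | count < 0 | count != round(count))
  if (length(bad) > 0) {
    stop("invalid ", what, " (must be a whole number >= 0) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  as.integer(round(count))
}

#' Construct a validated AP-MS count table
#'
#' Bundles long-format counts, a protein-length map and a bait identifier
#' into a `count_table` object, enforcing the structural invariants the
#' downstream normalization chain relies on: one count per (protein, assay)
#' cell, one positive length per protein, and a bait detected (count >= 1)
#' in every assay -- a pulldown in which the bait itself was not recovered
#' is not a usable pulldown.
#'
#' @param counts data.frame with columns `protein_id`, `assay_id`,
#'   `raw_count` (whole numbers >= 0). Identifiers are whitespace-trimmed
#'   and treated case-sensitively.
#' @param lengths named integer vector (or coercible) mapping every
#'   `protein_id` in `counts` to its length in amino acids (>= 1).
#' @param bait_id identifier of the bait protein; must appear in `counts`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (long data.frame), `lengths` (named integer vector), `bait_id`, and
#'   `assays` (sorted unique assay identifiers).
#' @examples
#' counts <- data.frame(
#'   protein_id = rep(c("BAIT", "P1"), each = 2),
#'   assay_id   = rep(c("a1", "a2"), 2),
#'   raw_count  = c(40L, 50L, 8L, 6L))
#' ct <- count_table(counts, c(BAIT = 500, P1 = 250), "BAIT")
#' ct$assays
#' @export
count_table <- function(counts, lengths, bait_id) {
  .require_columns(counts, c("protein_id", "assay_id", "raw_count"),
                   "count table")
  counts <- data.frame(
    protein_id = .trim(counts$protein_id),
    assay_id   = .trim(counts$assay_id),
    raw_count  = .check_counts(counts$raw_count, "raw_count"),
    stringsAsFactors = FALSE)
  if (any(counts$protein_id == "") || any(counts$assay_id == "")) {
    stop("empty protein_id or assay_id after trimming", call. = FALSE)
  }
  key <- paste(counts$protein_id, counts$assay_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (protein_id, assay_id) pair(s): ",
         paste(utils::head(sub("\r", " / ", key[dup]), 5L), collapse = "; "),
         call. = FALSE)
  }

  lengths <- stats::setNames(as.numeric(lengths), .trim(names(lengths)))
  if (anyNA(lengths) || any(lengths < 1) || any(lengths != round(lengths))) {
    stop("protein lengths must be whole numbers >= 1", call. = FALSE)
  }
  if (anyDuplicated(names(lengths))) {
    dn <- unique(names(lengths)[duplicated(names(lengths))])
    keep <- !duplicated(names(lengths))
    conflicting <- vapply(dn, function(p) {
      length(unique(lengths[names(lengths) == p])) > 1L
    }, logical(1))
    if (any(conflicting)) {
      stop("conflicting lengths for protein(s): ",
           paste(dn[conflicting], collapse = ", "), call. = FALSE)
    }
    lengths <- lengths[keep]
  }
  missing_len <- setdiff(unique(counts$protein_id), names(lengths))
  if (length(missing_len) > 0) {
    stop("protein(s) without a length: ",
         paste(utils::head(missing_len, 10L), collapse = ", "), call. = FALSE)
  }

  bait_id <- .trim(bait_id)
  if (length(bait_id) != 1L || is.na(bait_id) || bait_id == "") {
    stop("bait_id must be a single non-empty string", call. = FALSE)
  }
  assays <- sort(unique(counts$assay_id))
  bait_rows <- counts[counts$protein_id == bait_id, , drop = FALSE]
  bait_by_assay <- stats::setNames(
    bait_rows$raw_count[match(assays, bait_rows$assay_id)], assays)
  if (anyNA(bait_by_assay) || any(bait_by_assay < 1)) {
    stop("bait '", bait_id, "' must have raw_count >= 1 in every assay",
         call. = FALSE)
  }

  structure(list(counts = counts,
                 lengths = stats::setNames(as.integer(lengths), names(lengths)),
                 bait_id = bait_id,
                 assays = assays),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("AP-MS count table: ", length(x$lengths), " proteins x ",
      length(x$assays), " assays; bait = ", x$bait_id, "\n", sep = "")
  invisible(x)
}

#' Read a count table from a tab-separated file
#'
#' Three explicit dialects are supported; the dialect is never guessed.
#' `long` expects columns `protein_id`, `assay_id`, `count` (one row per
#' cell). `wide` expects `protein_id` plus one column per assay. `peptide`
#' expects `peptide_id`, `protein_id`, `assay_id`, `count` and sums peptide
#' rows per (protein, assay) before validation, which is how summed peptide
#' counts per protein are obtained from a peptide-level export.
#'
#' Zeros are retained at read time: whether zero cells enter mixture
#' training is a scoring-stage decision, not an I/O one.
#'
#' @param path path to a headed, tab-separated UTF-8 file.
#' @param format one of `"long"`, `"wide"`, `"peptide"`.
#' @param lengths optional named vector of protein lengths (or a path to a
#'   length table accepted by [read_lengths()]).
#' @param bait_id optional bait identifier.
#' @return With `lengths` and `bait_id`, a validated [count_table()];
#'   otherwise a validated long-format counts data.frame.
#' @seealso [read_lengths()], [write_calls()]
#' @export
read_count_table <- function(path, format = c("long", "wide", "peptide"),
                             lengths = NULL, bait_id = NULL) {
  format <- match.arg(format)
  df <- .read_tsv(path)
  counts <- switch(format,
    long = {
      .require_columns(df, c("protein_id", "assay_id", "count"), "long table")
      data.frame(protein_id = df$protein_id, assay_id = df$assay_id,
                 raw_count = df$count, stringsAsFactors = FALSE)
    },
    wide = {
      .require_columns(df, "protein_id", "wide table")
      assay_cols <- setdiff(names(df), "protein_id")
      if (length(assay_cols) == 0) {
        stop("wide table: no assay columns found", call. = FALSE)
      }
      data.frame(
        protein_id = rep(df$protein_id, times = length(assay_cols)),
        assay_id   = rep(assay_cols, each = nrow(df)),
        raw_count  = unlist(df[assay_cols], use.names = FALSE),
        stringsAsFactors = FALSE)
    },
    peptide = {
      .require_columns(df, c("peptide_id", "protein_id", "assay_id", "count"),
                       "peptide table")
      df$count <- .check_counts(df$count)
      agg <- stats::aggregate(count ~ protein_id + assay_id, data = df, FUN = sum)
      data.frame(protein_id = agg$protein_id, assay_id = agg$assay_id,
                 raw_count = agg$count, stringsAsFactors = FALSE)
    })
  counts$raw_count <- .check_counts(counts$raw_count, "raw_count")
  counts$protein_id <- .trim(counts$protein_id)
  counts$assay_id <- .trim(counts$assay_id)
  key <- paste(counts$protein_id, counts$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (protein_id, assay_id) pair(s) in ", format, " table",
         call. = FALSE)
  }
  if (is.null(lengths) || is.null(bait_id)) {
    return(counts)
  }
  if (is.character(lengths) && length(lengths) == 1L && is.null(names(lengths))) {
    lengths <- read_lengths(lengths)
  }
  count_table(counts, lengths, bait_id)
}

#' Read a protein-length table
#'
#' @param path two-column headed tab-separated file: `protein_id`, `length`
#'   (amino acids). Duplicate rows with conflicting lengths are rejected.
#' @return named integer vector of lengths.
#' @export
read_lengths <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("protein_id", "length"), "length table")
  ids <- .trim(df$protein_id)
  len <- suppressWarnings(as.numeric(df$length))
  if (anyNA(len) || any(len <= 0) || any(len != round(len))) {
    stop("length table: lengths must be whole numbers >= 1", call. = FALSE)
  }
  for (p in unique(ids[duplicated(ids)])) {
    if (length(unique(len[ids == p])) > 1L) {
      stop("length table: conflicting lengths for '", p, "'", call. = FALSE)
    }
  }
  keep <- !duplicated(ids)
  stats::setNames(as.integer(len[keep]), ids[keep])
}

#' Read a MaxQuant proteinGroups-style table as the wide dialect
#'
#' Maps the `Peptides <experiment>` columns of a proteinGroups export to one
#' wide-dialect assay column per experiment, with `Protein IDs` (first
#' semicolon-separated entry) as the protein identifier. Off the main path:
#' provided as a convenience for users whose counts live in a MaxQuant
#' output rather than a plain wide table.
#'
#' @param path proteinGroups-style tab-separated file.
#' @param id_column column holding protein identifiers
#'   (default `"Protein IDs"`).
#' @param peptide_prefix prefix of the per-experiment count columns
#'   (default `"Peptides "`).
#' @return long-format counts data.frame as from [read_count_table()].
#' @export
read_maxquant_groups <- function(path, id_column = "Protein IDs",
                                 peptide_prefix = "Peptides ") {
  df <- .read_tsv(path)
  .require_columns(df, id_column, "proteinGroups table")
  pep_cols <- grep(paste0("^", peptide_prefix), names(df), value = TRUE)
  if (length(pep_cols) == 0) {
    stop("proteinGroups table: no '", peptide_prefix, "<experiment>' columns",
         call. = FALSE)
  }
  ids <- vapply(strsplit(.trim(df[[id_column]]), ";", fixed = TRUE),
                `[`, character(1), 1L)
  counts <- data.frame(
    protein_id = rep(ids, times = length(pep_cols)),
    assay_id   = rep(sub(paste0("^", peptide_prefix), "", pep_cols),
                     each = nrow(df)),
    raw_count  = unlist(df[pep_cols], use.names = FALSE),
    stringsAsFactors = FALSE)
  counts$raw_count <- .check_counts(counts$raw_count, "raw_count")
  counts
}

#' Write a long-dialect count table
#'
#' Inverse of `read_count_table(..., format = "long")`: writing then reading
#' reproduces the (protein, assay, count) triples exactly.
#'
#' @param table a [count_table()] or long counts data.frame.
#' @param path output path.
#' @export
write_count_table <- function(table, path) {
  counts <- if (inherits(table, "count_table")) table$counts else table
  out <- data.frame(protein_id = counts$protein_id,
                    assay_id = counts$assay_id,
                    count = counts$raw_count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write interactor calls to a tab-separated file
#'
#' Rows are ordered by descending posterior, ties broken by descending total
#' raw count, then lexicographic protein identifier, so the top of the file
#' is always the strongest evidence of complex membership.
#'
#' @param calls data.frame of interactor calls as produced by [classify()];
#'   must be non-empty.
#' @param path output path.
#' @return invisibly, the ordered data.frame that was written.
#' @export
write_calls <- function(calls, path) {
  required <- c("protein_id", "total_raw_count", "mean_log2_score",
                "posterior", "is_interactor")
  .require_columns(calls, required, "calls table")
  if (nrow(calls) == 0) {
    stop("calls table is empty; nothing to write", call. = FALSE)
  }
  ord <- order(-calls$posterior, -calls$total_raw_count, calls$protein_id,
               method = "radix")
  out <- calls[ord, required, drop = FALSE]
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))
  out$mean_log2_score <- num(out$mean_log2_score)
  out$posterior <- num(out$posterior)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls[ord, , drop = FALSE])
}
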