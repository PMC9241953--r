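# Fixture builders shared across the suite. Everything is generated in code;
# powers of two are used where a test needs exact log2 values.

# small hand-sized count table: bait + preys with given per-assay counts
toy_table <- function(prey_counts, prey_lengths, bait_count = 64L,
                      bait_length = 256L, n_assays = 2L) {
  stopifnot(length(prey_counts) == length(prey_lengths))
  ids <- names(prey_counts)
  rows <- do.call(rbind, lapply(seq_len(n_assays), function(a) {
    data.frame(protein_id = c("BAIT", ids),
               assay_id = sprintf("assay%d", a),
               raw_count = c(bait_count, unname(prey_counts)),
               stringsAsFactors = FALSE)
  }))
  count_table(rows,
              c(BAIT = bait_length, prey_lengths),
              "BAIT")
}

# random valid count table for property tests
random_table <- function(seed, n_proteins = 8L, n_assays = 3L) {
  set.seed(seed)
  ids <- c("BAIT", sprintf("P%02d", seq_len(n_proteins - 1L)))
  rows <- do.call(rbind, lapply(seq_len(n_assays), function(a) {
    data.frame(protein_id = ids,
               assay_id = sprintf("assay%d", a),
               raw_count = c(sample(50:500, 1L),
                             rpois(n_proteins - 1L, 8)),
               stringsAsFactors = FALSE)
  }))
  lens <- stats::setNames(sample(100:3000, n_proteins), ids)
  count_table(rows, lens, "BAIT")
}

# hand-constructed mixture fit with known parameters
manual_fit <- function(weights, means, variances, n_obs = 100L) {
  structure(list(k = length(weights), weights = weights, means = means,
                 variances = variances, log_likelihood = 0,
                 n_obs = as.integer(n_obs), n_iter = 1L, converged = TRUE,
                 seed = 0L, ll_trace = 0),
            class = "gmm_fit")
}

# direct Bayes-rule posterior via unnormalized densities (the oracle the
# log-space implementation is checked against)
posterior_oracle <- function(weights, means, variances, x) {
  dens <- vapply(seq_along(weights), function(j) {
    weights[j] * stats::dnorm(x, means[j], sqrt(variances[j]))
  }, numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  dens / rowSums(dens)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
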