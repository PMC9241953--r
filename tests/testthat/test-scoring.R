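test_that("length normalization is element-wise division by protein length", {
  ct <- toy_table(c(P1 = 10L), c(P1 = 200L), bait_count = 100L,
                  bait_length = 200L, n_assays = 1L)
  ln <- length_normalize(ct)
  expect_equal(ln$value[ln$protein_id == "P1"], 0.05)

  # zero counts map to zero; random tables match brute force exactly
  for (seed in 1:4) {
    ct <- random_table(seed, n_proteins = 5L, n_assays = 3L)
    ln <- length_normalize(ct)
    for (i in seq_len(nrow(ln))) {
      row <- ct$counts[ct$counts$protein_id == ln$protein_id[i] &
                         ct$counts$assay_id == ln$assay_id[i], ]
      expect_identical(ln$value[i],
                       row$raw_count / as.numeric(ct$lengths[row$protein_id]))
    }
  }
})

test_that("bait normalization divides per assay and fixes the bait at 1", {
  values <- data.frame(
    protein_id = rep(c("BAIT", "P1"), 3),
    assay_id = rep(c("a1", "a2", "a3"), each = 2),
    value = c(0.5, 0.05, 0.25, 0.05, 1.0, 0.05))
  bn <- bait_normalize(values, "BAIT")
  expect_equal(bn$value[bn$protein_id == "BAIT"], c(1, 1, 1))
  # same raw prey value, assay-dependent result
  expect_equal(bn$value[bn$protein_id == "P1"],
               c(0.05 / 0.5, 0.05 / 0.25, 0.05 / 1.0))

  bad <- values
  bad$value[bad$protein_id == "BAIT" & bad$assay_id == "a2"] <- 0
  expect_error(bait_normalize(bad, "BAIT"), "positive")
})

test_that("per-assay count rescaling cancels only when the bait scales too", {
  for (seed in 1:3) {
    ct <- random_table(seed, n_proteins = 6L)
    bn0 <- bait_normalize(length_normalize(ct), "BAIT")
    # scale every count in assay1 (bait included) by 3: bait units unchanged
    scaled <- ct$counts
    idx <- scaled$assay_id == "assay1"
    scaled$raw_count[idx] <- scaled$raw_count[idx] * 3L
    ct2 <- count_table(scaled, ct$lengths, "BAIT")
    bn1 <- bait_normalize(length_normalize(ct2), "BAIT")
    expect_equal(bn1$value, bn0$value, tolerance = 1e-12)
    # scale only the preys: assay1 values change
    scaled2 <- ct$counts
    idx2 <- scaled2$assay_id == "assay1" & scaled2$protein_id != "BAIT"
    scaled2$raw_count[idx2] <- scaled2$raw_count[idx2] * 3L
    ct3 <- count_table(scaled2, ct$lengths, "BAIT")
    bn2 <- bait_normalize(length_normalize(ct3), "BAIT")
    changed <- bn2$assay_id == "assay1" & bn2$protein_id != "BAIT" &
      bn0$value > 0
    expect_false(any(bn2$value[changed] == bn0$value[changed]))
  }
})

test_that("merge_and_log2 pools assays, excludes bait and zeros, and keeps books", {
  # 5 preys + bait, 3 assays, no zeros
  ct <- toy_table(c(P1 = 8L, P2 = 4L, P3 = 2L, P4 = 16L, P5 = 1L),
                  c(P1 = 256L, P2 = 256L, P3 = 256L, P4 = 256L, P5 = 256L),
                  n_assays = 3L)
  bn <- bait_normalize(length_normalize(ct), "BAIT")
  obs <- merge_and_log2(bn, "BAIT")
  expect_identical(nrow(obs$entries), 15L)
  expect_identical(sum(obs$excluded$reason == "bait"), 3L)
  # powers of two: bait value 64/256 relative units, P2 = 4/64 = 2^-4
  expect_equal(unique(obs$entries$log2_value[obs$entries$protein_id == "P2"]),
               -4)

  # zero cells are excluded, with the bookkeeping identity holding exactly
  ct2 <- toy_table(c(P1 = 8L, P2 = 0L, P3 = 2L, P4 = 0L, P5 = 1L),
                   c(P1 = 256L, P2 = 256L, P3 = 256L, P4 = 256L, P5 = 256L),
                   n_assays = 2L)
  bn2 <- bait_normalize(length_normalize(ct2), "BAIT")
  obs2 <- merge_and_log2(bn2, "BAIT", min_obs = 1L)
  n_zero <- sum(ct2$counts$raw_count == 0 & ct2$counts$protein_id != "BAIT")
  expect_identical(sum(obs2$excluded$reason == "zero-count"), n_zero)
  expect_identical(nrow(obs2$entries),
                   (length(ct2$lengths) - 1L) * length(ct2$assays) - n_zero)

  expect_error(merge_and_log2(bn2, "BAIT", min_obs = 10L), "at least 10")
})

test_that("log2 of an exact quarter is exactly -2", {
  values <- data.frame(protein_id = c("BAIT", "P1"), assay_id = "a1",
                       value = c(1, 0.25))
  obs <- merge_and_log2(values, "BAIT", min_obs = 1L)
  expect_identical(obs$entries$log2_value, -2)
})

test_that("the dual-threshold call rule is exact, including boundaries", {
  # counts and lengths chosen so scores are exact powers-of-two log2 values
  # under bait value 64/256 per assay; fit fixed at the canonical two
  # components used throughout
  ct <- toy_table(
    c(P_HIGH = 32L,   # score -1: posterior > 0.5, total 64       -> TRUE
      P_MID = 16L,    # score -2: posterior exactly 0.5 (strict)  -> FALSE
      P_TINY = 2L,    # score +3 (length 1): posterior ~1, total 4 -> FALSE
      P_BG = 1L,      # score -6: posterior ~0                    -> FALSE
      P_ZERO = 0L,    # never detected: posterior 0               -> FALSE
      P_HIGH2 = 32L), # score +1 (length 64): posterior ~1        -> TRUE
    c(P_HIGH = 256L, P_MID = 256L, P_TINY = 1L, P_BG = 256L,
      P_ZERO = 256L, P_HIGH2 = 64L),
    n_assays = 2L)
  fit <- manual_fit(c(0.5, 0.5), c(-4, 0), c(1, 1))
  bn <- bait_normalize(length_normalize(ct), "BAIT")
  obs <- merge_and_log2(bn, "BAIT", min_obs = 1L)
  calls <- classify(obs, fit, ct)

  verdict <- stats::setNames(calls$is_interactor, calls$protein_id)
  expect_identical(verdict[["P_HIGH"]], TRUE)
  expect_identical(verdict[["P_HIGH2"]], TRUE)
  expect_identical(verdict[["P_MID"]], FALSE)   # posterior = 0.5 is not > 0.5
  expect_identical(verdict[["P_TINY"]], FALSE)  # total count 4 < 5
  expect_identical(verdict[["P_ZERO"]], FALSE)
  expect_identical(verdict[["P_BG"]], FALSE)

  mid <- calls[calls$protein_id == "P_MID", ]
  expect_identical(mid$posterior, 0.5)
  tiny <- calls[calls$protein_id == "P_TINY", ]
  expect_gt(tiny$posterior, 0.9)
  expect_identical(tiny$total_raw_count, 4L)
  zero <- calls[calls$protein_id == "P_ZERO", ]
  expect_identical(zero$posterior, 0)
  expect_true(is.na(zero$mean_log2_score))

  bait <- calls[calls$is_bait, ]
  expect_identical(bait$protein_id, "BAIT")
  expect_identical(bait$posterior, 1)
  expect_true(bait$is_interactor)

  unconverged <- fit
  unconverged$converged <- FALSE
  expect_error(classify(obs, unconverged, ct), "converge")
  expect_error(classify(obs, fit, ct, posterior_threshold = 1), "0, 1")
})

test_that("raising either threshold never turns a negative call positive", {
  truth <- simulate_pulldown(sim_config(n_background = 60L,
                                        n_interactors = 5L, seed = 4L))
  bn <- bait_normalize(length_normalize(truth$table), "BAIT")
  obs <- merge_and_log2(bn, "BAIT")
  fit <- fit_gmm(obs$entries$log2_value, k = 2)
  base <- classify(obs, fit, truth$table,
                   posterior_threshold = 0.3, count_threshold = 2L)
  for (pt in c(0.5, 0.7, 0.9)) {
    for (cth in c(2L, 5L, 10L)) {
      stricter <- classify(obs, fit, truth$table,
                           posterior_threshold = pt, count_threshold = cth)
      gained <- stricter$is_interactor & !base$is_interactor
      expect_false(any(gained[!stricter$is_bait]))
    }
  }
})

test_that("phase_sort applies the strict fold-change and padj filters", {
  de <- data.frame(
    transcript_id = sprintf("T%d", 1:7),
    log2_change = c(1.6, 1.5, -2.0, 4.0, -1.49, 2.5, 3.0),
    adjusted_p = c(0.01, 0.01, 0.05, 0.01, 0.01, 0.5, NA))
  ann <- data.frame(
    transcript_id = sprintf("T%d", 1:6),
    peak_phase = c("G1", "G1", "SMC", "NONCYCLICAL", "SMC", "G1"))
  # T1 passes into G1; T2 is exactly 1.5 (strict, excluded); T3 SMC;
  # T4 noncyclical; T5 below threshold; T6 fails padj; T7 NA padj dropped
  groups <- phase_sort(de, ann)
  expect_identical(groups$G1, "T1")
  expect_identical(groups$SMC, "T3")
  expect_identical(groups$NONCYCLICAL, "T4")

  # without the padj filter, T6 comes back and the unannotated T7
  # falls into NONCYCLICAL with a warning
  expect_warning(groups2 <- phase_sort(de, ann, padj_threshold = NULL),
                 "NONCYCLICAL")
  expect_setequal(groups2$G1, c("T1", "T6"))
  expect_setequal(groups2$NONCYCLICAL, c("T4", "T7"))
})

test_that("phase_sort partitions: groups disjoint, union equals retained set", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50L
    de <- data.frame(
      transcript_id = sprintf("T%03d", seq_len(n)),
      log2_change = runif(n, -4, 4),
      adjusted_p = runif(n))
    ann <- data.frame(
      transcript_id = sprintf("T%03d", seq_len(n)),
      peak_phase = sample(c("G1", "SMC", "NONCYCLICAL"), n, replace = TRUE))
    groups <- phase_sort(de, ann, lfc_threshold = 1.5, padj_threshold = 0.5)
    all_ids <- unlist(groups, use.names = FALSE)
    expect_identical(anyDuplicated(all_ids), 0L)
    expected <- de$transcript_id[abs(de$log2_change) > 1.5 &
                                   de$adjusted_p <= 0.5]
    expect_setequal(all_ids, expected)
  }
})

test_that("phase_sort rejects malformed annotations", {
  de <- data.frame(transcript_id = "T1", log2_change = 2, adjusted_p = 0.01)
  expect_error(phase_sort(de, data.frame(transcript_id = c("T1", "T1"),
                                         peak_phase = c("G1", "SMC"))),
               "more than one")
  expect_error(phase_sort(de, data.frame(transcript_id = "T1",
                                         peak_phase = "G2")),
               "peak_phase")
  de$adjusted_p <- 1.5
  expect_error(phase_sort(de, data.frame(transcript_id = "T1",
                                         peak_phase = "G1")),
               "adjusted_p")
})
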