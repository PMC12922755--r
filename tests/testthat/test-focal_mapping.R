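test_that("gain fraction profile equals hand-tabulated overlap counts", {
  bins <- toy_bins()
  qT <- which(!is.na(bins$arm) & bins$arm == "Tq")  # 15 bins
  arms <- arm_table(toy_build())

  # one partial-gain sample covering the first half of the arm
  half <- toy_matrix(list(s1 = toy_calls(bins, gain_rows = qT[1:7])))
  ac <- call_arms(half, arms, min_run = 6)
  prof <- gain_fraction_profile(half, ac, "Tq", "partial_only")
  expect_equal(prof$fraction, c(rep(1, 7), rep(0, 8)))
  expect_equal(attr(prof, "n_samples"), 1)

  # 4 samples with hand-chosen segments; fractions = overlap counts / 4
  segs <- list(a = qT[2:8], b = qT[4:10], c = qT[4:12], d = qT[9:14])
  mat <- toy_matrix(lapply(segs, function(r)
    toy_calls(bins, gain_rows = r)))
  ac4 <- call_arms(mat, arms, min_run = 6)
  prof4 <- gain_fraction_profile(mat, ac4, "Tq", "partial_only")
  hand <- vapply(qT, function(b)
    sum(vapply(segs, function(r) b %in% r, TRUE)) / 4, numeric(1))
  expect_equal(prof4$fraction, hand)

  # full-arm-only cohort: any_gain profile identically 1, partial_only
  # has an empty denominator
  full <- toy_matrix(list(f1 = toy_calls(bins, gain_rows = qT),
                          f2 = toy_calls(bins, gain_rows = qT)))
  acf <- call_arms(full, arms)
  expect_equal(
    gain_fraction_profile(full, acf, "Tq", "any_gain")$fraction,
    rep(1, 15))
  expect_error(gain_fraction_profile(full, acf, "Tq", "partial_only"),
               "empty denominator")
})

test_that("detect_peaks finds plateaus, merges gaps, handles edge cases", {
  mk_prof <- function(f) {
    out <- data.frame(chrom = rep("chrT", length(f)),
                      start = (seq_along(f) - 1) * 5e5 + 1,
                      end = seq_along(f) * 5e5, bin = seq_along(f),
                      fraction = f)
    class(out) <- c("gain_fraction_profile", "data.frame")
    out
  }
  # strictly unimodal: one peak containing the argmax
  uni <- mk_prof(c(0.1, 0.2, 0.5, 0.9, 0.5, 0.2))
  p <- detect_peaks(uni)
  expect_equal(nrow(p), 1)
  expect_true(p$first_bin <= 4 && p$last_bin >= 4)

  # two separated plateaus of comparable height -> two peaks, each
  # containing one anchor
  two <- mk_prof(c(0.1, 0.9, 0.9, 0.2, 0.1, 0.1, 0.1, 0.88, 0.88, 0.1))
  p2 <- detect_peaks(two, rel_tol = 0.05, merge_gap_bins = 3)
  expect_equal(nrow(p2), 2)
  expect_true(p2$first_bin[1] <= 2 && p2$last_bin[1] >= 3)
  expect_true(p2$first_bin[2] <= 8 && p2$last_bin[2] >= 9)
  # ... but merged into one when the gap allows
  p2m <- detect_peaks(two, rel_tol = 0.05, merge_gap_bins = 6)
  expect_equal(nrow(p2m), 1)

  # flat nonzero profile: one peak spanning the whole arm
  flat <- mk_prof(rep(0.4, 8))
  pf <- detect_peaks(flat)
  expect_equal(nrow(pf), 1)
  expect_equal(pf$n_bins, 8)

  # all-zero profile: empty result
  expect_equal(nrow(detect_peaks(mk_prof(rep(0, 5)))), 0)
  # peaks always contain the global argmax
  set.seed(60)
  for (i in 1:50) {
    f <- round(runif(30), 2)
    pk <- detect_peaks(mk_prof(f))
    am <- which.max(f)
    expect_true(any(pk$first_bin <= am & pk$last_bin >= am))
  }
  expect_error(detect_peaks(mk_prof(numeric(0))), "empty")
})

test_that("locus inclusion follows the strict-majority rule", {
  bins <- toy_bins()
  # 3-bin locus on chrT q arm
  locus <- list(chrom = "chrT", start = 3000001, end = 4500000)
  idx <- overlapping_bins(locus, bins)
  expect_length(idx, 3)

  all_g <- toy_calls(bins, gain_rows = idx)
  expect_true(locus_included(all_g, locus, bins)$included)
  one_g <- toy_calls(bins, gain_rows = idx[1])
  expect_false(locus_included(one_g, locus, bins)$included)
  two_g <- toy_calls(bins, gain_rows = idx[1:2])
  expect_true(locus_included(two_g, locus, bins)$included)   # 2/3 majority
  expect_false(locus_included(two_g, locus, bins,
                              rule = "all")$included)

  # single-bin locus
  single <- list(chrom = "chrT", start = 3100000, end = 3200000)
  sidx <- overlapping_bins(single, bins)
  expect_length(sidx, 1)
  expect_true(locus_included(toy_calls(bins, gain_rows = sidx), single,
                             bins)$included)

  # monotonicity: converting any overlapping bin N->G never flips
  # included TRUE -> FALSE
  set.seed(61)
  for (i in 1:100) {
    v <- toy_calls(bins, gain_rows = sample(idx, sample(0:3, 1)))
    before <- locus_included(v, locus, bins)$included
    flip <- setdiff(idx, which(v == "G"))
    if (!length(flip)) next
    v[sample(flip, 1)] <- "G"
    after <- locus_included(v, locus, bins)$included
    if (before) expect_true(after)
  }
})

test_that("joint classification counts the four locus categories", {
  bins <- toy_bins()
  arms <- arm_table(toy_build())
  qT <- which(!is.na(bins$arm) & bins$arm == "Tq")
  lA <- list(chrom = "chrT", start = 3000001, end = 3500000)  # bin qT[2]
  lB <- list(chrom = "chrT", start = 8000001, end = 8500000)  # bin qT[12]
  iA <- overlapping_bins(lA, bins)
  iB <- overlapping_bins(lB, bins)
  samples <- list(
    both1 = toy_calls(bins, gain_rows = qT),                 # full arm
    both2 = toy_calls(bins, gain_rows = qT[1:13]),           # covers A+B
    aonly = toy_calls(bins, gain_rows = qT[1:7]),
    bonly = toy_calls(bins, gain_rows = qT[8:14]),
    none  = toy_calls(bins, gain_rows = qT[4:10]))
  mat <- toy_matrix(samples)
  ac <- call_arms(mat, arms, min_run = 6)
  counts <- joint_locus_classification(mat, ac, "Tq", lA, lB)
  expect_equal(counts, c(both = 2L, A_only = 1L, B_only = 1L,
                         neither = 1L))
  expect_equal(sum(counts),
               sum(ac$arm == "Tq" & ac$state == "GAIN"))

  # full-arm-only cohort: everything in "both"
  full <- toy_matrix(list(x = toy_calls(bins, gain_rows = qT)))
  acf <- call_arms(full, arms)
  expect_equal(joint_locus_classification(full, acf, "Tq", lA, lB),
               c(both = 1L, A_only = 0L, B_only = 0L, neither = 0L))
})

test_that("dosage association flags degenerate genes and is calibrated", {
  set.seed(62)
  n <- 50
  cn <- rbind(g1 = sample(2:4, n, replace = TRUE),
              g2 = sample(2:4, n, replace = TRUE),
              g3 = rep(2, n))
  expr <- rbind(g1 = cn["g1", ],                       # perfect correlation
                g2 = rnorm(n),                          # pure noise
                g3 = rnorm(n))                          # zero-variance cn
  res <- dosage_expression_association(cn, expr, alpha = 1e-5)
  expect_true(res$significant[res$gene == "g1"])
  expect_lt(res$p[res$gene == "g1"], 1e-20)
  expect_false(res$significant[res$gene == "g2"])
  expect_true(res$flagged[res$gene == "g3"])
  expect_true(is.na(res$p[res$gene == "g3"]))

  # permuted labels: null calibration at alpha 0.05 over replicated genes
  set.seed(63)
  cnp <- matrix(sample(2:4, 200 * 60, replace = TRUE), nrow = 200)
  exprp <- cnp + matrix(rnorm(200 * 60, 0, 0.5), nrow = 200)
  exprp <- exprp[, sample.int(60)]  # break the pairing
  resp <- dosage_expression_association(cnp, exprp, alpha = 0.05)
  expect_lt(mean(resp$significant), 0.12)
  # spearman alternative exposed
  ress <- dosage_expression_association(cn[1:2, ], expr[1:2, ],
                                        method = "spearman")
  expect_true(ress$significant[1])
})
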