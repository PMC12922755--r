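build <- hg19_build()
arms <- arm_table(build)

test_that("NORMAL karyotypes are always copy-neutral", {
  cfg <- cohort_config(seed = 1)
  set.seed(5)
  for (i in 1:10) {
    k <- simulate_karyotype("NORMAL", cfg, build)
    expect_equal(nrow(k$events), 0)
    expect_equal(unique(k$segments$copies), 2)
  }
  expect_error(simulate_karyotype("BAD_GRADE", cfg, build),
               "unknown grade")
})

test_that("forced focal 1q gains always contain the configured anchor", {
  probs <- data.frame(grade = "PDAC", arm = "1q", state = "GAIN",
                      prob = 1, stringsAsFactors = FALSE)
  cfg <- cohort_config(
    arm_event_probs = probs, focal_prob = c("1q" = 1),
    focal_joint_probs = c(both = 0, A_only = 1, B_only = 0, neither = 0),
    wgd_prob = c(PDAC = 0))
  loci <- pancarm_loci()
  A <- loci[loci$name == "1q23.2", ]
  set.seed(9)
  for (i in 1:25) {
    k <- simulate_karyotype("PDAC", cfg, build)
    expect_equal(nrow(k$truth$focal), 1)
    expect_true(k$truth$focal$start <= A$start &&
                  k$truth$focal$end >= A$end)
    # every bp of the anchor is at 3 copies
    expect_true(all(copies_at(k, "chr1",
                              seq(A$start, A$end, by = 1e5)) == 3))
  }
})

test_that("arm-event frequency matches the configured probability", {
  cfg <- cohort_config(seed = 1)
  set.seed(1234)
  draws <- vapply(1:2000, function(i) {
    k <- simulate_karyotype("PDAC", cfg, build)
    any(k$truth$arm_events$arm == "1q" &
          k$truth$arm_events$state == "GAIN")
  }, TRUE)
  p <- 0.40
  se <- sqrt(p * (1 - p) / 2000)
  expect_lt(abs(mean(draws) - p), 3 * se)
})

test_that("render_bin_profile discretizes correctly", {
  bins <- assign_bins_to_arms(make_bins(build), arms)
  cfg <- cohort_config()
  set.seed(2)
  dip <- simulate_karyotype("NORMAL", cfg, build)

  prof <- render_bin_profile(dip, bins, purity = 1, noise_sd = 0)
  expect_true(all(prof$call == "N"))

  # uniform tetraploid is blind under median normalization
  wgd <- dip
  wgd$base_ploidy <- 4L
  wgd$segments <- karyotype_segments(wgd)
  prof_wgd <- render_bin_profile(wgd, bins, purity = 1, noise_sd = 0)
  expect_true(all(prof_wgd$call == "N"))
  # ... but visible without normalization
  prof_raw <- render_bin_profile(wgd, bins, purity = 1, noise_sd = 0,
                                 normalization = "none")
  expect_true(all(prof_raw$call == "G"))

  # one arm at 3 copies, purity 1: that arm G, log-ratio log2(1.5)
  tri <- dip
  q1 <- arms[arms$arm == "1q", ]
  tri$events <- data.frame(chrom = "chr1", start = q1$start, end = q1$end,
                           delta = 1L, arm = "1q",
                           stringsAsFactors = FALSE)
  tri$segments <- karyotype_segments(tri)
  prof3 <- render_bin_profile(tri, bins, purity = 1, noise_sd = 0)
  on_arm <- !is.na(bins$arm) & bins$arm == "1q"
  # the centromere-straddling chr1 bin has its midpoint inside the gained
  # q segment, so it is G too; it belongs to no arm and is never reported
  cen_bin <- bins$chrom == "chr1" & is.na(bins$arm)
  expect_true(all(prof3$call[on_arm] == "G"))
  expect_true(all(prof3$call[!on_arm & !cen_bin] == "N"))
  expect_equal(unique(prof3$log_ratio[on_arm]), log2(1.5),
               tolerance = 1e-12)
})

test_that("simulate_fish_counts follows the binomial detection model", {
  cfg <- cohort_config()
  set.seed(3)
  dip <- simulate_karyotype("NORMAL", cfg, build)
  probe <- list(chrom = "chr1", start = 179068462, end = 179112224)

  expect_true(all(simulate_fish_counts(dip, probe, 50, p_detect = 1) == 2))
  # diploid counts can never reach 3
  c900 <- simulate_fish_counts(dip, probe, 900, p_detect = 0.9)
  expect_equal(mean(c900 >= 3), 0)

  wgd <- dip; wgd$base_ploidy <- 4L
  wgd$segments <- karyotype_segments(wgd)
  c4 <- simulate_fish_counts(wgd, probe, 10000, p_detect = 0.9)
  se <- sqrt(4 * 0.9 * 0.1 / 10000)
  expect_lt(abs(mean(c4) - 3.6), 3 * se)

  expect_error(simulate_fish_counts(dip, list(chrom = "chrZ", start = 1,
                                              end = 2), 50),
               "not covered")
})

test_that("simulate_expression plants recoverable dosage response", {
  set.seed(4)
  n <- 200
  cn <- matrix(2, nrow = 20, ncol = n,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
  gained <- sample.int(n, 80)  # 40% gains
  cn[1:10, gained] <- 3
  responsive <- rep(c(TRUE, FALSE), each = 10)
  sim <- simulate_expression(cn, responsive, effect_size = 2,
                             noise_sd = 0.1)
  res <- dosage_expression_association(cn, sim$expr, alpha = 1e-5)
  # responsive genes with varying copy number all significant
  expect_true(all(res$significant[1:10]))
  # non-responsive genes: constant-cn genes flagged, none significant
  expect_false(any(res$significant[11:20]))

  # effect 0: null p-values roughly uniform
  sim0 <- simulate_expression(cn, rep(FALSE, 20), effect_size = 0,
                              noise_sd = 1)
  res0 <- dosage_expression_association(cn[1:10, ], sim0$expr[1:10, ],
                                        alpha = 1e-5)
  expect_false(any(res0$significant))
  expect_error(
    dosage_expression_association(cn[, 1, drop = FALSE],
                                  sim$expr[, 1, drop = FALSE]),
    ">= 3 samples")
})

test_that("duplex read simulation round-trips UIDs, strands and variants", {
  amp <- toy_amplicon()
  set.seed(6)
  sim <- simulate_duplex_reads(amp, n_templates = 10, per_base_error = 0)
  ex <- extract_uid(sim$reads$seq)
  expect_equal(ex$uid, sim$reads$uid)
  strands <- vapply(ex$insert, assign_strand, "", ref_seq = amp$ref_seq,
                    USE.NAMES = FALSE)
  expect_equal(strands, sim$reads$strand_truth)
  expect_equal(length(unique(sim$reads$uid)), 10)

  # planted variant propagates to exactly the carrier templates
  tv <- data.frame(offset = amp$hotspot_offset, alt = amp$hotspot_alt,
                   fraction = 0.25)
  sim2 <- simulate_duplex_reads(amp, n_templates = 20, true_variants = tv,
                                per_base_error = 0)
  groups <- build_duplex_groups(sim2$reads, amp)
  supported <- vapply(groups, function(g)
    call_duplex_variant(g, amp$hotspot_offset,
                        amp$hotspot_ref)$supported, TRUE)
  carrier_uids <- sim2$truth$uid[sim2$truth[[2]]]
  expect_setequal(vapply(groups, `[[`, "", "uid")[supported],
                  carrier_uids)

  expect_error(
    simulate_duplex_reads(amp, 5,
                          data.frame(offset = 500, alt = "A",
                                     fraction = 1)),
    "outside amplicon")
})

test_that("simulate_cohort is byte-identical under the same seed", {
  cfg <- cohort_config(n_per_grade = c(NORMAL = 2, HG_PANIN = 3, PDAC = 4),
                       seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg, include_duplex = TRUE, n_fish = 2), d1)
  write_cohort(simulate_cohort(cfg, include_duplex = TRUE, n_fish = 2), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 4)
  expect_equal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 10e6),
                     readBin(file.path(d2, f), "raw", 10e6),
                     label = f)
})

test_that("empty cohort yields schema-valid outputs", {
  cfg <- cohort_config(n_per_grade = c(PDAC = 0), seed = 1)
  co <- simulate_cohort(cfg, include_duplex = TRUE, n_fish = 0)
  expect_equal(ncol(co$bin_calls$calls), 0)
  expect_equal(nrow(co$meta), 0)
  expect_equal(nrow(co$truth$per_sample), 0)
})

test_that("pure WGD reproduces the WGS/FISH discordance mechanism", {
  cfg <- cohort_config()
  set.seed(8)
  k <- simulate_karyotype("NORMAL", cfg, build, sample_id = "WGD1")
  k$base_ploidy <- 4L
  k$truth$wgd <- TRUE
  k$segments <- karyotype_segments(k)
  bins <- assign_bins_to_arms(make_bins(build), arms)
  prof <- render_bin_profile(k, bins, purity = 1, noise_sd = 0.05)
  expect_true(mean(prof$call == "N") > 0.99)  # relative calls blind
  probe <- list(chrom = "chr1", start = 179068462, end = 179112224)
  counts <- simulate_fish_counts(k, probe, 100, p_detect = 1)
  expect_equal(unique(counts), 4)             # FISH sees absolute copies
  s <- fish_summary(counts)
  expect_true(classify_positive(s, "ge3_at_20pct"))
  arm_state <- call_arm(prof$call[!is.na(bins$arm) & bins$arm == "1q"])
  expect_equal(wgs_fish_concordance(arm_state$state, TRUE,
                                    tumor_fraction = 0.8),
               "discordant_relative_cn")
})
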