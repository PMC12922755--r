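amp <- toy_amplicon()
cosmic <- toy_cosmic(amp)

test_that("extract_uid takes the first 14 bases and enforces length", {
  r <- extract_uid("ACGTACGTACGTACGGG")
  expect_equal(r$uid, "ACGTACGTACGTAC")
  expect_equal(r$insert, "GGG")
  expect_error(extract_uid("ACGTACGTACGTAC"), "shorter")
})

test_that("assign_strand is deterministic and orientation-driven", {
  ref <- amp$ref_seq
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(ref, "")[[1]]), collapse = ""))
  expect_equal(assign_strand(ref, ref), "WATSON")
  expect_equal(assign_strand(rc, ref), "CRICK")
  # a couple of errors do not flip the assignment
  mut <- ref
  substr(mut, 5, 6) <- "TT"
  expect_equal(assign_strand(mut, ref), "WATSON")
})

test_that("build_duplex_groups groups by UID and strand", {
  uid <- paste(rep("A", 14), collapse = "")
  ref <- amp$ref_seq
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(ref, "")[[1]]), collapse = ""))
  # same uid, opposite strands: one group, both families
  reads <- data.frame(seq = paste0(uid, c(ref, rc)),
                      amplicon_id = amp$amplicon_id,
                      stringsAsFactors = FALSE)
  g <- build_duplex_groups(reads, amp)
  expect_length(g, 1)
  expect_false(is.null(g[[1]]$watson))
  expect_false(is.null(g[[1]]$crick))

  # same uid, same strand: one group, one family of 2 reads
  reads2 <- data.frame(seq = paste0(uid, c(ref, ref)),
                       amplicon_id = amp$amplicon_id,
                       stringsAsFactors = FALSE)
  g2 <- build_duplex_groups(reads2, amp)
  expect_length(g2, 1)
  expect_equal(g2[[1]]$watson$n_reads, 2)
  expect_null(g2[[1]]$crick)

  # n templates -> n groups, permutation-invariant
  set.seed(50)
  sim <- simulate_duplex_reads(amp, 15, per_base_error = 0)
  g3 <- build_duplex_groups(sim$reads, amp)
  expect_length(g3, 15)
  shuffled <- sim$reads[sample.int(nrow(sim$reads)), ]
  g4 <- build_duplex_groups(shuffled, amp)
  expect_equal(vapply(g3, `[[`, "", "uid"), vapply(g4, `[[`, "", "uid"))
})

test_that("duplex support requires >80% on both strands, strictly", {
  mk_family <- function(n_alt, n_total, pos, ref, alt, L) {
    seqs <- rep(paste(rep(ref, L), collapse = ""), n_total)
    # single-base amplicon logic: build tally directly
    tally <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    tally[ref, ] <- n_total
    tally[ref, pos] <- n_total - n_alt
    tally[alt, pos] <- n_alt
    list(n_reads = n_total, tally = tally)
  }
  g <- list(uid = "U", amplicon_id = "a",
            watson = mk_family(9, 10, 5, "A", "T", 20),
            crick = mk_family(5, 6, 5, "A", "T", 20))
  expect_true(call_duplex_variant(g, 5, "A")$supported)   # 0.9 and 0.833
  g$watson <- mk_family(8, 10, 5, "A", "T", 20)           # exactly 0.8
  expect_false(call_duplex_variant(g, 5, "A")$supported)
  g$watson <- mk_family(10, 10, 5, "A", "T", 20)
  g$crick <- NULL                                          # Watson-only
  expect_false(call_duplex_variant(g, 5, "A")$supported)
})

test_that("filters enforce the template, coverage, end and catalog rules", {
  cand <- data.frame(amplicon_id = amp$amplicon_id, offset = 50L,
                     chrom = amp$chrom, pos = amp$start + 49L,
                     ref = amp$hotspot_ref, alt = amp$hotspot_alt,
                     mutant_templates = 3L, total_templates = 5L,
                     stringsAsFactors = FALSE)
  # all boundaries inclusive where worded "at least", strict where "more
  # than": 3 groups / coverage 5 / offset 50 in a 100-bp amplicon passes
  r <- apply_filters(cand, cosmic, amp)
  expect_true(r$pass)
  expect_equal(r$filters, "")

  r2 <- apply_filters(transform(cand, mutant_templates = 2L), cosmic, amp)
  expect_false(r2$pass)
  expect_match(r2$filters, "min_mut_templates")

  r3 <- apply_filters(transform(cand, total_templates = 4L), cosmic, amp)
  expect_match(r3$filters, "coverage")

  # 30-bp end rule: offset 30 is 29 bp from the start -> fail; 31 passes
  r4 <- apply_filters(transform(cand, offset = 30L, pos = amp$start + 29L),
                      cosmic, amp)
  expect_match(r4$filters, "end_distance")
  expect_match(r4$filters, "cosmic")  # moved off the hotspot
  r5 <- apply_filters(transform(cand, offset = 31L, pos = amp$start + 30L),
                      cosmic, amp)
  expect_false(grepl("end_distance", r5$filters))
  # offset 70 in a 100-bp amplicon is 30 bp from the far end -> pass
  r6 <- apply_filters(transform(cand, offset = 70L, pos = amp$start + 69L),
                      cosmic, amp)
  expect_false(grepl("end_distance", r6$filters))
  r7 <- apply_filters(transform(cand, offset = 71L, pos = amp$start + 70L),
                      cosmic, amp)
  expect_match(r7$filters, "end_distance")

  # catalog: a singleton annotation or unconfirmed entry fails
  weak <- cosmic; weak$annotation_count <- 1L
  expect_match(apply_filters(cand, weak, amp)$filters, "cosmic")
  uncon <- cosmic; uncon$confirmed_somatic <- FALSE
  expect_match(apply_filters(cand, uncon, amp)$filters, "cosmic")
})

test_that("KRAS assessability threshold is >= 10 template molecules", {
  set.seed(51)
  mk <- function(n) build_duplex_groups(
    simulate_duplex_reads(amp, n, per_base_error = 0)$reads, amp)
  expect_true(sample_assessable(mk(10), amp))
  expect_false(sample_assessable(mk(9), amp))
  expect_false(sample_assessable(list(), amp))
})

test_that("planted clonal variants with >=3 carriers are always called", {
  tv <- data.frame(offset = amp$hotspot_offset, alt = amp$hotspot_alt,
                   fraction = 0.5)
  set.seed(52)
  for (i in 1:20) {
    sim <- simulate_duplex_reads(amp, 20, true_variants = tv,
                                 per_base_error = 0)
    n_carriers <- sum(sim$truth[[2]])
    res <- duplex_call_sample(sim$reads, amp, cosmic)
    if (n_carriers >= 3) {
      expect_equal(nrow(res$calls), 1)
      expect_equal(res$calls$pos, cosmic$pos[1])
      expect_equal(res$calls$alt, cosmic$alt[1])
      expect_equal(res$calls$mutant_templates, n_carriers)
    } else {
      expect_equal(nrow(res$calls), 0)
    }
  }
})

test_that("FASTQ round trip preserves reads", {
  set.seed(53)
  sim <- simulate_duplex_reads(amp, 5, per_base_error = 1e-3)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_duplex_fastq(sim$reads, path)
  back <- read_duplex_fastq(path)
  expect_equal(back$seq, sim$reads$seq)
  expect_equal(back$amplicon_id, sim$reads$amplicon_id)
  res <- duplex_call_sample(path, amp, cosmic)
  expect_true(is.data.frame(res$candidates))
})

test_that("lesion_mutation_table cross-tabulates against 1q gain", {
  # synthetic end-to-end: cohort with planted mutations
  cfg <- cohort_config(
    n_per_grade = c(HG_PANIN = 12, LG_IPMN = 12), seed = 99, noise_sd = 0,
    purity = list(HG_PANIN = c(1, 1), LG_IPMN = c(1, 1)),
    # clonal fractions so every planted variant has >= 3 carrier templates
    # (exact-recovery contract; sub-clonal sensitivity is covered in the
    # carrier-conditioned recall test)
    duplex = list(n_templates = 25, reads_per_strand_p = 0.4,
                  per_base_error = 1e-3, uid_length = 14L,
                  variant_fraction = c(0.5, 0.8)))
  co <- simulate_cohort(cfg, include_duplex = TRUE, n_fish = 0)
  panel <- synthetic_amplicon_panel()
  lookup <- synthetic_cosmic_lookup(panel)
  calls <- lapply(co$duplex, function(d)
    duplex_call_sample(d$reads, panel, lookup))
  # every planted gene set is recovered exactly (error 1e-3, clonal-ish
  # fractions, >=3-template filter)
  for (s in names(calls)) {
    expect_setequal(calls[[s]]$genes, co$duplex[[s]]$planted_genes)
    expect_true(calls[[s]]$assessable)
  }
  ac <- call_arms(co$bin_calls, arm_table(hg19_build()))
  mt <- lesion_mutation_table(calls, ac, co$meta)
  # all samples carry KRAS or GNAS (initiator planted in 100%)
  init <- intersect(c("KRAS", "GNAS"), colnames(mt$gene_status))
  expect_true(all(apply(mt$gene_status[, init, drop = FALSE], 1, any)))
  expect_equal(sum(mt$crosstab), length(calls))
  # cross-tab matches the truth table exactly
  truth_ts <- vapply(names(calls), function(s)
    any(c("CDKN2A", "TP53", "SMAD4") %in% co$duplex[[s]]$planted_genes),
    TRUE)
  truth_1q <- co$truth$per_sample$gain_1q[
    match(names(calls), co$truth$per_sample$sample_id)]
  expect_equal(mt$crosstab["1q_gain", "ts_mut"],
               sum(truth_1q & truth_ts))
  expect_equal(mt$crosstab["no_1q_gain", "no_ts_mut"],
               sum(!truth_1q & !truth_ts))
  # unknown sample triggers a warning and exclusion
  expect_warning(
    lesion_mutation_table(stats::setNames(calls[1], "GHOST"), ac, co$meta),
    "absent from metadata")
})
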