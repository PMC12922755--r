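#' End-to-end pipeline orchestration
#'
#' Runs simulate -> QC -> arm calls -> localization -> co-occurrence
#' statistics -> FISH scoring -> duplex calling and assembles a cohort
#' report. Every threshold is a named config key with its documented
#' default; the seed is recorded in the report so every number is
#' regenerable.
#'
#' @name cli-pipeline
NULL

#' Pipeline run configuration
#'
#' @param cohort a `cohort_config` for simulation, or NULL when reading
#'   real inputs via `inputs`.
#' @param inputs named list of file paths (`bins`, `meta`, `qc`, `fish`,
#'   `fastq_dir`, `amplicons`, `cosmic`) when not simulating.
#' @param min_run minimum consecutive gained/lost bins for an arm event
#'   (default 6 bins = 3 Mb).
#' @param mad_max sample QC MAD cutoff (default 0.15, strict <).
#' @param variance_ratio_max QC variance-ratio flag threshold (default 2).
#' @param rel_tol,merge_gap_bins peak detection parameters.
#' @param purity_min cellularity cutoff for discordance attribution.
#' @param alpha dosage-expression significance threshold (default 1e-5).
#' @param fish_rule positivity rule (default "ge3_at_20pct").
#' @param seed run seed (also forwarded to the simulator).
#' @param out_dir output directory or NULL to skip writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), inputs = NULL,
                       min_run = 6L, mad_max = 0.15,
                       variance_ratio_max = 2, rel_tol = 0.02,
                       merge_gap_bins = 4, purity_min = 0.2, alpha = 1e-5,
                       fish_rule = "ge3_at_20pct", seed = 1L,
                       out_dir = NULL) {
  if (!is.null(cohort)) cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, inputs = inputs, min_run = min_run,
                 mad_max = mad_max,
                 variance_ratio_max = variance_ratio_max,
                 rel_tol = rel_tol, merge_gap_bins = merge_gap_bins,
                 purity_min = purity_min, alpha = alpha,
                 fish_rule = fish_rule, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' @param config a `run_config`.
#' @param build genome build.
#' @param include_duplex run the duplex-calling stage (default TRUE when
#'   reads are available).
#' @return list of class `cohort_report`: per-grade arm frequency tables,
#'   full/partial breakdowns, peak regions, joint-locus counts, context
#'   fractions with Fisher p, FISH summaries, mutation cross-tab, and
#'   provenance.
#' @export
run_pipeline <- function(config, build = hg19_build(),
                         include_duplex = TRUE) {
  stopifnot(inherits(config, "run_config"))
  stage <- "simulate/ingest"
  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("pancarm")),
    seed = config$seed,
    thresholds = config[c("min_run", "mad_max", "variance_ratio_max",
                          "rel_tol", "merge_gap_bins", "purity_min",
                          "alpha", "fish_rule")]))
  res <- tryCatch({
    if (!is.null(config$cohort)) {
      cohort <- simulate_cohort(config$cohort, build,
                                include_duplex = include_duplex)
    } else {
      bins <- assign_bins_to_arms(make_bins(build), arm_table(build))
      cohort <- list(
        bin_calls = read_bin_call_matrix(config$inputs$bins, bins),
        meta = read_lesion_meta(config$inputs$meta),
        qc = if (!is.null(config$inputs$qc))
          utils::read.delim(config$inputs$qc) else NULL,
        fish = if (!is.null(config$inputs$fish))
          read_fish_table(config$inputs$fish) else NULL,
        duplex = NULL)
    }
    stage <- "qc"
    kept <- cohort$bin_calls$samples
    qc_table <- NULL
    if (!is.null(cohort$qc)) {
      qc_res <- lapply(seq_len(nrow(cohort$qc)), function(i)
        qc_sample(cohort$qc$mad[i], cohort$qc$observed_variance[i],
                  cohort$qc$expected_variance[i], config$mad_max,
                  config$variance_ratio_max))
      qc_table <- data.frame(
        sample_id = cohort$qc$sample_id,
        keep = vapply(qc_res, `[[`, TRUE, "keep"),
        flags = vapply(qc_res, function(r) paste(r$flags, collapse = ";"),
                       ""),
        stringsAsFactors = FALSE)
      kept <- intersect(kept, qc_table$sample_id[qc_table$keep])
    }
    stage <- "arm_calls"
    arms <- arm_table(build)
    mat <- cohort$bin_calls
    keep_idx <- match(kept, mat$samples)
    mat <- bin_call_matrix(mat$bins,
                           mat$calls[, keep_idx, drop = FALSE])
    arm_calls <- call_arms(mat, arms, config$min_run)
    stage <- "frequencies"
    grades_present <- intersect(pancarm_grades(), unique(cohort$meta$grade))
    freq_by_grade <- lapply(grades_present, function(g)
      cohort_arm_frequencies(arm_calls, cohort$meta, grades = g))
    names(freq_by_grade) <- grades_present
    breakdown_1q <- full_vs_partial_breakdown(arm_calls, "1q")
    breakdown_8q <- full_vs_partial_breakdown(arm_calls, "8q")
    stage <- "localization"
    peaks_1q <- NULL
    joint_1q <- NULL
    loci <- pancarm_loci()
    has_partial_1q <- breakdown_1q$n_partial > 0
    if (has_partial_1q) {
      prof <- gain_fraction_profile(mat, arm_calls, "1q", "partial_only")
      peaks_1q <- detect_peaks(prof, config$rel_tol,
                               config$merge_gap_bins)
      joint_1q <- joint_locus_classification(
        mat, arm_calls, "1q", loci[loci$name == "1q23.2", ],
        loci[loci$name == "1q42.13", ])
    }
    stage <- "cooccurrence"
    context <- tryCatch(
      context_fraction(arm_calls, meta = cohort$meta,
                       grades = grades_present),
      error = function(e) NULL)
    stage <- "fish"
    fish_summaries <- if (!is.null(cohort$fish))
      summarize_fish_table(cohort$fish, config$fish_rule) else NULL
    stage <- "duplex"
    mutation <- NULL
    if (include_duplex && !is.null(cohort$duplex)) {
      panel <- synthetic_amplicon_panel()
      cosmic <- synthetic_cosmic_lookup(panel)
      calls_by_sample <- lapply(cohort$duplex, function(d)
        duplex_call_sample(d$reads, panel, cosmic))
      mutation <- lesion_mutation_table(calls_by_sample, arm_calls,
                                        cohort$meta)
    }
    list(cohort = cohort, arm_calls = arm_calls, qc = qc_table,
         freq_by_grade = freq_by_grade,
         breakdown = list(`1q` = breakdown_1q, `8q` = breakdown_8q),
         peaks_1q = peaks_1q, joint_1q = joint_1q, context = context,
         fish = fish_summaries, mutation = mutation)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  report <- c(report, res)
  class(report) <- "cohort_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a cohort report's tables and JSON summary
#'
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_arm_calls(report$arm_calls, p("arm_calls.tsv"))
  for (g in names(report$freq_by_grade))
    data.table::fwrite(report$freq_by_grade[[g]],
                       p(sprintf("frequencies_%s.tsv", g)), sep = "\t")
  if (!is.null(report$peaks_1q) && nrow(report$peaks_1q)) {
    data.table::fwrite(report$peaks_1q, p("peaks_1q.tsv"), sep = "\t")
    write_bed_loci(data.frame(name = paste0("peak", seq_len(
      nrow(report$peaks_1q))), report$peaks_1q[, c("chrom", "start",
                                                   "end")]),
      p("peaks_1q.bed"))
  }
  if (!is.null(report$fish))
    data.table::fwrite(report$fish, p("fish_summary.tsv"), sep = "\t")
  summary <- list(
    provenance = report$provenance,
    breakdown = report$breakdown,
    joint_1q = as.list(report$joint_1q),
    context = report$context,
    frac_1q_without_ts = report$mutation$frac_1q_without_ts)
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}

#' Plot cohort summaries
#'
#' Per-grade arm gain/loss bar charts (gains up, losses down) and per-bin
#' gain-fraction profiles, written as PDF files.
#'
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @return character vector of files written.
#' @export
plot_summaries <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in names(report$freq_by_grade)) {
    f <- file.path(dir, sprintf("arm_frequencies_%s.pdf", g))
    grDevices::pdf(f, width = 10, height = 4)
    fr <- report$freq_by_grade[[g]]
    if (nrow(fr)) {
      ord <- order(match(fr$arm, fr$arm))
      graphics::barplot(fr$gain_frac[ord], names.arg = fr$arm[ord],
                        ylim = c(-1, 1), las = 2, col = "firebrick",
                        ylab = "fraction gained (up) / lost (down)",
                        main = g, cex.names = 0.6)
      graphics::barplot(-fr$loss_frac[ord], add = TRUE, col = "steelblue",
                        names.arg = FALSE, axes = FALSE)
      graphics::abline(h = 0)
    } else {
      graphics::plot.new()
      graphics::title(main = paste(g, "(empty)"))
    }
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (!is.null(report$peaks_1q)) {
    f <- file.path(dir, "gain_profile_1q.pdf")
    grDevices::pdf(f, width = 8, height = 4)
    prof <- tryCatch(
      gain_fraction_profile(
        bin_call_matrix(report$cohort$bin_calls$bins,
                        report$cohort$bin_calls$calls),
        report$arm_calls, "1q", "partial_only"),
      error = function(e) NULL)
    if (!is.null(prof)) {
      graphics::plot(prof$start / 1e6, prof$fraction, type = "l",
                     xlab = "chr1 position (Mb)",
                     ylab = "fraction of tumors with gain",
                     main = "1q, subchromosomal gains")
    } else {
      graphics::plot.new()
    }
    grDevices::dev.off()
    files <- c(files, f)
  }
  files
}
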