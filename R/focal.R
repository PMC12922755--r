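#' Minimal commonly gained region localization
#'
#' Localizes the minimal commonly gained regions of an arm from tumors with
#' subchromosomal gains, classifies per-sample inclusion of named loci, and
#' screens genes for dosage-expression association.
#'
#' @name focal-mapping
NULL

#' Per-bin gain fraction profile along an arm
#'
#' The fraction at each bin is the share of selected samples with a G call
#' at that bin. Mode `partial_only` restricts the denominator to samples
#' with a non-full-arm gain of the arm (the localization display); mode
#' `any_gain` uses every sample with a gain of the arm, full or partial
#' (the denominators behind locus-inclusion percentages).
#'
#' @param x a `bin_call_matrix` with arm-assigned bins.
#' @param arm_calls matching `arm_call_table`.
#' @param arm arm name, e.g. "1q".
#' @param mode "partial_only" (default) or "any_gain".
#' @param samples optional sample filter.
#' @return data.frame of class `gain_fraction_profile`: `chrom`, `start`,
#'   `end`, `bin` (row index into `x$bins`), `fraction`, with attributes
#'   `arm`, `mode`, `n_samples`.
#' @export
gain_fraction_profile <- function(x, arm_calls, arm,
                                  mode = c("partial_only", "any_gain"),
                                  samples = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "bin_call_matrix"))
  sub <- arm_calls[arm_calls$arm == arm & arm_calls$state == "GAIN", ]
  if (mode == "partial_only") sub <- sub[!sub$full_arm, ]
  sel <- sub$sample_id
  if (!is.null(samples)) sel <- intersect(sel, samples)
  if (!length(sel)) stop("empty denominator: no ", mode,
                         " gained samples on ", arm)
  rows <- which(x$bins$arm == arm)
  calls <- x$calls[rows, sel, drop = FALSE]
  out <- data.frame(chrom = x$bins$chrom[rows], start = x$bins$start[rows],
                    end = x$bins$end[rows], bin = rows,
                    fraction = rowMeans(calls == "G"),
                    stringsAsFactors = FALSE)
  attr(out, "arm") <- arm
  attr(out, "mode") <- mode
  attr(out, "n_samples") <- length(sel)
  class(out) <- c("gain_fraction_profile", "data.frame")
  out
}

#' Detect peak regions in a gain-fraction profile
#'
#' Peaks are maximal runs of bins whose fraction reaches
#' `max(fraction) * (1 - rel_tol)`; runs separated by fewer than
#' `merge_gap_bins` bins are merged. Returned sorted by height then width.
#'
#' @param profile a `gain_fraction_profile`.
#' @param rel_tol relative tolerance off the global maximum (default 0.02).
#' @param merge_gap_bins merge runs closer than this many bins (default 4,
#'   i.e. 2 Mb at 500-kb bins).
#' @param max_peaks cap on the number of returned peaks (default Inf).
#' @return data.frame: `chrom`, `start`, `end`, `height`, `n_bins`,
#'   `first_bin`, `last_bin` (indices into the profile); zero rows for an
#'   all-zero profile.
#' @export
detect_peaks <- function(profile, rel_tol = 0.02, merge_gap_bins = 4,
                         max_peaks = Inf) {
  if (!nrow(profile)) stop("empty profile")
  f <- profile$fraction
  top <- max(f)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), height = numeric(0),
                      n_bins = integer(0), first_bin = integer(0),
                      last_bin = integer(0), stringsAsFactors = FALSE)
  if (top <= 0) return(empty)
  at <- f >= top * (1 - rel_tol)
  r <- rle(at)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(first = starts[r$values], last = ends[r$values])
  # merge runs separated by small gaps
  if (nrow(runs) > 1) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap <- runs$first[i] - merged$last[nrow(merged)] - 1
      if (gap < merge_gap_bins) {
        merged$last[nrow(merged)] <- runs$last[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  peaks <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    sel <- runs$first[i]:runs$last[i]
    data.frame(chrom = profile$chrom[runs$first[i]],
               start = profile$start[runs$first[i]],
               end = profile$end[runs$last[i]],
               height = max(f[sel]), n_bins = length(sel),
               first_bin = runs$first[i], last_bin = runs$last[i],
               stringsAsFactors = FALSE)
  }))
  peaks <- peaks[order(-peaks$height, -peaks$n_bins), ]
  if (is.finite(max_peaks)) peaks <- utils::head(peaks, max_peaks)
  rownames(peaks) <- NULL
  peaks
}

#' Is a named locus gained in one sample?
#'
#' A sample includes (has gained) a locus when strictly more than half of
#' the bins overlapping the locus carry a G call (majority rule); the
#' stricter `all` rule requires every overlapping bin gained.
#'
#' @param calls the sample's full bin-call vector (G/N/L, aligned to
#'   `bins`).
#' @param locus list/row with `chrom`, `start`, `end`.
#' @param bins the `bin_grid` the calls are aligned to.
#' @param rule "majority" (default) or "all".
#' @return list: `included`, `gained_bins`, `total_bins`.
#' @export
locus_included <- function(calls, locus, bins, rule = c("majority", "all")) {
  rule <- match.arg(rule)
  idx <- overlapping_bins(locus, bins)
  g <- sum(calls[idx] == "G")
  inc <- if (rule == "majority") g > length(idx) / 2 else g == length(idx)
  list(included = inc, gained_bins = g, total_bins = length(idx))
}

#' Joint classification of two loci across arm-gained samples
#'
#' Over samples with any gain (full or partial) of the arm, counts how many
#' gained both loci, exactly one, or neither.
#'
#' @param x a `bin_call_matrix`.
#' @param arm_calls matching `arm_call_table`.
#' @param arm arm name.
#' @param locusA,locusB loci (list/row with `chrom`, `start`, `end`).
#' @param samples optional sample filter.
#' @param rule inclusion rule passed to [locus_included()].
#' @return named integer vector: `both`, `A_only`, `B_only`, `neither`
#'   (sums to the number of arm-gained samples).
#' @export
joint_locus_classification <- function(x, arm_calls, arm, locusA, locusB,
                                       samples = NULL, rule = "majority") {
  sub <- arm_calls[arm_calls$arm == arm & arm_calls$state == "GAIN", ]
  sel <- sub$sample_id
  if (!is.null(samples)) sel <- intersect(sel, samples)
  if (!length(sel)) stop("no samples with a gain of ", arm)
  res <- vapply(sel, function(s) {
    a <- locus_included(x$calls[, s], locusA, x$bins, rule)$included
    b <- locus_included(x$calls[, s], locusB, x$bins, rule)$included
    c(both = a && b, A_only = a && !b, B_only = !a && b,
      neither = !a && !b)
  }, logical(4))
  counts <- rowSums(res)
  storage.mode(counts) <- "integer"
  counts
}

#' Dosage-expression association screen
#'
#' Per gene, tests the linear correlation between copy number and
#' expression across samples (Pearson t-test by default; Spearman rank
#' alternative). A gene whose copy number or expression has zero variance
#' is flagged and excluded from significance calls.
#'
#' @param cn gene x sample numeric copy-number matrix.
#' @param expr gene x sample expression matrix, same dimnames.
#' @param alpha significance threshold (default 1e-5).
#' @param method "pearson" (default) or "spearman".
#' @return data.frame: `gene`, `estimate`, `statistic`, `p`, `significant`,
#'   `flagged`.
#' @export
dosage_expression_association <- function(cn, expr, alpha = 1e-5,
                                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(dim(cn), dim(expr)))
    stop("cn and expr must have identical dimensions")
  if (!is.null(rownames(cn)) && !is.null(rownames(expr)) &&
      !identical(rownames(cn), rownames(expr)))
    stop("gene rows of cn and expr are not aligned")
  if (ncol(cn) < 3) stop("need >= 3 samples")
  genes <- rownames(cn)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(cn)))
  out <- do.call(rbind, lapply(seq_len(nrow(cn)), function(i) {
    x <- cn[i, ]; y <- expr[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(gene = genes[i], estimate = NA_real_,
                        statistic = NA_real_, p = NA_real_,
                        significant = FALSE, flagged = TRUE,
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = method))
    data.frame(gene = genes[i], estimate = unname(ct$estimate),
               statistic = unname(ct$statistic), p = ct$p.value,
               significant = ct$p.value < alpha, flagged = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
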