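#' Synthetic cohort generation
#'
#' Generates ground-truthed synthetic cohorts -- integer karyotypes,
#' median-normalized bin-call matrices with purity admixture and Gaussian
#' bin noise, per-nucleus FISH counts with probe detection noise,
#' dosage-responsive expression matrices, and UID-barcoded duplex amplicon
#' reads with strand-independent sequencing error -- so that every
#' downstream stage of the pipeline can be run and verified without any
#' external data. Generator defaults encode the cohort structure reported
#' for pancreatic neoplasia: grade-dependent 1q-gain probabilities
#' (0.07/0.49/0.33/0.36/0.40 for LG PanIN / HG PanIN / LG IPMN / HG IPMN /
#' PDAC), a 34% focal (subchromosomal) share of 1q gains and 50% of 8q
#' gains, focal anchors at 1q23.2, 1q42.13 and 8q24.21, and whole-genome
#' doubling invisible to median-normalized relative calls.
#'
#' @name synthetic-cohort
NULL

#' Default cohort configuration
#'
#' All probabilities are overridable. `n_per_grade` defaults to the modeled
#' study's cohort sizes. Per-arm context-event probabilities for HG grades
#' (0.242) and LG grades (0.026) are chosen so the chance of at least one
#' of the four context events is ~0.67 and ~0.10 respectively.
#'
#' @param n_per_grade named integer vector over [pancarm_grades()].
#' @param seed integer seed governing every draw.
#' @param noise_sd per-bin log-ratio Gaussian noise (default 0.05).
#' @param purity named list of c(lo, hi) uniform purity ranges per grade.
#' @param arm_event_probs data.frame (grade, arm, state, prob).
#' @param focal_prob named vector: probability an arm gain is focal rather
#'   than full-arm (1q 0.34, 8q 0.50).
#' @param focal_joint_probs probabilities that a focal 1q gain covers both
#'   anchors, 1q23.2 only, 1q42.13 only, or neither (derived from the 77/13/8/2
#'   joint split and the 66% full-arm share).
#' @param focal_8q_anchor_prob probability a focal 8q gain covers 8q24.21.
#' @param wgd_prob named vector of whole-genome-doubling probabilities.
#' @param p_detect FISH probe detection probability per true copy.
#' @param fish_n_nuclei c(lo, hi) range of nuclei scored per sample.
#' @param expr_effect_size,expr_noise_sd dosage-expression generator.
#' @param duplex list: `n_templates`, `reads_per_strand_p` (geometric
#'   parameter; family size = 1 + Geom(p)), `per_base_error`, `uid_length`,
#'   `variant_fraction` c(lo, hi) template fraction of planted variants.
#' @param mut_probs list: `p_kras` (KRAS vs GNAS initiator),
#'   `p_ts_given_1q`, `p_ts_given_no1q` (any CDKN2A/TP53/SMAD4 mutation).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_per_grade = c(NORMAL = 45, LG_PANIN = 65, HG_PANIN = 37,
                    LG_IPMN = 76, HG_IPMN = 70, MCN = 9, SCA = 10,
                    PDAC = 535),
    seed = 1L,
    noise_sd = 0.05,
    purity = NULL,
    arm_event_probs = NULL,
    focal_prob = c("1q" = 0.34, "8q" = 0.50),
    focal_joint_probs = c(both = 0.3235, A_only = 0.3824,
                          B_only = 0.2353, neither = 0.0588),
    focal_8q_anchor_prob = 0.86,
    wgd_prob = c(NORMAL = 0, LG_PANIN = 0.05, HG_PANIN = 0.2,
                 LG_IPMN = 0.05, HG_IPMN = 0.2, MCN = 0, SCA = 0,
                 PDAC = 0.45),
    p_detect = 0.95,
    fish_n_nuclei = c(50, 100),
    expr_effect_size = 2,
    expr_noise_sd = 0.5,
    duplex = list(n_templates = 25, reads_per_strand_p = 0.4,
                  per_base_error = 1e-3, uid_length = 14L,
                  variant_fraction = c(0.25, 0.6)),
    mut_probs = list(p_kras = 0.8, p_ts_given_1q = 0.24,
                     p_ts_given_no1q = 0.173)) {
  grades <- pancarm_grades()
  if (is.null(purity)) {
    purity <- stats::setNames(rep(list(c(0.4, 0.9)), length(grades)), grades)
    purity$NORMAL <- c(1, 1)
  }
  if (is.null(arm_event_probs)) arm_event_probs <- .default_event_probs()
  stopifnot(all(names(n_per_grade) %in% grades),
            all(arm_event_probs$prob >= 0 & arm_event_probs$prob <= 1),
            all(focal_prob >= 0 & focal_prob <= 1),
            abs(sum(focal_joint_probs) - 1) < 1e-6,
            all(vapply(purity, function(p) all(p > 0 & p <= 1), TRUE)),
            p_detect > 0, p_detect <= 1)
  structure(list(n_per_grade = n_per_grade, seed = as.integer(seed),
                 noise_sd = noise_sd, purity = purity,
                 arm_event_probs = arm_event_probs,
                 focal_prob = focal_prob,
                 focal_joint_probs = focal_joint_probs,
                 focal_8q_anchor_prob = focal_8q_anchor_prob,
                 wgd_prob = wgd_prob, p_detect = p_detect,
                 fish_n_nuclei = fish_n_nuclei,
                 expr_effect_size = expr_effect_size,
                 expr_noise_sd = expr_noise_sd, duplex = duplex,
                 mut_probs = mut_probs),
            class = "cohort_config")
}

# Grade -> arm-event probability defaults. PDAC rows are the reported
# cohort frequencies; HG/LG context-arm rates are calibrated to the 67%/10%
# any-context fractions.
.default_event_probs <- function() {
  rows <- list(
    c("LG_PANIN", "1q", "GAIN", 0.07),
    c("HG_PANIN", "1q", "GAIN", 0.49),
    c("LG_IPMN", "1q", "GAIN", 0.33),
    c("HG_IPMN", "1q", "GAIN", 0.36),
    c("PDAC", "1q", "GAIN", 0.40),
    c("PDAC", "8q", "GAIN", 0.467),
    c("PDAC", "9p", "LOSS", 0.604),
    c("PDAC", "17p", "LOSS", 0.699),
    c("PDAC", "18q", "LOSS", 0.742),
    c("HG_PANIN", "8q", "GAIN", 0.242),
    c("HG_PANIN", "9p", "LOSS", 0.242),
    c("HG_PANIN", "17p", "LOSS", 0.242),
    c("HG_PANIN", "18q", "LOSS", 0.242),
    c("HG_IPMN", "8q", "GAIN", 0.242),
    c("HG_IPMN", "9p", "LOSS", 0.242),
    c("HG_IPMN", "17p", "LOSS", 0.242),
    c("HG_IPMN", "18q", "LOSS", 0.242),
    c("LG_PANIN", "8q", "GAIN", 0.026),
    c("LG_PANIN", "9p", "LOSS", 0.026),
    c("LG_PANIN", "17p", "LOSS", 0.026),
    c("LG_PANIN", "18q", "LOSS", 0.026),
    c("LG_IPMN", "8q", "GAIN", 0.026),
    c("LG_IPMN", "9p", "LOSS", 0.026),
    c("LG_IPMN", "17p", "LOSS", 0.026),
    c("LG_IPMN", "18q", "LOSS", 0.026),
    c("MCN", "8q", "GAIN", 0.2),
    c("MCN", "17p", "LOSS", 0.2),
    c("MCN", "18q", "LOSS", 0.2),
    c("SCA", "3p", "LOSS", 0.5))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("grade", "arm", "state", "prob")
  out$prob <- as.numeric(out$prob)
  out
}

.arm_span <- function(arms, arm) {
  row <- arms[arms$arm == arm, ]
  if (!nrow(row)) stop("unknown arm: ", arm)
  row
}

# Draw focal 1q segment endpoints for one joint-locus category. The
# extension of a segment beyond its anchor locus is exponential (mean
# .FOCAL_TAIL_MEAN), reflecting the short-tailed focal gains seen in real
# tumors; uniform extensions would cover the inter-anchor region more often
# than the weaker anchor itself and erase the two-peak profile structure.
# Segments always span >= 6 bins (3 Mb, the default min_run) so every
# planted focal gain is recoverable by the arm caller, and always leave
# >= 4 non-gained bins on the arm so they are never misread as full-arm
# gains.
.FOCAL_TAIL_MEAN <- 1e7

.tail_ext <- function() floor(stats::rexp(1, 1 / .FOCAL_TAIL_MEAN))

.draw_1q_segment <- function(category, arm_row, bin_size = 5e5) {
  loci <- pancarm_loci()
  A <- loci[loci$name == "1q23.2", ]
  B <- loci[loci$name == "1q42.13", ]
  lo <- arm_row$start + 4 * bin_size   # keep >=4 arm bins non-gained
  hi <- arm_row$end - 4 * bin_size
  min_len <- 6 * bin_size
  clamp <- function(x, a, b) min(max(x, a), b)
  switch(category,
         both = c(clamp(A$start - .tail_ext(), lo, A$start),
                  clamp(B$end + .tail_ext(), B$end, hi)),
         A_only = {
           s <- clamp(A$start - .tail_ext(), lo, A$start)
           c(s, clamp(max(A$end + .tail_ext(), s + min_len),
                      A$end, B$start - 1))
         },
         B_only = c(clamp(B$start - .tail_ext(), A$end + 1, B$start),
                    clamp(B$end + .tail_ext(), B$end, hi)),
         neither = {
           mid <- floor(stats::runif(1, A$end + 20 * bin_size,
                                     B$start - 20 * bin_size))
           len <- min_len + .tail_ext()
           c(clamp(mid - floor(len / 2), A$end + 1, mid),
             clamp(mid + ceiling(len / 2), mid + min_len, B$start - 1))
         },
         stop("unknown focal category: ", category))
}

.draw_8q_segment <- function(contains_anchor, arm_row, bin_size = 5e5) {
  loci <- pancarm_loci()
  P <- loci[loci$name == "8q24.21", ]
  lo <- arm_row$start + 4 * bin_size
  hi <- arm_row$end - 4 * bin_size
  min_len <- 6 * bin_size
  clamp <- function(x, a, b) min(max(x, a), b)
  if (contains_anchor)
    c(clamp(P$start - .tail_ext(), lo, P$start),
      clamp(P$end + .tail_ext(), P$end, hi))
  else {
    mid <- floor(stats::runif(1, lo + 20 * bin_size,
                              P$start - 20 * bin_size))
    len <- min_len + .tail_ext()
    c(clamp(mid - floor(len / 2), lo, mid),
      clamp(mid + ceiling(len / 2), mid + min_len, P$start - 1))
  }
}

#' Simulate one karyotype
#'
#' Arm events are drawn independently per the configured grade-specific
#' probabilities; a gain of 1q or 8q is focal with the configured
#' probability, in which case a contiguous segment is drawn whose span is
#' conditioned on the joint-locus category (for 1q) or anchor containment
#' (for 8q). NORMAL-grade samples are always copy-neutral. Whole-genome
#' doubling sets the base ploidy to 4; events add to the doubled genome.
#'
#' @param grade a grade from [pancarm_grades()].
#' @param config a `cohort_config`.
#' @param build genome build (default [hg19_build()]).
#' @param sample_id sample identifier.
#' @return object of class `karyotype`: `sample_id`, `grade`,
#'   `base_ploidy`, `events` (chrom, start, end, delta), `segments`
#'   (tiling with integer copies), `truth` (wgd, arm_events, focal table,
#'   mutations placeholder).
#' @export
simulate_karyotype <- function(grade, config, build = hg19_build(),
                               sample_id = "S1") {
  if (!grade %in% pancarm_grades()) stop("unknown grade: ", grade)
  arms <- arm_table(build)
  wgd <- grade != "NORMAL" &&
    stats::runif(1) < .cfg_get(config$wgd_prob, grade, 0)
  base <- if (wgd) 4L else 2L
  events <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), delta = integer(0),
                       arm = character(0), stringsAsFactors = FALSE)
  arm_events <- data.frame(arm = character(0), state = character(0),
                           full_arm = logical(0), stringsAsFactors = FALSE)
  focal <- data.frame(arm = character(0), start = numeric(0),
                      end = numeric(0), category = character(0),
                      stringsAsFactors = FALSE)
  if (grade != "NORMAL") {
    probs <- config$arm_event_probs
    probs <- probs[probs$grade == grade, , drop = FALSE]
    for (i in seq_len(nrow(probs))) {
      if (stats::runif(1) >= probs$prob[i]) next
      arm <- probs$arm[i]
      state <- probs$state[i]
      arow <- .arm_span(arms, arm)
      delta <- if (state == "GAIN") 1L else -1L
      is_focal <- state == "GAIN" && arm %in% names(config$focal_prob) &&
        stats::runif(1) < config$focal_prob[[arm]]
      if (is_focal && arm == "1q") {
        cat_i <- sample(names(config$focal_joint_probs), 1,
                        prob = config$focal_joint_probs)
        span <- .draw_1q_segment(cat_i, arow)
        focal <- rbind(focal, data.frame(arm = arm, start = span[1],
                                         end = span[2], category = cat_i,
                                         stringsAsFactors = FALSE))
      } else if (is_focal && arm == "8q") {
        anch <- stats::runif(1) < config$focal_8q_anchor_prob
        span <- .draw_8q_segment(anch, arow)
        focal <- rbind(focal, data.frame(
          arm = arm, start = span[1], end = span[2],
          category = if (anch) "anchor" else "off_anchor",
          stringsAsFactors = FALSE))
      } else {
        is_focal <- FALSE
        span <- c(arow$start, arow$end)
      }
      events <- rbind(events, data.frame(chrom = arow$chrom,
                                         start = span[1], end = span[2],
                                         delta = delta, arm = arm,
                                         stringsAsFactors = FALSE))
      arm_events <- rbind(arm_events, data.frame(
        arm = arm, state = state, full_arm = !is_focal,
        stringsAsFactors = FALSE))
    }
  }
  kary <- structure(list(sample_id = sample_id, grade = grade,
                         base_ploidy = base, events = events,
                         build = build,
                         truth = list(wgd = wgd, arm_events = arm_events,
                                      focal = focal,
                                      mutations = character(0))),
                    class = "karyotype")
  kary$segments <- karyotype_segments(kary)
  kary
}

.cfg_get <- function(vec, key, default) {
  if (!is.null(names(vec)) && key %in% names(vec)) vec[[key]] else default
}

#' Integer copy number segments of a karyotype
#'
#' @param kary a `karyotype`.
#' @return data.frame (chrom, start, end, copies) tiling every chromosome.
#' @export
karyotype_segments <- function(kary) {
  ci <- kary$build$chrom_info
  out <- lapply(seq_len(nrow(ci)), function(i) {
    chrom <- ci$chrom[i]; len <- ci$length[i]
    ev <- kary$events[kary$events$chrom == chrom, , drop = FALSE]
    if (!nrow(ev))
      return(data.frame(chrom = chrom, start = 1, end = len,
                        copies = kary$base_ploidy,
                        stringsAsFactors = FALSE))
    bp <- sort(unique(c(1, ev$start, ev$end + 1, len + 1)))
    starts <- bp[-length(bp)]
    ends <- bp[-1] - 1
    copies <- vapply(starts, function(s) {
      kary$base_ploidy +
        sum(ev$delta[ev$start <= s & ev$end >= s])
    }, numeric(1))
    data.frame(chrom = chrom, start = starts, end = ends,
               copies = pmax(copies, 0), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' True copy number at genomic positions
#'
#' @param kary a `karyotype`.
#' @param chrom chromosome name.
#' @param pos positions (bp).
#' @return integer copies at each position.
#' @export
copies_at <- function(kary, chrom, pos) {
  ev <- kary$events[kary$events$chrom == chrom, , drop = FALSE]
  base <- rep(kary$base_ploidy, length(pos))
  if (!nrow(ev)) return(base)
  for (i in seq_len(nrow(ev)))
    base <- base + ev$delta[i] * (pos >= ev$start[i] & pos <= ev$end[i])
  pmax(base, 0)
}

#' Render a karyotype into per-bin log-ratios and G/N/L calls
#'
#' The raw log-ratio of a bin with true copies c at tumor purity p is
#' log2((p c + 2 (1 - p)) / 2) plus Gaussian noise. Median normalization
#' subtracts the genome-wide median log-ratio before discretization,
#' emulating relative copy-number calling: a uniformly genome-doubled
#' sample is rendered all-neutral. Discretization assigns the integer copy
#' state whose expected centered log-ratio at that purity is nearest, with
#' the state grid anchored at the sample's median state (the basal copy
#' number the segmenter normalizes against), then maps states above the
#' median state to G, equal to N, below to L. Bin copy state is taken at
#' the bin midpoint.
#'
#' The per-bin log-ratios always carry independent Gaussian noise; the
#' discrete call, however, is made per *segment* by default
#' (`discretize = "segment"`): bins of the same true copy-number segment
#' share the state nearest to the segment's mean centered log-ratio. This
#' emulates what the upstream HMM segmentation emits -- the pipeline's
#' real-world input is segmented calls, in which per-bin independent state
#' flips do not occur. `discretize = "bin"` assigns each bin its own
#' nearest state instead.
#'
#' @param kary a `karyotype`.
#' @param bins a `bin_grid` on the same build.
#' @param purity tumor purity in (0, 1].
#' @param noise_sd Gaussian log-ratio noise (default 0.05).
#' @param normalization "median" (default) or "none".
#' @param discretize "segment" (default, emulating segmented calls) or
#'   "bin".
#' @param max_state highest copy state considered (default 12).
#' @return data.frame: `log_ratio` (raw, uncentered), `call`,
#'   `true_copies`.
#' @export
render_bin_profile <- function(kary, bins, purity, noise_sd = 0.05,
                               normalization = c("median", "none"),
                               discretize = c("segment", "bin"),
                               max_state = 12L) {
  normalization <- match.arg(normalization)
  discretize <- match.arg(discretize)
  stopifnot(purity > 0, purity <= 1, nrow(bins) > 0)
  mid <- (bins$start + bins$end) / 2
  copies <- numeric(nrow(bins))
  seg_id <- character(nrow(bins))
  segs <- kary$segments
  for (chrom in unique(bins$chrom)) {
    sel <- bins$chrom == chrom
    copies[sel] <- copies_at(kary, chrom, mid[sel])
    cs <- segs[segs$chrom == chrom, ]
    idx <- findInterval(mid[sel], cs$start)
    seg_id[sel] <- paste0(chrom, "_", idx)
  }
  mix <- (purity * copies + (1 - purity) * 2) / 2
  lr <- log2(pmax(mix, 0.01)) + stats::rnorm(nrow(bins), 0, noise_sd)
  states <- 0:max_state
  expected <- log2(pmax((purity * states + (1 - purity) * 2) / 2, 0.01))
  if (normalization == "median") {
    # relative calling: states are anchored at the sample's median state
    # (the basal copy number the segmenter normalizes to), so a genome
    # doubling is invisible while events on top of it remain callable
    med <- stats::median(lr)
    centered <- lr - med
    c_med <- states[which.min(abs(expected - med))]
    grid <- expected - expected[match(c_med, states)]
  } else {
    centered <- lr
    c_med <- 2L
    grid <- expected
  }
  nearest_state <- function(x)
    states[max.col(-abs(outer(x, grid, "-")), ties.method = "first")]
  if (discretize == "segment") {
    seg_mean <- tapply(centered, seg_id, mean)
    seg_state <- stats::setNames(nearest_state(as.numeric(seg_mean)),
                                 names(seg_mean))
    nearest <- unname(seg_state[seg_id])
  } else {
    nearest <- nearest_state(centered)
  }
  call <- ifelse(nearest > c_med, "G", ifelse(nearest < c_med, "L", "N"))
  data.frame(log_ratio = lr, call = call, true_copies = copies,
             stringsAsFactors = FALSE)
}

#' Simulate per-nucleus FISH signal counts
#'
#' Each nucleus reports Binomial(true copies at the probe locus, p_detect)
#' signals; counts are returned uncapped (capping is a scoring-stage rule).
#' An optional admixed fraction of normal (diploid) nuclei can be included.
#'
#' @param kary a `karyotype`.
#' @param probe_locus list/row with `chrom`, `start`, `end`.
#' @param n_nuclei number of nuclei scored.
#' @param p_detect per-copy detection probability in (0, 1].
#' @param frac_normal_nuclei admixed diploid nucleus fraction (default 0).
#' @return integer vector of per-nucleus counts.
#' @export
simulate_fish_counts <- function(kary, probe_locus, n_nuclei,
                                 p_detect = 0.95, frac_normal_nuclei = 0) {
  stopifnot(p_detect > 0, p_detect <= 1)
  if (!probe_locus$chrom %in% kary$build$chrom_info$chrom)
    stop("probe locus not covered by karyotype: ", probe_locus$chrom)
  mid <- (probe_locus$start + probe_locus$end) / 2
  copies <- copies_at(kary, probe_locus$chrom, mid)
  n_norm <- stats::rbinom(1, n_nuclei, frac_normal_nuclei)
  counts <- c(stats::rbinom(n_nuclei - n_norm, copies, p_detect),
              stats::rbinom(n_norm, 2, p_detect))
  counts[sample.int(length(counts))]
}

#' Simulate a dosage-responsive expression matrix
#'
#' Expression of a responsive gene is baseline + effect_size * (copies - 2)
#' + Gaussian noise; non-responsive genes are baseline + noise only.
#'
#' @param cn gene x sample copy-number matrix.
#' @param responsive logical vector per gene (the planted truth).
#' @param effect_size expression units per extra copy (>= 0).
#' @param noise_sd Gaussian noise sd.
#' @param baseline baseline expression (default 8, log2-microarray-like).
#' @return list: `expr` (gene x sample matrix), `responsive`.
#' @export
simulate_expression <- function(cn, responsive, effect_size = 2,
                                noise_sd = 0.5, baseline = 8) {
  stopifnot(effect_size >= 0, length(responsive) == nrow(cn))
  eff <- ifelse(responsive, effect_size, 0)
  expr <- baseline + eff * (cn - 2) +
    matrix(stats::rnorm(length(cn), 0, noise_sd), nrow(cn))
  dimnames(expr) <- dimnames(cn)
  list(expr = expr, responsive = responsive)
}

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), ""))
}

.mutate_seq <- function(seq, pos, alt) {
  substr(seq, pos, pos) <- alt
  seq
}

# apply i.i.d. per-base substitution errors to a character vector of reads
.apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  hits <- which(stats::runif(length(mat)) < error_rate)
  if (length(hits)) {
    for (h in hits) {
      mat[h] <- sample(setdiff(.BASES, mat[h]), 1)
    }
  }
  apply(mat, 1, paste, collapse = "")
}

#' Simulate UID-barcoded duplex amplicon reads
#'
#' Each template molecule receives a distinct random UID and yields a
#' Watson and a Crick read family (sizes 1 + Geometric(p)). A template
#' carrying a true variant propagates it to both strands; sequencing
#' errors are drawn independently per read per base on the insert
#' (strand-independent error model). Read 1 is UID + insert in the
#' strand's orientation (Watson: amplicon plus strand; Crick: reverse
#' complement).
#'
#' @param amplicon one row of an amplicon table (needs `amplicon_id`,
#'   `ref_seq`).
#' @param n_templates number of template molecules (>= 1).
#' @param true_variants data.frame (`offset` 1-based within the amplicon,
#'   `alt`, `fraction`) or NULL. Each template carries each variant
#'   independently with probability `fraction`.
#' @param per_base_error substitution error rate in [0, 0.05].
#' @param reads_per_strand_p geometric parameter for family size.
#' @param uid_length UID length (default 14).
#' @return list: `reads` (data.frame: read_id, uid, strand_truth, seq =
#'   read-1 sequence), `truth` (data.frame: uid, template carries-variant
#'   flags per variant).
#' @export
simulate_duplex_reads <- function(amplicon, n_templates,
                                  true_variants = NULL,
                                  per_base_error = 1e-3,
                                  reads_per_strand_p = 0.4,
                                  uid_length = 14L) {
  stopifnot(n_templates >= 1, per_base_error >= 0, per_base_error <= 0.05)
  ref <- amplicon$ref_seq
  L <- nchar(ref)
  if (!is.null(true_variants) && nrow(true_variants) &&
      any(true_variants$offset < 1 | true_variants$offset > L))
    stop("variant position outside amplicon")
  repeat {
    uids <- vapply(seq_len(n_templates), function(i) .random_seq(uid_length),
                   "")
    if (!anyDuplicated(uids)) break
  }
  nv <- if (is.null(true_variants)) 0L else nrow(true_variants)
  carries <- matrix(FALSE, n_templates, max(nv, 1))
  templates <- rep(ref, n_templates)
  if (nv) {
    for (v in seq_len(nv)) {
      carries[, v] <- stats::runif(n_templates) < true_variants$fraction[v]
      for (t in which(carries[, v]))
        templates[t] <- .mutate_seq(templates[t], true_variants$offset[v],
                                    true_variants$alt[v])
    }
  }
  reads <- vector("list", 2L * n_templates)
  k <- 0L
  for (t in seq_len(n_templates)) {
    for (strand in c("WATSON", "CRICK")) {
      fam_size <- 1L + stats::rgeom(1, reads_per_strand_p)
      insert <- if (strand == "WATSON") templates[t]
                else .revcomp(templates[t])
      seqs <- .apply_errors(rep(insert, fam_size), per_base_error)
      k <- k + 1L
      reads[[k]] <- data.frame(uid = uids[t], strand_truth = strand,
                               seq = paste0(uids[t], seqs),
                               stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, reads)
  reads$read_id <- sprintf("%s_read%05d", amplicon$amplicon_id,
                           seq_len(nrow(reads)))
  reads$amplicon_id <- amplicon$amplicon_id
  truth <- data.frame(uid = uids, stringsAsFactors = FALSE)
  if (nv) for (v in seq_len(nv))
    truth[[paste0("carries_", true_variants$offset[v],
                  true_variants$alt[v])]] <- carries[, v]
  list(reads = reads[, c("read_id", "amplicon_id", "uid", "strand_truth",
                         "seq")],
       truth = truth)
}

#' Synthetic 37-amplicon panel
#'
#' A synthetic stand-in for the targeted amplicon panel: 37 amplicons over
#' the six genes (KRAS, NRAS, GNAS, CDKN2A, TP53, SMAD4) at their hg19
#' loci, each with a randomly generated 120-bp reference sequence and one
#' hotspot position at its center. Deterministic: generated under an
#' internal fixed seed, independent of the caller's RNG state.
#'
#' @return data.frame: `amplicon_id`, `gene`, `chrom`, `start`, `end`,
#'   `ref_seq`, `hotspot_offset`, `hotspot_ref`, `hotspot_alt`.
#' @export
synthetic_amplicon_panel <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(20260911)
  genes <- data.frame(
    gene = c("KRAS", "NRAS", "GNAS", "CDKN2A", "TP53", "SMAD4"),
    chrom = c("chr12", "chr1", "chr20", "chr9", "chr17", "chr18"),
    gstart = c(25358180, 115247085, 57414773, 21967751, 7571720, 48556583),
    n_amp = c(4, 3, 4, 8, 12, 6),
    stringsAsFactors = FALSE)
  L <- 120L
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    starts <- g$gstart + (seq_len(g$n_amp) - 1) * 400L
    do.call(rbind, lapply(seq_len(g$n_amp), function(j) {
      ref <- .random_seq(L)
      off <- 60L
      rb <- substr(ref, off, off)
      alt <- sample(setdiff(.BASES, rb), 1)
      data.frame(amplicon_id = sprintf("%s_amp%02d", g$gene, j),
                 gene = g$gene, chrom = g$chrom, start = starts[j],
                 end = starts[j] + L - 1L, ref_seq = ref,
                 hotspot_offset = off, hotspot_ref = rb, hotspot_alt = alt,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Synthetic COSMIC-style annotation lookup
#'
#' One confirmed-somatic, multiply-annotated row per panel hotspot, plus a
#' singleton-annotation decoy 10 bp downstream of each (which must fail the
#' >=2-annotations filter).
#'
#' @param panel amplicon panel from [synthetic_amplicon_panel()].
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `annotation_count`,
#'   `confirmed_somatic`, `genome_wide_study`.
#' @export
synthetic_cosmic_lookup <- function(panel = synthetic_amplicon_panel()) {
  hot <- data.frame(chrom = panel$chrom,
                    pos = panel$start + panel$hotspot_offset - 1L,
                    ref = panel$hotspot_ref, alt = panel$hotspot_alt,
                    annotation_count = 50L, confirmed_somatic = TRUE,
                    genome_wide_study = TRUE, stringsAsFactors = FALSE)
  decoy <- hot
  decoy$pos <- decoy$pos + 10L
  decoy$annotation_count <- 1L
  rbind(hot, decoy)
}

#' Simulate a complete synthetic cohort
#'
#' Fully reproducible from `config$seed`. Generates per-sample karyotypes,
#' renders the bin-call matrix under purity admixture and median
#' normalization, simulates FISH counts for a subset of PDAC samples plus
#' diploid NORMAL controls, a dosage-responsive expression matrix over a
#' synthetic gene panel, and (optionally) duplex amplicon read sets with
#' planted driver mutations for precursor-grade samples.
#'
#' @param config a `cohort_config`.
#' @param build genome build.
#' @param include_duplex simulate duplex reads for precursor samples
#'   (default TRUE; the dominant cost at large cohort sizes).
#' @param n_fish number of PDAC samples given FISH data (default 10).
#' @param n_expr_genes genes in the expression panel (default 30; one third
#'   each in 1q23.2, 1q42.13 and elsewhere; half of the in-region genes
#'   are dosage-responsive).
#' @return list of class `synthetic_cohort`: `bin_calls`
#'   (`bin_call_matrix`), `meta`, `qc`, `karyotypes`, `purity`, `fish`,
#'   `expression` (list: cn, expr, responsive), `duplex` (per-sample read
#'   sets), `truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), build = hg19_build(),
                            include_duplex = TRUE, n_fish = 10,
                            n_expr_genes = 30) {
  set.seed(config$seed)
  bins <- assign_bins_to_arms(make_bins(build), arm_table(build))
  n_per_grade <- config$n_per_grade[config$n_per_grade > 0]
  grades <- rep(names(n_per_grade), n_per_grade)
  n <- length(grades)
  ids <- sprintf("SYN%04d", seq_len(n))
  karyotypes <- vector("list", n)
  purity <- numeric(n)
  calls <- matrix(NA_character_, nrow(bins), n,
                  dimnames = list(NULL, ids))
  mutations <- vector("list", n)
  precursor <- c("LG_PANIN", "HG_PANIN", "LG_IPMN", "HG_IPMN")
  for (i in seq_len(n)) {
    kary <- simulate_karyotype(grades[i], config, build, ids[i])
    pr <- config$purity[[grades[i]]]
    purity[i] <- stats::runif(1, pr[1], pr[2])
    prof <- render_bin_profile(kary, bins, purity[i], config$noise_sd)
    calls[, i] <- prof$call
    # plant driver point mutations for precursor lesions
    muts <- character(0)
    if (grades[i] %in% precursor) {
      muts <- if (stats::runif(1) < config$mut_probs$p_kras) "KRAS"
              else "GNAS"
      has_1q <- "1q" %in% kary$truth$arm_events$arm[
        kary$truth$arm_events$state == "GAIN"]
      p_ts <- if (has_1q) config$mut_probs$p_ts_given_1q
              else config$mut_probs$p_ts_given_no1q
      if (stats::runif(1) < p_ts)
        muts <- c(muts, sample(c("CDKN2A", "TP53", "SMAD4"), 1))
    }
    kary$truth$mutations <- muts
    mutations[[i]] <- muts
    karyotypes[[i]] <- kary
  }
  meta <- data.frame(sample_id = ids,
                     patient_id = sprintf("PT%d", seq_len(n)),
                     grade = grades,
                     preservation = rep_len(c("frozen", "FFPE"), n),
                     stringsAsFactors = FALSE)
  qc <- data.frame(sample_id = ids,
                   mad = stats::runif(n, 0.01, 0.10),
                   expected_variance = rep(1, n),
                   observed_variance = stats::runif(n, 0.8, 1.5),
                   n_segments = stats::rpois(n, 40),
                   stringsAsFactors = FALSE)
  # FISH: PDAC subset (neoplastic compartment) + NORMAL controls
  fish <- .simulate_cohort_fish(karyotypes, meta, config, n_fish)
  expression <- .simulate_cohort_expression(karyotypes, config,
                                            n_expr_genes)
  duplex <- NULL
  if (include_duplex)
    duplex <- .simulate_cohort_duplex(karyotypes, meta, config, precursor)
  truth <- list(
    per_sample = data.frame(
      sample_id = ids, grade = grades, purity = purity,
      wgd = vapply(karyotypes, function(k) k$truth$wgd, TRUE),
      gain_1q = vapply(karyotypes, function(k)
        any(k$truth$arm_events$arm == "1q" &
              k$truth$arm_events$state == "GAIN"), TRUE),
      full_1q = vapply(karyotypes, function(k)
        any(k$truth$arm_events$arm == "1q" &
              k$truth$arm_events$state == "GAIN" &
              k$truth$arm_events$full_arm), TRUE),
      mutations = vapply(mutations, paste, "", collapse = ","),
      stringsAsFactors = FALSE),
    arm_events = stats::setNames(
      lapply(karyotypes, function(k) k$truth$arm_events), ids),
    focal = stats::setNames(lapply(karyotypes, function(k) k$truth$focal),
                            ids))
  structure(list(bin_calls = bin_call_matrix(bins, calls), meta = meta,
                 qc = qc, karyotypes = stats::setNames(karyotypes, ids),
                 purity = stats::setNames(purity, ids), fish = fish,
                 expression = expression, duplex = duplex, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

.simulate_cohort_fish <- function(karyotypes, meta, config, n_fish) {
  loci <- pancarm_loci()
  probe <- list(name = "1q25_ABL2", chrom = "chr1",
                start = 179068462, end = 179112224)
  pdac <- which(meta$grade == "PDAC")
  norm <- which(meta$grade == "NORMAL")
  pick <- c(utils::head(pdac, n_fish), utils::head(norm, min(5, n_fish)))
  if (!length(pick)) return(NULL)
  out <- do.call(rbind, lapply(pick, function(i) {
    nn <- sample(config$fish_n_nuclei[1]:config$fish_n_nuclei[2], 1)
    counts <- simulate_fish_counts(karyotypes[[i]], probe, nn,
                                   config$p_detect)
    data.frame(sample_id = meta$sample_id[i], probe = probe$name,
               compartment = if (meta$grade[i] == "NORMAL") "nonneoplastic"
                             else "neoplastic",
               nucleus_index = seq_along(counts),
               signals = cap_counts(counts), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.simulate_cohort_expression <- function(karyotypes, config, n_genes) {
  loci <- pancarm_loci()
  A <- loci[loci$name == "1q23.2", ]
  B <- loci[loci$name == "1q42.13", ]
  k <- max(3, floor(n_genes / 3))
  place <- function(region, m, prefix) {
    pos <- round(seq(region$start + 1e4, region$end - 1e4,
                     length.out = m))
    data.frame(gene = paste0(prefix, seq_len(m)), chrom = region$chrom,
               pos = pos, stringsAsFactors = FALSE)
  }
  genes <- rbind(place(A, k, "g1q23_"), place(B, k, "g1q42_"),
                 data.frame(gene = paste0("gother_", seq_len(n_genes - 2 * k)),
                            chrom = "chr2",
                            pos = round(seq(1e6, 2e8,
                                            length.out = n_genes - 2 * k)),
                            stringsAsFactors = FALSE))
  # half of in-region genes respond to dosage; off-region genes never do
  responsive <- c(rep(c(TRUE, FALSE), length.out = k),
                  rep(c(TRUE, FALSE), length.out = k),
                  rep(FALSE, n_genes - 2 * k))
  cn <- vapply(karyotypes, function(kary)
    vapply(seq_len(nrow(genes)), function(g)
      copies_at(kary, genes$chrom[g], genes$pos[g]), numeric(1)),
    numeric(nrow(genes)))
  rownames(cn) <- genes$gene
  colnames(cn) <- vapply(karyotypes, function(k2) k2$sample_id, "")
  sim <- simulate_expression(cn, responsive, config$expr_effect_size,
                             config$expr_noise_sd)
  list(cn = cn, expr = sim$expr, responsive = responsive, genes = genes)
}

.simulate_cohort_duplex <- function(karyotypes, meta, config, precursor) {
  panel <- synthetic_amplicon_panel()
  dx <- config$duplex
  sel <- which(meta$grade %in% precursor)
  if (!length(sel)) return(NULL)
  out <- lapply(sel, function(i) {
    kary <- karyotypes[[i]]
    muts <- kary$truth$mutations
    # always sequence the KRAS amplicons (assessability) plus one amplicon
    # per mutated gene
    amp_ids <- panel$amplicon_id[panel$gene == "KRAS"]
    planted <- list()
    for (g in muts) {
      amp <- panel[panel$gene == g, ][1, ]
      amp_ids <- union(amp_ids, amp$amplicon_id)
      planted[[g]] <- amp
    }
    reads <- list()
    truth <- list()
    for (aid in amp_ids) {
      amp <- panel[panel$amplicon_id == aid, ]
      tv <- NULL
      if (amp$gene %in% muts && aid == planted[[amp$gene]]$amplicon_id) {
        frac <- stats::runif(1, dx$variant_fraction[1],
                             dx$variant_fraction[2])
        tv <- data.frame(offset = amp$hotspot_offset,
                         alt = amp$hotspot_alt, fraction = frac,
                         stringsAsFactors = FALSE)
      }
      sim <- simulate_duplex_reads(amp, dx$n_templates, tv,
                                   dx$per_base_error,
                                   dx$reads_per_strand_p, dx$uid_length)
      reads[[aid]] <- sim$reads
      truth[[aid]] <- sim$truth
    }
    list(sample_id = meta$sample_id[i], reads = do.call(rbind, reads),
         truth = truth, planted_genes = muts)
  })
  stats::setNames(out, meta$sample_id[sel])
}

#' Write a synthetic cohort to standard-format files
#'
#' Writes the bin-call TSV, metadata TSV, QC TSV, FISH TSV, expression
#' TSVs, per-sample FASTQ read files (UID as the first 14 bases of read 1),
#' the amplicon panel and COSMIC-style lookup, and the truth table as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_bin_call_matrix(cohort$bin_calls, p("bin_calls.tsv"))
  data.table::fwrite(cohort$meta, p("meta.tsv"), sep = "\t")
  data.table::fwrite(cohort$qc, p("qc.tsv"), sep = "\t")
  if (!is.null(cohort$fish))
    data.table::fwrite(cohort$fish, p("fish.tsv"), sep = "\t")
  ex <- cohort$expression
  data.table::fwrite(data.frame(gene = rownames(ex$cn), ex$cn,
                                check.names = FALSE),
                     p("expression_cn.tsv"), sep = "\t")
  data.table::fwrite(data.frame(gene = rownames(ex$expr),
                                round(ex$expr, 6), check.names = FALSE),
                     p("expression.tsv"), sep = "\t")
  data.table::fwrite(synthetic_amplicon_panel(), p("amplicons.tsv"),
                     sep = "\t")
  data.table::fwrite(synthetic_cosmic_lookup(), p("cosmic_lookup.tsv"),
                     sep = "\t")
  if (!is.null(cohort$duplex)) {
    dir.create(p("fastq"), showWarnings = FALSE)
    for (s in names(cohort$duplex))
      write_duplex_fastq(cohort$duplex[[s]]$reads,
                         p("fastq", paste0(s, "_R1.fastq")))
  }
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         per_sample = cohort$truth$per_sample),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
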