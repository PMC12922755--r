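# shared fixtures, all built in code

# tiny two-chromosome build: chrT (10 Mb, centromere 2.05 Mb -> 4 p bins /
# 15 q bins / 1 straddling), chrU (3 Mb, centromere 1.25 Mb)
toy_build <- function() {
  genome_build(data.frame(
    chrom = c("chrT", "chrU"),
    length = c(10e6, 3e6),
    centromere = c(2050000, 1250000)), name = "toy")
}

toy_bins <- function(build = toy_build()) {
  assign_bins_to_arms(make_bins(build), arm_table(build))
}

# bin-call matrix on the toy build from a named list of per-sample G/N/L
# vectors (length = number of bins)
toy_matrix <- function(samples, bins = toy_bins()) {
  calls <- do.call(cbind, samples)
  colnames(calls) <- names(samples)
  bin_call_matrix(bins, calls)
}

# one sample vector with given calls on a set of bin rows
toy_calls <- function(bins, gain_rows = integer(0), loss_rows = integer(0)) {
  v <- rep("N", nrow(bins))
  v[gain_rows] <- "G"
  v[loss_rows] <- "L"
  v
}

# brute-force arm-call oracle: counts and longest runs, independent of the
# package's rle-based path
oracle_call_arm <- function(calls, min_run = 6L) {
  n <- length(calls)
  gained <- sum(calls == "G")
  lost <- sum(calls == "L")
  longest <- function(sym) {
    best <- 0L; cur <- 0L
    for (x in calls) {
      cur <- if (x == sym) cur + 1L else 0L
      best <- max(best, cur)
    }
    best
  }
  gr <- longest("G"); lr <- longest("L")
  fg <- gained >= 1 && gained >= n - 3
  fl <- lost >= 1 && lost >= n - 3
  state <- if (fg || gr >= min_run) "GAIN"
           else if (fl || lr >= min_run) "LOSS" else "NEUTRAL"
  list(state = state,
       full_arm = (state == "GAIN" && fg) || (state == "LOSS" && fl),
       gained_bins = gained, lost_bins = lost, gain_run = gr,
       loss_run = lr)
}

# brute-force two-tailed Fisher oracle via direct table enumeration with
# lchoose (independent of dhyper)
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, ks) + lchoose(n - c1, r1 - ks) - lchoose(n, r1)
  p_obs <- exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1))
  min(sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-12)]), 1)
}

# small default duplex fixture; the repeat unit must not be its own
# reverse complement or strand assignment is ill-posed
toy_amplicon <- function(seq = NULL, L = 100L) {
  if (is.null(seq)) seq <- paste(rep(c("A", "A", "C", "G", "T"), L / 5),
                                 collapse = "")
  data.frame(amplicon_id = "TEST_amp01", gene = "KRAS", chrom = "chr12",
             start = 1000L, end = 1000L + L - 1L, ref_seq = seq,
             hotspot_offset = 50L, hotspot_ref = substr(seq, 50, 50),
             hotspot_alt = setdiff(c("A", "C", "G", "T"),
                                   substr(seq, 50, 50))[1],
             stringsAsFactors = FALSE)
}

toy_cosmic <- function(amp = toy_amplicon()) {
  data.frame(chrom = amp$chrom, pos = amp$start + amp$hotspot_offset - 1L,
             ref = amp$hotspot_ref, alt = amp$hotspot_alt,
             annotation_count = 10L, confirmed_somatic = TRUE,
             genome_wide_study = TRUE, stringsAsFactors = FALSE)
}
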