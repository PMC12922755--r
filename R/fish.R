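#' FISH signal-count scoring
#'
#' Per-nucleus probe signal counts are capped at 10 at recording time,
#' summarized into mean signals and tail fractions, and classified into
#' positivity calls (>=3 copies in >=20% of nuclei, >=4 copies in >=10%,
#' or the "most nuclei" majority rule). Scores from two analysts are
#' pooled (concatenated), not averaged.
#'
#' @name fish-scoring
NULL

#' Cap recorded signal counts at 10
#'
#' When more than 10 signals are observed in a nucleus the recorded value
#' is 10.
#'
#' @param counts integer vector of per-nucleus signal counts (>= 0).
#' @param cap recording cap (default 10).
#' @return capped counts.
#' @export
cap_counts <- function(counts, cap = 10L) {
  if (any(counts < 0)) stop("negative signal count")
  pmin(counts, cap)
}

#' Summarize per-nucleus counts for one sample/probe
#'
#' @param counts per-nucleus signal counts (capped on entry via
#'   [cap_counts()]).
#' @param warn_n warn when the nucleus count falls outside the expected
#'   50-100 range (default TRUE).
#' @return list of class `fish_summary`: `mean_signals`, `frac_ge3`,
#'   `frac_ge4`, `n_nuclei`.
#' @export
fish_summary <- function(counts, warn_n = TRUE) {
  if (!length(counts)) stop("empty counts")
  counts <- cap_counts(counts)
  n <- length(counts)
  if (warn_n && (n < 50 || n > 100))
    warning(sprintf("%d nuclei scored; 50-100 expected", n))
  structure(list(mean_signals = mean(counts),
                 frac_ge3 = mean(counts >= 3),
                 frac_ge4 = mean(counts >= 4),
                 n_nuclei = n),
            class = "fish_summary")
}

#' Classify a FISH summary as positive or negative
#'
#' Rules: `ge3_at_20pct` — at least three copies in at least 20% of nuclei
#' (inclusive); `ge4_at_10pct` — at least four copies in at least 10%
#' (inclusive); `majority_ge3` — strictly more than half of nuclei with at
#' least three copies ("most nuclei").
#'
#' @param summary a `fish_summary`.
#' @param rule one of "ge3_at_20pct", "ge4_at_10pct", "majority_ge3".
#' @return logical.
#' @export
classify_positive <- function(summary,
                              rule = c("ge3_at_20pct", "ge4_at_10pct",
                                       "majority_ge3")) {
  rule <- match.arg(rule)
  switch(rule,
         ge3_at_20pct = summary$frac_ge3 >= 0.20,
         ge4_at_10pct = summary$frac_ge4 >= 0.10,
         majority_ge3 = summary$frac_ge3 > 0.5)
}

#' Cross-classify a WGS arm call against FISH positivity
#'
#' FISH counts absolute copies while median-normalized WGS bin calls are
#' relative; a uniformly genome-doubled sample is WGS-neutral but
#' FISH-positive. A FISH-positive/WGS-negative discordance is attributed to
#' low tumor cellularity when the WGS tumor fraction is below `purity_min`,
#' otherwise to the relative-copy-number blindness of the WGS calls.
#'
#' @param wgs_state arm state from the WGS caller ("GAIN"/"LOSS"/"NEUTRAL").
#' @param fish_positive logical positivity call.
#' @param tumor_fraction estimated tumor fraction of the WGS sample, or
#'   `NULL`/`NA` when unknown.
#' @param purity_min cellularity cutoff (default 0.2).
#' @return one of "concordant", "discordant_low_purity",
#'   "discordant_relative_cn".
#' @export
wgs_fish_concordance <- function(wgs_state, fish_positive,
                                 tumor_fraction = NULL, purity_min = 0.2) {
  wgs_gain <- identical(wgs_state, "GAIN")
  if (wgs_gain == isTRUE(fish_positive)) return("concordant")
  if (isTRUE(fish_positive) && !wgs_gain) {
    if (!is.null(tumor_fraction) && !is.na(tumor_fraction) &&
        tumor_fraction < purity_min)
      return("discordant_low_purity")
    return("discordant_relative_cn")
  }
  # WGS gain without FISH positivity: relative call with no absolute
  # support; same mechanism class
  "discordant_relative_cn"
}

#' Read a per-nucleus FISH table
#'
#' @param path TSV with columns `sample_id`, `probe`, `compartment`,
#'   `nucleus_index`, `signals`.
#' @return data.frame.
#' @export
read_fish_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "probe", "compartment", "signals")
  if (!all(need %in% names(df)))
    stop("FISH TSV must contain columns ", paste(need, collapse = ", "))
  if (any(df$signals < 0)) stop("negative signal count in file")
  df
}

#' Summarize a FISH table per sample/probe/compartment
#'
#' Nuclei from multiple analysts (rows) are pooled; pooling is
#' order-invariant.
#'
#' @param fish data.frame from [read_fish_table()].
#' @param rule positivity rule passed to [classify_positive()].
#' @return data.frame: `sample_id`, `probe`, `compartment`, `n_nuclei`,
#'   `mean_signals`, `frac_ge3`, `frac_ge4`, `positive`.
#' @export
summarize_fish_table <- function(fish, rule = "ge3_at_20pct") {
  key <- interaction(fish$sample_id, fish$probe, fish$compartment,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(fish, key), function(g) {
    s <- fish_summary(g$signals, warn_n = FALSE)
    data.frame(sample_id = g$sample_id[1], probe = g$probe[1],
               compartment = g$compartment[1], n_nuclei = s$n_nuclei,
               mean_signals = s$mean_signals, frac_ge3 = s$frac_ge3,
               frac_ge4 = s$frac_ge4,
               positive = classify_positive(s, rule),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$sample_id, out$probe, out$compartment), ]
}
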