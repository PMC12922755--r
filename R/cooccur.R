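#' Co-occurrence and progression-context statistics
#'
#' Mutual-exclusivity / co-occurrence tests for arm-level events and the
#' progression-context comparison (does a focal event, by default 1q gain,
#' co-occur with gains of 8q or losses of 9p/17p/18q), using a two-tailed
#' Fisher exact test implemented from first principles.
#'
#' @name cooccur-stats
NULL

#' Two-tailed Fisher exact test
#'
#' Exact test on a 2x2 contingency table. The two-tailed p-value follows
#' the method of small p-values: the sum of hypergeometric probabilities of
#' every table with the same margins whose probability does not exceed that
#' of the observed table (relative tie tolerance 1e-12). A degenerate
#' margin (any row or column total of zero) gives p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts, or the count `a`
#'   when `b`, `c`, `d` are given.
#' @param b,c,d remaining cells (row-wise: a b / c d) when `table` is a
#'   scalar.
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_tailed <- function(table, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- table
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  n <- a + b + c + d
  if (n < 1) stop("table total must be >= 1")
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  k <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(k, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(p, 1)
}

.parse_event <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[2] %in% c("GAIN", "LOSS"))
    stop("event must look like '1q:GAIN' or '17p:LOSS', got: ", spec)
  list(arm = parts[1], state = parts[2])
}

.event_flags <- function(arm_calls, event, samples) {
  ev <- .parse_event(event)
  sub <- arm_calls[arm_calls$arm == ev$arm, ]
  flags <- sub$state[match(samples, sub$sample_id)] == ev$state
  flags[is.na(flags)] <- FALSE
  flags
}

#' Context fraction for a focal event
#'
#' Among samples carrying the focal event (default 1q gain), the fraction
#' that also carry at least one context event (default: 8q gain or loss of
#' 9p, 17p or 18q).
#'
#' @param arm_calls an `arm_call_table`.
#' @param focal focal event as "arm:STATE" (default "1q:GAIN").
#' @param context character vector of context events; must not contain the
#'   focal event.
#' @param meta,grades,samples stratum filters as in
#'   [cohort_arm_frequencies()].
#' @return list: `n_focal`, `n_with_context`, `fraction` (`NA` when no
#'   sample has the focal event).
#' @export
context_fraction <- function(arm_calls, focal = "1q:GAIN",
                             context = c("8q:GAIN", "9p:LOSS",
                                         "17p:LOSS", "18q:LOSS"),
                             meta = NULL, grades = NULL, samples = NULL) {
  if (focal %in% context) stop("focal event must not appear in context set")
  keep <- .filter_samples(arm_calls, meta, grades, samples)
  if (!length(keep)) stop("empty stratum")
  has_focal <- .event_flags(arm_calls, focal, keep)
  focal_samples <- keep[has_focal]
  if (!length(focal_samples))
    return(list(n_focal = 0L, n_with_context = 0L, fraction = NA_real_))
  ctx <- Reduce(`|`, lapply(context, .event_flags, arm_calls = arm_calls,
                            samples = focal_samples))
  list(n_focal = length(focal_samples), n_with_context = sum(ctx),
       fraction = mean(ctx))
}

#' Compare context fractions between two strata
#'
#' Builds the 2x2 table (stratum x with/without context, restricted to
#' samples carrying the focal event) and tests it with
#' [fisher_exact_two_tailed()].
#'
#' @param arm_calls an `arm_call_table`.
#' @param meta metadata with `sample_id` and `grade`.
#' @param gradesA,gradesB grade sets defining the two strata.
#' @param focal,context as in [context_fraction()].
#' @return list: `table` (2x2 matrix, rows = strata, cols =
#'   with/without context), `p`, `fractionA`, `fractionB`.
#' @export
compare_context_between_strata <- function(arm_calls, meta, gradesA, gradesB,
                                           focal = "1q:GAIN",
                                           context = c("8q:GAIN", "9p:LOSS",
                                                       "17p:LOSS",
                                                       "18q:LOSS")) {
  fa <- context_fraction(arm_calls, focal, context, meta, gradesA)
  fb <- context_fraction(arm_calls, focal, context, meta, gradesB)
  tab <- matrix(c(fa$n_with_context, fa$n_focal - fa$n_with_context,
                  fb$n_with_context, fb$n_focal - fb$n_with_context),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("with_context", "without")))
  list(table = tab, p = fisher_exact_two_tailed(tab),
       fractionA = fa$fraction, fractionB = fb$fraction)
}

#' Pairwise independence of arm events
#'
#' For each pair of events, cross-tabulates presence/absence across samples
#' and reports the odds ratio (Haldane +0.5 correction applied to all cells
#' when any cell is zero; the p-value is never computed on corrected
#' counts) and the two-tailed Fisher p. Raw p-values by default;
#' Benjamini-Hochberg adjustment optional.
#'
#' @param arm_calls an `arm_call_table`.
#' @param events character vector of >= 2 events ("arm:STATE").
#' @param meta,grades,samples stratum filters.
#' @param adjust "none" (default) or "BH".
#' @return data.frame: `event1`, `event2`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p` (and `p_adj` when adjusted).
#' @export
pairwise_event_independence <- function(arm_calls, events, meta = NULL,
                                        grades = NULL, samples = NULL,
                                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (length(events) < 2) stop("need at least 2 events")
  keep <- .filter_samples(arm_calls, meta, grades, samples)
  flags <- lapply(events, .event_flags, arm_calls = arm_calls,
                  samples = keep)
  names(flags) <- events
  pairs <- utils::combn(events, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    x <- flags[[pr[1]]]; y <- flags[[pr[2]]]
    a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
    or <- if (any(c(a, b, c, d) == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    else (a * d) / (b * c)
    data.frame(event1 = pr[1], event2 = pr[2], a = a, b = b, c = c, d = d,
               odds_ratio = or,
               p = fisher_exact_two_tailed(a, b, c, d),
               stringsAsFactors = FALSE)
  }))
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
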