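#' Arm-level copy-number calling from 500-kb bin calls
#'
#' Ingests discrete per-bin copy-number calls (G = gain, N = neutral,
#' L = loss) emitted by low-pass WGS segmentation, applies sample QC, and
#' calls arm-level events. An arm is a *full-arm* gain when the number of
#' gained bins is at least the number of bins on the arm minus 3 (no more
#' than 3 non-gained bins permitted); full-arm losses are defined
#' analogously. An arm counts as gained at all (full or partial) when it
#' carries a run of at least `min_run` consecutive gained bins.
#'
#' @name cna-calls
NULL

.GNL <- c("G", "N", "L")

#' Construct a bin-call matrix
#'
#' @param bins `bin_grid` rows matching the matrix rows (may carry an `arm`
#'   column from [assign_bins_to_arms()]).
#' @param calls character matrix, bins x samples, values in G/N/L.
#' @return Object of class `bin_call_matrix`: list with `bins`, `samples`,
#'   `calls`.
#' @export
bin_call_matrix <- function(bins, calls) {
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(bins))
    stop("calls has ", nrow(calls), " rows but bin grid has ", nrow(bins))
  if (ncol(calls) > 0 && is.null(colnames(calls)))
    stop("calls must have sample column names")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]),
               collapse = ", "))
  bad <- which(!calls %in% .GNL)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(calls)) + 1
    j <- ((bad[1] - 1) %/% nrow(calls)) + 1
    stop(sprintf(
      "invalid call '%s' at bin %s:%d-%d, sample '%s' (expected G, N or L)",
      calls[bad[1]], bins$chrom[i], bins$start[i], bins$end[i],
      colnames(calls)[j]))
  }
  structure(list(bins = bins,
                 samples = if (ncol(calls)) colnames(calls)
                           else character(0),
                 calls = calls),
            class = "bin_call_matrix")
}

#' @export
print.bin_call_matrix <- function(x, ...) {
  cat(sprintf("<bin_call_matrix: %d bins x %d samples>\n",
              nrow(x$calls), ncol(x$calls)))
  invisible(x)
}

#' Read a bin-call matrix from TSV
#'
#' Expected layout: columns `chrom`, `start`, `end`, then one column per
#' sample with values G/N/L. When a reference `bin_grid` is supplied the
#' file's bins must reconcile exactly against it.
#'
#' @param path TSV path.
#' @param bins optional reference `bin_grid` (with or without `arm` column).
#' @return A `bin_call_matrix`.
#' @export
read_bin_call_matrix <- function(path, bins = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom"))
  df <- as.data.frame(dt)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("bin-call TSV must start with columns chrom, start, end")
  sample_cols <- setdiff(names(df), need)
  if (!length(sample_cols)) stop("no sample columns found")
  file_bins <- df[, need]
  if (!is.null(bins)) {
    if (nrow(bins) != nrow(file_bins) ||
        !all(bins$chrom == file_bins$chrom) ||
        !all(bins$start == file_bins$start) ||
        !all(bins$end == file_bins$end))
      stop("bin grid in file does not match the reference grid")
    file_bins <- bins
  } else {
    file_bins$index <- stats::ave(file_bins$start, file_bins$chrom,
                                  FUN = seq_along)
  }
  calls <- as.matrix(df[, sample_cols, drop = FALSE])
  bin_call_matrix(file_bins, calls)
}

#' Write a bin-call matrix to TSV
#'
#' @param x a `bin_call_matrix`.
#' @param path output path.
#' @export
write_bin_call_matrix <- function(x, path) {
  out <- data.frame(chrom = x$bins$chrom, start = x$bins$start,
                    end = x$bins$end, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(x$calls))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Sample-level QC
#'
#' Drops a sample when its GC-correction MAD is at or above `mad_max`
#' (strict `< 0.15` keeps, per the source pipeline's practice). A sample
#' whose observed/expected segmentation variance ratio exceeds
#' `variance_ratio_max` is flagged, never auto-dropped: such samples were
#' retained, with a note, in the cohorts this pipeline models.
#'
#' @param mad GC-correction mean absolute deviation.
#' @param observed_variance,expected_variance segmentation QC variances
#'   (optional; `NA` to skip the variance flag).
#' @param mad_max drop threshold (default 0.15, strict inequality keeps).
#' @param variance_ratio_max flag threshold on observed/expected (default 2).
#' @return list with `keep` (logical), `flags` (character vector), `reason`.
#' @export
qc_sample <- function(mad, observed_variance = NA_real_,
                      expected_variance = NA_real_,
                      mad_max = 0.15, variance_ratio_max = 2) {
  stopifnot(mad_max > 0, variance_ratio_max > 0, mad >= 0)
  flags <- character(0)
  keep <- TRUE
  reason <- NA_character_
  if (mad >= mad_max) {
    keep <- FALSE
    reason <- sprintf("mad %.4g >= %.4g", mad, mad_max)
  }
  if (!is.na(observed_variance) && !is.na(expected_variance) &&
      expected_variance > 0 &&
      observed_variance / expected_variance > variance_ratio_max)
    flags <- c(flags, "high_variance_ratio")
  list(keep = keep, flags = flags, reason = reason)
}

.longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Call one arm for one sample
#'
#' Implements the full-arm rule (gained bins >= arm bins - 3, and
#' analogously for losses) plus a minimum-run criterion for counting an arm
#' as gained/lost at all. A full-arm event always implies a non-neutral
#' state. When both a qualifying gain run and loss run exist, both are
#' recorded in the counts and GAIN takes precedence for `state`.
#'
#' @param calls character vector of G/N/L bin calls for one arm, in genomic
#'   order.
#' @param min_run minimum consecutive-bin run (default 6 bins = 3 Mb).
#' @return list: `state` (GAIN/LOSS/NEUTRAL), `full_arm`, `gained_bins`,
#'   `lost_bins`, `arm_bins`, `gain_run`, `loss_run`.
#' @export
call_arm <- function(calls, min_run = 6L) {
  n <- length(calls)
  if (n == 0) stop("empty arm")
  gained <- sum(calls == "G")
  lost <- sum(calls == "L")
  gain_run <- .longest_run(calls == "G")
  loss_run <- .longest_run(calls == "L")
  # the >=1 guard keeps degenerate arms of <=3 bins from counting an
  # all-neutral arm as a "full" event
  full_gain <- gained >= 1L && gained >= n - 3L
  full_loss <- lost >= 1L && lost >= n - 3L
  has_gain <- full_gain || gain_run >= min_run
  has_loss <- full_loss || loss_run >= min_run
  state <- if (has_gain) "GAIN" else if (has_loss) "LOSS" else "NEUTRAL"
  full_arm <- (state == "GAIN" && full_gain) || (state == "LOSS" && full_loss)
  list(state = state, full_arm = full_arm, gained_bins = gained,
       lost_bins = lost, arm_bins = n, gain_run = gain_run,
       loss_run = loss_run)
}

#' Call all arms for all samples
#'
#' @param x a `bin_call_matrix` whose bins carry an `arm` column.
#' @param arms arm definitions from [arm_table()]; excluded arms are
#'   skipped.
#' @param min_run passed to [call_arm()].
#' @return data.frame of class `arm_call_table`: one row per
#'   (sample, arm) with columns `sample_id`, `arm`, `state`, `full_arm`,
#'   `gained_bins`, `lost_bins`, `arm_bins`, `gain_run`, `loss_run`.
#' @export
call_arms <- function(x, arms, min_run = 6L) {
  stopifnot(inherits(x, "bin_call_matrix"))
  if (is.null(x$bins$arm)) stop("bins have no arm assignment; ",
                                "run assign_bins_to_arms() first")
  use_arms <- arms$arm[!arms$excluded]
  use_arms <- use_arms[use_arms %in% x$bins$arm]
  rows_by_arm <- lapply(use_arms, function(a) which(x$bins$arm == a))
  names(rows_by_arm) <- use_arms
  res <- vector("list", length(use_arms) * length(x$samples))
  k <- 0L
  for (s in x$samples) {
    col <- x$calls[, s]
    for (a in use_arms) {
      cc <- call_arm(col[rows_by_arm[[a]]], min_run = min_run)
      k <- k + 1L
      res[[k]] <- data.frame(sample_id = s, arm = a, state = cc$state,
                             full_arm = cc$full_arm,
                             gained_bins = cc$gained_bins,
                             lost_bins = cc$lost_bins,
                             arm_bins = cc$arm_bins,
                             gain_run = cc$gain_run,
                             loss_run = cc$loss_run,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(sample_id = character(0), arm = character(0),
                      state = character(0), full_arm = logical(0),
                      gained_bins = integer(0), lost_bins = integer(0),
                      arm_bins = integer(0), gain_run = integer(0),
                      loss_run = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("arm_call_table", "data.frame")
  out
}

#' Read per-lesion metadata
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `grade`,
#'   `preservation`.
#' @return data.frame.
#' @export
read_lesion_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "grade")
  if (!all(need %in% names(meta)))
    stop("metadata TSV must contain columns sample_id and grade")
  bad <- setdiff(meta$grade, pancarm_grades())
  if (length(bad)) stop("unknown grade(s): ", paste(bad, collapse = ", "))
  meta
}

#' The lesion-grade levels used throughout
#' @return character vector of grade codes.
#' @export
pancarm_grades <- function() {
  c("NORMAL", "LG_PANIN", "HG_PANIN", "LG_IPMN", "HG_IPMN",
    "MCN", "SCA", "PDAC")
}

.filter_samples <- function(arm_calls, meta = NULL, grades = NULL,
                            samples = NULL) {
  keep <- unique(arm_calls$sample_id)
  if (!is.null(grades)) {
    if (is.null(meta)) stop("grade filtering requires metadata")
    keep <- intersect(keep, meta$sample_id[meta$grade %in% grades])
  }
  if (!is.null(samples)) keep <- intersect(keep, samples)
  keep
}

#' Per-arm gain/loss frequencies in a cohort stratum
#'
#' The fraction for an arm is the number of samples with state GAIN (full or
#' partial) over all samples in the stratum; losses analogous. Denominators
#' count tumors (samples), not patients.
#'
#' @param arm_calls an `arm_call_table`.
#' @param meta optional metadata (required when `grades` given).
#' @param grades optional grade filter (character vector).
#' @param samples optional explicit sample filter.
#' @return data.frame: `arm`, `n`, `n_gain`, `n_loss`, `gain_frac`,
#'   `loss_frac`, ordered as in the arm table.
#' @export
cohort_arm_frequencies <- function(arm_calls, meta = NULL, grades = NULL,
                                   samples = NULL) {
  keep <- .filter_samples(arm_calls, meta, grades, samples)
  if (!length(keep)) stop("empty stratum after filtering")
  ac <- arm_calls[arm_calls$sample_id %in% keep, ]
  arms <- unique(ac$arm)
  out <- do.call(rbind, lapply(arms, function(a) {
    sub <- ac[ac$arm == a, ]
    data.frame(arm = a, n = nrow(sub),
               n_gain = sum(sub$state == "GAIN"),
               n_loss = sum(sub$state == "LOSS"),
               stringsAsFactors = FALSE)
  }))
  out$gain_frac <- out$n_gain / out$n
  out$loss_frac <- out$n_loss / out$n
  rownames(out) <- NULL
  out
}

#' Full vs partial breakdown of arm gains (or losses)
#'
#' @param arm_calls an `arm_call_table`.
#' @param arm arm name, e.g. "1q".
#' @param state "GAIN" (default) or "LOSS".
#' @param meta,grades,samples stratum filters as in
#'   [cohort_arm_frequencies()].
#' @return list with `n_full`, `n_partial`, `n_event`.
#' @export
full_vs_partial_breakdown <- function(arm_calls, arm, state = "GAIN",
                                      meta = NULL, grades = NULL,
                                      samples = NULL) {
  keep <- .filter_samples(arm_calls, meta, grades, samples)
  sub <- arm_calls[arm_calls$arm == arm & arm_calls$sample_id %in% keep &
                     arm_calls$state == state, ]
  list(n_full = sum(sub$full_arm), n_partial = sum(!sub$full_arm),
       n_event = nrow(sub))
}

#' Write an arm-call table to TSV
#' @param arm_calls an `arm_call_table`.
#' @param path output path.
#' @export
write_arm_calls <- function(arm_calls, path) {
  data.table::fwrite(as.data.frame(arm_calls), path, sep = "\t")
  invisible(path)
}

#' Read an arm-call table from TSV
#' @param path TSV written by [write_arm_calls()].
#' @return an `arm_call_table`.
#' @export
read_arm_calls <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  class(out) <- c("arm_call_table", "data.frame")
  out
}
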