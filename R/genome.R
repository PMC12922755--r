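#' Genome coordinate scaffolding
#'
#' Chromosomes, arms, 500-kb bins and named driver loci shared by all other
#' stages. Coordinates are 1-based inclusive throughout; BED files are
#' converted from 0-based half-open on read and back on write.
#'
#' @name genome-model
NULL

# Acrocentric short arms carry no informative sequence at low-pass WGS
# resolution and are excluded from arm-level reporting by default.
.ACROCENTRIC_P <- c("13p", "14p", "15p", "21p", "22p")

#' Construct a genome build
#'
#' @param chrom_info data.frame with columns `chrom`, `length` (bp) and
#'   `centromere` (bp, strictly inside the chromosome). Autosomes only.
#' @param name build identifier.
#' @return An object of class `genome_build`.
#' @export
genome_build <- function(chrom_info, name = "custom") {
  stopifnot(is.data.frame(chrom_info),
            all(c("chrom", "length", "centromere") %in% names(chrom_info)))
  ci <- as.data.frame(chrom_info)[, c("chrom", "length", "centromere")]
  ci$chrom <- as.character(ci$chrom)
  if (anyDuplicated(ci$chrom)) stop("duplicate chromosome names")
  if (any(ci$length <= 0)) stop("chromosome lengths must be > 0")
  if (any(ci$centromere <= 1 | ci$centromere >= ci$length))
    stop("centromere must lie strictly inside the chromosome")
  structure(list(name = name, chrom_info = ci), class = "genome_build")
}

#' The packaged hg19 build (chr1-chr22)
#'
#' Chromosome lengths and centromere midpoints derived from the UCSC hg19
#' cytoband/gap tables.
#'
#' @return A `genome_build`.
#' @export
hg19_build <- function() {
  path <- system.file("extdata", "hg19_chrom_info.tsv", package = "pancarm")
  ci <- utils::read.delim(path, stringsAsFactors = FALSE)
  genome_build(ci, name = "hg19")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build '%s': %d chromosomes, %.2f Gb>\n", x$name,
              nrow(x$chrom_info), sum(x$chrom_info$length) / 1e9))
  invisible(x)
}

#' Tile a genome build into fixed-width bins
#'
#' Bins are anchored at position 1 of each chromosome; the last bin of each
#' chromosome may be shorter. Ordering is deterministic: chromosomes in build
#' order, then ascending start.
#'
#' @param build a `genome_build`.
#' @param bin_size bin width in bp (default 500 kb).
#' @param chroms optional subset of chromosome names.
#' @return data.frame with columns `chrom`, `start`, `end`, `index`
#'   (ordinal within chromosome); one row per bin, class `bin_grid`.
#' @export
make_bins <- function(build, bin_size = 5e5, chroms = NULL) {
  stopifnot(inherits(build, "genome_build"), bin_size > 0)
  ci <- build$chrom_info
  if (!is.null(chroms)) {
    missing <- setdiff(chroms, ci$chrom)
    if (length(missing)) stop("unknown chromosome name(s): ",
                              paste(missing, collapse = ", "))
    ci <- ci[match(chroms, ci$chrom), ]
  }
  pieces <- lapply(seq_len(nrow(ci)), function(i) {
    len <- ci$length[i]
    n <- ceiling(len / bin_size)
    idx <- seq_len(n)
    data.frame(chrom = ci$chrom[i],
               start = (idx - 1) * bin_size + 1,
               end = pmin(idx * bin_size, len),
               index = idx,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  attr(bins, "bin_size") <- bin_size
  class(bins) <- c("bin_grid", "data.frame")
  bins
}

#' Chromosome arm definitions for a build
#'
#' The p arm spans 1..(centromere - 1) and the q arm
#' (centromere + 1)..length. Acrocentric short arms (13p, 14p, 15p, 21p,
#' 22p) are flagged `excluded`.
#'
#' @param build a `genome_build`.
#' @param exclude_acrocentric flag acrocentric p arms (default TRUE).
#' @return data.frame with columns `arm`, `chrom`, `arm_letter`, `start`,
#'   `end`, `excluded`.
#' @export
arm_table <- function(build, exclude_acrocentric = TRUE) {
  ci <- build$chrom_info
  chrom_label <- sub("^chr", "", ci$chrom)
  arms <- rbind(
    data.frame(arm = paste0(chrom_label, "p"), chrom = ci$chrom,
               arm_letter = "p", start = 1, end = ci$centromere - 1,
               stringsAsFactors = FALSE),
    data.frame(arm = paste0(chrom_label, "q"), chrom = ci$chrom,
               arm_letter = "q", start = ci$centromere + 1, end = ci$length,
               stringsAsFactors = FALSE))
  arms <- arms[order(match(arms$chrom, ci$chrom), arms$start), ]
  arms$excluded <- exclude_acrocentric & arms$arm %in% .ACROCENTRIC_P
  rownames(arms) <- NULL
  arms
}

#' Assign bins to chromosome arms
#'
#' A bin containing the centromere coordinate is left unassigned (`NA`); the
#' paper's source data do not state how such bins were handled, so they are
#' excluded rather than guessed.
#'
#' @param bins a `bin_grid`.
#' @param arms arm definitions from [arm_table()].
#' @return `bins` with an added `arm` column (`NA` for unassigned bins).
#' @export
assign_bins_to_arms <- function(bins, arms) {
  arm <- rep(NA_character_, nrow(bins))
  for (i in seq_len(nrow(arms))) {
    sel <- bins$chrom == arms$chrom[i] &
      bins$start >= arms$start[i] & bins$end <= arms$end[i]
    arm[sel] <- arms$arm[i]
  }
  bins$arm <- arm
  bins
}

#' Bins overlapping a locus
#'
#' @param locus list or one-row data.frame with `chrom`, `start`, `end`
#'   (1-based inclusive). A zero-width query (`start == end`) returns the
#'   single bin containing that coordinate.
#' @param bins a `bin_grid`.
#' @return Integer vector of row indices into `bins` with >= 1 bp overlap.
#' @export
overlapping_bins <- function(locus, bins) {
  stopifnot(locus$start <= locus$end)
  on_chr <- bins$chrom == locus$chrom
  if (!any(on_chr)) stop("locus chromosome not present in bin grid: ",
                         locus$chrom)
  chr_max <- max(bins$end[on_chr])
  if (locus$start < 1 || locus$end > chr_max)
    stop(sprintf("locus %s:%d-%d outside chromosome bounds (1-%d)",
                 locus$chrom, locus$start, locus$end, chr_max))
  which(on_chr & bins$start <= locus$end & bins$end >= locus$start)
}

#' Packaged driver loci
#'
#' The two minimal commonly gained regions on 1q, the broad 8q peak, and the
#' c-MYC gene body (hg19 coordinates).
#'
#' @return data.frame with columns `name`, `chrom`, `start`, `end`.
#' @export
pancarm_loci <- function() {
  data.frame(
    name  = c("1q23.2", "1q42.13", "8q24.21", "MYC"),
    chrom = c("chr1", "chr1", "chr8", "chr8"),
    start = c(159100001, 227000001, 127300001, 128747681),
    end   = c(160500000, 230700000, 131500000, 128755197),
    stringsAsFactors = FALSE)
}

#' Read loci from a BED file
#'
#' BED is 0-based half-open on disk; coordinates are converted to 1-based
#' inclusive on read.
#'
#' @param path BED file (3+ columns; column 4, when present, is the name).
#' @return data.frame with `name`, `chrom`, `start`, `end`.
#' @export
read_bed_loci <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file must have at least 3 columns")
  data.frame(
    name = if (ncol(bed) >= 4) as.character(bed[[4]])
           else paste0("locus_", seq_len(nrow(bed))),
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]]),
    stringsAsFactors = FALSE)
}

#' Write loci to a BED file (converting to 0-based half-open)
#'
#' @param loci data.frame with `name`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param path output path.
#' @export
write_bed_loci <- function(loci, path) {
  bed <- data.frame(loci$chrom, loci$start - 1L, loci$end, loci$name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
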