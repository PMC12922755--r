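#' Duplex UID-consensus mutation calling
#'
#' Calls somatic mutations from UID-barcoded amplicon reads. The first 14
#' nucleotides of read 1 are the exogenous barcode (UID); reads sharing a
#' UID form a Watson and a Crick strand family, distinguished by the
#' orientation of the insert relative to the UID. A duplex mutation must be
#' present in more than 80% of BOTH strand families (strictly greater).
#' Final calls additionally require more than two mutant template molecules
#' (>= 3 duplex groups), template coverage of at least 5 duplex groups,
#' distance of at least 30 bp from both ends of the molecule, and at least
#' two confirmed-somatic annotations in the catalog lookup.
#'
#' @name duplex-caller
NULL

#' Extract the UID from a read
#'
#' @param read1 read-1 sequence(s); the first `uid_length` bases are the
#'   exogenous barcode.
#' @param uid_length barcode length (default 14).
#' @return list: `uid`, `insert` (read 1 with the barcode removed).
#' @export
extract_uid <- function(read1, uid_length = 14L) {
  if (any(nchar(read1) <= uid_length))
    stop("read shorter than or equal to the ", uid_length, "-nt UID")
  list(uid = substr(read1, 1L, uid_length),
       insert = substr(read1, uid_length + 1L, nchar(read1)))
}

.count_mismatches <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  sum(strsplit(substr(a, 1, n), "")[[1]] != strsplit(substr(b, 1, n),
                                                     "")[[1]]) +
    abs(nchar(a) - nchar(b))
}

#' Assign a read to the Watson or Crick strand
#'
#' WATSON when the UID-bearing read aligns to the amplicon in plus
#' orientation (fewer mismatches against the reference than against its
#' reverse complement); CRICK otherwise. Deterministic; an exact mismatch
#' tie is called WATSON.
#'
#' @param insert the read sequence after UID removal.
#' @param ref_seq amplicon plus-strand reference sequence.
#' @return "WATSON" or "CRICK".
#' @export
assign_strand <- function(insert, ref_seq) {
  fwd <- .count_mismatches(insert, ref_seq)
  rev <- .count_mismatches(insert, .revcomp(ref_seq))
  if (fwd <= rev) "WATSON" else "CRICK"
}

# per-position base-count matrix (4 x L) for a family of plus-oriented
# insert sequences
.base_tally <- function(inserts, L) {
  mat <- do.call(rbind, strsplit(inserts, ""))
  tall <- matrix(0L, 4, L, dimnames = list(.BASES, NULL))
  for (b in .BASES) tall[b, ] <- colSums(mat == b)
  tall
}

#' Group reads into duplex (Watson/Crick) families
#'
#' One group per (amplicon, UID). Crick-strand reads are reverse-
#' complemented into plus orientation before tallying, so both families'
#' base tallies are amplicon-coordinate aligned. Groups with only one
#' strand are retained but can never support a duplex call. Grouping is
#' invariant to read order.
#'
#' @param reads data.frame with columns `seq` (read 1 including UID) and
#'   `amplicon_id`.
#' @param amplicons amplicon table (needs `amplicon_id`, `ref_seq`).
#' @param uid_length barcode length (default 14).
#' @return list of duplex groups, each: `uid`, `amplicon_id`, `watson`,
#'   `crick` (each NULL or list(n_reads, tally)), sorted by
#'   (amplicon_id, uid).
#' @export
build_duplex_groups <- function(reads, amplicons, uid_length = 14L) {
  if (!nrow(reads)) return(list())
  ex <- extract_uid(reads$seq, uid_length)
  reads$uid <- ex$uid
  reads$insert <- ex$insert
  out <- list()
  for (aid in sort(unique(reads$amplicon_id))) {
    amp <- amplicons[amplicons$amplicon_id == aid, ]
    if (!nrow(amp)) stop("reads reference unknown amplicon: ", aid)
    sub <- reads[reads$amplicon_id == aid, ]
    strands <- vapply(sub$insert, assign_strand, "",
                      ref_seq = amp$ref_seq, USE.NAMES = FALSE)
    L <- nchar(amp$ref_seq)
    for (u in sort(unique(sub$uid))) {
      grp <- list(uid = u, amplicon_id = aid, watson = NULL, crick = NULL)
      for (st in c("WATSON", "CRICK")) {
        ins <- sub$insert[sub$uid == u & strands == st]
        if (!length(ins)) next
        if (st == "CRICK") ins <- .revcomp(ins)
        fam <- list(n_reads = length(ins), tally = .base_tally(ins, L))
        if (st == "WATSON") grp$watson <- fam else grp$crick <- fam
      }
      out[[length(out) + 1L]] <- grp
    }
  }
  out
}

#' Test duplex support for a variant in one group
#'
#' Supported iff the same alt allele exceeds 80% of reads in the Watson
#' family AND 80% in the Crick family (strictly greater), both families
#' present with at least `min_reads_per_strand` reads.
#'
#' @param group a duplex group from [build_duplex_groups()].
#' @param pos 1-based position within the amplicon.
#' @param ref reference base at `pos`.
#' @param min_frac strand-family consensus fraction (default 0.8, strict).
#' @param min_reads_per_strand family-size floor (default 1).
#' @return list: `supported`, `alt` (NA when unsupported).
#' @export
call_duplex_variant <- function(group, pos, ref, min_frac = 0.8,
                                min_reads_per_strand = 1L) {
  if (is.null(group$watson) || is.null(group$crick) ||
      group$watson$n_reads < min_reads_per_strand ||
      group$crick$n_reads < min_reads_per_strand)
    return(list(supported = FALSE, alt = NA_character_))
  alts <- setdiff(.BASES, ref)
  for (alt in alts) {
    fw <- group$watson$tally[alt, pos] / group$watson$n_reads
    fc <- group$crick$tally[alt, pos] / group$crick$n_reads
    if (fw > min_frac && fc > min_frac)
      return(list(supported = TRUE, alt = alt))
  }
  list(supported = FALSE, alt = NA_character_)
}

#' Scan all groups of one amplicon for candidate duplex variants
#'
#' @param groups duplex groups for one amplicon.
#' @param amplicon the amplicon row.
#' @param min_frac,min_reads_per_strand passed to [call_duplex_variant()].
#' @return data.frame of candidates: `amplicon_id`, `offset`, `chrom`,
#'   `pos`, `ref`, `alt`, `mutant_templates`, `total_templates` (duplex
#'   groups with both strands).
#' @export
scan_duplex_candidates <- function(groups, amplicon, min_frac = 0.8,
                                   min_reads_per_strand = 1L) {
  L <- nchar(amplicon$ref_seq)
  refs <- strsplit(amplicon$ref_seq, "")[[1]]
  duplexable <- Filter(function(g) !is.null(g$watson) && !is.null(g$crick),
                       groups)
  total <- length(duplexable)
  # mask of reference-base entries so only non-reference alleles count
  ref_mask <- vapply(seq_len(L), function(p) .BASES == refs[p],
                     logical(4))
  hits <- list()
  for (g in duplexable) {
    if (g$watson$n_reads < min_reads_per_strand ||
        g$crick$n_reads < min_reads_per_strand) next
    # positions where some non-reference base clears the strand threshold
    # in both families (vectorized over the 4 x L tallies)
    supp <- (g$watson$tally / g$watson$n_reads > min_frac) &
      (g$crick$tally / g$crick$n_reads > min_frac) & !ref_mask
    if (!any(supp)) next
    idx <- which(supp, arr.ind = TRUE)
    hits[[length(hits) + 1L]] <- data.frame(offset = idx[, 2],
                                            alt = .BASES[idx[, 1]],
                                            stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(amplicon_id = character(0), offset = integer(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      mutant_templates = integer(0),
                      total_templates = integer(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, hits)
  agg <- stats::aggregate(list(mutant_templates = hits$offset),
                          by = list(offset = hits$offset, alt = hits$alt),
                          FUN = length)
  data.frame(amplicon_id = amplicon$amplicon_id, offset = agg$offset,
             chrom = amplicon$chrom,
             pos = amplicon$start + agg$offset - 1L,
             ref = refs[agg$offset], alt = agg$alt,
             mutant_templates = agg$mutant_templates,
             total_templates = total, stringsAsFactors = FALSE)
}

#' Filter candidate duplex calls into final mutation calls
#'
#' A candidate passes when: mutant duplex groups > 2 (i.e. >= 3); template
#' coverage (duplex groups at the position) >= 5; the position is >= 30 bp
#' from both ends of the molecule; and the catalog lookup reports >= 2
#' annotations with a confirmed-somatic flag. Every failed criterion is
#' recorded.
#'
#' @param candidates from [scan_duplex_candidates()] (any amplicons).
#' @param cosmic lookup data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `annotation_count`, `confirmed_somatic`, optional
#'   `genome_wide_study`).
#' @param amplicons amplicon table.
#' @param min_mut_templates default 3 ("more than two").
#' @param min_coverage template coverage floor (default 5).
#' @param min_end_distance distance from both molecule ends (default 30).
#' @param min_cosmic_annotations default 2.
#' @param genome_wide_only restrict to genome-wide-study annotations
#'   (default FALSE).
#' @return data.frame: candidate columns plus `filters` (semicolon list of
#'   failed filters, "" when clean) and `pass`.
#' @export
apply_filters <- function(candidates, cosmic, amplicons,
                          min_mut_templates = 3L, min_coverage = 5L,
                          min_end_distance = 30L,
                          min_cosmic_annotations = 2L,
                          genome_wide_only = FALSE) {
  if (!nrow(candidates)) {
    candidates$filters <- character(0)
    candidates$pass <- logical(0)
    return(candidates)
  }
  filters <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    amp <- amplicons[amplicons$amplicon_id == cc$amplicon_id, ]
    if (!nrow(amp)) stop("candidate outside all amplicons: ",
                         cc$amplicon_id)
    fail <- character(0)
    if (cc$mutant_templates < min_mut_templates)
      fail <- c(fail, "min_mut_templates")
    if (cc$total_templates < min_coverage) fail <- c(fail, "coverage")
    L <- nchar(amp$ref_seq)
    if (cc$offset < min_end_distance + 1L ||
        L - cc$offset < min_end_distance)
      fail <- c(fail, "end_distance")
    hit <- cosmic[cosmic$chrom == cc$chrom & cosmic$pos == cc$pos &
                    cosmic$ref == cc$ref & cosmic$alt == cc$alt, ]
    if (genome_wide_only && "genome_wide_study" %in% names(hit))
      hit <- hit[hit$genome_wide_study, ]
    n_ann <- if (nrow(hit)) sum(hit$annotation_count[hit$confirmed_somatic])
             else 0L
    if (n_ann < min_cosmic_annotations) fail <- c(fail, "cosmic")
    filters[i] <- paste(fail, collapse = ";")
  }
  candidates$filters <- filters
  candidates$pass <- filters == ""
  candidates
}

#' Is a sample assessable for mutation calling?
#'
#' True iff at least `min_templates` (default 10) distinct duplex groups
#' overlap a KRAS amplicon.
#'
#' @param groups duplex groups for the sample.
#' @param amplicons amplicon table (with `gene`).
#' @param gene gene gating assessability (default "KRAS").
#' @param min_templates default 10 (inclusive).
#' @return logical.
#' @export
sample_assessable <- function(groups, amplicons, gene = "KRAS",
                              min_templates = 10L) {
  gene_amps <- amplicons$amplicon_id[amplicons$gene == gene]
  n <- sum(vapply(groups, function(g) g$amplicon_id %in% gene_amps, TRUE))
  n >= min_templates
}

#' End-to-end duplex calling for one sample's reads
#'
#' @param reads data.frame (`seq`, `amplicon_id`) or path to a FASTQ file
#'   written by [write_duplex_fastq()].
#' @param amplicons amplicon table.
#' @param cosmic annotation lookup.
#' @param ... thresholds passed to [apply_filters()].
#' @return list: `assessable`, `candidates`, `calls` (passing candidates),
#'   `genes` (genes with a passing call), `n_groups`.
#' @export
duplex_call_sample <- function(reads, amplicons, cosmic, ...) {
  if (is.character(reads)) reads <- read_duplex_fastq(reads)
  groups <- build_duplex_groups(reads, amplicons)
  assessable <- sample_assessable(groups, amplicons)
  cand <- do.call(rbind, lapply(sort(unique(reads$amplicon_id)),
                                function(aid) {
    amp <- amplicons[amplicons$amplicon_id == aid, ]
    gs <- Filter(function(g) g$amplicon_id == aid, groups)
    scan_duplex_candidates(gs, amp)
  }))
  if (is.null(cand))
    cand <- scan_duplex_candidates(list(),
                                   amplicons[1, , drop = FALSE])[0, ]
  cand <- apply_filters(cand, cosmic, amplicons, ...)
  calls <- cand[cand$pass, , drop = FALSE]
  genes <- unique(amplicons$gene[match(calls$amplicon_id,
                                       amplicons$amplicon_id)])
  list(assessable = assessable, candidates = cand, calls = calls,
       genes = genes, n_groups = length(groups))
}

#' Per-sample gene status and cross-tab against 1q gain
#'
#' Builds the per-sample mutated-gene table from passing duplex calls and
#' cross-tabulates 1q gain against mutation of any of CDKN2A, TP53 or
#' SMAD4. Samples with calls but no arm call/metadata are dropped with a
#' warning.
#'
#' @param calls_by_sample named list of [duplex_call_sample()] results.
#' @param arm_calls an `arm_call_table` covering the same samples.
#' @param meta metadata data.frame.
#' @param ts_genes tumor-suppressor gene set for the cross-tab.
#' @return list: `gene_status` (sample x gene logical data.frame),
#'   `crosstab` (2x2 matrix 1q gain x any TS mutation), `frac_1q_without_ts`,
#'   `frac_ts_without_1q`.
#' @export
lesion_mutation_table <- function(calls_by_sample, arm_calls, meta,
                                  ts_genes = c("CDKN2A", "TP53", "SMAD4")) {
  samples <- names(calls_by_sample)
  known <- intersect(samples, meta$sample_id)
  if (length(known) < length(samples))
    warning("dropping ", length(samples) - length(known),
            " sample(s) absent from metadata")
  all_genes <- sort(unique(unlist(lapply(calls_by_sample,
                                         function(x) x$genes))))
  if (!length(all_genes)) all_genes <- ts_genes
  if (!length(known)) {
    empty <- matrix(FALSE, 0, length(all_genes),
                    dimnames = list(NULL, all_genes))
    return(list(gene_status = as.data.frame(empty),
                crosstab = matrix(0L, 2, 2,
                                  dimnames = list(c("1q_gain",
                                                    "no_1q_gain"),
                                                  c("ts_mut",
                                                    "no_ts_mut"))),
                frac_1q_without_ts = NA_real_,
                frac_ts_without_1q = NA_real_))
  }
  gene_status <- do.call(rbind, lapply(known, function(s) {
    g <- calls_by_sample[[s]]$genes
    stats::setNames(as.data.frame(t(all_genes %in% g)), all_genes)
  }))
  rownames(gene_status) <- known
  has_ts <- apply(gene_status[, intersect(ts_genes, all_genes),
                              drop = FALSE], 1, any)
  sub <- arm_calls[arm_calls$arm == "1q", ]
  gain_1q <- sub$state[match(known, sub$sample_id)] == "GAIN"
  gain_1q[is.na(gain_1q)] <- FALSE
  tab <- matrix(c(sum(gain_1q & has_ts), sum(gain_1q & !has_ts),
                  sum(!gain_1q & has_ts), sum(!gain_1q & !has_ts)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("1q_gain", "no_1q_gain"),
                                c("ts_mut", "no_ts_mut")))
  list(gene_status = gene_status, crosstab = tab,
       frac_1q_without_ts = if (sum(gain_1q)) mean(!has_ts[gain_1q])
                            else NA_real_,
       frac_ts_without_1q = if (sum(has_ts)) mean(!gain_1q[has_ts])
                            else NA_real_)
}

#' Write reads as FASTQ (read 1; UID is the first 14 bases)
#'
#' @param reads data.frame with `read_id`, `amplicon_id`, `seq`.
#' @param path output FASTQ path.
#' @export
write_duplex_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- paste0(reads$read_id, " amplicon=", reads$amplicon_id)
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read duplex FASTQ back into the read data.frame
#'
#' @param path FASTQ written by [write_duplex_fastq()].
#' @return data.frame: `read_id`, `amplicon_id`, `seq`.
#' @export
read_duplex_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- names(x)
  read_id <- sub(" .*", "", ids)
  amplicon_id <- sub(".*amplicon=", "", ids)
  data.frame(read_id = read_id, amplicon_id = amplicon_id,
             seq = as.character(x), stringsAsFactors = FALSE)
}
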