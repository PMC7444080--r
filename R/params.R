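#' UMI primer/architecture design
#'
#' Describes the tagging primer used to label individual molecules: a 5'
#' universal primer (used to amplify all tagged molecules uniformly), a
#' structured UMI, and a 3' gene-specific sequence. The UMI pattern is a
#' string over A/C/G/T/N where N positions are random and fixed bases act as
#' a built-in structure check (e.g. `"NNNNTGNNNN"`): a candidate UMI whose
#' fixed positions do not match exactly is rejected, which screens out reads
#' whose UMI region was misread.
#'
#' @param universal_primer 5' universal primer sequence (non-empty).
#' @param umi_pattern UMI pattern over A/C/G/T/N, length 10-12, with at
#'   least one fixed (non-N) base.
#' @param gene_specific 3' gene-specific primer sequence (non-empty).
#' @param max_primer_mismatches maximum edit distance (substitutions and
#'   indels) tolerated when locating the universal primer in a read.
#'   Default 3, suited to raw long reads; use 1 for accurate short reads.
#' @param reverse_primer optional reverse PCR primer (used by design
#'   validation and two-ended tagging).
#' @return an object of class `umi_design`.
#' @seealso [validate_design()], [extract_umi()]
#' @export
umi_design <- function(universal_primer,
                       umi_pattern = "NNNNTGNNNN",
                       gene_specific = "",
                       max_primer_mismatches = 3L,
                       reverse_primer = "") {
  d <- structure(list(
    universal_primer = toupper(universal_primer),
    umi_pattern = toupper(umi_pattern),
    gene_specific = toupper(gene_specific),
    max_primer_mismatches = as.integer(max_primer_mismatches),
    reverse_primer = toupper(reverse_primer)
  ), class = "umi_design")
  if (!nzchar(d$universal_primer)) stop("universal_primer must be non-empty")
  if (grepl("[^ACGTN]", d$umi_pattern)) stop("umi_pattern must be over A/C/G/T/N")
  d
}

#' @export
print.umi_design <- function(x, ...) {
  cat("UMI design:\n")
  cat("  universal primer:", x$universal_primer, "\n")
  cat("  UMI pattern:     ", x$umi_pattern, "\n")
  if (nzchar(x$gene_specific)) cat("  gene-specific:   ", x$gene_specific, "\n")
  cat("  max primer edits:", x$max_primer_mismatches, "\n")
  v <- validate_design(x)
  if (length(v)) cat("  violations:", paste(v, collapse = "; "), "\n")
  invisible(x)
}

#' Alignment scoring parameters
#'
#' Scoring for the semi-global aligner with a two-piece gap cost: a gap of
#' length L costs `min(gap_open + L * gap_extend,
#' long_gap_open + L * long_gap_extend)`. The long-gap piece makes
#' multi-kilobase deletions affordable as single CIGAR runs, which is what
#' lets large repair-outcome deletions survive alignment intact.
#'
#' @param match match score (positive).
#' @param mismatch mismatch penalty (positive).
#' @param gap_open,gap_extend short-gap affine penalties.
#' @param long_gap_open,long_gap_extend long-gap affine penalties;
#'   `long_gap_extend` must be strictly smaller than `gap_extend`. The
#'   default long-gap extension of 0 makes the cost of a deletion saturate
#'   at `long_gap_open`: with end-clipping allowed, any per-base long-gap
#'   charge eventually makes clipping a flank cheaper than paying for a
#'   multi-kilobase deletion, which would silently discard the very repair
#'   outcomes this pipeline exists to count (a 5.5-kb deletion with a
#'   ~0.6-kb flank is a realistic case).
#' @param min_score_frac mappability floor: an alignment scoring below
#'   `min_score_frac * match * query_length` is reported unmapped.
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2L, mismatch = 4L,
                             gap_open = 4L, gap_extend = 2L,
                             long_gap_open = 24L, long_gap_extend = 0L,
                             min_score_frac = 0.3) {
  p <- structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                      gap_open = as.integer(gap_open),
                      gap_extend = as.integer(gap_extend),
                      long_gap_open = as.integer(long_gap_open),
                      long_gap_extend = as.integer(long_gap_extend),
                      min_score_frac = min_score_frac),
                 class = "alignment_params")
  if (any(unlist(p[2:6]) < 0)) stop("penalties must be >= 0")
  if (p$long_gap_extend >= p$gap_extend)
    stop("long_gap_extend must be < gap_extend (long gaps eventually cheaper)")
  p
}

#' Variant-calling and filtering thresholds
#'
#' @param min_reads minimum reads per UMI group for the group to be
#'   eligible for consensus calling (default 5).
#' @param consensus_fraction minimum fraction of a group's base calls at a
#'   position that must agree on an alternative base for an SNV (or small
#'   indel) to be called in that group. Default 0.75, so a 5-read group
#'   needs at least 4 concordant reads.
#' @param min_sv_len minimum length (bp) for an event to be classed as a
#'   structural variant; events of 1 to `min_sv_len - 1` bp are small
#'   indels. Default 31 (SVs are events > 30 bp).
#' @param sv_support_fraction minimum fraction of a group's reads that must
#'   carry a matching SV (same kind, breakpoints within `breakpoint_tol`).
#' @param breakpoint_tol tolerance (bp) when matching SV breakpoints within
#'   a group and when merging SVs across groups.
#' @param min_group_identity group filter: minimum mean read-to-consensus
#'   identity for a group to be kept.
#' @param min_depth,min_qual,vaf_bounds population-level VCF filter:
#'   minimum supporting-group count, minimum variant quality, and allowed
#'   VAF interval.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(min_reads = 5L, consensus_fraction = 0.75,
                          min_sv_len = 31L, sv_support_fraction = 0.6,
                          breakpoint_tol = 10L, min_group_identity = 0.7,
                          min_depth = 1L, min_qual = 0, vaf_bounds = c(0, 1)) {
  p <- structure(list(min_reads = as.integer(min_reads),
                      consensus_fraction = consensus_fraction,
                      min_sv_len = as.integer(min_sv_len),
                      sv_support_fraction = sv_support_fraction,
                      breakpoint_tol = as.integer(breakpoint_tol),
                      min_group_identity = min_group_identity,
                      min_depth = as.integer(min_depth),
                      min_qual = min_qual,
                      vaf_bounds = vaf_bounds),
                 class = "filter_params")
  stopifnot(p$min_reads >= 1L, p$min_sv_len >= 1L,
            p$consensus_fraction > 0, p$consensus_fraction <= 1,
            p$sv_support_fraction > 0, p$sv_support_fraction <= 1)
  p
}
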