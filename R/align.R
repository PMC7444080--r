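# Read-to-amplicon alignment. Full dynamic programming (no seeding
# heuristics): amplicon references are at most a few kilobases, and
# correctness of large-deletion representation matters more than speed.

#' Align a read to the amplicon reference
#'
#' Semi-global alignment under a two-piece gap cost (see
#' [alignment_params()]): the reference ends are free and the query ends may
#' be soft-clipped, so the aligner finds the best contiguous placement of
#' the read on the amplicon. Both strands are tried and the better-scoring
#' one kept. A single contiguous deletion of any length is representable as
#' one `D` run thanks to the long-gap piece of the cost.
#'
#' @param query read sequence (plain character string).
#' @param reference reference sequence.
#' @param params [alignment_params()].
#' @param read_id optional id stored in the result.
#' @return an object of class `umivar_alignment`: list with `read_id`,
#'   `mapped`, `strand` (`"+"`/`"-"`), `ref_start`/`ref_end` (0-based
#'   half-open), `cigar` (over `=`, `X`, `I`, `D`, `S`; for `-` strand
#'   alignments the CIGAR refers to the reverse-complemented query, as in
#'   SAM), `score`, and `query` (the strand-oriented query sequence).
#' @export
align_read <- function(query, reference, params = alignment_params(),
                       read_id = NA_character_, query_rc = NULL) {
  stopifnot(nzchar(query), nzchar(reference))
  query <- toupper(query)
  fwd <- align_dp_cpp(query, reference, params$match, params$mismatch,
                      params$gap_open, params$gap_extend,
                      params$long_gap_open, params$long_gap_extend)
  rcq <- if (is.null(query_rc)) revcomp(query) else query_rc
  rev <- align_dp_cpp(rcq, reference, params$match, params$mismatch,
                      params$gap_open, params$gap_extend,
                      params$long_gap_open, params$long_gap_extend)
  if (rev$score > fwd$score) {
    hit <- rev; strand <- "-"; oriented <- rcq
  } else {
    hit <- fwd; strand <- "+"; oriented <- query
  }
  floor_score <- params$min_score_frac * params$match * nchar(query)
  structure(list(read_id = read_id,
                 mapped = hit$score >= floor_score,
                 strand = strand,
                 ref_start = hit$r_start, ref_end = hit$r_end,
                 query_start = hit$q_start, query_end = hit$q_end,
                 cigar = hit$cigar, score = hit$score,
                 query = oriented,
                 ops = ops_list(hit$cigar)),
            class = "umivar_alignment")
}

# parsed CIGAR as parallel vectors (internal hot-path representation)
ops_list <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[M=XIDS]", cigar))[[1]]
  list(len = len, op = op, n = length(len))
}

aln_ops <- function(a) if (!is.null(a$ops)) a$ops else ops_list(a$cigar)

#' @export
print.umivar_alignment <- function(x, ...) {
  cat(sprintf("alignment %s: %s strand %s ref [%d,%d) score %d\n  %s\n",
              x$read_id, if (x$mapped) "mapped" else "UNMAPPED", x$strand,
              x$ref_start, x$ref_end, x$score, x$cigar))
  invisible(x)
}

#' Split a CIGAR string into operation lengths and codes
#'
#' @param cigar CIGAR string over `M=XIDS`.
#' @return data.frame with columns `len` (integer) and `op` (character).
#' @export
cigar_ops <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[M=XIDS]", cigar))[[1]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

# query/reference base counts consumed by a CIGAR (soft clips consume query)
cigar_consumed <- function(cigar) {
  ops <- cigar_ops(cigar)
  list(query = sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")]),
       ref = sum(ops$len[ops$op %in% c("M", "=", "X", "D")]))
}

# Per-read indel events extracted from an alignment.
# Returns data.frame(kind, start, end, len, seq) in 0-based ref coords;
# insertions have start == end (anchored before ref position start).
alignment_events <- function(aln) {
  ops <- aln_ops(aln)
  # ref/query position before each op
  radv <- ifelse(ops$op %in% c("M", "=", "X", "D"), ops$len, 0L)
  qadv <- ifelse(ops$op %in% c("M", "=", "X", "I"), ops$len, 0L)
  rpos <- aln$ref_start + c(0L, cumsum(radv))[seq_len(ops$n)]
  qpos <- aln$query_start + c(0L, cumsum(qadv))[seq_len(ops$n)]
  isD <- ops$op == "D"
  isI <- ops$op == "I"
  kind <- c(rep("deletion", sum(isD)), rep("insertion", sum(isI)))
  start <- c(rpos[isD], rpos[isI])
  len <- c(ops$len[isD], ops$len[isI])
  end <- c(rpos[isD] + ops$len[isD], rpos[isI])
  ins_seq <- if (any(isI))
    substring(aln$query, qpos[isI] + 1L, qpos[isI] + ops$len[isI]) else character(0)
  seq <- c(rep("", sum(isD)), ins_seq)
  data.frame(kind = kind, start = start, end = end, len = len, seq = seq,
             stringsAsFactors = FALSE)
}

# Left-align an indel against the reference (and inserted sequence):
# shift while the base entering the event from the left equals the base
# leaving it on the right. Standard VCF-style normalisation.
left_align_event <- function(kind, start, len, seq, reference) {
  refb <- function(p) substr(reference, p + 1L, p + 1L)  # 0-based
  if (kind == "deletion") {
    while (start > 0L && refb(start - 1L) == refb(start + len - 1L)) {
      start <- start - 1L
    }
  } else {
    while (start > 0L && refb(start - 1L) == substr(seq, len, len)) {
      seq <- paste0(refb(start - 1L), substr(seq, 1L, len - 1L))
      start <- start - 1L
    }
  }
  list(start = start, seq = seq)
}

#' Realign a poorly aligned internal read segment against the minus strand
#'
#' Inversions do not leave a clean CIGAR signature: the inverted middle of a
#' read either aligns with very low identity or is soft-clipped. This
#' function scans the primary alignment for such a segment (long soft clip,
#' or an internal query stretch dominated by mismatches/insertions), and
#' realigns it to the reference's reverse complement. Evidence is reported
#' when the minus-strand placement is nested between plus-strand flanking
#' alignments from the same read.
#'
#' @param primary [align_read()] result for the read (plus-strand oriented
#'   query is used).
#' @param query the read sequence as aligned (i.e. `primary$query`).
#' @param reference reference sequence.
#' @param params [alignment_params()].
#' @param min_sv_len minimum inverted-segment length to consider.
#' @param min_identity identity threshold below which an internal aligned
#'   stretch is considered a candidate inverted segment.
#' @return `NULL`, or a list with `ref_start`/`ref_end` (0-based half-open
#'   inverted interval), `middle`, `left_flank`, `right_flank` alignments.
#' @export
detect_inversion <- function(primary, query, reference,
                             params = alignment_params(),
                             min_sv_len = 31L, min_identity = 0.55) {
  if (!primary$mapped) return(NULL)
  qlen <- nchar(query)
  cand <- candidate_segments(primary, qlen, min_sv_len, min_identity)
  if (!nrow(cand)) return(NULL)
  for (i in seq_len(nrow(cand))) {
    qs <- cand$qstart[i]; qe <- cand$qend[i]
    seg <- substr(query, qs + 1L, qe)
    mid <- align_dp_only(revcomp(seg), reference, params)
    if (mid$score < params$min_score_frac * params$match * nchar(seg)) next
    lf <- if (qs >= 15L) align_dp_only(substr(query, 1L, qs), reference, params) else NULL
    rf <- if (qlen - qe >= 15L) align_dp_only(substr(query, qe + 1L, qlen), reference, params) else NULL
    if (is.null(lf) || is.null(rf)) next
    flank_floor <- function(a, len) a$score >= params$min_score_frac * params$match * len
    if (!flank_floor(lf, qs) || !flank_floor(rf, qlen - qe)) next
    tol <- 40L
    nested <- lf$r_end <= mid$r_start + tol && mid$r_end <= rf$r_start + tol &&
      lf$r_start <= mid$r_start && mid$r_end <= rf$r_end
    if (nested) {
      return(list(ref_start = mid$r_start, ref_end = mid$r_end,
                  middle = mid, left_flank = lf, right_flank = rf))
    }
  }
  NULL
}

# raw DP hit on the + strand only (no strand search, no class wrapper)
align_dp_only <- function(query, reference, params) {
  align_dp_cpp(toupper(query), reference, params$match, params$mismatch,
               params$gap_open, params$gap_extend,
               params$long_gap_open, params$long_gap_extend)
}

# Candidate query intervals that may hide an inverted segment:
# long soft clips at either end, and internal low-identity stretches
# (windows of the aligned region dominated by X/I ops).
candidate_segments <- function(aln, qlen, min_sv_len, min_identity) {
  ops <- aln_ops(aln)
  qs <- integer(0); qe <- integer(0)
  if (aln$query_start >= min_sv_len) { qs <- 0L; qe <- aln$query_start }
  if (qlen - aln$query_end >= min_sv_len) {
    qs <- c(qs, aln$query_end); qe <- c(qe, qlen)
  }
  # internal scan: contiguous X/I stretches, merged across short = runs
  if (any(ops$op %in% c("X", "I"))) {
    qpos <- aln$query_start
    seg_start <- NA_integer_
    seg_end <- NA_integer_
    good_run <- 0L
    for (i in seq_len(ops$n)) {
      len <- ops$len[i]; op <- ops$op[i]
      qadv <- if (op %in% c("M", "=", "X", "I")) len else 0L
      if (op %in% c("X", "I")) {
        if (is.na(seg_start)) seg_start <- qpos
        seg_end <- qpos + qadv
        good_run <- 0L
      } else if (op == "=") {
        good_run <- good_run + len
        if (!is.na(seg_start) && good_run > 15L) {
          if (seg_end - seg_start >= min_sv_len) {
            qs <- c(qs, seg_start); qe <- c(qe, seg_end)
          }
          seg_start <- NA_integer_
        }
      }
      qpos <- qpos + qadv
    }
    if (!is.na(seg_start) && seg_end - seg_start >= min_sv_len) {
      qs <- c(qs, seg_start); qe <- c(qe, seg_end)
    }
  }
  data.frame(qstart = qs, qend = qe)
}
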