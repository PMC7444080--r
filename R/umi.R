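# Structured-UMI extraction and grouping.
#
# Extraction looks for the universal primer within a window at the read
# start (and at the start of the reverse complement), using error-tolerant
# edit-distance matching -- raw long reads routinely carry indels inside
# the primer. The bases immediately following the primer are the candidate
# UMI; the fixed bases of the structured pattern must match exactly, which
# rejects reads whose UMI region was shifted or misread. Grouping is by
# exact UMI string: misread UMIs form low-count groups that the
# minimum-reads threshold removes, and Hamming-neighbour merging would risk
# fusing distinct molecules.

#' Validate a UMI design
#'
#' Checks: pattern length within 10-12; at least one fixed (non-N) base;
#' no run of 5 or more consecutive Ns (fixed-base interruptions are the
#' homopolymer guard the structured design exists for); primers must not
#' share a >= 10-base exact overlap.
#'
#' @param design [umi_design()].
#' @return character vector of violations; empty means valid.
#' @export
validate_design <- function(design) {
  v <- character(0)
  pat <- design$umi_pattern
  n <- nchar(pat)
  if (n < 10L || n > 12L)
    v <- c(v, sprintf("pattern length %d outside 10-12", n))
  if (!grepl("[ACGT]", pat))
    v <- c(v, "pattern has no fixed base (missing structure anchor)")
  if (grepl("N{5,}", pat))
    v <- c(v, "pattern contains a run of >= 5 Ns (homopolymer risk)")
  primers <- Filter(nzchar, c(design$universal_primer, design$gene_specific,
                              design$reverse_primer))
  if (length(primers) >= 2L) {
    pairs <- utils::combn(length(primers), 2L)
    for (k in seq_len(ncol(pairs))) {
      a <- primers[pairs[1L, k]]; b <- primers[pairs[2L, k]]
      if (shared_overlap(a, b) >= 10L)
        v <- c(v, "two primers share a >= 10-base exact overlap")
    }
  }
  v
}

# longest exact substring shared between two primers (either orientation)
shared_overlap <- function(a, b) {
  best <- 0L
  la <- nchar(a)
  for (w in seq.int(min(la, nchar(b)), 10L, by = -1L)) {
    if (w <= best) break
    for (s in seq_len(la - w + 1L)) {
      sub <- substr(a, s, s + w - 1L)
      if (grepl(sub, b, fixed = TRUE) || grepl(sub, revcomp(b), fixed = TRUE))
        return(w)
    }
  }
  best
}

umi_fixed_ok <- function(umi, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  fixed <- which(pat != "N")
  um <- strsplit(umi, "")[[1]]
  length(um) == length(pat) && all(um[fixed] == pat[fixed])
}

#' Extract structured UMIs from reads
#'
#' For each read, the universal primer is searched within the first
#' `window` bases of the read and of its reverse complement, tolerating up
#' to `design$max_primer_mismatches` edits (substitutions and indels). On
#' a hit, the next `nchar(umi_pattern)` bases are the candidate UMI,
#' accepted only if every fixed pattern base matches exactly. For paired
#' reads the UMI is extracted from mate 1 and propagated to mate 2.
#'
#' @param reads data.frame of reads (see [read_fastq()]).
#' @param design [umi_design()].
#' @param window primer search window; default 1.5x the primer+UMI length.
#' @return data.frame with columns `read_id`, `umi` (NA when rejected),
#'   `orientation` (`"forward"`/`"reverse"`), `reject_reason` (`"none"`,
#'   `"no_primer"`, `"bad_structure"`, `"bad_length"`), `insert_seq` (read
#'   sequence with primer+UMI prefix removed, strand-oriented), `mate`.
#' @export
extract_umi <- function(reads, design, window = NULL) {
  plen <- nchar(design$universal_primer)
  ulen <- nchar(design$umi_pattern)
  if (is.null(window)) window <- ceiling(1.5 * (plen + ulen))
  n <- nrow(reads)
  if (n == 0L)
    return(data.frame(read_id = character(), umi = character(),
                      orientation = character(), reject_reason = character(),
                      insert_seq = character(), mate = character(),
                      stringsAsFactors = FALSE))
  is_r2 <- reads$mate == "r2"
  seqs <- reads$seq
  rc <- revcomp(seqs)
  fwd <- primer_scan_cpp(substr(seqs, 1L, window), design$universal_primer,
                         design$max_primer_mismatches)
  rev <- primer_scan_cpp(substr(rc, 1L, window), design$universal_primer,
                         design$max_primer_mismatches)
  max_e <- design$max_primer_mismatches

  umi <- rep(NA_character_, n)
  orientation <- rep("forward", n)
  reject <- rep("none", n)
  insert <- seqs

  long_enough <- nchar(seqs) >= plen + ulen + 1L
  use_rev <- rev$edits < fwd$edits
  hit <- !is_r2 & long_enough & (pmin(fwd$edits, rev$edits) <= max_e)
  reject[!is_r2 & !hit] <- "no_primer"
  orientation[hit & use_rev] <- "reverse"

  str_hit <- ifelse(use_rev, rc, seqs)
  endpos <- ifelse(use_rev, rev$end, fwd$end)
  cand <- rep(NA_character_, n)
  cand[hit] <- substr(str_hit[hit], endpos[hit] + 1L, endpos[hit] + ulen)
  short <- hit & nchar(cand) < ulen
  reject[short] <- "bad_length"

  pat <- strsplit(design$umi_pattern, "")[[1]]
  struct_ok <- hit & !short
  for (f in which(pat != "N")) {
    struct_ok <- struct_ok & substr(cand, f, f) == pat[f]
  }
  reject[hit & !short & !struct_ok] <- "bad_structure"
  acc <- which(struct_ok)
  umi[acc] <- cand[acc]
  insert[acc] <- substr(str_hit[acc], endpos[acc] + ulen + 1L,
                        nchar(str_hit[acc]))
  if (any(is_r2)) {
    # mate 2 inherits mate 1's UMI (same template molecule)
    m1 <- match(reads$id[is_r2], reads$id[!is_r2 & reads$mate == "r1"])
    src <- which(!is_r2 & reads$mate == "r1")[m1]
    umi[is_r2] <- umi[src]
    reject[is_r2] <- reject[src]
    orientation[is_r2] <- "forward"
    reject[is_r2][is.na(reject[is_r2])] <- "no_primer"
  }
  data.frame(read_id = reads$id, umi = umi, orientation = orientation,
             reject_reason = reject, insert_seq = insert, mate = reads$mate,
             stringsAsFactors = FALSE)
}

#' Bin extracted reads into UMI groups
#'
#' Exact-string grouping of successful extractions; a group is *eligible*
#' for consensus calling when it holds at least `min_reads` reads.
#'
#' @param extractions result of [extract_umi()].
#' @param min_reads eligibility threshold (default 5 reads per group).
#' @return an object of class `umi_group_table`: data.frame with `umi`,
#'   `read_count`, `eligible`, and list-column `read_ids`, sorted by
#'   descending read count. Attributes `n_extractions`, `n_with_umi`,
#'   `n_eligible`, `median_eligible_reads` summarise the funnel.
#' @export
group_by_umi <- function(extractions, min_reads = 5L) {
  ok <- extractions[!is.na(extractions$umi), , drop = FALSE]
  if (nrow(ok)) {
    split_ids <- split(ok$read_id, ok$umi)
    # count distinct read ids (paired mates share an id and must not
    # double-count toward the molecule's read total)
    split_ids <- lapply(split_ids, unique)
    counts <- lengths(split_ids)
    tab <- data.frame(umi = names(split_ids),
                      read_count = as.integer(counts),
                      eligible = counts >= min_reads,
                      stringsAsFactors = FALSE)
    tab$read_ids <- unname(split_ids)
    tab <- tab[order(-tab$read_count, tab$umi), , drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(umi = character(), read_count = integer(),
                      eligible = logical(), stringsAsFactors = FALSE)
    tab$read_ids <- list()
  }
  structure(tab,
            n_extractions = nrow(extractions),
            n_with_umi = nrow(ok),
            n_eligible = sum(tab$eligible),
            median_eligible_reads =
              if (any(tab$eligible)) median(tab$read_count[tab$eligible]) else NA_real_,
            min_reads = as.integer(min_reads),
            class = c("umi_group_table", "data.frame"))
}

#' @export
print.umi_group_table <- function(x, ...) {
  cat(sprintf("UMI group table: %d UMIs from %d extracted reads (%d input)\n",
              nrow(x), attr(x, "n_with_umi"), attr(x, "n_extractions")))
  cat(sprintf("  eligible (>= %d reads): %d groups, median %s reads/group\n",
              attr(x, "min_reads"), attr(x, "n_eligible"),
              format(attr(x, "median_eligible_reads"))))
  invisible(x)
}

#' Subsample reads without replacement
#'
#' Uniform sample of `n` reads, deterministic under `seed`, preserving
#' input order.
#'
#' @param reads data.frame of reads.
#' @param n number of reads to keep (`0 <= n <= nrow(reads)`).
#' @param seed RNG seed.
#' @return subset of `reads` in original order.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  if (n < 0L || n > nrow(reads))
    stop(sprintf("cannot sample %d of %d reads", n, nrow(reads)))
  set.seed(seed)
  keep <- sort(sample.int(nrow(reads), n))
  reads[keep, , drop = FALSE]
}
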