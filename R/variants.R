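# Per-UMI-group consensus variant calling and population-level merging.
#
# Every eligible UMI group represents one original molecule, so a variant
# present in the molecule appears in (nearly) all of the group's reads,
# while amplification/sequencing errors are private to single reads. The
# consensus fraction turns this into a per-group call; merging across
# groups yields population VAFs as supporting-groups / eligible-groups.

# align a set of read sequences with caching over identical sequences
align_reads <- function(seqs, ids, reference, aparams = alignment_params()) {
  uniq <- !duplicated(seqs)
  useqs <- toupper(seqs[uniq])
  urc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(useqs)))
  cache <- mapply(function(s, rc) align_read(s, reference, aparams,
                                             query_rc = rc),
                  useqs, urc, SIMPLIFY = FALSE)
  names(cache) <- seqs[uniq]
  out <- cache[seqs]
  for (i in seq_along(out)) out[[i]]$read_id <- ids[i]
  unname(out)
}

#' Build a per-position pileup from one UMI group's alignments
#'
#' Tallies A/C/G/T/deletion counts per reference position from CIGAR
#' walks. Insertions are keyed to the reference position before which they
#' occur; soft-clipped bases are ignored.
#'
#' @param alignments list of mapped [align_read()] results from one group.
#' @param reference reference sequence.
#' @return an object of class `umivar_pileup`: list with `counts` (5 x L
#'   integer matrix, rows A/C/G/T/del), `insertions` (data.frame
#'   `read_id`, `pos`, `seq`), `n_reads`, and `spans` (per-read ref
#'   intervals).
#' @export
pileup_group <- function(alignments, reference) {
  alignments <- Filter(function(a) isTRUE(a$mapped), alignments)
  if (!length(alignments)) stop("empty group: no mapped alignments")
  L <- nchar(reference)
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c(BASES, "del"), NULL))
  ins <- list()
  spans <- data.frame(read_id = vapply(alignments, `[[`, "", "read_id"),
                      start = vapply(alignments, `[[`, 0L, "ref_start"),
                      end = vapply(alignments, `[[`, 0L, "ref_end"),
                      stringsAsFactors = FALSE)
  for (a in alignments) {
    ops <- aln_ops(a)
    rpos <- a$ref_start
    qpos <- a$query_start
    qb <- strsplit(a$query, "")[[1]]
    pos_acc <- integer(0)
    row_acc <- integer(0)
    for (i in seq_len(ops$n)) {
      len <- ops$len[i]; op <- ops$op[i]
      if (op %in% c("M", "=", "X")) {
        idx <- match(qb[(qpos + 1L):(qpos + len)], BASES)
        keep <- !is.na(idx)
        pos_acc <- c(pos_acc, (rpos + seq_len(len))[keep])
        row_acc <- c(row_acc, idx[keep])
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "D") {
        pos_acc <- c(pos_acc, rpos + seq_len(len))
        row_acc <- c(row_acc, rep(5L, len))
        rpos <- rpos + len
      } else if (op == "I") {
        ins[[length(ins) + 1L]] <- data.frame(
          read_id = a$read_id, pos = rpos,
          seq = paste(qb[(qpos + 1L):(qpos + len)], collapse = ""),
          stringsAsFactors = FALSE)
        qpos <- qpos + len
      }
      # S consumes query only and is outside the aligned block
    }
    counts[cbind(row_acc, pos_acc)] <- counts[cbind(row_acc, pos_acc)] + 1L
  }
  insertions <- if (length(ins)) do.call(rbind, ins) else
    data.frame(read_id = character(), pos = integer(), seq = character(),
               stringsAsFactors = FALSE)
  structure(list(counts = counts, insertions = insertions,
                 n_reads = length(alignments), spans = spans),
            class = "umivar_pileup")
}

#' Call SNVs from a group pileup by consensus
#'
#' A position is callable when at least `min_reads` group reads span it,
#' where spanning means contributing either a base or a deletion: a
#' per-read deletion error must not be able to black out a position in a
#' small group. At a callable position the alternative base `b` is called
#' iff `b` differs from the reference and
#' `count(b) / spanning >= consensus_fraction` -- reads showing a deletion
#' at the position count as evidence *against* the SNV, which keeps the
#' denominator consistent and blocks concordant-error artifacts at
#' positions thinned by deletions. At most one SNV is called per position
#' (the consensus base).
#'
#' @param pileup [pileup_group()] result.
#' @param reference reference sequence.
#' @param params [filter_params()].
#' @return data.frame with `pos` (0-based), `ref`, `alt`, `support`
#'   (fraction of spanning reads), `depth` (base depth).
#' @export
call_snvs <- function(pileup, reference, params = filter_params()) {
  bc <- pileup$counts[1:4, , drop = FALSE]
  depth <- colSums(bc)
  spanning <- depth + pileup$counts[5L, ]
  refb <- strsplit(reference, "")[[1]]
  top <- max.col(t(bc), ties.method = "first")
  topc <- bc[cbind(top, seq_len(ncol(bc)))]
  callable <- spanning >= params$min_reads &
    BASES[top] != refb &
    topc / pmax(spanning, 1L) >= params$consensus_fraction
  idx <- which(callable)
  data.frame(pos = idx - 1L, ref = refb[idx], alt = BASES[top[idx]],
             support = topc[idx] / spanning[idx],
             depth = as.integer(depth[idx]),
             stringsAsFactors = FALSE)
}

# all indel/inversion events across a group's reads, reference coords
group_events <- function(alignments, inversions = list()) {
  evs <- lapply(alignments, function(a) {
    e <- alignment_events(a)
    if (nrow(e)) e$read_id <- a$read_id
    e
  })
  evs <- evs[vapply(evs, nrow, 0L) > 0L]
  ev <- if (length(evs)) do.call(rbind, evs) else
    data.frame(kind = character(), start = integer(), end = integer(),
               len = integer(), seq = character(), read_id = character(),
               stringsAsFactors = FALSE)
  if (length(inversions)) {
    inv <- do.call(rbind, lapply(inversions, function(x)
      data.frame(kind = "inversion", start = x$ref_start, end = x$ref_end,
                 len = x$ref_end - x$ref_start, seq = "",
                 read_id = x$read_id, stringsAsFactors = FALSE)))
    ev <- rbind(ev, inv)
  }
  ev
}

# single-linkage clustering of events of one kind: two events link when
# both breakpoints are within tol (insertions: position and length).
cluster_events <- function(ev, tol) {
  n <- nrow(ev)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (ev$kind[i] != ev$kind[j]) next
    near <- if (ev$kind[i] == "insertion") {
      abs(ev$start[i] - ev$start[j]) <= tol && abs(ev$len[i] - ev$len[j]) <= tol
    } else {
      abs(ev$start[i] - ev$start[j]) <= tol && abs(ev$end[i] - ev$end[j]) <= tol
    }
    if (near) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 0L)
}

# summarise event clusters: median breakpoints, supporting reads
summarise_clusters <- function(ev, cl) {
  if (!nrow(ev))
    return(data.frame(kind = character(), start = integer(), end = integer(),
                      len = integer(), seq = character(), n_reads = integer(),
                      stringsAsFactors = FALSE))
  out <- lapply(split(seq_len(nrow(ev)), cl), function(ii) {
    e <- ev[ii, , drop = FALSE]
    md_len <- as.integer(round(median(e$len)))
    sq <- if (e$kind[1] == "insertion") {
      e$seq[which.min(abs(e$len - md_len))]
    } else ""
    data.frame(kind = e$kind[1],
               start = as.integer(round(median(e$start))),
               end = as.integer(round(median(e$end))),
               len = md_len, seq = sq,
               n_reads = length(unique(e$read_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call structural variants within a UMI group
#'
#' Deletion (`D`) and insertion (`I`) CIGAR runs of at least `min_sv_len`
#' bases, plus inversion evidence from minus-strand realignment, are
#' clustered across the group's reads (same kind, breakpoints within
#' `breakpoint_tol`). A cluster is emitted as an SV iff the fraction of the
#' group's reads exhibiting the event reaches `sv_support_fraction`;
#' reported breakpoints are per-read medians.
#'
#' @param alignments the group's mapped alignments.
#' @param inversions list of per-read inversion evidence
#'   ([detect_inversion()] results, each given a `read_id`).
#' @param params [filter_params()].
#' @param events precomputed per-read event table (internal use).
#' @return data.frame with `kind`, `start`, `end`, `len`, `seq`,
#'   `support` (fraction of group reads).
#' @export
call_svs <- function(alignments, inversions = list(),
                     params = filter_params(), events = NULL) {
  n_reads <- length(alignments)
  ev <- if (is.null(events)) group_events(alignments, inversions) else events
  ev <- ev[ev$len >= params$min_sv_len | ev$kind == "inversion", , drop = FALSE]
  cl <- cluster_events(ev, params$breakpoint_tol)
  cs <- summarise_clusters(ev, cl)
  cs$support <- cs$n_reads / n_reads
  cs[cs$support >= params$sv_support_fraction & cs$len >= params$min_sv_len,
     setdiff(names(cs), "n_reads"), drop = FALSE]
}

#' Call small indels (shorter than the SV boundary) within a UMI group
#'
#' Insertion/deletion runs of 1 to `min_sv_len - 1` bases are left-aligned
#' against the reference and called with the same consensus logic as SNVs:
#' an indel is emitted iff the fraction of reads spanning its position that
#' carry it reaches `consensus_fraction`.
#'
#' @param pileup [pileup_group()] result (supplies per-read spans).
#' @param alignments the group's mapped alignments.
#' @param reference reference sequence.
#' @param params [filter_params()].
#' @param events precomputed per-read event table (internal use).
#' @return data.frame with `kind`, `start` (0-based, left-aligned), `len`,
#'   `seq` (inserted sequence), `support`.
#' @export
call_small_indels <- function(pileup, alignments, reference,
                              params = filter_params(), events = NULL) {
  ev <- if (is.null(events)) group_events(alignments) else events
  ev <- ev[ev$kind %in% c("deletion", "insertion"), , drop = FALSE]
  ev <- ev[ev$len < params$min_sv_len & ev$kind != "inversion", , drop = FALSE]
  empty <- data.frame(kind = character(), start = integer(), len = integer(),
                      seq = character(), support = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(ev)) return(empty)
  # vectorised left-alignment: shift while the base entering from the left
  # equals the base leaving on the right (VCF-style normalisation)
  rb <- strsplit(reference, "")[[1]]
  isdel <- ev$kind == "deletion"
  repeat {
    leaving <- ifelse(isdel, rb[ev$start + ev$len],
                      substr(ev$seq, ev$len, ev$len))
    can <- ev$start > 0L & rb[pmax(ev$start, 1L)] == leaving
    can[is.na(can)] <- FALSE
    if (!any(can)) break
    ic <- can & !isdel
    ev$seq[ic] <- paste0(rb[ev$start[ic]], substr(ev$seq[ic], 1L,
                                                  ev$len[ic] - 1L))
    ev$start[can] <- ev$start[can] - 1L
  }
  spans <- pileup$spans
  key <- paste(ev$kind, ev$start, ev$len)
  first <- !duplicated(key)
  supp_n <- table(key[!duplicated(paste(key, ev$read_id))])
  uk <- data.frame(kind = ev$kind[first], start = ev$start[first],
                   len = ev$len[first], key = key[first],
                   stringsAsFactors = FALSE)
  spanning <- vapply(seq_len(nrow(uk)), function(i) {
    if (uk$kind[i] == "insertion")
      sum(spans$start < uk$start[i] & spans$end > uk$start[i])
    else
      sum(spans$start <= uk$start[i] & spans$end >= uk$start[i] + uk$len[i])
  }, 0L)
  support <- as.integer(supp_n[uk$key]) / pmax(spanning, 1L)
  pass <- spanning > 0L & support >= params$consensus_fraction
  if (!any(pass)) return(empty)
  out <- uk[pass, c("kind", "start", "len"), drop = FALSE]
  out$seq <- vapply(which(pass), function(i) {
    if (uk$kind[i] != "insertion") return("")
    e <- ev$seq[key == uk$key[i]]
    names(sort(-table(e)))[1]
  }, "")
  out$support <- support[pass]
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Run consensus calling on one UMI group
#'
#' Aligns the group's reads, builds the pileup, and calls SNVs, small
#' indels and SVs. Also computes the per-group quality statistics consumed
#' by [group_filter()]: mean read-to-consensus identity, positions with
#' conflicting near-even base calls, and unresolved (ambivalently
#' supported) SV clusters.
#'
#' @param seqs character vector of the group's read sequences (UMI/primer
#'   already trimmed, i.e. `insert_seq` from [extract_umi()]).
#' @param ids read ids, parallel to `seqs`.
#' @param umi the group's UMI string.
#' @param reference reference sequence.
#' @param params [filter_params()].
#' @param aparams [alignment_params()].
#' @return an object of class `umivar_group_calls`: list with `umi`,
#'   `read_count`, `n_mapped`, `snvs`, `small_indels`, `svs`,
#'   `mean_identity`, `conflict_positions`, `sv_ambiguous`, `pass_filter`
#'   (NA until [group_filter()] runs), `span` (consensus ref interval).
#' @export
group_call <- function(seqs, ids, umi, reference,
                       params = filter_params(),
                       aparams = alignment_params()) {
  alns <- align_reads(seqs, ids, reference, aparams)
  alns <- Filter(function(a) a$mapped, alns)
  if (!length(alns)) {
    return(structure(list(umi = umi, read_count = length(seqs), n_mapped = 0L,
                          snvs = NULL, small_indels = NULL, svs = NULL,
                          mean_identity = 0, conflict_positions = 0L,
                          sv_ambiguous = FALSE, pass_filter = FALSE,
                          span = c(NA_integer_, NA_integer_)),
                     class = "umivar_group_calls"))
  }
  pu <- pileup_group(alns, reference)

  inversions <- list()
  for (a in alns) {
    if (!nrow(candidate_segments(a, nchar(a$query), params$min_sv_len, 0.55)))
      next
    inv <- detect_inversion(a, a$query, reference, aparams,
                            min_sv_len = params$min_sv_len)
    if (!is.null(inv)) {
      inv$read_id <- a$read_id
      inversions[[length(inversions) + 1L]] <- inv
    }
  }
  snvs <- call_snvs(pu, reference, params)
  ev <- group_events(alns, inversions)
  # an inverted segment garbage-aligns as mismatch/indel runs on the primary
  # alignment; base calls and indel events inside a detected inversion
  # interval are artifacts of the inversion, not variants
  if (length(inversions)) {
    tol <- params$breakpoint_tol
    drop_ev <- rep(FALSE, nrow(ev))
    drop_snv <- rep(FALSE, nrow(snvs))
    for (iv in inversions) {
      drop_ev <- drop_ev | (ev$kind != "inversion" & ev$read_id == iv$read_id &
                              ev$start >= iv$ref_start - tol &
                              ev$end <= iv$ref_end + tol)
      drop_snv <- drop_snv | (snvs$pos >= iv$ref_start - tol &
                                snvs$pos < iv$ref_end + tol)
    }
    ev <- ev[!drop_ev, , drop = FALSE]
    snvs <- snvs[!drop_snv, , drop = FALSE]
  }
  small <- call_small_indels(pu, alns, reference, params,
                             events = ev[ev$kind != "inversion", , drop = FALSE])
  svs <- call_svs(alns, inversions, params, events = ev)

  qc <- group_qc(pu, alns, params, events = ev)
  structure(list(umi = umi, read_count = length(seqs),
                 n_mapped = length(alns),
                 snvs = snvs, small_indels = small, svs = svs,
                 mean_identity = qc$mean_identity,
                 conflict_positions = qc$conflict_positions,
                 sv_ambiguous = qc$sv_ambiguous,
                 pass_filter = NA,
                 span = c(min(pu$spans$start), max(pu$spans$end))),
            class = "umivar_group_calls")
}

#' @export
print.umivar_group_calls <- function(x, ...) {
  cat(sprintf("UMI group %s: %d reads (%d mapped), identity %.3f\n",
              x$umi, x$read_count, x$n_mapped, x$mean_identity))
  cat(sprintf("  %d SNVs, %d small indels, %d SVs\n",
              NROW(x$snvs), NROW(x$small_indels), NROW(x$svs)))
  invisible(x)
}

# per-group quality statistics: read-to-consensus identity, near-even
# conflicting positions that share a recurring minority read subset
# (evidence of a UMI collision), and ambivalently supported SV clusters.
group_qc <- function(pileup, alignments, params, events = NULL) {
  counts <- pileup$counts
  depth_all <- colSums(counts)
  covered <- which(depth_all > 0L)
  cons_row <- max.col(t(counts[, covered, drop = FALSE]), ties.method = "first")
  cons <- integer(ncol(counts))
  cons[covered] <- cons_row

  idents <- vapply(alignments, function(a) {
    ops <- aln_ops(a)
    rpos <- a$ref_start; qpos <- a$query_start
    qb <- strsplit(a$query, "")[[1]]
    agree <- 0L; tot <- 0L
    for (i in seq_len(ops$n)) {
      len <- ops$len[i]; op <- ops$op[i]
      if (op %in% c("M", "=", "X")) {
        idx <- match(qb[(qpos + 1L):(qpos + len)], BASES)
        agree <- agree + sum(idx == cons[(rpos + 1L):(rpos + len)], na.rm = TRUE)
        tot <- tot + len
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "D") {
        agree <- agree + sum(cons[(rpos + 1L):(rpos + len)] == 5L)
        tot <- tot + len
        rpos <- rpos + len
      } else if (op == "I") {
        qpos <- qpos + len
      }
    }
    if (tot == 0L) 0 else agree / tot
  }, 0)

  # conflicting positions: two calls each >= 2 reads and >= 35% of depth
  minority_keys <- character(0)
  for (p in covered) {
    v <- counts[, p]
    ord <- order(v, decreasing = TRUE)
    if (v[ord[2]] >= 2L && v[ord[2]] >= 0.35 * depth_all[p]) {
      minority_keys <- c(minority_keys,
                         minority_subset_key(alignments, p - 1L, ord[2]))
    }
  }
  conflict <- if (length(minority_keys)) max(table(minority_keys)) else 0L

  ev <- if (is.null(events)) group_events(alignments) else events
  ev <- ev[ev$len >= params$min_sv_len | ev$kind == "inversion", , drop = FALSE]
  sv_amb <- FALSE
  if (nrow(ev)) {
    cl <- cluster_events(ev, params$breakpoint_tol)
    cs <- summarise_clusters(ev, cl)
    n <- length(alignments)
    frac <- cs$n_reads / n
    sv_amb <- any(frac >= 1 - params$sv_support_fraction &
                    frac < params$sv_support_fraction &
                    cs$n_reads >= 2L & (n - cs$n_reads) >= 2L)
  }
  list(mean_identity = mean(idents), conflict_positions = as.integer(conflict),
       sv_ambiguous = sv_amb)
}

# key identifying which reads carry the minority call at a position
minority_subset_key <- function(alignments, pos0, row) {
  who <- vapply(alignments, function(a) {
    b <- base_at(a, pos0)
    !is.na(b) && b == row
  }, TRUE)
  paste(sort(vapply(alignments[who], `[[`, "", "read_id")), collapse = ",")
}

# the pileup row (1-4 base, 5 del) a read contributes at ref position pos0
base_at <- function(a, pos0) {
  if (pos0 < a$ref_start || pos0 >= a$ref_end) return(NA_integer_)
  ops <- aln_ops(a)
  rpos <- a$ref_start; qpos <- a$query_start
  qb <- strsplit(a$query, "")[[1]]
  for (i in seq_len(ops$n)) {
    len <- ops$len[i]; op <- ops$op[i]
    if (op %in% c("M", "=", "X")) {
      if (pos0 < rpos + len) return(match(qb[qpos + (pos0 - rpos) + 1L], BASES))
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      if (pos0 < rpos + len) return(5L)
      rpos <- rpos + len
    } else if (op == "I") {
      qpos <- qpos + len
    }
  }
  NA_integer_
}

#' Drop low-confidence UMI groups
#'
#' A group is removed when its mean read-to-consensus identity falls below
#' `min_group_identity`, when three or more conflicting positions share the
#' same minority read subset (two internally consistent but mutually
#' incompatible read sets under one UMI -- a barcode collision), or when a
#' large SV is supported by an ambivalent fraction of reads (neither
#' clearly present nor clearly absent).
#'
#' @param groups list of [group_call()] results.
#' @param params [filter_params()].
#' @return list of groups with `pass_filter` set; attribute `n_dropped`
#'   records how many failed.
#' @export
group_filter <- function(groups, params = filter_params()) {
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    groups[[i]]$pass_filter <- g$n_mapped > 0L &&
      g$mean_identity >= params$min_group_identity &&
      g$conflict_positions < 3L &&
      !g$sv_ambiguous
  }
  kept <- Filter(function(g) g$pass_filter, groups)
  attr(kept, "n_dropped") <- length(groups) - length(kept)
  kept
}

#' Merge per-group calls into a population call set
#'
#' Identical variants across groups are merged (SNVs and small indels by
#' exact position and alleles, SVs by kind with breakpoints within
#' `breakpoint_tol`); each variant's VAF is its supporting-group count
#' divided by the total number of eligible groups. Variants are classified
#' `target` (matches `target_variant`), `known` (present in
#' `known_variants`), or `somatic`; the population VCF filter
#' (`min_depth`, `min_qual`, `vaf_bounds`) is applied last.
#'
#' @param groups list of [group_call()] results that passed
#'   [group_filter()].
#' @param reference reference sequence.
#' @param params [filter_params()].
#' @param known_variants optional data.frame of known variants with
#'   columns `kind`, `start` (0-based), and `alt` (SNVs) or `end`/`len`.
#' @param target_variant optional single-variant spec (same columns) for
#'   the engineered spike-in.
#' @param reference_name contig name used in VCF output.
#' @return an object of class `umivar_callset`: list with `calls` (one row
#'   per distinct variant: `kind`, `start`, `end`, `len`, `ref`, `alt`,
#'   `seq`, `supp`, `total`, `vaf`, `class`, `qual`, list-column `umis`),
#'   `vcf` (data.frame of VCF entries for [write_vcf()]), and `total`
#'   (eligible group count).
#' @export
merge_and_filter <- function(groups, reference, params = filter_params(),
                             known_variants = NULL, target_variant = NULL,
                             reference_name = "amplicon") {
  total <- length(groups)
  rows <- list()
  for (g in groups) {
    gid <- sprintf("%s_%d", g$umi, g$read_count)
    if (NROW(g$snvs)) {
      s <- g$snvs
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "snv", start = s$pos, end = s$pos + 1L, len = 1L,
        alt = s$alt, seq = "", support = s$support, gid = gid,
        umi = g$umi, stringsAsFactors = FALSE)
    }
    if (NROW(g$small_indels)) {
      s <- g$small_indels
      rows[[length(rows) + 1L]] <- data.frame(
        kind = ifelse(s$kind == "deletion", "small_deletion", "small_insertion"),
        start = s$start, end = ifelse(s$kind == "deletion", s$start + s$len, s$start),
        len = s$len, alt = "", seq = s$seq, support = s$support, gid = gid,
        umi = g$umi, stringsAsFactors = FALSE)
    }
    if (NROW(g$svs)) {
      s <- g$svs
      rows[[length(rows) + 1L]] <- data.frame(
        kind = s$kind, start = s$start, end = s$end, len = s$len,
        alt = "", seq = s$seq, support = s$support, gid = gid,
        umi = g$umi, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    calls <- data.frame(kind = character(), start = integer(),
                        end = integer(), len = integer(), ref = character(),
                        alt = character(), seq = character(),
                        supp = integer(), total = integer(), vaf = numeric(),
                        class = character(), qual = numeric(), id = character(),
                        stringsAsFactors = FALSE)
    calls$umis <- list()
    return(structure(list(calls = calls, vcf = empty_vcf_entries(),
                          total = total),
                     class = "umivar_callset"))
  }
  ev <- do.call(rbind, rows)

  exact <- ev$kind %in% c("snv", "small_deletion", "small_insertion")
  key <- ifelse(exact,
                paste(ev$kind, ev$start, ev$len, ev$alt, ev$seq),
                NA_character_)
  svev <- ev[!exact, , drop = FALSE]
  if (nrow(svev)) {
    cl <- cluster_events(svev, params$breakpoint_tol)
    key[!exact] <- paste("sv", svev$kind, cl)
  }

  merged <- lapply(split(seq_len(nrow(ev)), key), function(ii) {
    e <- ev[ii, , drop = FALSE]
    e <- e[!duplicated(e$umi), , drop = FALSE]
    start <- as.integer(round(median(e$start)))
    end <- as.integer(round(median(e$end)))
    len <- as.integer(round(median(e$len)))
    data.frame(kind = e$kind[1], start = start, end = end, len = len,
               alt = e$alt[1], seq = e$seq[1],
               supp = nrow(e), qual = 100 * mean(e$support),
               id = paste(e$gid, collapse = ";"),
               umis = I(list(e$umi)), stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, merged)
  rownames(calls) <- NULL
  calls$total <- total
  calls$vaf <- calls$supp / total
  calls$ref <- vapply(seq_len(nrow(calls)), function(i)
    substr(reference, calls$start[i] + 1L, calls$start[i] + 1L), "")
  calls$ref[calls$kind != "snv"] <- ""

  calls$class <- classify_variants(calls, known_variants, target_variant,
                                   params$breakpoint_tol)
  keep <- calls$supp >= params$min_depth & calls$qual >= params$min_qual &
    calls$vaf >= params$vaf_bounds[1] & calls$vaf <= params$vaf_bounds[2]
  calls <- calls[keep, , drop = FALSE]
  calls <- calls[order(calls$start, calls$kind), , drop = FALSE]
  rownames(calls) <- NULL

  structure(list(calls = calls,
                 vcf = calls_to_vcf_entries(calls, reference, reference_name),
                 total = total),
            class = "umivar_callset")
}

#' @export
print.umivar_callset <- function(x, ...) {
  cat(sprintf("population call set: %d variants over %d eligible UMI groups\n",
              nrow(x$calls), x$total))
  if (nrow(x$calls)) {
    tb <- table(x$calls$kind)
    cat(" ", paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

variant_matches <- function(calls, spec, tol) {
  if (is.null(spec)) return(rep(FALSE, nrow(calls)))
  kind <- spec$kind
  if (kind == "snv") {
    calls$kind == "snv" & calls$start == spec$start &
      calls$alt == spec$alt
  } else {
    same_kind <- calls$kind == kind |
      (kind == "deletion" & calls$kind == "small_deletion") |
      (kind == "insertion" & calls$kind == "small_insertion")
    same_kind & abs(calls$start - spec$start) <= tol &
      (if (kind == "insertion") abs(calls$len - spec$len) <= tol
       else abs(calls$end - spec$end) <= tol)
  }
}

classify_variants <- function(calls, known_variants, target_variant, tol) {
  cls <- rep("somatic", nrow(calls))
  if (!is.null(known_variants) && nrow(known_variants)) {
    for (i in seq_len(nrow(known_variants))) {
      cls[variant_matches(calls, as.list(known_variants[i, ]), tol)] <- "known"
    }
  }
  cls[variant_matches(calls, target_variant, tol)] <- "target"
  cls
}

empty_vcf_entries <- function() {
  e <- data.frame(chrom = character(), pos = integer(), id = character(),
                  ref = character(), alt = character(), qual = numeric(),
                  stringsAsFactors = FALSE)
  e$info <- list()
  e
}

calls_to_vcf_entries <- function(calls, reference, reference_name) {
  if (!nrow(calls)) return(empty_vcf_entries())
  n <- nrow(calls)
  pos <- integer(n); ref <- character(n); alt <- character(n)
  info <- vector("list", n)
  refb <- function(from, to) substr(reference, from, to)  # 1-based
  for (i in seq_len(n)) {
    k <- calls$kind[i]; s <- calls$start[i]
    base_info <- list(SUPP = calls$supp[i], TOTAL = calls$total[i],
                      VAF = calls$vaf[i], CLASS = calls$class[i])
    if (k == "snv") {
      pos[i] <- s + 1L
      ref[i] <- refb(s + 1L, s + 1L)
      alt[i] <- calls$alt[i]
      info[[i]] <- c(list(TYPE = "SNV"), base_info)
    } else if (k == "small_deletion") {
      anchor <- max(s, 1L)  # 1-based position of the base before the event
      pos[i] <- anchor
      ref[i] <- refb(anchor, s + calls$len[i])
      alt[i] <- refb(anchor, anchor)
      info[[i]] <- c(list(TYPE = "DEL", END = s + calls$len[i],
                          SVLEN = -calls$len[i]), base_info)
    } else if (k == "small_insertion") {
      anchor <- max(s, 1L)
      pos[i] <- anchor
      ref[i] <- refb(anchor, anchor)
      alt[i] <- paste0(ref[i], calls$seq[i])
      info[[i]] <- c(list(TYPE = "INS", SVLEN = calls$len[i],
                          SEQ = calls$seq[i]), base_info)
    } else {
      anchor <- max(s, 1L)
      pos[i] <- anchor
      ref[i] <- refb(anchor, anchor)
      alt[i] <- paste0("<", c(deletion = "DEL", insertion = "INS",
                              inversion = "INV")[[k]], ">")
      svlen <- if (k == "deletion") -calls$len[i] else calls$len[i]
      info[[i]] <- c(list(TYPE = toupper(substr(alt[i], 2L, 4L)),
                          END = calls$end[i], SVLEN = svlen), base_info)
      if (k == "insertion" && nzchar(calls$seq[i]))
        info[[i]]$SEQ <- calls$seq[i]
    }
  }
  ord <- order(pos)
  e <- data.frame(chrom = reference_name, pos = pos[ord], id = calls$id[ord],
                  ref = ref[ord], alt = alt[ord], qual = calls$qual[ord],
                  stringsAsFactors = FALSE)
  e$info <- info[ord]
  e
}

#' Pooled (ensemble) SNV calling without UMI grouping
#'
#' Applies the same pileup-consensus rule to all reads pooled together,
#' ignoring UMIs -- the negative control showing why molecular barcoding is
#' needed: a rare variant's reads are swamped by the wild-type majority and
#' never reach the consensus fraction.
#'
#' @param seqs,ids read sequences and ids (all reads, one pool).
#' @param reference reference sequence.
#' @param params [filter_params()].
#' @param aparams [alignment_params()].
#' @return data.frame of SNVs as from [call_snvs()].
#' @export
ensemble_calls <- function(seqs, ids, reference, params = filter_params(),
                           aparams = alignment_params()) {
  alns <- align_reads(seqs, ids, reference, aparams)
  alns <- Filter(function(a) a$mapped, alns)
  if (!length(alns))
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      support = numeric(), depth = integer(),
                      stringsAsFactors = FALSE))
  pu <- pileup_group(alns, reference)
  call_snvs(pu, reference, params)
}
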