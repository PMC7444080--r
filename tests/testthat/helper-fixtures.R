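# Shared fixtures: a small amplicon, a UMI design, and simulation helpers.
# Everything is generated in code under fixed seeds; no data files.

FIX_REF_168 <- random_reference(168, seed = 42)
FIX_DESIGN <- umi_design("CAGTGGTATCAACGCAGAGTAC")

# spike-in SNV used across end-to-end tests: position 83, ref base T here
FIX_MUT_POS <- 83L
FIX_MUT_ALT <- setdiff(c("A", "C", "G", "T"),
                       substr(FIX_REF_168, FIX_MUT_POS + 1L, FIX_MUT_POS + 1L))[1]

spikein_spec <- function(n_molecules, f, seed, reference = FIX_REF_168,
                         somatic_snv_per_mb = 0) {
  population_spec(
    reference,
    list(allele_spec("WT", 1 - f),
         allele_spec("KI", f, data.frame(kind = "snv", pos = FIX_MUT_POS,
                                         payload = FIX_MUT_ALT))),
    n_molecules = n_molecules, somatic_snv_per_mb = somatic_snv_per_mb,
    umi_design = FIX_DESIGN, seed = seed)
}

# Independent alignment-score oracle: local alignment under the two-piece
# gap cost, with gap costs enumerated explicitly per gap length. O(nm(n+m)),
# usable only on tiny instances; shares no code with the package DP.
oracle_align_score <- function(q, r, p = alignment_params()) {
  gapcost <- function(L) pmin(p$gap_open + L * p$gap_extend,
                              p$long_gap_open + L * p$long_gap_extend)
  qb <- strsplit(q, "")[[1]]; rb <- strsplit(r, "")[[1]]
  n <- length(qb); m <- length(rb)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n + 1)) for (j in seq_len(m + 1)) {
    s <- 0
    if (i > 1 && j > 1)
      s <- max(s, H[i - 1, j - 1] +
                 if (qb[i - 1] == rb[j - 1]) p$match else -p$mismatch)
    if (j > 2)
      s <- max(s, max(H[i, (j - 1):1] - gapcost(1:(j - 1))))
    else if (j == 2)
      s <- max(s, H[i, 1] - gapcost(1))
    if (i > 2)
      s <- max(s, max(H[(i - 1):1, j] - gapcost(1:(i - 1))))
    else if (i == 2)
      s <- max(s, H[1, j] - gapcost(1))
    H[i, j] <- s
    best <- max(best, s)
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# canonical truth variant set over molecules with >= min_reads reads:
# data.frame(kind, start, len, alt, n_molecules), small/large indels split
# at min_sv_len, indels left-aligned like the caller's output
truth_variant_set <- function(truth, min_reads = 5L, reference,
                              min_sv_len = 31L) {
  el <- truth[truth$n_reads >= min_reads, , drop = FALSE]
  ed <- do.call(rbind, el$edits)
  if (is.null(ed) || !nrow(ed)) {
    return(data.frame(kind = character(), start = integer(), len = integer(),
                      alt = character(), n_molecules = integer(),
                      stringsAsFactors = FALSE))
  }
  kind <- ed$kind
  small <- ed$len < min_sv_len
  kind[kind == "deletion" & small] <- "small_deletion"
  kind[kind == "insertion" & small] <- "small_insertion"
  start <- ed$start
  for (i in which(ed$kind %in% c("deletion", "insertion"))) {
    la <- umivar:::left_align_event(ed$kind[i], ed$start[i], ed$len[i],
                                    ed$seq[i], reference)
    start[i] <- la$start
  }
  key <- paste(kind, start, ed$len, ed$alt)
  agg <- tapply(rep(1L, length(key)), key, sum)
  first <- !duplicated(key)
  out <- data.frame(kind = kind[first], start = start[first],
                    len = ed$len[first], alt = ed$alt[first],
                    n_molecules = as.integer(agg[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$start, out$kind), , drop = FALSE]
}
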