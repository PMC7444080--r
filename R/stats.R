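# Reporting statistics and experiment-design calculators.

#' Somatic SNV load per megabase
#'
#' `1e6 * n_snvs / (n_groups * surveyed_len_bp)`. The surveyed length is
#' the amplicon length minus the primer-covered bases (primers are
#' synthetic sequence and cannot carry somatic variants), so it must be
#' supplied by the caller.
#'
#' @param n_snvs number of somatic SNVs observed (each SNV-in-a-group
#'   counted once).
#' @param n_groups number of eligible UMI groups.
#' @param surveyed_len_bp surveyed region length in bp, primers excluded.
#' @return somatic SNVs per megabase (full precision; display rounds to
#'   one decimal).
#' @export
somatic_load <- function(n_snvs, n_groups, surveyed_len_bp) {
  stopifnot(n_snvs >= 0)
  if (n_groups < 1 || surveyed_len_bp < 1)
    stop("n_groups and surveyed_len_bp must be >= 1")
  1e6 * n_snvs / (n_groups * surveyed_len_bp)
}

#' Minimum number of UMI groups to detect a rare allele
#'
#' Smallest integer `n` with `1 - (1 - f)^n >= confidence`: the number of
#' original molecules that must be sampled so that an allele at frequency
#' `f` is seen in at least one UMI group with the requested probability.
#' Computed as `ceiling(log(1 - confidence) / log(1 - f))` with boundary
#' verification.
#'
#' @param f allele frequency (0 < f <= 1).
#' @param confidence detection probability (0 < confidence < 1).
#' @return integer number of UMI groups.
#' @export
min_groups_for_detection <- function(f, confidence = 0.9) {
  if (f <= 0) stop("an allele at frequency 0 is undetectable")
  stopifnot(f <= 1, confidence > 0, confidence < 1)
  if (f == 1) return(1L)
  n <- as.integer(ceiling(log(1 - confidence) / log(1 - f)))
  # guard against floating-point landing one off the true boundary
  while (1 - (1 - f)^n < confidence) n <- n + 1L
  while (n > 1L && 1 - (1 - f)^(n - 1L) >= confidence) n <- n - 1L
  n
}

#' Expected number of UMI groups carrying a first-copy polymerase error
#'
#' The inescapable error mode of UMI consensus sequencing is a polymerase
#' error in the barcoding (first-copy) step, which propagates to every
#' read of the molecule and is indistinguishable from a true variant. Its
#' expected count is `n_groups * molecule_len_bp * per_base_err`.
#'
#' @param n_groups number of UMI groups.
#' @param molecule_len_bp molecule length in bp.
#' @param per_base_err per-base polymerase substitution probability;
#'   default is the high-fidelity budget of 6 errors per 1e6 unique 168-bp
#'   molecules, i.e. `6e-6 / 168`.
#' @return expected number of error-carrying groups.
#' @export
expected_error_groups <- function(n_groups, molecule_len_bp,
                                  per_base_err = 6e-6 / 168) {
  stopifnot(n_groups >= 0, molecule_len_bp >= 1, per_base_err >= 0)
  n_groups * molecule_len_bp * per_base_err
}

#' Variant allele fraction with Wilson 95% interval
#'
#' VAF of a variant supported by `supporting` of `total` eligible UMI
#' groups, with a Wilson score interval (via [stats::prop.test()] without
#' continuity correction).
#'
#' @param supporting number of supporting UMI groups (> 0).
#' @param total total eligible UMI groups.
#' @return list with `vaf`, `lower`, `upper`.
#' @export
vaf_of_variant <- function(supporting, total) {
  if (total < 1) stop("total must be >= 1")
  stopifnot(supporting > 0, supporting <= total)
  ci <- suppressWarnings(
    prop.test(supporting, total, correct = FALSE)$conf.int)
  list(vaf = supporting / total, lower = ci[1], upper = ci[2])
}

#' Cluster recurrent structural variants across UMI groups
#'
#' Single-linkage clustering of per-group SVs on (kind, start, end), two
#' SVs linking when both breakpoints are within `breakpoint_tol`
#' (insertions: position and length). Recurrent clusters -- the same event
#' captured independently in many molecules -- are evidence of repair
#' hotspots rather than random breakage.
#'
#' @param svs data.frame with columns `umi` (group id), `kind`, `start`,
#'   `end`, `len`; one row per SV per group.
#' @param breakpoint_tol breakpoint tolerance in bp.
#' @param n_sv_groups number of SV-bearing groups used as the fraction
#'   denominator; defaults to the number of distinct `umi` values in
#'   `svs`.
#' @return data.frame with `kind`, `start`, `end`, `len` (medians),
#'   `count` (member groups), `fraction` (`count / n_sv_groups`), and
#'   list-column `umis`, sorted by descending count.
#' @export
cluster_recurrent_svs <- function(svs, breakpoint_tol = 10L,
                                  n_sv_groups = NULL) {
  if (is.null(n_sv_groups)) n_sv_groups <- length(unique(svs$umi))
  if (!nrow(svs)) {
    out <- data.frame(kind = character(), start = integer(), end = integer(),
                      len = integer(), count = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE)
    out$umis <- list()
    return(out)
  }
  if (!"len" %in% names(svs)) svs$len <- svs$end - svs$start
  cl <- cluster_events(svs, breakpoint_tol)
  out <- lapply(split(seq_len(nrow(svs)), cl), function(ii) {
    e <- svs[ii, , drop = FALSE]
    umis <- unique(e$umi)
    data.frame(kind = e$kind[1],
               start = as.integer(round(median(e$start))),
               end = as.integer(round(median(e$end))),
               len = as.integer(round(median(e$len))),
               count = length(umis),
               fraction = length(umis) / n_sv_groups,
               umis = I(list(umis)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$count, out$kind, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

spectrum_classes <- function() {
  cls <- c(outer(BASES, BASES, function(a, b) paste0(a, ">", b)))
  sort(cls[substr(cls, 1, 1) != substr(cls, 3, 3)])
}

#' Substitution spectrum of a set of SNVs
#'
#' Counts of the 12 ordered substitution classes (A>C, A>G, ..., T>G),
#' plus the strand-collapsed 6-class view (pyrimidine-referenced: C>A,
#' C>G, C>T, T>A, T>C, T>G).
#'
#' @param snvs data.frame with columns `ref` and `alt` (single A/C/G/T
#'   bases).
#' @return list with `counts` (named integer vector, 12 classes),
#'   `collapsed` (named integer vector, 6 classes), `n`, and
#'   `transition_fraction`.
#' @export
substitution_spectrum <- function(snvs) {
  counts <- setNames(integer(12L), spectrum_classes())
  if (NROW(snvs)) {
    if (any(!snvs$ref %in% BASES) || any(!snvs$alt %in% BASES))
      stop("spectrum requires A/C/G/T ref and alt alleles")
    if (any(snvs$ref == snvs$alt)) stop("ref == alt is not a substitution")
    tb <- table(paste0(snvs$ref, ">", snvs$alt))
    counts[names(tb)] <- as.integer(tb)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  coll_key <- vapply(names(counts), function(k) {
    r <- substr(k, 1, 1); a <- substr(k, 3, 3)
    if (r %in% c("C", "T")) k else paste0(comp[[r]], ">", comp[[a]])
  }, "")
  collapsed <- tapply(counts, coll_key, sum)
  transitions <- c("A>G", "G>A", "C>T", "T>C")
  n <- sum(counts)
  list(counts = counts,
       collapsed = setNames(as.integer(collapsed), names(collapsed)),
       n = n,
       transition_fraction = if (n) sum(counts[transitions]) / n else NA_real_)
}

#' Partition UMI groups into haplotypes by their SNV fingerprints
#'
#' Groups carrying the same SV often descend from distinct original
#' molecules; their SNV sets tell the haplotypes apart. Fingerprints are
#' restricted to positions covered in *all* members, so partial reads do
#' not split a haplotype.
#'
#' @param group_snvs named list (one element per group) of data.frames
#'   with columns `pos` and `alt` (the group's SNVs).
#' @param covered optional named list of integer vectors giving each
#'   group's covered reference positions; default assumes full coverage.
#' @return list of haplotype classes, each a list with `members` (group
#'   names) and `fingerprint` (character key).
#' @export
haplotype_partition <- function(group_snvs, covered = NULL) {
  stopifnot(length(group_snvs) >= 1)
  nm <- names(group_snvs)
  if (is.null(nm)) nm <- as.character(seq_along(group_snvs))
  shared <- NULL
  if (!is.null(covered)) {
    shared <- Reduce(intersect, covered)
  }
  fps <- vapply(group_snvs, function(s) {
    if (!NROW(s)) return("")
    if (!is.null(shared)) s <- s[s$pos %in% shared, , drop = FALSE]
    if (!NROW(s)) return("")
    paste(sort(paste0(s$pos, s$alt)), collapse = "|")
  }, "")
  classes <- split(nm, fps)
  unname(lapply(names(classes), function(k)
    list(members = classes[[k]], fingerprint = k)))
}
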