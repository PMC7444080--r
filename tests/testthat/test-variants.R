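# helpers to build small constructed groups
mk_aln <- function(seqs, reference, ids = sprintf("r%02d", seq_along(seqs))) {
  umivar:::align_reads(seqs, ids, reference)
}

test_that("pileup of identical error-free reads is uniform and mismatch-free", {
  ref <- random_reference(100, seed = 60)
  alns <- mk_aln(rep(ref, 5), ref)
  pu <- pileup_group(alns, ref)
  depth <- colSums(pu$counts[1:4, ])
  expect_true(all(depth == 5L))
  refb <- strsplit(ref, "")[[1]]
  on_ref <- pu$counts[cbind(match(refb, c("A", "C", "G", "T")), 1:100)]
  expect_true(all(on_ref == 5L))
  expect_error(pileup_group(list(), ref), "empty group")
})

test_that("a 4-of-5 alternative base is counted and called; 3-of-5 is not", {
  ref <- random_reference(100, seed = 61)
  stopifnot(substr(ref, 51, 51) != "T")
  mut <- ref
  substr(mut, 51, 51) <- "T"
  refbase <- substr(ref, 51, 51)

  pu <- pileup_group(mk_aln(c(rep(mut, 4), ref), ref), ref)
  expect_equal(unname(pu$counts["T", 51]), 4L)
  expect_equal(unname(pu$counts[refbase, 51]), 1L)
  calls <- call_snvs(pu, ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 50L)
  expect_equal(calls$alt, "T")
  expect_equal(calls$support, 0.8)

  pu2 <- pileup_group(mk_aln(c(rep(mut, 3), ref, ref), ref), ref)
  expect_equal(nrow(call_snvs(pu2, ref)), 0L)
})

test_that("mismatch totals in noisy groups match the binomial expectation", {
  ref <- FIX_REF_168
  set.seed(62)
  tot <- 0L
  nrep <- 30L
  # substitutions confined to the read middle: terminal mismatches can be
  # soft-clipped by the aligner, which would bias the tally downward
  head10 <- substr(ref, 1, 10)
  mid <- substr(ref, 11, 158)
  tail10 <- substr(ref, 159, 168)
  for (k in seq_len(nrep)) {
    seqs <- paste0(head10,
                   as.character(umivar:::mutate_reads_cpp(mid, 8L, 0.05, 0, 0)),
                   tail10)
    pu <- pileup_group(mk_aln(seqs, ref), ref)
    refb <- strsplit(ref, "")[[1]]
    on_ref <- pu$counts[cbind(match(refb, c("A", "C", "G", "T")), 1:168)]
    tot <- tot + sum(colSums(pu$counts[1:4, ]) - on_ref)
  }
  expected <- 0.05 * 8 * 148 * nrep
  halfw <- 2.576 * sqrt(expected * 0.95)
  expect_lt(abs(tot - expected), halfw)
})

test_that("a shared large deletion with breakpoint jitter is called once", {
  ref <- random_reference(4000, seed = 63)
  # 2375-bp deletion starting near 1000, per-read jitter within +/- 3
  set.seed(64)
  seqs <- vapply(1:8, function(k) {
    s <- 1000L + sample(-3:3, 1)
    paste0(substr(ref, 1, s), substr(ref, s + 2375L + 1L, 4000))
  }, "")
  alns <- mk_aln(seqs, ref)
  svs <- call_svs(alns)
  expect_equal(nrow(svs), 1L)
  expect_equal(svs$kind, "deletion")
  expect_lte(abs(svs$start - 1000L), 3L)
  expect_lte(abs(svs$end - 3375L), 3L)
  expect_equal(svs$support, 1)
})

test_that("the 30/31-bp boundary separates small indels from SVs", {
  ref <- random_reference(500, seed = 65)
  del30 <- paste0(substr(ref, 1, 200), substr(ref, 231, 500))
  alns <- mk_aln(rep(del30, 8), ref)
  pu <- pileup_group(alns, ref)
  expect_equal(nrow(call_svs(alns)), 0L)
  small <- call_small_indels(pu, alns, ref)
  expect_equal(nrow(small), 1L)
  expect_equal(small$len, 30L)

  del31 <- paste0(substr(ref, 1, 200), substr(ref, 232, 500))
  alns31 <- mk_aln(rep(del31, 8), ref)
  svs31 <- call_svs(alns31)
  expect_equal(nrow(svs31), 1L)
  expect_equal(svs31$len, 31L)
  expect_equal(nrow(call_small_indels(pileup_group(alns31, ref), alns31, ref)),
               0L)
})

test_that("chimeric minority SVs stay below the support threshold", {
  ref <- random_reference(1500, seed = 66)
  del <- paste0(substr(ref, 1, 500), substr(ref, 1001, 1500))
  alns <- mk_aln(c(rep(del, 2), rep(ref, 6)), ref)
  expect_equal(nrow(call_svs(alns)), 0L)
})

test_that("small indels at a cut site are recovered with exact lengths", {
  ref <- FIX_REF_168
  cut <- 84L  # 0-based cut position
  alleles <- list(
    allele_spec("del2", 0.4, data.frame(kind = "deletion", pos = cut,
                                        payload = "2")),
    allele_spec("del5", 0.3, data.frame(kind = "deletion", pos = cut,
                                        payload = "5")),
    allele_spec("ins1", 0.3, data.frame(kind = "insertion", pos = cut,
                                        payload = "A")))
  spec <- population_spec(ref, alleles, n_molecules = 60,
                          umi_design = FIX_DESIGN, seed = 67)
  sim <- simulate_run(spec, model = error_model_preset("perfect"),
                      reads_per_molecule = list(mean = 8, dispersion = 3))
  cfg <- run_config(sim$reads, c(amplicon = ref), FIX_DESIGN)
  run <- suppressMessages(run_pipeline(cfg))
  calls <- run$callset$calls
  expect_setequal(calls$kind, c("small_deletion", "small_insertion"))
  expect_setequal(calls$len[calls$kind == "small_deletion"], c(2L, 5L))
  expect_equal(calls$len[calls$kind == "small_insertion"], 1L)
  truth <- truth_variant_set(sim$truth, reference = ref)
  m <- match(paste(calls$kind, calls$start, calls$len),
             paste(truth$kind, truth$start, truth$len))
  expect_false(any(is.na(m)))
  expect_equal(calls$supp, truth$n_molecules[m])
})

test_that("a lone 1-base insertion in one of 8 reads is not called", {
  ref <- random_reference(300, seed = 68)
  ins1 <- paste0(substr(ref, 1, 150), "A", substr(ref, 151, 300))
  alns <- mk_aln(c(ins1, rep(ref, 7)), ref)
  pu <- pileup_group(alns, ref)
  expect_equal(nrow(call_small_indels(pu, alns, ref)), 0L)
})

test_that("the group filter keeps clean groups and drops collisions and junk", {
  ref <- random_reference(1200, seed = 69)
  clean <- group_call(rep(ref, 6), sprintf("r%d", 1:6), "AAAATGAAAA", ref)
  expect_gte(clean$mean_identity, 0.99)

  # synthetic UMI collision: 4 wild-type reads + 4 reads with a 1-kb deletion
  delseq <- paste0(substr(ref, 1, 100), substr(ref, 1101, 1200))
  collided <- group_call(c(rep(ref, 4), rep(delseq, 4)),
                         sprintf("r%d", 1:8), "CCCCTGCCCC", ref)
  expect_true(collided$sv_ambiguous)

  # 40% shuffled bases: identity collapses
  set.seed(70)
  junk <- vapply(1:6, function(k) {
    b <- strsplit(ref, "")[[1]]
    idx <- sample.int(1200, 480)
    b[idx] <- sample(c("A", "C", "G", "T"), 480, replace = TRUE)
    paste(b, collapse = "")
  }, "")
  noisy <- group_call(junk, sprintf("r%d", 1:6), "GGGGTGGGGG", ref)

  kept <- group_filter(list(clean, collided, noisy))
  expect_equal(vapply(kept, `[[`, "", "umi"), "AAAATGAAAA")
  expect_equal(attr(kept, "n_dropped"), 2L)
})

test_that("a two-haplotype collision under one UMI is dropped by the conflict rule", {
  ref <- random_reference(400, seed = 71)
  hapA <- ref
  hapB <- ref
  for (p in c(50L, 150L, 250L, 350L)) {
    cur <- substr(hapB, p, p)
    substr(hapB, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  collided <- group_call(c(rep(hapA, 4), rep(hapB, 4)),
                         sprintf("r%d", 1:8), "TTTTTGTTTT", ref)
  expect_gte(collided$conflict_positions, 3L)
  expect_length(group_filter(list(collided)), 0L)
})

test_that("identical variants merge across groups with correct supports", {
  ref <- random_reference(200, seed = 72)
  mk_mut <- function(pos1, alt) { s <- ref; substr(s, pos1, pos1) <- alt; s }
  altA <- setdiff(c("A", "C", "G", "T"), substr(ref, 101, 101))[1]
  altB <- setdiff(c("A", "C", "G", "T"), substr(ref, 51, 51))[1]
  g1 <- group_call(rep(mk_mut(101, altA), 5), sprintf("a%d", 1:5),
                   "AAAATGAAAA", ref)
  g2 <- group_call(rep(mk_mut(101, altA), 6), sprintf("b%d", 1:6),
                   "CCCCTGCCCC", ref)
  g3 <- group_call(rep(mk_mut(51, altB), 5), sprintf("c%d", 1:5),
                   "GGGGTGGGGG", ref)
  cs <- merge_and_filter(group_filter(list(g1, g2, g3)), ref)
  expect_equal(nrow(cs$calls), 2L)
  expect_setequal(cs$calls$supp, c(2L, 1L))
  two <- cs$calls[cs$calls$supp == 2L, ]
  expect_equal(two$start, 100L)
  expect_equal(two$vaf, 2 / 3)
  expect_equal(sort(strsplit(two$id, ";")[[1]]),
               c("AAAATGAAAA_5", "CCCCTGCCCC_6"))
  expect_equal(cs$vcf$pos, c(51L, 101L))  # sorted, 1-based
})

test_that("classification distinguishes target, known, and somatic variants", {
  ref <- random_reference(200, seed = 73)
  alts <- vapply(c(31L, 101L, 171L), function(p)
    setdiff(c("A", "C", "G", "T"), substr(ref, p, p))[1], "")
  mk <- function(p, a) { s <- ref; substr(s, p, p) <- a; s }
  gs <- lapply(1:3, function(i)
    group_call(rep(mk(c(31L, 101L, 171L)[i], alts[i]), 5),
               sprintf("g%d_%d", i, 1:5),
               c("AAAATGAAAA", "CCCCTGCCCC", "GGGGTGGGGG")[i], ref))
  cs <- merge_and_filter(
    group_filter(gs), ref,
    known_variants = data.frame(kind = "snv", start = 30L, alt = alts[1],
                                stringsAsFactors = FALSE),
    target_variant = list(kind = "snv", start = 100L, alt = alts[2]))
  got <- cs$calls[order(cs$calls$start), ]
  expect_equal(got$class, c("known", "target", "somatic"))
})

test_that("calling is deterministic: identical inputs give byte-identical VCFs", {
  sim <- simulate_run(spikein_spec(60, 0.05, seed = 74),
                      platform = "nanopore",
                      reads_per_molecule = list(mean = 12, dispersion = 3))
  render <- function() {
    d <- withr::local_tempdir()
    cfg <- run_config(sim$reads, c(amplicon = FIX_REF_168), FIX_DESIGN,
                      output_dir = d)
    suppressMessages(run_pipeline(cfg))
    readLines(file.path(d, "variants.vcf"))
  }
  expect_identical(render(), render())
})

test_that("raising thresholds never yields more calls (monotonicity)", {
  ref <- random_reference(150, seed = 75)
  set.seed(76)
  seqs <- as.character(umivar:::mutate_reads_cpp(ref, 8L, 0.08, 0, 0))
  alns <- mk_aln(seqs, ref)
  pu <- pileup_group(alns, ref)
  n_lo <- nrow(call_snvs(pu, ref, filter_params(consensus_fraction = 0.5)))
  n_hi <- nrow(call_snvs(pu, ref, filter_params(consensus_fraction = 0.9)))
  expect_lte(n_hi, n_lo)

  sim <- simulate_run(spikein_spec(80, 0.02, seed = 77),
                      platform = "nanopore",
                      reads_per_molecule = list(mean = 8, dispersion = 3))
  ex <- extract_umi(sim$reads, FIX_DESIGN)
  e5 <- attr(group_by_umi(ex, min_reads = 5L), "n_eligible")
  e8 <- attr(group_by_umi(ex, min_reads = 8L), "n_eligible")
  expect_lte(e8, e5)
})

test_that("an inversion allele is called as an SV through the group caller", {
  ref <- random_reference(800, seed = 78)
  invseq <- paste0(substr(ref, 1, 250), revcomp(substr(ref, 251, 450)),
                   substr(ref, 451, 800))
  g <- group_call(rep(invseq, 6), sprintf("r%d", 1:6), "AAAATGAAAA", ref)
  expect_equal(g$svs$kind, "inversion")
  expect_lte(abs(g$svs$start - 250L), 5L)
  expect_lte(abs(g$svs$end - 450L), 5L)
})
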