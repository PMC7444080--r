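test_that("a pure wild-type population with no somatic rate is all reference", {
  spec <- population_spec(FIX_REF_168, list(allele_spec("WT", 1)),
                          n_molecules = 100, umi_design = FIX_DESIGN, seed = 1)
  pop <- build_population(spec)
  expect_length(pop$molecules, 100L)
  expect_true(all(pop$molecules == FIX_REF_168))
  expect_true(all(vapply(pop$truth$edits, nrow, 0L) == 0L))
})

test_that("spike-in molecule counts follow the binomial at 1:100", {
  spec <- spikein_spec(10000, 0.01, seed = 13)
  pop <- build_population(spec)
  n_ki <- sum(pop$truth$allele == "KI")
  sd3 <- 3 * sqrt(10000 * 0.01 * 0.99)
  expect_lte(abs(n_ki - 100), sd3)
  ki <- which(pop$truth$allele == "KI")[1]
  expect_equal(pop$truth$edits[[ki]]$start, FIX_MUT_POS)
})

test_that("a 1:1000 design is representable and edits land on molecules", {
  spec <- spikein_spec(3000, 0.001, seed = 21)
  pop <- build_population(spec)
  ki <- pop$truth$allele == "KI"
  expect_true(all(substr(pop$molecules[ki], FIX_MUT_POS + 1, FIX_MUT_POS + 1)
                  == FIX_MUT_ALT))
  wt <- !ki
  expect_true(all(pop$molecules[wt] == FIX_REF_168))
})

test_that("somatic SNVs are recorded in reference coordinates even on deletion alleles", {
  del_allele <- allele_spec("DEL", 1, data.frame(kind = "deletion", pos = 40,
                                                 payload = "50"))
  spec <- population_spec(FIX_REF_168, list(del_allele), n_molecules = 200,
                          somatic_snv_per_mb = 20000,
                          umi_design = FIX_DESIGN, seed = 3)
  pop <- build_population(spec)
  ed <- do.call(rbind, pop$truth$edits)
  som <- ed[ed$kind == "snv", , drop = FALSE]
  expect_gt(nrow(som), 10)
  # never inside the deleted interval [40, 90)
  expect_true(all(som$start < 40 | som$start >= 90))
  # the recorded ref position carries the recorded alt base on the molecule
  m1 <- which(vapply(pop$truth$edits, function(e) any(e$kind == "snv"), TRUE))[1]
  e1 <- pop$truth$edits[[m1]]
  s1 <- e1[e1$kind == "snv", ][1, ]
  allele_pos <- if (s1$start >= 90) s1$start - 50L else s1$start
  expect_equal(substr(pop$molecules[m1], allele_pos + 1, allele_pos + 1),
               s1$alt)
})

test_that("edits overlapping a deleted interval are rejected", {
  bad <- allele_spec("BAD", 1, data.frame(
    kind = c("deletion", "snv"), pos = c(40L, 60L), payload = c("50", "A")))
  spec <- population_spec(FIX_REF_168, list(bad), n_molecules = 2,
                          umi_design = FIX_DESIGN, seed = 1)
  expect_error(build_population(spec), "deleted interval")
})

test_that("structured UMIs respect fixed bases, are unique, and reproducible", {
  spec <- spikein_spec(500, 0.01, seed = 7)
  pop <- build_population(spec)
  t1 <- tag_with_umis(pop, FIX_DESIGN, seed = 7)
  t2 <- tag_with_umis(pop, FIX_DESIGN, seed = 7)
  expect_identical(t1$truth$umi, t2$truth$umi)
  expect_false(anyDuplicated(t1$truth$umi) > 0)
  expect_true(all(substr(t1$truth$umi, 5, 6) == "TG"))
  expect_true(all(startsWith(t1$molecules, FIX_DESIGN$universal_primer)))
})

test_that("the structured-UMI space bounds the population size", {
  expect_equal(umivar:::umi_space_size("NNNNTGNNNN"), 65536)
  ref <- random_reference(30, seed = 2)
  spec <- population_spec(ref, list(allele_spec("WT", 1)),
                          n_molecules = 65537, umi_design = FIX_DESIGN,
                          seed = 1)
  pop <- build_population(spec)
  expect_error(tag_with_umis(pop, FIX_DESIGN, seed = 1), "too small")
})

test_that("two-ended tagging adds a second unique UMI at the 3' end", {
  spec <- spikein_spec(50, 0.02, seed = 9)
  pop <- tag_with_umis(build_population(spec), FIX_DESIGN, two_ended = TRUE,
                       seed = 9)
  expect_false(any(duplicated(c(pop$truth$umi, pop$truth$umi3))))
  tail_expected <- revcomp(paste0(FIX_DESIGN$universal_primer,
                                  pop$truth$umi3[1]))
  expect_true(endsWith(pop$molecules[1], tail_expected))
})

test_that("zero-error sequencing reproduces the template exactly (up to strand)", {
  spec <- spikein_spec(30, 0.05, seed = 15)
  pop <- tag_with_umis(build_population(spec), FIX_DESIGN, seed = 16)
  out <- amplify_and_sequence(pop, error_model(pcr_per_base = 0),
                              reads_per_molecule = list(mean = 5, dispersion = 1e6),
                              platform = "nanopore", seed = 17)
  tmpl <- setNames(pop$molecules, pop$truth$molecule_id)
  mol_of <- sub("_r.*$", "", out$reads$id)
  ok <- out$reads$seq == tmpl[mol_of] | out$reads$seq == revcomp(tmpl[mol_of])
  expect_true(all(ok))
  expect_gt(mean(out$reads$seq == tmpl[mol_of]), 0.3)  # both strands present
  expect_lt(mean(out$reads$seq == tmpl[mol_of]), 0.7)
})

test_that("substitution counts match the binomial mean on a 168-base template", {
  spec <- population_spec(FIX_REF_168, list(allele_spec("WT", 1)),
                          n_molecules = 1, umi_design = FIX_DESIGN, seed = 19)
  pop <- tag_with_umis(build_population(spec), FIX_DESIGN, seed = 19)
  out <- amplify_and_sequence(pop, error_model(pcr_per_base = 0, seq_sub = 0.05),
                              reads_per_molecule = list(mean = 10000,
                                                        dispersion = 1e9),
                              platform = "nanopore", seed = 20)
  tmpl <- pop$molecules[1]
  L <- nchar(tmpl)
  seqs <- out$reads$seq
  flip <- seqs != tmpl & revcomp(seqs) == tmpl
  # revcomp-ing flipped reads is exact only for error-free reads; instead
  # count mismatches per read against the appropriate strand template
  tb <- strsplit(tmpl, "")[[1]]
  rb <- strsplit(revcomp(tmpl), "")[[1]]
  nmis <- vapply(seqs, function(s) {
    sb <- strsplit(s, "")[[1]]
    min(sum(sb != tb), sum(sb != rb))
  }, 0L, USE.NAMES = FALSE)
  n <- length(seqs)
  expect_gt(n, 5000)
  p <- 0.05
  se <- sqrt(L * p * (1 - p) / n)
  expect_lt(abs(mean(nmis) - L * p), 4 * se + 0.05)
})

test_that("empirical per-base substitution rate matches the model at 1e5+ bases", {
  ref200 <- random_reference(200, seed = 30)
  spec <- population_spec(ref200, list(allele_spec("WT", 1)),
                          n_molecules = 300, umi_design = FIX_DESIGN, seed = 30)
  pop <- tag_with_umis(build_population(spec), FIX_DESIGN, seed = 30)
  sim <- amplify_and_sequence(pop, error_model(pcr_per_base = 0, seq_sub = 0.03),
                              reads_per_molecule = list(mean = 8, dispersion = 3),
                              platform = "nanopore", seed = 31)
  tmpl <- setNames(pop$molecules, pop$truth$molecule_id)
  mol_of <- sub("_r.*$", "", sim$reads$id)
  # substitution-only model: read length equals template length
  expect_true(all(nchar(sim$reads$seq) == nchar(tmpl[mol_of])))
  nmis <- mapply(function(s, t) {
    sb <- strsplit(s, "")[[1]]
    min(sum(sb != strsplit(t, "")[[1]]),
        sum(sb != strsplit(revcomp(t), "")[[1]]))
  }, sim$reads$seq, tmpl[mol_of])
  nbases <- sum(nchar(sim$reads$seq))
  expect_gt(nbases, 1e5)
  phat <- sum(nmis) / nbases
  halfw <- 2.576 * sqrt(0.03 * 0.97 / nbases)
  expect_lt(abs(phat - 0.03), halfw + 1e-4)
})

test_that("truth-table read ids partition the emitted FASTQ exactly", {
  sim <- simulate_run(spikein_spec(40, 0.05, seed = 23),
                      reads_per_molecule = list(mean = 6, dispersion = 3),
                      platform = "nanopore")
  ids <- unlist(sim$truth$read_ids)
  expect_false(anyDuplicated(ids) > 0)
  expect_setequal(ids, sim$reads$id)
  expect_equal(sum(sim$truth$n_reads), nrow(sim$reads))
})

test_that("illumina mode emits 150-base paired ends sharing an id", {
  sim <- simulate_run(spikein_spec(30, 0.05, seed = 25),
                      platform = "illumina",
                      reads_per_molecule = list(mean = 6, dispersion = 3))
  expect_setequal(unique(sim$reads$mate), c("r1", "r2"))
  expect_true(all(nchar(sim$reads$seq) <= 150L))
  per_id <- table(sim$reads$id)
  expect_true(all(per_id == 2L))
  # mate 2 is the reverse-complemented 3' end of the template
  r1 <- sim$reads[sim$reads$mate == "r1", ][1, ]
  expect_true(startsWith(r1$seq, substr(FIX_DESIGN$universal_primer, 1, 20)))
})

test_that("simulation is deterministic under the spec seed", {
  s1 <- simulate_run(spikein_spec(25, 0.04, seed = 31),
                     reads_per_molecule = list(mean = 5, dispersion = 2))
  s2 <- simulate_run(spikein_spec(25, 0.04, seed = 31),
                     reads_per_molecule = list(mean = 5, dispersion = 2))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$umi, s2$truth$umi)
})
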