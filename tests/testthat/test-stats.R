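test_that("somatic load follows the per-megabase formula", {
  expect_equal(somatic_load(0, 1000, 5000), 0)
  expect_equal(round(somatic_load(275, 3479, 6995), 1), 11.3)
  expect_equal(round(somatic_load(103, 3867, 6506), 1), 4.1)
  expect_error(somatic_load(1, 0, 100), ">= 1")
  # linear in the SNV count, inversely proportional to group count
  set.seed(80)
  for (k in 1:20) {
    n <- sample(1:500, 1); g <- sample(100:5000, 1); l <- sample(100:8000, 1)
    expect_equal(somatic_load(2 * n, g, l), 2 * somatic_load(n, g, l))
    expect_equal(somatic_load(n, 2 * g, l), somatic_load(n, g, l) / 2)
  }
})

test_that("detection-power calculator satisfies its boundary invariant", {
  expect_equal(min_groups_for_detection(1, 0.9), 1L)
  expect_equal(min_groups_for_detection(0.5, 0.75), 2L)
  expect_error(min_groups_for_detection(0, 0.9), "undetectable")
  set.seed(81)
  for (k in 1:50) {
    f <- runif(1, 0.001, 0.9)
    conf <- runif(1, 0.5, 0.999)
    n <- min_groups_for_detection(f, conf)
    expect_gte(1 - (1 - f)^n, conf)
    if (n > 1L) expect_lt(1 - (1 - f)^(n - 1L), conf)
  }
})

test_that("the polymerase error budget scales with groups and length", {
  expect_equal(expected_error_groups(0, 168), 0)
  expect_equal(expected_error_groups(1e6, 168), 6, tolerance = 1e-12)
  expect_equal(round(expected_error_groups(15598, 168), 2), 0.09)
})

test_that("VAF arithmetic and Wilson intervals behave", {
  v <- vaf_of_variant(1, 15598)
  expect_equal(signif(v$vaf, 2), 6.4e-5)
  expect_lt(v$lower, v$vaf)
  expect_gt(v$upper, v$vaf)
  expect_equal(vaf_of_variant(10, 10)$vaf, 1)
  expect_error(vaf_of_variant(0, 10))
  expect_error(vaf_of_variant(1, 0), ">= 1")
})

test_that("recurrence clustering groups jittered breakpoints and sorts by count", {
  set.seed(82)
  # 3 hotspot deletions (12, 5, 3 groups) + 4 singleton SVs among 24 groups
  mk <- function(n, s, e, tag) data.frame(
    umi = sprintf("%s%02d", tag, seq_len(n)), kind = "deletion",
    start = s + sample(-3:3, n, TRUE), end = e + sample(-3:3, n, TRUE),
    stringsAsFactors = FALSE)
  svs <- rbind(mk(12, 1000, 6494, "a"), mk(5, 2000, 6715, "b"),
               mk(3, 3000, 5750, "c"),
               data.frame(umi = sprintf("s%d", 1:4), kind = "deletion",
                          start = c(100, 300, 500, 700),
                          end = c(4000, 4300, 4600, 4900),
                          stringsAsFactors = FALSE))
  cl <- cluster_recurrent_svs(svs, breakpoint_tol = 10L)
  expect_equal(cl$count[1:3], c(12L, 5L, 3L))
  expect_equal(sum(cl$count), nrow(svs))
  expect_equal(cl$fraction[1], 12 / 24)
  expect_lte(abs(cl$start[1] - 1000L), 3L)
  # all pairwise-distant events are singletons
  singles <- cluster_recurrent_svs(svs[21:24, ], breakpoint_tol = 10L)
  expect_true(all(singles$count == 1L))
})

test_that("substitution spectra count the 12 classes and the collapsed view", {
  z <- substitution_spectrum(NULL)
  expect_true(all(z$counts == 0L))
  s <- substitution_spectrum(data.frame(ref = c("G", "G", "C"),
                                        alt = c("A", "A", "T"),
                                        stringsAsFactors = FALSE))
  expect_equal(unname(s$counts["G>A"]), 2L)
  expect_equal(unname(s$counts["C>T"]), 1L)
  expect_equal(sum(s$counts), 3L)
  expect_equal(unname(s$collapsed["C>T"]), 3L)  # G>A collapses onto C>T
  expect_equal(s$transition_fraction, 1)
  expect_error(substitution_spectrum(data.frame(ref = "N", alt = "A")))
  expect_error(substitution_spectrum(data.frame(ref = "A", alt = "A")))
})

test_that("a transition-biased SNV set lands near its expected transition fraction", {
  set.seed(83)
  n <- 600L
  is_ti <- runif(n) < 0.8   # Ti:Tv = 4
  ti_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  tv_pairs <- list(c("A", "C"), c("A", "T"), c("C", "A"), c("C", "G"),
                   c("G", "C"), c("G", "T"), c("T", "A"), c("T", "G"))
  pick <- function(pool) pool[[sample.int(length(pool), 1)]]
  snvs <- t(vapply(is_ti, function(t) pick(if (t) ti_pairs else tv_pairs), c("", "")))
  s <- substitution_spectrum(data.frame(ref = snvs[, 1], alt = snvs[, 2],
                                        stringsAsFactors = FALSE))
  halfw <- 2.576 * sqrt(0.8 * 0.2 / n)
  expect_lt(abs(s$transition_fraction - 0.8), halfw + 0.02)
  expect_equal(sum(s$counts), n)
})

test_that("haplotype partitioning merges identical fingerprints", {
  part <- haplotype_partition(list(
    g1 = data.frame(pos = 10L, alt = "A"),
    g2 = data.frame(pos = 50L, alt = "T"),
    g3 = data.frame(pos = 50L, alt = "T")))
  expect_length(part, 2L)
  sizes <- sort(lengths(lapply(part, `[[`, "members")))
  expect_equal(sizes, c(1L, 2L))

  expect_length(haplotype_partition(list(g = data.frame(pos = 1L, alt = "C"))),
                1L)
})

test_that("haplotype fingerprints ignore positions not covered by all members", {
  # g2's read does not cover position 90: its extra SNV there must not split
  part <- haplotype_partition(
    list(g1 = data.frame(pos = c(10L, 50L), alt = c("A", "T")),
         g2 = data.frame(pos = c(10L, 50L, 90L), alt = c("A", "T", "G"))),
    covered = list(g1 = 0:79, g2 = 0:100))
  expect_length(part, 1L)
  expect_setequal(part[[1]]$members, c("g1", "g2"))
})

test_that("simulated two-haplotype SV carriers partition by their phased SNVs", {
  ref <- random_reference(2000, seed = 84)
  posA <- c(100L, 400L, 700L, 1600L, 1900L)
  posB <- c(150L, 450L, 750L, 1650L, 1950L)
  mk_hap <- function(pos) {
    s <- paste0(substr(ref, 1, 1000), substr(ref, 1501, 2000))  # shared 500-del
    for (p in pos) {
      p1 <- if (p >= 1500) p - 500L else p
      cur <- substr(s, p1 + 1, p1 + 1)
      substr(s, p1 + 1, p1 + 1) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    s
  }
  gs <- list(h1a = mk_hap(posA), h1b = mk_hap(posA), h2 = mk_hap(posB))
  calls <- lapply(names(gs), function(nm)
    group_call(rep(gs[[nm]], 6), sprintf("%s_%d", nm, 1:6), nm, ref))
  snv_sets <- setNames(lapply(calls, function(g)
    g$snvs[, c("pos", "alt")]), names(gs))
  part <- haplotype_partition(snv_sets)
  expect_length(part, 2L)
  memb <- lapply(part, `[[`, "members")
  two <- memb[[which(lengths(memb) == 2L)]]
  expect_setequal(two, c("h1a", "h1b"))
})
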