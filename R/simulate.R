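# Synthetic UMI-labeled amplicon reads with molecule-level ground truth.
#
# The generative model mirrors a spike-in experiment: a molecule population
# drawn from a small set of alleles (wild-type, a knock-in SNV at a preset
# frequency, optionally large deletion/insertion/inversion alleles), plus
# independent somatic SNVs per molecule at a per-megabase rate. Each
# molecule is tagged with a unique structured UMI, suffers at most one
# first-copy PCR substitution pass (the dominant, inescapable artifact
# mode: an error in the barcoded first copy propagates to every read of
# that molecule), and is then sequenced with platform-specific per-read
# errors.

#' Generate a random amplicon reference
#'
#' @param length reference length in bp.
#' @param seed RNG seed.
#' @param gc GC content.
#' @return a single character string.
#' @export
random_reference <- function(length, seed = 1L, gc = 0.5) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' Define an allele of the simulated population
#'
#' @param label allele name.
#' @param frequency allele frequency in the molecule population.
#' @param edits data.frame with columns `kind` (`"snv"`, `"deletion"`,
#'   `"insertion"`, `"inversion"`), `pos` (0-based reference coordinate;
#'   insertions are placed before this position), and `payload` (alt base
#'   for SNVs, length for deletions/inversions, inserted sequence for
#'   insertions). `NULL` for a wild-type allele.
#' @return an object of class `allele_spec`.
#' @export
allele_spec <- function(label, frequency, edits = NULL) {
  if (is.null(edits))
    edits <- data.frame(kind = character(), pos = integer(),
                        payload = character(), stringsAsFactors = FALSE)
  stopifnot(frequency >= 0, frequency <= 1,
            all(edits$kind %in% c("snv", "deletion", "insertion", "inversion")))
  structure(list(label = label, frequency = frequency,
                 edits = data.frame(kind = edits$kind,
                                    pos = as.integer(edits$pos),
                                    payload = as.character(edits$payload),
                                    stringsAsFactors = FALSE)),
            class = "allele_spec")
}

#' Sequencing/PCR error model
#'
#' @param pcr_per_base per-base substitution probability of the single
#'   first-copy PCR pass. Default derived from a high-fidelity polymerase
#'   budget of ~6 errors per 1e6 unique 168-bp molecules, i.e.
#'   `6e-6 / 168` per base.
#' @param seq_sub,seq_ins,seq_del per-base substitution / insertion /
#'   deletion probabilities of a sequencing read.
#' @param read_len read length in bp, or `"full"` for full-length long
#'   reads.
#' @return an object of class `error_model`.
#' @export
error_model <- function(pcr_per_base = 6e-6 / 168,
                        seq_sub = 0, seq_ins = 0, seq_del = 0,
                        read_len = "full") {
  stopifnot(pcr_per_base >= 0, pcr_per_base < 1,
            seq_sub >= 0, seq_ins >= 0, seq_del >= 0,
            seq_sub + seq_ins + seq_del < 1)
  structure(list(pcr_per_base = pcr_per_base, seq_sub = seq_sub,
                 seq_ins = seq_ins, seq_del = seq_del, read_len = read_len),
            class = "error_model")
}

#' Platform error-model presets
#'
#' Calibration choices for three platform archetypes: `"nanopore"`
#' (high substitution and indel error, full-length reads), `"illumina"`
#' (low substitution error, 150-bp paired ends), `"pacbio"` (HiFi-like low
#' error, full-length reads).
#'
#' @param platform one of `"nanopore"`, `"illumina"`, `"pacbio"`, or
#'   `"perfect"` (no sequencing error; PCR error still applies).
#' @return an [error_model()].
#' @export
error_model_preset <- function(platform = c("nanopore", "illumina", "pacbio",
                                            "perfect")) {
  platform <- match.arg(platform)
  switch(platform,
    nanopore = error_model(seq_sub = 0.05, seq_ins = 0.03, seq_del = 0.04),
    illumina = error_model(seq_sub = 0.001, seq_ins = 1e-5, seq_del = 1e-5,
                           read_len = 150L),
    pacbio = error_model(seq_sub = 0.002, seq_ins = 0.002, seq_del = 0.002),
    perfect = error_model(pcr_per_base = 0))
}

#' Specify a simulated molecule population
#'
#' @param reference amplicon reference sequence.
#' @param alleles list of [allele_spec()]; frequencies must sum to 1.
#' @param n_molecules number of original molecules.
#' @param somatic_snv_per_mb expected somatic SNVs per megabase per
#'   molecule (independent across molecules).
#' @param umi_design [umi_design()] used for tagging.
#' @param seed RNG seed governing the whole simulation.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(reference, alleles, n_molecules,
                            somatic_snv_per_mb = 0, umi_design = NULL,
                            seed = 1L) {
  spec <- structure(list(reference = toupper(reference), alleles = alleles,
                         n_molecules = as.integer(n_molecules),
                         somatic_snv_per_mb = somatic_snv_per_mb,
                         umi_design = umi_design, seed = as.integer(seed)),
                    class = "population_spec")
  v <- validate_population_spec(spec)
  if (length(v)) stop("invalid population spec: ", paste(v, collapse = "; "))
  spec
}

#' Validate a population spec
#'
#' @param spec a `population_spec` (or a bare list with the same fields).
#' @return character vector of violations; empty when valid.
#' @export
validate_population_spec <- function(spec) {
  v <- character(0)
  L <- nchar(spec$reference)
  if (L < 1L) v <- c(v, "reference is empty")
  if (is.null(spec$alleles) || !length(spec$alleles)) {
    v <- c(v, "no alleles")
  } else {
    fsum <- sum(vapply(spec$alleles, function(a) a$frequency, 0))
    if (abs(fsum - 1) > 1e-6)
      v <- c(v, sprintf("allele frequencies sum to %g, not 1", fsum))
    for (a in spec$alleles) {
      e <- a$edits
      if (!nrow(e)) next
      if (any(e$pos < 0L | e$pos >= L))
        v <- c(v, sprintf("allele %s: edit position outside reference", a$label))
      iv <- e$kind %in% c("deletion", "inversion")
      if (any(iv) && any(e$pos[iv] + as.integer(e$payload[iv]) > L))
        v <- c(v, sprintf("allele %s: interval extends past reference end", a$label))
    }
  }
  if (is.na(spec$n_molecules) || spec$n_molecules < 1L)
    v <- c(v, "n_molecules must be >= 1")
  if (spec$somatic_snv_per_mb < 0) v <- c(v, "somatic_snv_per_mb must be >= 0")
  v
}

# Apply an allele's edits to the reference. Returns the allele sequence and
# `ref_of`, the 0-based reference coordinate of each allele base (NA for
# inserted or inverted bases), used to place somatic SNVs in reference
# coordinates. Edits are applied right-to-left so positions stay valid.
apply_edits <- function(reference, edits) {
  b <- strsplit(reference, "")[[1]]
  src <- seq_along(b) - 1L
  if (nrow(edits)) {
    deleted <- rep(FALSE, length(b))
    for (i in which(edits$kind == "deletion")) {
      deleted[(edits$pos[i] + 1L):(edits$pos[i] + as.integer(edits$payload[i]))] <- TRUE
    }
    other <- edits$kind != "deletion"
    if (any(other) && any(deleted[edits$pos[other] + 1L]))
      stop("edit overlaps a deleted interval")
    for (i in order(edits$pos, decreasing = TRUE)) {
      kind <- edits$kind[i]; pos <- edits$pos[i]; pl <- edits$payload[i]
      if (kind == "snv") {
        b[pos + 1L] <- pl
      } else if (kind == "deletion") {
        len <- as.integer(pl)
        keep <- setdiff(seq_along(b), (pos + 1L):(pos + len))
        b <- b[keep]; src <- src[keep]
      } else if (kind == "insertion") {
        ins <- strsplit(toupper(pl), "")[[1]]
        b <- append(b, ins, after = pos)
        src <- append(src, rep(NA_integer_, length(ins)), after = pos)
      } else if (kind == "inversion") {
        len <- as.integer(pl)
        idx <- (pos + 1L):(pos + len)
        b[idx] <- strsplit(revcomp(paste(b[idx], collapse = "")), "")[[1]]
        src[idx] <- NA_integer_
      }
    }
  }
  list(seq = paste(b, collapse = ""), ref_of = src)
}

# canonical truth representation of an allele's edits (reference coords)
canonical_edits <- function(edits) {
  if (!nrow(edits))
    return(empty_edits())
  out <- lapply(seq_len(nrow(edits)), function(i) {
    kind <- edits$kind[i]; pos <- edits$pos[i]; pl <- edits$payload[i]
    if (kind == "snv") {
      data.frame(kind = "snv", start = pos, end = pos + 1L, len = 1L,
                 alt = pl, seq = "", stringsAsFactors = FALSE)
    } else if (kind == "insertion") {
      data.frame(kind = "insertion", start = pos, end = pos,
                 len = nchar(pl), alt = "", seq = toupper(pl),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(kind = kind, start = pos, end = pos + as.integer(pl),
                 len = as.integer(pl), alt = "", seq = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

empty_edits <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             len = integer(), alt = character(), seq = character(),
             stringsAsFactors = FALSE)
}

#' Draw a molecule population with ground truth
#'
#' Each molecule draws an allele by frequency, then receives independent
#' somatic SNVs at the per-base rate implied by `somatic_snv_per_mb`
#' (placed only at positions that survive the allele's indels, so every
#' somatic edit has a reference coordinate).
#'
#' @param spec [population_spec()].
#' @return list with `molecules` (character vector of sequences) and
#'   `truth`, a data.frame with `molecule_id`, `allele`, and list-column
#'   `edits` of canonical per-molecule edit tables (reference coordinates).
#' @export
build_population <- function(spec) {
  set.seed(spec$seed)
  labels <- vapply(spec$alleles, function(a) a$label, "")
  freqs <- vapply(spec$alleles, function(a) a$frequency, 0)
  applied <- lapply(spec$alleles, function(a) apply_edits(spec$reference, a$edits))
  names(applied) <- labels
  base_truth <- lapply(spec$alleles, function(a) canonical_edits(a$edits))
  names(base_truth) <- labels

  draw <- sample(labels, spec$n_molecules, replace = TRUE, prob = freqs)
  rate <- spec$somatic_snv_per_mb * 1e-6
  molecules <- character(spec$n_molecules)
  edits <- vector("list", spec$n_molecules)
  for (m in seq_len(spec$n_molecules)) {
    al <- applied[[draw[m]]]
    seq <- al$seq
    ed <- base_truth[[draw[m]]]
    if (rate > 0) {
      alive <- which(!is.na(al$ref_of))
      nmut <- rbinom(1L, length(alive), rate)
      if (nmut > 0L) {
        at <- sample(alive, nmut)
        b <- strsplit(seq, "")[[1]]
        for (p in at) {
          alt <- sample(setdiff(BASES, b[p]), 1L)
          ed <- rbind(ed, data.frame(kind = "snv", start = al$ref_of[p],
                                     end = al$ref_of[p] + 1L, len = 1L,
                                     alt = alt, seq = "",
                                     stringsAsFactors = FALSE))
          b[p] <- alt
        }
        seq <- paste(b, collapse = "")
      }
    }
    molecules[m] <- seq
    edits[[m]] <- ed[order(ed$start), , drop = FALSE]
  }
  truth <- data.frame(molecule_id = sprintf("m%05d", seq_len(spec$n_molecules)),
                      allele = draw, stringsAsFactors = FALSE)
  truth$edits <- edits
  list(molecules = molecules, truth = truth)
}

umi_space_size <- function(pattern) {
  4^sum(strsplit(pattern, "")[[1]] == "N")
}

# encode 1-based indices into the structured-UMI space as UMI strings
encode_umis <- function(idx, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  npos <- which(pat == "N")
  k <- length(npos)
  out <- matrix(rep(pat, length(idx)), nrow = length(idx), byrow = TRUE)
  x <- idx - 1
  for (d in seq_len(k)) {
    out[, npos[k - d + 1L]] <- BASES[(x %% 4) + 1]
    x <- x %/% 4
  }
  apply(out, 1L, paste, collapse = "")
}

#' Tag molecules with unique structured UMIs
#'
#' Prepends `universal_primer + UMI` to each molecule. UMIs are sampled
#' uniformly *without replacement* from the structured space (fixed pattern
#' bases respected, N positions random), so UMIs are collision-free by
#' construction. With `two_ended = TRUE` the 3' end is additionally tagged
#' with the reverse complement of `universal_primer + UMI2`.
#'
#' @param population result of [build_population()].
#' @param design [umi_design()].
#' @param two_ended also tag the 3' end with a second UMI.
#' @param seed RNG seed.
#' @return `population` with `molecules` replaced by tagged sequences and
#'   `truth` gaining a `umi` column (and `umi3` when two-ended).
#' @export
tag_with_umis <- function(population, design, two_ended = FALSE, seed = 1L) {
  set.seed(seed)
  n <- length(population$molecules)
  space <- umi_space_size(design$umi_pattern)
  need <- if (two_ended) 2L * n else n
  if (need > space)
    stop(sprintf("structured-UMI space (%d) too small for %d molecules",
                 space, n))
  idx <- sample.int(space, need)
  umis <- encode_umis(idx[seq_len(n)], design$umi_pattern)
  tagged <- paste0(design$universal_primer, umis, population$molecules)
  population$truth$umi <- umis
  if (two_ended) {
    umi3 <- encode_umis(idx[(n + 1L):(2L * n)], design$umi_pattern)
    tagged <- paste0(tagged, revcomp(paste0(design$universal_primer, umi3)))
    population$truth$umi3 <- umi3
  }
  population$molecules <- tagged
  population
}

# inject per-base errors (substitution/insertion/deletion, disjoint per
# base); compiled hot path, driven by R's RNG for set.seed reproducibility
mutate_seq <- function(seq, sub, ins, del) {
  if (sub + ins + del == 0) return(seq)
  mutate_reads_cpp(seq, 1L, sub, ins, del)
}

platform_qchar <- c(nanopore = "-", illumina = "F", pacbio = "?")

#' Amplify tagged molecules and emit sequencing reads
#'
#' Per molecule: one PCR substitution pass at `pcr_per_base` applied to the
#' barcoded copy (so a PCR error propagates to all reads of that molecule),
#' then per-read independent sequencing errors. Long-read platforms emit
#' full-length reads, about half reverse-complemented; `illumina` emits
#' paired 150-bp ends (mate 2 reverse-complemented).
#'
#' @param population tagged population from [tag_with_umis()].
#' @param model [error_model()].
#' @param reads_per_molecule list with `mean` and `dispersion` of a
#'   negative binomial read-count distribution (default mean 8).
#' @param platform `"nanopore"`, `"illumina"` or `"pacbio"`.
#' @param seed RNG seed.
#' @return list with `reads` (data.frame id/seq/qual/mate) and `truth`
#'   (the input truth gaining a `read_ids` list-column and `n_reads`).
#' @export
amplify_and_sequence <- function(population, model,
                                 reads_per_molecule = list(mean = 8, dispersion = 3),
                                 platform = c("nanopore", "illumina", "pacbio"),
                                 seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(reads_per_molecule$mean >= 1)
  set.seed(seed)
  n <- length(population$molecules)
  nreads <- rnbinom(n, mu = reads_per_molecule$mean,
                    size = reads_per_molecule$dispersion)
  qc <- platform_qchar[[platform]]
  ids <- vector("list", n); seqs <- vector("list", n)
  mates <- vector("list", n); flips <- vector("list", n)
  read_ids <- vector("list", n)
  for (m in seq_len(n)) {
    if (nreads[m] == 0L) {
      ids[[m]] <- character(0); seqs[[m]] <- character(0)
      mates[[m]] <- character(0); flips[[m]] <- logical(0)
      read_ids[[m]] <- character(0)
      next
    }
    template <- mutate_seq(population$molecules[m], model$pcr_per_base, 0, 0)
    base_id <- sprintf("%s_r%03d", population$truth$molecule_id[m],
                       seq_len(nreads[m]))
    rs <- mutate_reads_cpp(template, nreads[m], model$seq_sub, model$seq_ins,
                           model$seq_del)
    if (platform == "illumina") {
      rl <- if (identical(model$read_len, "full")) 150L else as.integer(model$read_len)
      r1 <- substr(rs, 1L, rl)
      r2 <- substr(rs, pmax(1L, nchar(rs) - rl + 1L), nchar(rs))
      ids[[m]] <- rep(base_id, each = 2L)
      seqs[[m]] <- as.vector(rbind(r1, r2))
      mates[[m]] <- rep(c("r1", "r2"), nreads[m])
      flips[[m]] <- rep(c(FALSE, TRUE), nreads[m])   # mate 2 reported revcomp
    } else {
      ids[[m]] <- base_id
      seqs[[m]] <- rs
      mates[[m]] <- rep("single", nreads[m])
      flips[[m]] <- runif(nreads[m]) < 0.5
    }
    read_ids[[m]] <- base_id
  }
  reads <- data.frame(id = unlist(ids), seq = unlist(seqs),
                      stringsAsFactors = FALSE)
  flip <- unlist(flips)
  if (any(flip)) reads$seq[flip] <- revcomp(reads$seq[flip])
  reads$qual <- strrep(qc, nchar(reads$seq))
  reads$mate <- unlist(mates)
  population$truth$read_ids <- read_ids
  population$truth$n_reads <- nreads
  list(reads = reads, truth = population$truth)
}

#' Simulate a full UMI-labeled amplicon sequencing run
#'
#' Composes [build_population()], [tag_with_umis()] and
#' [amplify_and_sequence()], deriving stage seeds from `spec$seed`.
#'
#' @param spec [population_spec()] (must carry a `umi_design`).
#' @param model [error_model()]; default is the platform preset.
#' @param reads_per_molecule negative binomial read-count spec.
#' @param platform sequencing platform archetype.
#' @param two_ended tag both molecule ends.
#' @return list with `reads`, `truth`, and a `manifest` list (counts,
#'   seed, platform).
#' @export
simulate_run <- function(spec, model = NULL,
                         reads_per_molecule = list(mean = 8, dispersion = 3),
                         platform = c("nanopore", "illumina", "pacbio"),
                         two_ended = FALSE) {
  platform <- match.arg(platform)
  if (is.null(model)) model <- error_model_preset(platform)
  if (is.null(spec$umi_design)) stop("population_spec needs a umi_design")
  pop <- build_population(spec)
  pop <- tag_with_umis(pop, spec$umi_design, two_ended = two_ended,
                       seed = spec$seed + 1L)
  out <- amplify_and_sequence(pop, model, reads_per_molecule, platform,
                              seed = spec$seed + 2L)
  out$manifest <- list(n_molecules = spec$n_molecules,
                       n_reads = nrow(out$reads),
                       platform = platform, seed = spec$seed,
                       somatic_snv_per_mb = spec$somatic_snv_per_mb,
                       alleles = setNames(
                         lapply(spec$alleles, function(a) a$frequency),
                         vapply(spec$alleles, function(a) a$label, "")))
  out
}
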