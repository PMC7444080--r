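# End-to-end orchestration: extract -> group -> align -> call -> merge ->
# stats. Per-group work is independent; results do not depend on the
# worker count.

#' Assemble a pipeline run configuration
#'
#' @param reads FASTQ path or a reads data.frame (see [read_fastq()]).
#' @param reference FASTA path or a named character vector of length 1.
#' @param design [umi_design()].
#' @param params [filter_params()].
#' @param aparams [alignment_params()].
#' @param known_variants optional known-variant data.frame (see
#'   [merge_and_filter()]).
#' @param target_variant optional spike-in/target variant spec.
#' @param paired treat the FASTQ as paired-end.
#' @param output_dir optional directory for VCF/TSV/JSON outputs; `NULL`
#'   keeps results in memory only.
#' @param seed seed recorded in the manifest (the calling stages are
#'   deterministic; the seed matters only for simulation upstream).
#' @param threads worker count for per-group calling; any value yields
#'   identical results.
#' @return an object of class `run_config`.
#' @export
run_config <- function(reads, reference, design,
                       params = filter_params(),
                       aparams = alignment_params(),
                       known_variants = NULL, target_variant = NULL,
                       paired = FALSE, output_dir = NULL, seed = 1L,
                       threads = 1L) {
  structure(list(reads = reads, reference = reference, design = design,
                 params = params, aparams = aparams,
                 known_variants = known_variants,
                 target_variant = target_variant, paired = paired,
                 output_dir = output_dir, seed = as.integer(seed),
                 threads = as.integer(threads)),
            class = "run_config")
}

resolve_reads <- function(reads, paired) {
  if (is.character(reads)) read_fastq(reads, paired = paired) else reads
}

resolve_reference <- function(reference) {
  if (length(reference) == 1L && is.character(reference) &&
      file.exists(reference) && !grepl("^[ACGTN]+$", reference)) {
    reference <- read_fasta(reference)
  }
  if (is.null(names(reference)) || !nzchar(names(reference)[1]))
    names(reference) <- "amplicon"
  if (length(reference) != 1L) stop("exactly one reference sequence expected")
  reference
}

#' Run the full UMI consensus variant-calling pipeline
#'
#' Stages, in order: read input, extract structured UMIs, bin reads into
#' UMI groups, per-group alignment and consensus calling (SNVs, small
#' indels, SVs), group filtering, population-level merge/classification,
#' and summary statistics. With `output_dir` set, writes `variants.vcf`,
#' `groups.tsv`, `stats.json` and `manifest.json`.
#'
#' @param config [run_config()].
#' @return an object of class `umivar_run`: list with `manifest` (stage
#'   funnel counts and variant counts by class), `groups` (the
#'   [group_by_umi()] table), `group_calls` (post-filter
#'   [group_call()] results), `callset` ([merge_and_filter()] result), and
#'   `stats` (somatic load inputs, spectrum, SV recurrence).
#' @export
run_pipeline <- function(config) {
  reads <- resolve_reads(config$reads, config$paired)
  reference <- resolve_reference(config$reference)
  refseq <- unname(reference[1])
  refname <- names(reference)[1]
  params <- config$params

  message(sprintf("[umivar] %d reads in", nrow(reads)))
  extr <- extract_umi(reads, config$design)
  groups_tab <- group_by_umi(extr, min_reads = params$min_reads)
  n_with_umi <- attr(groups_tab, "n_with_umi")
  message(sprintf("[umivar] %d reads with high-confidence UMI (%.1f%%), %d UMI groups, %d eligible",
                  n_with_umi, 100 * n_with_umi / max(1L, nrow(reads)),
                  nrow(groups_tab), attr(groups_tab, "n_eligible")))

  eligible <- groups_tab[groups_tab$eligible, , drop = FALSE]
  insert_of <- split(extr$insert_seq, extr$read_id)
  call_one <- function(i) {
    ids <- eligible$read_ids[[i]]
    seqs <- unlist(insert_of[ids], use.names = FALSE)
    ids_full <- rep(ids, lengths(insert_of[ids]))
    group_call(seqs, ids_full, eligible$umi[i], refseq, params,
               config$aparams)
  }
  idx <- seq_len(nrow(eligible))
  gcalls <- if (config$threads > 1L) {
    parallel::mclapply(idx, call_one, mc.cores = config$threads)
  } else {
    lapply(idx, call_one)
  }
  kept <- group_filter(gcalls, params)
  message(sprintf("[umivar] %d/%d groups pass the group filter",
                  length(kept), length(gcalls)))

  callset <- merge_and_filter(kept, refseq, params,
                              known_variants = config$known_variants,
                              target_variant = config$target_variant,
                              reference_name = refname)
  calls <- callset$calls

  snv_calls <- calls[calls$kind == "snv", , drop = FALSE]
  somatic_snvs <- snv_calls[snv_calls$class == "somatic", , drop = FALSE]
  sv_calls <- calls[calls$kind %in% c("deletion", "insertion", "inversion"),
                    , drop = FALSE]
  sv_group_umis <- unique(unlist(sv_calls$umis))
  spectrum <- if (nrow(snv_calls))
    substitution_spectrum(snv_calls) else substitution_spectrum(NULL)

  manifest <- list(
    n_reads = nrow(reads),
    n_with_umi = n_with_umi,
    n_umi_groups = nrow(groups_tab),
    n_eligible_groups = length(gcalls),
    n_groups_pass_filter = length(kept),
    median_reads_per_group = attr(groups_tab, "median_eligible_reads"),
    n_variants = nrow(calls),
    variants_by_class = as.list(table(calls$class)),
    n_snvs = nrow(snv_calls),
    n_somatic_snvs = sum(vapply(seq_len(nrow(somatic_snvs)), function(i)
      somatic_snvs$supp[i], 0L)),
    n_sv_groups = length(sv_group_umis),
    sv_group_fraction = if (length(kept))
      length(sv_group_umis) / length(kept) else 0,
    seed = config$seed,
    params = unclass(params),
    version = as.character(utils::packageVersion("umivar"))
  )

  run <- structure(list(manifest = manifest, groups = groups_tab,
                        group_calls = kept, callset = callset,
                        stats = list(spectrum = spectrum,
                                     sv_calls = sv_calls)),
                   class = "umivar_run")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(callset$vcf, refname,
              file.path(config$output_dir, "variants.vcf"),
              reference_length = nchar(refseq))
    gt <- as.data.frame(groups_tab)[, c("umi", "read_count", "eligible")]
    write.table(gt, file.path(config$output_dir, "groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(spectrum = as.list(spectrum$counts),
           transition_fraction = spectrum$transition_fraction),
      file.path(config$output_dir, "stats.json"), auto_unbox = TRUE,
      digits = NA)
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.umivar_run <- function(x, ...) {
  m <- x$manifest
  cat("umivar run\n")
  cat(sprintf("  reads: %d total, %d with UMI\n", m$n_reads, m$n_with_umi))
  cat(sprintf("  groups: %d total, %d eligible, %d pass filter (median %s reads)\n",
              m$n_umi_groups, m$n_eligible_groups, m$n_groups_pass_filter,
              format(m$median_reads_per_group)))
  cat(sprintf("  variants: %d (%s)\n", m$n_variants,
              paste(sprintf("%s %d", names(m$variants_by_class),
                            unlist(m$variants_by_class)), collapse = ", ")))
  invisible(x)
}

#' Simulate a run from a population spec and write FASTQ + truth to disk
#'
#' Accepts either a `population_spec` built in code or a path to a JSON
#' spec with fields `reference` (sequence or FASTA path), `alleles`
#' (label/frequency/edits), `n_molecules`, `somatic_snv_per_mb`, `seed`,
#' `design` (universal_primer/umi_pattern/...), `platform`, and
#' `reads_per_molecule` (mean/dispersion).
#'
#' @param spec `population_spec` or JSON path.
#' @param output_dir output directory; receives `reads.fastq`,
#'   `truth.tsv`, `reference.fa` and `manifest.json`.
#' @param model optional [error_model()] override.
#' @param reads_per_molecule read-count distribution spec.
#' @param platform platform archetype.
#' @return the [simulate_run()] result, invisibly.
#' @export
simulate_cmd <- function(spec, output_dir,
                         model = NULL,
                         reads_per_molecule = list(mean = 8, dispersion = 3),
                         platform = "nanopore") {
  if (is.character(spec)) {
    js <- jsonlite::read_json(spec, simplifyVector = FALSE)
    parsed <- parse_spec_json(js)
    spec <- parsed$spec
    if (!is.null(parsed$platform)) platform <- parsed$platform
    if (!is.null(parsed$reads_per_molecule))
      reads_per_molecule <- parsed$reads_per_molecule
    if (!is.null(parsed$model)) model <- parsed$model
  }
  sim <- simulate_run(spec, model = model,
                      reads_per_molecule = reads_per_molecule,
                      platform = platform)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads, file.path(output_dir, "reads.fastq"))
  write_fasta(c(amplicon = spec$reference),
              file.path(output_dir, "reference.fa"))
  tt <- sim$truth
  flat <- data.frame(
    molecule_id = tt$molecule_id, allele = tt$allele, umi = tt$umi,
    n_reads = tt$n_reads,
    edits = vapply(tt$edits, function(e) {
      if (!nrow(e)) return("")
      paste(sprintf("%s:%d-%d:%s%s", e$kind, e$start, e$end,
                    e$alt, e$seq), collapse = ",")
    }, ""),
    read_ids = vapply(tt$read_ids, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  write.table(flat, file.path(output_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

# build a population_spec (+ run options) from a parsed JSON list,
# reporting all schema violations at once
parse_spec_json <- function(js) {
  errs <- character(0)
  need <- c("reference", "alleles", "n_molecules")
  for (f in need) if (is.null(js[[f]])) errs <- c(errs, paste("missing field:", f))
  if (length(errs)) stop("invalid spec: ", paste(errs, collapse = "; "))
  ref <- js$reference
  if (file.exists(ref)) ref <- unname(read_fasta(ref)[1])
  alleles <- lapply(js$alleles, function(a) {
    ed <- if (is.null(a$edits)) NULL else
      do.call(rbind, lapply(a$edits, function(e)
        data.frame(kind = e$kind, pos = e$pos, payload = as.character(e$payload),
                   stringsAsFactors = FALSE)))
    allele_spec(a$label, a$frequency, ed)
  })
  design <- if (is.null(js$design)) NULL else
    umi_design(js$design$universal_primer,
               umi_pattern = js$design$umi_pattern %||% "NNNNTGNNNN",
               gene_specific = js$design$gene_specific %||% "",
               max_primer_mismatches = js$design$max_primer_mismatches %||% 3L)
  spec <- tryCatch(
    population_spec(ref, alleles, js$n_molecules,
                    somatic_snv_per_mb = js$somatic_snv_per_mb %||% 0,
                    umi_design = design, seed = js$seed %||% 1L),
    error = function(e) stop("invalid spec: ", conditionMessage(e)))
  model <- if (is.null(js$error_model)) NULL else
    error_model(pcr_per_base = js$error_model$pcr_per_base %||% (6e-6 / 168),
                seq_sub = js$error_model$seq_sub %||% 0,
                seq_ins = js$error_model$seq_ins %||% 0,
                seq_del = js$error_model$seq_del %||% 0,
                read_len = js$error_model$read_len %||% "full")
  rpm <- if (is.null(js$reads_per_molecule)) NULL else js$reads_per_molecule
  list(spec = spec, platform = js$platform, model = model,
       reads_per_molecule = rpm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
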