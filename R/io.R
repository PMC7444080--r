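# File formats: FASTA, FASTQ (optionally gzipped), VCF v4.2.
# Reads are kept as a plain data.frame (id, seq, qual, mate) -- amplicon
# runs are small enough that a specialised container buys nothing.

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records (gzip accepted, detected by `.gz` extension)
#' into a data frame of reads. Qualities are kept as Phred+33 strings; use
#' [phred_scores()] to decode them to integers.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @param paired if `TRUE`, read ids suffixed `/1` and `/2` (or containing a
#'   trailing space-separated mate tag) are interleaved by shared id and the
#'   `mate` column is set to `"r1"`/`"r2"`; otherwise all reads are
#'   `"single"`.
#' @return data.frame with columns `id`, `seq`, `qual`, `mate`.
#' @export
read_fastq <- function(path, paired = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      mate = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L)
    stop("truncated FASTQ record starting at line ", (n %/% 4L) * 4L + 1L)
  hd <- lines[seq(1L, n, by = 4L)]
  sq <- toupper(lines[seq(2L, n, by = 4L)])
  pl <- lines[seq(3L, n, by = 4L)]
  ql <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop("malformed FASTQ header at line ", (bad[1L] - 1L) * 4L + 1L)
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop("malformed FASTQ separator at line ", (bad[1L] - 1L) * 4L + 3L)
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop("sequence/quality length mismatch at line ", (bad[1L] - 1L) * 4L + 2L)
  bad <- which(nchar(sq) == 0L)
  if (length(bad))
    stop("empty sequence at line ", (bad[1L] - 1L) * 4L + 2L)
  id <- sub("\\s.*$", "", substring(hd, 2L))
  mate <- rep("single", length(id))
  if (paired) {
    is1 <- grepl("/1$", id)
    is2 <- grepl("/2$", id)
    mate[is1] <- "r1"
    mate[is2] <- "r2"
    id <- sub("/[12]$", "", id)
    ord <- order(match(id, unique(id)), match(mate, c("r1", "r2", "single")))
    id <- id[ord]; sq <- sq[ord]; ql <- ql[ord]; mate <- mate[ord]
  }
  data.frame(id = id, seq = sq, qual = ql, mate = mate,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param path output path; `.gz` extension triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  id <- reads$id
  if (!is.null(reads$mate) && any(reads$mate %in% c("r1", "r2"))) {
    sfx <- ifelse(reads$mate == "r1", "/1", ifelse(reads$mate == "r2", "/2", ""))
    id <- paste0(id, sfx)
  }
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", id)
  out[seq(2L, length(out), by = 4L)] <- reads$seq
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- reads$qual
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()]; sequences are uppercased and
#' multi-line records concatenated. Duplicate record names are an error.
#'
#' @param path path to a FASTA file (gzip accepted).
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate FASTA record name: ",
                              nm[duplicated(nm)][1L])
  setNames(toupper(as.character(ss)), nm)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# INFO keys this package emits; write_vcf() refuses anything else so the
# header always declares every key present in the body.
VCF_INFO_SCHEMA <- data.frame(
  key = c("TYPE", "END", "SVLEN", "SUPP", "TOTAL", "VAF", "CLASS", "SEQ"),
  number = c("1", "1", "1", "1", "1", "1", "1", "1"),
  type = c("String", "Integer", "Integer", "Integer", "Integer", "Float",
           "String", "String"),
  desc = c("Variant type (SNV, DEL, INS, INV)",
           "End position of the event on the reference (1-based, inclusive)",
           "Event length in bp (negative for deletions)",
           "Number of UMI groups supporting the variant",
           "Total number of eligible UMI groups",
           "Variant allele fraction: SUPP / TOTAL",
           "Variant class (target, known, somatic)",
           "Inserted sequence for insertions"),
  stringsAsFactors = FALSE
)

format_info <- function(info) {
  if (is.null(info) || length(info) == 0L) return(".")
  keys <- names(info)
  bad <- setdiff(keys, VCF_INFO_SCHEMA$key)
  if (length(bad)) stop("unknown INFO key: ", paste(bad, collapse = ", "))
  paste(vapply(keys, function(k) {
    v <- info[[k]]
    if (is.double(v) && !is.na(v)) v <- format(v, scientific = FALSE, digits = 6)
    paste0(k, "=", v)
  }, ""), collapse = ";")
}

#' Write variant calls to a VCF v4.2 file
#'
#' The ID column carries the supporting UMI groups in the form
#' `<UMI>_<read_count>`, semicolon-separated when a variant is supported by
#' more than one group.
#'
#' @param entries data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, `qual`, and a list-column `info` of named lists whose
#'   keys must belong to the declared INFO schema. Must be sorted by
#'   (`chrom`, `pos`).
#' @param reference_name name of the reference sequence (contig header).
#' @param path output path.
#' @param reference_length optional contig length for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(entries, reference_name, path, reference_length = NA) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=umivar",
           if (is.na(reference_length))
             sprintf("##contig=<ID=%s>", reference_name)
           else
             sprintf("##contig=<ID=%s,length=%d>", reference_name,
                     as.integer(reference_length)),
           sprintf("##INFO=<ID=%s,Number=%s,Type=%s,Description=\"%s\">",
                   VCF_INFO_SCHEMA$key, VCF_INFO_SCHEMA$number,
                   VCF_INFO_SCHEMA$type, VCF_INFO_SCHEMA$desc),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(entries)) {
    if (is.unsorted(order(entries$chrom, entries$pos)) ||
        any(diff(order(entries$chrom, entries$pos)) < 0) ||
        !identical(order(entries$chrom, entries$pos), seq_len(nrow(entries))))
      stop("VCF entries must be sorted by (chrom, pos)")
    if (any(entries$pos < 1L)) stop("VCF positions are 1-based")
    if (any(!nzchar(entries$ref)) || any(!nzchar(entries$alt)))
      stop("ref and alt must be non-empty")
    info <- vapply(entries$info, format_info, "")
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\tPASS\t%s",
                    entries$chrom, as.integer(entries$pos), entries$id,
                    entries$ref, entries$alt,
                    formatC(entries$qual, format = "g", digits = 6), info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse a VCF file written by [write_vcf()]
#'
#' Minimal reader for this package's own VCF output (used by downstream
#' reporting); for general VCFs use a dedicated parser.
#'
#' @param path VCF path.
#' @return data.frame with the 8 fixed columns, INFO expanded to a
#'   list-column `info`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(), qual = numeric(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- lapply(f, function(x) {
    if (x[8] == ".") return(list())
    kv <- strsplit(strsplit(x[8], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    setNames(lapply(kv, function(p) p[2]), vapply(kv, `[`, "", 1))
  })
  out <- data.frame(chrom = vapply(f, `[`, "", 1),
                    pos = as.integer(vapply(f, `[`, "", 2)),
                    id = vapply(f, `[`, "", 3),
                    ref = vapply(f, `[`, "", 4),
                    alt = vapply(f, `[`, "", 5),
                    qual = as.numeric(vapply(f, `[`, "", 6)),
                    stringsAsFactors = FALSE)
  out$info <- info
  out
}
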