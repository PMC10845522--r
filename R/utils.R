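#' Internal: random DNA sequence as a character scalar
#'
#' @param n length in bases
#' @param gc target GC fraction; A/T and C/G are split evenly
#' @noRd
random_dna <- function(n, gc = 0.35) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- charToRaw("ACGT")
  rawToChar(bases[sample.int(4L, n, replace = TRUE, prob = p)])
}

#' Internal: reverse complement of a character vector of sequences
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Internal: mutate a sequence with random substitutions at a given rate
#' @noRd
mutate_seq <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  r <- charToRaw(seq)
  hit <- which(runif(length(r)) < divergence)
  if (length(hit)) {
    bases <- charToRaw("ACGT")
    repl <- bases[sample.int(4L, length(hit), replace = TRUE)]
    same <- repl == r[hit]
    while (any(same)) {
      repl[same] <- bases[sample.int(4L, sum(same), replace = TRUE)]
      same <- repl == r[hit]
    }
    r[hit] <- repl
  }
  rawToChar(r)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a named character vector or a [Biostrings::DNAStringSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file path (uncompressed or gzip).
#' @return tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x),
    quality = as.character(S4Vectors::mcols(x)$qualities)
  )
}

#' Write a read table to a FASTQ file
#'
#' @param reads tibble with columns `id`, `sequence`, `quality`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Write intervals to a BED file (0-based half-open)
#'
#' @param x tibble with columns `chrom`, `start`, `end`; any further columns are
#'   appended as extra BED columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  out <- x[, c("chrom", "start", "end", extra)]
  for (cl in names(out)[vapply(out, is.list, logical(1))]) {
    out[[cl]] <- vapply(out[[cl]], paste, character(1), collapse = ",")
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Parses features typed `gene` and returns their coordinates converted to
#' 0-based half-open intervals. Each line is validated; a malformed line stops
#' with its line number.
#'
#' @param path GFF3 file path.
#' @param feature feature type to keep (column 3), default `"gene"`.
#' @return tibble with columns `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @export
read_gff_genes <- function(path, feature = "gene") {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    abort(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
                  idx[bad[1]], lengths(fields)[bad[1]]))
  }
  m <- do.call(rbind, fields)
  starts <- suppressWarnings(as.integer(m[, 4]))
  ends <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad)) {
    abort(sprintf("malformed GFF3 line %d: non-numeric start/end", idx[bad[1]]))
  }
  sel <- m[, 3] == feature
  attrs <- m[sel, 9]
  ids <- ifelse(grepl("ID=", attrs),
                sub(".*ID=([^;]+).*", "\\1", attrs),
                paste0("feature", seq_len(sum(sel))))
  tibble(
    chrom = m[sel, 1],
    start = starts[sel] - 1L,   # GFF3 is 1-based inclusive
    end = ends[sel],
    strand = m[sel, 7],
    gene_id = ids
  )
}

#' Internal: validate a read table
#' @noRd
check_reads <- function(reads) {
  if (!is.data.frame(reads) || !all(c("id", "sequence", "quality") %in% names(reads)))
    abort("`reads` must be a data frame with columns id, sequence, quality")
  if (nrow(reads) && any(nchar(reads$sequence) != nchar(reads$quality)))
    abort("quality string length must equal sequence length for every read")
  invisible(reads)
}

#' Internal: tibble of (chrom, length) from assorted inputs
#' @noRd
as_chrom_lengths <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "length") %in% names(x)))
    tibble(chrom = as.character(x$chrom), length = as.integer(x$length))
  } else {
    if (is.null(names(x))) names(x) <- paste0("chr", seq_along(x))
    tibble(chrom = names(x), length = as.integer(x))
  }
}

#' Internal: interval tibble -> GRanges (0-based half-open in, 1-based in GRanges)
#' @noRd
to_granges <- function(x, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels %||% unique(x$chrom)),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}
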