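#' Read and write sequence sets
#'
#' Thin wrappers around Biostrings for FASTA/FASTQ I/O; sequences travel
#' through the package as named character vectors.
#'
#' @param path file path.
#' @return `read_fasta()` / `read_fastq()` return a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line width for FASTA wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_seqs(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(nchar(s), starts + width - 1L)), con)
  }
  invisible(path)
}

#' @rdname read_fasta
#' @param qual_char flat per-base quality character for FASTQ output.
#' @export
write_fastq <- function(seqs, path, qual_char = "I") {
  seqs <- as_seqs(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    writeLines(c(paste0("@", names(seqs)[i]), s, "+",
                 strrep(qual_char, nchar(s))), con)
  }
  invisible(path)
}

#' Read/write a read truth table
#'
#' Tab-separated: read_id, genome, strain, start, end, strand (0-based
#' half-open intervals).
#'
#' @param truth data.frame as produced by [simulate_reads()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a simulated community to disk
#'
#' Long reads are written as FASTA, short reads as FASTQ with flat
#' qualities; the truth table as TSV and the genome set as FASTA. A manifest
#' (YAML) records what was written.
#'
#' @param sim a `read_sim` from [simulate_reads()].
#' @param dir output directory (created if absent).
#' @param mode `"long"` or `"short"`; decides the read format.
#' @export
write_community <- function(sim, dir, mode = c("long", "short")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "read_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gpath <- file.path(dir, "genomes.fasta")
  write_fasta(as_seqs(sim$genomes), gpath)
  rpath <- file.path(dir, if (mode == "long") "reads.fasta" else "reads.fastq")
  if (mode == "long") write_fasta(sim$reads, rpath)
  else write_fastq(sim$reads, rpath)
  tpath <- file.path(dir, "truth.tsv")
  write_truth(sim$truth, tpath)
  manifest <- list(genomes = basename(gpath), reads = basename(rpath),
                   truth = basename(tpath), n_reads = length(sim$reads),
                   mode = mode)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Write alignments as BLAST outfmt-6-compatible TSV
#'
#' Columns follow the conventional 12-column tabular format; coordinates are
#' converted to 1-based inclusive (noted in the header comment).
#'
#' @param hits alignment data.frame from [map_reads()] or [align_pair()].
#' @param path file path.
#' @export
write_alignments <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# qseqid\tsseqid\tpident\tlength\tmismatch\tgapopen\t",
                    "qstart\tqend\tsstart\tsend\tevalue\tbitscore ",
                    "(coordinates 1-based inclusive)"), con)
  if (nrow(hits) > 0L) {
    mismatch <- round(hits$aln_len - hits$matches)
    out <- data.frame(hits$query_id, hits$subject_id,
                      sprintf("%.2f", hits$pident), hits$aln_len, mismatch,
                      0L, hits$qstart + 1L, hits$qend, hits$sstart + 1L,
                      hits$send, NA, hits$score)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
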