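#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read gene models from GFF3, splicing transcripts from exon features
#'
#' Exon features are grouped by their `Parent` attribute (falling back to
#' `ID` when no parent is recorded), ordered by start coordinate, extracted
#' from the genome (1-based inclusive coordinates, as in GFF3) and
#' concatenated; minus-strand transcripts are reverse-complemented so the
#' returned sequence reads 5' to 3'.
#'
#' @param path GFF3 file.
#' @param genome named character vector of chromosome sequences (e.g. from
#'   [read_fasta()]).
#' @return data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `transcript_seq`, suitable for [build_reference_index()].
#' @export
read_gene_models <- function(path, genome) {
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  is_exon <- tolower(as.character(meta$type)) == "exon"
  if (!any(is_exon)) stop("no exon features in ", path)
  ex <- gr[is_exon]
  exm <- S4Vectors::mcols(ex)
  parent <- if ("Parent" %in% names(exm)) {
    vapply(as.list(exm$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(ex))
  if ("ID" %in% names(exm)) {
    parent[is.na(parent)] <- as.character(exm$ID)[is.na(parent)]
  }
  if (anyNA(parent)) stop("exon features must carry Parent or ID attributes")

  ord <- order(parent, GenomicRanges::start(ex))
  ex <- ex[ord]
  parent <- parent[ord]
  ids <- unique(parent)
  out <- lapply(ids, function(g) {
    e <- ex[parent == g]
    chrom <- as.character(GenomicRanges::seqnames(e))[1]
    strand <- as.character(GenomicRanges::strand(e))[1]
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    pieces <- substring(genome[[chrom]], GenomicRanges::start(e),
                        GenomicRanges::end(e))
    s <- paste(pieces, collapse = "")
    if (strand == "-") s <- revcomp(s)
    data.frame(gene_id = g, chrom = chrom, strand = strand,
               transcript_seq = s, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write single-exon gene models as GFF3
#'
#' Emits a `gene` and an `exon` feature per row (1-based inclusive
#' coordinates).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tdgetag_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id), con)
    writeLines(sprintf("%s\tdgetag_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e1;Parent=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id,
                       g$gene_id), con)
  }
  invisible(path)
}

#' Read a FASTQ file as a character vector of read sequences
#'
#' Quality strings are parsed by the reader but carry no information used by
#' this pipeline beyond the `N` calls already present in the sequence, so
#' only the sequences are returned.
#'
#' @param path FASTQ file.
#' @return character vector of reads (uppercased).
#' @export
read_fastq_reads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  toupper(unname(as.character(x)))
}

#' Write reads as FASTQ (Sanger encoding)
#'
#' Constant quality `I` (Phred 40) everywhere except `N` positions, which get
#' `!` (Phred 0).
#'
#' @param reads character vector of read sequences.
#' @param path output path.
#' @param id_prefix read-name prefix.
#' @export
write_fastq <- function(reads, path, id_prefix = "read") {
  quals <- chartr("ACGTN", "IIII!", reads)
  lines <- character(4L * length(reads))
  lines[seq(1L, by = 4L, length.out = length(reads))] <-
    sprintf("@%s_%d", id_prefix, seq_along(reads))
  lines[seq(2L, by = 4L, length.out = length(reads))] <- reads
  lines[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(reads))] <- quals
  writeLines(lines, path)
  invisible(path)
}
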