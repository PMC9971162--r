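## Format boundaries. Everything internal is 1-based inclusive; BED and
## bedGraph are converted on read. Writers round-trip losslessly.

#' Read a circRNA candidate table (TSV, 1-based coordinates)
#'
#' Expects at least circ_id, chrom, acceptor_pos, donor_pos, strand, gene_id;
#' extra factor columns are preserved. Validates the backsplice orientation
#' (donor downstream of acceptor on `+`, mirrored on `-`) and, when a genome
#' is supplied, that coordinates lie inside their chromosome.
#'
#' @param path TSV file path.
#' @param genome Optional genome for coordinate validation.
#' @return Data.frame of candidates.
#' @export
read_candidates <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("circ_id", "chrom", "acceptor_pos", "donor_pos", "strand", "gene_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stopf("candidate table misses column(s): %s",
                               paste(miss, collapse = ", "))
  validate_candidates(df, genome)
  df
}

validate_candidates <- function(df, genome = NULL) {
  bad_strand <- !df$strand %in% c("+", "-")
  if (any(bad_strand)) stopf("invalid strand for candidate(s): %s",
                             paste(df$circ_id[bad_strand], collapse = ", "))
  bad_orient <- (df$strand == "+" & df$donor_pos <= df$acceptor_pos) |
                (df$strand == "-" & df$donor_pos >= df$acceptor_pos)
  if (any(bad_orient)) stopf("backsplice orientation violated for: %s",
                             paste(df$circ_id[bad_orient], collapse = ", "))
  if (!is.null(genome)) {
    gchr <- as_genome_chr(genome)
    for (i in seq_len(nrow(df))) {
      ch <- df$chrom[i]
      if (!ch %in% names(gchr)) stopf("candidate %s: chromosome '%s' not in genome",
                                      df$circ_id[i], ch)
      n <- nchar(gchr[[ch]])
      if (df$acceptor_pos[i] < 1L || df$acceptor_pos[i] > n ||
          df$donor_pos[i] < 1L || df$donor_pos[i] > n) {
        stopf("candidate %s: coordinates outside chromosome '%s' (length %d)",
              df$circ_id[i], ch, n)
      }
    }
  }
  invisible(df)
}

#' Write a table as TSV (lossless round-trip with the readers)
#' @param df Data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read exon models from a GTF file
#'
#' Imports `exon` records (1-based inclusive, as GTF is defined) and returns
#' the internal exon table. Records with end < start are rejected.
#'
#' @param path GTF file.
#' @return Data.frame: gene_id, transcript_id, chrom, start, end, strand.
#' @export
read_gtf_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- data.frame(gene_id = gr$gene_id, transcript_id = gr$transcript_id,
                   chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   stringsAsFactors = FALSE)
  if (any(df$end < df$start)) stopf("GTF exon with end < start")
  df
}

#' Write exon models to a GTF file
#' @param exons Exon table (see [read_gtf_exons()]).
#' @param path Output GTF path.
#' @export
write_gtf_exons <- function(exons, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand)
  gr$type <- "exon"
  gr$source <- "circReliability"
  gr$gene_id <- exons$gene_id
  gr$transcript_id <- exons$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read genomic intervals from a BED file (converted to 1-based inclusive)
#' @param path BED file (0-based half-open on disk).
#' @return Data.frame: chrom, start, end (1-based inclusive), plus name/score
#'   when present.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  df
}

#' Read a per-base conservation track from a bedGraph file
#'
#' Expands interval scores to one row per base (1-based positions).
#'
#' @param path bedGraph file (0-based half-open on disk).
#' @return Data.frame: chrom, pos, score.
#' @export
read_conservation_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)
  widths <- ends - starts + 1L
  data.frame(chrom = rep(as.character(GenomeInfoDb::seqnames(gr)), widths),
             pos = unlist(lapply(seq_along(gr), function(i) starts[i]:ends[i])),
             score = rep(gr$score, widths),
             stringsAsFactors = FALSE)
}

#' Write genome sequences as FASTA
#' @param genome Named character vector or DNAStringSet.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- if (methods::is(genome, "DNAStringSet")) genome
         else Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path FASTA path (line wrapping tolerated).
#' @return [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)
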