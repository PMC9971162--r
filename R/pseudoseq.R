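#' Build the BSJ pseudo-sequence of a circRNA candidate
#'
#' Concatenates the 50 exonic-strand nucleotides ending at the donor splice
#' site with the 50 nucleotides starting at the acceptor splice site, yielding
#' the 100-nt junction-centred sequence that a BSJ-spanning read must match.
#' On the minus strand both flanks are reverse-complemented so the
#' pseudo-sequence reads 5'->3' along the transcript. Flanks truncated by a
#' chromosome edge shorten the pseudo-sequence and shift the junction index,
#' with a warning.
#'
#' @param candidate One-row data.frame (or list) with `chrom`, `acceptor_pos`,
#'   `donor_pos`, `strand` (1-based genomic coordinates; on `+` the donor is
#'   downstream of the acceptor, mirrored on `-`).
#' @param genome Named character vector or [Biostrings::DNAStringSet].
#' @param flank Nucleotides taken on each side of the junction (default 50).
#' @return A list of class `"pseudo_seq"`: `circ_id`, `sequence`,
#'   `junction_index` (last donor-side base; 50 for full-length flanks) and
#'   `truncated`.
#' @export
build_pseudo_seq <- function(candidate, genome, flank = 50L) {
  gchr <- as_genome_chr(genome)
  ch <- as.character(candidate$chrom)
  if (!ch %in% names(gchr)) stopf("chromosome '%s' not in genome", ch)
  seq <- gchr[[ch]]
  n <- nchar(seq)
  acc <- as.integer(candidate$acceptor_pos)
  don <- as.integer(candidate$donor_pos)
  strand <- as.character(candidate$strand)
  if (acc < 1L || acc > n || don < 1L || don > n) {
    stopf("BSJ coordinates (%d, %d) outside chromosome '%s' (length %d)",
          acc, don, ch, n)
  }
  if (strand == "+") {
    if (don <= acc) stopf("on + strand donor_pos must exceed acceptor_pos")
    donor_side <- clip_substr(seq, don - flank + 1L, don)
    acceptor_side <- clip_substr(seq, acc, acc + flank - 1L)
  } else if (strand == "-") {
    if (don >= acc) stopf("on - strand donor_pos must be below acceptor_pos")
    donor_side <- revcomp(clip_substr(seq, don, don + flank - 1L))
    acceptor_side <- revcomp(clip_substr(seq, acc - flank + 1L, acc))
  } else {
    stopf("strand must be '+' or '-'")
  }
  truncated <- nchar(donor_side) < flank || nchar(acceptor_side) < flank
  if (truncated) {
    warnf("pseudo-sequence for %s truncated by chromosome edge (%d|%d nt)",
          as.character(candidate$circ_id %||% "candidate"),
          nchar(donor_side), nchar(acceptor_side))
  }
  structure(list(circ_id = as.character(candidate$circ_id %||% NA_character_),
                 sequence = paste0(donor_side, acceptor_side),
                 junction_index = nchar(donor_side),
                 truncated = truncated),
            class = "pseudo_seq")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pseudo_seq <- function(x, ...) {
  cat(sprintf("BSJ pseudo-sequence %s: %d nt, junction after base %d%s\n",
              x$circ_id, nchar(x$sequence), x$junction_index,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}
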