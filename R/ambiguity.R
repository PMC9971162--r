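#' Screen a circRNA candidate for alignment ambiguity
#'
#' Candidates whose BSJ pseudo-sequence can be explained without a back-splice
#' are unreliable and are excluded from all downstream statistics. Two flags
#' are raised:
#' \describe{
#'   \item{has_colinear_explanation}{the full pseudo-sequence aligns to a
#'     single contiguous genomic window (at most `max_window` long, default
#'     2x the pseudo-sequence) or to an annotated transcript's spliced
#'     sequence, covering >= `min_cover_frac` of the pseudo-sequence at
#'     >= `identity_thresh` identity — e.g. a tandem duplication that mimics
#'     the junction;}
#'   \item{has_multiple_hits}{either 50-nt half of the pseudo-sequence
#'     matches two or more distinct genomic loci (either strand) at
#'     approximately `identity_thresh` identity, so the junction placement
#'     is not unique.}
#' }
#' This is a self-contained screen of the same two ambiguity classes used to
#' pre-filter candidate tables in practice; it relies on exhaustive local
#' alignment and mismatch-tolerant exact search rather than an external
#' aligner.
#'
#' @param candidate One-row candidate data.frame.
#' @param pseudo Its [build_pseudo_seq()] result (built if `NULL`).
#' @param genome Named character vector or DNAStringSet.
#' @param exons Optional exon annotation data.frame; when supplied, spliced
#'   transcript sequences are also searched for colinear explanations.
#' @param identity_thresh Identity threshold of the colinear screen
#'   (default 0.9).
#' @param min_cover_frac Minimum covered fraction of the pseudo-sequence
#'   (default 0.8).
#' @param max_window Maximum genomic window accepted as a colinear
#'   explanation (default 2x pseudo-sequence length).
#' @return A one-row data.frame: circ_id, has_colinear_explanation,
#'   has_multiple_hits, ambiguous.
#' @export
screen_ambiguity <- function(candidate, pseudo = NULL, genome, exons = NULL,
                             identity_thresh = 0.9, min_cover_frac = 0.8,
                             max_window = NULL) {
  gchr <- as_genome_chr(genome)
  if (is.null(pseudo)) pseudo <- build_pseudo_seq(candidate, gchr)
  pseq <- pseudo$sequence
  plen <- nchar(pseq)
  if (is.null(max_window)) max_window <- 2L * plen

  colinear <- FALSE
  for (subj in gchr) {
    for (s in c(FALSE, TRUE)) {
      qq <- if (s) revcomp(pseq) else pseq
      aln <- align_local_batch(qq, subj)
      if (is.na(aln$sub_start[1])) next
      cover <- aln$read_end[1] - aln$read_start[1] + 1L
      window <- aln$sub_end[1] - aln$sub_start[1] + 1L
      identity <- if (aln$n_cols[1] > 0L) aln$n_match[1] / aln$n_cols[1] else 0
      if (cover >= min_cover_frac * plen && window <= max_window &&
          identity >= identity_thresh) colinear <- TRUE
    }
    if (colinear) break
  }
  if (!colinear && !is.null(exons)) {
    for (ts in transcript_seqs(exons, gchr)) {
      aln <- align_local_batch(pseq, ts)
      if (is.na(aln$sub_start[1])) next
      cover <- aln$read_end[1] - aln$read_start[1] + 1L
      identity <- if (aln$n_cols[1] > 0L) aln$n_match[1] / aln$n_cols[1] else 0
      if (cover >= min_cover_frac * plen && identity >= identity_thresh) {
        colinear <- TRUE
        break
      }
    }
  }

  ## multiple loci for either 50-nt half (mismatch-tolerant exact search)
  halves <- c(substr(pseq, 1L, pseudo$junction_index),
              substr(pseq, pseudo$junction_index + 1L, plen))
  halves <- halves[nchar(halves) >= 20L]
  multi <- FALSE
  for (h in halves) {
    mm <- floor((1 - identity_thresh) * nchar(h))
    n_loci <- 0L
    for (subj in gchr) {
      dn <- Biostrings::DNAString(subj)
      for (q in c(h, revcomp(h))) {
        m <- Biostrings::matchPattern(Biostrings::DNAString(q), dn,
                                      max.mismatch = mm)
        if (length(m) > 0L) {
          rr <- IRanges::reduce(methods::as(m, "IRanges"))
          n_loci <- n_loci + length(rr)
        }
      }
    }
    if (n_loci >= 2L) { multi <- TRUE; break }
  }

  data.frame(circ_id = as.character(candidate$circ_id %||% NA_character_),
             has_colinear_explanation = colinear,
             has_multiple_hits = multi,
             ambiguous = colinear || multi,
             stringsAsFactors = FALSE)
}

#' Screen many candidates for alignment ambiguity
#'
#' @param candidates Candidate table.
#' @inheritParams screen_ambiguity
#' @return Data.frame with one row per candidate (see [screen_ambiguity()]).
#' @export
screen_ambiguity_all <- function(candidates, genome, exons = NULL,
                                 identity_thresh = 0.9, min_cover_frac = 0.8,
                                 max_window = NULL) {
  do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
    screen_ambiguity(candidates[i, ], NULL, genome, exons,
                     identity_thresh, min_cover_frac, max_window)
  }))
}

## Spliced sequence of every annotated transcript (5'->3').
transcript_seqs <- function(exons, genome) {
  gchr <- as_genome_chr(genome)
  vapply(split(exons, exons$transcript_id), function(df) {
    df <- df[order(df$start), , drop = FALSE]
    s <- paste(substring(gchr[[df$chrom[1]]], df$start, df$end), collapse = "")
    if (df$strand[1] == "-") revcomp(s) else s
  }, character(1))
}
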