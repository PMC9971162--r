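## BSJ read assignment: a read supports a BSJ when its best local alignment
## to the junction pseudo-sequence covers >= min_cover_frac of the
## pseudo-sequence, spans the junction by >= min_span bases on both sides,
## and aligns at >= min_identity per aligned column.

## Best local alignment of each read (optionally also its reverse complement)
## against one subject sequence. Returns a data.frame with one row per read.
best_local_alignment <- function(reads, subject, both_strands = TRUE,
                                 match = 1, mismatch = -1, gap = -2) {
  seqs <- as.character(reads)
  fwd <- align_local_batch(seqs, subject, match, mismatch, gap)
  fwd$strand <- "+"
  if (!both_strands) return(fwd)
  rev <- align_local_batch(revcomp(seqs), subject, match, mismatch, gap)
  rev$strand <- "-"
  take_rev <- rev$score > fwd$score
  out <- fwd
  out[take_rev, ] <- rev[take_rev, ]
  out
}

## Decision rule shared by implementation and reporting.
bsj_hit_rule <- function(aln, pseudo_len, junction_index,
                         min_cover_frac, min_span, min_identity) {
  cover <- aln$sub_end - aln$sub_start + 1L
  left_span <- junction_index - aln$sub_start + 1L
  right_span <- aln$sub_end - junction_index
  identity <- ifelse(aln$n_cols > 0L, aln$n_match / aln$n_cols, 0)
  hit <- !is.na(aln$sub_start) &
    cover >= min_cover_frac * pseudo_len &
    left_span >= min_span & right_span >= min_span &
    identity >= min_identity
  hit & !is.na(hit)
}

#' Count BSJ-supporting reads for one pseudo-sequence
#'
#' A read is counted if its best local alignment (Smith-Waterman, match +1 /
#' mismatch -1 / gap -2 by default) to the pseudo-sequence covers at least
#' `min_cover_frac` of the pseudo-sequence length, includes at least
#' `min_span` bases on each side of the junction, and matches at
#' `min_identity` per aligned column. Each read is counted at most once per
#' BSJ; by default the reverse complement of the read is also tried
#' (unstranded libraries).
#'
#' @param reads Character vector or [Biostrings::DNAStringSet] of reads.
#' @param pseudo A `"pseudo_seq"` from [build_pseudo_seq()].
#' @param min_cover_frac Minimum aligned fraction of the pseudo-sequence
#'   (default 0.8).
#' @param min_span Minimum junction span on each side, bp (default 10).
#' @param min_identity Minimum per-aligned-column identity (default 0.95);
#'   the coverage criterion is interpreted as alignment coverage, with
#'   identity exposed separately.
#' @param both_strands Also align the reverse complement of each read.
#' @param return_hits Return the per-read logical vector instead of the count.
#' @return Integer count (or logical vector when `return_hits = TRUE`).
#' @export
count_bsj_reads <- function(reads, pseudo, min_cover_frac = 0.8,
                            min_span = 10L, min_identity = 0.95,
                            both_strands = TRUE, return_hits = FALSE) {
  if (length(reads) == 0L) return(if (return_hits) logical(0) else 0L)
  aln <- best_local_alignment(reads, pseudo$sequence, both_strands)
  hit <- bsj_hit_rule(aln, nchar(pseudo$sequence), pseudo$junction_index,
                      min_cover_frac, min_span, min_identity)
  if (return_hits) hit else sum(hit)
}

## k-mer prefilter: which pseudo-sequences share at least one k-mer with each
## read (either strand)? Returns a list of candidate pseudo indices per read.
## Purely an accelerator: alignment makes the final call.
kmer_shortlist <- function(read_seqs, pseudo_seqs, k = 16L) {
  tab <- lapply(seq_along(pseudo_seqs), function(i) {
    km <- unique(kmers_of(pseudo_seqs[[i]], k))
    data.frame(kmer = km, idx = i, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)
  n <- length(read_seqs)
  rk <- lapply(seq_len(n), function(i) {
    unique(c(kmers_of(read_seqs[[i]], k), kmers_of(revcomp(read_seqs[[i]]), k)))
  })
  lens <- lengths(rk)
  all_km <- unlist(rk, use.names = FALSE)
  pos <- match(all_km, tab$kmer)
  read_of <- rep.int(seq_len(n), lens)
  keep <- !is.na(pos)
  hits <- split(tab$idx[pos[keep]], read_of[keep])
  out <- rep(list(integer(0)), n)
  out[as.integer(names(hits))] <- lapply(hits, unique)
  out
}

#' Drop reads explainable by the colinear genome
#'
#' Emulates restricting BSJ matching to reads the genome aligner left
#' unmapped: reads that are exact substrings of the reference (either strand)
#' are removed before pseudo-sequence matching. Only exact occurrence is
#' tested, which suffices for the error-free simulated libraries this
#' package generates; real data would arrive pre-filtered by a genome
#' aligner.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector.
#' @param genome Named character vector or DNAStringSet.
#' @return Logical vector, TRUE for reads to keep.
#' @export
filter_linear_reads <- function(reads, genome) {
  gchr <- as_genome_chr(genome)
  rd <- Biostrings::DNAStringSet(as.character(reads))
  widths <- Biostrings::width(rd)
  mapped <- logical(length(rd))
  for (w in unique(widths)) {
    sel <- which(widths == w)
    pd <- Biostrings::PDict(rd[sel])
    pdr <- Biostrings::PDict(Biostrings::reverseComplement(rd[sel]))
    cnt <- integer(length(sel))
    for (ch in names(gchr)) {
      subj <- Biostrings::DNAString(gchr[[ch]])
      cnt <- cnt + Biostrings::countPDict(pd, subj) +
        Biostrings::countPDict(pdr, subj)
    }
    mapped[sel] <- cnt > 0L
  }
  !mapped
}

#' Count BSJ reads for many candidates at once
#'
#' Builds the pseudo-sequence of every candidate, optionally removes reads
#' explainable by the colinear genome, shortlists read/BSJ pairs by shared
#' k-mers, and applies [count_bsj_reads()]'s alignment rule to the shortlist.
#' A read may support several BSJs (all are counted) unless
#' `unique_assignment = TRUE`, in which case it is assigned only to the BSJ
#' with its highest alignment score.
#'
#' @inheritParams count_bsj_reads
#' @param candidates Candidate table (see [read_candidates()]).
#' @param genome Named character vector or DNAStringSet.
#' @param exclude_linear Drop exact genomic substring reads first.
#' @param unique_assignment Assign each read to at most one BSJ.
#' @param prefilter_k k-mer length of the shortlist filter (0 disables).
#' @return Integer vector of counts, named by `circ_id`.
#' @export
count_bsj_reads_multi <- function(reads, candidates, genome,
                                  min_cover_frac = 0.8, min_span = 10L,
                                  min_identity = 0.95, both_strands = TRUE,
                                  exclude_linear = TRUE,
                                  unique_assignment = FALSE,
                                  prefilter_k = 16L) {
  gchr <- as_genome_chr(genome)
  seqs <- as.character(reads)
  if (length(seqs) > 0L && exclude_linear) {
    seqs <- seqs[filter_linear_reads(seqs, gchr)]
  }
  pseudos <- lapply(seq_len(nrow(candidates)),
                    function(i) build_pseudo_seq(candidates[i, ], gchr))
  counts <- stats::setNames(integer(nrow(candidates)), candidates$circ_id)
  if (length(seqs) == 0L) return(counts)
  pseqs <- vapply(pseudos, `[[`, character(1), "sequence")
  short <- if (prefilter_k > 0L) kmer_shortlist(seqs, pseqs, prefilter_k)
           else rep(list(seq_along(pseqs)), length(seqs))
  ## regroup: reads per pseudo
  per_pseudo <- vector("list", length(pseqs))
  idx <- rep.int(seq_along(seqs), lengths(short))
  ps <- unlist(short, use.names = FALSE)
  if (length(ps) > 0L) per_pseudo <- split(idx, factor(ps, levels = seq_along(pseqs)))
  best_score <- rep(-Inf, length(seqs))
  best_bsj <- rep(NA_integer_, length(seqs))
  hit_pairs <- list()
  for (p in seq_along(pseudos)) {
    rid <- per_pseudo[[p]]
    if (length(rid) == 0L) next
    aln <- best_local_alignment(seqs[rid], pseqs[[p]], both_strands)
    hit <- bsj_hit_rule(aln, nchar(pseqs[[p]]), pseudos[[p]]$junction_index,
                        min_cover_frac, min_span, min_identity)
    if (unique_assignment) {
      upd <- hit & aln$score > best_score[rid]
      best_score[rid[upd]] <- aln$score[upd]
      best_bsj[rid[upd]] <- p
    } else {
      counts[p] <- sum(hit)
    }
  }
  if (unique_assignment) {
    tabbed <- table(factor(best_bsj, levels = seq_along(pseudos)))
    counts[] <- as.integer(tabbed)
  }
  counts
}
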