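#' Overlap of CLIP RBP-binding sites with BSJ flanking regions
#'
#' Flags candidates whose BSJ has at least one CLIP-supported RBP-binding
#' interval within `flank` nucleotides of either splice site, and reports the
#' minimum distance from any site to the nearer BSJ coordinate (0 when an
#' interval covers the coordinate).
#'
#' @param candidate One-row candidate data.frame.
#' @param clip_sites Data.frame of genomic intervals (chrom, start, end,
#'   1-based inclusive; use [read_bed_intervals()] for BED input).
#' @param flank Window on each side of each splice site, bp (default 1000).
#' @return One-row data.frame: circ_id, rbp_flank, rbp_min_dist
#'   (NA when no site is on the candidate's chromosome).
#' @export
rbp_flank_overlap <- function(candidate, clip_sites, flank = 1000L) {
  circ_id <- as.character(candidate$circ_id %||% NA_character_)
  sites <- clip_sites[clip_sites$chrom == candidate$chrom, , drop = FALSE]
  if (nrow(sites) == 0L) {
    return(data.frame(circ_id = circ_id, rbp_flank = FALSE,
                      rbp_min_dist = NA_integer_, stringsAsFactors = FALSE))
  }
  dist_to <- function(pos) {
    inside <- sites$start <= pos & sites$end >= pos
    d <- pmin(abs(sites$start - pos), abs(sites$end - pos))
    d[inside] <- 0L
    d
  }
  d <- pmin(dist_to(candidate$donor_pos), dist_to(candidate$acceptor_pos))
  data.frame(circ_id = circ_id, rbp_flank = min(d) <= flank,
             rbp_min_dist = as.integer(min(d)), stringsAsFactors = FALSE)
}

#' Junction-span filter for predicted sites on the pseudo-sequence
#'
#' A predicted G-quadruplex, miRNA-binding or RBP-binding site on the 100-nt
#' BSJ pseudo-sequence is only informative when it actually spans the
#' junction: it must extend at least `min_span[kind]` bases into the
#' donor-side (positions <= `junction_index`) and the acceptor-side
#' (positions > `junction_index`). Defaults: G4 >= 5 bp, miRNA >= 5 bp,
#' RBP >= 2 bp on each side.
#'
#' @param sites Data.frame with columns circ_id, kind (`"G4"`, `"miRNA"`,
#'   `"RBP"`), start, end (1-based inclusive on the pseudo-sequence).
#' @param junction_index Last donor-side base (default 50).
#' @param min_span Named minimum spans per kind.
#' @param pseudo_len Pseudo-sequence length used for validation (default 100).
#' @return Data.frame keyed by circ_id with logical columns g4_span,
#'   mirna_span, rbp_span (one row per circ_id present in `sites`).
#' @export
span_filter <- function(sites, junction_index = 50L,
                        min_span = c(G4 = 5L, miRNA = 5L, RBP = 2L),
                        pseudo_len = 100L) {
  if (nrow(sites) == 0L) {
    return(data.frame(circ_id = character(0), g4_span = logical(0),
                      mirna_span = logical(0), rbp_span = logical(0)))
  }
  if (any(sites$start < 1L | sites$end > pseudo_len | sites$start > sites$end)) {
    stopf("site intervals must satisfy 1 <= start <= end <= %d", pseudo_len)
  }
  if (!all(sites$kind %in% names(min_span))) {
    stopf("unknown site kind(s): %s",
          paste(setdiff(unique(sites$kind), names(min_span)), collapse = ", "))
  }
  ms <- min_span[sites$kind]
  passes <- (junction_index - sites$start + 1L) >= ms &
            (sites$end - junction_index) >= ms
  ids <- unique(sites$circ_id)
  agg <- function(kind) {
    vapply(ids, function(id) {
      any(passes[sites$circ_id == id & sites$kind == kind])
    }, logical(1))
  }
  data.frame(circ_id = ids, g4_span = agg("G4"), mirna_span = agg("miRNA"),
             rbp_span = agg("RBP"), row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean evolutionary rate in the four 10-nt windows around a BSJ
#'
#' Averages per-base conservation scores (phyloP- or phastCons-style) over
#' four windows defined in transcript orientation: the first 10 exonic bases
#' inside the circle at the acceptor, the 10 intronic bases outside it, the
#' last 10 exonic bases at the donor, and the 10 intronic bases beyond the
#' donor. Bases missing from the track are skipped; a fully missing window
#' yields NA. Per-window coverage is reported.
#'
#' @param candidate One-row candidate data.frame.
#' @param score_track Data.frame with columns chrom, pos, score (per-base,
#'   1-based; see [read_conservation_track()]).
#' @param window_size Window width in bp (default 10).
#' @return One-row data.frame: circ_id, the four means
#'   (evo_acceptor_exon, evo_acceptor_intron, evo_donor_exon,
#'   evo_donor_intron) and the four coverage counts.
#' @export
evo_rate_regions <- function(candidate, score_track, window_size = 10L) {
  w <- window_size
  acc <- candidate$acceptor_pos
  don <- candidate$donor_pos
  regions <- if (candidate$strand == "+") {
    list(acceptor_exon = c(acc, acc + w - 1L),
         acceptor_intron = c(acc - w, acc - 1L),
         donor_exon = c(don - w + 1L, don),
         donor_intron = c(don + 1L, don + w))
  } else {
    list(acceptor_exon = c(acc - w + 1L, acc),
         acceptor_intron = c(acc + 1L, acc + w),
         donor_exon = c(don, don + w - 1L),
         donor_intron = c(don - w, don - 1L))
  }
  tr <- score_track[score_track$chrom == candidate$chrom, , drop = FALSE]
  out <- data.frame(circ_id = as.character(candidate$circ_id %||% NA_character_),
                    stringsAsFactors = FALSE)
  for (nm in names(regions)) {
    sel <- tr$pos >= regions[[nm]][1] & tr$pos <= regions[[nm]][2]
    out[[paste0("evo_", nm)]] <- if (any(sel)) mean(tr$score[sel]) else NA_real_
    out[[paste0("cov_", nm)]] <- sum(sel)
  }
  out
}

#' Simple G-quadruplex detector on a pseudo-sequence
#'
#' Reports motifs of four runs of >= 2 guanines separated by loops of up to
#' 12 nt within a total span of at most `max_len` nt (the canonical QGRS
#' motif shape). Presence/absence only; external site tables take precedence
#' when available.
#'
#' @param seq Nucleotide string.
#' @param max_len Maximum motif span (default 30).
#' @return Data.frame with columns start, end (possibly empty).
#' @export
detect_g4 <- function(seq, max_len = 30L) {
  pat <- "G{2,}[ACGT]{0,12}?G{2,}[ACGT]{0,12}?G{2,}[ACGT]{0,12}?G{2,}"
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  keep <- (end - start + 1L) <= max_len
  data.frame(start = start[keep], end = end[keep])
}
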