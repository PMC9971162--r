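#' Count reverse-complementary sequence (RCS) pairs around a BSJ
#'
#' Reverse-complementary sequence pairs in the regions flanking a BSJ can
#' base-pair and bring the two splice sites together, a proposed driver of
#' backsplicing. This counts maximal exact reverse-complement matches of
#' length >= `min_len`:
#' \describe{
#'   \item{rcs_across}{between the two flanks outside the circle (the
#'     `window` nucleotides upstream of the circle's 5' end and downstream of
#'     its 3' end);}
#'   \item{rcs_within}{inside each single flank (hairpin-style), summed over
#'     both flanks; self-reverse-complementary palindromes count once.}
#' }
#' Matching is exact with a configurable minimum length: maximal runs of
#' shared `min_len`-mers on a common alignment diagonal are merged into one
#' match, so an exact complementary stretch of any length >= `min_len` counts
#' exactly once. Flanks are truncated at chromosome ends.
#'
#' @param candidate One-row candidate data.frame.
#' @param genome Named character vector or DNAStringSet.
#' @param window Flank width in bp (default 20000).
#' @param min_len Minimum exact match length (default 30, the scale of the
#'   shorter repeat elements that drive pairing; exact matching keeps the
#'   count brute-force verifiable).
#' @param within_aggregate `"sum"` (default) or `"max"` over the two flanks
#'   for `rcs_within`.
#' @return One-row data.frame: circ_id, rcs_across, rcs_within, rcs_diff.
#' @export
count_rcs <- function(candidate, genome, window = 20000L, min_len = 30L,
                      within_aggregate = c("sum", "max")) {
  within_aggregate <- match.arg(within_aggregate)
  gchr <- as_genome_chr(genome)
  seq <- gchr[[as.character(candidate$chrom)]]
  if (is.null(seq)) stopf("chromosome '%s' not in genome", candidate$chrom)
  lo <- min(candidate$acceptor_pos, candidate$donor_pos)
  hi <- max(candidate$acceptor_pos, candidate$donor_pos)
  up <- clip_substr(seq, lo - window, lo - 1L)
  down <- clip_substr(seq, hi + 1L, hi + window)
  across <- n_rc_matches_between(up, down, min_len)
  w_up <- n_rc_matches_within(up, min_len)
  w_down <- n_rc_matches_within(down, min_len)
  within <- if (within_aggregate == "sum") w_up + w_down else max(w_up, w_down)
  data.frame(circ_id = as.character(candidate$circ_id %||% NA_character_),
             rcs_across = across, rcs_within = within,
             rcs_diff = across - within, stringsAsFactors = FALSE)
}

## Maximal exact matches (as diagonal runs of shared k-mers) between a and
## revcomp(b), reported as a data.frame of segment pairs in the coordinates
## of a and b.
rc_match_segments <- function(a, b, k) {
  ka <- kmers_of(a, k)
  kb <- kmers_of(revcomp(b), k)
  if (length(ka) == 0L || length(kb) == 0L) return(NULL)
  pos_b <- split(seq_along(kb), kb)
  hit_a <- which(ka %in% names(pos_b))
  if (length(hit_a) == 0L) return(NULL)
  bs <- pos_b[ka[hit_a]]
  i <- rep.int(hit_a, lengths(bs))
  j <- unlist(bs, use.names = FALSE)
  d <- i - j
  ord <- order(d, i)
  i <- i[ord]; j <- j[ord]; d <- d[ord]
  new_run <- c(TRUE, diff(d) != 0L | diff(i) != 1L)
  run_id <- cumsum(new_run)
  a1 <- tapply(i, run_id, min)
  a2 <- tapply(i, run_id, max) + k - 1L
  b1r <- tapply(j, run_id, min)
  b2r <- tapply(j, run_id, max) + k - 1L
  nb <- nchar(b)
  ## revcomp(b) position p corresponds to b position nb - p + 1
  data.frame(a_start = as.integer(a1), a_end = as.integer(a2),
             b_start = nb - as.integer(b2r) + 1L,
             b_end = nb - as.integer(b1r) + 1L)
}

n_rc_matches_between <- function(a, b, min_len) {
  seg <- rc_match_segments(a, b, min_len)
  if (is.null(seg)) 0L else nrow(seg)
}

n_rc_matches_within <- function(a, min_len) {
  seg <- rc_match_segments(a, a, min_len)
  if (is.null(seg)) return(0L)
  ## each hairpin appears twice (segment pair and its mirror); canonicalise
  key1 <- paste(seg$a_start, seg$a_end)
  key2 <- paste(seg$b_start, seg$b_end)
  canon <- ifelse(key1 <= key2, paste(key1, key2), paste(key2, key1))
  length(unique(canon))
}
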