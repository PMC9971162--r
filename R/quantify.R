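#' Classify circRNA candidates from mock/treated BSJ counts
#'
#' Computes BSJ reads per million raw reads (RPM) in each library, the
#' treat/mock RPM ratio, and the depletion class: candidates with fewer than
#' `min_mock_reads` mock BSJ reads are `"excluded"`; otherwise a ratio >= 1
#' is `"not-depleted"` and a ratio < 1 `"depleted"` (a treated count of 0
#' gives ratio 0, hence depleted). Candidates not detected in the mock sample
#' at all (0 reads) are omitted, matching detection-based candidate lists.
#'
#' @param circ_id Candidate identifiers.
#' @param mock_count,treated_count BSJ read counts per candidate.
#' @param mock_total,treated_total Raw read totals of the two libraries
#'   (RPM denominators).
#' @param min_mock_reads Minimum mock BSJ reads for a candidate to be
#'   classified (default 2).
#' @return Data.frame: circ_id, mock_count, treated_count, mock_total,
#'   treated_total, mock_rpm, treated_rpm, ratio, depletion_class.
#' @export
quantify_counts <- function(circ_id, mock_count, treated_count,
                            mock_total, treated_total, min_mock_reads = 2L) {
  if (any(c(mock_total, treated_total) <= 0)) stopf("read totals must be positive")
  stopifnot(length(mock_count) == length(circ_id),
            length(treated_count) == length(circ_id))
  keep <- mock_count >= 1L
  circ_id <- circ_id[keep]
  mock_count <- mock_count[keep]
  treated_count <- treated_count[keep]
  mock_rpm <- mock_count * 1e6 / mock_total
  treated_rpm <- treated_count * 1e6 / treated_total
  ratio <- treated_rpm / mock_rpm
  cls <- ifelse(mock_count < min_mock_reads, "excluded",
                ifelse(ratio >= 1, "not-depleted", "depleted"))
  data.frame(circ_id = circ_id, mock_count = mock_count,
             treated_count = treated_count,
             mock_total = mock_total, treated_total = treated_total,
             mock_rpm = mock_rpm, treated_rpm = treated_rpm,
             ratio = ratio, depletion_class = cls,
             stringsAsFactors = FALSE)
}

#' Quantify one mock/treated sample pair from reads
#'
#' Counts junction-spanning reads for every candidate in both libraries (see
#' [count_bsj_reads_multi()]) and classifies candidates with
#' [quantify_counts()]. Alignment-ambiguous candidates should be removed
#' beforehand (see [screen_ambiguity_all()]).
#'
#' @param candidates Candidate table.
#' @param genome Named character vector or DNAStringSet.
#' @param mock_reads,treated_reads Read sets (character or DNAStringSet).
#' @param mock_total,treated_total Raw read totals (RPM denominators).
#' @param min_mock_reads Minimum mock BSJ reads (default 2).
#' @param ... Passed to [count_bsj_reads_multi()] (thresholds, strand and
#'   uniqueness options, linear-read exclusion).
#' @return See [quantify_counts()].
#' @export
quantify_pair <- function(candidates, genome, mock_reads, treated_reads,
                          mock_total, treated_total, min_mock_reads = 2L, ...) {
  mc <- count_bsj_reads_multi(mock_reads, candidates, genome, ...)
  tc <- count_bsj_reads_multi(treated_reads, candidates, genome, ...)
  quantify_counts(candidates$circ_id, as.integer(mc), as.integer(tc),
                  mock_total, treated_total, min_mock_reads)
}

#' Check the inclusion criteria of a mock/treated sample pair
#'
#' A pair enters the analysis only if strictly more than `min_mock_circ`
#' candidates are detected in the mock sample and strictly more than
#' `min_overlap_frac` of them are also detected in the treated sample.
#'
#' @param quant Output of [quantify_counts()] / [quantify_pair()].
#' @param min_mock_circ Required mock-detected candidates (default 600).
#' @param min_overlap_frac Required mock-and-treated overlap fraction
#'   (default 1/3).
#' @return List: pass, n_mock_detected, n_overlap, overlap_frac.
#' @export
check_pair_inclusion <- function(quant, min_mock_circ = 600L,
                                 min_overlap_frac = 1 / 3) {
  n_mock <- sum(quant$mock_count >= 1L)
  n_overlap <- sum(quant$mock_count >= 1L & quant$treated_count >= 1L)
  frac <- if (n_mock > 0L) n_overlap / n_mock else 0
  list(pass = (n_mock > min_mock_circ) && (frac > min_overlap_frac),
       n_mock_detected = n_mock, n_overlap = n_overlap, overlap_frac = frac)
}
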