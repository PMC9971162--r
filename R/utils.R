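## Small shared helpers. Coordinates are 1-based inclusive everywhere.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' Every stochastic stage of the package draws its randomness through this
#' helper so that a single master seed makes whole runs reproducible without
#' clobbering the user's RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Deterministic per-stage seed derived from a master seed; kept < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(reference = 101L, candidates = 211L, reads = 307L,
               pairs = 401L, boot = 503L, logistic = 601L, pipeline = 701L)
  if (!stage %in% names(offsets)) stopf("unknown RNG stage '%s'", stage)
  (as.integer(seed) %% 1000000L) * 2000L + offsets[[stage]]
}

## Reverse complement for plain character vectors (ACGTN only).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Extract a 1-based inclusive substring of a chromosome, clipped to bounds.
clip_substr <- function(seq, start, end) {
  n <- nchar(seq)
  substr(seq, max(1L, start), min(n, end))
}

## Coerce a genome given as DNAStringSet or named character to named character.
as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stopf("genome sequences must be named by chromosome")
    genome
  } else {
    stopf("genome must be a DNAStringSet or a named character vector")
  }
}

## All k-mers of a string as a character vector (empty if too short).
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}
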