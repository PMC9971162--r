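## Independent oracles used across the suite. These deliberately take
## different code paths from the package implementation.

## Full dynamic-programming oracle for BSJ read counting, built on
## Biostrings::pairwiseAlignment with the same scoring scheme
## (match +1, mismatch -1, linear gap -2). Vectorised over reads.
oracle_count_bsj <- function(reads, pseudo, min_cover_frac = 0.8,
                             min_span = 10L, min_identity = 0.95,
                             both_strands = TRUE) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  rd <- Biostrings::DNAStringSet(as.character(reads))
  stats_of <- function(pat) {
    al <- Biostrings::pairwiseAlignment(pat, pseudo$sequence, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2)
    data.frame(score = Biostrings::score(al),
               sub_start = BiocGenerics::start(Biostrings::subject(al)),
               sub_end = BiocGenerics::end(Biostrings::subject(al)),
               n_match = Biostrings::nmatch(al),
               n_cols = Biostrings::nchar(al))
  }
  best <- stats_of(rd)
  if (both_strands) {
    rev <- stats_of(Biostrings::reverseComplement(rd))
    take <- rev$score > best$score
    best[take, ] <- rev[take, ]
  }
  plen <- nchar(pseudo$sequence)
  j <- pseudo$junction_index
  cover <- best$sub_end - best$sub_start + 1L
  identity <- ifelse(best$n_cols > 0, best$n_match / best$n_cols, 0)
  hits <- best$score > 0 &
    cover >= min_cover_frac * plen &
    (j - best$sub_start + 1L) >= min_span &
    (best$sub_end - j) >= min_span &
    identity >= min_identity
  sum(hits)
}

## Step-up Benjamini-Hochberg oracle, written from the definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

## One-sided Wilcoxon rank-sum p by full enumeration of group assignments,
## counting (x > y) pairs directly (ties 0.5) rather than via ranks.
wrst_enum_oracle <- function(x, y, direction = "greater") {
  pooled <- c(x, y)
  n1 <- length(x)
  U_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U_obs <- U_of(seq_len(n1))
  sets <- utils::combn(length(pooled), n1)
  Us <- apply(sets, 2, U_of)
  if (direction == "greater") mean(Us >= U_obs - 1e-9) else mean(Us <= U_obs + 1e-9)
}

## Brute-force RCS oracle: scan every min_len-mer of `a` against revcomp(b)
## with Biostrings::matchPattern, merge diagonal runs, count maximal matches.
rcs_oracle_between <- function(a, b, min_len) {
  brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  subj <- Biostrings::DNAString(brc)
  hits <- NULL
  na <- nchar(a)
  for (i in seq_len(max(0L, na - min_len + 1L))) {
    pat <- substr(a, i, i + min_len - 1L)
    m <- Biostrings::matchPattern(pat, subj)
    if (length(m) > 0L) {
      hits <- rbind(hits, data.frame(i = i, j = BiocGenerics::start(m)))
    }
  }
  if (is.null(hits)) return(data.frame(a_start = integer(0), a_end = integer(0),
                                       b_start = integer(0), b_end = integer(0)))
  d <- hits$i - hits$j
  ord <- order(d, hits$i)
  i <- hits$i[ord]; j <- hits$j[ord]; d <- d[ord]
  run <- cumsum(c(TRUE, diff(d) != 0L | diff(i) != 1L))
  nb <- nchar(b)
  data.frame(a_start = as.integer(tapply(i, run, min)),
             a_end = as.integer(tapply(i, run, max)) + min_len - 1L,
             b_start = nb - (as.integer(tapply(j, run, max)) + min_len - 1L) + 1L,
             b_end = nb - as.integer(tapply(j, run, min)) + 1L)
}

rcs_oracle <- function(a, b, min_len) {
  across <- nrow(rcs_oracle_between(a, b, min_len))
  within_one <- function(s) {
    seg <- rcs_oracle_between(s, s, min_len)
    if (nrow(seg) == 0L) return(0L)
    k1 <- paste(seg$a_start, seg$a_end)
    k2 <- paste(seg$b_start, seg$b_end)
    length(unique(ifelse(k1 <= k2, paste(k1, k2), paste(k2, k1))))
  }
  list(across = across, within = within_one(a) + within_one(b))
}

## Random DNA string helper.
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
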