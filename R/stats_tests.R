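## Per-factor enrichment tests contrasting not-depleted vs depleted
## candidates: Fisher's exact test for binary factors, one-sided Wilcoxon
## rank-sum tests with effect sizes for quantitative factors, and
## Benjamini-Hochberg FDR across sample pairs within each factor.

#' Fisher exact enrichment of a binary factor in not-depleted circRNAs
#'
#' Builds the 2x2 table (factor+/- x not-depleted/depleted), reports the
#' cross-product odds ratio `OR = (a*d)/(b*c)` with a Woolf 95% CI, and the
#' two-tailed exact p-value by hypergeometric enumeration (all tables with
#' probability at most that of the observed table). When any cell is zero
#' the odds ratio and CI use the Haldane +0.5 correction and are flagged;
#' the p-value is always from the uncorrected exact test.
#'
#' @param factor_pos Logical vector: factor present.
#' @param not_depleted Logical vector: candidate classified not-depleted.
#' @param pair_id,factor Labels carried into the result row.
#' @return One-row data.frame (`FactorTestResult`): pair_id, factor, test,
#'   direction, the four cell counts, odds_ratio, ci95_low, ci95_high, p,
#'   effect_direction, haldane.
#' @export
fet_enrichment <- function(factor_pos, not_depleted, pair_id = NA_character_,
                           factor = NA_character_) {
  stopifnot(length(factor_pos) == length(not_depleted))
  keep <- !is.na(factor_pos) & !is.na(not_depleted)
  factor_pos <- as.logical(factor_pos[keep])
  not_depleted <- as.logical(not_depleted[keep])
  if (!any(not_depleted)) stopf("no candidates in the not-depleted class")
  if (!any(!not_depleted)) stopf("no candidates in the depleted class")
  a <- sum(factor_pos & not_depleted)
  b <- sum(factor_pos & !not_depleted)
  c_ <- sum(!factor_pos & not_depleted)
  d <- sum(!factor_pos & !not_depleted)
  p <- fet_two_sided_p(a, b, c_, d)
  haldane <- any(c(a, b, c_, d) == 0L)
  cc <- if (haldane) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c_ + cc))
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc))
  ## Woolf interval on log OR (Haldane cells when any cell is empty)
  lo <- exp(log(or) - stats::qnorm(0.975) * se)
  hi <- exp(log(or) + stats::qnorm(0.975) * se)
  data.frame(pair_id = pair_id, factor = factor, test = "FET",
             direction = "two-sided",
             n_pos_notdep = a, n_pos_dep = b, n_neg_notdep = c_, n_neg_dep = d,
             odds_ratio = or, ci95_low = lo, ci95_high = hi, p = p,
             effect_direction = if (or > 1) "positive" else if (or < 1) "negative" else "none",
             haldane = haldane, stringsAsFactors = FALSE)
}

## Two-tailed Fisher exact p by full hypergeometric enumeration over the
## support of cell a given the table margins.
fet_two_sided_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  support <- max(0L, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' One-sided Wilcoxon rank-sum enrichment of a quantitative factor
#'
#' Compares factor values of not-depleted vs depleted candidates with the
#' Mann-Whitney U statistic (ties counted 0.5). The p-value uses the
#' tie-corrected normal approximation with 0.5 continuity correction, or full
#' enumeration of rank assignments when both groups have at most `exact_max`
#' members. The effect size is `r = |z| / sqrt(N)` (the standardized rank
#' statistic), with a percentile-bootstrap 95% confidence interval.
#'
#' @param values Numeric factor values.
#' @param not_depleted Logical class vector (TRUE = not-depleted, the first
#'   group of the comparison).
#' @param direction `"greater"` (not-depleted values tend larger) or
#'   `"less"`.
#' @param pair_id,factor Labels carried into the result row.
#' @param exact_max Largest group size for exact enumeration (default 9).
#' @param boot Bootstrap replicates for the CI (default 1000; 0 disables).
#' @param boot_seed Seed of the bootstrap stream.
#' @return One-row data.frame: pair_id, factor, test, direction, group sizes,
#'   U statistic, effect_size_r, ci95_low, ci95_high, p, effect_direction.
#' @export
wrst_enrichment <- function(values, not_depleted,
                            direction = c("greater", "less"),
                            pair_id = NA_character_, factor = NA_character_,
                            exact_max = 9L, boot = 1000L, boot_seed = 1L) {
  direction <- match.arg(direction)
  keep <- !is.na(values) & !is.na(not_depleted)
  values <- values[keep]; not_depleted <- as.logical(not_depleted[keep])
  x <- values[not_depleted]; y <- values[!not_depleted]
  if (length(x) == 0L || length(y) == 0L) stopf("both depletion classes must be non-empty")
  st <- wrst_stat(x, y, direction, exact_max)
  if (st$degenerate) warnf("all factor values tied across both groups; p = 0.5, r = 0")
  ci <- c(NA_real_, NA_real_)
  if (boot > 0L && !st$degenerate) {
    ci <- with_seed(boot_seed, {
      rb <- vapply(seq_len(boot), function(i) {
        xs <- sample(x, replace = TRUE); ys <- sample(y, replace = TRUE)
        wrst_stat(xs, ys, direction, exact_max = 0L)$r
      }, numeric(1))
      stats::quantile(rb, c(0.025, 0.975), names = FALSE)
    })
  }
  data.frame(pair_id = pair_id, factor = factor, test = "WRST",
             direction = direction, n_notdep = length(x), n_dep = length(y),
             U = st$U, effect_size_r = st$r, ci95_low = ci[1], ci95_high = ci[2],
             p = st$p,
             effect_direction = if (st$U > length(x) * length(y) / 2) "positive"
                                else if (st$U < length(x) * length(y) / 2) "negative"
                                else "none",
             stringsAsFactors = FALSE)
}

## Core rank-sum computation shared by the test and its bootstrap.
wrst_stat <- function(x, y, direction, exact_max) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  t <- table(pooled)
  tie_term <- sum(t^3 - t) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 0.5, r = 0, degenerate = TRUE))
  sigma <- sqrt(sigma2)
  z <- if (direction == "greater") (U - mu - 0.5) / sigma else (U - mu + 0.5) / sigma
  p <- if (direction == "greater") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z)
  if (exact_max > 0L && max(n1, n2) <= exact_max) {
    sets <- utils::combn(N, n1)
    Us <- colSums(matrix(rk[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- if (direction == "greater") mean(Us >= U - 1e-9) else mean(Us <= U + 1e-9)
  }
  r_raw <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p = p, r = abs(r_raw) / sqrt(N), degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment within factor families
#'
#' Adjusts p-values by the BH step-up procedure, by default within families
#' defined by `family` (one family per examined factor across all sample
#' pairs, matching a per-factor adjustment across pairs). With `family =
#' NULL` a single family covers all tests.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param family Optional family labels (same length as `p`).
#' @return Adjusted values (FDR), same order as `p`.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  stopifnot(length(family) == length(p))
  out <- numeric(length(p))
  for (f in unique(family)) {
    sel <- family == f
    out[sel] <- stats::p.adjust(p[sel], method = "BH")
  }
  out
}
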