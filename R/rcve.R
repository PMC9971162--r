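## Binomial GLM of depletion class on the eight reliability factors, and
## factor importance by relative contribution to variability explained
## (RCVE): remove one factor, refit, and measure the drop in pseudo-r2.

#' Fit the binomial GLM of depletion class on reliability factors
#'
#' Maximum-likelihood logistic regression of `y` (1 = not-depleted,
#' 0 = depleted) on the supplied factor columns, with an intercept. Constant
#' columns are dropped with a warning. Under perfect separation the model is
#' refit with a small ridge penalty (penalised IRLS) and flagged. The
#' pseudo-r2 is McFadden's `1 - ll_model / ll_null` by default, which for
#' nested likelihood-based fits keeps RCVE inside `[0, 1]`; Cox-Snell,
#' Nagelkerke and Tjur are selectable.
#'
#' @param factors Data.frame of numeric/logical factor columns.
#' @param y Binary response (1 = not-depleted).
#' @param pseudo_r2 Pseudo-r2 definition.
#' @param ridge_lambda Ridge penalty used on separation (default 1e-3).
#' @param force_ridge Always use the penalised fit (used by [rcve()] to keep
#'   full and reduced models on the same estimator).
#' @return List of class `"depletion_glm"`: coefficients, logLik, null
#'   logLik, pseudo_r2, n, dropped columns, ridge flag, converged.
#' @export
fit_depletion_glm <- function(factors, y,
                              pseudo_r2 = c("mcfadden", "coxsnell",
                                            "nagelkerke", "tjur"),
                              ridge_lambda = 1e-3, force_ridge = FALSE) {
  pseudo_r2 <- match.arg(pseudo_r2)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("both depletion classes must be present to fit the GLM")
  X <- as.data.frame(lapply(factors, as.numeric))
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  const <- vapply(X, function(v) length(unique(v)) < 2L, logical(1))
  if (any(const)) {
    warnf("dropping constant factor column(s): %s",
          paste(names(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  n <- length(y)
  separated <- FALSE
  fit_mu <- NULL
  beta <- NULL
  converged <- TRUE
  if (ncol(X) > 0L && force_ridge) {
    separated <- TRUE
    rf <- ridge_logistic(as.matrix(X), y, lambda = ridge_lambda)
    fit_mu <- rf$mu; beta <- rf$beta; converged <- rf$converged
    if (!converged) stopf("logistic fit failed to converge (%d iterations)", rf$iter)
  } else if (ncol(X) > 0L) {
    dat <- cbind(y = y, X)
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separated <<- TRUE
          invokeRestart("muffleWarning")
        }
        if (grepl("did not converge", conditionMessage(w))) {
          separated <<- TRUE  # treat as separation-like; refit with ridge
          invokeRestart("muffleWarning")
        }
      })
    converged <- fit$converged
    ## glm can converge silently on separated designs; probe the fit
    if (!separated && any(stats::fitted(fit) < 1e-8 | stats::fitted(fit) > 1 - 1e-8)) {
      separated <- TRUE
    }
    if (separated || !converged) {
      rf <- ridge_logistic(as.matrix(X), y, lambda = ridge_lambda)
      fit_mu <- rf$mu; beta <- rf$beta; converged <- rf$converged
      if (!converged) stopf("logistic fit failed to converge (%d iterations)", rf$iter)
    } else {
      fit_mu <- stats::fitted(fit)
      beta <- stats::coef(fit)
    }
  } else {
    fit_mu <- rep(mean(y), n)
    beta <- c(`(Intercept)` = stats::qlogis(mean(y)))
  }
  ll <- bernoulli_ll(y, fit_mu)
  ll0 <- bernoulli_ll(y, rep(mean(y), n))
  r2 <- switch(pseudo_r2,
    mcfadden = 1 - ll / ll0,
    coxsnell = 1 - exp(2 * (ll0 - ll) / n),
    nagelkerke = (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n)),
    tjur = mean(fit_mu[y == 1L]) - mean(fit_mu[y == 0L]))
  structure(list(coefficients = beta, logLik = ll, logLik_null = ll0,
                 pseudo_r2 = r2, pseudo_r2_type = pseudo_r2, n = n,
                 dropped = names(const)[const], ridge = separated,
                 converged = converged, fitted = fit_mu),
            class = "depletion_glm")
}

bernoulli_ll <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

## Penalised IRLS logistic regression (ridge on all non-intercept terms);
## fallback for separated designs. Log-likelihood is reported unpenalised.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100L, tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  P <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  iter <- 0L
  converged <- FALSE
  for (it in seq_len(maxit)) {
    iter <- it
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X1, X1 * w) + P, crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- drop(beta_new); converged <- TRUE; break }
    beta <- drop(beta_new)
  }
  mu <- stats::plogis(drop(X1 %*% beta))
  list(beta = stats::setNames(beta, colnames(X1)), mu = mu,
       converged = converged || iter < maxit, iter = iter)
}

#' RCVE decomposition of factor importance for one sample pair
#'
#' Fits the full binomial GLM on all factors and one reduced model per
#' factor on the identical candidate rows (listwise-complete), and computes
#' each factor's relative contribution to variability explained,
#' `RCVE = (r2_all - r2_reduced) / r2_all`, ranking factors by descending
#' RCVE (ties mid-ranked). Numerically negative RCVE values within tolerance
#' are clipped to 0 and flagged.
#'
#' @param factors Data.frame of factor columns (e.g. the eight model factors
#'   of [glm_input()]).
#' @param y Binary response (1 = not-depleted).
#' @param pair_id Label carried into the report.
#' @param pseudo_r2 Pseudo-r2 definition (see [fit_depletion_glm()]).
#' @param tol Clipping tolerance for negative RCVE (default 1e-6).
#' @return List of class `"rcve_report"`: pair_id, r2_all, `table`
#'   (factor, r2_reduced, rcve, rank), and diagnostics. When `r2_all` is 0
#'   the RCVE values are NA and a warning is raised.
#' @export
rcve <- function(factors, y, pair_id = NA_character_,
                 pseudo_r2 = "mcfadden", tol = 1e-6) {
  X <- as.data.frame(factors)
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  full <- fit_depletion_glm(X, y, pseudo_r2 = pseudo_r2)
  r2_all <- full$pseudo_r2
  nms <- names(X)
  clipped <- character(0)
  if (abs(r2_all) < .Machine$double.eps * 100) {
    warnf("full-model pseudo-r2 is 0; RCVE undefined for pair %s", pair_id)
    tab <- data.frame(factor = nms, r2_reduced = NA_real_, rcve = NA_real_,
                      rank = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(pair_id = pair_id, r2_all = r2_all, table = tab,
                          diagnostics = list(ridge = full$ridge, clipped = clipped,
                                             undefined = TRUE)),
                     class = "rcve_report"))
  }
  ## reduced models must share the estimator with the full model, otherwise
  ## the penalised/unpenalised mix breaks nesting and RCVE can go negative
  r2_red <- vapply(nms, function(f) {
    fit_depletion_glm(X[, setdiff(nms, f), drop = FALSE], y,
                      pseudo_r2 = pseudo_r2,
                      force_ridge = full$ridge)$pseudo_r2
  }, numeric(1))
  rc <- (r2_all - r2_red) / r2_all
  neg <- rc < 0
  ## the penalised fallback preserves nesting only approximately, so allow a
  ## correspondingly looser numerical band before warning
  tol <- if (full$ridge) max(tol, 1e-2) else tol
  if (any(neg)) {
    if (any(rc < -tol)) {
      warnf("RCVE below -tolerance for factor(s) %s; check model nesting",
            paste(nms[rc < -tol], collapse = ", "))
    }
    clipped <- nms[neg]
    rc[neg] <- 0
  }
  tab <- data.frame(factor = nms, r2_reduced = unname(r2_red),
                    rcve = unname(rc),
                    rank = rank(-rc, ties.method = "average"),
                    stringsAsFactors = FALSE)
  structure(list(pair_id = pair_id, r2_all = r2_all, table = tab,
                 diagnostics = list(ridge = full$ridge, clipped = clipped,
                                    undefined = FALSE)),
            class = "rcve_report")
}

#' @export
print.rcve_report <- function(x, ...) {
  cat(sprintf("RCVE report for pair %s (r2_all = %.4f)\n", x$pair_id, x$r2_all))
  print(x$table[order(x$table$rank), ], row.names = FALSE)
  invisible(x)
}

#' Combine per-pair RCVE reports into rankings and average ranks
#'
#' @param reports List of [rcve()] reports.
#' @return List with `ranks` (long data.frame: pair_id, factor, rcve, rank)
#'   and `average_rank` (factor, average_rank, mean_rcve; sorted by average
#'   rank, 1 = most important).
#' @export
rank_across_pairs <- function(reports) {
  if (length(reports) == 0L) stopf("at least one RCVE report required")
  long <- do.call(rbind, lapply(reports, function(r) {
    cbind(pair_id = r$pair_id, r$table[, c("factor", "rcve", "rank")])
  }))
  rownames(long) <- NULL
  avg <- aggregate(cbind(rank, rcve) ~ factor, data = long, FUN = mean)
  names(avg) <- c("factor", "average_rank", "mean_rcve")
  avg <- avg[order(avg$average_rank), ]
  rownames(avg) <- NULL
  list(ranks = long, average_rank = avg)
}
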