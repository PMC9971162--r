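test_that("Fisher enrichment reproduces the cross-product OR and the exact p", {
  f <- rep(c(TRUE, TRUE, FALSE, FALSE), c(30, 10, 20, 40))
  nd <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 20, 40))
  r <- fet_enrichment(f, nd)
  expect_equal(r$odds_ratio, 6.0)
  expect_equal(r$p, stats::fisher.test(table(f, nd))$p.value, tolerance = 1e-12)
  expect_equal(r$effect_direction, "positive")
  expect_false(r$haldane)
  expect_error(fet_enrichment(c(TRUE, FALSE), c(TRUE, TRUE)), "depleted")
})

test_that("Fisher p matches fisher.test over random and exhaustive tables", {
  ## exhaustive: every table with n <= 12
  for (n in 2:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (c_ in 0:(n - a - b)) {
      d <- n - a - b - c_
      if ((a + c_) == 0 || (b + d) == 0) next  # empty class
      p_pkg <- circReliability:::fet_two_sided_p(a, b, c_, d)
      p_ref <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
      expect_equal(p_pkg, p_ref, tolerance = 1e-9)
    }
  }
  ## random larger tables up to n = 200
  with_seed(53L, {
    for (i in 1:200) {
      n <- sample(20:200, 1)
      cuts <- sort(sample(0:n, 3, replace = TRUE))
      cells <- c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], n - cuts[3])
      if (cells[1] + cells[3] == 0 || cells[2] + cells[4] == 0) next
      p_pkg <- circReliability:::fet_two_sided_p(cells[1], cells[2], cells[3], cells[4])
      p_ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
      expect_equal(p_pkg, p_ref, tolerance = 1e-9)
    }
  })
})

test_that("zero cells trigger the flagged Haldane odds ratio", {
  f <- rep(c(TRUE, FALSE, FALSE), c(5, 3, 7))
  nd <- rep(c(TRUE, TRUE, FALSE), c(5, 3, 7))
  r <- fet_enrichment(f, nd)
  expect_true(r$haldane)
  expect_equal(r$odds_ratio, (5.5 * 7.5) / (0.5 * 3.5))
  expect_true(is.finite(r$ci95_low) && is.finite(r$ci95_high))
})

test_that("Wilcoxon enrichment: exact enumeration on the canonical example", {
  ## not-depleted {4,5,6} vs depleted {1,2,3}: U = 9, one-sided p = 1/20
  values <- c(4, 5, 6, 1, 2, 3)
  nd <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- wrst_enrichment(values, nd, "greater", boot = 0L)
  expect_equal(r$U, 9)
  expect_equal(r$p, 0.05)
  expect_equal(r$effect_direction, "positive")
  ## identical groups: effect size ~ 0
  r2 <- wrst_enrichment(c(1, 2, 3, 1, 2, 3), nd, "greater", boot = 0L)
  expect_lt(abs(r2$effect_size_r), 1e-9)
  ## fully tied data: degenerate, p = 0.5
  expect_warning(r3 <- wrst_enrichment(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE),
                                       "greater", boot = 0L), "tied")
  expect_equal(r3$p, 0.5)
  expect_equal(r3$effect_size_r, 0)
})

test_that("Wilcoxon exact p equals the full-enumeration oracle with ties", {
  with_seed(59L, {
    for (i in 1:12) {
      x <- sample(1:6, sample(3:6, 1), replace = TRUE)
      y <- sample(1:6, sample(3:6, 1), replace = TRUE)
      for (dir in c("greater", "less")) {
        r <- wrst_enrichment(c(x, y), rep(c(TRUE, FALSE), c(length(x), length(y))),
                             dir, boot = 0L)
        expect_equal(r$p, wrst_enum_oracle(x, y, dir), tolerance = 1e-12)
      }
    }
  })
})

test_that("the normal approximation tracks the exact p for n = 8 + 8", {
  with_seed(61L, {
    for (i in 1:10) {
      vals <- stats::rnorm(16)
      nd <- rep(c(TRUE, FALSE), each = 8)
      p_exact <- wrst_enrichment(vals, nd, "greater", exact_max = 9L, boot = 0L)$p
      p_approx <- wrst_enrichment(vals, nd, "greater", exact_max = 0L, boot = 0L)$p
      expect_lt(abs(p_exact - p_approx), 0.02)
      ## cross-check the approximate branch against wilcox.test
      p_wt <- stats::wilcox.test(vals[nd], vals[!nd], alternative = "greater",
                                 exact = FALSE, correct = TRUE)$p.value
      expect_equal(p_approx, p_wt, tolerance = 1e-9)
    }
  })
})

test_that("effect-size bootstrap CIs are seeded, ordered and cover r", {
  with_seed(67L, {
    vals <- c(stats::rnorm(40, 1), stats::rnorm(40))
    nd <- rep(c(TRUE, FALSE), each = 40)
  })
  r1 <- wrst_enrichment(vals, nd, "greater", boot = 300L, boot_seed = 9L)
  r2 <- wrst_enrichment(vals, nd, "greater", boot = 300L, boot_seed = 9L)
  expect_identical(r1, r2)
  expect_true(r1$ci95_low <= r1$effect_size_r && r1$effect_size_r <= r1$ci95_high)
  expect_true(r1$ci95_low >= 0 || r1$ci95_high <= 1)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  with_seed(71L, {
    for (i in 1:50) {
      p <- stats::runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
  ## per-factor families adjust independently across pairs
  p <- c(0.01, 0.2, 0.03, 0.6)
  fam <- c("f1", "f1", "f2", "f2")
  expect_equal(bh_adjust(p, fam), c(bh_oracle(p[1:2]), bh_oracle(p[3:4])))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  ## adjusted values are monotone in raw p within a family
  with_seed(73L, {
    p <- stats::runif(30)
    f <- bh_adjust(p)
    expect_true(all(diff(f[order(p)]) >= -1e-12))
  })
})

test_that("trend tables report per-level percentages and rank correlations", {
  nd <- rep(c(FALSE, TRUE), c(9, 1))
  nd2 <- rep(c(FALSE, TRUE), c(1, 9))
  tt <- trend_table(c(nd, nd2), rep(c(1, 2), each = 10))
  expect_equal(tt$table$pct_not_depleted, c(10, 90))
  expect_equal(tt$table$n_candidates, c(10L, 10L))
  ## perfectly increasing relationship
  lev <- rep(1:5, each = 20)
  prob <- rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 20)
  with_seed(79L, nd3 <- stats::runif(100) < prob)
  tt3 <- trend_table(nd3, lev)
  expect_equal(tt3$spearman, 1)
  ## single level: correlation undefined but table emitted
  tt1 <- trend_table(c(TRUE, FALSE), c(3, 3))
  expect_equal(nrow(tt1$table), 1L)
  expect_true(is.na(tt1$spearman))
})

test_that("significance summary applies the strict all-pairs importance rule", {
  mk <- function(fdrs, dir = "positive") {
    data.frame(pair_id = sprintf("p%02d", seq_along(fdrs)), factor = "f",
               effect_direction = dir, p = fdrs, fdr = fdrs,
               stringsAsFactors = FALSE)
  }
  s_all <- significance_summary(mk(rep(0.01, 19)))
  expect_true(s_all$important)
  expect_equal(s_all$n_significant, 19L)
  s_18 <- significance_summary(mk(c(rep(0.01, 18), 0.2)))
  expect_false(s_18$important)
  expect_false(significance_summary(mk(rep(0.01, 19)), alpha = 0)$important)
  ## inconsistent directions block importance even when all pairs pass
  incons <- mk(rep(0.01, 4))
  incons$effect_direction[2] <- "negative"
  expect_false(significance_summary(incons)$important)
})

test_that("label-set enrichment separates truth-linked labels from null labels", {
  sim <- small_sim()
  pc <- simulate_pair_counts(sim$truth, sim$config, 1L)
  q <- quantify_counts(pc$circ_id, pc$mock_count, pc$treated_count,
                       pc$mock_total[1], pc$treated_total[1])
  truth_label <- sim$truth$circ_id[sim$truth$is_true_circ]
  r <- labelset_enrichment(q, truth_label, pair_id = "p1", label = "truth")
  expect_gt(r$odds_ratio, 1)
  expect_lt(r$p, 0.05)
  expect_gt(r$pct_labeled_not_depleted, r$pct_labeled_depleted)
  ## independent label: OR near 1 on a larger resample
  with_seed(83L, {
    nd <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
    q2 <- data.frame(circ_id = sprintf("c%04d", 1:4000),
                     depletion_class = ifelse(nd, "not-depleted", "depleted"),
                     stringsAsFactors = FALSE)
    r2 <- labelset_enrichment(q2, q2$circ_id[lab], label = "null")
    expect_lt(abs(log(r2$odds_ratio)), 0.3)
  })
  ## degenerate label sets are skipped with a warning
  expect_warning(r3 <- labelset_enrichment(q, q$circ_id, label = "all"),
                 "degenerate")
  expect_null(r3)
})

test_that("factor-count stratification is monotone under a logistic label", {
  with_seed(89L, {
    k <- sample(0:7, 5000, replace = TRUE)
    lab <- stats::runif(5000) < stats::plogis(-3 + 0.9 * k)
    st <- factor_count_stratification(k, lab)
    expect_equal(st$k, 0:7)
    expect_true(all(diff(st$pct_labeled_exact) > 0))
    expect_true(all(diff(st$pct_labeled_at_least) > 0))
    ## all labelled: 100% everywhere
    st2 <- factor_count_stratification(k, rep(TRUE, 5000))
    expect_true(all(st2$pct_labeled_exact == 100))
  })
})
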