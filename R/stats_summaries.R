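#' Trend table: percentage not-depleted per factor level
#'
#' Bins a numeric or ordinal factor and reports, per level, the number of
#' candidates and the percentage classified not-depleted, together with the
#' Spearman (primary; levels are ordinal) and Pearson correlations between
#' level order and percentage.
#'
#' @param not_depleted Logical class vector.
#' @param values Factor values (numeric or ordinal).
#' @param breaks Optional numeric breaks passed to [cut()]; by default each
#'   distinct value is a level.
#' @param pair_id,factor Labels carried into the output.
#' @return A list with `table` (pair_id, factor, level, n_candidates,
#'   pct_not_depleted), `spearman` and `pearson` (NA with fewer than two
#'   levels).
#' @export
trend_table <- function(not_depleted, values, breaks = NULL,
                        pair_id = NA_character_, factor = NA_character_) {
  keep <- !is.na(values) & !is.na(not_depleted)
  values <- values[keep]; not_depleted <- as.logical(not_depleted[keep])
  lev <- if (is.null(breaks)) base::factor(values, levels = sort(unique(values)))
         else cut(values, breaks = breaks, include.lowest = TRUE)
  n <- tapply(not_depleted, lev, length)
  pct <- tapply(not_depleted, lev, function(v) 100 * mean(v))
  present <- !is.na(n)
  tab <- data.frame(pair_id = pair_id, factor = factor,
                    level = levels(lev)[present],
                    n_candidates = as.integer(n[present]),
                    pct_not_depleted = as.numeric(pct[present]),
                    stringsAsFactors = FALSE)
  sp <- pe <- NA_real_
  if (nrow(tab) >= 2L) {
    idx <- seq_len(nrow(tab))
    sp <- suppressWarnings(stats::cor(idx, tab$pct_not_depleted, method = "spearman"))
    pe <- suppressWarnings(stats::cor(idx, tab$pct_not_depleted, method = "pearson"))
  }
  list(table = tab, spearman = sp, pearson = pe)
}

#' Summarise per-factor significance across sample pairs
#'
#' Counts, per factor, the sample pairs passing `fdr < alpha`, checks that
#' the significant pairs agree in effect direction, and marks a factor
#' "important" when it passes with a consistent direction in every pair —
#' the strict all-pairs rule used to nominate reliability indicators.
#'
#' @param results Data.frame of test rows (from [fet_enrichment()] /
#'   [wrst_enrichment()]) with an `fdr` column (see [bh_adjust()]).
#' @param alpha FDR threshold (default 0.05).
#' @return Data.frame: factor, n_pairs, n_significant, consistent_direction,
#'   important.
#' @export
significance_summary <- function(results, alpha = 0.05) {
  if (!"fdr" %in% names(results)) stopf("results must carry an 'fdr' column")
  out <- lapply(split(results, results$factor), function(df) {
    sig <- df$fdr < alpha
    dirs <- unique(df$effect_direction[sig])
    consistent <- length(dirs) <= 1L
    data.frame(factor = df$factor[1], n_pairs = nrow(df),
               n_significant = sum(sig),
               consistent_direction = consistent,
               important = all(sig) && nrow(df) > 0L && consistent,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enrichment of an external circRNA label set among not-depleted candidates
#'
#' Tests whether membership in an external identifier set (validated
#' circRNAs, database-specific candidates, multi-replicate detections, ...)
#' is associated with the depletion class, by two-tailed Fisher exact test,
#' and reports the percentage of labelled candidates in each class.
#'
#' @param quant Quantification table of one pair ([quantify_counts()]).
#' @param label_ids Character vector of circ_ids in the label set.
#' @param pair_id,label Labels carried into the result.
#' @return One-row data.frame extending [fet_enrichment()] with
#'   pct_labeled_not_depleted and pct_labeled_depleted, or `NULL` (with a
#'   warning) when the table is degenerate (no or only labelled candidates,
#'   or a missing class).
#' @export
labelset_enrichment <- function(quant, label_ids, pair_id = NA_character_,
                                label = "label") {
  q <- quant[quant$depletion_class != "excluded", , drop = FALSE]
  labeled <- q$circ_id %in% label_ids
  nd <- q$depletion_class == "not-depleted"
  if (!any(labeled) || all(labeled)) {
    warnf("label set '%s' is degenerate in pair %s (all or no candidates labelled); test skipped",
          label, pair_id)
    return(NULL)
  }
  if (!any(nd) || all(nd)) {
    warnf("depletion classes degenerate in pair %s; test skipped", pair_id)
    return(NULL)
  }
  res <- fet_enrichment(labeled, nd, pair_id = pair_id, factor = label)
  res$pct_labeled_not_depleted <- 100 * mean(labeled[nd])
  res$pct_labeled_depleted <- 100 * mean(labeled[!nd])
  res
}

#' Stratify label membership by supporting-factor count
#'
#' For each supporting-factor count k, reports the percentage of candidates
#' with exactly k (and with at least k) supporting factors that belong to the
#' label set — the additive-effect view of the reliability indicators.
#'
#' @param n_supporting Integer vector of supporting-factor counts (0..7).
#' @param labeled Logical membership vector (same length).
#' @param max_k Largest count reported (default 7).
#' @return Data.frame: k, n_exact, pct_labeled_exact, n_at_least,
#'   pct_labeled_at_least (percentages NA for empty strata).
#' @export
factor_count_stratification <- function(n_supporting, labeled, max_k = 7L) {
  stopifnot(length(n_supporting) == length(labeled))
  labeled <- as.logical(labeled)
  do.call(rbind, lapply(0:max_k, function(k) {
    ex <- n_supporting == k
    ge <- n_supporting >= k
    data.frame(k = k, n_exact = sum(ex),
               pct_labeled_exact = if (any(ex)) 100 * mean(labeled[ex]) else NA_real_,
               n_at_least = sum(ge),
               pct_labeled_at_least = if (any(ge)) 100 * mean(labeled[ge]) else NA_real_)
  }))
}

#' Run every factor test for one sample pair
#'
#' Applies [fet_enrichment()] to the binary factors and [wrst_enrichment()]
#' (direction `"greater"`: higher values expected in not-depleted circRNAs)
#' to the quantitative factors of a pair's merged quantification + factor
#' table, returning one result row per factor.
#'
#' @param glm_df Output of [glm_input()] for one pair.
#' @param pair_id Label for the pair.
#' @param boot Bootstrap replicates for WRST effect-size CIs.
#' @param boot_seed Seed of the bootstrap stream.
#' @return Data.frame of test rows (no FDR yet; see [bh_adjust()]).
#' @export
test_pair_factors <- function(glm_df, pair_id = NA_character_, boot = 200L,
                              boot_seed = 1L) {
  nd <- glm_df$y == 1L
  binary <- c("multi_tool", "full_length", "both_annotated", "same_isoform",
              "both_AS")
  quant <- c("bsj_read_count", "n_samples", "n_functional_features")
  rows <- list()
  for (f in binary) {
    rows[[f]] <- fet_enrichment(glm_df[[f]] == 1L, nd, pair_id, f)
  }
  for (f in quant) {
    rows[[f]] <- wrst_enrichment(glm_df[[f]], nd, "greater", pair_id, f,
                                 boot = boot, boot_seed = boot_seed)
  }
  common <- c("pair_id", "factor", "test", "direction", "p", "effect_direction")
  out <- lapply(rows, function(r) {
    cbind(r[common],
          stat = if ("odds_ratio" %in% names(r)) r$odds_ratio else r$effect_size_r,
          stat_name = if ("odds_ratio" %in% names(r)) "odds_ratio" else "effect_size_r",
          ci95_low = r$ci95_low, ci95_high = r$ci95_high)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
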