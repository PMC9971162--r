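#' Run the full synthetic benchmark pipeline
#'
#' Drives every stage on a simulated dataset with known ground truth:
#' simulate (reference, candidates, reads), quantify (read-level for the
#' first sample pair, count-level replicate pairs for the remainder), screen
#' alignment ambiguity, annotate factors, test per-factor enrichment with BH
#' FDR across pairs, and rank factor importance by RCVE. All randomness
#' derives from `config$seed`. Outputs are written as TSV/JSON into
#' `out_dir`; stages whose output files already exist are skipped unless
#' `force = TRUE`, making reruns resumable and idempotent.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_pairs Number of mock/treated sample pairs (default 5; pair 1 is
#'   quantified from reads, the others from count-level replicates of the
#'   same depletion model).
#' @param alpha FDR threshold of the significance summary.
#' @param force Recompute stages whose outputs already exist.
#' @return List: quant (per-pair list), factor_matrix, ambiguity, inclusion,
#'   results (test rows with fdr), summary (per-factor significance), rcve
#'   (per-pair reports), ranking, and the paths written.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("circrun"),
                         n_pairs = 5L, alpha = 0.05, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, paste0(...))
  log_stage <- function(fmt, ...) message(sprintf(paste0("[circReliability] ", fmt), ...))

  ## stage 1: simulate ------------------------------------------------------
  ref <- simulate_reference(config)
  cand <- simulate_candidates(config, ref)
  if (force || !file.exists(pth("candidates.tsv"))) {
    write_genome_fasta(ref$genome, pth("genome.fa"))
    write_gtf_exons(ref$exons, pth("annotation.gtf"))
    write_tsv(cand$candidates, pth("candidates.tsv"))
    write_tsv(cand$truth, pth("truth.tsv"))
    yaml::write_yaml(unclass(config), pth("config.yaml"))
    log_stage("simulated %d candidates on %d chromosome(s)",
              nrow(cand$candidates), config$genome_n_chroms)
  }

  ## stage 2: ambiguity screen ---------------------------------------------
  if (!force && file.exists(pth("ambiguity.tsv"))) {
    amb <- utils::read.delim(pth("ambiguity.tsv"), stringsAsFactors = FALSE)
  } else {
    amb <- screen_ambiguity_all(cand$candidates, ref$genome, ref$exons)
    write_tsv(amb, pth("ambiguity.tsv"))
    log_stage("ambiguity screen: %d of %d candidates flagged",
              sum(amb$ambiguous), nrow(amb))
  }
  keep <- cand$candidates$circ_id[!amb$ambiguous]
  candidates <- cand$candidates[cand$candidates$circ_id %in% keep, ]
  truth <- cand$truth[cand$truth$circ_id %in% keep, ]

  ## stage 3: quantify ------------------------------------------------------
  if (!force && file.exists(pth("quant.tsv"))) {
    quant_long <- utils::read.delim(pth("quant.tsv"), stringsAsFactors = FALSE)
    quant <- split(quant_long[, -1], quant_long$pair_id)
  } else {
    reads <- simulate_read_pairs(candidates, truth, config, ref$genome)
    q1 <- quantify_pair(candidates, ref$genome, reads$mock_reads,
                        reads$treated_reads, reads$mock_total, reads$treated_total)
    quant <- list(pair01 = q1)
    if (n_pairs > 1L) {
      pc <- simulate_pair_counts(truth, config, n_pairs - 1L)
      for (p in unique(pc$pair_id)) {
        sub <- pc[pc$pair_id == p, ]
        quant[[sprintf("pair%02d", as.integer(substr(p, 5, 6)) + 1L)]] <-
          quantify_counts(sub$circ_id, sub$mock_count, sub$treated_count,
                          sub$mock_total[1], sub$treated_total[1])
      }
    }
    quant_long <- do.call(rbind, lapply(names(quant), function(p) {
      cbind(pair_id = p, quant[[p]])
    }))
    write_tsv(quant_long, pth("quant.tsv"))
    log_stage("quantified %d pair(s); pair01 from %d+%d reads", length(quant),
              length(reads$mock_reads), length(reads$treated_reads))
  }
  inclusion <- lapply(quant, check_pair_inclusion)

  ## stage 4: factors -------------------------------------------------------
  if (!force && file.exists(pth("factors.tsv"))) {
    fm <- utils::read.delim(pth("factors.tsv"), stringsAsFactors = FALSE)
  } else {
    fm <- build_factor_matrix(candidates, ref$exons)
    write_tsv(fm, pth("factors.tsv"))
    log_stage("annotated %d factor columns for %d candidates", ncol(fm) - 1L, nrow(fm))
  }

  ## stage 5: per-pair tests + FDR across pairs -----------------------------
  glm_dfs <- lapply(quant, function(q) glm_input(fm, q))
  usable <- vapply(glm_dfs, function(g) length(unique(g$y)) == 2L, logical(1))
  results <- do.call(rbind, lapply(names(glm_dfs)[usable], function(p) {
    test_pair_factors(glm_dfs[[p]], pair_id = p,
                      boot_seed = stage_seed(config$seed, "boot"))
  }))
  results$fdr <- bh_adjust(results$p, results$factor)
  write_tsv(results, pth("results.tsv"))
  summary_df <- significance_summary(results, alpha = alpha)

  ## stage 6: RCVE ----------------------------------------------------------
  factor_cols <- c("bsj_read_count", "multi_tool", "full_length", "n_samples",
                   "both_annotated", "same_isoform", "both_AS",
                   "n_functional_features")
  reports <- lapply(names(glm_dfs)[usable], function(p) {
    rcve(glm_dfs[[p]][, factor_cols], glm_dfs[[p]]$y, pair_id = p)
  })
  ranking <- rank_across_pairs(reports)
  write_tsv(ranking$ranks, pth("rcve.tsv"))
  write_tsv(ranking$average_rank, pth("rcve_average_rank.tsv"))

  summary <- list(
    n_candidates = nrow(candidates),
    n_ambiguous = sum(amb$ambiguous),
    pair_inclusion = lapply(inclusion, function(x) x[c("pass", "n_mock_detected",
                                                       "overlap_frac")]),
    important_factors = summary_df$factor[summary_df$important],
    average_rank = ranking$average_rank)
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(quant = quant, factor_matrix = fm, ambiguity = amb,
                 inclusion = inclusion, results = results,
                 summary = summary_df, rcve = reports, ranking = ranking,
                 paths = list(out_dir = out_dir)))
}
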