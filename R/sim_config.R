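#' Configuration for the synthetic circRNA benchmark generator
#'
#' Bundles every knob of the synthetic-data module: the toy genome layout, the
#' mixture of true circRNAs and artifacts, the depletion model of the three
#' mock/treated library designs (RNase R, A-tailing + RNase R, non-poly(A)
#' selection), the logistic factor effects, and the sequencing parameters.
#'
#' Class-conditional factor draws are parameterised so that the log-odds of a
#' candidate being a true circRNA is exactly the linear combination
#' `sum(factor_effects * factor_values)` plus a constant: binary factors are
#' Bernoulli with success logit shifted by the effect, count factors are
#' Poisson (mean scaled by `exp(effect)`) or Binomial (success logit shifted),
#' all of which have logistic likelihood ratios in the factor value.
#'
#' @param genome_n_chroms Number of toy chromosomes.
#' @param chrom_len Chromosome length (bp).
#' @param n_genes Number of simulated genes (round-robin across chromosomes).
#' @param exons_per_gene Integer range `c(lo, hi)` of exons per gene.
#' @param isoform_fraction Fraction of genes (with >= 3 exons) receiving a
#'   second, exon-skipping isoform, so same-isoform and alternative-splicing
#'   factors have positive and negative cases.
#' @param n_circ_true,n_circ_artifact Sizes of the two mixture components.
#' @param depletion_model Named list, one entry per treatment group, each a
#'   numeric vector `c(retain_prob_true=, retain_prob_artifact=)` in `[0,1]`:
#'   the probability that a mock BSJ molecule survives the treatment.
#' @param treatment_group Which `depletion_model` entry the simulated pair uses.
#' @param factor_effects Named numeric vector of logistic coefficients
#'   (log-odds of being a true circRNA per unit of the factor) for the drawn
#'   factors: `bsj_read_count`, `multi_tool`, `full_length`, `n_samples`,
#'   `n_functional_features`. Structural factors (annotated boundaries, same
#'   isoform, alternative splicing) are governed by the placement
#'   probabilities below, because they are realised through coordinates, not
#'   drawn values.
#' @param factor_baselines Named numeric vector of artifact-class baselines:
#'   `multi_tool` and `full_length` success probabilities, `n_samples` Poisson
#'   rate (of the count above 1), `n_functional_features` per-feature
#'   probability (out of 9 features).
#' @param artifact_on_boundary_prob Probability that an artifact keeps
#'   annotated exon boundaries (the rest are perturbed off-boundary).
#' @param chimera_prob_true,chimera_prob_artifact Probability that an
#'   on-boundary candidate is a two-gene chimera (annotated boundaries but no
#'   shared isoform).
#' @param as_pair_prob_true,as_pair_prob_artifact Probability that an
#'   on-boundary same-isoform candidate is placed on a skipped exon, making
#'   both BSJ splice sites alternatively spliced.
#' @param lambda_mock Poisson mean of mock BSJ molecule counts for artifacts;
#'   true circRNAs use `lambda_mock * exp(factor_effects["bsj_read_count"])`.
#' @param library_size_mock,library_size_treated Raw read totals used as RPM
#'   denominators. The treated default is half the mock default: digesting
#'   linear RNA shrinks the treated library, which is what lifts the
#'   treat/mock RPM ratio of surviving circles above 1.
#' @param n_background_mock,n_background_treated Linear (colinear genomic)
#'   background reads added to each library.
#' @param read_len Read length (bp), at most 100 so BSJ reads are contained in
#'   the 100-nt pseudo-sequence.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_dataset()], [simulate_reference()]
#' @export
sim_config <- function(genome_n_chroms = 2L,
                       chrom_len = 100000L,
                       n_genes = 40L,
                       exons_per_gene = c(3L, 6L),
                       isoform_fraction = 0.5,
                       n_circ_true = 150L,
                       n_circ_artifact = 150L,
                       depletion_model = list(
                         group1 = c(retain_prob_true = 0.9,  retain_prob_artifact = 0.05),
                         group2 = c(retain_prob_true = 0.85, retain_prob_artifact = 0.05),
                         group3 = c(retain_prob_true = 0.8,  retain_prob_artifact = 0.10)
                       ),
                       treatment_group = "group1",
                       factor_effects = c(bsj_read_count = 0.4,
                                          multi_tool = 1.0,
                                          full_length = 2.0,
                                          n_samples = 0.8,
                                          n_functional_features = 0.6),
                       factor_baselines = c(multi_tool = 0.3,
                                            full_length = 0.2,
                                            n_samples = 1.2,
                                            n_functional_features = 0.15),
                       artifact_on_boundary_prob = 0.25,
                       chimera_prob_true = 0.02,
                       chimera_prob_artifact = 0.5,
                       as_pair_prob_true = 0.4,
                       as_pair_prob_artifact = 0.3,
                       lambda_mock = 8,
                       library_size_mock = 1e6,
                       library_size_treated = 5e5,
                       n_background_mock = 1000L,
                       n_background_treated = 300L,
                       read_len = 100L,
                       seed = 1L) {
  cfg <- list(genome_n_chroms = as.integer(genome_n_chroms),
              chrom_len = as.integer(chrom_len),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              isoform_fraction = isoform_fraction,
              n_circ_true = as.integer(n_circ_true),
              n_circ_artifact = as.integer(n_circ_artifact),
              depletion_model = depletion_model,
              treatment_group = treatment_group,
              factor_effects = factor_effects,
              factor_baselines = factor_baselines,
              artifact_on_boundary_prob = artifact_on_boundary_prob,
              chimera_prob_true = chimera_prob_true,
              chimera_prob_artifact = chimera_prob_artifact,
              as_pair_prob_true = as_pair_prob_true,
              as_pair_prob_artifact = as_pair_prob_artifact,
              lambda_mock = lambda_mock,
              library_size_mock = library_size_mock,
              library_size_treated = library_size_treated,
              n_background_mock = as.integer(n_background_mock),
              n_background_treated = as.integer(n_background_treated),
              read_len = as.integer(read_len),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$isoform_fraction, cfg$artifact_on_boundary_prob,
             cfg$chimera_prob_true, cfg$chimera_prob_artifact,
             cfg$as_pair_prob_true, cfg$as_pair_prob_artifact,
             unlist(cfg$depletion_model),
             cfg$factor_baselines[c("multi_tool", "full_length",
                                    "n_functional_features")])
  if (any(probs < 0 | probs > 1)) {
    stopf("all probabilities in sim_config must lie in [0, 1]")
  }
  if (cfg$read_len < 1L || cfg$read_len > 100L) {
    stopf("read_len must be in [1, 100] so reads fit in the 100-nt pseudo-sequence")
  }
  if (length(cfg$exons_per_gene) != 2L || cfg$exons_per_gene[1] < 1L ||
      diff(cfg$exons_per_gene) < 0L) {
    stopf("exons_per_gene must be an increasing integer range c(lo, hi)")
  }
  if (!cfg$treatment_group %in% names(cfg$depletion_model)) {
    stopf("treatment_group '%s' not found in depletion_model", cfg$treatment_group)
  }
  need <- c("retain_prob_true", "retain_prob_artifact")
  for (g in names(cfg$depletion_model)) {
    if (!all(need %in% names(cfg$depletion_model[[g]]))) {
      stopf("depletion_model[['%s']] must name %s", g, paste(need, collapse = ", "))
    }
  }
  if (cfg$n_circ_true < 0L || cfg$n_circ_artifact < 0L ||
      cfg$n_circ_true + cfg$n_circ_artifact < 1L) {
    stopf("need at least one candidate (n_circ_true + n_circ_artifact >= 1)")
  }
  if (cfg$library_size_mock <= 0 || cfg$library_size_treated <= 0) {
    stopf("library sizes must be positive")
  }
  invisible(cfg)
}
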