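## Hand-built miniature annotation/genome fixtures used by the factor tests.

## A two-gene fixture on one 6-kb chromosome:
##  geneA (+): t1 = exons E1 [501,700], E2 [1001,1150], E3 [1401,1600]
##             t2 = E1, E3 (skips E2)  -> E2 boundaries AS, E1-donor/E3-acceptor AS
##  geneB (-): t1 = exons [3001,3200], [3501,3700]  (single isoform)
fixture_annotation <- function() {
  data.frame(
    gene_id = c(rep("geneA", 5), rep("geneB", 2)),
    transcript_id = c(rep("geneA.t1", 3), rep("geneA.t2", 2), rep("geneB.t1", 2)),
    chrom = "chrT",
    start = c(501L, 1001L, 1401L, 501L, 1401L, 3001L, 3501L),
    end = c(700L, 1150L, 1600L, 700L, 1600L, 3200L, 3700L),
    strand = c(rep("+", 5), rep("-", 2)),
    stringsAsFactors = FALSE)
}

fixture_genome <- function(seed = 42L) {
  circReliability::with_seed(seed, c(chrT = rand_dna(6000L)))
}

fixture_candidate <- function(circ_id, acceptor, donor, strand = "+",
                              gene_id = "geneA", chrom = "chrT") {
  data.frame(circ_id = circ_id, chrom = chrom, acceptor_pos = acceptor,
             donor_pos = donor, strand = strand, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

## A small simulated dataset shared by several tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_circ_true = 40L, n_circ_artifact = 40L,
                        n_genes = 20L, chrom_len = 60000L,
                        n_background_mock = 200L, n_background_treated = 50L,
                        seed = 7L)
      cache <<- list(config = cfg, ref = simulate_reference(cfg))
      cand <- simulate_candidates(cfg, cache$ref)
      cache$candidates <<- cand$candidates
      cache$truth <<- cand$truth
    }
    cache
  }
})
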