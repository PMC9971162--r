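test_that("the BSJ read matching rule follows coverage, span and identity", {
  g <- fixture_genome()
  ps <- build_pseudo_seq(fixture_candidate("c1", 301L, 500L), g)
  full <- ps$sequence
  expect_equal(count_bsj_reads(full, ps), 1L)                      # 100% / 50|50
  expect_equal(count_bsj_reads(substr(full, 1, 55), ps), 0L)       # cov 55%, span 5
  expect_equal(count_bsj_reads(substr(full, 11, 95), ps), 1L)      # cov 85%, span 40|45
  expect_equal(count_bsj_reads(substr(full, 1, 79), ps), 0L)       # cov 79% < 80%
  expect_equal(count_bsj_reads(character(0), ps), 0L)              # empty read set
  ## reverse-complement reads count only in unstranded mode
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(full)))
  expect_equal(count_bsj_reads(rc, ps, both_strands = TRUE), 1L)
  expect_equal(count_bsj_reads(rc, ps, both_strands = FALSE), 0L)
})

test_that("counting matches the dynamic-programming oracle on a read mix", {
  g <- fixture_genome()
  ps <- build_pseudo_seq(fixture_candidate("c1", 301L, 500L), g)
  with_seed(31L, {
    reads <- c(
      ps$sequence,
      vapply(1:25, function(i) {            # junction-spanning fragments
        st <- sample(1:15, 1); en <- min(100L, st + sample(80:99, 1))
        substr(ps$sequence, st, en)
      }, character(1)),
      vapply(1:15, function(i) {            # interior point mutations
        s <- strsplit(ps$sequence, "")[[1]]
        pos <- sample(5:95, sample(1:6, 1))
        s[pos] <- vapply(s[pos], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
        paste(s, collapse = "")
      }, character(1)),
      vapply(1:20, function(i) rand_dna(100L), character(1)),  # noise
      vapply(1:10, function(i) {            # one-sided (non-spanning) reads
        substr(g[["chrT"]], 401 + i, 500 + i)
      }, character(1)))
    expect_equal(count_bsj_reads(reads, ps), oracle_count_bsj(reads, ps))
  })
})

test_that("multi-candidate counting agrees with per-candidate counting", {
  sim <- small_sim()
  cand <- sim$candidates[1:12, ]
  reads <- simulate_read_pairs(cand, sim$truth[1:12, ], sim$config,
                               sim$ref$genome)
  multi <- count_bsj_reads_multi(reads$mock_reads, cand, sim$ref$genome)
  keep <- filter_linear_reads(reads$mock_reads, sim$ref$genome)
  single <- vapply(seq_len(nrow(cand)), function(i) {
    ps <- build_pseudo_seq(cand[i, ], sim$ref$genome)
    count_bsj_reads(as.character(reads$mock_reads)[keep], ps)
  }, integer(1))
  expect_equal(unname(multi), single)
  ## and recovers the simulated molecule counts exactly (unique BSJs)
  expect_equal(unname(multi), reads$counts$mock_sim[1:12])
})

test_that("RPM, ratio and class follow the piecewise rule exactly", {
  q <- quantify_counts(c("a", "b", "c", "d"),
                       mock_count = c(7L, 2L, 1L, 0L),
                       treated_count = c(7L, 1L, 5L, 2L),
                       mock_total = 3.5e6, treated_total = 3.5e6)
  expect_equal(q$circ_id, c("a", "b", "c"))  # zero-mock candidate dropped
  expect_equal(q$mock_rpm[1], 2.0)
  expect_equal(q$depletion_class, c("not-depleted", "depleted", "excluded"))
  ## ratio exactly 1 is not-depleted (boundary), treated 0 is depleted
  q2 <- quantify_counts(c("x", "y"), c(4L, 4L), c(2L, 0L), 1e6, 5e5)
  expect_equal(q2$ratio, c(1, 0))
  expect_equal(q2$depletion_class, c("not-depleted", "depleted"))
  expect_error(quantify_counts("a", 1L, 1L, 0, 1e6), "positive")
})

test_that("classification is scale-invariant and order-equivariant", {
  with_seed(37L, {
    n <- 60L
    mc <- stats::rpois(n, 10); tc <- stats::rbinom(n, mc, 0.6)
    ids <- sprintf("c%02d", seq_len(n))
    q1 <- quantify_counts(ids, mc, tc, 2e6, 1e6)
    q3 <- quantify_counts(ids, 3L * mc, 3L * tc, 3 * 2e6, 3 * 1e6)
    expect_equal(q1$ratio, q3$ratio)
    expect_equal(q1$depletion_class, q3$depletion_class)
    perm <- sample(n)
    qp <- quantify_counts(ids[perm], mc[perm], tc[perm], 2e6, 1e6)
    expect_equal(qp[order(qp$circ_id), ], q1[order(q1$circ_id), ],
                 ignore_attr = TRUE)
  })
})

test_that("pair inclusion applies both strict thresholds", {
  mk <- function(n_mock, n_both) {
    quantify_counts(sprintf("c%04d", seq_len(n_mock)),
                    rep(5L, n_mock),
                    c(rep(3L, n_both), rep(0L, n_mock - n_both)),
                    1e6, 1e6)
  }
  expect_true(check_pair_inclusion(mk(601L, 300L))$pass)    # 300/601 > 1/3
  expect_false(check_pair_inclusion(mk(600L, 400L))$pass)   # not > 600
  expect_false(check_pair_inclusion(mk(900L, 200L))$pass)   # 2/9 <= 1/3
})

test_that("the ambiguity screen flags planted colinear and multi-locus cases", {
  with_seed(41L, {
    base <- rand_dna(8000L)
    cand <- fixture_candidate("amb", acceptor = 2001L, donor = 2500L)
    ps_seq <- paste0(substr(base, 2451, 2500), substr(base, 2001, 2050))
    ## plant the concatenated junction sequence elsewhere (tandem-duplication
    ## style colinear explanation)
    g_colin <- c(chrT = paste0(substr(base, 1, 5000), ps_seq,
                               substr(base, 5101, 8000)))
    ## plant a second copy of the donor flank only (multiple hits)
    g_multi <- c(chrT = paste0(substr(base, 1, 5000), substr(base, 2451, 2500),
                               substr(base, 5051, 8000)))
    g_plain <- c(chrT = base)
    a1 <- screen_ambiguity(cand, genome = g_colin)
    expect_true(a1$has_colinear_explanation)
    expect_true(a1$ambiguous)
    a2 <- screen_ambiguity(cand, genome = g_multi)
    expect_true(a2$has_multiple_hits)
    a3 <- screen_ambiguity(cand, genome = g_plain)
    expect_false(a3$has_colinear_explanation)
    expect_false(a3$has_multiple_hits)
    expect_false(a3$ambiguous)
  })
})

test_that("read-level classification recovers truth under extreme retention", {
  cfg <- sim_config(n_circ_true = 30L, n_circ_artifact = 30L, n_genes = 20L,
                    chrom_len = 60000L, lambda_mock = 50,
                    depletion_model = list(g = c(retain_prob_true = 1,
                                                 retain_prob_artifact = 0)),
                    treatment_group = "g",
                    library_size_mock = 1e6, library_size_treated = 1e6,
                    n_background_mock = 150L, n_background_treated = 150L,
                    seed = 43L)
  ref <- simulate_reference(cfg)
  cand <- simulate_candidates(cfg, ref)
  reads <- simulate_read_pairs(cand$candidates, cand$truth, cfg, ref$genome)
  q <- quantify_pair(cand$candidates, ref$genome, reads$mock_reads,
                     reads$treated_reads, reads$mock_total, reads$treated_total)
  m <- merge(q[q$depletion_class != "excluded", ], cand$truth, by = "circ_id")
  sens <- mean(m$depletion_class[m$is_true_circ] == "not-depleted")
  spec <- mean(m$depletion_class[!m$is_true_circ] == "depleted")
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})
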