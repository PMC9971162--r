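ann <- fixture_annotation()

test_that("boundary annotation is strand-aware and isoform-aware", {
  ## E2-only circle of geneA: both boundaries in t1, E2 skipped in t2
  b <- annotate_boundaries(fixture_candidate("f1", 1001L, 1150L), ann)
  expect_true(b$donor_annotated && b$acceptor_annotated)
  expect_true(b$both_annotated && b$same_isoform)
  ## one-nucleotide shift of the donor breaks the donor flag only
  b2 <- annotate_boundaries(fixture_candidate("f2", 1001L, 1151L), ann)
  expect_false(b2$donor_annotated)
  expect_true(b2$acceptor_annotated)
  expect_false(b2$both_annotated)
  expect_false(b2$same_isoform)
  ## minus-strand gene: donor is the genomic start of an exon
  b3 <- annotate_boundaries(
    fixture_candidate("f3", 3700L, 3001L, strand = "-", gene_id = "geneB"), ann)
  expect_true(b3$both_annotated && b3$same_isoform)
  ## no annotation on the locus at all
  b4 <- annotate_boundaries(fixture_candidate("f4", 4501L, 4700L), ann)
  expect_false(any(unlist(b4)))
})

test_that("both boundaries annotated in different isoforms is not same-isoform", {
  ## add an isoform-3 exon so one boundary exists only in t3
  ann2 <- rbind(ann, data.frame(gene_id = "geneA", transcript_id = "geneA.t3",
                                chrom = "chrT", start = 1801L, end = 1950L,
                                strand = "+", stringsAsFactors = FALSE))
  b <- annotate_boundaries(fixture_candidate("f5", 1001L, 1950L), ann2)
  expect_true(b$both_annotated)
  expect_false(b$same_isoform)
})

test_that("alternative splicing uses the partner and skip rules", {
  ## skipped exon E2: both of its sites AS via the skip rule
  a1 <- annotate_as(fixture_candidate("a1", 1001L, 1150L), ann)
  expect_true(a1$donor_AS && a1$acceptor_AS && a1$both_AS)
  ## E1 donor pairs with two distinct acceptors (E2 in t1, E3 in t2): rule (a)
  a2 <- annotate_as(fixture_candidate("a2", 501L, 700L), ann)
  expect_true(a2$donor_AS)
  expect_false(a2$acceptor_AS)  # E1 acceptor is a transcript start, constitutive
  expect_false(a2$both_AS)
  ## single-isoform gene: constitutive sites
  a3 <- annotate_as(
    fixture_candidate("a3", 3700L, 3001L, strand = "-", gene_id = "geneB"), ann)
  expect_false(a3$donor_AS || a3$acceptor_AS)
  ## disabling both rules switches everything off
  a4 <- annotate_as(fixture_candidate("a1", 1001L, 1150L), ann,
                    use_partner_rule = FALSE, use_skip_rule = FALSE)
  expect_false(a4$both_AS)
})

test_that("RCS counts find planted matches and agree with the brute-force oracle", {
  with_seed(47L, {
    up <- rand_dna(1000L)
    down <- rand_dna(1000L)
    insert <- rand_dna(40L)
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    ## plant insert in the upstream flank and its reverse complement downstream
    up2 <- paste0(substr(up, 1, 400), insert, substr(up, 441, 1000))
    down2 <- paste0(substr(down, 1, 700), rc(insert), substr(down, 741, 1000))
    circle <- rand_dna(200L)
    genome <- c(chrP = paste0(up2, circle, down2))
    cand <- fixture_candidate("r1", acceptor = 1001L, donor = 1200L,
                              chrom = "chrP")
    res <- count_rcs(cand, genome, window = 1000L, min_len = 30L)
    orc <- rcs_oracle(up2, down2, 30L)
    expect_gte(res$rcs_across, 1L)
    expect_equal(res$rcs_across, orc$across)
    expect_equal(res$rcs_within, orc$within)
    expect_equal(res$rcs_diff, res$rcs_across - res$rcs_within)

    ## random flanks: no match of length >= 30, oracle agrees
    genome0 <- c(chrP = paste0(up, circle, down))
    res0 <- count_rcs(cand, genome0, window = 1000L, min_len = 30L)
    orc0 <- rcs_oracle(up, down, 30L)
    expect_equal(res0$rcs_across, orc0$across)
    expect_equal(res0$rcs_across, 0L)

    ## hairpin inside the downstream flank raises rcs_within only
    hp <- paste0(insert, "AAAAA", rc(insert))
    down3 <- paste0(substr(down, 1, 500), hp, substr(down, 501 + nchar(hp), 1000))
    genome3 <- c(chrP = paste0(up, circle, substr(paste0(down3, down), 1, 1000)))
    res3 <- count_rcs(cand, genome3, window = 1000L, min_len = 30L)
    expect_gte(res3$rcs_within, 1L)
    expect_equal(res3$rcs_across, 0L)
  })
})

test_that("RBP flank overlap reports the minimum distance to either site", {
  cand <- fixture_candidate("b1", acceptor = 5000L, donor = 8000L)
  sites <- data.frame(chrom = "chrT",
                      start = c(8100L, 2000L), end = c(8120L, 2100L))
  r <- rbp_flank_overlap(cand, sites, flank = 1000L)
  expect_true(r$rbp_flank)
  expect_equal(r$rbp_min_dist, 100L)
  ## boundary: nearest site exactly 1001 nt away -> outside the flank
  r2 <- rbp_flank_overlap(cand, data.frame(chrom = "chrT", start = 9001L,
                                           end = 9050L), flank = 1000L)
  expect_false(r2$rbp_flank)
  expect_equal(r2$rbp_min_dist, 1001L)
  ## a site covering the donor coordinate has distance 0
  r3 <- rbp_flank_overlap(cand, data.frame(chrom = "chrT", start = 7990L,
                                           end = 8010L))
  expect_equal(r3$rbp_min_dist, 0L)
  expect_true(r3$rbp_flank)
  ## empty site table: flag false, distance missing
  r4 <- rbp_flank_overlap(cand, data.frame(chrom = character(0),
                                           start = integer(0), end = integer(0)))
  expect_false(r4$rbp_flank)
  expect_true(is.na(r4$rbp_min_dist))
})

test_that("the junction-span filter applies per-kind minimum spans", {
  sites <- data.frame(circ_id = "c", kind = c("RBP", "miRNA", "G4", "miRNA"),
                      start = c(48L, 48L, 52L, 46L), end = c(57L, 57L, 80L, 55L),
                      stringsAsFactors = FALSE)
  f <- span_filter(sites)
  expect_true(f$rbp_span)     # [48,57]: spans 3|7, RBP needs >= 2
  expect_true(f$mirna_span)   # [46,55]: spans 5|5 passes; [48,57] alone fails
  expect_false(f$g4_span)     # [52,80]: donor-side span 0
  f2 <- span_filter(sites[sites$kind == "miRNA" & sites$start == 48L, ])
  expect_false(f2$mirna_span)
  ## appending non-spanning sites never changes decisions
  extra <- data.frame(circ_id = "c", kind = c("RBP", "G4"),
                      start = c(60L, 1L), end = c(90L, 49L),
                      stringsAsFactors = FALSE)
  f3 <- span_filter(rbind(sites, extra))
  expect_equal(f3, f)
  expect_error(span_filter(data.frame(circ_id = "c", kind = "G4",
                                      start = 0L, end = 10L)), "start")
})

test_that("evolutionary-rate windows average the right strand-aware bases", {
  cand <- fixture_candidate("e1", acceptor = 1001L, donor = 1150L)
  const_track <- data.frame(chrom = "chrT", pos = 1:6000, score = 0.5)
  e <- evo_rate_regions(cand, const_track)
  expect_equal(unlist(e[paste0("evo_", c("acceptor_exon", "acceptor_intron",
                                         "donor_exon", "donor_intron"))],
                      use.names = FALSE), rep(0.5, 4))
  ## position-index track gives closed-form window means
  idx_track <- data.frame(chrom = "chrT", pos = 1:6000, score = 1:6000)
  e2 <- evo_rate_regions(cand, idx_track)
  expect_equal(e2$evo_acceptor_exon, mean(1001:1010))
  expect_equal(e2$evo_acceptor_intron, mean(991:1000))
  expect_equal(e2$evo_donor_exon, mean(1141:1150))
  expect_equal(e2$evo_donor_intron, mean(1151:1160))
  ## minus strand mirrors the windows
  cand_m <- fixture_candidate("e2", acceptor = 3200L, donor = 3001L,
                              strand = "-", gene_id = "geneB")
  e3 <- evo_rate_regions(cand_m, idx_track)
  expect_equal(e3$evo_acceptor_exon, mean(3191:3200))
  expect_equal(e3$evo_acceptor_intron, mean(3201:3210))
  expect_equal(e3$evo_donor_exon, mean(3001:3010))
  expect_equal(e3$evo_donor_intron, mean(2991:3000))
  ## half-covered window: mean over covered bases, coverage reported
  half_track <- idx_track[idx_track$pos >= 1006, ]
  e4 <- evo_rate_regions(cand, half_track)
  expect_equal(e4$evo_acceptor_exon, mean(1006:1010))
  expect_equal(e4$cov_acceptor_exon, 5L)
  ## fully missing window is NA
  e5 <- evo_rate_regions(cand, idx_track[idx_track$pos > 2000, ])
  expect_true(is.na(e5$evo_acceptor_exon))
})

test_that("functional-feature and supporting-factor counts apply the cutoffs", {
  expect_equal(count_functional_features(rep(TRUE, 9)), 9L)
  expect_equal(count_functional_features(c(mirna_span = TRUE)), 1L)
  expect_equal(count_functional_features(c(NA, NA, FALSE)), 0L)
  expect_error(count_functional_features(rep(TRUE, 10)), "at most 9")
  full <- data.frame(multi_tool = TRUE, full_length = TRUE, n_samples = 5L,
                     both_annotated = TRUE, same_isoform = TRUE, both_AS = TRUE,
                     n_functional_features = 4L)
  expect_equal(count_supporting_factors(full), 7L)
  none <- data.frame(multi_tool = FALSE, full_length = FALSE, n_samples = 2L,
                     both_annotated = FALSE, same_isoform = FALSE,
                     both_AS = FALSE, n_functional_features = 2L)
  expect_equal(count_supporting_factors(none), 0L)
  only_ns <- transform(none, n_samples = 3L)  # boundary: count == cutoff
  expect_equal(count_supporting_factors(only_ns), 1L)
})

test_that("simulated placements reproduce their intended structural flags", {
  sim <- small_sim()
  fm <- build_factor_matrix(sim$candidates, sim$ref$exons)
  m <- merge(fm, sim$truth, by = "circ_id", suffixes = c("", ".truth"))
  expect_equal(m$both_annotated, m$both_annotated.truth)
  expect_equal(m$same_isoform, m$same_isoform.truth)
  expect_equal(m$both_AS, m$both_AS.truth)
  ## annotated placements are 100% flagged, perturbed placements 0%
  expect_true(all(m$both_annotated[m$kind %in% c("true", "chimera",
                                                 "artifact_on_boundary")]))
  expect_false(any(m$both_annotated[m$kind == "perturbed"]))
  expect_true(all(m$n_supporting_factors >= 0L & m$n_supporting_factors <= 7L))
  ## recomputation is idempotent
  expect_identical(fm, build_factor_matrix(sim$candidates, sim$ref$exons))
})
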