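## Synthetic-data generator: toy genome + annotation, circRNA truth set with
## class-conditional factor values, and paired mock/treated read sets.

BASES <- c("A", "C", "G", "T")

#' Simulate a toy genome and multi-isoform transcript annotation
#'
#' Genes are placed left to right (round-robin across chromosomes) with
#' intergenic gaps; a configurable fraction of genes with >= 3 exons receives
#' a second isoform that skips one internal exon, so that same-isoform and
#' alternative-splicing factors have both positive and negative cases
#' downstream. Exon coordinates are 1-based inclusive.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a [Biostrings::DNAStringSet]), `exons` (a
#'   data.frame with columns gene_id, transcript_id, chrom, start, end,
#'   strand) and `genes` (one row per gene).
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  with_seed(stage_seed(config$seed, "reference"), {
    chroms <- paste0("chr", seq_len(config$genome_n_chroms))
    genome <- vapply(chroms, function(ch) {
      paste(sample(BASES, config$chrom_len, replace = TRUE), collapse = "")
    }, character(1))

    margin <- 1500L
    cursor <- stats::setNames(rep(margin, length(chroms)), chroms)
    exon_rows <- list()
    gene_rows <- list()
    for (g in seq_len(config$n_genes)) {
      n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
      ex_len <- sample(120:250, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) sample(200:600, n_ex - 1L, replace = TRUE) else integer(0)
      g_len <- sum(ex_len) + sum(in_len)
      ## first chromosome (round-robin order) with room left
      order_try <- chroms[((g - 1L + seq_along(chroms) - 1L) %% length(chroms)) + 1L]
      ch <- NA_character_
      for (cand in order_try) {
        if (cursor[[cand]] + g_len + margin <= config$chrom_len) { ch <- cand; break }
      }
      if (is.na(ch)) {
        stopf("chrom_len %d too small to place %d genes (failed at gene %d)",
              config$chrom_len, config$n_genes, g)
      }
      start <- cursor[[ch]]
      starts <- start + cumsum(c(0L, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len - 1L
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("gene%03d", g)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
        chrom = ch, start = starts, end = ends, strand = strand,
        stringsAsFactors = FALSE)
      skipped <- NA_integer_
      if (n_ex >= 3L && stats::runif(1) < config$isoform_fraction) {
        skipped <- sample(2:(n_ex - 1L), 1L)
        keep <- setdiff(seq_len(n_ex), skipped)
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          gene_id = gene_id, transcript_id = paste0(gene_id, ".t2"),
          chrom = ch, start = starts[keep], end = ends[keep], strand = strand,
          stringsAsFactors = FALSE)
      }
      gene_rows[[g]] <- data.frame(
        gene_id = gene_id, chrom = ch, strand = strand, n_exons = n_ex,
        skipped_exon = skipped,
        n_transcripts = if (is.na(skipped)) 1L else 2L,
        stringsAsFactors = FALSE)
      cursor[[ch]] <- ends[n_ex] + sample(800:2000, 1L)
    }
    exons <- do.call(rbind, exon_rows)
    rownames(exons) <- NULL
    list(genome = Biostrings::DNAStringSet(genome),
         exons = exons,
         genes = do.call(rbind, gene_rows))
  })
}

## Strand-aware BSJ coordinates of a circle covering exons i..j (genomic
## order) of one transcript: the acceptor is the first exonic base of the
## circle in transcript orientation, the donor the last.
bsj_coords <- function(exons_t, i, j) {
  if (exons_t$strand[1] == "+") {
    list(acceptor = exons_t$start[i], donor = exons_t$end[j])
  } else {
    list(acceptor = exons_t$end[j], donor = exons_t$start[i])
  }
}

## One structural placement draw for candidate k (see simulate_candidates).
place_candidate <- function(k, on_boundary, chimera, want_as, is_true,
                            chim_pool, as_pool, const_pool, tr_split, config) {
  if (on_boundary[k] && chimera[k]) {
    pr <- chim_pool[sample(nrow(chim_pool), 1L), ]
    tl <- tr_split[[paste0(pr$left, ".t1")]]
    tr <- tr_split[[paste0(pr$right, ".t1")]]
    s <- tl$strand[1]
    if (s == "+") {
      acc <- tl$start[sample(nrow(tl), 1L)]
      don <- tr$end[sample(nrow(tr), 1L)]
    } else {
      don <- tl$start[sample(nrow(tl), 1L)]
      acc <- tr$end[sample(nrow(tr), 1L)]
    }
    list(chrom = tl$chrom[1], acceptor = acc, donor = don,
         strand = s, gene_id = if (s == "+") pr$left else pr$right,
         kind = "chimera", ba = TRUE, si = FALSE, as = FALSE)
  } else if (on_boundary[k]) {
    pool <- if (want_as[k]) as_pool else const_pool
    pr <- pool[sample(nrow(pool), 1L), ]
    tt <- tr_split[[pr$transcript_id]]
    co <- bsj_coords(tt, pr$i, pr$j)
    list(chrom = tt$chrom[1], acceptor = co$acceptor,
         donor = co$donor, strand = tt$strand[1], gene_id = pr$gene_id,
         kind = if (is_true[k]) "true" else "artifact_on_boundary",
         ba = TRUE, si = TRUE, as = want_as[k])
  } else {
    pr <- const_pool[sample(nrow(const_pool), 1L), ]
    tt <- tr_split[[pr$transcript_id]]
    co <- bsj_coords(tt, pr$i, pr$j)
    sh <- function() sample(c(-15:-1, 1:15), 1L)
    acc <- co$acceptor + sh(); don <- co$donor + sh()
    ## keep backsplice orientation and room for 50-nt flanks
    lo <- min(acc, don); hi <- max(acc, don)
    if (lo < 60L || hi > config$chrom_len - 60L ||
        (tt$strand[1] == "+" && don <= acc) ||
        (tt$strand[1] == "-" && don >= acc) || abs(don - acc) < 110L) {
      acc <- co$acceptor + 3L; don <- co$donor - 3L
    }
    list(chrom = tt$chrom[1], acceptor = acc, donor = don,
         strand = tt$strand[1], gene_id = pr$gene_id,
         kind = "perturbed", ba = FALSE, si = FALSE, as = FALSE)
  }
}

#' Simulate circRNA candidates with known ground truth
#'
#' Generates a mixture of `n_circ_true` genuine circRNAs (BSJ boundaries on
#' annotated exon boundaries of one isoform) and `n_circ_artifact` artifacts
#' (boundary-perturbed events, two-gene chimeras, or on-boundary false
#' positives), together with class-conditionally drawn identification /
#' conservation / function factor values whose log-odds for the true class
#' follow `config$factor_effects` exactly (naive-Bayes construction).
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return A list with `candidates` (circ_id, chrom, acceptor_pos, donor_pos,
#'   strand, gene_id and drawn factor columns) and `truth` (one record per
#'   candidate: is_true_circ, kind, expected_class, Poisson read rate lambda,
#'   and the intended structural flags).
#' @export
simulate_candidates <- function(config, reference) {
  validate_sim_config(config)
  exons <- reference$exons
  if (is.null(exons) || nrow(exons) == 0L) stopf("no annotated exons available")
  genes <- reference$genes

  ## placement pools --------------------------------------------------------
  tr_split <- split(exons, exons$transcript_id)
  tr_split <- lapply(tr_split, function(df) df[order(df$start), , drop = FALSE])
  single_iso_genes <- genes$gene_id[genes$n_transcripts == 1L]
  multi_iso_genes <- genes$gene_id[genes$n_transcripts == 2L]
  ## skipped exons (AS-capable single-exon circles, in transcript .t1)
  as_pool <- do.call(rbind, lapply(multi_iso_genes, function(g) {
    sk <- genes$skipped_exon[genes$gene_id == g]
    t1 <- tr_split[[paste0(g, ".t1")]]
    data.frame(gene_id = g, i = sk, j = sk, transcript_id = paste0(g, ".t1"),
               stringsAsFactors = FALSE)
  }))
  ## constitutive exon pairs from single-isoform genes (no AS sites there)
  const_pool <- do.call(rbind, lapply(single_iso_genes, function(g) {
    t1 <- tr_split[[paste0(g, ".t1")]]
    n <- nrow(t1)
    idx <- expand.grid(i = seq_len(n), j = seq_len(n))
    idx <- idx[idx$j >= idx$i & idx$j - idx$i <= 3L, , drop = FALSE]
    data.frame(gene_id = g, i = idx$i, j = idx$j,
               transcript_id = paste0(g, ".t1"), stringsAsFactors = FALSE)
  }))
  if (is.null(const_pool) || nrow(const_pool) == 0L) {
    stopf("no single-isoform genes available for constitutive placements; lower isoform_fraction")
  }
  if (is.null(as_pool)) as_pool <- const_pool[0, ]
  ## chimera pairs: two single-isoform genes, same chromosome and strand
  chim_pool <- NULL
  gi <- genes[genes$gene_id %in% single_iso_genes, ]
  for (ch in unique(gi$chrom)) for (s in c("+", "-")) {
    gg <- gi$gene_id[gi$chrom == ch & gi$strand == s]
    if (length(gg) >= 2L) {
      prs <- t(combn(gg, 2L))
      chim_pool <- rbind(chim_pool, data.frame(left = prs[, 1], right = prs[, 2],
                                               stringsAsFactors = FALSE))
    }
  }

  eff <- function(nm) if (nm %in% names(config$factor_effects)) config$factor_effects[[nm]] else 0
  base <- config$factor_baselines
  retain <- config$depletion_model[[config$treatment_group]]

  n_true <- config$n_circ_true
  n_art <- config$n_circ_artifact
  n <- n_true + n_art

  with_seed(stage_seed(config$seed, "candidates"), {
    is_true <- rep(c(TRUE, FALSE), c(n_true, n_art))

    ## drawn factors: class-conditional draws with exactly logistic log-odds
    p_mt <- ifelse(is_true, stats::plogis(stats::qlogis(base[["multi_tool"]]) + eff("multi_tool")),
                   base[["multi_tool"]])
    multi_tool <- stats::rbinom(n, 1L, p_mt) == 1L
    n_tools <- ifelse(multi_tool, sample(2:4, n, replace = TRUE), 1L)
    p_fl <- ifelse(is_true, stats::plogis(stats::qlogis(base[["full_length"]]) + eff("full_length")),
                   base[["full_length"]])
    full_length <- stats::rbinom(n, 1L, p_fl) == 1L
    lam_ns <- ifelse(is_true, base[["n_samples"]] * exp(eff("n_samples")), base[["n_samples"]])
    n_samples <- 1L + stats::rpois(n, lam_ns)
    p_ff <- ifelse(is_true,
                   stats::plogis(stats::qlogis(base[["n_functional_features"]]) + eff("n_functional_features")),
                   base[["n_functional_features"]])
    n_func <- stats::rbinom(n, 9L, p_ff)
    lambda <- config$lambda_mock * ifelse(is_true, exp(eff("bsj_read_count")), 1)

    ## structural placement -------------------------------------------------
    on_boundary <- is_true | (stats::runif(n) < config$artifact_on_boundary_prob)
    p_chim <- ifelse(is_true, config$chimera_prob_true, config$chimera_prob_artifact)
    chimera <- on_boundary & (stats::runif(n) < p_chim) & !is.null(chim_pool)
    p_as <- ifelse(is_true, config$as_pair_prob_true, config$as_pair_prob_artifact)
    want_as <- on_boundary & !chimera & (stats::runif(n) < p_as) & nrow(as_pool) > 0L

    rows <- vector("list", n)
    used <- character(0)  # BSJ events are unique in a candidate table
    for (k in seq_len(n)) {
      wa <- want_as
      for (attempt in seq_len(60L)) {
        ## small placement pools (AS exons, chimera gene pairs) can run dry;
        ## fall back to the constitutive pool rather than emit duplicates
        if (attempt > 20L) wa[k] <- FALSE
        if (attempt > 40L) chimera[k] <- FALSE
        row_k <- place_candidate(k, on_boundary, chimera, wa, is_true,
                                 chim_pool, as_pool, const_pool, tr_split,
                                 config)
        key <- paste(row_k$chrom, row_k$acceptor, row_k$donor, row_k$strand)
        if (!key %in% used) break
      }
      used <- c(used, key)
      rows[[k]] <- row_k
    }
    pl <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))

    circ_id <- sprintf("circ%05d", seq_len(n))
    retain_k <- ifelse(is_true, retain[["retain_prob_true"]], retain[["retain_prob_artifact"]])
    expected_ratio <- retain_k * config$library_size_mock / config$library_size_treated
    candidates <- data.frame(
      circ_id = circ_id, chrom = pl$chrom,
      acceptor_pos = as.integer(pl$acceptor), donor_pos = as.integer(pl$donor),
      strand = pl$strand, gene_id = pl$gene_id,
      n_tools = as.integer(n_tools), full_length = full_length,
      n_samples = as.integer(n_samples),
      n_functional_features = as.integer(n_func),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      circ_id = circ_id, is_true_circ = is_true, kind = pl$kind,
      expected_class = ifelse(expected_ratio >= 1, "not-depleted", "depleted"),
      lambda = lambda, multi_tool = multi_tool, n_tools = as.integer(n_tools),
      full_length = full_length, n_samples = as.integer(n_samples),
      n_functional_features = as.integer(n_func),
      both_annotated = pl$ba, same_isoform = pl$si, both_AS = pl$as,
      stringsAsFactors = FALSE)
    list(candidates = candidates, truth = truth)
  })
}

## Draw `cnt` BSJ reads from a pseudo-sequence, each spanning the junction by
## at least `min_span` bases on both sides.
draw_bsj_reads <- function(pseudo_seq, junction, cnt, read_len, min_span = 10L) {
  if (cnt == 0L) return(character(0))
  plen <- nchar(pseudo_seq)
  if (read_len >= plen) return(rep(pseudo_seq, cnt))
  lo <- max(1L, junction + min_span + 1L - read_len)
  hi <- min(plen - read_len + 1L, junction - min_span + 1L)
  if (hi < lo) { lo <- 1L; hi <- plen - read_len + 1L }
  starts <- sample(lo:hi, cnt, replace = TRUE)
  substring(pseudo_seq, starts, starts + read_len - 1L)
}

#' Simulate a paired mock/treated read set for one sample pair
#'
#' Mock BSJ molecule counts are Poisson with the per-candidate rate recorded
#' in the truth table; treated counts are Binomial thinnings with the
#' retention probability of the configured treatment group (high for true
#' circles, low for artifacts). BSJ reads are substrings of the candidate's
#' pseudo-sequence spanning the junction; colinear background reads drawn
#' from the genome are added to both libraries. Raw read totals for the RPM
#' denominators come from the configured library sizes.
#'
#' @param candidates,truth Output of [simulate_candidates()].
#' @param config A [sim_config()].
#' @param genome Toy genome from [simulate_reference()].
#' @return List with `mock_reads` and `treated_reads`
#'   ([Biostrings::DNAStringSet]), `mock_total`, `treated_total`, and
#'   `counts` (the simulated per-candidate molecule counts).
#' @export
simulate_read_pairs <- function(candidates, truth, config, genome) {
  validate_sim_config(config)
  gchr <- as_genome_chr(genome)
  retain <- config$depletion_model[[config$treatment_group]]
  with_seed(stage_seed(config$seed, "reads"), {
    n <- nrow(candidates)
    m <- stats::rpois(n, truth$lambda)
    pr <- ifelse(truth$is_true_circ, retain[["retain_prob_true"]],
                 retain[["retain_prob_artifact"]])
    tr <- stats::rbinom(n, m, pr)
    mock <- character(0); treated <- character(0)
    mock_nm <- character(0); treated_nm <- character(0)
    for (k in seq_len(n)) {
      if (m[k] == 0L) next
      ps <- build_pseudo_seq(candidates[k, ], gchr)
      rd <- draw_bsj_reads(ps$sequence, ps$junction_index, m[k], config$read_len)
      mock <- c(mock, rd)
      mock_nm <- c(mock_nm, sprintf("%s_mock_%d", candidates$circ_id[k], seq_len(m[k])))
      if (tr[k] > 0L) {
        rdt <- draw_bsj_reads(ps$sequence, ps$junction_index, tr[k], config$read_len)
        treated <- c(treated, rdt)
        treated_nm <- c(treated_nm, sprintf("%s_treated_%d", candidates$circ_id[k], seq_len(tr[k])))
      }
    }
    bg <- function(n_bg, tag) {
      if (n_bg == 0L) return(list(seq = character(0), nm = character(0)))
      ch <- sample(names(gchr), n_bg, replace = TRUE)
      st <- vapply(ch, function(c1) sample.int(nchar(gchr[[c1]]) - config$read_len, 1L),
                   integer(1))
      sq <- substring(gchr[ch], st, st + config$read_len - 1L)
      flip <- stats::runif(n_bg) < 0.5
      sq[flip] <- revcomp(sq[flip])
      list(seq = unname(sq), nm = sprintf("bg_%s_%d", tag, seq_len(n_bg)))
    }
    bgm <- bg(config$n_background_mock, "mock")
    bgt <- bg(config$n_background_treated, "treated")
    mock_all <- c(mock, bgm$seq); names(mock_all) <- c(mock_nm, bgm$nm)
    treated_all <- c(treated, bgt$seq); names(treated_all) <- c(treated_nm, bgt$nm)
    om <- sample(length(mock_all)); ot <- sample(length(treated_all))
    list(mock_reads = Biostrings::DNAStringSet(mock_all[om]),
         treated_reads = Biostrings::DNAStringSet(treated_all[ot]),
         mock_total = config$library_size_mock,
         treated_total = config$library_size_treated,
         counts = data.frame(circ_id = candidates$circ_id,
                             mock_sim = m, treated_sim = tr,
                             stringsAsFactors = FALSE))
  })
}

#' Simulate mock/treated BSJ count tables for several sample pairs
#'
#' Count-level shortcut with the identical Poisson/Binomial depletion model as
#' [simulate_read_pairs()] but without read sequences, for multi-pair
#' statistical analyses where sequence-level quantification has already been
#' validated separately.
#'
#' @param truth Truth table from [simulate_candidates()].
#' @param config A [sim_config()].
#' @param n_pairs Number of independent mock/treated sample pairs.
#' @return A data.frame with columns pair_id, circ_id, mock_count,
#'   treated_count, mock_total, treated_total.
#' @export
simulate_pair_counts <- function(truth, config, n_pairs = 5L) {
  validate_sim_config(config)
  retain <- config$depletion_model[[config$treatment_group]]
  pr <- ifelse(truth$is_true_circ, retain[["retain_prob_true"]],
               retain[["retain_prob_artifact"]])
  with_seed(stage_seed(config$seed, "pairs"), {
    do.call(rbind, lapply(seq_len(n_pairs), function(p) {
      m <- stats::rpois(nrow(truth), truth$lambda)
      tr <- stats::rbinom(nrow(truth), m, pr)
      data.frame(pair_id = sprintf("pair%02d", p), circ_id = truth$circ_id,
                 mock_count = m, treated_count = tr,
                 mock_total = config$library_size_mock,
                 treated_total = config$library_size_treated,
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate a plain logistic factor design with known effects
#'
#' Draws the eight reliability factors independently from realistic marginal
#' distributions and a binary depletion outcome from the logistic model
#' `logit P(not-depleted) = b0 + sum(effects * f)`. Used to validate
#' coefficient and importance recovery of the GLM/RCVE stage under a design
#' where the generating standardized effects are known exactly.
#'
#' @param n Number of candidates.
#' @param effects Named coefficients for the eight factors (missing names
#'   default to 0).
#' @param intercept Intercept `b0`; default centres the linear predictor so
#'   classes are roughly balanced.
#' @param seed Seed for this draw.
#' @return List with `factors` (data.frame), `y` (0/1 integer vector),
#'   `effects`, and `std_effects` (`|effect| * sd(factor)`).
#' @export
simulate_factor_logistic <- function(n, effects, intercept = NULL, seed = 1L) {
  factor_names <- c("bsj_read_count", "multi_tool", "full_length", "n_samples",
                    "both_annotated", "same_isoform", "both_AS",
                    "n_functional_features")
  beta <- stats::setNames(numeric(length(factor_names)), factor_names)
  beta[names(effects)] <- effects
  with_seed(seed, {
    X <- data.frame(
      bsj_read_count = stats::rpois(n, 8) + 2L,
      multi_tool = stats::rbinom(n, 1L, 0.4),
      full_length = stats::rbinom(n, 1L, 0.3),
      n_samples = stats::rpois(n, 1.5) + 1L,
      both_annotated = stats::rbinom(n, 1L, 0.6),
      same_isoform = stats::rbinom(n, 1L, 0.45),
      both_AS = stats::rbinom(n, 1L, 0.3),
      n_functional_features = stats::rbinom(n, 9L, 0.2))
    Xm <- as.matrix(X)
    if (is.null(intercept)) intercept <- -sum(beta * colMeans(Xm))
    p <- stats::plogis(intercept + drop(Xm %*% beta))
    y <- stats::rbinom(n, 1L, p)
    list(factors = X, y = y, effects = beta,
         std_effects = abs(beta) * apply(Xm, 2, stats::sd))
  })
}

#' Run the full synthetic generator: reference, candidates, one read pair
#'
#' @param config A [sim_config()].
#' @return List with `reference`, `candidates`, `truth`, `reads`
#'   (see [simulate_read_pairs()]) and the echoed `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  reference <- simulate_reference(config)
  cand <- simulate_candidates(config, reference)
  reads <- simulate_read_pairs(cand$candidates, cand$truth, config, reference$genome)
  list(reference = reference, candidates = cand$candidates, truth = cand$truth,
       reads = reads, config = config)
}
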