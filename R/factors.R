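## Factor annotation: splice-annotation agreement, alternative splicing,
## functional-feature and supporting-factor counts.

## Strand-aware annotated boundary positions of an exon table:
## donor = 3' end of an exon (genomic end on +, start on -),
## acceptor = 5' start of an exon (genomic start on +, end on -).
exon_boundaries <- function(exons) {
  donor <- ifelse(exons$strand == "+", exons$end, exons$start)
  acceptor <- ifelse(exons$strand == "+", exons$start, exons$end)
  cbind(donor = donor, acceptor = acceptor)
}

#' Does a candidate's BSJ agree with annotated exon boundaries?
#'
#' The donor is annotated when `donor_pos` equals the 3' boundary of some
#' annotated exon on the candidate's chromosome and strand; the acceptor
#' analogously for a 5' exon boundary. `same_isoform` requires a single
#' transcript carrying both boundaries.
#'
#' @param candidate One-row candidate data.frame.
#' @param exons Exon annotation data.frame (gene_id, transcript_id, chrom,
#'   start, end, strand).
#' @return One-row data.frame: donor_annotated, acceptor_annotated,
#'   both_annotated, same_isoform.
#' @export
annotate_boundaries <- function(candidate, exons) {
  ex <- exons[exons$chrom == candidate$chrom & exons$strand == candidate$strand, ,
              drop = FALSE]
  if (nrow(ex) == 0L) {
    return(data.frame(donor_annotated = FALSE, acceptor_annotated = FALSE,
                      both_annotated = FALSE, same_isoform = FALSE))
  }
  b <- exon_boundaries(ex)
  don_ok <- b[, "donor"] == candidate$donor_pos
  acc_ok <- b[, "acceptor"] == candidate$acceptor_pos
  donor_annotated <- any(don_ok)
  acceptor_annotated <- any(acc_ok)
  same_isoform <- FALSE
  if (donor_annotated && acceptor_annotated) {
    same_isoform <- length(intersect(ex$transcript_id[don_ok],
                                     ex$transcript_id[acc_ok])) > 0L
  }
  data.frame(donor_annotated = donor_annotated,
             acceptor_annotated = acceptor_annotated,
             both_annotated = donor_annotated && acceptor_annotated,
             same_isoform = same_isoform)
}

## Annotated introns of an exon table: one row per transcript gap, with the
## donor (3' boundary of the upstream-in-transcript exon) and acceptor.
annotated_introns <- function(exons) {
  out <- lapply(split(exons, exons$transcript_id), function(df) {
    if (nrow(df) < 2L) return(NULL)
    df <- df[order(df$start), , drop = FALSE]
    n <- nrow(df)
    if (df$strand[1] == "+") {
      data.frame(transcript_id = df$transcript_id[1],
                 donor = df$end[-n], acceptor = df$start[-1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = df$transcript_id[1],
                 donor = df$start[-1], acceptor = df$end[-n],
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

## Is a splice site alternatively spliced under the annotation?
## (a) it pairs with >= 2 distinct partner sites across annotated introns, or
## (b) some transcript's genomic span covers the site without using it as the
##     same kind of boundary (skipped / unused exon).
site_is_as <- function(pos, kind, ex, introns, use_partner_rule = TRUE,
                       use_skip_rule = TRUE) {
  as_flag <- FALSE
  if (use_partner_rule && !is.null(introns)) {
    partners <- if (kind == "donor") introns$acceptor[introns$donor == pos]
                else introns$donor[introns$acceptor == pos]
    if (length(unique(partners)) >= 2L) as_flag <- TRUE
  }
  if (!as_flag && use_skip_rule) {
    b <- exon_boundaries(ex)
    used_here <- b[, kind] == pos
    if (any(used_here)) {  # unannotated sites are not AS
      for (tid in unique(ex$transcript_id)) {
        sel <- ex$transcript_id == tid
        span <- range(c(ex$start[sel], ex$end[sel]))
        covered <- pos >= span[1] && pos <= span[2]
        uses <- any(used_here[sel])
        if (covered && !uses) { as_flag <- TRUE; break }
      }
    }
  }
  as_flag
}

#' Are a candidate's BSJ splice sites subject to alternative splicing?
#'
#' A site counts as alternatively spliced (AS) when, across the annotated
#' transcripts of its chromosome and strand, it either pairs with two or more
#' distinct partner splice sites in annotated introns (alternative
#' donor/acceptor usage) or is covered but unused by at least one transcript
#' (exon skipping). Both rules can be disabled individually. Unannotated
#' sites are never AS.
#'
#' @param candidate One-row candidate data.frame.
#' @param exons Exon annotation data.frame.
#' @param use_partner_rule,use_skip_rule Enable the two AS rules.
#' @return One-row data.frame: donor_AS, acceptor_AS, both_AS.
#' @export
annotate_as <- function(candidate, exons, use_partner_rule = TRUE,
                        use_skip_rule = TRUE) {
  ex <- exons[exons$chrom == candidate$chrom & exons$strand == candidate$strand, ,
              drop = FALSE]
  if (nrow(ex) == 0L) {
    return(data.frame(donor_AS = FALSE, acceptor_AS = FALSE, both_AS = FALSE))
  }
  introns <- annotated_introns(ex)
  donor_AS <- site_is_as(candidate$donor_pos, "donor", ex, introns,
                         use_partner_rule, use_skip_rule)
  acceptor_AS <- site_is_as(candidate$acceptor_pos, "acceptor", ex, introns,
                            use_partner_rule, use_skip_rule)
  data.frame(donor_AS = donor_AS, acceptor_AS = acceptor_AS,
             both_AS = donor_AS && acceptor_AS)
}

#' Count supporting functional features
#'
#' Sums nine binary indicators of circRNA functionality: seven coding-potential
#' evidence types (ribosome/polysome binding, experimentally supported
#' translation initiation site, internal ribosome entry site, predicted m6A
#' site, circRNA-specific ORF, ORF sequence-composition score, mass
#' spectrometry peptide across the BSJ) plus junction-spanning predicted
#' miRNA- and RBP-binding sites. Missing indicators count as absent.
#'
#' @param flags Logical vector or one-row data.frame of up to 9 indicators.
#' @return Integer in 0..9.
#' @export
count_functional_features <- function(flags) {
  v <- unlist(flags, use.names = FALSE)
  if (length(v) > 9L) stopf("at most 9 functional-feature indicators expected")
  v[is.na(v)] <- FALSE
  as.integer(sum(as.logical(v)))
}

#' Count supporting reliability factors per candidate
#'
#' Counts, out of seven, the binary/thresholded indicators supporting a
#' candidate: detected by multiple tools, full-length evidence, observed in
#' at least `cutoff_counts` samples, both boundaries annotated, boundaries on
#' the same isoform, both sites alternatively spliced, and at least
#' `cutoff_counts` functional features. The BSJ read count is deliberately
#' not included because it depends on the examined sample.
#'
#' @param row One-row data.frame (or vectorised data.frame) with columns
#'   multi_tool, full_length, n_samples, both_annotated, same_isoform,
#'   both_AS, n_functional_features.
#' @param cutoff_counts Threshold applied to the two count-valued factors
#'   (default 3; a count equal to the cutoff supports).
#' @return Integer vector in 0..7.
#' @export
count_supporting_factors <- function(row, cutoff_counts = 3L) {
  as.integer(as.logical(row$multi_tool) + as.logical(row$full_length) +
             (row$n_samples >= cutoff_counts) + as.logical(row$both_annotated) +
             as.logical(row$same_isoform) + as.logical(row$both_AS) +
             (row$n_functional_features >= cutoff_counts))
}

#' Assemble the per-candidate factor matrix
#'
#' Combines the identification/conservation/function factor columns carried
#' on the candidate table (n_tools, full_length, n_samples,
#' n_functional_features and any passthrough scores) with the
#' annotation-derived boundary, isoform and AS flags, and the supporting-
#' factor count. The sample-dependent BSJ read count joins later from a
#' pair's quantification (see [glm_input()]).
#'
#' @param candidates Candidate table.
#' @param exons Exon annotation data.frame.
#' @param cutoff_counts Cutoff for [count_supporting_factors()].
#' @return Data.frame keyed by circ_id with one column per factor.
#' @export
build_factor_matrix <- function(candidates, exons, cutoff_counts = 3L) {
  ann <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
    cbind(annotate_boundaries(candidates[i, ], exons),
          annotate_as(candidates[i, ], exons))
  }))
  fm <- data.frame(circ_id = candidates$circ_id,
                   n_tools = candidates$n_tools,
                   multi_tool = candidates$n_tools >= 2L,
                   full_length = as.logical(candidates$full_length),
                   n_samples = candidates$n_samples,
                   n_functional_features = candidates$n_functional_features,
                   stringsAsFactors = FALSE)
  fm <- cbind(fm, ann)
  passthrough <- intersect(c("tissue_specificity_index", "splice_strength_donor",
                             "splice_strength_acceptor", "n_species", "n_tissues"),
                           names(candidates))
  for (col in passthrough) fm[[col]] <- candidates[[col]]
  fm$n_supporting_factors <- count_supporting_factors(fm, cutoff_counts)
  fm
}

#' Merge a sample pair's quantification into the factor matrix for the GLM
#'
#' Restricts to classified (non-excluded) candidates of the pair, attaches the
#' mock BSJ read count as the `bsj_read_count` factor and the binary response
#' `y` (1 = not-depleted, 0 = depleted).
#'
#' @param factor_matrix Output of [build_factor_matrix()].
#' @param quant Output of [quantify_counts()] for one pair.
#' @return Data.frame with circ_id, y and the eight model factors.
#' @export
glm_input <- function(factor_matrix, quant) {
  q <- quant[quant$depletion_class != "excluded", ]
  m <- merge(q[, c("circ_id", "mock_count", "depletion_class")],
             factor_matrix, by = "circ_id")
  data.frame(circ_id = m$circ_id,
             y = as.integer(m$depletion_class == "not-depleted"),
             bsj_read_count = m$mock_count,
             multi_tool = as.integer(m$multi_tool),
             full_length = as.integer(m$full_length),
             n_samples = m$n_samples,
             both_annotated = as.integer(m$both_annotated),
             same_isoform = as.integer(m$same_isoform),
             both_AS = as.integer(m$both_AS),
             n_functional_features = m$n_functional_features,
             stringsAsFactors = FALSE)
}
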