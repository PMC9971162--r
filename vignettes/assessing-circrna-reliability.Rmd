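---
title: "Assessing circRNA reliability from mock/treated RNA-seq pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing circRNA reliability from mock/treated RNA-seq pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circReliability)
```

## The problem

Circular RNAs are called from RNA-seq by reads spanning a back-splice
junction (BSJ): a downstream splice donor joined to an upstream splice
acceptor. The same read pattern is produced by reverse-transcription template
switching, alignment ambiguity, and other artifacts, so a large fraction of
database circRNA candidates is of uncertain origin. The experimental
gold-standard proxy for reliability is behaviour under linear-RNA depletion:
in a paired design, a mock (rRNA-depleted) library and a treated library
(RNase R digestion, A-tailing + RNase R, or rRNA/poly(A) double depletion)
are sequenced, and a genuine circle — resistant to exonucleolytic digestion —
keeps or increases its relative abundance, while linear by-products are
depleted.

`circReliability` implements this assessment as a reusable pipeline, and
couples it with a synthetic-data generator with known ground truth so every
stage is testable without external downloads.

## Quantification model

For each candidate, a **pseudo-sequence** concatenates the 50 genomic
nucleotides ending at the donor site with the 50 starting at the acceptor
site, reverse-complemented on the minus strand so the sequence reads 5'->3'
along the transcript. A read supports the BSJ when its best local alignment
to the pseudo-sequence (Smith–Waterman, match +1, mismatch −1, gap −2)

* covers at least 80% of the pseudo-sequence (`min_cover_frac`),
* includes at least 10 bp on each side of the junction (`min_span`), and
* matches at ≥ 95% per aligned column (`min_identity`).

The 80% criterion is a *coverage* threshold here; because short-read
aligner phrasings blur coverage and identity, the identity requirement is
exposed as a separate, configurable knob rather than folded into coverage.
Reads explainable by the colinear genome are removed first (exact substring
test at simulation scale; real data arrive pre-filtered by a genome
aligner), and a read may support several BSJs unless `unique_assignment`
is set.

Candidates whose pseudo-sequence can be explained without a back-splice are
screened out before statistics ([screen_ambiguity()]): a contiguous genomic
window or an annotated spliced transcript reproducing ≥ 80% of the
pseudo-sequence at ≥ 90% identity ("colinear explanation"), or either
50-nt half matching two or more genomic loci ("multiple hits").

Expression is BSJ reads per million raw reads (RPM); with mock and treated
counts $c_m, c_t$ and library totals $T_m, T_t$,

$$\mathrm{ratio} = \frac{c_t \cdot 10^6 / T_t}{c_m \cdot 10^6 / T_m},$$

and a candidate with at least two mock BSJ reads is **not-depleted** when
the ratio is ≥ 1 (the boundary value inclusive; no epsilon) and
**depleted** otherwise; candidates with a single mock read are excluded.
A sample pair enters the analysis only when more than 600 candidates are
detected in the mock sample and more than one third of them are also
detected in the treated sample.

## Factors

Eight factors enter the importance model, per candidate and pair:

| factor | type | source |
|---|---|---|
| `bsj_read_count` | count | mock BSJ reads of the pair |
| `multi_tool` | flag (`n_tools >= 2`) | candidate table |
| `full_length` | flag | candidate table |
| `n_samples` | count | candidate table |
| `both_annotated` | flag | annotation |
| `same_isoform` | flag | annotation |
| `both_AS` | flag | annotation |
| `n_functional_features` | count 0–9 | feature flags / site filters |

Annotation-derived definitions:

* **both_annotated** — donor equals an annotated exon 3' boundary and
  acceptor an exon 5' boundary (strand-aware) on the candidate's chromosome
  and strand; **same_isoform** additionally requires one transcript carrying
  both.
* **both_AS** — a site is alternatively spliced when it (a) pairs with two
  or more distinct partner sites across annotated introns, or (b) is covered
  but unused by some transcript (skipped exon). The annotation-only reading
  was chosen because "subject to alternative splicing" is not otherwise
  formalisable from a GTF; each rule can be disabled, and the scope is the
  chromosome/strand (equivalently the gene, since genes do not overlap in
  the generator).

Additional biogenesis/conservation factors are computed for enrichment
testing: reverse-complementary sequence (RCS) pairs across/within ±20,000-nt
flanks (`count_rcs()`, exact maximal matches of ≥ 30 bp — exact matching
keeps the count brute-force-verifiable, with the 30-bp default at the scale
of the short repeat elements that drive pairing), CLIP RBP sites within
±1,000 nt of either splice site with the minimum distance
(`rbp_flank_overlap()`), junction-spanning predicted sites (G-quadruplex and
miRNA ≥ 5 bp, RBP ≥ 2 bp on both sides; `span_filter()`), and mean
conservation scores over four strand-aware 10-nt windows around the
junction (`evo_rate_regions()`). The supporting-factor count
(`count_supporting_factors()`) counts seven indicators (all model factors
except the sample-dependent read count), with counts thresholded at 3.
Splice-site strength and tissue-specificity scores are passthrough input
columns: their computation requires external tools and is out of scope.

## Statistics

Per sample pair, not-depleted and depleted candidates are contrasted per
factor:

* binary factors: two-tailed Fisher's exact test. The reported odds ratio is
  the cross-product $ad/bc$ (the quantity plotted in this kind of analysis),
  not the conditional MLE; the p-value is the exact hypergeometric
  enumeration. Zero cells get the Haldane +0.5 correction for the OR and its
  Woolf CI, flagged, with the p-value always from the uncorrected table.
* quantitative factors: one-sided Wilcoxon rank-sum test. The p-value uses
  the tie-corrected normal approximation with 0.5 continuity correction,
  switching to full enumeration when both groups have ≤ 9 members (the R
  convention of exact small-sample p-values, made explicit and testable).
  The effect size is $r = |z|/\sqrt{N}$ with a seeded percentile-bootstrap
  95% CI (1,000 replicates by default).
* FDR: Benjamini–Hochberg within one family per factor across sample pairs
  (`bh_adjust(p, family = factor)`), matching a per-factor adjustment across
  the pairs of a study; a single all-tests family is available by passing
  `family = NULL`.

A factor is flagged **important** only when it passes FDR < 0.05 with a
consistent direction in *every* pair — the strict all-pairs rule. Label-set
enrichment (`labelset_enrichment()`) reuses the Fisher machinery for any
external membership vector (validated circRNAs, database-specific sets,
multi-replicate detections), and `factor_count_stratification()` reports
label percentages by supporting-factor count.

## Factor importance: binomial GLM and RCVE

Per pair, the depletion class ($y = 1$ for not-depleted) is modelled as

$$\mathrm{glm}(y \sim f_1 + \dots + f_8,\ \mathrm{family=binomial}),$$

and each factor's importance is its relative contribution to variability
explained,

$$\mathrm{RCVE}_j = \frac{r^2_{\mathrm{all}} - r^2_{\mathrm{reduced}(j)}}{r^2_{\mathrm{all}}},$$

where the reduced model omits factor $j$ and is fit on the identical
candidate rows (listwise-complete). The pseudo-$r^2$ is McFadden's
$1 - \ell/\ell_0$ by default because nested likelihood fits then guarantee
$\mathrm{RCVE} \in [0,1]$; Cox–Snell, Nagelkerke and Tjur are selectable
since the convention differs between analysis stacks. Numeric factors enter
untransformed (RCVE is invariant to linear rescaling). Under perfect
separation — common when depletion is strong — the fit falls back to a
lightly ridge-penalised IRLS ($\lambda = 10^{-3}$, intercept unpenalised),
flagged in the diagnostics; reduced models then use the same estimator,
because mixing penalised and unpenalised fits breaks nesting. Penalised
fits preserve nesting only approximately, so RCVE values are clipped at 0
with a correspondingly looser warning tolerance. Factors are ranked by
descending RCVE with mid-ranks on ties, and `rank_across_pairs()` averages
ranks over pairs.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_reference()`,
`simulate_candidates()` and `simulate_read_pairs()` generate a toy genome
with multi-isoform genes, a candidate mixture, and paired reads.

* **Genome/annotation** — by default 2 chromosomes × 100 kb, 40 genes of
  3–6 exons (exons 120–250 bp, introns 200–600 bp); half of the eligible
  genes carry a second isoform skipping one internal exon, which creates
  genuine alternative-splicing sites and same-isoform negatives.
* **Candidates** — 150 true circles (boundaries on annotated exon pairs of
  one isoform; backsplice orientation donor > acceptor on `+`, mirrored on
  `-`) and 150 artifacts: boundary-perturbed events (±1–15 nt), two-gene
  chimeras (annotated boundaries, no shared isoform — true negatives for
  the same-isoform factor and the ambiguity screen), and on-boundary false
  positives. BSJ events are unique, as in a real candidate table.
* **Factors** — drawn class-conditionally: Bernoulli flags with the success
  logit shifted by the configured effect, counts as Poisson (mean scaled by
  $e^\beta$) or Binomial (logit-shifted). Because these families have
  likelihood ratios linear in the factor value, the posterior log-odds of
  being a true circle is *exactly* the configured linear combination — the
  naive-Bayes construction. Structural flags (annotated boundaries, same
  isoform, AS) are instead governed by the placement probabilities, since
  they are realised through coordinates.
* **Depletion** — mock molecules are Poisson (mean 8 for artifacts, scaled
  by the read-count effect for true circles); treated counts are Binomial
  thinnings with retention 0.9 (true) vs 0.05 (artifact) for the RNase R
  group. The treated library total defaults to half the mock total: removing
  linear RNA shrinks the library, which is the mechanism that lifts the
  RPM ratio of surviving circles above 1. A Poisson/Binomial model was
  preferred to a negative binomial because the classifier consumes only
  counts and ratios; overdispersion would change power, not correctness.
* **Reads** — 100-nt junction-spanning substrings of the pseudo-sequence
  plus colinear genomic background reads in both libraries. Reads are
  error-free with uniform coverage; no quality scores, paired-end inserts,
  or rRNA are simulated. Passing tests therefore demonstrate correctness of
  the computation, not robustness to sequencing noise — on real data the
  identity threshold and the external aligner absorb that role.
* **Reproducibility** — each stage (reference, candidates, reads, replicate
  pairs, bootstraps) draws from its own stream derived from the master
  seed, so identical configurations give byte-identical outputs and stages
  can be regenerated independently.

`simulate_pair_counts()` replicates the depletion model at count level for
multi-pair designs once read-level quantification has been validated, and
`simulate_factor_logistic()` draws the eight factors independently with a
logistic outcome for GLM/RCVE calibration, where the generating
standardized effects must be known exactly (the structural generator
correlates the annotation flags by construction).

## Numerical choices and degenerate inputs

* Alignment ties are broken deterministically (diagonal move preferred,
  first-best cell in row-major order).
* Flanks and windows truncate at chromosome ends; truncated pseudo-sequences
  shift the junction index and warn.
* All-tied Wilcoxon input returns p = 0.5 and r = 0 with a warning; empty
  depletion classes are errors naming the class; degenerate label sets skip
  the test with a warning.
* `r2_all = 0` makes RCVE undefined: reported as NA with a warning rather
  than silently dropped.
* Constant factor columns are dropped from the GLM with a warning.
* A k-mer shortlist (k = 16) prunes read/BSJ alignment pairs in
  `count_bsj_reads_multi()`; it is purely an accelerator — the alignment
  rule makes every final decision — and can be disabled with
  `prefilter_k = 0`.

## Validation scale

The shipped test-suite exercises: exact agreement of the Fisher engine with
full hypergeometric enumeration (all 2×2 tables to n = 24, random tables to
n = 200), Wilcoxon exact p against complete rank-assignment enumeration, BH
against the step-up oracle (1,000 random vectors), the BSJ counter against
an independent full dynamic-programming oracle (≤ 1,000 reads × 50 BSJs),
the RCS counter against brute-force substring search on 1-kb flanks,
RCVE importance-ordering recovery on 20 replicate logistic pairs of
n = 5,000, end-to-end truth recovery (sensitivity/specificity ≥ 0.95 under
total retention/depletion at mean mock coverage 50), and type-I control of
the FDR pipeline on 500 null replicates. These sizes were chosen so the
whole suite runs in minutes on a laptop while keeping Monte-Carlo error
well below every asserted margin.

## Known limitations

* The ambiguity screen is a self-contained reimplementation of the two
  ambiguity classes (colinear explanation, multiple hits); it is exact at
  toy-genome scale but not a drop-in for a production screen against a
  full genome.
* RCS counting is exact-match based; diverged inverted repeats that still
  pair thermodynamically are not counted. The `min_len` default documents
  this approximation.
* The generator does not emulate sequencing error, fragment-length bias,
  rolling-circle multi-junction reads, or inter-candidate expression
  correlation.
* Tissue-specificity and splice-site strength are consumed, never computed.
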