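---
title: "Methods: angle-based scoring of noncoding variants in a decorrelated annotation space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: angle-based scoring of noncoding variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most disease-associated variants fall outside protein-coding exons, where
the only systematic functional evidence available genome-wide is epigenetic:
histone-modification and DNase peak calls per cell type, chromatin-state
segmentations, conservation elements, chromatin-interaction anchors. A
variant is therefore summarized as a binary annotation vector `x` of length
`d` (one column per (mark, cell type) pair plus a few global tracks; the
packaged reference layout, `epigenome_schema()`, has 639 columns: 5 marks x
127 epigenomes + 4 global columns). Two properties of this representation
drive every design choice in the package:

* the columns are strongly, positively correlated (the same enhancer is
  called in many related cell types), so raw annotation *counts* double-count
  evidence; and
* a high annotation load is itself evidence of function, so a plain outlier
  statistic that treats "overlaps everything" as expected-and-boring points
  the wrong way.

## The score

Let `mu` and `Sigma` be the mean and covariance of the annotation vectors of
a large set of background variants. `Sigma` is a noisy estimate, so we use
its rank-k truncation: with eigenpairs `(lambda_i, u_i)`,
`SigmaHat = sum_{i<=k} lambda_i u_i u_i'`, and its Moore-Penrose inverse
`SigmaHat^+ = sum_{i<=k} (1/lambda_i) u_i u_i'`. A diagonal weight matrix
`W` (identity in the unweighted analysis) encodes phenotype relevance per
annotation. The whitening map implemented in `whiten()` is

    z_i = lambda_i^{-1/2} u_i' W (x - mu),   i = 1..k,

so `||z||^2 = (x-mu)' W SigmaHat^+ W (x-mu)` — the reweighted Mahalanobis
length (`mahalanobis_score()`). We whiten through the eigendecomposition
rather than a triangular (Cholesky) factor because the rank-deficient
`SigmaHat^+` has no Cholesky factorization; the eigen route reproduces the
defining quadratic forms exactly, which the test suite verifies against an
explicitly formed dense pseudo-inverse to 1e-8.

The Mahalanobis length alone mis-handles saturation: with positively
correlated columns, vectors near full annotation load drift back toward the
leading eigendirection and *lose* significance (the package demonstrates
this with `simulate_correlated_annotations()`; significance of nested
overlap vectors rises with load, peaks, then collapses near 100/100). Since
high load should rank first, the score instead measures the angle to the
all-1 vector — the direction of maximal annotation load — in the whitened
space, scaled by the whitened lengths:

    score(x) = acos( <z_x, z_1> / (||z_x|| ||z_1||) ) / ( ||z_x|| ||z_1|| )

(`pines_score()`; radians — any fixed angular unit rescales all scores
equally and leaves empirical p-values unchanged). Smaller is better; the
all-1 vector attains the global minimum 0, for every admissible `W`, and
scaling `W -> cW` multiplies all scores by `1/c^2` without changing any
ranking or p-value.

Raw scores have no absolute unit, so significance is empirical: the add-one
left-tail quantile among background scores of the same variant class,
`p = (1 + #{b <= s}) / (N + 1)` (`empirical_pvalue()`). The add-one form
never returns 0 and is the standard convention for resampling nulls; ties
count toward the tail (conservative). Intronic and intergenic variants have
visibly different annotation architectures, so `mu`, the eigenpairs and the
background score distribution are all estimated per class (we also apply the
per-class choice to `mu`, for internal consistency). Variants in exons or
UTRs are never scored: the score is defined for noncoding variants only.

## Background variants

The empirical null comes from common variants purged of known signal by an
ordered filter cascade (`construct_background()`): drop ClinVar-style
Pathogenic / Likely pathogenic / Uncertain significance entries; drop
variants present in a GWAS-catalog-style table; drop variants overlapping
enhancer intervals; drop variants with allele frequency at or below 5% in
*any* continental ancestry column (rare sites can harbor penetrant
mutations), with missing frequencies treated as removals, not errors. Every
step logs its counts. The size of the surviving background set is data — a
property of the inputs, not a constant of the method.

## Weights

* **Unweighted**: `W = I`.
* **Manual** (`manual_weights()`): a constant on user-selected annotations,
  1 elsewhere. A constant of 1 recovers the unweighted analysis. The default
  of 4 reflects a power trade-off that `sweep_weight_constant()` makes
  explicit: as the constant grows from 0 to 20 on a block of correlated
  annotations, the p-value of a variant overlapping only that block falls
  monotonically while the p-value of a variant overlapping only the other
  annotations rises; 4 sits before the complementary power loss becomes
  severe. Constants below 1 (including 0) are accepted so the sweep itself
  is expressible.
* **Enrichment** (`enrichment_weights()`): given GWAS lead SNPs, draw 1000
  variant sets from a background universe matched to the leads' allele
  frequencies (fixed-width bins, default width 0.05 on the reference AF
  column — only AF is matched; matching further covariates such as TSS
  distance is a possible refinement we do not attempt), compare per-column
  overlap counts, and set the weight to `-log10` of the add-one upper-tail
  enrichment p-value, floored at 0.1 so that no annotation is ever excluded
  from the model. The lead SNPs are used only in aggregate and are never
  themselves scored. Global (non-cell-type) columns are weighted by the same
  procedure. Draws within each AF bin are made over a canonically ordered
  candidate pool, so results are reproducible under a seed and independent
  of the universe's row order.

## Cell-type-specific profiles

Scoring the same variants twice — unweighted and weighted — places each
variant in a significance plane `(u, w) = (-log10 p_unweighted,
-log10 p_weighted)`; the weighted axis uses background scores recomputed
under the same `W`, which is what makes the two axes comparable. The signed
angle to the main diagonal, `atan2(w, u) - pi/4` (`diagonal_angle()`),
isolates variants whose evidence concentrates in the up-weighted
annotations. We read the plane in significance units (not raw scores), and
define the angle sign so that positive means weighted-more-significant;
both are package conventions, stated here because the plane could also be
drawn in raw-score units. Query angles get add-one upper-tail empirical
p-values against background angles, flagged at 0.05 by default
(`detect_specific_variants()`).

## Simulators, and what they do not emulate

`simulate_celltype_specific()` reproduces the standard study design for the
specificity analysis: 5000 background variants with 100 independent
Bernoulli(0.3) annotations, plus 100 specific variants with 10 "hot"
annotations at Bernoulli(0.9) and the remaining 90 at Bernoulli(0.1). These
defaults are the stated conditions of that design, not tuning knobs.
`simulate_blocks()` produces ten blocks of ten annotations with exchangeable
within-block correlation via a Gaussian copula thresholded at the Bernoulli
quantile; the latent correlation is calibrated by root-finding on the
bivariate-normal rectangle probability so that the *binary* correlation
matches the requested value (default 0.7 — the block correlation magnitude
is our choice; marginal p = 0.3). `simulate_correlated_annotations()` draws
20,000 vectors over 100 annotations from a random factor-model correlation
matrix with one dominant positive factor (marginal p fixed at 0.3, matching
the background marginal used elsewhere). `generate_fixture_tracks()` writes
a deterministic on-disk toy bundle (BED/VCF/GFF3/TSV) with a brute-force
ground-truth overlap matrix and a filter cascade whose survivor counts
(10 -> 8 -> 7 -> 6 -> 4) are enumerable by hand.

None of these emulate real marginal peak frequencies, genome-wide linkage
disequilibrium, or the actual cross-cell-type correlation structure of
reference epigenomes; passing simulation checks demonstrates the statistical
machinery, not performance on real epigenomes.

## Numerical and interface choices

* **Coordinates.** BED input is 0-based half-open; variant positions are
  1-based (VCF convention). A 1-based position `p` overlaps `[start, end)`
  iff `p-1` lies in it, i.e. `p` in `[start+1, end]`; a variant at `end+1`
  never overlaps. Indels are annotated by their leftmost position (no
  span rule is imposed). Chromosome names are normalized to one dialect
  (default: strip `chr`).
* **Missing data.** A schema column without a track is missing, not zero.
  Missing entries are imputed to the background column mean at scoring time,
  contributing zero to `x - mu` — a neutral choice that distinguishes
  "absent" from "unknown".
* **Rank.** Default `k = 30` as a reproducible stand-in for scree-plot
  inspection, with a `variance_target` escape hatch (smallest rank reaching
  a variance-explained fraction). Eigenvalues below `1e-10 * lambda_1` are
  dropped before inversion.
* **Degeneracies.** Cosines are clipped to `[-1, 1]` before `acos`; a
  zero-length whitened projection has no angle — such variants are reported
  with p = 1 and flagged rather than scored.
* **Problem sizes in the checks.** The shipped verification scripts use the
  simulation designs at their stated sizes (5000+100, 10 x 10 blocks at
  n = 10,000, 20,000 x 100) and 100 random oracle instances at n <= 200,
  d <= 20; all run in seconds on one CPU.

## Known limitations

* Query variants are out-of-sample with respect to the background
  eigenspace, while the background's own significance distribution is
  in-sample. With moderate background sizes this inflates the diagonal-angle
  flag rate under the null to roughly twice the nominal threshold (it
  shrinks as the background grows). The background-in-sample construction is
  intrinsic to the procedure; treat the angle flag as a screen, not a
  calibrated test.
* Annotations are strictly binary; signal-valued tracks must be
  pre-thresholded (conservation is consumed as pre-called elements).
* Enrichment weighting matches allele frequency only, and does no linkage
  expansion of the lead SNPs.
* The angle detector compares profiles to one weighted axis at a time; it
  does not assign variants to named tissues.
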