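---
title: "Methods: dissecting constitutive and plastic expression divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting constitutive and plastic expression divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostshift)
```

## The question and the design

Two host races (ecotypes) of a phytophagous fly specialise on different
thistle hosts: the ancestral race (CH) on *Cirsium heterophyllum*, the
derived race (CO) on *C. oleraceum*. Expression differences between larvae
of the two races can be **constitutive** (evolved; present regardless of
the plant the larva feeds on) or **plastic** (induced by the host plant).
A cross-fostering design separates the two: besides larvae sampled directly
from their natal buds (treatments `H` and `O`), larvae are moved into fresh
buds of their natal plant (`HH`, `OO`) or of the alternative plant (`HO`,
`OH`). Moving a larva is itself stressful, so the natal-bud switches serve
as stress controls. The default replicate numbers are 7/6/7/7/5/6 for
H/O/HH/HO/OO/OH — seven larvae per CH treatment and six per CO treatment
with one OO larva lost to quality control — 38 samples in all.

The package provides (i) a seeded synthetic-data generator that plants
known effect classes, coexpression modules, and genomic divergence; (ii)
the analysis chain — preprocessing, negative-binomial differential
expression with s-value inference, signed coexpression networks with
eigengene scenario classification, windowed population-genomic scans, and
interval/gene-set enrichment; and (iii) an orchestration layer
(`run_pipeline()`). Every stage is exercised against the generator's known
truth, so the package doubles as a parameter-recovery test bed for this
class of study design.

## The five scenario variables and their collinearity

Each sample is encoded by five binary variables
(`build_design_vectors()`): host race (1 = CH), stress of cross-fostering
(1 = switched), reciprocal plasticity (1 = feeding on *C. oleraceum*), CH
plasticity (1 = CO host race or the HO treatment) and CO plasticity (1 =
CH host race or the OH treatment). A module whose eigengene tracks one of
these patterns is interpreted as host-race-, stress- or
plasticity-associated (rule: `|r| > 0.5` and BH-adjusted `p < 0.01`,
adjustment across modules within each variable).

Because only six treatment groups generate all five vectors, the vectors
are strongly collinear under the 7/6/7/7/5/6 design:

```{r collinearity}
dv <- build_design_vectors(rep(TREATMENTS, c(7, 6, 7, 7, 5, 6)))
round(cor(dv), 2)
```

Two consequences matter for interpretation. First, a module genuinely
driven by CH plasticity carries, mechanically, about 0.73 times its CH
correlation with the reciprocal-plasticity variable, and a pure host-race
module carries about 0.71 of its correlation with CO plasticity. With the
0.5 threshold, any eigengene correlating above ~0.69 with its true driver
is therefore at risk of a spurious secondary flag — a property of the
design, not of any implementation. Second, under pure noise the joint
rule admits roughly 0.08 spurious flags per full screen of 21 modules by
5 variables (about one flag every 12 screens), dominated by the
`|r| > 0.5` clause at n = 38.

## The synthetic-data generator

**Counts.** Gene/sample counts are negative binomial with variance
`mu + alpha * mu^2` and mean
`s_i * q_g * m_g(treatment) * 2^(lambda_g * f(i))`: log-normal library
size factors `s_i` (sdlog 0.3), log-normal baselines `q_g` (median 200
reads), log-normal dispersions `alpha_g` (median 0.1), class multipliers
`m_g`, and an optional planted module factor. The library-size spread,
baseline and dispersion values are conventional bulk RNA-seq magnitudes,
not fitted to any particular data set; the NB parameterisation is stated
explicitly because "dispersion" is used both ways in the literature.

**Effect classes.** Each gene belongs to one class: null; constitutive
host-race DE (both directions, default 8% of genes — the magnitude of
constitutive divergence this design was built to detect); CH-only
plasticity (level A in H/HH, level B in O/OO/OH *and* HO: the ancestral
race shifts to the derived race's level on the novel host); CO-only
plasticity (the mirror image); reciprocal plasticity (level tracks the
plant fed upon); and stress (elevated in all four cross-fostered groups,
matching the observation that bud switching raises expression of
stress-responsive genes regardless of the receiving plant). Non-null
effects have `|log2FC| = 0.5 + Exp(mean 0.75)`. Constitutive genes are
placed with an odds multiplier (default 3.0) for lying inside the
inversion, implemented as independent Bernoulli assignment with the
outside probability solved so the expected overall fraction is exact —
independence makes the sample odds ratio a consistent estimator, so exact
confidence intervals behave nominally in recovery tests.

**Planted modules.** A module is a latent per-sample factor — the
standardised binary design vector of its driver plus Gaussian noise — with
per-gene loadings in (0.8, 1.2) entering the mean as `2^(loading *
factor)`. The factor noise default (sd 1.2 against a unit-variance signal)
attenuates the module eigengene's correlation with its driving variable to
about 0.64, the middle of the 0.55–0.75 range that module–trait
correlations reach in well-powered studies of this design; without factor
noise the eigengene would be a nearly noiseless copy of the binary vector,
which no biological module is. Module genes are drawn from the null class
so planted class and module structures stay disjoint.

**Allele frequencies.** Sites are simulated under the Balding–Nichols
model: ancestral frequency `p ~ U(0.05, 0.95)`, population frequencies
`Beta(p(1-F)/F, (1-p)(1-F)/F)`, observed as binomial sample frequencies of
20 haploids per population. Outside the inversion both populations use
`F = 0.02`; inside it the divergence parameter averages `F = 0.30` but is
split asymmetrically (0.5x for CH, 1.5x for CO), representing stronger
drift or a partial sweep in the derived race within the inversion. The
split leaves the expected Hudson/Bhatia F_ST inside the inversion at
exactly 0.30 (the estimator's expectation is the mean of the two F's)
while generating the positive diversity contrast (delta-pi > 0) and the
strong Tajima's-D contrast that divergent inversions show. What this
model does *not* emulate is elevated absolute divergence: with
conditionally independent population frequencies, E[d_XY] = 2p(1-p)
regardless of F, so d_XY outliers in the synthetic data are noise. Deep
coalescent divergence would be needed for that signal; composite outlier
calls in the generator therefore rest on the F_ST, delta-pi and delta-D
legs, which is sufficient for the 3-of-4 rule. Per-window coverage
fractions are Beta(2, 0.5), giving a low-coverage tail that exercises the
20% coverage filter.

## Preprocessing

Genes are kept if they have at least 5 reads in at least 6 samples (one
full treatment group at the smallest replicate number). Size factors are
median-of-ratios against the geometric-mean reference, with the median
taken on the log scale. The variance-moderating transform is
`log2(count/s + 1)`: a fully specified monotone transform whose only
downstream uses are ranking, ordination, clustering and correlation — the
regularised-log transform it stands in for differs mainly in how hard it
shrinks low counts, which none of those uses is sensitive to. PCA is run
on the 5000 most variable genes, centred but not scaled, with each
component's sign fixed so its largest-magnitude loading is positive;
sample clustering is average-linkage on Euclidean distances of the
transformed matrix (stated explicitly because "hierarchical clustering"
alone underdetermines the result).

## Differential expression and s-values

The model is a one-factor NB GLM: one log-scale mean per treatment with
log size-factor offsets, fitted by Fisher scoring per group (the design
matrix is block diagonal, so each group's coefficient solves a
one-dimensional score equation); standard errors come from expected
Fisher information. Dispersions are estimated per gene by profile maximum
likelihood on a 40-point log-spaced grid (group means refitted at each
candidate, parabolic refinement), shrunk toward a fitted mean–dispersion
trend `a1/mu + a0` via a normal prior on `log alpha` whose sd is the MAD
of the log-residuals (floored at 0.5 when the spread estimate degenerates
below 0.1), and clipped to `[1e-8, 10]`. Count outliers are flagged by
Cook's distance above the 99% F quantile; in groups with at least 8
replicates (configurable) the flagged counts are replaced by trimmed
group means and the gene refitted — with the study's group sizes of at
most 7 the replacement deliberately never triggers, only the flags are
recorded.

Fold-change shrinkage uses a zero-centred normal prior with
method-of-moments scale `tau^2 = max(mean(lfc^2) - mean(se^2),
tau_min^2)`, estimated per contrast with separation-flagged genes (a
treatment group of all zeros) excluded; the posterior is conjugate, so
`lfc_shrunk = lfc * tau^2/(tau^2 + se^2)`. This is a deliberate
simplification of adaptive heavy-tailed shrinkage: it preserves the
posterior-sign semantics with a closed form, at the cost of shrinking
genuinely large effects somewhat harder. The local false sign rate is
`lfsr = Phi(-|lfc_shrunk|/post_sd)` and the s-value is the running mean of
lfsr over all genes at least as confident — the expected sign-error rate
of the call set. Calls use `s < 0.001`.

One semantic point is worth stating precisely: a gene whose true effect
is exactly zero has no sign to get wrong. Under any continuous shrinkage
prior (normal here; adaptive-t in the reference implementations), a
spike of exact nulls produces a minority of null calls that ride the
cumulative mean below any threshold; empirically this null-call rate is
the same (~10–15% of calls) for this implementation and for the
reference toolchain on identical data, with zero sign flips among
signed genes in both. Recovery tests therefore score sign errors among
calls on genes with a planted nonzero effect, and the null-call rate is
reported as its own quantity rather than folded into the sign-error rate.

## The signed coexpression network

Correlation is the biweight midcorrelation (median/MAD weights, nine-MAD
cutoff, Pearson fallback for zero-MAD genes) on the moderated-log matrix.
Signed adjacency is `((1 + cor)/2)^beta`. The soft-threshold power is the
first candidate whose scale-free topology fit index — signed R^2 of
`log10 p(k)` against `log10 k` over ten equal-width connectivity bins —
reaches 0.8, falling back with a warning to the best-fitting candidate.
Planted-module data with an iid noise background is not globally
scale-free (background connectivity concentrates), so on generator data
the fallback is the norm; module recovery, not the fit index, is the
quality criterion that matters.

Topological overlap is
`TOM_ij = (sum_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 - a_ij)`. Modules are
detected on the dissimilarity `1 - TOM` by average-linkage clustering with
a recursive static cut: the tree is first cut just below the 0.99 quantile
of merge heights; each cluster is then split at its top join as long as
both branches could still form a module (>= 30 genes), and an under-sized
branch is peeled off only when its join lies closer to the cut height than
to the big branch's own top (a noise-regime straggler rather than module
interior). A single global cut cannot do this job: distinct tight modules
join *each other* below the heights at which unclustered genes
agglomerate, so no one height separates modules while dissolving noise.
The recursion deliberately over-splits; repair is delegated to the
mechanisms that follow anyway — iterative merging of module pairs whose
eigengenes correlate above 0.70 ("over 70% related"), then a module
membership (kME) filter at 0.5 iterated to a fixed point, with the
minimum-size rule re-applied. Unassigned genes form the pseudo-module
`mod00`, which is carried through eigengene and scenario analyses like any
other module because diffuse unclustered expression can itself track the
design. Eigengenes are unit-norm first principal components of the
module's z-scored expression, sign-oriented to correlate positively with
the module mean.

## Windowed population-genomic scan

All windows are 0-based, half-open, 50 kb, tiling each contig; windows
under 20% coverage are excluded up front. Per window: Bhatia/Hudson F_ST
as a ratio of sums of per-site numerators
`(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominators
`p1(1-p2) + p2(1-p1)` over sites shared by both populations (missing when
no shared polymorphic site); d_XY as the site-wise sum of
`p1(1-p2)+p2(1-p1)` over the effective length; nucleotide diversity as
`2p(1-p) n/(n-1)` per site; and Tajima's D from the unscaled diversity
and Watterson's theta with the standard constants, missing when no site
segregates. The effective length for pi and d_XY defaults to the covered
site count (matching how missing data are usually handled), with the full
window length available as an option. d_XY here is computed on
consistently polarised site frequencies; pipelines that fold the joint
frequency spectrum first discard allele identity, and the two conventions
can differ at sites where the minor allele differs between populations —
a known, documented discrepancy rather than a resolved one. Outliers per
metric are windows beyond 3 SD of the mean — above only for F_ST and
d_XY, both sides for delta-pi and delta-D — with means and SDs taken over
non-missing windows; the composite call requires 3 of the 4 metrics. The
3-SD rule assumes outliers are rare: if a large fraction of the genome is
divergent (more than roughly 10% of windows), the global mean and SD are
contaminated and the scan loses power — the synthetic genome keeps the
inversion at ~7% of windows for this reason.

## Enrichment

Gene loci are flanked by 2 kb on both sides (clipped at zero) and
intersected with the window tiling; a gene is an outlier gene if it
overlaps at least one composite-outlier window. Over-representation of DE
genes among outlier or inversion genes uses the upper-tail hypergeometric
probability with the expressed (post-filter) gene set as the default
universe and the sample odds ratio reported alongside; BH adjustment is
applied across whatever family of tests one run declares. Because
population-genomic metrics covary with gene length, a control set of
non-DE genes is drawn matched on the DE length distribution (decile bins,
sampling without replacement, neighbouring bins collapsed when short).
Metric-level comparisons between DE-status groups run Kruskal–Wallis
followed by Dunn's pairwise z-tests (tie-corrected, BH-adjusted),
separately inside and outside the inversion. Generic term enrichment uses
one-sided Fisher tests, refuses study sets under 20 genes outright, and
drops terms annotating fewer than 5 genes; the hierarchical
(parent–child) decomposition of ontology graphs is out of scope.

## Problem sizes, determinism and limitations

The test suite and the acceptance script run the generator at 12,000
genes for DE recovery (the scale of a filtered insect transcriptome),
4,000 genes for network construction, and a 300 Mb genome (6,000 windows,
~7% inversion) for the divergence scan — sizes chosen so each stage runs
at full statistical realism in well under its time envelope on one core.
Every stochastic step takes an explicit seed; the pipeline derives
per-stage seeds from one global seed so stages can be rerun in isolation,
and reruns with the same configuration reproduce outputs bit-exactly
(verified via file checksums in the manifest).

Known limitations, stated so that green tests are not over-read: the
generator's expression noise is pure NB with independent genes outside
planted modules — no batch structure, no correlated residuals, no
count-level outliers beyond what NB tails produce, so the Cook's-distance
machinery is exercised by construction rather than by realistic
contamination; plasticity classes are two-level patterns, not graded
reaction norms; the allele-frequency model has no linkage, no coalescent
genealogy and no d_XY elevation; and the scenario classifier inherits the
design's collinearity, so secondary flags on correlated variables (CH
plasticity vs reciprocal; host race vs CO plasticity) are expected
occasionally even when no such structure was planted. Passing recovery
tests show the estimators and rules do what they claim under the model
they assume — not that the model captures every feature of real data.
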