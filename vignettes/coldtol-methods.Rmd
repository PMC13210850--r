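---
title: "Methods: composite cold-tolerance scoring and gene-family expression analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite cold-tolerance scoring and gene-family expression analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldtol)
library(dplyr)
```

`coldtol` packages the quantitative backbone of a cold-tolerance screen of a
transcription-factor gene family in tetraploid potato: scoring cultivars from
physiological panels, profiling a gene family's expression across tissues and
a cold time course, validating candidates by qPCR, scanning promoters for
regulatory elements, and characterizing the duplication history of the family.
Every stage is paired with a seeded generator that produces inputs with
embedded ground truth, so each method can be exercised and falsified without
the original study data. This vignette explains the models, the tunable
parameters and the design decisions; it states no number that the package's
tests or acceptance script do not themselves compute.

## The comprehensive cold-tolerance score (D value)

Cultivars are measured for five physiological indicators under cold stress:
superoxide dismutase (SOD, U/g) and peroxidase (POD, U/g) activities, soluble
sugar (mg/g), soluble protein (mg/g) — all rising with tolerance — and
malondialdehyde (MDA, nmol/g), a lipid-peroxidation marker that falls with
tolerance. The composite evaluation proceeds in four steps:

1. **Membership standardization.** Each indicator is mapped through the
   membership function U(X) = (X − X_min)/(X_max − X_min), so every variable
   spans [0, 1] across cultivars.
2. **Composite indicators.** Covariance PCA of the standardized matrix turns
   the correlated indicators into orthogonal composite indicators. The
   contribution rate of component j is p_j = λ_j / Σλ, and the shortest
   prefix of components whose cumulative contribution strictly exceeds 85%
   is retained.
3. **Weights.** Retained components are weighted by their renormalized
   contribution rates, W_j = p_j / Σ_retained p_j.
4. **D value.** Component scores are themselves membership-standardized
   across cultivars and combined as D = Σ U_j W_j, giving D ∈ [0, 1].
   Cultivars are classed strong (D ≥ 0.70), moderate (0.40 ≤ D < 0.70) or
   weak (D < 0.40), and Ward/Euclidean clustering on D (k = 3) provides a
   model-free cross-check of the classes.

Design decisions worth knowing:

* **Aggregation.** Measurements arrive per cultivar × indicator × timepoint
  × replicate; the matrix entering PCA needs one value per cultivar and
  indicator. The default collapses replicates to means and averages over the
  stress timepoints, excluding the unstressed day-0 baseline — stress
  response, not baseline physiology, is what separates tolerant cultivars.
  Single-day and stress/baseline-ratio aggregations are available.
* **PCA flavor.** PCA is run on the covariance of the membership-standardized
  columns, not on z-scores: the membership function is the standardization
  the procedure prescribes, and columns already share the [0, 1] scale.
* **Component orientation.** Eigenvector signs are arbitrary but propagate
  into U and D. Each component is oriented so that its direction-weighted
  loading sum (benefit indicators +, MDA −) is non-negative, which pins
  "larger D = more tolerant". A sum of exactly zero leaves the component
  as returned by the decomposition.
* **MDA handling.** MDA is not inverted before standardization; its cost
  direction enters only through the orientation rule. The membership
  function is applied uniformly to all five indicators.
* **Class boundaries.** The printed class bands (0–0.39, 0.4–0.69, 0.7–1)
  leave (0.39, 0.40) and (0.69, 0.70) unassigned; the package closes them
  with half-open intervals [0, 0.40), [0.40, 0.70), [0.70, 1].
* **Degenerate inputs.** A constant indicator column, or a constant retained
  component score, makes the membership function undefined and is rejected
  with an error naming the variable. Ties in D during clustering fall into
  one group deterministically via `stats::hclust` (Ward.D2).

The physiology generator draws a latent tolerance θ ~ U(0, 1) per cultivar
and makes indicator means logistic in θ, scaled by a time ramp that is zero
at day 0: benefit indicators rise with θ, MDA falls. Replicate noise is
multiplicative log-normal parameterized by its coefficient of variation, so
`noise_cv = 0` returns exact means and assay error stays scale-proportional,
as enzyme-activity and metabolite assays behave. Baselines (SOD 250 U/g,
POD 300 U/g, sugar 12 mg/g, protein 8 mg/g, MDA 6 nmol/g) are round numbers
on realistic scales; the source study reports no raw indicator
distributions, so these are stated assumptions, not reproductions. Under
the default study design (14 cultivars, days 0/1/3/5/7, five replicates,
CV 0.1) the tests require Spearman agreement between D and θ of at least
0.9 in ≥95% of 200 seeded replicates, and exact rank agreement when noise
is switched off. That validates the scoring chain, not the biology: real
cultivar panels have correlated assay errors and indicator-specific
nonlinearities the generator does not emulate.

## Tissue specificity (τ) and the cold-induction screen

The τ index of a gene with per-tissue abundances x_i is
τ = Σ(1 − x_i/max x)/(n − 1): 0 for uniform expression, 1 for single-tissue
expression, undefined for an all-zero gene. Genes are classed specific
(τ > 0.8, strict, with the argmax tissue), ubiquitous (τ < 0.2),
not expressed (silent everywhere) or intermediate; τ = 0.8 exactly is
intermediate. τ is computed on linear abundances with replicates collapsed
to means, and is invariant to rescaling a gene's row — so TPM-like units,
which remove library-size effects, are appropriate inputs. The "expressed"
call behind the expressed-fraction summary uses a default threshold of
zero (any detectable signal); the threshold is exposed because atlas
studies sometimes require a minimum TPM.

The cold screen compares the 12 h peak to the 0 h baseline per gene:
log2FC on pseudocounted means (pseudocount 1 on a TPM-like scale,
configurable), a two-sided two-sample t test on log2(x + 1) replicate
values, and Benjamini–Hochberg adjustment across genes. A gene is induced
when log2FC ≥ 1 and FDR < 0.05, and strongly induced when log2FC ≥ 2. Two
choices deserve comment:

* **Pooled variance by default.** Under multiplicative noise the log-scale
  variance is the same at both timepoints, so pooling is the correct model;
  with the typical three replicates the Welch–Satterthwaite approximation
  collapses to ~2 degrees of freedom and costs most of the power after FDR
  adjustment (planted-gene sensitivity drops from 1.0 to roughly 0.88 in
  the package's own recovery simulations). `test = "welch"` restores the
  unequal-variance test when heteroscedasticity is a genuine concern, and
  externally computed p-values (e.g. from a count-model DE tool) can be
  supplied instead.
* **Degenerate replicates.** If both groups are constant the p-value is 1
  when the means agree and effectively 0 when they differ, which keeps the
  noiseless planted-truth limits exact.

The time-course generator plants transient induction — the 12 h mean sits
exactly `induction_log2fc` doublings above baseline *on the pseudocounted
scale the screen uses*, and the 24 h mean lies between baseline and peak —
so a noiseless run recovers the planted effect size exactly, and the
recovery tests (8 planted genes among 191, effect 2, CV 0.1, n = 3, 100
seeds) demand sensitivity ≥ 0.95 with the null false-positive fraction
within Monte-Carlo error of the FDR target. The generator draws genes
independently; real RNA-seq has correlated genes, dispersion trends and
count noise, so passing these tests demonstrates the screen's arithmetic
and calibration, not robustness to those features.

## qPCR relative quantification

Relative expression uses the 2^−ΔΔCt method with amplification efficiency
fixed at 2: technical replicates are averaged on the Ct scale; per
biological replicate ΔCt = Ct_target − Ct_reference within the same sample;
ΔΔCt subtracts the mean ΔCt of the calibrator condition of the same
cultivar and gene, which the package takes to be the 0 h sample — the
conventional calibrator for a time course, since the method's description
leaves it implicit. The mean calibrator ΔΔCt is zero by construction, and
ΔΔCt is invariant to any per-sample additive Ct shift (e.g. input amount),
which the tests assert. Fold statistics are summarized on the linear scale
by default; a geometric-mean option (equivalent to averaging ΔΔCt) is
exposed, because the ratio of printed fold means and the fold of mean ΔΔCt
differ under noise — both readings of a published between-cultivar ratio
are therefore available.

Group comparisons use the Kruskal–Wallis test with tie correction, Dunn
z-statistics on mean ranks with Bonferroni multiplication by the number of
pairs, and an insert-and-absorb compact letter display (groups sharing a
letter are not significantly different). With three replicates per group
the χ² approximation to the Kruskal–Wallis statistic is poor, so for total
n ≤ 10 the omnibus p is computed by exact enumeration of all rank
assignments; the tests check this against an independently coded
permutation oracle. All-identical observations short-circuit to p = 1 and
a single letter.

## Promoter cis-element scanning

Promoters (2000 bp upstream windows by default; a helper slices them from a
genome given gene coordinates and strand, clipping at contig edges) are
scanned against an explicit dictionary of IUPAC patterns, each assigned to
one of five functional classes: hormone, stress, light, development, other.
Matching counts every occurrence on both strands — minus-strand hits are
matches of the reverse-complement pattern on the forward sequence, reported
at forward-strand 0-based positions; overlapping occurrences all count and
palindromes count once per strand. N in a subject sequence never matches.
These conventions make the scan deterministic and checkable against a naive
sliding-window matcher, which the tests do on random 2-kb promoters.

The dictionary ships as an editable YAML starter of 30 canonical elements
(ABRE and its variants, G-box, LTR, MBS, W-box, and so on) because public
motif-database definitions are versioned and unverifiable; reproducing any
published element total therefore depends on dictionary fidelity, and the
dictionary is data, not code. Summaries report per-element and per-class
totals, the most abundant elements excluding "other", and the fraction of
promoters containing hormone-, stress- and light-responsive elements. The
joint statistic defaults to requiring all three classes simultaneously —
the stricter reading of such statements — with `joint_mode = "any"`
available for the union reading.

The promoter generator inserts concrete realizations of requested patterns
at recorded non-overlapping positions (reverse-complemented for minus-strand
plants) into i.i.d. background at a target GC content, and can
rejection-sample the background until no dictionary pattern occurs outside
the plants, which gives scans with exactly known expected output.

## Ka/Ks estimation and duplication classes

The estimator is Nei–Gojobori (1986). Per codon, each position contributes
a synonymous-site fraction equal to the share of its single-base mutations
that preserve the amino acid, with mutations into stop codons excluded from
the denominator; sites are averaged over the two sequences. Between
differing codons, synonymous and nonsynonymous differences are averaged
over all minimal mutational pathways that avoid stop codons (falling back
to all pathways in the rare case none is stop-free). The proportions are
corrected with the one-parameter distance d = −(3/4)·ln(1 − 4p/3). The
ratio is undefined when Ks = 0 (identical or purely nonsynonymously
diverged sequences) or when either proportion reaches the p ≥ 3/4
saturation of the correction — mirroring how published pipelines report
unobtainable pairs. NG86 was chosen because the study names only a toolbox,
and NG86 is the classical estimator whose every intermediate (sites,
pathway counts, correction) can be verified by enumeration; published mean
Ka/Ks values from outsourced pipelines are not reproduction targets.

The codon simulator evolves each descendant from a uniform-random ancestral
sense-codon sequence under a continuous-time process with equal base
exchangeabilities, nonsynonymous rates scaled by ω and stop codons
disallowed, run by Gillespie simulation so realized substitution counts are
recorded. The overall rate is calibrated so the expected number of
substitutions per codon equals `t`. Because the only asymmetry in the
process is the ω scaling, the true Ka/Ks equals ω, and the tests require
the mean estimate over 200 pairs of 1000 codons at t = 0.2 to fall within
±0.05 of ω for ω ∈ {0.3, 1.0}. Codons with no allowed moves under ω = 0
(Met, Trp) simply never substitute.

Duplication classes are assigned from a gene map (order indices along
chromosomes) and a homolog pair list: pairs anchoring a collinear block are
WGD/segmental (block precedence); remaining same-chromosome pairs within 10
intervening genes (configurable; published tandem criteria vary) are
tandem; the rest are dispersed. Collinear blocks come from a deliberately
simple greedy chainer — per chromosome pair, repeatedly extract the longest
strictly monotone anchor chain (either orientation, rising preferred on
ties) with order-index gaps ≤ 25 on both chromosomes, keeping chains of ≥ 5
anchors. This is a deterministic stand-in in the spirit of anchor-chaining
synteny tools, not a re-implementation of any of them: it ignores e-values,
weights and interleaved blocks. Its chain lengths are tested against
exhaustive subset search on small anchor sets, and the map generator places
tandem arrays, collinear runs and dispersed decoys so that planted class
tallies are recovered exactly — decoys are rejection-sampled so they can
neither extend a planted block nor form one among themselves under the
default chaining parameters.

## Problem sizes and reproducibility

All generators take an explicit integer seed and restore the caller's RNG
state, so results are reproducible and no global state is touched. The
recovery studies run at the design sizes described above (200 scoring
replicates; 100 screen seeds on 191 genes; 200 codon pairs of 1000 codons
per ω; 2-kb promoters against the 30-entry dictionary), which the package
adopts as its standard evidence set; `scripts/acceptance.R` re-runs them
end to end from a single seed and writes the resulting quantities as JSON.

## Known limitations

* The generators emulate design and effect structure, not full biological
  realism: no gene–gene correlation, no tetraploid allele dosage, no
  count-level RNA-seq noise, no indicator cross-correlation beyond the
  shared latent tolerance.
* The scoring pipeline assumes one value per cultivar × indicator after
  aggregation; unbalanced or missing cells must be resolved upstream.
* The promoter dictionary is a starter set; element totals depend on it.
* The collinearity chainer is a simplification (see above) and codon
  alignments must arrive gapless and in frame — alignment construction is
  out of scope.
* NG86 with equal exchangeabilities ignores transition/transversion and
  codon-usage bias; estimates on real, biased sequences inherit NG86's
  known behavior there.
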