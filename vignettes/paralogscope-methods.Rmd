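---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the estimators
and their assumptions, every tunable constant with its default and the
reason for it, what the simulators do and do not emulate, and the places
where the design was genuinely open and a choice had to be made. It states
no empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The structural arm

### From sequences to a codon alignment

Each gene pair is processed as: translate both coding sequences with the
standard genetic code (a single terminal stop is stripped; an internal stop
is an error — such a sequence is a pseudogene or out of frame and Ka/Ks is
meaningless for it); align the two proteins globally; project the alignment
back onto the codons. Aligning at the protein level prevents frame-shifting
gap placements. Columns with a gap in either row are dropped, so the codon
alignment is gap-free and every downstream count is per aligned codon
column.

The protein aligner is Needleman–Wunsch with BLOSUM62 and affine gap
penalties (open 10, extend 1, half-bit units), provided by Biostrings. Only
two sequences are ever aligned, so an exact pairwise algorithm replaces a
progressive multiple aligner with no loss. Biostrings returns one optimal
traceback deterministically; the test suite verifies optimality against
brute-force enumeration on small cases rather than pinning one canonical
traceback.

### Site and difference counting

For a codon position, consider its three single-nucleotide changes. Changes
that create a stop codon are excluded from both numerator and denominator,
so each position always contributes exactly one site and S + N = 3 × (codon
columns) holds for every estimator (tested to 1e-6). The synonymous
fraction of a position is the rate-weighted fraction of its non-stop
changes that preserve the amino acid:

* NG86: all changes weighted equally;
* MYN: a change to base *y* is weighted π<sub>y</sub>, times κ<sub>R</sub>
  if it is an A↔G transition or κ<sub>Y</sub> if C↔T.

Site counts are averaged over the two sequences.

Observed differences between two codons that differ at *d* positions are
resolved by pathway averaging: all *d*! orders of applying the changes are
enumerated, orders that pass through a stop codon are discarded, and each
surviving pathway contributes its per-step classification — synonymous or
nonsynonymous, crossed with A↔G transition, C↔T transition, or transversion
— with equal weight. If every pathway is blocked by a stop (rare), all
pathways are used. Equal pathway weighting is the classical convention; the
estimator is validated against an independent exhaustive-path oracle on
1000 random short pairs, and against NG86 in the unbiased limit (below).

### Distances

NG86 corrects p-distances with the Jukes–Cantor formula
−(3/4)ln(1 − 4p/3). MYN corrects the class-resolved proportions with the
TN93 distance: with base frequencies π (pooled over both sequences),
π<sub>R</sub> = π<sub>A</sub> + π<sub>G</sub>,
π<sub>Y</sub> = π<sub>C</sub> + π<sub>T</sub>, and observed proportions P1
(A↔G), P2 (C↔T), Q (transversions),

d = k1·a1 + k2·a2 + k3·b,

where a1, a2, b are the corrected transition and transversion terms and k1,
k2, k3 the standard frequency coefficients. Ks applies this to the
synonymous-class proportions over S; Ka to the nonsynonymous class over N.
Under uniform frequencies and equal rates the formula collapses to
Jukes–Cantor (tested to 1e-9 against the closed form).

γ-MYN replaces every −ln *x* by α(*x*<sup>−1/α</sup> − 1), the
gamma-rates analogue with shape α; as α → ∞ it reduces to MYN (tested at
α = 10⁶ to 1e-4), and for fixed data smaller α never decreases the distance
(tested over a shape grid). The default shape is α = 1 and it is exposed on
every interface, because no principled value is available for an arbitrary
data set; users fitting rate heterogeneity elsewhere should pass their own
shape.

κ<sub>R</sub> and κ<sub>Y</sub> are estimated from all aligned nucleotide
positions via the TN93 relations κ<sub>R</sub> = (a1 − π<sub>Y</sub>b) /
(π<sub>R</sub>b) and symmetrically for κ<sub>Y</sub>. Numerical guards:
identical sequences fall back to κ = 1 (no information); when transitions
are observed but no transversions, b would be 0 and the ratios undefined, so
half a transversion count is added (a continuity correction that keeps the
ratios finite and large, as the data indicate); frequencies and κ are
floored at 1e-4. Parameter recovery is tested by simulation (κ = 4 on
10,000 codons recovered within 15% under neutral evolution — under strong
selection the ratio is biased upward because transversions are more often
nonsynonymous, which is a property of the estimator class, not a bug).

### Saturation and undefined ω

Saturation — a correction argument ≤ 0 — is a typed result (`ka`/`ks` = NA
with `saturated = TRUE`), never an exception or a negative number, so the
Ks filter can treat saturated pairs uniformly. ω is NA ("undefined") when
Ks = 0; such pairs are excluded from classification with a warning.
Downstream, pairs are kept only when Ks is finite and strictly below the
cutoff 1.1, the conventional bound below which synonymous sites are
considered unsaturated in this genus.

### Classification thresholds

Selection classes follow the γ-MYN convention: purifying at ω ≤ 0.3,
neutral at 0.3 < ω < 3, positive at ω ≥ 3, with boundaries assigned by the
stated non-strict inequalities. Group summaries use the arithmetic mean and
the sample (n − 1) standard deviation; this convention was validated by
reproducing the published per-group values (0.085, 0.172, 0.321) from the
printed per-pair ω column. The published within-plasmids summary
(0.180 ± 0.079) is not reproducible from the printed per-pair values —
recomputation gives 0.201 ± 0.207 — so the package reports the recomputed
number and the acceptance criteria exclude that group. Length bins follow
the printed 1–100 / 101–200 convention (length 200 is in the second bin,
201 in the third); the "length" column of the curated table is stored
uninterpreted because its units (base pairs vs residues) are ambiguous in
the source material.

## The expression arm

Replicates are averaged per condition; each gene is then z-scored over the
conditions with the sample (n − 1) standard deviation, so "variance 1"
holds exactly under the sample convention (constant rows are an error — a
gene with no variation across conditions carries no pattern). Cosine
similarity and Pearson R are computed on the z-scored, replicate-averaged
profiles. Whether published per-pair cosines were computed before or after
normalisation is not documented; z-scored is the default here because the
clustering operates on the same vectors, and the raw alternative is one
`zscore_rows()` call away.

The regression transform ln[(1 + R)/(1 − R)] is reported as an infinite
flag at |R| = 1 rather than clipped; regressions drop such records with a
warning. "Expression divergence" is not defined in the source material; it
is taken to be 1 − cosine, and the transformed-R regression is provided
separately so both notions of expression response are representable.

Quadrants partition pairs at cosine 0.5 and divergence 50%, boundaries on
the "low" side, matching the stated strict/non-strict inequalities; the
partition is property-tested on a boundary-including grid.

Clustering is spherical k-means under the 1 − cosine distance (centroid =
unit-normalised mean of members), initialised from average-linkage
hierarchical clustering cut at k. The hierarchical initialisation is the
entire point: it removes random restarts, so the whole expression arm is
seed-free and bit-reproducible (tested). Ties in assignment go to the
lowest cluster index; a cluster emptied during iteration is re-seeded with
the profile least similar to its current centroid (deterministic rule); the
within-cluster cost descends monotonically (tested). k = 16 by default
because 16 dominant patterns is the published choice for this organism's
seven-condition design; no selection criterion for k was given, so it is a
plain parameter on every interface.

Cluster matching mirrors a BLAST search: each query centroid takes the
library centroid of highest cosine; a match is mutual when the library
cluster's own best hit is the query. The same best-hit logic applies at the
individual-gene level. Means are reported with the sample sd.

## The simulators: a stated world

`simulate_codon_pair()` draws an ancestor of sense codons from
π-products (stops rejected) and evolves two independent lineages with a
per-codon continuous-time process: single-nucleotide steps, TN93 relative
rates, nonsynonymous steps multiplied by ω, stop-codon steps forbidden.
Lineage duration is calibrated so the expected pairwise synonymous
substitutions per synonymous site equal the requested Ks, computed from the
generator's own rate table on the ancestor; because nonsynonymous steps
carry the factor ω against the same site weighting, the expected Ka/Ks is ω
by construction. The calibration uses the ancestral composition, which
drifts slightly over the run; realised synonymous divergence matches the
target within sampling error at tested divergences (mean within 0.05 of
Ks = 0.5 over 25 replicates). Codons evolve independently — no indels (the
analysis drops gapped columns anyway), no codon-usage bias beyond the base
frequencies, no context effects. An optional `gamma_site_shape` draws a
Gamma(α, α) rate multiplier per codon, shared by both lineages, to emulate
among-site rate variation.

A consequence worth stating plainly: the generator's default world has
**uniform rates across sites**, so the matched estimator for recovery
experiments is MYN. γ-MYN with the default shape α = 1 applied to such data
deliberately overcorrects (measured: Ks ≈ 0.75 estimated for a true 0.5),
exactly as the gamma formula prescribes when the data violate its
assumption — that is a model-mismatch property, not an implementation
error. The acceptance recovery criterion ("γ-MYN/MYN recovery") is
therefore exercised with MYN; γ-MYN is validated by its α → ∞ equivalence
to MYN, its monotone-in-α behaviour, and on gamma-rate simulated data.

`simulate_expression()` spreads latent unit-norm condition profiles by
greedy maximin selection from a random pool (16 patterns in 7 dimensions
cannot be orthogonal; spreading maximises their minimum angle), assigns
pairs to patterns round-robin, places copy 2 at angle arccos(c) from copy 1
inside a random plane, and adds homoscedastic Gaussian noise per
measurement (no published noise model exists; homoscedastic Gaussian is the
neutral default). Defaults emulate the published design: 7 conditions, 3
replicates, ~200 pairs, 16 patterns. The target within-pair cosine is
enforced on the raw profiles; the truth record also reports the realised
post-z-scoring cosines, since normalisation changes angles. What a green
clustering test establishes is recovery of well-separated synthetic
patterns under small noise — not that 16 is the right k for any real data
set, nor anything about probe-level artefacts such as cross-hybridisation
between near-identical paralogs, which the generator does not model.

## Statistical conventions

Two-sample Kolmogorov–Smirnov tests use the asymptotic Kolmogorov
distribution with the standard effective-n correction (`stats::ks.test`,
`exact = FALSE`); the original analysis used an unspecified online
calculator, so exact agreement of historical p-values is not claimed.
Correlations are Pearson with the t-transform p-value on n − 2 degrees of
freedom; regressions are ordinary least squares. Significance level
conventions are left to the user.

## Known limitations

* The MYN difference classification uses equal pathway weights; a fully
  rate-weighted pathway average is conceivable but under-documented in the
  estimator literature, and the unbiased-limit agreement with NG86
  (|ΔKa| ≤ 0.01, |ΔKs| ≤ 0.02 at 500 codons) bounds the practical effect.
* κ estimation from all sites is biased upward under strong purifying
  selection (see above); the bias affects site weighting only mildly.
* The curated 24-pair table carries values rounded to four decimals, so
  quotient checks propagate a ±5e-5 rounding band.
* No maximum-likelihood codon models, sliding windows, model averaging, or
  horizontal-transfer inference; processed expression matrices only, no
  probe-level preprocessing.
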