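# paralogscope

Selective-constraint and expression-similarity analysis of duplicated gene
pairs in bacteria with multipartite genomes (a primary chromosome CI, a
second chromosome CII, and plasmids PA–PE, as in *Rhodobacter sphaeroides*
2.4.1).

## Who this is for

Researchers asking how a genome maintains its paralogs: are young duplicate
pairs under purifying selection, does the replicon a copy lives on matter,
and do the two copies of a pair keep the same expression program across
growth conditions? The package takes unaligned coding sequences plus a
gene-pair table, and optionally a replicated expression matrix, and produces
the full analysis offline.

## What it computes

**Structural arm.** For each pair of coding sequences: translate (standard
code), align the proteins globally (BLOSUM62, affine gaps), back-translate
to a gap-free codon alignment, and estimate

- *K*<sub>a</sub> — nonsynonymous substitutions per nonsynonymous site,
- *K*<sub>s</sub> — synonymous substitutions per synonymous site,
- ω = *K*<sub>a</sub>/*K*<sub>s</sub> — the selective constraint,

with three estimators: NG86 (Nei–Gojobori counting with Jukes–Cantor
correction), MYN (modified Yang–Nielsen: sites, differences and corrections
all weighted under the Tamura–Nei 1993 model with separate purine and
pyrimidine transition/transversion ratios κ<sub>R</sub>, κ<sub>Y</sub>), and
γ-MYN (every multiple-hit correction −ln *x* replaced by its gamma-rates
analogue α(*x*<sup>−1/α</sup> − 1)). Pairs with saturated synonymous sites
(*K*<sub>s</sub> ≥ 1.1, or an undefined correction) are filtered out;
remaining pairs are classified as purifying (ω ≤ 0.3), neutral
(0.3 < ω < 3) or positive (ω ≥ 3) and summarised by replicon relation
(within CI, within CII, between CI and CII, within plasmids,
chromosome–plasmid) and by gene-length bins.

**Expression arm.** Replicates are averaged per growth condition, each gene
is z-scored over conditions (mean 0, sample variance 1), and within-pair
similarity is measured by cosine and Pearson R (with the regression
transform ln[(1 + R)/(1 − R)]). Pairs fall into four quadrants by cosine
(> 0.5 vs ≤ 0.5) and amino-acid divergence (≤ 50% vs > 50%). Latent
expression patterns come from spherical k-means (distance 1 − cosine)
initialised by average-linkage hierarchical clustering — fully
deterministic — and the in-paralog and out-paralog clusterings are matched
both ways by best-cosine centroid hits, flagging mutual (symmetric) best
matches.

**Simulators.** `simulate_codon_pair()` evolves two lineages from a common
ancestor under a TN93-rate codon process with a chosen ω and a lineage
length calibrated to a target *K*<sub>s</sub>; `simulate_expression()`
builds a replicated expression matrix from well-spread latent patterns with
a chosen within-pair cosine and Gaussian noise. Both are seed-reproducible
and carry truth records, so every stage of the pipeline is testable without
external downloads.

## Worked example

The package ships the curated table of the 24 young (*K*<sub>s</sub> < 1.1)
in-paralog pairs of *R. sphaeroides* 2.4.1 with their published
*K*<sub>a</sub>, *K*<sub>s</sub>, ω, divergence and replicon locations:

```r
library(paralogscope)
pairs <- read_pair_table(system.file("extdata",
  "rsphaeroides_inparalogs.tsv", package = "paralogscope"))
kept <- filter_unsaturated(pairs, ks_max = 1.1)
table(classify_selection(kept$omega))
#> purifying   neutral  positive undefined
#>        19         5         0         0
summarize_omega_by_group(kept)
#>                group n mean_omega sd_omega
#> 1          within-CI 4      0.123   0.0853
#> 2         within-CII 4      0.145   0.1722
#> 3     between-CI-CII 8      0.284   0.3211
#> 4    within-plasmids 7      0.201   0.2071
#> 5 chromosome-plasmid 1      0.207       NA
```

19 of 24 young pairs are under purifying selection and none under positive
selection; pairs split between the two chromosomes are on average less
constrained (ω ≈ 0.28) than pairs within either chromosome (ω ≈ 0.12–0.15).
(The within-plasmids mean printed in the original figure, 0.180 ± 0.079, is
not reproducible from the per-pair values; the package reports the
recomputed 0.201 ± 0.207.)

Estimating ω from sequences simulated with known truth:

```r
sim <- simulate_codon_pair(n_codons = 300, ks = 0.5, omega = 0.2, seed = 42)
res <- pair_kaks_pipeline(sim$seq1, sim$seq2, method = "MYN")
res$estimate
#> MYN estimate: Ka=0.1150923 Ks=0.503649 omega=0.2285169
#>   S=274.51 N=625.49 Sd=94.000 Nd=66.000
```

The estimate recovers the generating *K*<sub>s</sub> = 0.5 and ω = 0.2
within sampling error of a single 300-codon pair.

## Command line

```sh
exec/paralogscope simulate seqs --n-codons 300 --ks 0.5 --omega 0.2 \
    --seed 42 -o pair.fasta --truth truth.json
exec/paralogscope kaks --fasta seqs.fa --pairs pairs.tsv --out kaks.tsv
exec/paralogscope classify --pairs pairs.tsv --out-dir out/
exec/paralogscope run --pairs pairs.tsv --fasta seqs.fa --expr expr.tsv \
    --out-dir out/
```

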