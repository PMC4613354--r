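---
title: "Quantifying replicating strand composition bias in bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying replicating strand composition bias in bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandbias)
```

## The problem

Bacterial chromosomes are typically single circular molecules replicated
bidirectionally from one origin (*ori*) to one terminus (*ter*). The two
arcs between them — the replichores — are copied with opposite polarity:
on one arc the published (plus) strand is the continuously synthesised
leading strand, on the other arc the leading strand is its reverse
complement. Because mutational and repair processes act differently on
leading and lagging strands (e.g. cytosine deamination in transiently
single-stranded DNA), most bacterial leading strands accumulate an excess
of G over C and, more weakly, T over A — a violation of Chargaff's second
parity rule known as replicating strand composition bias.

This package quantifies that bias per genome, derives companion genomic
features (gene orientation bias, GC content, rearrangement-frequency
proxies, COG functional-subcategory usage, KEGG replication-and-repair
pathway content), and provides the cohort-level statistics that relate the
features to the bias across hundreds of genomes. A synthetic-genome
generator with fully known ground truth replaces any dependency on
external sequence databases, so the entire analysis is reproducible from a
seed.

## Per-genome statistics

**Replichore partitioning.** From single ori/ter breakpoints (0-based,
half-open arithmetic modulo the chromosome length) the chromosome is split
into arc 1 = `[ori, ter)` (published strand leading) and arc 2 =
`[ter, ori)` (reverse complement leading). Every position belongs to
exactly one arc. Genes are assigned to a replichore by the position of
their midpoint, taken modulo the length so genes wrapping the coordinate
origin need no special casing; a gene is *leading* when its transcription
direction matches the fork direction of its replichore. The midpoint rule
is deterministic and handles ori/ter-spanning genes without ambiguity —
the convention for such genes is not dictated by the biology, and the
choice only affects the handful of genes that straddle a breakpoint.

**Composition-bias score.** With `G, C, T, A` counted on the composite
leading strand (published bases over arc 1 plus complemented bases over
arc 2),

$$\mathrm{Score} = \frac{|G - C| + |T - A|}{L}.$$

Ambiguous bases (N and other IUPAC codes) are excluded from the four
counts but the denominator stays the full chromosome length `L`, so a
genome with many ambiguous calls is (conservatively) pulled towards zero
bias. By complementarity the lagging strand yields the identical value.
The score is computed over whole replichores (coding and intergenic
alike), the literal reading of "bases in leading strands"; an alternative
would count only gene bodies, but with bacterial genomes ~85–90% coding
the two differ little, and the whole-arc version needs no annotation.

**gcRF and taRF.** For each leading-strand gene *i* with length $L_i$ the
coding-orientation skews $(G_i - C_i)/L_i$ and $(T_i - A_i)/L_i$ are
collected, and the rearrangement-frequency proxy is

$$\mathrm{RF} = \frac{\operatorname{Var}(\text{skews})}{\overline{\text{skew}}},$$

the sample variance over the mean. Chromosomal rearrangement moves genes
between strands, scattering per-gene skews around a reduced mean, so
higher RF indicates more recombination counteracting the replication
bias; genomes whose mean skew is negative yield negative RF, matching the
sign behaviour seen in real phylum summaries. The printed rendering of
this index is ambiguous about a square root over the variance term; the
package defaults to the literal variance-over-mean and offers
`rf_variant = "sd_over_mean"` (a coefficient of variation) as a switch —
both produce the same sign pattern and very similar rankings. A mean skew
of exactly zero yields `NA` rather than an infinity. Zero-length genes
after coordinate clipping are excluded with a warning.

**COG and KEGG features.** The percentage of each COG functional
subcategory (pCOG) counts every (gene, letter) assignment after dropping
the uninformative letters R, S and X, normalised to sum to one;
multi-letter annotations (e.g. "KL") contribute one count per letter,
which keeps the vector a proper composition. Pathway proportions are the
fraction of a genome's genes assigned to each of the ten KEGG
replication-and-repair pathways (ko03030–ko03460).

## Cohort statistics

**Strong/weak split and AVDT.** The cohort is split by score into a
strong-biased group (top `floor(N/2)` genomes; ties broken by genome id so
the split is reproducible) and a weak-biased group. For each COG ortholog
group the ratio of its summed gene count in the strong half to the weak
half is formed; the average of those ratios within each functional
subcategory is the AVDT statistic. Groups absent from the weak half have
an undefined ratio and are excluded by default (a pseudocount alternative
is provided). Ortholog groups with a ratio above 5 are the strong-biased
COG groups (SCOGs), below 0.2 the weak-biased groups (WCOGs), and each
genome's SCOG/WCOG fractions (over its COG-annotated genes) become
features. The ratio statistic could in principle be formed directly at
subcategory level instead, but subcategory-level ratios concentrate
towards 1 (typical AVDT minima are ~0.6, far above the 0.2 threshold), so
the WCOG set would be empty and its correlation undefined; the package
therefore defaults to ortholog-group-level ratios with AVDT as the
per-subcategory mean — the reading under which all downstream quantities
are simultaneously computable. `diff_level = "subcategory"` provides the
coarser alternative. Raw gene counts are used without per-genome
normalisation, as literally defined. Whether the correct denominator for
the SCOG/WCOG fractions is all genes or COG-annotated genes is likewise
unstated; the package uses COG-annotated genes, which makes the fraction
insensitive to annotation coverage.

**Correlations and tests.** Associations between features and the score
use Spearman's rank correlation (midranks for ties) with the asymptotic
two-sided p-value from $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees
of freedom — appropriate at cohort sizes of hundreds; an exact permutation
p-value is available for $n \le 10$ and is used to cross-check the
asymptotic path in the tests. Two significance conventions are annotated
rather than applying a multiple-testing correction, mirroring common
practice in this literature: p < 0.05 overall and a strict p < 1e-8 for
the COG subcategory battery. The obligate-intracellular comparison uses
Welch's unequal-variance t-test by default (the pooled-variance variant is
a switch); the two groups are of very different sizes and there is no a
priori reason to assume equal variances. Missing values are removed
pairwise for correlations and listwise for the regression, each deletion
counted and reported.

**Principal component regression.** The selected features are
z-standardised and principal components with unit-norm loadings are
extracted; all components with non-zero variance are retained. Because
components are mutually orthogonal, the squared correlation $R^2_m$
between component $m$ and the score sums over components to the ordinary
least-squares $R^2$ of the score on the full feature set, and

$$\text{contribution}_f = \sum_m w_{fm}^2 \, R^2_m$$

(with $\sum_f w_{fm}^2 = 1$) re-attributes that total exactly to the
original features. No retention rule is applied because dropping
components would break the exact additivity; the decomposition is one
defensible choice among several (e.g. Shapley-style attributions) and is
validated in the tests against the OLS oracle to 1e-9. Features enter the
regression when their battery p-value passes the strict cutoff; if fewer
than two qualify the looser 0.05 convention is used, then a fixed core set
(size, density, GC, gcRF, taRF, SCOG/WCOG fractions), and the feature
count is always capped below the genome count. An explicit
`pcr_features` list overrides the selection.

## The synthetic-genome generator

`simulate_genome()` draws each leading-strand position independently with

$$P(G) = \tfrac{gc}{2} + \tfrac{\delta_{gc}}{2},\quad
  P(C) = \tfrac{gc}{2} - \tfrac{\delta_{gc}}{2},\quad
  P(T) = \tfrac{1-gc}{2} + \tfrac{\delta_{ta}}{2},\quad
  P(A) = \tfrac{1-gc}{2} - \tfrac{\delta_{ta}}{2},$$

and complements arc 2 onto the published strand, so the expected score
with no rearrangement is exactly $|\delta_{gc}| + |\delta_{ta}|$ and every
per-genome feature has a closed-form expectation recorded in the
ground-truth table. A site-independent model suffices because all the
statistics above depend only on base counts; codon structure, operons and
real intergenic architecture are deliberately not modelled. Consequently,
passing tests demonstrate that the *estimators* recover known parameters
and planted relationships — they say nothing about codon-level selection,
annotation noise, or phylogenetic non-independence in real data, none of
which the generator emulates.

Non-overlapping genes are placed uniformly (never across the coordinate
origin), oriented to the leading strand with probability $\rho$, assigned
COG letters/ortholog groups (including a 5% rate of the excluded letter R
so the downstream filter is exercised) and KEGG pathways at configurable
rates. `apply_inversions()` reverse-complements random segments in place
— flipped genes change strand and coordinates, genes straddling a
breakpoint are deleted with a log line, and segments never contain ori or
ter so the replichore map stays well defined (the RF index presumes fixed
replication coordinates). Inversions lower the expected score by
2×(flipped fraction) and scatter per-gene skews, raising RF — the
qualitative trend the index was designed to capture.

`simulate_cohort()` draws a latent per-genome bias level
$\delta_{\text{sum}}$ (log-normal around 0.035, matching the scale of
published cohort means of ~0.04) and plants the reported relationships
through its standardised value $z$: leading-gene density increases with
$z$, GC content and log genome size decrease, obligate-intracellular
genomes (12% of the cohort) receive a +0.018 score offset, and five COG
letters (D, F, J, L, V) are up-weighted while four (A, C, I, Q) are
down-weighted by $e^{\pm 1.3 z}$ — which simultaneously plants the pCOG
correlation signs and, at the ortholog-group level, makes those groups'
strong/weak count ratios cross the 5 and 0.2 thresholds, so the SCOG (+)
and WCOG (−) correlations emerge through the full selection mechanism
rather than being wired in directly. The gcRF/taRF
negative correlations are not planted at all: they follow mechanically
because RF ≈ (per-gene skew variance)/δ, an inverse function of the
score-driving delta. Each genome also receives independent noise on
density, GC and size so the planted correlations are strong but not
degenerate. With `effects = "null"` every coupling is zeroed and
$\delta_{\text{sum}}$ is held constant at 0.037 while the other genome
properties keep varying independently.

```{r cohort-example}
co <- simulate_cohort(cohort_sim_params(n_genomes = 20, seed = 1,
                                        mean_length = 50000))
feats <- suppressWarnings(cohort_features(co))
dplyr::select(feats, genome_id, score, gene_density_leading, gc_content)[1:5, ]
```

## Calibration limits of the RF indices

One estimator property deserves emphasis. Under the null cohort the score
and the RF indices are computed from the *same* realised sequence, so
their sampling noises are correlated (the whole-chromosome skew and the
mean per-gene skew share the gene-body sites, correlation roughly the
square root of the leading-gene coverage). RF divides by the mean skew,
flipping the sign, so even with no planted effect the battery shows a
modest negative Spearman correlation between the score and gcRF/taRF
(|rho| ~ 0.2–0.35 at 200 genomes with realistic delta magnitudes). The effect is
scale-invariant in genome length — both noise terms shrink together — and
grows as the true delta shrinks. It is a genuine property of
ratio-of-statistics estimators sharing data with the response, not a
pipeline artifact; in real cohorts it means weak RF–score correlations
near these magnitudes should not be over-interpreted. The calibration
test in the suite documents the measured magnitude.

## Problem sizes and numerical choices

The package's own test and demonstration sizes are chosen to keep a full
run comfortable on a laptop-class single core: cohorts of 200 genomes
with log-normal lengths around 300 kb (~130 genes each) for
planted-effect and calibration runs, 500 kb genomes for the inversion
trend, and 1–3 Mb single genomes for parameter-recovery checks. A full
`run_all()` at those sizes completes in well under a minute; the complete
test suite in a few minutes. Monte-Carlo assertions use 3-sigma binomial
bounds on the known expectations.

Other fixed conventions: coordinates are 0-based half-open internally
with GFF3's 1-based inclusive form converted at the I/O boundary; ori/ter
supplied as intervals are collapsed to (modular) midpoints, since the
analysis needs single breakpoints; genomes without ori/ter entries are
skipped with a warning rather than failing a cohort run; cohort splits
and all written tables are deterministically ordered so identical inputs
give byte-identical outputs; principal components with standard deviation
below 1e-10 are treated as rank deficiency and dropped with a message.

## Known limitations

* Single circular chromosome per genome; plasmids, chromids and linear
  chromosomes are out of scope, as is predicting ori/ter from skew.
* The generator's site-independence means codon-usage statistics (e.g.
  selected codon usage bias) cannot be simulated meaningfully; the
  `s_value` and `generation_time` metadata columns are arbitrary numbers
  used only to exercise the optional-column plumbing.
* Correlations are not corrected for phylogenetic non-independence; the
  phylum labels exist for grouped summaries, not for comparative methods.
* Published real-cohort correlation magnitudes depend on the underlying
  genome snapshot and annotation vintage and are not reproducible from
  synthetic data; the pipeline targets signs, identities and calibration
  instead.
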