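# strandbias

Quantitative analysis of **replicating strand composition bias** in
circular bacterial genomes, with a ground-truth synthetic-genome
simulator so the whole pipeline runs end to end from a seed — no external
sequence databases required.

## The science

Bacterial chromosomes replicate bidirectionally from an origin (*ori*) to
a terminus (*ter*), splitting the circle into two **replichores** whose
leading strands have opposite polarity relative to the published
sequence. Strand-asymmetric mutation and repair leave the leading strand
with an excess of G over C (and, more weakly, T over A). The package
measures this per genome as

```
Score = (|G − C| + |T − A|) / L
```

with bases counted on the composite leading strand (published bases over
`[ori, ter)`, complemented bases over `[ter, ori)`) and `L` the
chromosome length. Around that score it computes the companion features
used in cohort analyses of the phenomenon:

* **Leading-strand gene density** — fraction of genes co-oriented with
  the replication fork (midpoint rule, modular arithmetic).
* **gcRF / taRF** — variance-over-mean of per-gene `(G−C)/L` and
  `(T−A)/L` skews among leading-strand genes: dispersion proxies for how
  much rearrangement has counteracted the uniform replication bias.
* **pCOG** — percentage of each COG functional subcategory (letters R,
  S, X excluded), per-letter counting for multi-letter annotations.
* **SBG/WBG ratios, AVDT, SCOGs/WCOGs** — the cohort is split into
  strong- and weak-biased halves by score; per COG ortholog group the
  strong:weak gene-count ratio is formed, averaged per subcategory
  (AVDT), and groups with ratio > 5 / < 0.2 become SCOGs/WCOGs whose
  per-genome fractions are features.
* **KEGG replication-and-repair pathway proportions** (ko03030–ko03460).

Cohort statistics: a Spearman battery of every feature against the score
(asymptotic t p-values, two significance conventions annotated), a Welch
t-test comparing obligate-intracellular genomes with the rest, per-phylum
summaries, and a **principal component regression** that attributes the
regression R² back to the original features via squared loadings — the
attribution sums exactly to the OLS R².

The simulator draws leading-strand bases site-wise with controllable
per-replichore deltas (`E[Score] = |δ_gc| + |δ_ta|`), places genes with a
controllable leading-strand probability, couples COG usage to the bias
level, applies segment inversions, and writes FASTA/GFF3/TSV bundles
with a full ground-truth table.

## Worked example

```r
library(strandbias)

# One genome with known bias: delta_gc = 0.04, delta_ta = 0.02
sim <- simulate_genome(genome_sim_params(length = 200000, delta_gc = 0.04,
                                         delta_ta = 0.02, seed = 42))
genome_features(sim$record, sim$cog, sim$kegg)[, 1:6]
#>   genome_id  score gc_content gene_density_leading   gcRF   taRF
#> 1 sim1      0.0609      0.502                0.636 0.0112 0.0202
```

The recovered score 0.0609 sits within sampling error of the planted
0.06; the gene density reflects the default leading-strand placement
probability.

```r
# A 60-genome cohort with planted feature couplings
co    <- simulate_cohort(cohort_sim_params(n_genomes = 60, seed = 7,
                                           mean_length = 80000))
feats <- cohort_features(co)
rep   <- cohort_stats(feats)

rep$battery[rep$battery$feature %in%
            c("genome_size", "gene_density_leading", "gcRF"), 1:3]
#>                feature     rho   p_value
#> 1          genome_size -0.8682 2.646e-19
#> 2 gene_density_leading  0.4777 1.137e-04
#> 3                 gcRF -0.8397 5.124e-17

glance(rep$pcr)
#>   total_r2  n n_components dropped_rows
#> 1    0.849 60           11            0
```

Genome size and gcRF correlate negatively with the bias score, gene
density positively — the planted directions — and the selected features
jointly explain 84.9% of the score variance, additively attributed per
feature by `tidy(rep$pcr)`. `autoplot(rep$battery)` and
`plot_phylum_scores(feats)` give the standard figures, and
`run_all(out_dir, params)` writes the cohort plus all report tables as
deterministic TSVs. A command-line front end with the same verbs lives
at `inst/scripts/strandbias-cli.R`.

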