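# riverphylo

Tools to assess the **riverine barrier hypothesis** (RBH) — the proposal
that the formation of large rivers drove allopatric speciation — from
phylogenies of georeferenced samples, built for phylogeographers working
on taxa like Amazonian primates. A divergence between two clades counts as
congruent with a river only if

1. the clades are distinct evolutionary lineages found exclusively on
   opposite banks (*spatial congruence*), and
2. the divergence does not postdate the river's geological formation
   (*temporal congruence*).

The package covers the whole workflow: Poisson Tree Processes (PTP)
lineage delimitation on an ML tree, bank assignment of samples against
oriented river polylines, enumeration and classification of
between-lineage divergences, node-age extraction from posterior tree sets
with 95% highest-posterior-density (HPD) intervals, synchrony grouping,
and the river-age test — plus seeded synthetic-data generators so every
stage is testable against planted truth.

## The model in brief

PTP assigns every edge of the ML tree to a between-lineage ("speciation")
or within-lineage ("coalescent") exponential branch-length regime. With
per-class plug-in MLE rates λ̂ = n/Σbᵢ, a class with *n* edges of total
length *S* contributes *n* log(*n*/*S*) − *n* to the log-likelihood, so
delimitation is a search over tree partitions: exhaustive on small trees
(the oracle), seeded multi-restart hill-climbing otherwise. Single-rate
mode pools all coalescent edges; multi-rate gives each lineage its own λᵢ
(more conservative). The HPD of a clade's age is the shortest window
containing 95% of its MRCA ages across the posterior trees; a divergence
is temporally congruent with a river of minimum age *m* iff
`hpd_high >= m`.

## Worked example

Delimit a simulated two-regime tree and reproduce the published
desk arithmetic from the HPD intervals shipped with the package:

```r
library(riverphylo)

sp <- simulate_species_tree(6, birth_rate = 0.3, seed = 11)
gr <- graft_coalescent_samples(sp, samples_per_species = 4,
                               lambda_speciation = 1,
                               lambda_coalescent_mean = 20, seed = 12)
delimit_search(gr$tree, mode = "multi", seed = 1)
#> PTP delimitation (multi-rate): 6 lineage(s), logL = 70.30759

res <- intervals_only_mode(published_divergence_hpds(), published_rivers())
res$Amazon$congruent_names
#> [1] "Saguinus"    "Leontocebus" "Cebuella"    "Chiropotes"
res$Negro$n_congruent
#> [1] 0
```

The six planted species are recovered exactly. Of the nine published
divergence-age HPDs across the Amazon, four reach back past the river's
2.4 Ma minimum formation age (the marmoset/tamarin genera and the bearded
sakis) — the published conclusion; none of the three Rio Negro divergences
predates its 1.9 Ma minimum, so that river shows no temporally congruent
split. Synchrony grouping on the Amazon intervals separates an older
partially overlapping group from a younger clique:

```r
for (g in res$Amazon$synchrony)
  cat(paste(g$members, collapse = ", "), "| clique:", g$clique, "\n")
#> Saguinus, Leontocebus, Cebuella, Chiropotes, Cheracebus, Saimiri_2 | clique: FALSE
#> Saimiri, Cebus, Ateles | clique: TRUE
```

Bank assignment against an oriented polyline:

```r
rv <- synthetic_river(min_age_ma = 2.4)   # straight meridian river
plan <- setNames(rep(c("left", "right"), 3), names(gr$truth$lineages))
md <- simulate_river_geography(lineage_map(gr$truth), rv, plan, seed = 5)
head(assign_banks_table(md, list(rv)), 3)
#>   sample_id river_name bank distance_km
#> 1    sp1_s1 SynthRiver left    90.34397
#> 2    sp1_s2 SynthRiver left    89.46444
#> 3    sp1_s3 SynthRiver left   124.48192
```

`run_pipeline(config)` chains all stages from a JSON config (file paths,
delimitation mode, burnin, HPD level, seed) into a self-describing JSON
report with per-divergence verdicts, synchrony groups, and
barrier-violation flags; `inst/cli/riverphylo` exposes the same stages as
shell subcommands (`run`, `delimit`, `banks`, `synthesize`, `intervals`).

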