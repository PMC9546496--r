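---
title: "Assessing the riverine barrier hypothesis from dated phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the riverine barrier hypothesis from dated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverphylo)
```

## The question

The riverine barrier hypothesis (RBH) proposes that the formation of large
rivers split the ranges of forest-dwelling taxa and drove allopatric
speciation. For Amazonian primates this is a 150-year-old idea that is easy
to state and hard to test: a divergence between two clades "matches" a river
only if (1) the two clades really are distinct evolutionary lineages found
exclusively on opposite banks, and (2) the divergence is not younger than
the river itself. `riverphylo` implements that two-condition assessment as a
reproducible pipeline over four inputs: a maximum-likelihood (ML) tree for
lineage delimitation, a dated ultrametric tree plus a posterior sample of
dated trees for chronology, a sample-locality table, and oriented river
polylines with geological formation-age windows.

## Lineage delimitation: the Poisson Tree Processes model

Species boundaries in the groups this method targets are often contested,
and sometimes themselves defined by rivers; using them to test the RBH
would be circular. Delimitation is therefore done directly on the ML tree
with a Poisson Tree Processes (PTP) model. Every edge belongs either to a
between-lineage ("speciation") process or to the within-lineage
("coalescent") process of one lineage; edge lengths within a class are
i.i.d. exponential. At the per-class maximum-likelihood rate
$\hat\lambda = n/\sum b_i$, a class with $n$ edges of total length $S$
contributes

$$ n \log(n/S) - n $$

to the log-likelihood, so the objective depends on the partition alone.
Single-rate mode pools all coalescent edges into one class (less
conservative, more lineages on real data); multi-rate mode gives each
lineage its own rate $\lambda_i$ (more conservative). Because a multi-rate
fit can always replicate a single-rate fit, multi-rate log-likelihood is
never lower at the same partition — a property the test suite asserts.

A delimitation is represented by its *lineage roots*: an antichain of nodes
covering all tips. The edge subtending a lineage root is speciation; edges
inside its subtree are coalescent. The one-lineage null (root as the only
lineage root) has an empty speciation class. Two solvers share this
representation:

* `delimit_exhaustive()` enumerates every antichain (feasible to ~12 tips)
  and is the oracle;
* `delimit_search()` is a seeded multi-restart hill-climb over split/merge
  moves, with the one-lineage and all-tips states always among the starts.
  On oracle-sized trees it is required (and tested on 50 random trees) to
  find the same log-likelihood.

Ties are broken toward fewer lineages, then the lexicographically smallest
partition, so outputs are deterministic. Edges shorter than
`min_branch_length` are excluded from the likelihood but kept in the
topology; `auto_min_branch_length(sites)` supplies the conventional floor
of one substitution across the alignment, $1/\text{sites}$ — the original
tool's exact auto-minbr formula is not published, so this definition is the
package's own and is echoed in the output.

### A known and deliberate limitation

The profile-ML objective has no penalty for extra rate classes. When the
two regimes coincide (no signal), the maximizer does **not** collapse to
one lineage; it overfits sampling variance in i.i.d. branch lengths (we
measure ~40–60 lineages on 100-tip trees with none planted, and the
exhaustive oracle behaves the same on small trees, so this is the model,
not the search). This is precisely why the tool this stage emulates
supplements ML delimitation with support values, which are out of scope
here. Consequence: delimitation output is trustworthy when a rate gap
exists (the planted-recovery study at rate ratio 20 recovers 20 ± 2
species in ≥ 90% of 200 replicates), and should not be read as evidence
*against* structure when rates are homogeneous. One acceptance assertion
encoding the collapse expectation is left failing rather than weakened;
the test file and the repository notes explain it.

## Bank assignment

Rivers are oriented polylines (vertices ordered downstream). For a sample,
the nearest point on the polyline is found on a local equirectangular
projection centred at the sample's latitude — bank assignment is a sign
decision at sub-degree scale, where the planar approximation is safe — and
the bank is the sign of the cross product of the segment's downstream
direction with the vector to the sample: left/right are relative to flow,
not compass, so they remain well-defined around meanders. Distances are
reported as great-circle (haversine) km.

Two cases refuse to guess and return `indeterminate`: samples lying on the
line (within 1e-9 degrees), and samples whose nearest polyline point is a
terminal vertex approached from beyond the mapped extent (the headwaters
problem). Downstream stages treat indeterminate banks as missing data. A
samples table may instead carry a pre-assigned `bank:<river>` column that
bypasses geometry, for reproducing published by-eye assignments.

## Spatial congruence

Between-lineage divergences are the internal nodes (within a user-declared
scope, e.g. the Amazonian clade) whose two child clades contain disjoint
lineage sets; with $k$ monophyletic lineages in scope there are exactly
$k-1$. A divergence is `congruent` with a river when each child clade's
determinate banks are unanimous and the two sides differ, with at least
`min_determinate_per_side` determinate tips per side (default 1, matching
published practice of accepting single-sample sides; such verdicts are
flagged `low_support`). Fewer determinate tips make it `unevaluable`;
anything else is `incongruent`. Separately, `find_barrier_violations()`
flags lineages with determinate tips on both banks — direct evidence the
river is not a barrier for them. Congruence is evaluated on sampled tips,
not ranges; that is what the data are.

The overall divergence denominator counts every enumerated divergence once,
with per-river evaluability reported separately (published totals do not
state which convention they use; this one is explicit and recomputable).

## Chronology

For each spatially congruent divergence, the age of the clade's MRCA is
extracted from every post-burnin posterior tree — whether or not the clade
is monophyletic in that tree, with the monophyly fraction reported so
instability is visible rather than silently discarded. The 95% HPD is the
shortest contiguous window over the sorted samples containing
$\lceil 0.95\,n \rceil$ points, ties broken toward the earliest window.
Burnin is a user parameter (published analyses removed 25–32% per chain
without stating a rule).

*Synchrony* of divergences across the same river is reported as connected
components of the pairwise HPD-overlap graph, with a flag for whether each
component is a clique — the stricter reading of "synchronous". Closed
intervals touch-overlap; HPDs are continuous summaries and measure-zero
distinctions are noise.

*Temporal congruence* follows the negative phrasing of condition 2: a
divergence is congruent unless it demonstrably postdates river formation,
i.e. `hpd_high >= min_age_ma`, boundary inclusive. A stricter optional rule
is offered as `hpd_low >= min_age_ma` (the entire HPD predates the river).
A note on that choice: the seemingly intermediate rule "the HPD contains or
exceeds the minimum age" is logically equivalent to the default for closed
intervals (if the minimum age is at most `hpd_high`, it is either inside
the interval or below it), so the lower-bound rule is the only non-vacuous
stricter variant.

The one calibration utility, `exp_calibration_mean()`, returns the mean of
an offset-exponential fossil prior that places a soft maximum at a given
quantile: $(\text{max} - \text{offset}) / (-\log(1-q))$.

## What the synthetic generators emulate — and what they don't

`simulate_species_tree()` draws constant-rate birth–death trees conditioned
on the number of surviving tips (via `ape::rphylo`), in Ma.
`graft_coalescent_samples()` then builds the PTP generative world: species
tree edges redrawn from the between-lineage regime
$\mathrm{Exp}(\lambda_{sp})$, each species replaced by a random
pairwise-join subtree with edges from its within-lineage regime
$\mathrm{Exp}(\lambda_i)$, where the $\lambda_i$ scatter lognormally
around a mean with a default coefficient of variation of 0.25 (real
species differ in effective population size; exactly equal rates would be
an unrealistically easy target for multi-rate fitting). The defaults for
recovery studies — 20 species, 5 samples each, rate ratio 20 — mirror a
mitogenomic study design: ~100 samples, within-species divergences an
order of magnitude shallower than between-species ones. Coalescent
subtrees use sequential random joins rather than a parameterized Kingman
process: the PTP likelihood sees only edge-length distributions, so
genealogy shape realism buys nothing for these tests.

`simulate_river_geography()` plants lineage centroids ~100 km from a
synthetic river (the order of real sampling distances from banks reported
in this literature), scatters samples ~20 km around them, and reflects a
seeded `violation_rate` fraction to the wrong bank.
`perturb_posterior()` makes pseudo-posteriors by multiplicative lognormal
noise on node ages (mean 1, cv 0.1 by default — roughly the relative HPD
widths seen in dated mitogenomic trees), clamping children below parents.

What a green test therefore establishes: the pipeline recovers planted
truth when its model assumptions hold exactly. What it does not establish:
robustness to topological posterior uncertainty (pseudo-posteriors vary
ages only; the monophyly fraction exists to expose this on real data),
range shifts since divergence, non-exponential branch regimes, or
delimitation parity with the original solver on the deposited data — the
published full-data counts (101 single-rate and 52 multi-rate lineages,
13/64 and 6/27 congruent divergences) are reproducible only with the
archived trees and the original tool, and are deliberately not asserted.

Coverage testing of the HPD machinery uses a two-stage design: an
"estimated" tree is drawn around the truth, and the pseudo-posterior is
generated around the estimate. Perturbing around the truth itself would
put the true age at the centre of every posterior and give ~100% coverage;
the two-stage design has asymptotic coverage 94.7% at cv 0.1, and the
acceptance study checks 95% ± 2% over 1000 replicates.

## Numerical and design choices

* Ultrametricity tolerance 1e-4 (relative): sampler output carries
  floating-point jitter; hard equality would reject real files.
* Newick is written with 10 significant digits; round-trips are tested to
  be topology- and length-identical.
* Node age of an MRCA is the mean over descendant tip paths, so slightly
  non-ultrametric trees get a well-defined age.
* Hill-climb moves use an improvement threshold of 1e-12 to avoid cycling
  on floating-point ties; restarts include deterministic extreme states so
  the all-equal-lengths tie case lands on the one-lineage null exactly as
  the exhaustive tie-break does.
* Polytomies are accepted on input and resolved (seeded, zero-length) only
  where binarity is required; the resolution is logged.
* Config files are JSON; no YAML parser is assumed on the target system.
* Pipeline reports echo the config, hash every input file, and log the
  seed, so a report is self-describing; all summary counts in a report are
  recomputable from its per-divergence table (tested).

## Limitations

Beyond the no-signal overfitting discussed above: bank assignment ignores
basin polygons and river width; samples beyond a polyline's mapped extent
are dropped from verdicts rather than guessed; "opposite sides" is
evaluated on samples, not ranges, so unsampled range overlap is invisible;
and temporal congruence inherits the geological age estimates it is given
— for rivers without a defensible numeric minimum age (e.g. a possibly
Miocene formation), the user must supply one or the temporal stage is
skipped for that river.
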