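---
title: "Models and methods behind halopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind halopan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halopan)
```

halopan is a desk-scale pan-genome analysis toolkit for sets of prokaryotic
proteomes, built around the workflow used in comparative studies of
halophilic archaea: cluster proteins into gene families, partition families
by genome occupancy, fit pan/core size curves, build core-gene and
pan-genome trees, and reconstruct ancestral gene content on a guide tree.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic benchmark does and does not establish.

## The synthetic pangenome generator

Every stage of the pipeline is validated against simulations with known
ground truth, so the generator is first-class, tested code.

**Tree model.** Genome phylogenies are simulated under a Yule (pure-birth)
process: with $k$ extant lineages the next speciation arrives after an
$\mathrm{Exp}(k\lambda)$ wait and splits a uniformly chosen lineage. The
expected root-to-tip height is $\sum_{k=2}^{n} 1/(k\lambda)$, which gives a
closed form to test against. By default branch lengths are rescaled by that
expectation so tree height has unit mean; gain, loss and substitution rates
are then "per tree height" and transfer across genome counts.

**Gene content.** The root carries `root_families` families. Along a branch
of length $t$, new families arrive as a Poisson process with rate
`gain_rate` and every family present is lost at per-family rate
`loss_rate`; a family gained at position $s$ survives the remaining
$t - s$ with probability $e^{-\ell(t-s)}$. Families gained and lost within
one branch are unobservable anywhere, so they are not represented; the
recorded per-branch gains are the survivors. Under this process the
expected family count at depth $T$ is
$R\,e^{-\ell T} + (g/\ell)\,(1 - e^{-\ell T})$, the birth-death expectation
the test suite checks by Monte Carlo. Because family identifiers are
globally unique, a lost family is never regained — loss is irreversible in
the simulation, which favours parsimony-style reconstruction; see
"Limitations".

**Sequences.** Each family gets one ancestral protein: length geometric
with mean `mean_protein_len` (floor 30, avoiding degenerate alignments),
residues uniform over the 20-letter alphabet. Sequences evolve down the
subtree where the family survives, accumulating
$\mathrm{Poisson}(r \cdot L \cdot t)$ substitutions per branch, each
replacing a site with a uniformly chosen *different* residue. This uniform
model keeps the identity-divergence relationship analytic and monotone;
there are no indels, so within-family members are equal-length. Between
families, sequences are independent, giving ~5% background identity.
Defaults (12 genomes, 250 root families, gain 12 and loss 0.08 per unit
height, substitution rate 0.05/site/height, mean length 90) describe an
open-pangenome regime with within-family identity around 85–95% — the
"easy but realistic" end of ortholog detection, scaled down from real
haloarchaeal proteomes (thousands of genes of ~300 residues) to keep the
full pipeline runnable in seconds to minutes. The
`target_genes_per_genome_range` field records the intended per-genome gene
count range for validation; realised counts follow from the rates. An
optional per-family, per-genome `duplication_prob` plants paralogs so the
strict-core filter can be exercised.

## Ortholog clustering

The similarity stage is a self-contained, desk-scale analogue of an
all-vs-all BLASTP: Smith–Waterman local alignment under BLOSUM62 with
affine gaps (open 11, extend 1), an E-value surrogate, and a k-mer
prefilter (pairs sharing at least 3 distinct 4-mers are aligned; unrelated
uniform-background pairs share essentially none, while pairs above ~50%
identity share dozens). The decision contract — coverage and E-value
thresholds — is unchanged from the tool it stands in for, and an adapter
(`read_blast_tsv()`) accepts externally computed tabular hits for real
data.

**E-values.** Local alignment scores of unrelated sequences follow a
Gumbel law; `calibrate_evalue()` fits $(\lambda, K)$ by the method of
moments on a few hundred uniform-random decoy pairs and
`estimate_evalue()` applies $E = K\,m\,N\,e^{-\lambda s}$. The calibration
is computed once per session on a fixed internal seed; a decoy test checks
that the predicted fraction of pairs with $E \le 1$ matches the empirical
one.

**Hit filter.** Defaults keep hits with coverage $\ge$ 75% and E-value
$\le 10^{-10}$; the coverage threshold is applied to *both* query and
subject spans (a `coverage_mode = "query"` flag relaxes this), since
"coverage of the pairwise alignment" without both-side control lets short
domain matches through. The `min_identity` floor (default 0) supports the
30%-identity screening mode used for horizontal-transfer candidate scans.
The E-value cutoff is treated as $\le$.

**BDBH + MCL.** For each protein and each other genome, the best hit is
the top score (ties: lower E-value, then lexicographic subject id); an
undirected edge requires reciprocity. Reciprocal best non-self hits within
a genome are kept as paralog support. Edge weights are
$-\log_{10}(\max(E, 10^{-180}))$ — the floor avoids infinite weights; the
larger of the two directed E-values is used, the conservative choice.
Markov clustering then runs per connected component (clusters can only
refine components, so this is exact, and it keeps matrices small):
column-stochastic normalisation, expansion (matrix squaring), inflation
(default 1.5, the customary OrthoMCL value), pruning below $10^{-5}$, to a
$10^{-6}$ fixed-point tolerance. Self-loops weighted by the column maximum
stabilise the iteration. Clusters are read off attractor rows; a node
claimed by several attractor systems goes to the larger cluster, ties
broken lexicographically, so the output is a deterministic partition
independent of node input order.

## Occupancy partition

With $G$ genomes, a family's occupancy is the number of genomes carrying
it. Core = occupancy $G$; softcore = occupancy $\ge \lceil 0.95G \rceil$
(so 106 of 111, for instance), reported as a superset of core, as
conventionally displayed; for downstream arithmetic the disjoint
"softcore-only" set is used. The cloud is defined from the modal
occupancy $M$ among non-softcore families (ties to the smallest): cloud =
occupancy $\le M + 1$; shell is the remainder. The "+1 neighbouring
class" offset is configurable; this formalises the common "most populated
non-core cluster and its neighbours" heuristic, whose exact published
form varies between tool versions. The strict core keeps core families
with exactly one member in every genome — the single-copy orthologs used
for concatenated trees.

## Pan/core size curves and openness

For random genome orderings (default 10, seeded; all $G!$ orderings are
enumerated exactly when requested and feasible), the pan size (union),
core size (intersection) and new-family count are recorded as genomes are
added. Each curve is fitted with the Tettelin exponential
$F(n) = \kappa\,e^{-n/\tau} + \Omega$. For fixed $\tau$ the model is
linear in $(\kappa, \Omega)$, so the fit profiles the residual sum of
squares over $\tau$ (80-point log grid on $[0.1, 10G]$, then a local
optimisation to $10^{-10}$) and solves the linear part exactly. This is
deterministic, recovers exact parameters on model-generated curves, and
degrades gracefully on near-flat curves (a constant curve returns
$\kappa = 0$ with the constant as offset) — the regime where generic
3-parameter exponential fits are badly conditioned. Openness is decided
on the *new-genes* curve: the pangenome is open iff its fitted asymptote
$\Omega$ (expected new families per additional genome) exceeds 1 family.
For core fits, `saturation_n` reports the smallest $n$ at which the
exponential term falls below 1% of $|\kappa|$ — an explicit, reproducible
stand-in for "how many genomes suffice to see the core", not a claim of
equivalence with any particular published criterion.

## Trees

**Core-gene tree.** Strict-core families are aligned by an in-repo
progressive aligner: guide order from average-linkage clustering of
pairwise 3-mer distances, profile-profile merges by global affine-gap
dynamic programming (the horizontal gap state folds into a running
maximum, making the DP row-vectorised). External MSA tools are not
reimplemented; any externally computed alignment or guide tree can be
substituted. Alignments are concatenated in cluster-name order; distances
are Poisson-corrected, $d = -\ln(1 - p)$, with $p$ the fraction of
differing sites under complete deletion by default (pairwise available);
$p \ge 1$ raises a saturation error naming the pair. Trees come from
Saitou–Nei neighbor joining (negative branches clamped to zero, deficit
moved to a sister edge), then minimum-evolution refinement: hill-climbing
over NNI rearrangements with OLS branch re-estimation, accepting only
length reductions — tree length never increases. Bootstrap support
resamples concatenated columns (default 500 replicates, seeded) and
reports bipartition percentages.

**Pan-genome tree.** Family presence/absence forms binary characters;
with 0/1 states, unordered multistate parsimony reduces to Fitch
counting. The search is random stepwise addition plus NNI over several
restarts (seeded); an all-constant matrix returns a star tree with score
0 and a warning.

## Ancestral gene content (Wagner/Sankoff parsimony)

Per family, a Sankoff dynamic program over states (presence 0/1 by
default; copy numbers 0..cap in count mode) minimises total event cost
with per-unit costs `gain_cost` (default 2) and `loss_cost` (default 1),
plus one origination charge of `gain_cost` per copy present at the root —
the family had to arise somewhere, and without this charge a family
confined to one clade would be "free" at the root and everything would
be reconstructed as ancestral. The gain-2/loss-1 default is the
gain-penalty convention of gene-content parsimony tools when the
"gain/loss cost" dial is set to 2; the symmetric (2, 2) reading is one
argument away. The DP is vectorised across families (two cost matrices
for presence mode), so thousands of families reconstruct in milliseconds.

Ties in the top-down pass prefer the parent's state, which minimises
spurious events. Root ties are resolved toward *presence*: the
origination charge already penalises root presence, and presence-at-tie
makes symmetric unit costs realise exactly the Fitch change count (with
absence-at-tie there are tied optima whose realised event count exceeds
the Fitch minimum — e.g. a family in three leaves of a balanced
four-leaf tree). The reported per-family cost is the realised per-branch
event cost, so an invariant family costs 0; the origination-inclusive DP
objective is returned separately and is what the exhaustive-enumeration
tests check.

`classify_lca()` decomposes a target node's pool into *derived* families
(gained on the branch entering the node) and *ancestral* families
(present at the node and its parent). Percentages are truncated to one
decimal — the reporting convention under which a 44.84/55.16 split prints
as 44.8/55.1 and the pair may sum to 99.9.

## Pipeline, seeds, and the evaluation harness

`run_pipeline()` chains the stages with stage-named errors and writes
every artifact as it goes; the summary contains no paths or timestamps,
so identical configurations (including the master seed) produce
byte-identical `summary.json`. Each stochastic stage draws its own seed
deterministically from the master seed. `evaluate_against_truth()` scores
a synthetic run: adjusted Rand index of clusters against planted
families, Robinson–Foulds distance of the core tree to the true tree,
precision/recall of per-branch gain events (reconstruction rerun on the
true tree so branches correspond; clusters mapped to families by member
majority), and the relative error of the root family count.

Default problem sizes in the shipped tests — 6–12 genomes, 60–300
families, proteins of mean length 60–90, 10–100 bootstrap replicates —
were chosen so the complete benchmark, including two full pipeline runs,
executes in a few minutes on one core while leaving every recovery
property comfortably attainable; they are the package's reference
conditions, not tuning knobs.

## Limitations

* The simulator has no indels, no rate heterogeneity, no realistic
  substitution matrix, no gene conversion and no convergent re-gain of a
  lost family. Passing recovery tests therefore shows the pipeline is
  correct *under its own model assumptions*; it does not show that real
  haloarchaeal data would be clustered or reconstructed this well.
* The E-value surrogate is calibrated on uniform-composition decoys; real
  proteomes have biased composition and low-complexity regions, for which
  dedicated search tools remain preferable (and can be plugged in via the
  tabular-hit adapter).
* The progressive aligner is adequate for high-identity single-copy
  families at desk scale; deeply diverged or indel-rich families should
  be aligned externally.
* Asymmetric gain costs deliberately bias reconstruction toward calling
  clade-confined families "derived"; with frequent parallel loss the
  root size can be overestimated. The cost grid is exposed so this
  sensitivity can be examined.
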