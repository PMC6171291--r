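---
title: "Delimiting bacterial taxa by genome-wide exclusivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting bacterial taxa by genome-wide exclusivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(exclutax)
```

## The problem and the statistic

Whether bacterial species are real entities is contested because horizontal
gene transfer (HGT) gives different genes different genealogies: no single
gene tree is "the" history of a genome, and monophyly is undefined at the
genome level. `exclutax` takes the genealogical view that taxa should be
*exclusive*: every member of the group is more closely related to every
other member than any member is to any genome outside the group, with
relatedness averaged over the whole genome.

Relatedness between two genomes $i, j$ is the mean of their patristic
(cophenetic) distances over the $G$ core-gene trees:

$$\bar d_{ij} = \frac{1}{G}\sum_{g=1}^{G} d^{(g)}_{ij}.$$

For a group $C$ of genomes the **exclusivity score** is

$$E(C) \;=\; \min_{i \in C,\, k \notin C} \bar d_{ik}
        \;-\; \max_{i,j \in C} \bar d_{ij},$$

the minimum distance out of the group minus the maximum distance within
it. $E(C) > 0$ means the group is exclusive; larger scores mean a wider
margin. Singletons have $\max_{i,j\in C}\bar d_{ij} = 0$ and are trivially
exclusive. The score is invariant to adding a constant to all distances
and scales linearly with them, so it is comparable across clock rescalings
of the input trees.

Exclusive groups form a laminar family (any two are nested or disjoint),
and every group with a positive score appears as a clade of the UPGMA tree
of $\bar d$: while such a group is only partly merged, any average
distance between two of its sub-clusters is at most $\max_{i,j\in C} \bar
d_{ij}$, which is strictly smaller than any cluster average involving an
outsider, so the group coalesces completely before joining anything else.
`enumerate_exclusive_groups()` exploits this guarantee — it scores the
$n-2$ non-root clades of the UPGMA tree instead of the $2^n$ subsets — and
the test suite verifies the guarantee against exhaustive subset search for
$n \le 12$.

## Pipeline stages and their parameters

**Orthology** (`filter_hits()`, `reciprocal_best_hits()`,
`mcl_cluster()`). Pairwise protein hits are screened by E-value
($\le 10^{-3}$), HSSP distance ($\ge 20$), and match length ($\ge 30\%$ of
the shorter sequence; the denominator is configurable to the longer one).
The HSSP distance is percent identity above the length-dependent homology
threshold curve $480\,L^{-0.32(1+e^{-L/1000})}$ for $11 < L \le 450$,
constant $19.5$ beyond; alignments of $\le 11$ residues are below the
curve's domain and fail outright. Edges require reciprocal best hits
(ties on bit score break by lower E-value, then smallest subject id, so
results are independent of input order) and $\ge 60\%$ global amino-acid
identity (BLOSUM62, gap open 11 / extend 1, identical columns over all
alignment columns; when sequences are unavailable a local-alignment proxy
$\mathrm{pid} \cdot L / \max(q\mathrm{len}, s\mathrm{len})$ is used and
flagged). Markov clustering runs at inflation 1.8 with self-loops equal to
each vertex's maximum incident weight, convergence $10^{-8}$, 200
iterations; these loop/convergence details are fixed for determinism, and
edge weights default to bit scores. Genomes are kept when they carry at
least $\lceil 0.957 \cdot |\text{reference core}|\rceil$ of the clusters
shared by all trusted complete genomes.

**Trees** (`upgma()`, `jaccard_matrix()`). UPGMA uses proportional
(size-weighted) averaging — classic UPGMA rather than WPGMA, matching the
default of the clustering implementations in common use; WPGMA is exposed
as an option. Equal minimal merge distances break by the
lexicographically smallest member label, then the smaller second label,
making the merge schedule a pure function of the labeled matrix. The
gene-content distance is the binary Jaccard distance, which ignores
shared absences, so the enormous number of clusters absent from any two
genomes carries no signal of relatedness.

**Congruence** (`robinson_foulds()`, `random_rf_null()`). Trees are
compared on non-trivial unrooted bipartitions; rooted inputs are unrooted
first because a UPGMA tree is compared against trees whose root carries
no information. The null model is two independent uniform fully resolved
unrooted topologies. The expected number of shared splits is computed
exactly as $\sum_a c_a p_a^2$, where $c_a$ counts the possible splits with
side sizes $(a, n-a)$ and $p_a = (2a-3)!!\,(2(n-a)-3)!!/(2n-5)!!$ is the
probability a uniform tree contains one of them; the expectation is
validated against exhaustive enumeration of all topologies for
$n = 4$–$6$ and Monte-Carlo sampling at $n = 10, 20$. Tail probabilities
use a Poisson approximation to the shared-split count with that exact
mean (which tends to $1/8$ as $n$ grows), evaluated entirely in log10
space because the interesting probabilities (e.g. $10^{-1225}$ at
$n = 701$) are far below double-precision underflow.

**Gain/loss mapping** (`fitch_gains_losses()`, `map_pan_genome()`).
Binary presence characters are mapped onto a rooted tree by Fitch
parsimony, generalized to multifurcations by the frequency
(Hartigan-style) rule, which preserves the global minimum for two states.
When the root's state set is ambiguous it resolves to *absent*: auxiliary
genes missing from the core genome are parsimoniously ancestrally absent,
which matches the strong excess of gains over losses expected when gene
content is acquired laterally; the opposite convention is available via
`root_state = 1`. The top-down pass keeps the parental state wherever a
node's set allows, counting $0\!\to\!1$ transitions as gains and
$1\!\to\!0$ as losses. Per-branch averages divide by the $2n-3$ branches
of the unrooted resolved tree.

**Delimitation** (`delimit_species()`). Species are the most inclusive
UPGMA clades that are exclusive at the configured slack and whose members
satisfy the joint threshold ANI $\ge 96.5\%$ and AF $\ge 0.60$ (both
inclusive). The tree is walked from the root; the first qualifying clade
on each root-to-tip path wins and its descendants are not revisited, so
nestedness guarantees a partition; unclaimed genomes become singleton
species. Under complete linkage every within-group pair must meet the
threshold. Under single linkage the group's threshold graph must be
connected: each member then meets the threshold with at least one other
member, but a clade that merely unites two internally-cohesive,
mutually-dissimilar blocks is rejected and resolution descends to its
children. We chose connectivity over the looser "at least one partner"
reading (available as `linkage = "single_literal"`) because the looser
rule would let any exclusive union of whole species qualify, collapsing
the partition toward the root and breaking exact recovery of planted
species in simulation; connectivity is also what single-linkage
clustering at a similarity cutoff produces. Pairs absent from the
similarity table conservatively fail the threshold (splitting rather
than lumping). The slack (`exclusivity_slack`, default 0; 0.01 as the
relaxed variant) admits clades whose score is marginally negative, which
protects against minor distance-matrix noise breaking large
near-exclusive groups; stored scores are always raw and the slack applies
only at classification time.

**ANI/AF input.** ANI tools report two directed values per genome pair;
`read_pair_similarity()` combines them by the arithmetic mean (order
invariant and conventional), with minimum as the conservative
alternative; a pair seen in one direction is used as-is with a warning.

## What the synthetic generator emulates

`simulate_scenario()` produces data with the statistical structure the
method assumes, so every stage is testable without downloads:

* a clock-like species tree of depth 1 with `n_species` planted clades:
  within-species subtrees of depth 0.05 grafted onto a coalescent
  backbone whose internal nodes all sit above height 0.3, giving
  unambiguous within/between separation;
* gene trees copied from the species tree and perturbed by a Poisson
  number of horizontal transfers, each implemented as a time-consistent
  prune-and-regraft: a lineage alive at a uniformly drawn time moves onto
  a contemporaneous donor edge, so gene trees stay ultrametric while
  topologies and path lengths diverge; a lognormal rate multiplier (unit
  mean, $\sigma = 0.25$) rescales each gene. The default of 4 transfers
  per gene was calibrated once so that patristic matrices of different
  genes correlate at mean $R^2 \approx 0.44$, the level observed between
  real core genes;
* auxiliary gene content: each cluster originates at a point chosen
  uniformly along the tree's total branch length and evolves below it by
  a two-state gain/loss Markov process (defaults 0.2 / 0.7 per unit
  time), reproducing the single-origin-with-subsequent-loss structure
  that makes pan-genome content phylogenetically informative;
* ANI and AF generated as decreasing exponentials of genome distance
  ($100\,e^{-0.3 d}$ and $e^{-0.5 d}$) with optional Gaussian noise; the
  scales put within-species pairs above the 96.5%/0.60 threshold and
  between-species pairs below it, as the real threshold does for
  well-sampled genera.

What the generator does **not** emulate: recombination tracts and
site-level sequence evolution (trees are perturbed directly, so there is
no alignment/tree-estimation error), rate variation along branches,
biased donor–recipient transfer preferences, correlated gain/loss across
clusters, and the extreme genome-count and cluster-count scales of real
surveys. Passing tests therefore demonstrate correctness of the
statistics and the delimitation logic under the stated generative
assumptions, not robustness to every artifact of real data.

## Numerical choices and degenerate inputs

* Distance matrices must be symmetric to $10^{-9}$ with zero diagonals;
  the symmetric average is enforced exactly on input. Distances serialize
  with 10 significant digits; tests compare at $10^{-8}$.
* UPGMA merge heights are mathematically non-decreasing; decreases beyond
  $10^{-9}$ (relative) abort, smaller ones are clamped (floating-point
  jitter).
* Scoring the full label set is an error (no outside genome exists)
  unless `permissive = TRUE`, which returns `min_out = Inf`; the UPGMA
  root clade is therefore never scored, while both clades flanking the
  root are.
* An all-equal ("star") matrix yields score 0 for every clade: nothing is
  exclusive at slack 0, everything at positive slack.
* Multifurcating trees are accepted everywhere: they contribute fewer
  bipartitions, and the Fitch engine handles multi-child nodes by the
  frequency rule.
* `brute_force_exclusive_groups()` refuses more than 15 taxa ($2^n$
  guard); it exists as an oracle, not a production path.
* Problem sizes in the shipped tests — 100 random matrices up to
  $n = 40$ for the UPGMA oracle, 200 matrices up to $n = 12$ for the
  enumeration oracle, all characters on trees up to 8 leaves for the
  Fitch oracle, $10^4$ Monte-Carlo tree pairs for the RF null, 20-plus
  replicates for the HGT-erosion property — were chosen to make each
  comparison exhaustive or statistically decisive at desk scale.

## Known limitations

* The Poisson tail of the RF null is an approximation (exact far beyond
  reach for large $n$); its expectation is exact, and the tail agrees
  with the reference computation to the order of magnitude.
* Exclusivity at slack $> 0$ loses the laminar-family guarantee in
  principle; the implementation still reports only UPGMA clades, so the
  output remains a partition.
* Fitch parsimony weights gains and losses equally; reported totals are
  minimum estimates, and the root-absent convention shifts ambiguous
  changes toward gains by design.
* The delimitation is fully automatic; deciding whether a delimited
  exclusive group deserves a Linnaean name remains a human judgment, and
  no rank other than species is assigned.
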