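---
title: "Cross-tissue trait-pathway networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue trait-pathway networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspath)
```

## The problem

Complex metabolic disorders such as obesity-induced type 2 diabetes involve
coordinated dysfunction across several tissues — pancreatic islets, liver,
adipose, muscle, hypothalamus — and express themselves in a panel of
quantitative traits (plasma glucose, insulin, body weight, circulating
adipokines, ...).  Single-gene co-expression networks in this setting are
noisy and miss gene sets whose members shift subtly but consistently.  This
package works at the pathway level instead: it scores the activity state of
every annotated pathway in every tissue of every animal, links pathway
states to each other and to the measured traits, and analyzes the topology
of the resulting cross-tissue trait-pathway network.

## The Pathway Connectivity Index

For one tissue, let $e_{is}$ be the log-ratio expression of gene $i$ in
animal $s$.  Each gene is normalized to zero mean and unit variance across
the animals ($z_{is}$), then passed through a centered sigmoid

$$h_{is} = \frac{1}{1 + e^{-z_{is}}} - \tfrac12 \in (-0.5, 0.5),$$

which preserves the sign (up/down-regulation) while damping extreme values.
Given a pathway with $N$ scored member genes and a gene functional network
with link probabilities $a_{ij} \in [0, 1]$ (with $a_{ii} = 1$), the
Pathway Connectivity Index of that pathway in animal $s$ is

$$\mathrm{PCI}_s = \frac{1}{N} \sum_{i \le j}
  \mathrm{sgn}(h_{is} + h_{js})\, \sqrt{|h_{is}|}\; a_{ij}\, \sqrt{|h_{js}|}.$$

Each term carries the joint regulation status of a gene pair (the sign),
a symmetric magnitude (the square roots), and the confidence that the two
genes functionally interact ($a_{ij}$).  Diagonal terms reduce to $h_{is}$,
so every gene contributes even without annotated partners, and genes with
many or strong links — hubs — contribute more.  Division by $N$ makes
scores comparable across pathway sizes.

Two details of the score are genuinely open design choices: whether the
self terms belong in the sum, and whether the normalization is $1/N$ or one
over the number of summed pairs.  The defaults here are *include the
diagonal* and *divide by $N$* (the diagonal is what lets a pathway without
any internal links still track its members' mean regulation; $1/N$ avoids
double-penalizing large pathways whose pair count grows quadratically).
Both are switchable via `include_diagonal` and `normalization` in
`compute_pci()` / `pci_matrix()`, and every downstream step is invariant to
the choice of z-score denominator because only ranks are used; the sample
($n-1$) standard deviation is used as is conventional at small $n$.

Degenerate inputs are handled explicitly: zero-variance genes get all-zero
z-scores (with a warning) rather than NaNs; pathway members without
expression data are dropped and $N$ counts only scored genes; a pathway
with no scored members is skipped with a warning.

## The pathway coordination network

Nodes are (pathway, tissue) pairs.  A pair of nodes is a *candidate* edge
when the two pathways are curated as linked in the pathway database (taken
across every tissue combination: same tissue or two different tissues) or
when the same pathway appears in two different tissues.  Candidacy is a
hard gate — no other pair is ever connected — reflecting that the curated
link set defines which coordinations are interpretable.

A candidate becomes an edge when the absolute Spearman correlation of the
two PCI rows across animals passes a permutation-calibrated threshold.
Spearman (Pearson on mid-ranks) is used because only monotone association
is assumed; the package verifies end-to-end that any strictly monotone
per-row rescaling of the PCI matrix leaves all downstream results
unchanged.  Correlation signs are kept as edge attributes; thresholding is
on $|r|$.

The null is built by randomly permuting gene-row labels within each
tissue's expression matrix, recomputing all PCIs and all candidate
pairwise correlations each round, and pooling absolute values across
rounds and pairs (one pooled null, since a single threshold is wanted).
Permuting labels within tissue detaches pathway membership from expression
while preserving every animal's value multiset; per-tissue (rather than
global) shuffling keeps each tissue's value distribution intact.  Empirical
p-values use the add-one rule $p(r) = (1 + \#\{\mathrm{null} \ge |r|\}) /
(1 + \#\mathrm{null})$, so $p$ is never zero and is exact under
exchangeability.  `threshold_for_p()` inverts this tail exactly, including
ties.

Tie handling matters at small sample sizes.  With only 5 animals the
Spearman statistic is discrete and the null has an atom of mass
$2/5! \approx 1.7\%$ at $|r| = 1$; consequently **no** correlation attains
$p < 0.005$ in a 5-animal group, and `threshold_for_p()` honestly returns
a threshold just above the null maximum.  Group-specific analyses
(`group_analysis()`) therefore default to a fixed operating threshold of
$|r| \ge 0.7$, with permutation recalibration available for larger groups.
With 40 animals the calibrated threshold at $p < 0.005$ lands near
$|r| \approx 0.45$ on the default synthetic scale, and 1000 permutation
rounds give ample resolution ($1/(1 + 1000 \cdot \#\mathrm{pairs})$).

## Traits: relevance, linking, refinement

A (pathway, tissue) node is *relevant* to a trait when $|\rho|$ between
its PCI row and the trait across animals is significant.  No single
canonical rule exists for what counts as significant here, so the package
mirrors the network machinery: an empirical null from permuting the animal labels of the trait
vector (1000 rounds, pooled across nodes) with the same $p < 0.005$
cutoff; a fixed-$|r|$ mode (`r_threshold`) is also provided.  Missing
trait values are dropped pairwise; constant or nearly absent traits yield
empty relevant sets with a warning rather than an error, since a trait can
legitimately carry no signal in a subset of animals.

*Linking* pathways connect two traits by one of three rules: **direct** —
relevant to two or more traits; **path2** — relevant to at least one trait
and adjacent to a node relevant to a trait it is not itself relevant to
(both endpoints are marked when each qualifies); **path3** — adjacent to
nodes whose combined relevance covers two or more traits (a single
neighbor relevant to both traits suffices; the node itself need not be
relevant to anything).  A node receives every class it satisfies.  These
rules are validated against an exhaustive enumeration oracle on random
graphs.

The merged trait-pathway network contains the trait nodes, the relevant
and linking pathway nodes, co-expression edges restricted to that node
set, and trait-pathway relevance edges.  *Refinement* focuses the network
on interactive, trait-proximal pathways: one pass that first removes
pathway nodes of degree 0 or 1 and then removes nodes whose shortest-path
distances to their two nearest traits sum to more than 6 (unreachable
counts as infinite, so nodes seeing fewer than two traits are dropped).
The degree filter precedes the distance filter, so trait distances are
computed on the already degree-pruned graph, and they are computed on the
merged graph including trait nodes, since "distance to a trait" requires
traits in the graph.  An iterative mode (`iterate = TRUE`) repeats both filters to a
fixed point; the single pass is the default and the refined node set is
always a subset of the input's.

## Topology analytics

Degree distributions are reported as counts in 10 evenly spaced bins on
the natural-log degree axis (half-open bins, last bin closed), the
representation in which a power-law regime is linear.  Betweenness uses
Brandes' algorithm (via igraph), unnormalized, counting each unordered
pair once and excluding endpoints — the convention under which only
relative rankings matter.  Densely connected subregions use a
reimplementation of the MCODE procedure with its published defaults
(vertex weight percentage 0.2, haircut on, fluff off); haircut is applied
repeatedly so every reported cluster member has within-cluster degree at
least 2.  Enrichment questions — is a pathway category over-represented in
the network within a tissue; does a node realize more of its candidate
interactions than the network-wide rate — are Fisher exact tests, the
latter on the table $[[k_v, O_v - k_v], [K - k_v, (O - O_v) - (K -
k_v)]]$ with $k_v$ the node degree, $O_v$ its candidate opportunities and
$K, O$ the network totals, followed by Benjamini-Hochberg adjustment.
The opportunities-based contingency construction is a design choice: it
asks exactly the "enhancement relative to what curation permits"
question.

## The synthetic cohort generator

The generator emulates the structure of a two-strain, two-obesity-status,
two-age, five-replicate multi-tissue expression study (40 animals, 8
groups, every animal profiled in every tissue) with log10-ratio values:

* **Pathways** get disjoint core memberships from a common gene universe
  plus 10% overlapping members; curated links are sampled at density 0.05;
  five category labels emulate top-level pathway classification.
* **Gene network**: same-pathway gene pairs are linked with probability
  0.5 (weights uniform on (0.5, 1]), other pairs with probability 0.01
  (weights uniform on (0, 0.5]); annotated functional partners thus carry
  denser, stronger linkage evidence, as in probabilistic functional
  networks.
* **Expression**: baseline noise is i.i.d. Normal(0, 0.2) per gene and
  animal — 0.2 is a realistic per-gene SD on the log10-ratio scale of
  two-color arrays.  For each planted (group, pathway, tissue) a single
  latent shift ~ Normal(0, 1) (five times the noise SD) is added to all
  member genes in all animals of the group.  A shared shift is the
  simplest mechanism that makes member genes — and therefore PCIs of
  co-active pathways — co-vary across animals; the gene network plays no
  role in the noise model, which is why `generate_expression()` does not
  take it.
* **Traits**: each of the eight default traits is a linear combination of
  the z-scored PCI rows of its planted drivers (effect 1 SD) plus
  Normal(0, 0.2) noise, i.e. planted effects are five times the trait
  noise.  Spearman-based detection is invariant to monotone links, so
  linearity is without loss of generality.  Planted co-active pathway
  pairs are forced into the curated link set so that their coordination is
  detectable by the curation-gated network.

The default scale — 60 pathways, 1200 genes, 3 tissues, 40 animals — keeps
a full pipeline run (including a 1000-round permutation null) around a
minute; the full emulated scale (187 pathways, 6 tissues) is available by
passing the corresponding arguments.  The test suite runs null calibration
at 500 permutation rounds over 5 seeds and driver recovery over 20 seeds
at this default scale.

What the generator does **not** emulate: probe-level artifacts, dye bias,
array normalization, correlated baseline noise between genes outside
planted pathways, strain- or age-specific baseline differences, and
missing values.  Passing tests therefore demonstrate that the pipeline's
statistics are calibrated and that planted structure of realistic
magnitude is recovered — not that every biological confounder of real
microarray data is handled.

## Calibration and recovery, concretely

Two properties anchor the test suite.  On effect-free cohorts the full
pipeline at $p < 0.005$ declares a fraction of candidate pairs
co-expressed that is binomially consistent with 0.005, and trait-relevance
p-values are approximately uniform.  On planted cohorts with effects five
times the noise, the planted (trait, pathway, tissue) drivers are
recovered with sensitivity well above 0.8 while planted-free pathways are
rejected with specificity above 0.95.  Specificity is assessed over
planted-free pathways deliberately: pathways that share planted group
shifts genuinely correlate with each other's traits, so counting them as
false positives would conflate true correlation with error.

## Known limitations

* Curated gating means the network can never propose a pathway pair absent
  from the curated link set; discovery is bounded by annotation quality.
* The pooled permutation null assumes candidate pairs are exchangeable;
  pathway-size-specific null differences are diluted rather than modeled.
* Group-specific networks at $n = 5$ cannot reach $p < 0.005$ under an
  exact permutation null (see above); fixed-threshold operation is the
  honest alternative and is what `group_analysis()` does by default.
* MCODE output depends on its seed ordering for overlapping dense regions;
  only the plug-in's default parameterization is validated here.
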