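---
title: "Aligning food webs by motif roles: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning food webs by motif roles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwalign)
```

## The problem

Food webs from different ecosystems differ in size, connectance, and many
summary statistics, yet they keep being described by the same small set of
structural regularities. One way to reconcile both observations is to ask
whether every web contains a *backbone of interactions* — a connected core
of species that play equivalent ecological roles and interact in the same
way everywhere — surrounded by a periphery of idiosyncratic species.
`fwalign` implements the machinery needed to ask that question with data:
it aligns pairs of directed food webs species-by-species, quantifies how
good each alignment is, and mines the full set of pairwise alignments for
consistently co-aligned substructure.

Throughout the package a link `(resource, consumer)` points in the
direction of energy flow. Self-loops (cannibalism) are accepted on input
but stripped before any motif or alignment computation, because the role
definition below is built on loop-free 2- and 3-species subgraphs.

## Species roles and role similarity

The role of a species is defined by where it sits inside the small
building blocks of its web. Enumerating all weakly connected directed
graphs on two and three nodes gives 2 + 13 motifs; collapsing the nodes of
each motif under its automorphism group leaves 3 + 30 *position orbits*.
The role profile $\vec c_a$ of species $a$ is the 33-vector counting, for
every orbit, how many induced 2- or 3-species subgraphs place $a$ in that
position. `build_motif_catalog()` constructs the catalog by brute force
over the $2^6$ labelled 3-node digraphs (no canonical-labelling library is
needed at this size) and `count_roles()` fills the profiles with an exact
triad census written in C++ (a naive $O(S^3)$ R scan serves as the test
oracle).

Role similarity is the Pearson correlation

$$\rho(a, b) = \frac{\operatorname{cov}(\vec c_a, \vec c_b)}
  {\sigma_{\vec c_a}\, \sigma_{\vec c_b}} \in [-1, 1],$$

equal to 1 for equivalent roles and −1 for opposite ones. Pearson is
undefined for a constant profile (e.g. an isolated species); the package
defines $\rho = 1$ when the two profiles are elementwise equal and $\rho =
0$ otherwise, so that identical degenerate roles align freely while
mismatched ones are neutral. The two-species motifs are included by
default (`max_n = 3`, `include_two_node = TRUE`); a 30-slot,
three-species-only variant is available since the literature uses both
conventions.

## Alignments and their costs

An alignment $\lambda$ between webs $A$ and $B$ is a set of one-to-one
pairings in which every species of either web occurs exactly once, either
matched or explicitly unpaired. Two cost functions are provided.

The *simple* cost sums the role dissimilarity of every matched pair and
charges a penalty $\varepsilon$ for every unpaired species:

$$e_{AB}(\lambda) = \sum_{(a,b)\in\lambda} \big(1 - \rho(a, b)\big),$$

with each unpaired element contributing $\varepsilon$. The default
$\varepsilon = 1$ is the midpoint of the per-pair cost range $[0, 2]$: an
unpaired species costs as much as a pairing with an uncorrelated partner,
so the optimizer neither shreds alignments into unpaired singletons nor
forces hopeless matches.

The simple cost matches species on their own roles but says nothing about
whether their *neighborhoods* are mutually consistent. The default
*neighborhood* cost therefore scores each pairing $x = (a, b)$ by its
neighbors' pairings:

$$e_{AB}(\lambda) = \sum_{x\in\lambda} \Big(
  \sum_{(\alpha,\beta)\in\lambda_x} \big(1 - \rho(\alpha, \beta)\big)
  + \xi_x \Big),$$

where $\lambda_x$ contains the pairings that join a neighbor of $a$ with a
neighbor of $b$, and $\xi_x = \varepsilon\,(u_a + u_b)$ counts the
neighbors of $a$ not paired with any neighbor of $b$ and vice versa — the
simplest penalty that is linear in the number of locally unmatched
neighbors. An unpaired species contributes $\varepsilon$ times its degree.
By default a neighbor is any in- or out-neighbor; setting
`directed_neighborhood = TRUE` in `align_config()` evaluates prey and
predator neighbor sets separately, for users who want neighbor matching to
respect trophic direction beyond what the role vectors already encode.

Because the optimized cost grows with web size, comparisons across a
dataset use the size-normalized *alignment quality*

$$\hat e_{AB}(\hat\lambda) = \frac{1}{N} \sum_{(a,b)}
  \big(1 - \rho(a, b)\big),$$

the mean dissimilarity over the $N$ real-to-real matches; unpaired species
contribute nothing (their similarity is fixed at 1). A degenerate
alignment with $N = 0$ is assigned the maximal quality 2 so it can never
masquerade as a good one.

## The optimizer

`optimize_alignment()` minimizes the configured cost by simulated
annealing over bijections between the two species sets, the smaller one
padded with dummy species (a dummy partner marks an unpaired species). The
schedule is deliberately conventional:

* **moves** — swap the partners of two uniformly chosen species;
* **initial temperature** — `"auto"` probes 200 random swaps and sets
  $T_0$ so that roughly 80% of uphill moves would be accepted;
* **stage length** — `50 * max(|A|, |B|)` proposals, then geometric
  cooling by 0.95;
* **stopping** — 20 stages without improvement, or $T < 10^{-6}$, or a
  cost of zero (which cannot be improved);
* **restarts** — 5 independent runs from fresh random states (restart $r$
  uses `seed + r - 1`); the best-ever state wins;
* **polish** — a final first-improvement swap descent, so the returned
  alignment is always locally optimal.

Every stochastic draw comes from R's seeded generator, so results are
bit-reproducible given `config$seed`, and the pair of webs is
canonicalized internally so that aligning $(A, B)$ and $(B, A)$ gives the
same answer. Swap proposals are evaluated incrementally in C++ — only the
cost terms touching the two swapped pairings change — and the test suite
cross-checks the incremental evaluation against an independent, pure-R
spelling of both cost functions, as well as against exhaustive enumeration
(`exhaustive_alignment()`) on webs small enough to scan all bijections.

## Ensemble analyses

`all_pairs_align()` runs the $n(n-1)/2$ optimizations for a web set
(computing role profiles once per web, deriving per-pair seeds from the
global one, and optionally caching finished pairs as JSON so interrupted
runs resume) and assembles the dissimilarity matrix $\hat E$. Downstream:

* `rank_species()` averages $\rho$ over every pairing a species takes part
  in — its tendency to align well — optionally split into same- and
  cross-ecosystem partners. Unpaired occurrences are excluded from the
  mean rather than counted as failures, to avoid penalizing species from
  webs of very different sizes.
* `alignment_transitivity()` asks, for a species paired with $b$ in one
  web and $c$ in another, how often $b$ and $c$ are themselves paired: the
  fraction of closing partner-web pairs. Species with fewer than two
  real partners get `NA`, not 0. `transitivity_null()` re-draws the
  partners within every alignment uniformly (keeping each alignment's
  number of real pairings fixed) to give the chance expectation.
* `path_connectedness()` measures, inside the subweb induced by a species
  set, the fraction of pairs joined by an undirected path — 1 exactly when
  the induced subweb is connected. The induced subweb is used
  deliberately: the question is whether the best-aligned species form a
  connected component *on their own*, not through intermediaries.
  `path_likelihood_test()` compares against equally sized uniform random
  subsets with the permutation p-value $(1 + \#\{null \ge obs\})/(n+1)$.
  The "best-aligned" set defaults to the top quartile of species by mean
  role similarity, a cutoff exposed to the user since no principled value
  exists.

## Backbones

`link_overlap()` weights each link of a web by the number of alignments in
which its two endpoints map onto species that are themselves linked *in
the same energy-flow direction* — directionality is the point of the whole
method, so a reversed image does not count. The k-link backbone is the
top-k links by weight, with ties broken by weight descending then
lexicographic `(resource, consumer)`: determinism matters more than any
particular tie convention. Backbones are re-aligned with the same
optimizer to give $E_k$; entries are raw optimal costs rather than
normalized qualities because all k-link backbones have the same size (a
flag switches to qualities).

The number of distinct backbone shapes is chosen by majority vote of three
internal indices — average silhouette width, Calinski–Harabasz on the
principal-coordinate embedding, and Dunn — over PAM (medoid) partitions;
ties go to the smaller count, and an all-equal distance matrix returns the
smallest candidate with a warning. A larger index/method ensemble would be
possible, but three well-understood indices with one clustering method
keep the vote interpretable and dependency-free.

Each cluster is summarized by its medoid: every member backbone is aligned
to it, member links are mapped through the pairing, and a consensus link's
likelihood $l$ is the exact fraction of members whose image contains it
(links with $l < 0.01$ are dropped by default). Member species with no
partner in the medoid are aggregated into a single auxiliary node, so
recurring structure that the medoid happens to lack stays visible.
`strength_test()` checks, for weighted webs, whether backbone links are
stronger than `k` uniformly drawn links.

## Group comparisons

`permanova()` implements the standard one-factor pseudo-F on squared
dissimilarities,

$$F = \frac{(SS_{total} - SS_{within})/(g-1)}{SS_{within}/(n-g)},
\qquad SS_{total} = \tfrac1n \sum_{i<j} d_{ij}^2,
\quad SS_{within} = \sum_g \tfrac1{n_g} \sum_{i<j \in g} d_{ij}^2,$$

with significance by label permutation (default 9999 permutations,
explicit seed) and +1 smoothing so p = 0 is never reported. The degrees of
freedom follow the standard $(g-1, n-g)$ convention.
`pairwise_permanova()` repeats the test per group pair with Holm
adjustment — chosen as the most conservative of the common step-down
corrections, since nothing in the analysis argues for a specific one.
`pcoa()` wraps classical metric scaling (`stats::cmdscale`), dropping
non-positive eigenvalues and reporting the proportion of (positive)
inertia per axis. The test suite verifies the pseudo-F against an
independent spreadsheet-style evaluation and against `vegan::adonis2`, and
checks the permutation test's type-I error at the nominal 5% level.

## Synthetic data

No large public collection of comparably curated food webs ships with the
package, so the generators in `synthgen` are first-class citizens and the
basis of the test suite:

* `niche_web()` — the classic one-dimensional niche model (uniform niche
  values, beta-distributed diet ranges), the field's standard generator of
  ecologically plausible random webs; `er_web()` provides a structureless
  directed Erdős–Rényi null.
* `permuted_copy()` — a uniformly relabeled isomorphic copy with its
  ground-truth map, the oracle for alignment-recovery tests.
* `planted_backbone_ensemble()` — webs sharing an exact copy of a chosen
  backbone plus a fresh periphery per web: random links among periphery
  species and directed periphery → backbone attachment links (the backbone
  species consume idiosyncratic local resources). Defaults: a 6-link star
  backbone, 15 periphery species, periphery connectance 0.1 (the middle of
  the empirically typical 0.05–0.3 range), attachment probability 0.1.
* `toy_web_triple()` — a hand-built triple of four-species webs with stored
  reference alignments realizing both transitivity extremes (a species
  whose partners are mutually paired, and one whose partners never are).

**What the benchmarks do and do not show.** The planted-backbone ensemble
emulates one specific data-generating story: an identical core embedded in
independent random peripheries. Real webs differ in ways the generator
does not attempt — heterogeneous sizes, sampling effort, weighted and
partially observed interactions, and backbones that are themselves only
approximately shared. Passing the recovery benchmarks therefore shows the
pipeline can find a core that is genuinely there; it does not show that
empirical food webs have one. A further caveat is intrinsic to label-level
scoring: an attachment link can place a periphery species in a position
automorphically equivalent to a backbone position (an extra consumer of a
star's center is a seventh satellite, an extra resource of a satellite
mirrors a planted one). Such clone links are structurally
indistinguishable from planted ones, are consistently co-aligned across
webs, and can displace individual planted links from the top-k set even
when the recovered *shape* is exactly the planted one. Recovery rates
counted on link labels are accordingly a conservative lower bound on
structural recovery, and they fall as the attachment probability grows.

## Problem sizes and numerical choices

The shipped tests and benchmarks run at sizes chosen to exercise every
code path at desk scale: tiny webs (3–6 species) wherever exhaustive
enumeration is the oracle, niche webs of 10–50 species for
self/isomorph-recovery, 20-web ensembles over 10 generator seeds for
backbone recovery, and 1000 simulated datasets of 40 webs (199
permutations each) for the PERMANOVA calibration. Other conventions worth
knowing:

* equality of costs is judged at $10^{-12}$ inside the optimizer and
  $10^{-9}$ in recovery assertions;
* backbone top-k ties and cluster-count ties are broken deterministically
  (lexicographic links; smaller count);
* duplicate links collapse to one with a warning; species labels are
  opaque UTF-8 strings compared exactly;
* webs whose resource and consumer sets are disjoint look bipartite and
  are flagged on load but never auto-excluded — the alignment machinery
  assumes unipartite webs, and the decision is left with the user;
* the manifest loader's size filter (5–133 species by default) mirrors the
  range over which pairwise alignment stays tractable and non-degenerate.

## Known limitations

Motif roles stop at three species; larger motifs grow the catalog
combinatorially and are out of scope. The annealer offers no optimality
certificate — only the tiny-web exhaustive oracle, restart consistency,
and the isomorph-recovery tests bound its behavior. Alignment of genuinely
bipartite networks (e.g. plant–pollinator webs) is unsupported, and
interaction strengths never enter the cost function: they are used only
descriptively, in `strength_test()`.
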