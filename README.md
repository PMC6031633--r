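# fwalign — motif-role alignment of directed food webs

`fwalign` compares directed food webs by *aligning* them: it pairs up
species from two webs that occupy equivalent structural positions, scores
how good that alignment is, and mines the full set of pairwise alignments
of a dataset for a shared "backbone of interactions" — a core of species
that interact the same way in every community, surrounded by an
idiosyncratic periphery. It is aimed at community ecologists and network
scientists who want to compare whole interaction structures across
ecosystems rather than summary statistics.

## The method in brief

* **Roles.** Each species gets a role vector $\vec c_a$ counting how often
  it occupies each of the 33 automorphism-distinct positions of the 2- and
  3-species directed motifs. Role similarity is the Pearson correlation
  $\rho(a,b) = \operatorname{cov}(\vec c_a, \vec c_b) /
  (\sigma_{\vec c_a} \sigma_{\vec c_b}) \in [-1, 1]$.
* **Alignment.** An alignment $\lambda$ is a one-to-one species matching
  (unpaired species allowed). The default cost scores each pairing
  $x=(a,b)$ by its neighbors' pairings,
  $e_{AB}(\lambda) = \sum_{x} \big( \sum_{(\alpha,\beta) \in \lambda_x}
  (1-\rho(\alpha,\beta)) + \xi_x \big)$, where $\xi_x$ charges
  $\varepsilon$ per locally unmatched neighbor; a simpler per-pair cost
  $\sum (1-\rho)$ is also provided. Costs are minimized by seeded
  simulated annealing with restarts and a greedy polish, validated against
  exhaustive search on small webs.
* **Quality.** Webs are compared by the size-normalized dissimilarity
  $\hat e_{AB} = \frac1N \sum (1 - \rho(a,b))$ over the $N$ matched pairs.
* **Ensembles.** From all $n(n-1)/2$ alignments of a dataset the package
  builds the dissimilarity matrix $\hat E$ (PERMANOVA, PCoA), ranks
  species by mean $\rho$ across their pairings, computes alignment
  transitivity against a shuffled null, tests the connectedness of
  best-aligned species, extracts per-web k-link backbones from link
  overlap, and clusters backbones into medoid-based consensus structures
  with per-link likelihoods.
* **Synthetic data.** Niche-model webs, relabeled isomorphic copies, and
  planted-backbone ensembles generate all benchmark inputs.

## Worked example

```r
library(fwalign)
webs <- lapply(1:4, function(i)
  niche_web(12, 0.15, seed = i, id = sprintf("web%d", i),
            ecosystem = c("lake", "lake", "stream", "stream")[i]))

res <- all_pairs_align(webs, align_config(seed = 42, restarts = 3))
round(res$matrix, 3)
#>       web1  web2  web3  web4
#> web1 0.000 0.356 0.658 0.477
#> web2 0.356 0.000 0.697 0.559
#> web3 0.658 0.697 0.000 0.592
#> web4 0.477 0.559 0.592 0.000
```

The matrix holds the normalized alignment quality $\hat e$ for every pair:
web1 and web2 are the most similar pair (0.356 — their matched species
disagree by about 0.36 units of role dissimilarity on average), web2 and
web3 the least similar (0.697). Individual alignments expose the actual
species pairings and their role similarities:

```r
aln <- get_alignment(res$store, "web1", "web2")
aln
#> <web_alignment web1 ~ web2> 12 matched, 0 + 0 unpaired; cost 16.65, quality 0.3563
head(aln$rho_pairs, 4)
#>    a   b       rho
#> 1 s1 s12 1.0000000
#> 2 s2  s1 0.9239943
#> 3 s3  s4 0.8566627
#> 4 s4 s10 0.0000000

ranking <- rank_species(res$store, webs, attr(res$matrix, "groups"))
head(ranking, 3)
#>   web_id species mean_rho_all mean_rho_same_ecosystem mean_rho_cross_ecosystem n_pairings transitivity
#> 1   web1      s3        0.803                   0.857                    0.777          3        0.000
#> 2   web1     s12        0.667                   1.000                    0.500          3        0.000
#> 3   web1      s2        0.655                   0.924                    0.521          3        0.333
```

Species `s3` of web1 aligns well everywhere (mean $\rho$ = 0.80 across its
three pairings); the `transitivity` column reports how often its partners
in two other webs are themselves paired. From here,
`permanova(res$matrix)` tests lake-vs-stream structure, `link_overlap()` +
`extract_backbone()` extract each web's most consistently aligned links,
and `backbone_matrix()` + `choose_n_clusters()` +
`cluster_and_consensus()` summarize the recurring backbone shapes. A
command-line front end over the same functions ships in
`inst/cli/fwalign.R` (`Rscript fwalign.R --help`).

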