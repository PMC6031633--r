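Package: fwalign
Title: Motif-Role Alignment of Directed Food Webs and Backbone Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns directed food webs by matching species with similar
    motif-based structural roles. Species roles are vectors of counts over
    the position orbits of all two- and three-species directed motifs; role
    similarity is the Pearson correlation between role vectors. Optimal
    one-to-one species alignments are found by simulated annealing under a
    neighborhood-aware cost function, yielding a size-normalized
    dissimilarity between any two webs. Downstream tools rank species by
    average role similarity across alignments, measure alignment
    transitivity against a shuffled null, test the connectedness of
    best-aligned species, extract per-web interaction backbones from link
    overlap across alignments, cluster backbones around medoids to produce
    consensus structures with per-link likelihoods, and compare groups of
    webs with PERMANOVA and principal coordinate analysis. Includes
    generators for niche-model webs, isomorphic copies, and
    planted-backbone ensembles used as synthetic benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    cluster,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
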