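# Synthetic food-web generators: the niche model, relabeled isomorphic
# copies, planted-backbone ensembles, and a small hand-built three-web
# fixture with reference alignments. All generators are deterministic per
# seed.

#' Generate a niche-model food web
#'
#' Classic one-dimensional niche construction: each species draws a niche
#' value uniformly on (0, 1) and a diet range equal to the niche value
#' times a `Beta(1, 1/(2C) - 1)` variate, centered uniformly between half
#' the range and the niche value; it consumes every species whose niche
#' value falls inside the range. Self-loops are stripped, so realized connectance sits
#' slightly below the target for small webs.
#'
#' @param n_species number of species (>= 2).
#' @param connectance target directed connectance `L / S^2`, in (0, 0.5).
#' @param seed integer seed.
#' @param id web identifier.
#' @param ecosystem optional ecosystem label.
#' @return a [food_web] with species `s1 ... sn` ordered by niche value.
#' @export
niche_web <- function(n_species, connectance = 0.15, seed = 1L,
                      id = sprintf("niche%d", seed), ecosystem = NULL) {
  stopifnot(n_species >= 2)
  if (connectance <= 0 || connectance >= 0.5)
    stop("connectance must lie in (0, 0.5)")
  set.seed(seed)
  n <- n_species
  eta <- sort(stats::runif(n))
  beta <- 1 / (2 * connectance) - 1
  r <- eta * stats::rbeta(n, 1, beta)
  centre <- stats::runif(n, r / 2, pmax(r / 2, eta))
  labels <- sprintf("s%d", seq_len(n))
  links <- NULL
  for (i in seq_len(n)) {
    prey <- which(eta >= centre[i] - r[i] / 2 & eta <= centre[i] + r[i] / 2)
    prey <- setdiff(prey, i)
    if (length(prey))
      links <- rbind(links, cbind(labels[prey], labels[i]))
  }
  food_web(labels, links, id = id, ecosystem = ecosystem)
}

#' Directed Erdos-Renyi web (structureless null generator)
#'
#' @inheritParams niche_web
#' @return a [food_web] in which every ordered species pair is linked
#'   independently with probability `connectance`.
#' @export
er_web <- function(n_species, connectance = 0.15, seed = 1L,
                   id = sprintf("er%d", seed), ecosystem = NULL) {
  stopifnot(n_species >= 2, connectance > 0, connectance < 1)
  set.seed(seed)
  labels <- sprintf("s%d", seq_len(n_species))
  pairs <- expand.grid(r = seq_len(n_species), c = seq_len(n_species))
  pairs <- pairs[pairs$r != pairs$c, ]
  keep <- stats::runif(nrow(pairs)) < connectance
  links <- if (any(keep))
    cbind(labels[pairs$r[keep]], labels[pairs$c[keep]]) else NULL
  food_web(labels, links, id = id, ecosystem = ecosystem)
}

#' Uniformly relabeled isomorphic copy of a web
#'
#' @param web a [food_web].
#' @param seed integer seed.
#' @param prefix label prefix of the copy's species.
#' @return list with `web` (the relabeled copy, id `<id>.perm`) and `map`
#'   (named character vector, original label -> new label), the ground-truth
#'   isomorphism for alignment-recovery tests.
#' @export
permuted_copy <- function(web, seed = 1L, prefix = "p") {
  set.seed(seed)
  n <- n_species(web)
  perm <- sample.int(n)
  new_labels <- sprintf("%s%d", prefix, seq_len(n))
  map <- stats::setNames(new_labels[perm], web$species)
  links <- web$links
  links$resource <- unname(map[links$resource])
  links$consumer <- unname(map[links$consumer])
  copy <- food_web(new_labels, links[, c("resource", "consumer")],
                   id = paste0(web$id, ".perm"),
                   weights = if (is_weighted(web)) links$weight else NULL,
                   ecosystem = web$ecosystem)
  list(web = copy, map = map)
}

#' Ensemble of webs sharing a planted backbone
#'
#' Every generated web contains an exact copy of the `backbone` web (same
#' labels) plus a fresh periphery: random links among periphery species and
#' random attachment links between periphery and backbone species, drawn
#' independently per web. The ground truth marks which links are planted,
#' for backbone-recovery benchmarks.
#'
#' @param backbone a [food_web]; copied verbatim into every ensemble member.
#' @param n_webs number of webs.
#' @param periphery_species periphery size per web.
#' @param periphery_connectance probability of a directed link between two
#'   periphery species.
#' @param attach_prob probability that a given periphery species links to a
#'   given backbone species (a directed periphery -> backbone link: the
#'   backbone species consumes the local resource).
#' @param seed integer seed.
#' @return list with `webs` (list of [food_web]) and `planted` (list of
#'   logical vectors flagging each web's planted links, in link order).
#' @export
planted_backbone_ensemble <- function(backbone, n_webs = 20L,
                                      periphery_species = 15L,
                                      periphery_connectance = 0.1,
                                      attach_prob = 0.1, seed = 1L) {
  stopifnot(n_webs >= 1, periphery_species >= 0)
  webs <- vector("list", n_webs)
  planted <- vector("list", n_webs)
  for (w in seq_len(n_webs)) {
    set.seed(seed * 1000L + w)
    per <- if (periphery_species > 0)
      sprintf("q%d", seq_len(periphery_species)) else character()
    species <- c(backbone$species, per)
    links <- backbone$links[, c("resource", "consumer")]
    if (periphery_species > 1) {
      pp <- expand.grid(r = per, c = per, stringsAsFactors = FALSE)
      pp <- pp[pp$r != pp$c, ]
      keep <- stats::runif(nrow(pp)) < periphery_connectance
      links <- rbind(links, data.frame(resource = pp$r[keep],
                                       consumer = pp$c[keep]))
    }
    if (periphery_species > 0 && attach_prob > 0) {
      at <- expand.grid(p = per, b = backbone$species,
                        stringsAsFactors = FALSE)
      keep <- which(stats::runif(nrow(at)) < attach_prob)
      if (length(keep))
        links <- rbind(links, data.frame(resource = at$p[keep],
                                         consumer = at$b[keep]))
    }
    webs[[w]] <- food_web(species, links, id = sprintf("pw%d", w))
    planted[[w]] <- seq_len(nrow(webs[[w]]$links)) <= nrow(backbone$links)
  }
  list(webs = webs, planted = planted)
}

#' Star-shaped backbone web
#'
#' A central resource consumed by `n_leaves` satellite species: the
#' high-centrality structure used as a planted backbone in benchmarks.
#'
#' @param n_leaves number of satellite consumers (= number of links).
#' @param id web identifier.
#' @param prefix species label prefix.
#' @return a [food_web] with `n_leaves + 1` species and `n_leaves` links.
#' @export
star_backbone <- function(n_leaves = 6L, id = "star", prefix = "b") {
  centre <- paste0(prefix, "0")
  leaves <- sprintf("%s%d", prefix, seq_len(n_leaves))
  food_web(c(centre, leaves), cbind(centre, leaves), id = id)
}

#' Bipartite consumer-resource backbone web
#'
#' `n_resources * n_consumers` links from every resource to every consumer:
#' the "half eats the other half" structure used as a contrast to
#' [star_backbone()] in clustering benchmarks.
#'
#' @param n_resources,n_consumers sizes of the two classes.
#' @inheritParams star_backbone
#' @return a [food_web].
#' @export
bipartite_backbone <- function(n_resources = 2L, n_consumers = 3L,
                               id = "bip", prefix = "b") {
  res <- sprintf("%sr%d", prefix, seq_len(n_resources))
  con <- sprintf("%sc%d", prefix, seq_len(n_consumers))
  links <- expand.grid(resource = res, consumer = con,
                       stringsAsFactors = FALSE)
  food_web(c(res, con), links, id = id)
}

#' Three-web toy fixture with reference alignments
#'
#' A hand-built triple of small webs with stored pairwise alignments that
#' realize the two limiting alignment-transitivity scenarios: species `r1`
#' of the first web is paired with `g1` and `b1`, which are themselves
#' paired in the second-third alignment (transitivity 1), while `r3` is
#' paired with `g3` and `b3`, which are not paired with each other
#' (transitivity 0).
#'
#' @return list with `webs` (three [food_web]s: `red`, `green`, `blue`) and
#'   `store` (a [pairing_store] of the three reference alignments), plus
#'   `transitive_species` (`"r1"`) and `intransitive_species` (`"r3"`).
#' @export
toy_web_triple <- function() {
  chain <- function(labels, id) {
    food_web(labels, cbind(labels[-length(labels)], labels[-1L]), id = id)
  }
  red <- chain(sprintf("r%d", 1:4), "red")
  green <- chain(sprintf("g%d", 1:4), "green")
  blue <- chain(sprintf("b%d", 1:4), "blue")
  rg <- web_alignment(red$species, green$species, 1:4, "red", "green")
  rb <- web_alignment(red$species, blue$species, 1:4, "red", "blue")
  # green-blue alignment crosses g3/g4: b-partners (b1, b2, b4, b3)
  gb <- web_alignment(green$species, blue$species, c(1L, 2L, 4L, 3L),
                      "green", "blue")
  store <- pairing_store(list(rg, rb, gb),
                         web_ids = c("red", "green", "blue"))
  list(webs = list(red = red, green = green, blue = blue), store = store,
       transitive_species = "r1", intransitive_species = "r3")
}
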