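#' Alignment configuration
#'
#' Bundles the tunable parameters of the alignment optimizer.
#'
#' @param epsilon penalty for an unpaired species (and, in the neighborhood
#'   cost, per unmatched neighbor); nonnegative, default 1, the midpoint of
#'   the per-pair cost range `[0, 2]`.
#' @param cost which cost function drives the optimization:
#'   `"neighborhood"` (default; rewards pairings whose neighbors are also
#'   well paired) or `"simple"` (sum of per-pair role dissimilarities).
#' @param T0 initial simulated-annealing temperature, or `"auto"` to
#'   calibrate it so that roughly 80% of uphill moves are accepted over a
#'   200-move probe.
#' @param cooling geometric cooling factor per stage, in (0, 1).
#' @param sweep_length proposals per temperature stage, or `"auto"` for
#'   `50 * max(|A|, |B|)`.
#' @param max_stale_stages stop after this many stages without improvement.
#' @param restarts independent annealing restarts; the best result wins.
#' @param seed integer seed; restart `r` uses `seed + r - 1`.
#' @param directed_neighborhood evaluate the neighborhood cost separately on
#'   prey (in-) and predator (out-) neighbor sets instead of their union.
#' @param max_n motif size for role profiles (2 or 3).
#' @param include_two_node include the two-species motifs in role profiles.
#' @return a list of class `align_config`.
#' @export
align_config <- function(epsilon = 1, cost = c("neighborhood", "simple"),
                         T0 = "auto", cooling = 0.95, sweep_length = "auto",
                         max_stale_stages = 20L, restarts = 5L, seed = 1L,
                         directed_neighborhood = FALSE, max_n = 3L,
                         include_two_node = TRUE) {
  cost <- match.arg(cost)
  stopifnot(epsilon >= 0, cooling > 0, cooling < 1, max_stale_stages >= 1,
            restarts >= 1)
  structure(list(epsilon = epsilon, cost = cost, T0 = T0, cooling = cooling,
                 sweep_length = sweep_length,
                 max_stale_stages = as.integer(max_stale_stages),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 directed_neighborhood = isTRUE(directed_neighborhood),
                 max_n = as.integer(max_n),
                 include_two_node = isTRUE(include_two_node)),
            class = "align_config")
}

#' Construct an alignment between two webs
#'
#' An alignment is a set of one-to-one species pairings in which every
#' species of either web occurs exactly once, possibly paired with nothing
#' (unpaired).
#'
#' @param species_a,species_b species labels of the two webs.
#' @param map_ab integer vector of length `length(species_a)`; entry `i`
#'   gives the index in `species_b` paired with species `i` of A, or `NA`
#'   when that species is unpaired. No index may repeat.
#' @param web_a,web_b ids of the two webs.
#' @return an object of class `web_alignment` with the pairings as a
#'   data.frame (`NA` marks an unpaired side).
#' @export
web_alignment <- function(species_a, species_b, map_ab,
                          web_a = "A", web_b = "B") {
  map_ab <- as.integer(map_ab)
  if (length(map_ab) != length(species_a))
    stop("map_ab must have one entry per species of A")
  hit <- map_ab[!is.na(map_ab)]
  if (anyDuplicated(hit)) stop("alignment is not one-to-one")
  if (length(hit) && (min(hit) < 1L || max(hit) > length(species_b)))
    stop("map_ab index out of range")
  un_b <- setdiff(seq_along(species_b), hit)
  pairs <- data.frame(
    a = c(species_a, rep(NA_character_, length(un_b))),
    b = c(ifelse(is.na(map_ab), NA_character_, species_b[map_ab]),
          species_b[un_b]),
    stringsAsFactors = FALSE)
  structure(list(web_a = web_a, web_b = web_b,
                 species_a = species_a, species_b = species_b,
                 map_ab = map_ab, pairs = pairs),
            class = "web_alignment")
}

#' @export
print.web_alignment <- function(x, ...) {
  nm <- sum(!is.na(x$map_ab))
  cat(sprintf("<web_alignment %s ~ %s> %d matched, %d + %d unpaired",
              x$web_a, x$web_b, nm, length(x$species_a) - nm,
              length(x$species_b) - nm))
  if (!is.null(x$score))
    cat(sprintf("; cost %.4g, quality %.4g", x$score$cost, x$score$quality))
  cat("\n")
  invisible(x)
}

# neighbor systems for the configured neighborhood mode
neighbor_systems <- function(web, directed = FALSE) {
  if (directed) list(neighbor_lists(web, "in"), neighbor_lists(web, "out"))
  else list(neighbor_lists(web, "all"))
}

#' Simple alignment cost
#'
#' Sum over matched pairs of `1 - rho(a, b)` plus `epsilon` for every
#' unpaired species of either web.
#'
#' @param alignment a [web_alignment].
#' @param rho role-similarity matrix `|A| x |B|` (rows in the order of
#'   `alignment$species_a`, columns of `alignment$species_b`), e.g. from
#'   [rho_matrix()].
#' @param epsilon unpaired-species penalty.
#' @return nonnegative cost (when `epsilon >= 0`).
#' @export
cost_simple <- function(alignment, rho, epsilon = 1) {
  ia <- which(!is.na(alignment$map_ab))
  ib <- alignment$map_ab[ia]
  n_un <- (length(alignment$species_a) - length(ia)) +
    (length(alignment$species_b) - length(ia))
  sum(1 - rho[cbind(ia, ib)]) + epsilon * n_un
}

#' Neighborhood alignment cost
#'
#' Each matched pairing `x = (a, b)` contributes the summed role
#' dissimilarity `1 - rho` over the pairings that join a neighbor of `a`
#' with a neighbor of `b`, plus `epsilon` for every neighbor of `a` not
#' paired with a neighbor of `b` and vice versa. An unpaired species
#' contributes `epsilon` times its degree. This is the reference (pure R)
#' evaluation; the optimizer uses an equivalent incremental form that the
#' test suite cross-checks against this one.
#'
#' @inheritParams cost_simple
#' @param web_a,web_b the two [food_web]s (sources of the neighbor sets).
#' @param directed evaluate prey and predator neighbor sets separately
#'   instead of their union.
#' @return nonnegative cost.
#' @export
cost_neighborhood <- function(alignment, rho, web_a, web_b, epsilon = 1,
                              directed = FALSE) {
  sys_a <- neighbor_systems(web_a, directed)
  sys_b <- neighbor_systems(web_b, directed)
  map <- alignment$map_ab
  inv <- rep(NA_integer_, length(alignment$species_b))
  inv[map[!is.na(map)]] <- which(!is.na(map))
  total <- 0
  for (s in seq_along(sys_a)) {
    nb_a <- sys_a[[s]]; nb_b <- sys_b[[s]]
    for (ia in seq_along(map)) {
      ib <- map[ia]
      if (is.na(ib)) {
        total <- total + epsilon * length(nb_a[[ia]])
        next
      }
      na_ <- nb_a[[ia]]; nb_ <- nb_b[[ib]]
      matched <- 0
      for (al in na_) {
        be <- map[al]
        if (!is.na(be) && be %in% nb_) {
          total <- total + (1 - rho[al, be])
          matched <- matched + 1
        }
      }
      u_a <- length(na_) - matched
      u_b <- sum(vapply(nb_, function(be) {
        al <- inv[be]
        is.na(al) || !(al %in% na_)
      }, TRUE))
      total <- total + epsilon * (u_a + u_b)
    }
    for (ib in which(is.na(inv))) {
      total <- total + epsilon * length(nb_b[[ib]])
    }
  }
  total
}

#' Normalized alignment quality
#'
#' The size-independent dissimilarity between two aligned webs: the mean of
#' `1 - rho(a, b)` over the `N` real-to-real matches (unpaired species
#' contribute nothing, their similarity being fixed at 1). Lies in
#' `[0, 2]`; 0 means every matched pair plays an identical role. When no
#' species are matched at all the alignment is maximally uninformative and
#' the quality is defined as 2.
#'
#' @inheritParams cost_simple
#' @return quality in `[0, 2]`.
#' @export
alignment_quality <- function(alignment, rho) {
  ia <- which(!is.na(alignment$map_ab))
  if (!length(ia)) return(2)
  ib <- alignment$map_ab[ia]
  mean(1 - rho[cbind(ia, ib)])
}

# shared setup for the optimizers
align_context <- function(web_a, web_b, config, roles_a = NULL,
                          roles_b = NULL, catalog = NULL) {
  web_a <- strip_self_loops(web_a, quiet = TRUE)
  web_b <- strip_self_loops(web_b, quiet = TRUE)
  if (is.null(catalog))
    catalog <- build_motif_catalog(config$max_n, config$include_two_node)
  if (is.null(roles_a)) roles_a <- count_roles(web_a, catalog)
  if (is.null(roles_b)) roles_b <- count_roles(web_b, catalog)
  rho <- rho_matrix(roles_a, roles_b)
  list(web_a = web_a, web_b = web_b, rho = rho,
       nb_a = neighbor_systems(web_a, config$directed_neighborhood),
       nb_b = neighbor_systems(web_b, config$directed_neighborhood))
}

score_alignment <- function(alignment, ctx, config) {
  alignment$score <- list(
    cost = NA_real_,
    cost_simple = cost_simple(alignment, ctx$rho, config$epsilon),
    cost_neighborhood = cost_neighborhood(alignment, ctx$rho, ctx$web_a,
                                          ctx$web_b, config$epsilon,
                                          config$directed_neighborhood),
    quality = alignment_quality(alignment, ctx$rho),
    n_matched = sum(!is.na(alignment$map_ab)))
  alignment$score$cost <- if (config$cost == "simple")
    alignment$score$cost_simple else alignment$score$cost_neighborhood
  ia <- which(!is.na(alignment$map_ab))
  ib <- alignment$map_ab[ia]
  alignment$rho_pairs <- data.frame(a = alignment$species_a[ia],
                                    b = alignment$species_b[ib],
                                    rho = ctx$rho[cbind(ia, ib)],
                                    stringsAsFactors = FALSE)
  alignment
}

full_state <- function(map_ab, nA, nB) {
  # pad to a bijection over max(nA, nB) indices (0-based) for the C++ core
  m <- max(nA, nB)
  state <- rep(NA_integer_, m)
  state[seq_len(nA)] <- ifelse(is.na(map_ab), NA_integer_, map_ab - 1L)
  free_b <- setdiff(seq_len(m) - 1L, state[!is.na(state)])
  state[is.na(state)] <- free_b
  state
}

#' Find an optimal alignment by simulated annealing
#'
#' Minimizes the configured cost over one-to-one species alignments between
#' two webs. The optimizer pads the smaller web with dummy species so a
#' state is a bijection, proposes partner swaps of two uniformly chosen
#' species, anneals with geometric cooling from an auto-calibrated initial
#' temperature, keeps the best state ever visited across independent
#' restarts, and finishes with a greedy swap descent to the nearest local
#' optimum. Results are deterministic given `config$seed`. The pair of webs
#' is canonicalized internally (ordered by id) so that
#' `optimize_alignment(A, B)` and `optimize_alignment(B, A)` explore the
#' same state space.
#'
#' @param web_a,web_b [food_web]s to align.
#' @param config an [align_config].
#' @param roles_a,roles_b optional precomputed [count_roles()] matrices
#'   (useful when aligning many pairs from the same set of webs).
#' @param catalog optional motif catalog matching the roles.
#' @return a scored [web_alignment]; `$score` holds `cost` (the optimized
#'   kind), `cost_simple`, `cost_neighborhood`, `quality` and `n_matched`.
#' @export
optimize_alignment <- function(web_a, web_b, config = align_config(),
                               roles_a = NULL, roles_b = NULL,
                               catalog = NULL) {
  if (n_species(web_a) < 1L || n_species(web_b) < 1L)
    stop("both webs must be nonempty")
  flip <- web_a$id > web_b$id
  if (flip) {
    tmp <- web_a; web_a <- web_b; web_b <- tmp
    tmp <- roles_a; roles_a <- roles_b; roles_b <- tmp
  }
  ctx <- align_context(web_a, web_b, config, roles_a, roles_b, catalog)
  nA <- n_species(web_a); nB <- n_species(web_b)
  m <- max(nA, nB)
  sweep <- if (identical(config$sweep_length, "auto")) 50L * m
           else as.integer(config$sweep_length)
  T0 <- if (identical(config$T0, "auto")) -1 else as.numeric(config$T0)
  kind <- if (config$cost == "simple") 0L else 1L
  best <- NULL
  for (r in seq_len(config$restarts)) {
    set.seed(config$seed + r - 1L)
    init <- sample.int(m) - 1L
    res <- sa_align_cpp(ctx$rho, ctx$nb_a, ctx$nb_b, config$epsilon, kind,
                        init, T0, config$cooling, sweep,
                        config$max_stale_stages, 1e-6)
    if (is.null(best) || res$cost < best$cost - 1e-12) best <- res
    if (best$cost <= 1e-12) break
  }
  aln <- web_alignment(web_a$species, web_b$species, best$map_ab,
                       web_a$id, web_b$id)
  aln <- score_alignment(aln, ctx, config)
  aln$provenance <- list(seed = config$seed, restarts = config$restarts,
                         method = "sa")
  if (flip) aln <- flip_alignment(aln)
  aln
}

#' Exhaustive optimal alignment (brute-force oracle)
#'
#' Scans every bijection between the padded species sets and returns the
#' global optimum of the configured cost. Only feasible for tiny webs; used
#' as the ground truth against which the annealer is validated.
#'
#' @inheritParams optimize_alignment
#' @param size_guard refuse when `|A| + |B|` exceeds this (factorial blowup).
#' @return a scored [web_alignment] at the global optimum.
#' @export
exhaustive_alignment <- function(web_a, web_b, config = align_config(),
                                 size_guard = 14L) {
  if (n_species(web_a) + n_species(web_b) > size_guard)
    stop(sprintf("exhaustive search refused: |A| + |B| = %d exceeds %d",
                 n_species(web_a) + n_species(web_b), size_guard))
  flip <- web_a$id > web_b$id
  if (flip) { tmp <- web_a; web_a <- web_b; web_b <- tmp }
  ctx <- align_context(web_a, web_b, config)
  kind <- if (config$cost == "simple") 0L else 1L
  res <- exhaustive_align_cpp(ctx$rho, ctx$nb_a, ctx$nb_b, config$epsilon,
                              kind)
  aln <- web_alignment(web_a$species, web_b$species, res$map_ab,
                       web_a$id, web_b$id)
  aln <- score_alignment(aln, ctx, config)
  aln$provenance <- list(method = "exhaustive")
  if (flip) aln <- flip_alignment(aln)
  aln
}

flip_alignment <- function(aln) {
  inv <- rep(NA_integer_, length(aln$species_b))
  ok <- which(!is.na(aln$map_ab))
  inv[aln$map_ab[ok]] <- ok
  out <- web_alignment(aln$species_b, aln$species_a, inv,
                       aln$web_b, aln$web_a)
  out$score <- aln$score
  out$provenance <- aln$provenance
  if (!is.null(aln$rho_pairs))
    out$rho_pairs <- data.frame(a = aln$rho_pairs$b, b = aln$rho_pairs$a,
                                rho = aln$rho_pairs$rho,
                                stringsAsFactors = FALSE)
  out
}

#' Partner of a species under an alignment
#' @param alignment a [web_alignment].
#' @param species a species label of web A (`side = "a"`) or web B.
#' @param side which web the species belongs to.
#' @return the partner label, or `NA` if unpaired.
#' @export
partner_of <- function(alignment, species, side = c("a", "b")) {
  side <- match.arg(side)
  if (side == "a") {
    i <- match(species, alignment$species_a)
    if (is.na(i)) stop("species not in web A: ", species)
    j <- alignment$map_ab[i]
    if (is.na(j)) NA_character_ else alignment$species_b[j]
  } else {
    j <- match(species, alignment$species_b)
    if (is.na(j)) stop("species not in web B: ", species)
    i <- which(alignment$map_ab == j)
    if (!length(i)) NA_character_ else alignment$species_a[i]
  }
}
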