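#' Link overlap of a web across its alignments
#'
#' For every link `(a, a')` of `web` and every partner web, the link's
#' overlap weight is incremented when both endpoints have real partners
#' `(b, b')` there and `b -> b'` is a link of the partner web with the same
#' direction of energy flow. Weights therefore lie in
#' `[0, n_webs - 1]`.
#'
#' @param web a [food_web] covered by the store.
#' @param store a [pairing_store].
#' @param webs named list of all stored [food_web]s.
#' @return data.frame `resource`, `consumer`, `weight` in the web's link
#'   order.
#' @export
link_overlap <- function(web, store, webs) {
  if (!web$id %in% store$web_ids) stop("web not covered by the store: ",
                                       web$id)
  webs <- webs_by_id(webs, store$web_ids)
  links <- web$links[, c("resource", "consumer")]
  weight <- integer(nrow(links))
  for (other in setdiff(store$web_ids, web$id)) {
    aln <- get_alignment(store, web$id, other)
    if (is.null(aln)) next
    map <- stats::setNames(rep(NA_character_, length(aln$species_a)),
                           aln$species_a)
    ok <- !is.na(aln$map_ab)
    map[aln$species_a[ok]] <- aln$species_b[aln$map_ab[ok]]
    olinks <- paste(webs[[other]]$links$resource,
                    webs[[other]]$links$consumer, sep = "\r")
    pa <- map[links$resource]
    pb <- map[links$consumer]
    hit <- !is.na(pa) & !is.na(pb) & paste(pa, pb, sep = "\r") %in% olinks
    weight <- weight + hit
  }
  data.frame(links, weight = as.integer(weight), stringsAsFactors = FALSE)
}

#' Extract the k-link backbone of a web
#'
#' The backbone is the `k` most-overlapped links; ties at the k-th weight
#' are broken deterministically by decreasing weight, then lexicographic
#' `(resource, consumer)`.
#'
#' @param web the [food_web] the overlap belongs to.
#' @param overlap a [link_overlap()] result for `web`.
#' @param k backbone size; must not exceed the web's link count (webs with
#'   fewer links are dropped from backbone analyses).
#' @return an object of class `backbone`: list `web_id`, `k`, `links`
#'   (data.frame with weights), `species` (the induced species set).
#' @export
extract_backbone <- function(web, overlap, k) {
  if (k < 1L) stop("k must be positive")
  if (k > nrow(overlap))
    stop(sprintf("web '%s' has only %d links; cannot take a %d-link backbone",
                 web$id, nrow(overlap), k))
  ord <- order(-overlap$weight, overlap$resource, overlap$consumer)
  links <- overlap[ord[seq_len(k)], , drop = FALSE]
  rownames(links) <- NULL
  structure(list(web_id = web$id, k = as.integer(k), links = links,
                 species = sort(unique(c(links$resource, links$consumer)))),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone of '%s'> k = %d links, %d species\n",
              x$web_id, x$k, length(x$species)))
  invisible(x)
}

#' Convert a backbone to a food web
#' @param backbone an [extract_backbone()] result.
#' @return a [food_web] with the backbone's species and links and the
#'   original web's id.
#' @export
backbone_web <- function(backbone) {
  food_web(backbone$species,
           backbone$links[, c("resource", "consumer")],
           id = backbone$web_id)
}

#' Dissimilarity matrix between k-link backbones
#'
#' Aligns every pair of backbones with the same optimizer used for full
#' webs and records the optimal alignment cost (backbones share the same
#' number of links, so size normalization is unnecessary; set
#' `value = "quality"` for the normalized variant).
#'
#' @param backbones list of [extract_backbone()] results sharing one `k`.
#' @param config an [align_config].
#' @param value `"cost"` (default) or `"quality"`.
#' @return list with `matrix` (symmetric E_k) and `store`.
#' @export
backbone_matrix <- function(backbones, config = align_config(),
                            value = c("cost", "quality")) {
  value <- match.arg(value)
  ks <- vapply(backbones, function(b) b$k, 1L)
  if (length(unique(ks)) != 1L)
    stop("backbones have mixed k: ", paste(unique(ks), collapse = ", "))
  all_pairs_align(lapply(backbones, backbone_web), config, value = value)
}

# internal clustering helpers -------------------------------------------

dunn_index <- function(d, labels) {
  d <- as.matrix(d)
  ks <- unique(labels)
  diam <- max(vapply(ks, function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2L) 0 else max(d[idx, idx])
  }, 1))
  sep <- min(vapply(utils::combn(ks, 2L, simplify = FALSE), function(pr) {
    min(d[labels == pr[1L], labels == pr[2L], drop = FALSE])
  }, 1))
  if (diam == 0) Inf else sep / diam
}

ch_index <- function(coords, labels) {
  n <- nrow(coords)
  k <- length(unique(labels))
  centroid <- colMeans(coords)
  w <- 0; b <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    cg <- colMeans(coords[idx, , drop = FALSE])
    w <- w + sum(sweep(coords[idx, , drop = FALSE], 2L, cg)^2)
    b <- b + length(idx) * sum((cg - centroid)^2)
  }
  if (w == 0) Inf else (b / (k - 1)) / (w / (n - k))
}

#' Choose the number of backbone clusters by majority rule
#'
#' Runs medoid clustering (PAM) for every candidate count and scores each
#' partition with three internal indices: average silhouette width, the
#' Calinski-Harabasz ratio on the principal-coordinate embedding, and the
#' Dunn index. Each index votes for its best count; the majority wins, with
#' ties resolved toward the smallest count.
#'
#' @param matrix symmetric dissimilarity matrix (e.g. from
#'   [backbone_matrix()]).
#' @param k_range candidate cluster counts, a subset of `2 .. n - 1`.
#' @return the chosen count, with the vote table as attribute `"votes"`.
#' @export
choose_n_clusters <- function(matrix, k_range = 2:5) {
  m <- as.matrix(matrix)
  n <- nrow(m)
  if (n < 4L) stop("need at least 4 objects to vote on a cluster count")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > n - 1L)
    stop("k_range must lie within [2, n - 1]")
  off <- m[upper.tri(m)]
  if (length(unique(round(off, 12L))) == 1L) {
    warning("degenerate dissimilarity matrix (all distances equal); ",
            "returning the smallest candidate count")
    return(structure(min(k_range), votes = NULL))
  }
  d <- stats::as.dist(m)
  emb <- pcoa(m)
  coords <- emb$coordinates
  if (is.null(coords) || ncol(coords) == 0L)
    coords <- matrix(0, n, 1L)
  scores <- data.frame(k = k_range, silhouette = NA_real_, ch = NA_real_,
                       dunn = NA_real_)
  for (i in seq_along(k_range)) {
    fit <- cluster::pam(d, k_range[i], diss = TRUE)
    lab <- fit$clustering
    scores$silhouette[i] <- fit$silinfo$avg.width
    scores$ch[i] <- ch_index(coords, lab)
    scores$dunn[i] <- dunn_index(m, lab)
  }
  votes <- vapply(c("silhouette", "ch", "dunn"), function(ix)
    scores$k[which.max(scores[[ix]])], 1L)
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  structure(min(winners), votes = scores)
}

#' Cluster backbones and build their consensus structures
#'
#' Partitions the backbones by medoid clustering of their dissimilarity
#' matrix. Within each cluster, the medoid (the member minimizing the
#' summed within-cluster distance) is the reference frame: every member
#' backbone is aligned to it and its links are mapped through the pairing.
#' A consensus link's likelihood `l` is the fraction of cluster members
#' whose aligned image contains it; links with `l` below `l_threshold` are
#' dropped. Member species with no partner in the medoid are aggregated
#' into a single auxiliary node (label `"(aux)"`), so links involving them
#' remain visible in the consensus.
#'
#' @param matrix dissimilarity matrix over the backbones.
#' @param backbones list of [extract_backbone()] results in the matrix's id order.
#' @param n_clusters number of clusters (from [choose_n_clusters()] or
#'   fixed by the user).
#' @param l_threshold minimum link likelihood retained (default 0.01).
#' @param config an [align_config] for the member-to-medoid alignments.
#' @return list of `consensus_backbone` objects, one per cluster: list
#'   `cluster_id`, `medoid_web_id`, `member_ids`, `nodes`, `links`
#'   (data.frame `resource`, `consumer`, `l`), `l_threshold`.
#' @export
cluster_and_consensus <- function(matrix, backbones, n_clusters,
                                  l_threshold = 0.01,
                                  config = align_config()) {
  m <- as.matrix(matrix)
  ids <- rownames(m)
  bb_ids <- vapply(backbones, function(b) b$web_id, "")
  if (!setequal(ids, bb_ids))
    stop("backbones do not match the matrix ids")
  backbones <- backbones[match(ids, bb_ids)]
  fit <- cluster::pam(stats::as.dist(m), n_clusters, diss = TRUE)
  out <- vector("list", n_clusters)
  for (g in seq_len(n_clusters)) {
    members <- ids[fit$clustering == g]
    if (!length(members)) stop("empty cluster ", g)
    medoid <- fit$medoids[g]
    med_bb <- backbones[[match(medoid, ids)]]
    med_web <- backbone_web(med_bb)
    counts <- new.env(parent = emptyenv())
    bump <- function(key) assign(key, (if (exists(key, envir = counts))
      get(key, envir = counts) else 0L) + 1L, envir = counts)
    for (mem in members) {
      bb <- backbones[[match(mem, ids)]]
      if (mem == medoid) {
        img <- bb$links[, c("resource", "consumer")]
      } else {
        aln <- optimize_alignment(backbone_web(bb), med_web, config)
        map <- stats::setNames(rep("(aux)", length(aln$species_a)),
                               aln$species_a)
        ok <- !is.na(aln$map_ab)
        map[aln$species_a[ok]] <- aln$species_b[aln$map_ab[ok]]
        img <- unique(data.frame(resource = unname(map[bb$links$resource]),
                                 consumer = unname(map[bb$links$consumer]),
                                 stringsAsFactors = FALSE))
        img <- img[!(img$resource == "(aux)" & img$consumer == "(aux)"), ]
      }
      for (r in seq_len(nrow(img)))
        bump(paste(img$resource[r], img$consumer[r], sep = "\r"))
    }
    keys <- ls(envir = counts)
    l <- vapply(keys, function(k) get(k, envir = counts), 1L) /
      length(members)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    links <- data.frame(resource = vapply(parts, `[[`, "", 1L),
                        consumer = vapply(parts, `[[`, "", 2L),
                        l = unname(l), stringsAsFactors = FALSE)
    links <- links[links$l >= l_threshold, , drop = FALSE]
    links <- links[order(-links$l, links$resource, links$consumer), ]
    rownames(links) <- NULL
    out[[g]] <- structure(
      list(cluster_id = g, medoid_web_id = medoid, member_ids = members,
           nodes = sort(unique(c(links$resource, links$consumer))),
           links = links, l_threshold = l_threshold),
      class = "consensus_backbone")
  }
  out
}

#' @export
print.consensus_backbone <- function(x, ...) {
  cat(sprintf("<consensus_backbone %d> medoid '%s', %d members, %d links (l >= %g)\n",
              x$cluster_id, x$medoid_web_id, length(x$member_ids),
              nrow(x$links), x$l_threshold))
  invisible(x)
}

#' Are backbone links stronger than random links?
#'
#' Tests whether a backbone is made of the strongest interactions of its
#' (weighted) web: the statistic is the mean interaction strength of the
#' backbone links, compared against `n_perm` uniformly drawn equal-size
#' link sets.
#'
#' @param web a weighted [food_web].
#' @param backbone an [extract_backbone()] result for that web.
#' @param n_perm number of random link sets (>= 1).
#' @param seed integer seed.
#' @return list with `observed` (mean backbone link weight), `percentile`
#'   (mid-rank fraction of null draws below the observed value) and
#'   `p_value` (one-sided, upper tail).
#' @export
strength_test <- function(web, backbone, n_perm = 999L, seed = 1L) {
  if (!is_weighted(web)) stop("web has no interaction strengths")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  key <- paste(web$links$resource, web$links$consumer, sep = "\r")
  bkey <- paste(backbone$links$resource, backbone$links$consumer, sep = "\r")
  idx <- match(bkey, key)
  if (anyNA(idx)) stop("backbone links not all present in the web")
  obs <- mean(web$links$weight[idx])
  set.seed(seed)
  null <- replicate(n_perm, mean(web$links$weight[
    sample.int(nrow(web$links), backbone$k)]))
  list(observed = obs,
       percentile = mean(null < obs) + 0.5 * mean(null == obs),
       p_value = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Sweep backbone sizes and count clusters at each
#'
#' For every `k` in `k_range`, extracts the k-link backbones of all webs
#' with at least `k` links, builds E_k, and records the majority-rule
#' cluster count.
#'
#' @param webs named list of [food_web]s.
#' @param store a [pairing_store] over those webs.
#' @param k_range backbone sizes to sweep.
#' @param config an [align_config] for backbone alignments.
#' @param cluster_range candidate cluster counts.
#' @return data.frame `k`, `n_webs`, `n_clusters`.
#' @export
backbone_sweep <- function(webs, store, k_range = 6:31,
                           config = align_config(), cluster_range = 2:5) {
  webs <- webs_by_id(webs, store$web_ids)
  overlaps <- lapply(webs, link_overlap, store = store, webs = webs)
  out <- data.frame(k = integer(), n_webs = integer(),
                    n_clusters = integer())
  for (k in k_range) {
    keep <- names(webs)[vapply(overlaps, nrow, 1L) >= k]
    if (length(keep) < 4L) next
    bbs <- lapply(keep, function(id)
      extract_backbone(webs[[id]], overlaps[[id]], k))
    ek <- backbone_matrix(bbs, config)
    nc <- tryCatch(choose_n_clusters(ek$matrix, cluster_range),
                   warning = function(w) min(cluster_range))
    out <- rbind(out, data.frame(k = k, n_webs = length(keep),
                                 n_clusters = as.integer(nc)))
  }
  out
}
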