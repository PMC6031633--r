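make_identical_store <- function(n_webs = 4L, n_sp = 5L) {
  webs <- lapply(seq_len(n_webs), function(i)
    chain_web(n_sp, id = sprintf("w%d", i)))
  plan <- plan_all_pairs(sprintf("w%d", seq_len(n_webs)))
  alns <- lapply(seq_len(nrow(plan)), function(k)
    web_alignment(webs[[1]]$species, webs[[1]]$species, seq_len(n_sp),
                  plan$web_a[k], plan$web_b[k]))
  list(webs = stats::setNames(webs, sprintf("w%d", seq_len(n_webs))),
       store = pairing_store(alns, sprintf("w%d", seq_len(n_webs))))
}

test_that("link overlap counts shared links across identity alignments", {
  fix <- make_identical_store(4L)
  ov <- link_overlap(fix$webs$w1, fix$store, fix$webs)
  expect_equal(ov$weight, rep(3L, nrow(ov)))  # m - 1 identical partners
  expect_error(link_overlap(chain_web(3L, id = "zz"), fix$store, fix$webs),
               "not covered")
})

test_that("overlap respects the direction of energy flow", {
  wa <- food_web(c("a", "b"), rbind(c("a", "b")), id = "A")
  wb <- food_web(c("x", "y"), rbind(c("y", "x")), id = "B")  # reversed
  aln <- web_alignment(wa$species, wb$species, c(1L, 2L), "A", "B")
  store <- pairing_store(list(aln), c("A", "B"))
  ov <- link_overlap(wa, store, list(wa, wb))
  expect_equal(ov$weight, 0L)  # a->b maps onto x->y which does not exist
})

test_that("backbone extraction takes top-k with deterministic tie-breaking", {
  w <- food_web(letters[1:5],
                rbind(c("a", "b"), c("a", "c"), c("b", "d"), c("c", "e")))
  ov <- data.frame(w$links, weight = c(5L, 2L, 2L, 1L))
  bb <- extract_backbone(w, ov, 2L)
  expect_equal(bb$k, 2L)
  # tie at weight 2 resolved lexicographically: (a,c) beats (b,d)
  expect_equal(paste(bb$links$resource, bb$links$consumer),
               c("a b", "a c"))
  bb_all <- extract_backbone(w, ov, 4L)
  expect_setequal(paste(bb_all$links$resource, bb_all$links$consumer),
                  paste(w$links$resource, w$links$consumer))
  expect_error(extract_backbone(w, ov, 5L), "only 4 links")
})

test_that("planted links out-weigh periphery links in overlap", {
  bb <- star_backbone(6L)
  ens <- planted_backbone_ensemble(bb, n_webs = 8L, periphery_species = 10L,
                                   periphery_connectance = 0.1,
                                   attach_prob = 0.1, seed = 5)
  res <- all_pairs_align(ens$webs, align_config(seed = 15, restarts = 2L,
                                                max_stale_stages = 10L))
  ratio <- vapply(seq_along(ens$webs), function(i) {
    ov <- link_overlap(ens$webs[[i]], res$store, ens$webs)
    mean(ov$weight[ens$planted[[i]]]) -
      mean(ov$weight[!ens$planted[[i]]])
  }, 1)
  expect_gt(mean(ratio), 0)
})

test_that("backbone dissimilarities separate star from bipartite shapes", {
  cfg <- align_config(seed = 21, restarts = 3L)
  stars <- lapply(1:3, function(i) {
    w <- permuted_copy(star_backbone(6L, id = "s"), seed = i)$web
    w$id <- sprintf("star%d", i)
    structure(list(web_id = w$id, k = 6L,
                   links = data.frame(w$links, weight = 1L),
                   species = w$species), class = "backbone")
  })
  bips <- lapply(1:3, function(i) {
    w <- permuted_copy(bipartite_backbone(2L, 3L, id = "b"), seed = i)$web
    w$id <- sprintf("bip%d", i)
    structure(list(web_id = w$id, k = 6L,
                   links = data.frame(w$links, weight = 1L),
                   species = w$species), class = "backbone")
  })
  res <- backbone_matrix(c(stars, bips), cfg)
  m <- res$matrix
  expect_equal(m, t(m))
  within_star <- m[1:3, 1:3][upper.tri(diag(3))]
  across <- m[1:3, 4:6]
  expect_true(all(within_star < 1e-9))  # relabeled copies align exactly
  expect_true(all(across > max(within_star) + 0.1))
  expect_error(backbone_matrix(c(stars, list(structure(
    list(web_id = "odd", k = 5L, links = stars[[1]]$links[1:5, ],
         species = stars[[1]]$species), class = "backbone")))),
    "mixed k")
})

test_that("cluster-count vote recovers planted blob structure", {
  blob_matrix <- function(sizes, within = 0.05, between = 1) {
    n <- sum(sizes)
    lab <- rep(seq_along(sizes), sizes)
    m <- matrix(between, n, n)
    for (g in seq_along(sizes)) m[lab == g, lab == g] <- within
    diag(m) <- 0
    # tiny deterministic jitter so distances are not exactly tied
    jit <- outer(seq_len(n), seq_len(n), function(i, j) abs(i - j) * 1e-4)
    m <- m + (jit + t(jit)) / 2
    diag(m) <- 0
    dimnames(m) <- list(sprintf("o%d", 1:n), sprintf("o%d", 1:n))
    m
  }
  expect_equal(as.integer(choose_n_clusters(blob_matrix(c(5, 5)), 2:4)), 2L)
  expect_equal(as.integer(choose_n_clusters(blob_matrix(c(4, 4, 4)), 2:5)),
               3L)
  flat <- matrix(1, 6, 6) - diag(6)
  dimnames(flat) <- list(sprintf("o%d", 1:6), sprintf("o%d", 1:6))
  expect_warning(k <- choose_n_clusters(flat, 2:4), "degenerate")
  expect_equal(as.integer(k), 2L)
  expect_error(choose_n_clusters(blob_matrix(c(2, 1)), 2:3), "at least 4")
})

test_that("consensus links carry exact within-cluster likelihoods", {
  # four identical chain backbones plus one variant link
  mk_bb <- function(id, extra = NULL) {
    links <- rbind(c("x1", "x2"), c("x2", "x3"), c("x3", "x4"))
    if (!is.null(extra)) links <- rbind(links, extra) else
      links <- rbind(links, c("x1", "x4"))
    structure(list(web_id = id, k = 4L,
                   links = data.frame(resource = links[, 1],
                                      consumer = links[, 2],
                                      weight = 1L),
                   species = sprintf("x%d", 1:4)), class = "backbone")
  }
  bbs <- list(mk_bb("m1"), mk_bb("m2"), mk_bb("m3"),
              mk_bb("m4", extra = c("x2", "x4")))
  m <- matrix(0.1, 4, 4) - diag(rep(0.1, 4))
  dimnames(m) <- list(sprintf("m%d", 1:4), sprintf("m%d", 1:4))
  cons <- cluster_and_consensus(m, bbs, n_clusters = 1L,
                                config = align_config(seed = 3,
                                                      restarts = 3L))
  expect_length(cons, 1L)
  l <- stats::setNames(cons[[1]]$links$l,
                       paste(cons[[1]]$links$resource,
                             cons[[1]]$links$consumer))
  expect_equal(unname(l["x1 x2"]), 1)
  expect_equal(unname(l["x2 x3"]), 1)
  expect_equal(unname(l["x1 x4"]), 3 / 4)
  expect_equal(unname(l["x2 x4"]), 1 / 4)
})

test_that("strength test flags backbones made of the heaviest links", {
  set.seed(1)
  w <- niche_web(12L, 0.25, seed = 50)
  w$links$weight <- stats::runif(nrow(w$links), 0.1, 10)
  ov <- data.frame(w$links[, c("resource", "consumer")],
                   weight = rank(w$links$weight))
  bb <- extract_backbone(w, ov, 4L)  # the 4 heaviest links
  res <- strength_test(w, bb, n_perm = 199L, seed = 2)
  expect_equal(res$p_value, 1 / 200)
  expect_gt(res$percentile, 0.95)
  # equal weights: percentile near one half
  w2 <- w
  w2$links$weight <- rep(1, nrow(w2$links))
  res2 <- strength_test(w2, bb, n_perm = 199L, seed = 3)
  expect_equal(res2$percentile, 0.5)
  expect_error(strength_test(niche_web(8L, 0.2, 1), bb, 9L), "strengths")
})

test_that("the k-sweep reports webs retained and cluster counts per k", {
  fix <- make_identical_store(6L, 8L)  # 7-link chains, identity alignments
  sweep <- suppressWarnings(
    backbone_sweep(fix$webs, fix$store, k_range = 6:7,
                   config = align_config(seed = 2, restarts = 2L),
                   cluster_range = 2:3))
  expect_equal(sweep$k, 6:7)
  expect_equal(sweep$n_webs, c(6L, 6L))
  # identical backbones: degenerate distances fall back to the smallest count
  expect_equal(sweep$n_clusters, c(2L, 2L))
})
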