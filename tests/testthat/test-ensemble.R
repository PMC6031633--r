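test_that("the all-pairs planner schedules n(n-1)/2 alignments", {
  expect_equal(nrow(plan_all_pairs(sprintf("w%d", 1:10))), 45L)
  expect_error(plan_all_pairs(c("a", "a")), "duplicated")
  expect_error(plan_all_pairs("a"), "at least two")
})

test_that("all-pairs alignment yields a symmetric zero-diagonal matrix", {
  webs <- lapply(1:3, function(i) {
    w <- chain_web(4L, id = sprintf("w%d", i),
                   prefix = sprintf("w%d.%d", i, 1:4))
    w$ecosystem <- c("lake", "lake", "stream")[i]
    w
  })
  res <- all_pairs_align(webs, align_config(seed = 4, restarts = 2L))
  m <- res$matrix
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(m, t(m))
  # identical chains align perfectly
  expect_true(all(m < 1e-9))
  expect_length(res$store$alignments, 3L)
  expect_equal(unname(attr(m, "groups")),
               c("lake", "lake", "stream"))
})

test_that("per-pair caching reproduces results and is reused", {
  webs <- lapply(1:3, function(i) niche_web(7L, 0.2, seed = 20 + i,
                                            id = sprintf("n%d", i)))
  dir <- withr::local_tempdir()
  cfg <- align_config(seed = 2, restarts = 2L)
  r1 <- all_pairs_align(webs, cfg, cache_dir = dir)
  expect_length(list.files(dir, pattern = "\\.json$"), 3L)
  msgs <- capture_messages(
    r2 <- all_pairs_align(webs, cfg, cache_dir = dir, progress = TRUE))
  expect_true(all(grepl("cached", msgs)))
  expect_equal(r1$matrix, r2$matrix)
})

test_that("species ranking averages rho over real pairings", {
  webs <- lapply(1:3, function(i) niche_web(8L, 0.2, seed = 30 + i,
                                            id = sprintf("n%d", i)))
  groups <- stats::setNames(c("lake", "lake", "stream"),
                            sprintf("n%d", 1:3))
  res <- all_pairs_align(webs, align_config(seed = 3, restarts = 2L))
  rank <- rank_species(res$store, webs, groups)
  expect_true(all(rank$mean_rho_all >= -1 & rank$mean_rho_all <= 1,
                  na.rm = TRUE))
  expect_true(all(rank$n_pairings <= 2L))
  # independent recomputation straight from the stored alignments
  for (r in sample(nrow(rank), 10L)) {
    vals <- c()
    for (other in setdiff(sprintf("n%d", 1:3), rank$web_id[r])) {
      aln <- get_alignment(res$store, rank$web_id[r], other)
      hit <- aln$rho_pairs$rho[aln$rho_pairs$a == rank$species[r]]
      vals <- c(vals, hit)
    }
    expect_equal(rank$mean_rho_all[r],
                 if (length(vals)) mean(vals) else NA_real_,
                 tolerance = 1e-12)
  }
  # same/cross ecosystem split is consistent with the pooled mean
  n1 <- rank[rank$web_id == "n1", ]
  both <- !is.na(n1$mean_rho_same_ecosystem) &
    !is.na(n1$mean_rho_cross_ecosystem)
  expect_equal(n1$mean_rho_all[both],
               (n1$mean_rho_same_ecosystem[both] +
                  n1$mean_rho_cross_ecosystem[both]) / 2,
               tolerance = 1e-12)
})

test_that("toy-fixture transitivity gives the closure and no-closure limits", {
  toys <- toy_web_triple()
  expect_equal(alignment_transitivity(toys$store, "red",
                                      toys$transitive_species), 1)
  expect_equal(alignment_transitivity(toys$store, "red",
                                      toys$intransitive_species), 0)
})

test_that("identity-aligned identical webs are fully transitive, the shuffled null is not", {
  webs <- lapply(1:3, function(i) chain_web(5L, id = sprintf("w%d", i)))
  alns <- list(
    web_alignment(webs[[1]]$species, webs[[2]]$species, 1:5, "w1", "w2"),
    web_alignment(webs[[1]]$species, webs[[3]]$species, 1:5, "w1", "w3"),
    web_alignment(webs[[2]]$species, webs[[3]]$species, 1:5, "w2", "w3"))
  store <- pairing_store(alns, sprintf("w%d", 1:3))
  for (s in webs[[1]]$species)
    expect_equal(alignment_transitivity(store, "w1", s), 1)
  null <- transitivity_null(store, webs, n_shuffles = 1000L, seed = 7)
  # closed form: partners drawn as independent uniform bijections of 5
  # elements close the triangle with probability 1/5
  expect_lt(abs(mean(null$null_mean) - 0.2), 0.03)
  expect_true(all(null$null_mean < 1))
  # reproducibility
  null2 <- transitivity_null(store, webs, n_shuffles = 10L, seed = 11)
  null3 <- transitivity_null(store, webs, n_shuffles = 10L, seed = 11)
  expect_equal(null2, null3)
})

test_that("transitivity is undefined with fewer than two partnered webs", {
  toys <- toy_web_triple()
  store <- toys$store
  store$alignments <- store$alignments[1]  # keep only red-green
  expect_true(is.na(alignment_transitivity(store, "red", "r1")))
})

test_that("path connectedness counts component pairs of the induced subweb", {
  # components of sizes 3 and 2 among 5 chosen species -> 4/10
  w <- food_web(c("a", "b", "c", "d", "e", "f"),
                rbind(c("a", "b"), c("b", "c"), c("d", "e"), c("e", "f")))
  expect_equal(path_connectedness(w, c("a", "b", "c", "d", "e")), 0.4)
  expect_equal(path_connectedness(w, c("a", "b", "c")), 1)
  w2 <- food_web(c("x", "y", "z"))
  expect_equal(path_connectedness(w2, c("x", "y", "z")), 0)
  expect_error(path_connectedness(w, "a"), "at least two")
})

test_that("path-likelihood test behaves at its extremes and is seeded", {
  w <- chain_web(8L, prefix = sprintf("c%d", 1:8))
  res <- path_likelihood_test(w, w$species[1:7], n_random = 99L, seed = 1)
  expect_equal(res$observed, 1)
  expect_lte(res$p_value, 1)
  res2 <- path_likelihood_test(w, w$species[1:7], n_random = 99L, seed = 1)
  expect_equal(res$p_value, res2$p_value)
  expect_error(path_likelihood_test(w, w$species, n_random = 9L), "strict")
})

test_that("best-aligned species are the top quartile by mean rho", {
  ranking <- data.frame(web_id = "w", species = sprintf("s%d", 1:8),
                        mean_rho_all = seq(1, 0.3, length.out = 8L))
  expect_equal(best_aligned_species(ranking, "w"), c("s1", "s2"))
})
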