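test_that("simple cost reproduces the hand-computed cases", {
  w <- niche_web(8L, 0.2, seed = 1)
  roles <- count_roles(w)
  rho <- rho_matrix(roles, roles)
  expect_equal(cost_simple(identity_alignment(w), rho), 0)

  # nothing paired: |A| = 3, |B| = 2, epsilon = 1 -> 5
  empty <- web_alignment(letters[1:3], letters[4:5], rep(NA_integer_, 3L))
  expect_equal(cost_simple(empty, matrix(0, 3, 2), epsilon = 1), 5)

  # two pairings with rho 0.5 and -0.2 plus one unpaired species
  rho_toy <- matrix(0, 3, 2)
  rho_toy[1, 1] <- 0.5
  rho_toy[2, 2] <- -0.2
  aln <- web_alignment(letters[1:3], letters[4:5], c(1L, 2L, NA))
  expect_equal(cost_simple(aln, rho_toy, epsilon = 1), 2.7)
})

test_that("simple cost is monotone in the unpaired penalty", {
  aln <- web_alignment(letters[1:4], letters[5:6], c(1L, NA, 2L, NA))
  rho <- matrix(stats::runif(8, -1, 1), 4, 2)
  costs <- vapply(c(0, 0.5, 1, 2), function(e) cost_simple(aln, rho, e), 1)
  expect_true(all(diff(costs) > 0))
})

test_that("neighborhood cost is zero for identity and isomorphic link pairs", {
  w <- niche_web(10L, 0.2, seed = 2)
  rho <- rho_matrix(count_roles(w), count_roles(w))
  expect_equal(cost_neighborhood(identity_alignment(w), rho, w, w), 0)

  # two disjoint single links, aligned link-to-link
  wa <- food_web(c("a", "a2"), rbind(c("a", "a2")), id = "A")
  wb <- food_web(c("b", "b2"), rbind(c("b", "b2")), id = "B")
  rho2 <- rho_matrix(count_roles(wa), count_roles(wb))
  aln <- web_alignment(wa$species, wb$species, c(1L, 2L), "A", "B")
  expect_equal(cost_neighborhood(aln, rho2, wa, wb), 0)
})

test_that("pairing a star center with a leaf costs more than center-center", {
  wa <- star3_web("A", "x")
  wb <- star3_web("B", "y")
  rho <- rho_matrix(count_roles(wa), count_roles(wb))
  centre_centre <- web_alignment(wa$species, wb$species, c(1L, 2L, 3L, 4L),
                                 "A", "B")
  centre_leaf <- web_alignment(wa$species, wb$species, c(2L, 1L, 3L, 4L),
                               "A", "B")
  expect_equal(cost_neighborhood(centre_centre, rho, wa, wb), 0)
  expect_gt(cost_neighborhood(centre_leaf, rho, wa, wb),
            cost_neighborhood(centre_centre, rho, wa, wb))
})

test_that("alignment quality averages matched dissimilarity only", {
  w <- niche_web(8L, 0.2, seed = 3)
  rho <- rho_matrix(count_roles(w), count_roles(w))
  expect_equal(alignment_quality(identity_alignment(w), rho), 0)

  rho_toy <- diag(c(1, 0.5, -0.5))
  aln <- web_alignment(letters[1:3], letters[4:6], 1:3)
  expect_equal(alignment_quality(aln, rho_toy), 2 / 3)

  rho0 <- matrix(0, 3, 3)
  expect_equal(alignment_quality(aln, rho0), 1)

  nothing <- web_alignment(letters[1:3], letters[4:6], rep(NA_integer_, 3L))
  expect_equal(alignment_quality(nothing, rho_toy), 2)
})

test_that("incremental C++ cost agrees with the reference R evaluation", {
  set.seed(99)
  for (t in 1:12) {
    wa <- niche_web(sample(4:12, 1L), 0.2, seed = 600 + t)
    wb <- niche_web(sample(4:12, 1L), 0.2, seed = 700 + t)
    rho <- rho_matrix(count_roles(wa), count_roles(wb))
    m <- max(nrow(rho), ncol(rho))
    st <- sample.int(m) - 1L
    map <- st[seq_len(nrow(rho))] + 1L
    map[map > ncol(rho)] <- NA_integer_
    aln <- web_alignment(wa$species, wb$species, map, wa$id, wb$id)
    for (directed in c(FALSE, TRUE)) {
      nba <- fwalign:::neighbor_systems(wa, directed)
      nbb <- fwalign:::neighbor_systems(wb, directed)
      expect_equal(
        fwalign:::alignment_cost_cpp(rho, nba, nbb, 1.0, 1L, st),
        cost_neighborhood(aln, rho, wa, wb, 1.0, directed),
        tolerance = 1e-10)
    }
    nba <- fwalign:::neighbor_systems(wa)
    nbb <- fwalign:::neighbor_systems(wb)
    expect_equal(fwalign:::alignment_cost_cpp(rho, nba, nbb, 1.0, 0L, st),
                 cost_simple(aln, rho, 1.0), tolerance = 1e-10)
  }
})

test_that("annealing attains the exhaustive optimum on tiny pairs", {
  hits <- 0L
  n_pairs <- 20L
  for (t in seq_len(n_pairs)) {
    wa <- niche_web(sample(3:6, 1L), 0.25, seed = 800 + t)
    wb <- niche_web(sample(3:6, 1L), 0.25, seed = 900 + t)
    cfg <- align_config(seed = t, restarts = 5L)
    sa <- optimize_alignment(wa, wb, cfg)
    ex <- exhaustive_alignment(wa, wb, cfg)
    expect_gte(sa$score$cost, ex$score$cost - 1e-9)
    if (sa$score$cost <= ex$score$cost + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_pairs))
})

test_that("exhaustive search handles the degenerate one-species case", {
  wa <- food_web("a", id = "A")
  wb <- food_web("b", id = "B")
  ex <- exhaustive_alignment(wa, wb, align_config(cost = "simple"))
  expect_equal(ex$score$n_matched, 1L)
  expect_equal(ex$score$cost, 1 - 1)  # both roles all-zero: rho = 1
  expect_error(exhaustive_alignment(niche_web(10, 0.2, 1),
                                    niche_web(10, 0.2, 2)),
               "exceeds")
})

test_that("self-alignment reaches quality zero and isomorphs are recovered", {
  for (seed in 1:5) {
    w <- niche_web(sample(8:20, 1L), 0.15, seed = 40 + seed)
    cfg <- align_config(seed = seed)
    self <- optimize_alignment(w, w, cfg)
    expect_lt(self$score$quality, 1e-9)
    pc <- permuted_copy(w, seed = seed)
    aln <- optimize_alignment(w, pc$web, cfg)
    expect_lt(aln$score$quality, 1e-9)
    # the recovered mapping must be a graph isomorphism (equality up to
    # automorphism with the generating permutation)
    mapped <- vapply(w$species, function(s) partner_of(aln, s, "a"), "")
    relinked <- paste(mapped[w$links$resource], mapped[w$links$consumer])
    expect_setequal(relinked,
                    paste(pc$web$links$resource, pc$web$links$consumer))
  }
})

test_that("costs are invariant under species relabeling", {
  wa <- niche_web(9L, 0.2, seed = 77)
  wb <- niche_web(7L, 0.2, seed = 78)
  cfg <- align_config(seed = 5)
  base <- optimize_alignment(wa, wb, cfg)
  rel <- permuted_copy(wa, seed = 3)$web
  rel$id <- "A-relabeled"
  again <- optimize_alignment(rel, wb, cfg)
  expect_equal(again$score$cost, base$score$cost, tolerance = 1e-9)
})

test_that("optimization is symmetric in its arguments", {
  wa <- niche_web(8L, 0.2, seed = 81)
  wb <- niche_web(6L, 0.2, seed = 82)
  cfg <- align_config(seed = 9)
  ab <- optimize_alignment(wa, wb, cfg)
  ba <- optimize_alignment(wb, wa, cfg)
  expect_equal(ab$score$cost, ba$score$cost, tolerance = 1e-12)
  expect_equal(ab$score$quality, ba$score$quality, tolerance = 1e-12)
  expect_equal(ab$web_a, ba$web_b)
})

test_that("alignment objects enforce one-to-one coverage", {
  expect_error(web_alignment(letters[1:3], letters[4:5], c(1L, 1L, NA)),
               "one-to-one")
  expect_error(web_alignment(letters[1:3], letters[4:5], c(1L, 3L, NA)),
               "range")
  aln <- web_alignment(letters[1:3], letters[4:5], c(2L, NA, 1L))
  expect_equal(nrow(aln$pairs), 3L)  # every real species appears once
  expect_equal(partner_of(aln, "a", "a"), "e")
  expect_equal(partner_of(aln, "d", "b"), "c")
  expect_true(is.na(partner_of(aln, "b", "a")))
})
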