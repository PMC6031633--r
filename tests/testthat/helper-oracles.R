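# Independent oracles, deliberately naive: used to validate the package's
# fast implementations on small inputs.

.oracle_pairs3 <- rbind(c(1L, 2L), c(2L, 1L), c(1L, 3L), c(3L, 1L),
                        c(2L, 3L), c(3L, 2L))
.oracle_perms3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

.oracle_code3 <- function(a) sum(a[.oracle_pairs3] * 2^(0:5))

# position signature of each node of a 3-node digraph: two nodes share a
# signature iff they occupy the same automorphism orbit of the same motif
oracle_triple_signature <- function(adj) {
  vapply(1:3, function(v) {
    best <- Inf
    for (p in .oracle_perms3) {
      b <- matrix(0L, 3L, 3L)
      for (i in 1:3) for (j in 1:3) b[p[i], p[j]] <- adj[i, j]
      best <- min(best, .oracle_code3(b) * 4 + p[v])
    }
    best
  }, 1)
}

oracle_connected3 <- function(adj) {
  u <- (adj + t(adj)) > 0
  reach <- u | diag(TRUE, 3L)
  for (s in 1:3) reach <- reach | (reach %*% reach > 0)
  all(reach[1L, ])
}

# naive O(S^3) triad scan: counts per (species, signature); also tallies
# motif occurrences per canonical code
oracle_triad_scan <- function(web) {
  a <- adjacency(strip_self_loops(web, quiet = TRUE))
  storage.mode(a) <- "integer"
  n <- nrow(a)
  counts <- list()
  occ <- list()
  if (n >= 3L) {
    for (tri in utils::combn(n, 3L, simplify = FALSE)) {
      sub <- a[tri, tri]
      if (sum(sub) == 0L || !oracle_connected3(sub)) next
      sigs <- oracle_triple_signature(sub)
      canon <- min(vapply(.oracle_perms3, function(p) {
        b <- matrix(0L, 3L, 3L)
        for (i in 1:3) for (j in 1:3) b[p[i], p[j]] <- sub[i, j]
        .oracle_code3(b)
      }, 1))
      ck <- as.character(canon)
      occ[[ck]] <- (occ[[ck]] %||% 0L) + 1L
      for (v in 1:3) {
        key <- paste(web$species[tri[v]], sigs[v], sep = "\r")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  list(counts = counts, occurrences = occ)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# map catalog 3-node slots to oracle signatures (computed from the motif
# representatives, independently of the catalog's own orbit bookkeeping)
oracle_slot_signatures <- function(catalog) {
  out <- list()
  for (m in catalog$motifs) {
    if (m$n != 3L) next
    sigs <- oracle_triple_signature(m$adj)
    for (o in seq_along(m$orbits)) {
      s <- unique(sigs[m$orbits[[o]]])
      stopifnot(length(s) == 1L)  # orbit members must share a signature
      out[[as.character(m$slots[o])]] <- s
    }
  }
  out
}

# Pearson correlation spelled out from the textbook formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  cv / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
        sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# direct spreadsheet-style evaluation of the PERMANOVA pseudo-F
oracle_pseudo_f <- function(d, groups) {
  n <- nrow(d)
  levs <- unique(groups)
  g <- length(levs)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + d[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (lev in levs) {
    idx <- which(groups == lev)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + d[i, j]^2
    ssw <- ssw + acc / length(idx)
  }
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}
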