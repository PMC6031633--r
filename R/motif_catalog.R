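# Catalog of 2- and 3-species directed motifs and their position orbits.
#
# A motif is a weakly connected directed graph on n nodes, considered up to
# isomorphism. Within a motif, nodes equivalent under its automorphism group
# form a "position orbit"; orbits are the units of a species' role vector.
# Everything here is built by brute force over labelled digraphs (2^2 codes
# for n = 2, 2^6 for n = 3), which is exact and needs no canonical-labelling
# dependency.

ordered_pairs <- function(n) {
  out <- matrix(0L, 0L, 2L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) out <- rbind(out, c(i, j), c(j, i))
  }
  # fixed order: (1,2),(2,1),(1,3),(3,1),(2,3),(3,2)
  ord <- order(pmin(out[, 1L], out[, 2L]) * n + pmax(out[, 1L], out[, 2L]),
               out[, 1L])
  out[ord, , drop = FALSE]
}

adj_from_code <- function(code, n, pairs = ordered_pairs(n)) {
  a <- matrix(0L, n, n)
  bits <- as.integer(intToBits(code))[seq_len(nrow(pairs))]
  a[pairs] <- bits
  a
}

code_from_adj <- function(a, pairs = ordered_pairs(nrow(a))) {
  sum(a[pairs] * 2L^(seq_len(nrow(pairs)) - 1L))
}

relabel_adj <- function(a, perm) {
  n <- nrow(a)
  b <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) b[perm[i], perm[j]] <- a[i, j]
  b
}

perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) for (k in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  }
  # deterministic lexicographic order
  out[order(vapply(out, function(p) sum(p * n^(rev(seq_len(n)) - 1L)), 1))]
}

weakly_connected <- function(a) {
  u <- (a + t(a)) > 0
  n <- nrow(a)
  seen <- rep(FALSE, n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    nb <- which(u[v, ] & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Build the motif-position catalog
#'
#' Enumerates all weakly connected directed motifs on 2 and/or 3 species and
#' their automorphism position orbits. There are 2 two-species motifs (single
#' link, mutual link) with 3 orbits, and 13 three-species motifs with 30
#' orbits, so the full catalog has 33 role-vector slots.
#'
#' @param max_n largest motif size, 2 or 3.
#' @param include_two_node keep the two-species motifs when `max_n = 3`;
#'   setting this to `FALSE` gives the 30-slot three-species-only catalog.
#' @return an object of class `motif_catalog`: list with `motifs` (each a
#'   list `n`, `code`, `adj`, `orbits`, `slots`), `n_slots`, `slot_names`,
#'   and the internal census lookup tables.
#' @examples
#' cat3 <- build_motif_catalog(3)
#' cat3$n_slots  # 33
#' @export
build_motif_catalog <- function(max_n = 3L, include_two_node = TRUE) {
  if (!max_n %in% c(2L, 3L)) stop("max_n must be 2 or 3")
  sizes <- if (max_n == 2L) 2L else if (include_two_node) c(2L, 3L) else 3L
  motifs <- list()
  for (n in sizes) {
    pairs <- ordered_pairs(n)
    perms <- perms_of(n)
    canon <- integer()
    for (code in seq_len(2L^nrow(pairs) - 1L)) {
      a <- adj_from_code(code, n, pairs)
      if (!weakly_connected(a)) next
      cc <- min(vapply(perms, function(p) code_from_adj(relabel_adj(a, p), pairs), 1))
      canon <- c(canon, cc)
    }
    for (cc in sort(unique(canon))) {
      a <- adj_from_code(cc, n, pairs)
      autos <- Filter(function(p) code_from_adj(relabel_adj(a, p), pairs) == cc,
                      perms)
      # orbit closure under the automorphism group
      orbit_id <- seq_len(n)
      for (p in autos) for (v in seq_len(n)) {
        ids <- c(orbit_id[v], orbit_id[p[v]])
        orbit_id[orbit_id %in% ids] <- min(ids)
      }
      orbits <- split(seq_len(n), orbit_id)
      orbits <- orbits[order(vapply(orbits, min, 1L))]
      names(orbits) <- NULL
      motifs[[length(motifs) + 1L]] <- list(n = n, code = cc, adj = a,
                                            orbits = orbits)
    }
  }
  # global slot numbering in catalog order
  k <- 0L
  for (m in seq_along(motifs)) {
    nor <- length(motifs[[m]]$orbits)
    motifs[[m]]$slots <- k + seq_len(nor)
    k <- k + nor
  }
  slot_names <- unlist(lapply(seq_along(motifs), function(m) {
    sprintf("n%d.m%d.p%d", motifs[[m]]$n, m,
            seq_along(motifs[[m]]$orbits))
  }))
  out <- structure(list(motifs = motifs, n_slots = k, slot_names = slot_names,
                        sizes = sizes),
                   class = "motif_catalog")
  if (3L %in% sizes) out$triad_table <- triad_slot_table(out)
  out
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("<motif_catalog> sizes {%s}: %d motifs, %d position orbits\n",
              paste(x$sizes, collapse = ","), length(x$motifs), x$n_slots))
  invisible(x)
}

# 64 x 3 integer matrix: for every labelled 3-node code, the global slot of
# nodes 1..3 (0 when the code is not weakly connected). Row index = code + 1.
triad_slot_table <- function(catalog) {
  pairs <- ordered_pairs(3L)
  perms <- perms_of(3L)
  by_code <- new.env()
  for (m in seq_along(catalog$motifs)) {
    mo <- catalog$motifs[[m]]
    if (mo$n == 3L) assign(as.character(mo$code), m, envir = by_code)
  }
  tab <- matrix(0L, 64L, 3L)
  for (code in seq.int(1L, 63L)) {
    a <- adj_from_code(code, 3L, pairs)
    if (!weakly_connected(a)) next
    codes <- vapply(perms, function(p) code_from_adj(relabel_adj(a, p), pairs), 1)
    best <- which.min(codes)
    cc <- codes[best]
    perm <- perms[[best]]
    mo <- catalog$motifs[[get(as.character(cc), envir = by_code)]]
    for (v in 1:3) {
      orb <- which(vapply(mo$orbits, function(o) perm[v] %in% o, TRUE))
      tab[code + 1L, v] <- mo$slots[orb]
    }
  }
  tab
}
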