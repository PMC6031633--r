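#' Count motif-position roles of every species
#'
#' For every induced, weakly connected 2- or 3-species subgraph of the web,
#' each member species' count at its position orbit is incremented by one.
#' The resulting integer vector per species (the concatenation over motif
#' sizes) is the species' role profile. Self-loops are stripped first, since
#' motif positions are defined on loop-free graphs.
#'
#' @param web a [food_web].
#' @param catalog a [build_motif_catalog()] result (built at the default
#'   `max_n = 3` when omitted).
#' @return integer matrix, rows = species (in web order), columns = catalog
#'   position orbits.
#' @examples
#' w <- food_web(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' count_roles(w)
#' @export
count_roles <- function(web, catalog = build_motif_catalog(3L)) {
  web <- strip_self_loops(web, quiet = TRUE)
  a <- adjacency(web)
  storage.mode(a) <- "integer"
  n <- nrow(a)
  counts <- matrix(0L, n, catalog$n_slots,
                   dimnames = list(web$species, catalog$slot_names))
  if (2L %in% catalog$sizes) {
    m2 <- Filter(function(m) m$n == 2L, catalog$motifs)
    single_slots <- m2[[1L]]$slots   # (resource, consumer) orbits
    mutual_slot <- m2[[2L]]$slots
    if (n >= 2L) {
      s <- (a == 1L) & (t(a) == 0L)
      mu <- (a == 1L) & (t(a) == 1L)
      counts[, single_slots[1L]] <- as.integer(rowSums(s))
      counts[, single_slots[2L]] <- as.integer(colSums(s))
      counts[, mutual_slot] <- as.integer(rowSums(mu))
    }
  }
  if (3L %in% catalog$sizes && n >= 3L) {
    # triad_table slots are already global for this catalog (they start at 4
    # when the two-node block is present, at 1 otherwise)
    tri <- triad_role_census(a, catalog$triad_table, catalog$n_slots)
    counts <- counts + tri
  }
  counts
}

#' Pearson role similarity between two species
#'
#' The similarity \eqn{\rho(a, b)} between two role profiles is their Pearson
#' correlation: 1 when the species play equivalent roles, 0 when their roles
#' are uncorrelated, and -1 when they play opposite roles. Profiles with zero
#' variance make the correlation undefined; such a pair scores 1 when the
#' vectors are elementwise equal and 0 otherwise, so that identical
#' degenerate roles align freely while mismatched ones stay neutral.
#'
#' @param ca,cb numeric role vectors of equal length (rows of
#'   [count_roles()] output).
#' @return similarity in `[-1, 1]`.
#' @examples
#' role_similarity(c(1, 2, 3), c(3, 2, 1))  # -1
#' @export
role_similarity <- function(ca, cb) {
  ca <- as.numeric(ca); cb <- as.numeric(cb)
  if (length(ca) != length(cb)) stop("role profiles differ in length")
  sa <- stats::sd(ca); sb <- stats::sd(cb)
  if (sa == 0 || sb == 0) {
    return(if (isTRUE(all.equal(ca, cb))) 1 else 0)
  }
  stats::cor(ca, cb)
}

#' Role-similarity matrix between the species of two webs
#'
#' Computes \eqn{\rho} for every species pair across two webs (or within one
#' web) from their role-count matrices, applying the same zero-variance
#' policy as [role_similarity()].
#'
#' @param roles_a,roles_b role-count matrices from [count_roles()], built
#'   against the same catalog.
#' @return numeric matrix `nrow(roles_a) x nrow(roles_b)` of similarities.
#' @export
rho_matrix <- function(roles_a, roles_b) {
  if (ncol(roles_a) != ncol(roles_b))
    stop("role matrices built against different catalogs")
  a <- t(roles_a); b <- t(roles_b)
  sa <- apply(a, 2L, stats::sd)
  sb <- apply(b, 2L, stats::sd)
  rho <- suppressWarnings(stats::cor(a, b))
  dz_a <- which(sa == 0); dz_b <- which(sb == 0)
  if (length(dz_a) || length(dz_b)) {
    rho[dz_a, ] <- 0
    rho[, dz_b] <- 0
    for (i in dz_a) for (j in dz_b) {
      if (isTRUE(all.equal(a[, i], b[, j], check.attributes = FALSE)))
        rho[i, j] <- 1
    }
  }
  dimnames(rho) <- list(rownames(roles_a), rownames(roles_b))
  rho
}
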