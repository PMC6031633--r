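# PERMANOVA and principal coordinate analysis on web dissimilarity
# matrices.

permanova_f <- function(d2, groups) {
  n <- length(groups)
  g <- length(unique(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    ss_within <- ss_within +
      sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Anderson-style pseudo-F computed from squared dissimilarities:
#' `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within = sum_g sum_{i<j in g}
#' d_ij^2 / n_g`, `F = ((SS_total - SS_within)/(g-1)) /
#' (SS_within/(n-g))`. Significance comes from random permutations of the
#' group labels, with `p = (1 + #\{F_perm >= F_obs\}) / (n_permutations +
#' 1)`, so the smallest reportable p is `1/(n_permutations + 1)`.
#'
#' @param matrix symmetric dissimilarity matrix with zero diagonal (ids as
#'   dimnames); a `groups` attribute is used when `groups` is missing.
#' @param groups vector of group labels, one per row of `matrix`; every
#'   group needs at least two members.
#' @param n_permutations number of label permutations (default 9999).
#' @param seed integer seed.
#' @return list of class `permanova_result`: `pseudo_F`, `df_between`,
#'   `df_within`, `p_value`, `n_permutations`, `seed`.
#' @export
permanova <- function(matrix, groups = NULL, n_permutations = 9999L,
                      seed = 1L) {
  m <- as.matrix(matrix)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("matrix diagonal must be zero")
  if (is.null(groups)) groups <- attr(matrix, "groups")
  if (is.null(groups)) stop("group labels required")
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("one group label per matrix row")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (any(sizes < 2L))
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2L],
                                       collapse = ", "))
  d2 <- m^2
  f_obs <- permanova_f(d2, groups)
  set.seed(seed)
  n_ge <- 0L
  for (p in seq_len(n_permutations)) {
    if (permanova_f(d2, sample(groups)) >= f_obs) n_ge <- n_ge + 1L
  }
  structure(list(pseudo_F = f_obs,
                 df_between = length(sizes) - 1L,
                 df_within = length(groups) - length(sizes),
                 p_value = (1 + n_ge) / (n_permutations + 1),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.4g, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_F, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA between all group pairs
#'
#' Runs [permanova()] on the submatrix of every unordered pair of groups
#' and adjusts the p-values for multiple testing (Holm by default).
#'
#' @inheritParams permanova
#' @param correction method passed to [stats::p.adjust()].
#' @return data.frame `group_1`, `group_2`, `pseudo_F`, `df_between`,
#'   `df_within`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(matrix, groups = NULL,
                               n_permutations = 9999L,
                               correction = "holm", seed = 1L) {
  m <- as.matrix(matrix)
  if (is.null(groups)) groups <- attr(matrix, "groups")
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (length(levs) < 2L) stop("need at least two groups")
  cmb <- utils::combn(levs, 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    keep <- groups %in% cmb[, k]
    res <- permanova(m[keep, keep, drop = FALSE], groups[keep],
                     n_permutations, seed + k)
    data.frame(group_1 = cmb[1L, k], group_2 = cmb[2L, k],
               pseudo_F = res$pseudo_F, df_between = res$df_between,
               df_within = res$df_within, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = correction)
  out
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower double
#' centering of `-d^2/2` followed by eigendecomposition (via
#' [stats::cmdscale()]). Axes with non-positive eigenvalues are dropped
#' (with a message when negative eigenvalues indicate a non-Euclidean
#' matrix). Euclidean distances between the retained coordinates reproduce
#' `d` exactly when `d` is Euclidean-embeddable.
#'
#' @param matrix symmetric dissimilarity matrix with zero diagonal.
#' @return list of class `pcoa_result`: `coordinates` (n x m, column means
#'   zero), `eigenvalues` (the retained positive ones, descending),
#'   `proportion_explained` (relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(matrix) {
  m <- as.matrix(matrix)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(m)
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # filtering below handles that case explicitly
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-10 * max(abs(eig), 1))
  if (any(eig < -1e-8 * max(abs(eig), 1)))
    message("negative eigenvalues dropped: matrix is not Euclidean-embeddable")
  coords <- if (length(pos)) fit$points[, pos, drop = FALSE]
            else matrix(0, n, 0L)
  if (ncol(coords))
    colnames(coords) <- sprintf("PCo%d", seq_len(ncol(coords)))
  rownames(coords) <- rownames(m)
  structure(list(coordinates = coords, eigenvalues = eig[pos],
                 proportion_explained = if (length(pos))
                   eig[pos] / sum(eig[pos]) else numeric()),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d points, %d retained axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (length(x$proportion_explained))
    cat("  proportion explained:",
        paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained, 5L)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Per-group median and spread of an ordination
#'
#' Helper for plotting group summaries on a PCoA: the coordinate-wise
#' median and standard deviation of each group on the first two axes.
#'
#' @param pcoa_result a [pcoa()] result.
#' @param groups vector of group labels, one per point.
#' @return data.frame `group`, `median_1`, `median_2`, `sd_1`, `sd_2`.
#' @export
group_summary <- function(pcoa_result, groups) {
  co <- pcoa_result$coordinates
  if (ncol(co) < 2L) stop("need at least two retained axes")
  groups <- as.character(groups)
  do.call(rbind, lapply(sort(unique(groups)), function(g) {
    idx <- which(groups == g)
    data.frame(group = g,
               median_1 = stats::median(co[idx, 1L]),
               median_2 = stats::median(co[idx, 2L]),
               sd_1 = stats::sd(co[idx, 1L]),
               sd_2 = stats::sd(co[idx, 2L]),
               stringsAsFactors = FALSE)
  }))
}
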