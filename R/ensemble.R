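#' Store of pairwise alignments across a set of webs
#'
#' Holds one alignment per unordered pair of webs, indexed by web id, and
#' backs the species-level analyses (ranking, alignment transitivity, link
#' overlap).
#'
#' @param alignments list of [web_alignment]s, at most one per unordered
#'   pair of webs.
#' @param web_ids ordered character vector of all web ids covered.
#' @return an object of class `pairing_store`.
#' @export
pairing_store <- function(alignments, web_ids) {
  if (anyDuplicated(web_ids)) stop("duplicated web ids")
  keys <- vapply(alignments, function(al) {
    if (!al$web_a %in% web_ids || !al$web_b %in% web_ids)
      stop("alignment references unknown web id")
    paste(sort(c(al$web_a, al$web_b)), collapse = "\r")
  }, "")
  if (anyDuplicated(keys)) stop("more than one alignment for the same pair")
  names(alignments) <- keys
  structure(list(alignments = alignments, web_ids = web_ids),
            class = "pairing_store")
}

#' @export
print.pairing_store <- function(x, ...) {
  cat(sprintf("<pairing_store> %d webs, %d alignments\n",
              length(x$web_ids), length(x$alignments)))
  invisible(x)
}

#' Look up the alignment between two webs
#' @param store a [pairing_store].
#' @param id_a,id_b web ids; the result is oriented so that `web_a == id_a`.
#' @return a [web_alignment], or `NULL` when the pair is absent.
#' @export
get_alignment <- function(store, id_a, id_b) {
  key <- paste(sort(c(id_a, id_b)), collapse = "\r")
  al <- store$alignments[[key]]
  if (is.null(al)) return(NULL)
  if (al$web_a != id_a) al <- flip_alignment(al)
  al
}

#' Plan the all-pairs alignment schedule
#'
#' @param web_ids character vector of web ids.
#' @return data.frame with columns `web_a`, `web_b`, one row per unordered
#'   pair (`n * (n - 1) / 2` rows).
#' @export
plan_all_pairs <- function(web_ids) {
  if (anyDuplicated(web_ids)) stop("duplicated web ids")
  n <- length(web_ids)
  if (n < 2L) stop("need at least two webs")
  idx <- utils::combn(n, 2L)
  data.frame(web_a = web_ids[idx[1L, ]], web_b = web_ids[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Align every pair of webs and build the dissimilarity matrix
#'
#' Runs [optimize_alignment()] for all `n(n-1)/2` unordered pairs (role
#' profiles are computed once per web) and assembles the symmetric,
#' zero-diagonal dissimilarity matrix whose entries are the normalized
#' alignment quality (or the raw optimized cost). Per-pair seeds are derived
#' from `config$seed` with stable offsets so any pair can be reproduced in
#' isolation. When `cache_dir` is given, finished pairs are written there as
#' JSON and reused by later runs with the same configuration and webs.
#'
#' @param webs named list of [food_web]s (names are ignored; ids must be
#'   unique).
#' @param config an [align_config].
#' @param value matrix entries: `"quality"` (normalized, default) or
#'   `"cost"` (the optimized cost).
#' @param cache_dir optional directory for per-pair JSON artifacts.
#' @param progress print one line per pair.
#' @return list with `matrix` (dissimilarity matrix with web ids as
#'   dimnames and an `groups` attribute of ecosystem labels) and `store`
#'   (a [pairing_store]).
#' @export
all_pairs_align <- function(webs, config = align_config(),
                            value = c("quality", "cost"), cache_dir = NULL,
                            progress = FALSE) {
  value <- match.arg(value)
  ids <- vapply(webs, function(w) w$id, "")
  if (anyDuplicated(ids)) stop("duplicated web ids")
  if (length(webs) < 2L) stop("need at least two webs")
  catalog <- build_motif_catalog(config$max_n, config$include_two_node)
  webs <- lapply(webs, strip_self_loops, quiet = TRUE)
  roles <- lapply(webs, count_roles, catalog = catalog)
  plan <- plan_all_pairs(ids)
  fp <- config_fingerprint(config, value)
  alignments <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    i <- match(plan$web_a[k], ids)
    j <- match(plan$web_b[k], ids)
    cached <- cache_read(cache_dir, ids[i], ids[j], fp, webs[[i]], webs[[j]])
    if (!is.null(cached)) {
      aln <- cached
      if (progress) message(sprintf("[%d/%d] %s ~ %s (cached)", k,
                                    nrow(plan), ids[i], ids[j]))
    } else {
      cfg <- config
      cfg$seed <- config$seed + (k - 1L) * config$restarts
      aln <- optimize_alignment(webs[[i]], webs[[j]], cfg,
                                roles_a = roles[[i]], roles_b = roles[[j]],
                                catalog = catalog)
      cache_write(cache_dir, aln, fp, webs[[i]], webs[[j]])
      if (progress) message(sprintf("[%d/%d] %s ~ %s cost %.4g", k,
                                    nrow(plan), ids[i], ids[j],
                                    aln$score$cost))
    }
    alignments[[k]] <- aln
  }
  store <- pairing_store(alignments, ids)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (aln in alignments) {
    v <- if (value == "quality") aln$score$quality else aln$score$cost
    m[aln$web_a, aln$web_b] <- v
    m[aln$web_b, aln$web_a] <- v
  }
  groups <- vapply(webs, function(w)
    if (is.null(w$ecosystem)) "unknown" else w$ecosystem, "")
  names(groups) <- ids
  attr(m, "groups") <- groups
  list(matrix = m, store = store)
}

config_fingerprint <- function(config, value) {
  paste(c(value, unlist(lapply(config, as.character))), collapse = "|")
}

web_fingerprint <- function(web) {
  key <- sort(paste(web$links$resource, web$links$consumer, sep = ">"))
  paste(length(web$species), paste(key, collapse = ";"), sep = "|")
}

cache_path <- function(cache_dir, id_a, id_b) {
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  file.path(cache_dir, sprintf("%s__%s.json", safe(id_a), safe(id_b)))
}

cache_read <- function(cache_dir, id_a, id_b, fp, web_a, web_b) {
  if (is.null(cache_dir)) return(NULL)
  path <- cache_path(cache_dir, id_a, id_b)
  if (!file.exists(path)) return(NULL)
  rec <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(rec) || !identical(rec$fingerprint, fp)) return(NULL)
  if (!identical(rec$web_fp_a, web_fingerprint(web_a)) ||
      !identical(rec$web_fp_b, web_fingerprint(web_b))) return(NULL)
  aln <- web_alignment(web_a$species, web_b$species,
                       ifelse(rec$map_ab < 0, NA_integer_,
                              as.integer(rec$map_ab)),
                       id_a, id_b)
  aln$score <- as.list(rec$score)
  if (!is.null(rec$rho_pairs))
    aln$rho_pairs <- as.data.frame(rec$rho_pairs, stringsAsFactors = FALSE)
  aln$provenance <- list(method = "cache")
  aln
}

cache_write <- function(cache_dir, aln, fp, web_a, web_b) {
  if (is.null(cache_dir)) return(invisible(NULL))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- list(fingerprint = fp,
              web_fp_a = web_fingerprint(web_a),
              web_fp_b = web_fingerprint(web_b),
              web_a = aln$web_a, web_b = aln$web_b,
              map_ab = ifelse(is.na(aln$map_ab), -1L, aln$map_ab),
              score = aln$score, rho_pairs = aln$rho_pairs)
  jsonlite::write_json(rec, cache_path(cache_dir, aln$web_a, aln$web_b),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Rank species by their average role similarity across alignments
#'
#' For every species of every web, averages the role similarity `rho` of the
#' pairings it takes part in (unpaired occurrences are excluded from the
#' mean). With ecosystem labels, separate means over same- and
#' cross-ecosystem partner webs are reported. With three or more webs the
#' species' alignment transitivity is included.
#'
#' @param store a [pairing_store] whose alignments carry per-pair `rho`
#'   values (as produced by [optimize_alignment()] / [all_pairs_align()]).
#' @param webs named list of [food_web]s backing the store (names or ids
#'   matching `store$web_ids`).
#' @param groups optional named vector web id -> ecosystem label.
#' @return data.frame with columns `web_id`, `species`, `mean_rho_all`,
#'   `mean_rho_same_ecosystem`, `mean_rho_cross_ecosystem`, `n_pairings`,
#'   `transitivity`, sorted by decreasing `mean_rho_all` within each web.
#' @export
rank_species <- function(store, webs, groups = NULL) {
  ids <- store$web_ids
  webs <- webs_by_id(webs, ids)
  rows <- list()
  for (id in ids) {
    sp <- webs[[id]]$species
    rho_all <- stats::setNames(vector("list", length(sp)), sp)
    rho_grp <- stats::setNames(vector("list", length(sp)), sp)
    for (other in setdiff(ids, id)) {
      aln <- get_alignment(store, id, other)
      if (is.null(aln)) next
      if (is.null(aln$rho_pairs))
        stop("alignment lacks per-pair rho values; score it first")
      rp <- aln$rho_pairs
      for (r in seq_len(nrow(rp))) {
        s <- rp$a[r]
        rho_all[[s]] <- c(rho_all[[s]], rp$rho[r])
        rho_grp[[s]] <- c(rho_grp[[s]],
                          if (!is.null(groups)) unname(groups[other])
                          else NA_character_)
      }
    }
    tr <- vapply(sp, function(s)
      alignment_transitivity(store, id, s), 1)
    g_own <- if (!is.null(groups)) unname(groups[id]) else NA_character_
    rows[[id]] <- data.frame(
      web_id = id, species = sp,
      mean_rho_all = vapply(sp, function(s) {
        v <- rho_all[[s]]
        if (length(v)) mean(v) else NA_real_
      }, 1),
      mean_rho_same_ecosystem = vapply(sp, function(s) {
        v <- rho_all[[s]][rho_grp[[s]] == g_own]
        if (length(v)) mean(v) else NA_real_
      }, 1),
      mean_rho_cross_ecosystem = vapply(sp, function(s) {
        v <- rho_all[[s]][rho_grp[[s]] != g_own]
        if (length(v)) mean(v) else NA_real_
      }, 1),
      n_pairings = vapply(sp, function(s) length(rho_all[[s]]), 1L),
      transitivity = tr,
      stringsAsFactors = FALSE, row.names = NULL)
    rows[[id]] <- rows[[id]][order(-rows[[id]]$mean_rho_all), ]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

webs_by_id <- function(webs, ids) {
  got <- vapply(webs, function(w) w$id, "")
  if (!all(ids %in% got)) stop("webs missing for ids: ",
                               paste(setdiff(ids, got), collapse = ", "))
  stats::setNames(webs[match(ids, got)], ids)
}

#' Alignment transitivity of a species
#'
#' Given that species `a` of `web` is paired with `b` in web B and `c` in
#' web C, transitivity asks how often `b` and `c` are themselves paired in
#' the B-C alignment: the fraction of unordered partner-web pairs in which
#' that closure holds. Pairs where `a` is unpaired on either side are
#' skipped; with no valid pair the value is undefined (`NA`).
#'
#' @param store a [pairing_store] covering at least three webs.
#' @param web id of the species' web.
#' @param species species label.
#' @return fraction in `[0, 1]`, or `NA` when undefined.
#' @export
alignment_transitivity <- function(store, web, species) {
  others <- setdiff(store$web_ids, web)
  if (length(others) < 2L) return(NA_real_)
  partners <- lapply(others, function(o) {
    aln <- get_alignment(store, web, o)
    if (is.null(aln)) NA_character_ else partner_of(aln, species, "a")
  })
  names(partners) <- others
  hits <- 0L
  tot <- 0L
  cmb <- utils::combn(others, 2L)
  for (k in seq_len(ncol(cmb))) {
    bweb <- cmb[1L, k]; cweb <- cmb[2L, k]
    b <- partners[[bweb]]; cc <- partners[[cweb]]
    if (is.na(b) || is.na(cc)) next
    bc <- get_alignment(store, bweb, cweb)
    if (is.null(bc)) next
    tot <- tot + 1L
    if (identical(partner_of(bc, b, "a"), cc)) hits <- hits + 1L
  }
  if (tot == 0L) NA_real_ else hits / tot
}

#' Null expectation of alignment transitivity under shuffled alignments
#'
#' Shuffles the partners within every alignment (a uniform permutation of
#' the matched partners, keeping the number of real pairings per alignment
#' fixed) and recomputes every species' transitivity. Repeated `n_shuffles`
#' times; reports the Monte-Carlo mean and a central 95% interval.
#'
#' @param store a [pairing_store].
#' @param webs named list of the stored [food_web]s.
#' @param n_shuffles number of shuffles (>= 1).
#' @param seed integer seed.
#' @return data.frame `web_id`, `species`, `null_mean`, `null_lo`,
#'   `null_hi`.
#' @export
transitivity_null <- function(store, webs, n_shuffles = 100L, seed = 1L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  set.seed(seed)
  ids <- store$web_ids
  webs <- webs_by_id(webs, ids)
  sp_tab <- do.call(rbind, lapply(ids, function(id)
    data.frame(web_id = id, species = webs[[id]]$species,
               stringsAsFactors = FALSE)))
  vals <- matrix(NA_real_, nrow(sp_tab), n_shuffles)
  for (s in seq_len(n_shuffles)) {
    shuf <- store
    shuf$alignments <- lapply(store$alignments, function(al) {
      matched <- which(!is.na(al$map_ab))
      if (length(matched) > 1L)
        al$map_ab[matched] <- al$map_ab[matched][sample.int(length(matched))]
      al2 <- web_alignment(al$species_a, al$species_b, al$map_ab,
                           al$web_a, al$web_b)
      al2
    })
    vals[, s] <- mapply(function(w, p) alignment_transitivity(shuf, w, p),
                        sp_tab$web_id, sp_tab$species)
  }
  sp_tab$null_mean <- rowMeans(vals, na.rm = TRUE)
  qs <- t(apply(vals, 1L, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  sp_tab$null_lo <- qs[, 1L]
  sp_tab$null_hi <- qs[, 2L]
  sp_tab
}

#' Connectedness of a species subset within its web
#'
#' The fraction of unordered pairs of the subset joined by an undirected
#' path inside the induced subweb (paths through species outside the subset
#' do not count). Equals 1 exactly when the induced subweb is connected.
#'
#' @param web a [food_web].
#' @param subset character vector of at least two species of `web`.
#' @return fraction in `[0, 1]`.
#' @export
path_connectedness <- function(web, subset) {
  subset <- unique(subset)
  if (length(subset) < 2L) stop("subset must contain at least two species")
  if (!all(subset %in% web$species))
    stop("subset species not in web: ",
         paste(setdiff(subset, web$species), collapse = ", "))
  g <- as_igraph(web)
  sub <- igraph::induced_subgraph(g, subset)
  comp <- igraph::components(sub, mode = "weak")
  sizes <- comp$csize
  sum(choose(sizes, 2)) / choose(length(subset), 2)
}

#' Permutation test for the connectedness of a species subset
#'
#' Compares the observed [path_connectedness()] of a subset (typically the
#' best-aligned species) against `n_random` uniformly drawn subsets of the
#' same size: `p = (1 + #\{null >= observed\}) / (n_random + 1)`.
#'
#' @inheritParams path_connectedness
#' @param n_random number of random subsets (>= 1).
#' @param seed integer seed.
#' @return list with `observed`, `p_value`, `null` (the simulated values).
#' @export
path_likelihood_test <- function(web, subset, n_random = 999L, seed = 1L) {
  subset <- unique(subset)
  if (length(subset) >= n_species(web))
    stop("subset must be a strict subset of the web's species")
  if (n_random < 1L) stop("n_random must be >= 1")
  obs <- path_connectedness(web, subset)
  set.seed(seed)
  null <- replicate(n_random, path_connectedness(
    web, sample(web$species, length(subset))))
  list(observed = obs,
       p_value = (1 + sum(null >= obs)) / (n_random + 1),
       null = null)
}

#' Best-aligned species of a web
#'
#' The top fraction of a web's species by mean role similarity across
#' alignments, the working definition of the candidate backbone species
#' set.
#'
#' @param ranking output of [rank_species()].
#' @param web_id web to select from.
#' @param top fraction of species to keep (default the top quartile).
#' @return character vector of species labels.
#' @export
best_aligned_species <- function(ranking, web_id, top = 0.25) {
  r <- ranking[ranking$web_id == web_id & !is.na(ranking$mean_rho_all), ]
  if (!nrow(r)) stop("no ranked species for web ", web_id)
  r <- r[order(-r$mean_rho_all), ]
  r$species[seq_len(max(2L, ceiling(nrow(r) * top)))]
}
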