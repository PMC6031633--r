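#' Read a food web from disk
#'
#' Two plain-text formats are supported. An *edge list* is a TSV with no
#' header, columns `resource`, `consumer` and an optional numeric `weight`;
#' lines starting with `#` are comments. An *adjacency* file is a CSV whose
#' first row and first column hold species labels; a nonzero entry `(i, j)`
#' is a link `i -> j` (energy flows from the row species to the column
#' species), and entries are used as weights when `weighted = TRUE`.
#'
#' Isolated species can only be represented in the adjacency format (they
#' appear in the headers); duplicate edge-list rows are collapsed with a
#' warning. Self-loops are kept and flagged with a message.
#'
#' @param path file to read.
#' @param format `"edgelist"` or `"adjacency"`.
#' @param id web identifier; defaults to the file name without extension.
#' @param weighted read interaction strengths (third column / cell values).
#' @param ecosystem optional ecosystem label to attach.
#' @return a [food_web].
#' @export
load_web <- function(path, format = c("edgelist", "adjacency"),
                     id = NULL, weighted = FALSE, ecosystem = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "edgelist") {
    lines <- readLines(path, encoding = "UTF-8")
    keep <- !grepl("^\\s*(#|$)", lines)
    rows <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(vapply(rows, length, 1L) < 2L)
    if (length(bad))
      stop(sprintf("malformed edge-list row at line %d of %s",
                   which(keep)[bad[1L]], path))
    if (!length(rows)) stop("empty edge list: ", path)
    res <- vapply(rows, `[[`, "", 1L)
    con <- vapply(rows, `[[`, "", 2L)
    w <- NULL
    if (weighted) {
      if (any(vapply(rows, length, 1L) < 3L))
        stop("weighted = TRUE but some rows lack a weight column: ", path)
      w <- as.numeric(vapply(rows, `[[`, "", 3L))
      if (anyNA(w)) stop("non-numeric weight in ", path)
    }
    species <- unique(c(res, con))
    web <- food_web(species, data.frame(res, con), id = id, weights = w,
                    ecosystem = ecosystem)
  } else {
    m <- utils::read.csv(path, row.names = 1L, check.names = FALSE,
                         fileEncoding = "UTF-8")
    m <- as.matrix(m)
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
      stop("adjacency matrix must be square with matching row/column labels: ",
           path)
    idx <- which(m != 0, arr.ind = TRUE)
    links <- data.frame(resource = rownames(m)[idx[, 1L]],
                        consumer = colnames(m)[idx[, 2L]])
    w <- if (weighted && nrow(idx)) as.numeric(m[idx]) else NULL
    web <- food_web(rownames(m), links, id = id, weights = w,
                    ecosystem = ecosystem)
  }
  if (has_self_loops(web))
    message(sprintf("web '%s' contains self-loop(s); they are stripped before motif analysis",
                    web$id))
  web
}

#' Write a food web to disk
#'
#' @inheritParams load_web
#' @param web a [food_web].
#' @return the path, invisibly. `load_web(save_web(w, ...))` round-trips the
#'   species set, links and weights.
#' @export
save_web <- function(web, path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    if (length(setdiff(web$species,
                       c(web$links$resource, web$links$consumer))))
      warning("isolated species cannot be represented in an edge list; ",
              "use the adjacency format to keep them")
    cols <- c("resource", "consumer", if (is_weighted(web)) "weight")
    utils::write.table(web$links[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    m <- adjacency(web, weighted = is_weighted(web))
    utils::write.csv(m, path, quote = TRUE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a dataset manifest and its food webs
#'
#' The manifest is a TSV with a header line `web_id  path  ecosystem`.
#' Relative paths are resolved against the manifest's directory. When
#' `enforce_size_filter` is on, webs whose species count falls outside
#' `size_filter` are excluded (and listed in the result); the defaults keep
#' communities of 5 to 133 species, the range over which alignment remains
#' computationally tractable and non-degenerate. Webs whose resource and
#' consumer sets are disjoint look bipartite and are flagged with a warning,
#' but exclusion is left to the user.
#'
#' @param path manifest file.
#' @param enforce_size_filter apply the species-count filter.
#' @param size_filter length-2 integer vector `(min, max)` of species counts.
#' @param weighted passed to [load_web()].
#' @return a list with elements `webs` (named list of [food_web]),
#'   `manifest` (the parsed table), `excluded` (data.frame of excluded
#'   entries with reasons) and `bipartite_flagged` (character vector of ids).
#' @export
load_manifest <- function(path, enforce_size_filter = TRUE,
                          size_filter = c(5L, 133L), weighted = FALSE) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  need <- c("web_id", "path", "ecosystem")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$web_id))
    stop("duplicated web_id in manifest: ",
         paste(unique(tab$web_id[duplicated(tab$web_id)]), collapse = ", "))
  ok_labels <- c(ecosystem_labels(), "unknown")
  bad <- setdiff(unique(tab$ecosystem), ok_labels)
  if (length(bad))
    stop("unknown ecosystem label(s): ", paste(bad, collapse = ", "))
  base <- dirname(normalizePath(path))
  files <- ifelse(grepl("^(/|[A-Za-z]:)", tab$path), tab$path,
                  file.path(base, tab$path))
  miss <- !file.exists(files)
  if (any(miss))
    stop("manifest entries point to missing files: ",
         paste(tab$web_id[miss], collapse = ", "))
  fmt <- ifelse(grepl("\\.csv$", files, ignore.case = TRUE),
                "adjacency", "edgelist")
  webs <- lapply(seq_len(nrow(tab)), function(i) {
    load_web(files[i], format = fmt[i], id = tab$web_id[i],
             weighted = weighted, ecosystem = tab$ecosystem[i])
  })
  names(webs) <- tab$web_id
  excluded <- data.frame(web_id = character(), n_species = integer(),
                         reason = character())
  if (enforce_size_filter) {
    ns <- vapply(webs, n_species, 1L)
    out <- ns < size_filter[1L] | ns > size_filter[2L]
    if (any(out)) {
      excluded <- data.frame(web_id = tab$web_id[out], n_species = ns[out],
                             reason = sprintf("species count outside [%d, %d]",
                                              size_filter[1L], size_filter[2L]))
      message(sprintf("size filter excluded %d web(s): %s", sum(out),
                      paste(tab$web_id[out], collapse = ", ")))
      webs <- webs[!out]
    }
  }
  flagged <- names(webs)[vapply(webs, looks_bipartite, TRUE)]
  if (length(flagged))
    warning("web(s) with disjoint resource and consumer sets (bipartite-like): ",
            paste(flagged, collapse = ", "),
            "; they are kept but alignment assumes unipartite webs")
  list(webs = webs, manifest = tab, excluded = excluded,
       bipartite_flagged = flagged)
}
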