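#' Construct a food web
#'
#' A food web is a labelled directed graph in which a link `(resource,
#' consumer)` points in the direction of energy flow: the consumer eats the
#' resource. Links form a set (no duplicates); isolated species are allowed;
#' self-loops (cannibalism) are kept in storage but flagged, and are stripped
#' before motif-role computation and alignment.
#'
#' @param species character vector of unique species labels (order is kept).
#' @param links two-column matrix or data.frame of links, first column the
#'   resource, second the consumer. May have zero rows.
#' @param id identifier for the web.
#' @param weights optional numeric vector of positive interaction strengths,
#'   one per link row.
#' @param ecosystem optional ecosystem label, one of `"estuary"`, `"lake"`,
#'   `"marine"`, `"stream"`, `"terrestrial"`, or `"unknown"`.
#' @return An object of class `food_web`: a list with elements `id`,
#'   `species`, `links` (data.frame with columns `resource`, `consumer` and,
#'   if weighted, `weight`) and `ecosystem`.
#' @examples
#' w <- food_web(c("grass", "rabbit", "fox"),
#'               rbind(c("grass", "rabbit"), c("rabbit", "fox")))
#' w
#' @export
food_web <- function(species, links = NULL, id = "web", weights = NULL,
                     ecosystem = NULL) {
  species <- as.character(species)
  if (length(species) < 1L) stop("a food web needs at least one species")
  if (anyDuplicated(species)) stop("duplicated species labels")
  if (is.null(links) || NROW(links) == 0L) {
    links <- data.frame(resource = character(), consumer = character(),
                        stringsAsFactors = FALSE)
    weights <- NULL
  } else {
    links <- as.data.frame(links, stringsAsFactors = FALSE)
    if (ncol(links) < 2L) stop("links need two columns (resource, consumer)")
    links <- data.frame(resource = as.character(links[[1L]]),
                        consumer = as.character(links[[2L]]),
                        stringsAsFactors = FALSE)
  }
  missing <- setdiff(unique(c(links$resource, links$consumer)), species)
  if (length(missing))
    stop("link endpoints not in species list: ", paste(missing, collapse = ", "))
  if (!is.null(weights)) {
    if (length(weights) != nrow(links))
      stop("weights must have one entry per link")
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be positive and finite")
    links$weight <- as.numeric(weights)
  }
  key <- paste(links$resource, links$consumer, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate links collapsed to one")
    links <- links[!duplicated(key), , drop = FALSE]
    rownames(links) <- NULL
  }
  if (!is.null(ecosystem)) {
    ecosystem <- match.arg(ecosystem, c(ecosystem_labels(), "unknown"))
  }
  structure(list(id = as.character(id), species = species, links = links,
                 ecosystem = ecosystem),
            class = "food_web")
}

ecosystem_labels <- function() {
  c("estuary", "lake", "marine", "stream", "terrestrial")
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf("<food_web '%s'> %d species, %d links%s%s\n",
              x$id, length(x$species), nrow(x$links),
              if (is_weighted(x)) ", weighted" else "",
              if (!is.null(x$ecosystem)) paste0(", ", x$ecosystem) else ""))
  invisible(x)
}

#' Number of species / links of a food web
#' @param web a `food_web`.
#' @return integer count.
#' @export
n_species <- function(web) length(web$species)

#' @rdname n_species
#' @export
n_links <- function(web) nrow(web$links)

is_weighted <- function(web) "weight" %in% names(web$links)

has_self_loops <- function(web) any(web$links$resource == web$links$consumer)

#' Remove self-loops (cannibalistic links)
#'
#' Motif positions and alignments are defined on loop-free graphs, so
#' cannibalistic links are dropped (with a message) before those analyses.
#'
#' @param web a `food_web`.
#' @param quiet suppress the message.
#' @return the web without self-loops.
#' @export
strip_self_loops <- function(web, quiet = FALSE) {
  loop <- web$links$resource == web$links$consumer
  if (any(loop)) {
    if (!quiet)
      message(sprintf("web '%s': stripped %d self-loop(s)", web$id, sum(loop)))
    web$links <- web$links[!loop, , drop = FALSE]
    rownames(web$links) <- NULL
  }
  web
}

#' Adjacency matrix of a food web
#'
#' @param web a `food_web`.
#' @param weighted fill entries with link weights instead of 0/1.
#' @return square numeric matrix, rows = resources, columns = consumers, with
#'   species labels as dimnames; entry `(i, j) != 0` means link `i -> j`.
#' @export
adjacency <- function(web, weighted = FALSE) {
  n <- n_species(web)
  m <- matrix(0, n, n, dimnames = list(web$species, web$species))
  if (nrow(web$links)) {
    idx <- cbind(match(web$links$resource, web$species),
                 match(web$links$consumer, web$species))
    m[idx] <- if (weighted && is_weighted(web)) web$links$weight else 1
  }
  m
}

#' Convert a food web to an igraph graph
#' @param web a `food_web`.
#' @return an igraph directed graph whose vertices are the species.
#' @export
as_igraph <- function(web) {
  igraph::graph_from_data_frame(web$links, directed = TRUE,
                                vertices = data.frame(name = web$species))
}

# Union (in + out) neighbour lists, 1-based indices into web$species.
neighbor_lists <- function(web, mode = c("all", "in", "out")) {
  mode <- match.arg(mode)
  n <- n_species(web)
  r <- match(web$links$resource, web$species)
  co <- match(web$links$consumer, web$species)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer()
  add <- function(nb, from, to) {
    for (e in seq_along(from)) nb[[from[e]]] <- c(nb[[from[e]]], to[e])
    nb
  }
  if (mode %in% c("all", "out")) nb <- add(nb, r, co)   # consumers of i
  if (mode %in% c("all", "in")) nb <- add(nb, co, r)    # resources of i
  lapply(nb, function(v) sort(unique(v)))
}

# TRUE when resources and consumers are disjoint species sets (ignoring
# isolated species): the simple signature of a bipartite consumer-resource web.
looks_bipartite <- function(web) {
  if (!nrow(web$links)) return(FALSE)
  length(intersect(unique(web$links$resource),
                   unique(web$links$consumer))) == 0L
}

#' Test whether two food webs are equal
#' @param a,b `food_web` objects.
#' @param check_weights compare weights too.
#' @return logical.
#' @export
webs_equal <- function(a, b, check_weights = TRUE) {
  if (!setequal(a$species, b$species)) return(FALSE)
  ka <- paste(a$links$resource, a$links$consumer, sep = "\r")
  kb <- paste(b$links$resource, b$links$consumer, sep = "\r")
  if (!setequal(ka, kb)) return(FALSE)
  if (check_weights && (is_weighted(a) || is_weighted(b))) {
    if (!is_weighted(a) || !is_weighted(b)) return(FALSE)
    wa <- a$links$weight[order(ka)]
    wb <- b$links$weight[order(kb)]
    if (!isTRUE(all.equal(wa, wb, tolerance = 1e-8))) return(FALSE)
  }
  TRUE
}
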