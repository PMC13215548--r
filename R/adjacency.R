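#' Region adjacency graph
#'
#' Constructs the neighbourhood structure used by the ICAR spatial prior.
#' Edges are unordered region pairs; the relation must be symmetric and
#' irreflexive, and most operations additionally require a connected graph
#' (the ICAR model is defined per connected component).
#'
#' @param region_names character vector of unique region labels.
#' @param edges a list of length-2 character vectors, or a 2-column matrix,
#'   each row an unordered pair of neighbouring regions.
#' @return an object of class `mort_graph` with elements `region_names`,
#'   `n_regions` and `edges` (2-column character matrix, deduplicated).
#' @export
adjacency_graph <- function(region_names, edges) {
  region_names <- as.character(region_names)
  if (anyDuplicated(region_names))
    stop_ms("duplicated region labels: %s",
            paste(unique(region_names[duplicated(region_names)]), collapse = ", "))
  if (length(region_names) < 2)
    stop_ms("at least 2 regions are required (ICAR undefined on a single region)")
  if (is.list(edges)) {
    if (!all(lengths(edges) == 2)) stop_ms("each edge must name exactly 2 regions")
    edges <- do.call(rbind, lapply(edges, as.character))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop_ms("edges must be pairs")
  unknown <- setdiff(c(edges), region_names)
  if (length(unknown))
    stop_ms("edge refers to unknown region(s): %s", paste(unknown, collapse = ", "))
  if (any(edges[, 1] == edges[, 2]))
    stop_ms("self-loop edges are not allowed")
  # store unordered, deduplicated
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  structure(list(region_names = region_names,
                 n_regions = length(region_names),
                 edges = edges),
            class = "mort_graph")
}

#' @export
print.mort_graph <- function(x, ...) {
  cat(sprintf("mort_graph: %d regions, %d edges\n", x$n_regions, nrow(x$edges)))
  invisible(x)
}

#' Neighbours of a region
#' @param graph a `mort_graph`.
#' @param region region label.
#' @return character vector of neighbouring region labels.
#' @export
neighbours <- function(graph, region) {
  stopifnot(inherits(graph, "mort_graph"))
  if (!region %in% graph$region_names) stop_ms("unknown region '%s'", region)
  e <- graph$edges
  sort(unique(c(e[e[, 2] == region, 1], e[e[, 1] == region, 2])))
}

adjacency_matrix <- function(graph) {
  n <- graph$n_regions
  W <- matrix(0, n, n, dimnames = list(graph$region_names, graph$region_names))
  W[cbind(match(graph$edges[, 1], graph$region_names),
          match(graph$edges[, 2], graph$region_names))] <- 1
  W + t(W)
}

#' Is the adjacency graph connected?
#' @param graph a `mort_graph`.
#' @return logical.
#' @export
is_connected <- function(graph) {
  W <- adjacency_matrix(graph)
  n <- nrow(W)
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack)) {
    v <- stack[1]
    stack <- stack[-1]
    nb <- which(W[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Load a region adjacency graph from a YAML config
#'
#' The config either lists `regions:` plus symmetric `edges:` pairs, or a
#' `neighbours:` map of region -> list of neighbours (which is validated for
#' symmetry). The package ships a default 8-division Bangladesh fixture
#' (`inst/extdata/bangladesh_adjacency.yaml`), intended to be edited for
#' other geographies: adjacency is configuration, not hard-coded geometry.
#'
#' @param path path to a YAML file, or `NULL` for the bundled default.
#' @return a validated `mort_graph`.
#' @export
load_adjacency <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "bangladesh_adjacency.yaml",
                        package = "mortsmooth", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$neighbours)) {
    regions <- names(cfg$neighbours)
    edges <- list()
    for (r in regions) for (nb in cfg$neighbours[[r]]) {
      if (!nb %in% regions) stop_ms("neighbour map refers to unknown region '%s'", nb)
      if (!r %in% (cfg$neighbours[[nb]] %||% character()))
        stop_ms("asymmetric neighbour map: %s lists %s but not vice versa", r, nb)
      edges[[length(edges) + 1]] <- c(r, nb)
    }
    g <- adjacency_graph(regions, edges)
  } else {
    if (is.null(cfg$regions) || is.null(cfg$edges))
      stop_ms("adjacency config needs 'regions' and 'edges' (or a 'neighbours' map)")
    g <- adjacency_graph(unlist(cfg$regions), cfg$edges)
  }
  g
}

#' ICAR structure matrix
#'
#' Returns the intrinsic conditional autoregressive structure matrix
#' Q = D - W (node degree on the diagonal, minus adjacency), which is
#' symmetric, has zero row sums and rank n-1 on a connected graph. The
#' spatial prior is the improper Gaussian with precision tau * Q, identified
#' by a sum-to-zero constraint.
#'
#' @param graph a connected `mort_graph`.
#' @return an n x n matrix with region-name dimnames.
#' @export
build_icar_precision <- function(graph) {
  stopifnot(inherits(graph, "mort_graph"))
  if (!is_connected(graph))
    stop_ms("adjacency graph is disconnected; ICAR requires a single component")
  W <- adjacency_matrix(graph)
  diag(rowSums(W)) - W
}
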