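#' Embedded network container
#'
#' An undirected simple graph with optional per-node polar coordinates in the
#' hyperbolic plane and optional model parameters. Nodes are identified by
#' stable character ids. This is the container every analysis stage consumes.
#'
#' @param graph An \code{igraph} undirected graph with named vertices.
#' @param coords Optional data.frame with columns \code{node}, \code{r},
#'   \code{theta}. If present, every node of \code{graph} must appear exactly
#'   once. Angles are normalised to \eqn{[0, 2\pi)} on ingestion.
#' @param params Optional named list of model parameters
#'   (\code{N}, \code{gamma}, \code{T}, \code{R}, \code{zeta}).
#' @return An object of class \code{embedded_network}.
#' @export
embedded_network <- function(graph, coords = NULL, params = NULL) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse")
  }
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  graph <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE,
                            edge.attr.comb = "max")
  if (!is.null(coords)) {
    coords <- as.data.frame(coords, stringsAsFactors = FALSE)
    stopifnot(all(c("node", "r", "theta") %in% names(coords)))
    coords$node <- as.character(coords$node)
    nodes <- igraph::V(graph)$name
    missing <- setdiff(nodes, coords$node)
    if (length(missing) > 0) {
      stop("missing coordinates for node(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    coords <- coords[match(nodes, coords$node), c("node", "r", "theta")]
    if (any(coords$r < 0)) stop("radial coordinates must be nonnegative")
    coords$theta <- normalize_angle(coords$theta)
    rownames(coords) <- NULL
  }
  structure(
    list(graph = graph, coords = coords, params = params),
    class = "embedded_network"
  )
}

#' @export
print.embedded_network <- function(x, ...) {
  cat(sprintf(
    "<embedded_network> %d nodes, %d edges; coordinates: %s\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    if (is.null(x$coords)) "absent" else "present"
  ))
  if (!is.null(x$params)) {
    p <- x$params
    cat(sprintf("  params: gamma=%s T=%s R=%s\n",
                format(p$gamma), format(p$T), format(p$R)))
  }
  invisible(x)
}

#' Node ids of an embedded network
#' @param net An \code{embedded_network}.
#' @return Character vector of node ids.
#' @export
net_nodes <- function(net) igraph::V(net$graph)$name

#' Coordinates of an embedded network
#' @param net An \code{embedded_network}.
#' @return data.frame with columns \code{node}, \code{r}, \code{theta}.
#' @export
net_coords <- function(net) {
  if (is.null(net$coords)) stop("network has no coordinates")
  net$coords
}

#' Model parameters of an embedded network
#' @param net An \code{embedded_network}.
#' @return Named list of parameters (possibly empty).
#' @export
net_params <- function(net) {
  if (is.null(net$params)) list() else net$params
}

#' Attach coordinates and/or parameters to a network
#' @param net An \code{embedded_network}.
#' @param coords Optional replacement coordinate data.frame.
#' @param params Optional named list merged over the existing parameters.
#' @return The updated \code{embedded_network}.
#' @export
net_set <- function(net, coords = NULL, params = NULL) {
  if (!is.null(params)) {
    net$params <- utils::modifyList(if (is.null(net$params)) list() else net$params,
                                    params)
  }
  embedded_network(net$graph, coords = if (is.null(coords)) net$coords else coords,
                   params = net$params)
}

# Internal: adjacency in CSR-like form for the C++ kernels (0-based indices).
net_csr <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  lens <- lengths(adj)
  list(
    ptr = as.integer(c(0L, cumsum(lens))),
    idx = as.integer(unlist(lapply(adj, as.integer), use.names = FALSE) - 1L),
    n = n
  )
}
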