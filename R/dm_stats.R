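#' Connected components of a module's induced subgraph
#'
#' @param net An \code{embedded_network}.
#' @param members Character vector of member node ids.
#' @return List with \code{components} (list of id vectors, largest first)
#'   and \code{lcc_size}.
#' @export
module_components <- function(net, members) {
  members <- unique(as.character(members))
  unknown <- setdiff(members, net_nodes(net))
  if (length(unknown) > 0) {
    stop("unknown member id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (length(members) < 1) stop("empty member set")
  sub <- igraph::induced_subgraph(net$graph, members)
  comp <- igraph::components(sub)
  parts <- split(igraph::V(sub)$name, comp$membership)
  parts <- parts[order(-lengths(parts))]
  list(components = unname(parts), lcc_size = max(comp$csize))
}

#' Distance from each module member to its nearest co-member
#'
#' For every member, the minimum distance to any \emph{other} member, in
#' network hops (\code{metric = "shortest_path"}) or exact hyperbolic
#' distance (\code{metric = "hyperbolic"}). Members with no reachable
#' co-member under the shortest-path metric are excluded from the mean (with
#' a message); this cannot happen when the network is a connected component.
#'
#' @param net An \code{embedded_network}.
#' @param members Character vector of member ids (>= 2).
#' @param metric "shortest_path" or "hyperbolic".
#' @return List with \code{distances} (named per-member minima) and
#'   \code{mean}.
#' @export
nearest_member_distances <- function(net, members,
                                     metric = c("shortest_path", "hyperbolic")) {
  metric <- match.arg(metric)
  members <- unique(as.character(members))
  if (length(members) < 2) stop("at least two members are required")
  if (metric == "shortest_path") {
    d <- igraph::distances(net$graph, v = members, to = members)
  } else {
    co <- net_coords(net)
    ix <- match(members, co$node)
    d <- hyperbolic_distance_matrix(co$r[ix], co$theta[ix])
    dimnames(d) <- list(members, members)
  }
  diag(d) <- Inf
  mins <- apply(d, 1, min)
  unreachable <- !is.finite(mins)
  if (any(unreachable)) {
    message(sprintf("%d member(s) with no reachable co-member excluded",
                    sum(unreachable)))
    mins <- mins[!unreachable]
  }
  list(distances = mins, mean = mean(mins))
}

#' Null distribution of a module statistic under uniform node sampling
#'
#' Draws \code{n_samples} uniform node subsets of the module's size (without
#' replacement within a subset, independently across subsets) and evaluates
#' the statistic on each.
#'
#' @param net An \code{embedded_network}.
#' @param module_size Subset size.
#' @param statistic "lcc_size", "mean_ds" or "mean_dh".
#' @param n_samples Number of random subsets.
#' @param seed Integer seed.
#' @return A \code{null_distribution} list with \code{statistic},
#'   \code{n_samples}, \code{values}, \code{mean}, \code{sd} and
#'   \code{degenerate} (TRUE when sd is 0).
#' @export
sampling_null <- function(net, module_size,
                          statistic = c("lcc_size", "mean_ds", "mean_dh"),
                          n_samples = 1000, seed = 1L) {
  statistic <- match.arg(statistic)
  nodes <- net_nodes(net)
  if (module_size > length(nodes)) stop("module_size exceeds network size")
  stat_fun <- switch(statistic,
    lcc_size = function(m) module_components(net, m)$lcc_size,
    mean_ds = function(m) nearest_member_distances(net, m, "shortest_path")$mean,
    mean_dh = function(m) nearest_member_distances(net, m, "hyperbolic")$mean
  )
  set.seed(seed)
  vals <- vapply(seq_len(n_samples), function(s) {
    stat_fun(sample(nodes, module_size))
  }, numeric(1))
  structure(list(statistic = statistic, n_samples = as.integer(n_samples),
                 values = vals, mean = mean(vals), sd = stats::sd(vals),
                 degenerate = stats::sd(vals) == 0),
            class = "null_distribution")
}

#' One-sided z-test of an observed statistic against a sampling null
#'
#' @param observed Observed value.
#' @param null A \code{\link{sampling_null}} result.
#' @param side "greater" (enrichment above the null) or "less".
#' @return List with \code{z} and \code{p}; both NA with
#'   \code{degenerate = TRUE} when the null has zero spread.
#' @export
ztest <- function(observed, null, side = c("greater", "less")) {
  side <- match.arg(side)
  if (null$sd == 0) {
    return(list(z = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  z <- (observed - null$mean) / null$sd
  p <- if (side == "greater") stats::pnorm(z, lower.tail = FALSE)
       else stats::pnorm(z, lower.tail = TRUE)
  list(z = z, p = p, degenerate = FALSE)
}

#' Topological and geometric statistics for every disease module
#'
#' For each disease: member count, number of components and LCC size of the
#' induced subgraph, mean nearest-co-member shortest-path and hyperbolic
#' distances, and one-sided z-tests against uniform sampling nulls (LCC size:
#' greater; both distance means: less). Null distributions are cached per
#' module size.
#'
#' @param net An \code{embedded_network} with coordinates.
#' @param dms A \code{\link{disease_module_set}}.
#' @param config A \code{\link{pipeline_config}}.
#' @return data.frame with one row per disease.
#' @export
dm_stats <- function(net, dms, config = pipeline_config()) {
  null_cache <- new.env(parent = emptyenv())
  get_null <- function(size, statistic) {
    key <- paste(statistic, size)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- sampling_null(
        net, size, statistic, n_samples = config$n_null_samples,
        seed = config$seed + size)
    }
    null_cache[[key]]
  }
  rows <- lapply(names(dms$modules), function(id) {
    members <- intersect(dms$modules[[id]], net_nodes(net))
    if (length(members) < 2) return(NULL)
    comp <- module_components(net, members)
    ds <- nearest_member_distances(net, members, "shortest_path")
    dh <- nearest_member_distances(net, members, "hyperbolic")
    zl <- ztest(comp$lcc_size, get_null(length(members), "lcc_size"), "greater")
    zs <- ztest(ds$mean, get_null(length(members), "mean_ds"), "less")
    zh <- ztest(dh$mean, get_null(length(members), "mean_dh"), "less")
    data.frame(
      disease = id, n_members = length(members),
      n_components = length(comp$components),
      lcc_size = comp$lcc_size,
      lcc_fraction = comp$lcc_size / length(members),
      mean_ds = ds$mean, mean_dh = dh$mean,
      z_lcc = zl$z, p_lcc = zl$p,
      z_ds = zs$z, p_ds = zs$p,
      z_dh = zh$z, p_dh = zh$p,
      sig_lcc = !is.na(zl$p) & zl$p < config$alpha,
      sig_ds = !is.na(zs$p) & zs$p < config$alpha,
      sig_dh = !is.na(zh$p) & zh$p < config$alpha,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
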