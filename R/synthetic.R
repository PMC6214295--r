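#' Configuration for the static popularity-similarity network generator
#'
#' @param N Number of nodes.
#' @param gamma Target degree-distribution exponent (> 2).
#' @param T_ Network temperature (> 0); lower values give stronger geometric
#'   determinism and higher clustering.
#' @param target_mean_degree Desired mean degree (< N - 1).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A \code{psm_config} list.
#' @export
psm_config <- function(N, gamma = 2.5, T_ = 0.5, target_mean_degree = 10,
                       seed = 1L) {
  stopifnot(N >= 2, gamma > 2, T_ > 0, target_mean_degree < N - 1,
            target_mean_degree > 0)
  structure(list(N = as.integer(N), gamma = gamma, T = T_,
                 target_mean_degree = target_mean_degree,
                 seed = as.integer(seed)),
            class = "psm_config")
}

# Inverse-CDF sampling of radii with density a*exp(a*(r - R)) on [0, R],
# a = (gamma - 1)/2, given uniform quantiles u. Radii concentrate near the
# rim R; smaller radii (future hubs) are exponentially rare.
psm_radii <- function(u, gamma, R) {
  a <- (gamma - 1) / 2
  log1p(u * expm1(a * R)) / a
}

#' Generate a network from the static popularity-similarity model
#'
#' Nodes receive ground-truth polar coordinates: angles uniform on
#' \eqn{[0, 2\pi)} and radii with density
#' \eqn{\rho(r) \propto \alpha_r e^{\alpha_r (r - R)}} on \eqn{[0, R]},
#' \eqn{\alpha_r = (\gamma - 1)/2}. Every pair is linked independently with
#' the Fermi-Dirac probability at its hyperbolic distance. The disk radius
#' \code{R} is calibrated by bisection so the mean expected degree matches
#' \code{cfg$target_mean_degree} (radii are re-derived from the same
#' quantiles at each candidate \code{R}, keeping the stated radial density on
#' \eqn{[0, R]} exactly).
#'
#' @param cfg A \code{\link{psm_config}}.
#' @return An \code{\link{embedded_network}} with coordinates and parameters;
#'   isolated nodes are retained (use \code{\link{largest_component}} before
#'   stages that need connectivity).
#' @export
generate_psm_network <- function(cfg) {
  stopifnot(inherits(cfg, "psm_config"))
  set.seed(cfg$seed)
  u <- stats::runif(cfg$N)
  theta <- stats::runif(cfg$N, 0, 2 * pi)
  # mean expected degree is decreasing in R (distances grow ~2R vs the
  # threshold's R), so bisect on a decreasing function
  g <- function(R) {
    cpp_mean_expected_degree(psm_radii(u, cfg$gamma, R), theta, R, cfg$T)
  }
  lo <- 1e-3
  hi <- max(4 * log(cfg$N), 4)
  while (g(hi) > cfg$target_mean_degree) hi <- hi * 2
  if (g(lo) < cfg$target_mean_degree) {
    stop("target mean degree unattainable: increase N or lower the target")
  }
  R <- NA_real_
  for (iter in seq_len(100)) {
    mid <- (lo + hi) / 2
    val <- g(mid)
    if (abs(val - cfg$target_mean_degree) <=
        1e-3 * cfg$target_mean_degree || (hi - lo) < 1e-10) {
      R <- mid
      break
    }
    if (val > cfg$target_mean_degree) lo <- mid else hi <- mid
  }
  if (is.na(R)) R <- (lo + hi) / 2
  r <- psm_radii(u, cfg$gamma, R)
  edges <- cpp_sample_psm_edges(r, theta, R, cfg$T)
  ids <- sprintf("n%0*d", nchar(as.character(cfg$N)), seq_len(cfg$N))
  g_ <- igraph::make_empty_graph(n = cfg$N, directed = FALSE)
  igraph::V(g_)$name <- ids
  if (nrow(edges) > 0) g_ <- igraph::add_edges(g_, t(edges))
  embedded_network(
    g_,
    coords = data.frame(node = ids, r = r, theta = theta),
    params = list(N = cfg$N, gamma = cfg$gamma, T = cfg$T, R = R, zeta = 1)
  )
}

#' Extract the largest connected component, keeping coordinates
#' @param net An \code{embedded_network}.
#' @return The sub-network induced by the largest component.
#' @export
largest_component <- function(net) {
  comp <- igraph::components(net$graph)
  keep <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(net$graph, keep)
  co <- if (is.null(net$coords)) NULL else
    net$coords[net$coords$node %in% igraph::V(g)$name, , drop = FALSE]
  embedded_network(g, coords = co, params = net$params)
}

#' Empirical connection probability as a function of hyperbolic distance
#'
#' Splits the range of pairwise hyperbolic distances into \code{n_bins}
#' equal-width windows and reports, per window, the fraction of node pairs
#' that are linked in the network.
#'
#' @param net An \code{embedded_network} with coordinates.
#' @param n_bins Number of distance windows.
#' @return data.frame with columns \code{mid} (window midpoint),
#'   \code{n_pairs}, \code{n_connected}, \code{fraction} (NA for empty
#'   windows), and \code{model_p} (the Fermi-Dirac value at the midpoint when
#'   the network carries \code{R} and \code{T}).
#' @export
empirical_connection_probability <- function(net, n_bins = 20) {
  co <- net_coords(net)
  if (nrow(co) < 2) stop("network too small")
  csr <- net_csr(net)
  res <- cpp_connection_bins(co$r, co$theta, csr$ptr, csr$idx, as.integer(n_bins))
  width <- (res$max - res$min) / n_bins
  mid <- res$min + (seq_len(n_bins) - 0.5) * width
  frac <- ifelse(res$total > 0, res$connected / res$total, NA_real_)
  pa <- net_params(net)
  model_p <- if (!is.null(pa$R) && !is.null(pa$T)) {
    connection_probability(pmax(mid, 0), pa$R, pa$T)
  } else NA_real_
  data.frame(mid = mid, n_pairs = res$total, n_connected = res$connected,
             fraction = frac, model_p = model_p)
}

#' Configuration for planting synthetic disease modules
#'
#' Emulates the empirical structure of disease modules: each disease is
#' fragmented into several components whose members concentrate in narrow
#' angular sectors, with a hub bias (annotation studies over-represent
#' high-degree proteins) and a fraction of background members placed
#' uniformly. Diseases whose sectors fall in the same angular block share a
#' category label, giving ground truth for clustering recovery.
#'
#' @param n_diseases Number of diseases to plant.
#' @param members_per_disease Length-2 integer range of module sizes.
#' @param components_per_disease Length-2 integer range of component counts.
#' @param angular_concentration Half-width (radians) of the sector around
#'   each component centre.
#' @param background_fraction Fraction of members sampled uniformly from the
#'   whole network.
#' @param n_categories Number of angular blocks defining category labels.
#' @param hub_bias If TRUE, in-sector members are drawn with probability
#'   proportional to degree.
#' @param seed Integer seed; per-disease sub-seeds are \code{seed + index}.
#' @return A \code{synthetic_disease_config} list.
#' @export
synthetic_disease_config <- function(n_diseases = 12,
                                     members_per_disease = c(20L, 40L),
                                     components_per_disease = c(2L, 6L),
                                     angular_concentration = 0.25,
                                     background_fraction = 0.1,
                                     n_categories = 3,
                                     hub_bias = TRUE,
                                     seed = 1L) {
  stopifnot(min(members_per_disease) >= 2,
            angular_concentration > 0, angular_concentration <= pi,
            background_fraction >= 0, background_fraction <= 1,
            min(components_per_disease) >= 1)
  structure(list(n_diseases = as.integer(n_diseases),
                 members_per_disease = as.integer(members_per_disease),
                 components_per_disease = as.integer(components_per_disease),
                 angular_concentration = angular_concentration,
                 background_fraction = background_fraction,
                 n_categories = as.integer(n_categories),
                 hub_bias = isTRUE(hub_bias),
                 seed = as.integer(seed)),
            class = "synthetic_disease_config")
}

#' Plant geometrically clustered, fragmented disease modules
#'
#' For each disease, component centres are drawn inside one of
#' \code{n_categories} angular blocks (the block index is the disease's
#' category label); \code{1 - background_fraction} of the members are sampled
#' from nodes within \code{angular_concentration} of a component centre
#' (degree-proportionally when \code{hub_bias}), the rest uniformly from the
#' network. Ground truth (centres, per-member component) is attached as
#' attribute \code{"truth"}.
#'
#' @param net An \code{embedded_network} with coordinates.
#' @param cfg A \code{\link{synthetic_disease_config}}.
#' @return A \code{\link{disease_module_set}} with category labels.
#' @export
plant_disease_modules <- function(net, cfg) {
  stopifnot(inherits(cfg, "synthetic_disease_config"))
  co <- net_coords(net)
  n <- nrow(co)
  deg <- igraph::degree(net$graph)[co$node]
  block_width <- 2 * pi / cfg$n_categories
  modules <- list()
  categories <- character(0)
  truth <- list()
  for (d in seq_len(cfg$n_diseases)) {
    set.seed(cfg$seed + d)
    m <- if (cfg$members_per_disease[1] == cfg$members_per_disease[2])
      cfg$members_per_disease[1] else
      sample(cfg$members_per_disease[1]:cfg$members_per_disease[2], 1)
    if (m > n) stop("requested more members than network nodes")
    ncomp <- if (cfg$components_per_disease[1] == cfg$components_per_disease[2])
      cfg$components_per_disease[1] else
      sample(cfg$components_per_disease[1]:cfg$components_per_disease[2], 1)
    category <- ((d - 1) %% cfg$n_categories)
    block_lo <- category * block_width
    primary <- stats::runif(1, block_lo + 0.15 * block_width,
                            block_lo + 0.85 * block_width)
    centres <- normalize_angle(primary +
                                 stats::rnorm(ncomp, 0, block_width / 10))
    n_bg <- round(cfg$background_fraction * m)
    n_core <- m - n_bg
    comp_of <- sort(rep_len(seq_len(ncomp), n_core))
    members <- character(0)
    member_comp <- integer(0)
    for (k in seq_len(ncomp)) {
      need <- sum(comp_of == k)
      if (need == 0) next
      sep <- angular_separation(co$theta, centres[k])
      elig <- setdiff(which(sep <= cfg$angular_concentration),
                      match(members, co$node))
      if (length(elig) < need) {
        # widen to the nearest nodes by angular distance
        ord <- order(sep)
        elig <- setdiff(ord, match(members, co$node))[seq_len(
          min(need * 3, n - length(members)))]
      }
      w <- if (cfg$hub_bias) deg[elig] + 1 else rep(1, length(elig))
      pick <- elig[sample.int(length(elig), min(need, length(elig)),
                              prob = w)]
      members <- c(members, co$node[pick])
      member_comp <- c(member_comp, rep(k, length(pick)))
    }
    if (n_bg > 0) {
      pool <- setdiff(seq_len(n), match(members, co$node))
      pick <- pool[sample.int(length(pool), n_bg)]
      members <- c(members, co$node[pick])
      member_comp <- c(member_comp, rep(0L, n_bg))
    }
    id <- sprintf("disease%02d", d)
    modules[[id]] <- members
    categories[id] <- sprintf("cat%d", category + 1)
    truth[[id]] <- list(centres = centres, component = member_comp,
                        category = category + 1)
  }
  out <- disease_module_set(modules, categories)
  attr(out, "truth") <- truth
  out
}

#' Default disjoint angular sectors for the six protein classes
#' @param classes Class labels.
#' @param width Sector width in radians (must leave gaps between sectors).
#' @return Named list class -> c(lo, hi).
#' @export
default_sector_map <- function(classes = c("TF", "Rec", "RBP", "Trans",
                                           "Skel", "Ubi"),
                               width = 0.7) {
  k <- length(classes)
  stopifnot(width < 2 * pi / k)
  lo <- (seq_len(k) - 1) * 2 * pi / k
  stats::setNames(lapply(seq_len(k), function(i) c(lo[i], lo[i] + width)),
                  classes)
}

#' Plant protein-class annotations concentrated in angular sectors
#'
#' Nodes whose angle falls inside a class's sector are annotated with that
#' class with probability \code{purity} (otherwise a uniformly random class);
#' nodes outside every sector are annotated with a uniformly random class
#' with probability \code{background_rate}, and left unannotated otherwise.
#'
#' @param net An \code{embedded_network} with coordinates.
#' @param sector_map Named list class -> angular interval \code{c(lo, hi)};
#'   intervals must be disjoint.
#' @param purity Probability that an in-sector node gets its sector's class.
#' @param background_rate Annotation rate outside all sectors.
#' @param seed Integer seed.
#' @return Named list node id -> character vector of classes (one per node).
#' @export
plant_class_annotations <- function(net, sector_map = default_sector_map(),
                                    purity = 0.9, background_rate = 0.3,
                                    seed = 1L) {
  classes <- names(sector_map)
  iv <- do.call(rbind, sector_map)
  if (any(iv[, 2] <= iv[, 1])) stop("each interval must satisfy lo < hi")
  o <- order(iv[, 1])
  if (any(iv[o, 1][-1] < iv[o, 2][-nrow(iv)])) {
    stop("sector intervals must be disjoint")
  }
  co <- net_coords(net)
  set.seed(seed)
  ann <- list()
  for (i in seq_len(nrow(co))) {
    th <- co$theta[i]
    inside <- which(th >= iv[, 1] & th < iv[, 2])
    if (length(inside) == 1) {
      cls <- if (stats::runif(1) < purity) classes[inside] else
        sample(classes, 1)
      ann[[co$node[i]]] <- cls
    } else if (stats::runif(1) < background_rate) {
      ann[[co$node[i]]] <- sample(classes, 1)
    }
  }
  ann
}
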