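#' Embedding configuration
#'
#' @param gamma Degree-distribution exponent used for the radial rule
#'   (> 2); supply the value fitted elsewhere or use
#'   \code{\link{fit_power_law_gamma}}.
#' @param T_ Network temperature of the Fermi-Dirac likelihood.
#' @param w Angular search window (radians) for likelihood refinement; the
#'   full circle \code{2*pi} by default.
#' @param n_candidate_angles Candidate angles per node and sweep (the current
#'   angle is always a candidate, so refinement never lowers the likelihood).
#' @param n_sweeps Refinement sweeps over all nodes.
#' @param refine Whether to run the likelihood-refinement stage.
#' @param seed Integer seed for candidate sampling.
#' @return An \code{embedding_config} list.
#' @export
embedding_config <- function(gamma = 2.5, T_ = 0.5, w = 2 * pi,
                             n_candidate_angles = 100, n_sweeps = 1,
                             refine = TRUE, seed = 1L) {
  stopifnot(gamma > 2, T_ > 0, w > 0, w <= 2 * pi, n_candidate_angles >= 1)
  structure(list(gamma = gamma, T = T_, w = w,
                 n_candidate_angles = as.integer(n_candidate_angles),
                 n_sweeps = as.integer(n_sweeps), refine = isTRUE(refine),
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Maximum-likelihood power-law exponent of a degree sequence
#' @param degrees Integer degree vector.
#' @param xmin Lower cut-off passed to \code{igraph::fit_power_law}.
#' @return The fitted exponent.
#' @export
fit_power_law_gamma <- function(degrees, xmin = NULL) {
  degrees <- degrees[degrees > 0]
  fit <- igraph::fit_power_law(degrees, xmin = if (is.null(xmin)) NA else xmin)
  if (is.list(fit)) fit$alpha else fit
}

# Decreasing-degree node order with ties broken by node id, shared by the
# radial rule and the refinement sweep.
degree_order <- function(net) {
  deg <- igraph::degree(net$graph)
  ids <- igraph::V(net$graph)$name
  order(-deg, ids)
}

#' Infer radial coordinates from the degree ranking
#'
#' Nodes are sorted by decreasing degree (ties broken by node id); the node
#' of rank \eqn{i} receives
#' \deqn{r_i = 2\beta \ln i + 2 (1 - \beta) \ln N, \quad \beta = 1/(\gamma-1),}
#' so the highest-degree node sits closest to the disk centre and the radius
#' never exceeds \eqn{2 \ln N}.
#'
#' @param net A connected \code{embedded_network}.
#' @param gamma Degree exponent (> 2).
#' @return Named numeric vector of radii in \code{net_nodes(net)} order.
#' @export
infer_radial_coordinates <- function(net, gamma) {
  if (gamma <= 2) stop("gamma must be > 2")
  n <- igraph::vcount(net$graph)
  beta <- 1 / (gamma - 1)
  ord <- degree_order(net)
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  r <- 2 * beta * log(rank_of) + 2 * (1 - beta) * log(n)
  names(r) <- igraph::V(net$graph)$name
  r
}

#' Infer angular coordinates by Laplacian eigenmaps
#'
#' Computes the two eigenvectors of the symmetric normalised graph Laplacian
#' \eqn{L = I - D^{-1/2} A D^{-1/2}} with the smallest nonzero eigenvalues
#' and reads each node's angle as \code{atan2(y, x)} of its two spectral
#' coordinates, normalised to \eqn{[0, 2\pi)}.
#'
#' @param net A connected \code{embedded_network}.
#' @return Named numeric vector of angles in \code{net_nodes(net)} order.
#' @export
infer_angular_coordinates <- function(net) {
  g <- net$graph
  if (!igraph::is_connected(g)) stop("network must be connected")
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  dinv <- 1 / sqrt(igraph::degree(g))
  Lsym <- diag(n) - outer(dinv, dinv) * A
  ev <- eigen(Lsym, symmetric = TRUE)
  vals <- rev(ev$values)
  vecs <- ev$vectors[, rev(seq_len(n)), drop = FALSE]
  nz <- which(vals > 1e-9)
  if (length(nz) < 2) stop("network too small for spectral embedding")
  x <- vecs[, nz[1]]
  y <- vecs[, nz[2]]
  th <- normalize_angle(atan2(y, x))
  names(th) <- igraph::V(g)$name
  th
}

# Full Fermi-Dirac graph log-likelihood of an embedded network,
# sum over unordered pairs of a*log(p) + (1-a)*log(1-p).
#' Fermi-Dirac log-likelihood of a network given its coordinates
#' @param net An \code{embedded_network} with coordinates and params R, T.
#' @return Scalar log-likelihood.
#' @export
network_loglikelihood <- function(net) {
  co <- net_coords(net)
  pa <- net_params(net)
  d <- hyperbolic_distance_matrix(co$r, co$theta)
  p <- connection_probability(d, pa$R, pa$T)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  A <- as.matrix(igraph::as_adjacency_matrix(net$graph, sparse = TRUE))
  ll <- A * log(p) + (1 - A) * log(1 - p)
  diag(ll) <- 0
  sum(ll) / 2
}

#' Pairwise hyperbolic distance matrix
#' @param r,theta Coordinate vectors.
#' @return Symmetric matrix of exact hyperbolic distances.
#' @export
hyperbolic_distance_matrix <- function(r, theta) {
  ch <- cosh(r); sh <- sinh(r)
  cth <- cos(theta); sth <- sin(theta)
  arg <- outer(ch, ch) - outer(sh, sh) * (outer(cth, cth) + outer(sth, sth))
  d <- acosh(pmax(arg, 1))
  diag(d) <- 0
  d
}

#' Refine angular coordinates by likelihood maximisation
#'
#' Visits nodes in decreasing-degree order (ties by id); each node's angle is
#' replaced by the best of its current angle plus
#' \code{n_candidate_angles - 1} uniform draws within \eqn{\pm w/2} of it,
#' judged by the node's contribution to the full Fermi-Dirac graph
#' log-likelihood. Keeping the current angle among the candidates makes each
#' replacement, and hence every sweep, non-decreasing in total likelihood.
#'
#' @param net An \code{embedded_network} with coordinates; if \code{R} is not
#'   in the parameters it is fitted to the observed mean degree first.
#' @param cfg An \code{\link{embedding_config}}.
#' @return The network with refined angles (params include the fitted
#'   \code{R}).
#' @export
refine_angles_likelihood <- function(net, cfg) {
  stopifnot(inherits(cfg, "embedding_config"))
  co <- net_coords(net)
  pa <- net_params(net)
  if (is.null(pa$R)) {
    kbar <- mean(igraph::degree(net$graph))
    pa$R <- fit_disk_radius(co$r, co$theta, cfg$T, kbar)
  }
  T_ <- cfg$T
  R <- pa$R
  n <- nrow(co)
  A <- as.matrix(igraph::as_adjacency_matrix(net$graph, sparse = TRUE)) > 0
  r <- co$r
  theta <- co$theta
  ch <- cosh(r); sh <- sinh(r)
  set.seed(cfg$seed)
  ord <- degree_order(net)
  for (sweep in seq_len(cfg$n_sweeps)) {
    for (i in ord) {
      cand <- theta[i]
      if (cfg$n_candidate_angles > 1) {
        cand <- c(cand, normalize_angle(
          theta[i] + stats::runif(cfg$n_candidate_angles - 1,
                                  -cfg$w / 2, cfg$w / 2)))
      }
      a_i <- A[i, -i]
      # candidate x others distance matrix for node i
      dth <- outer(cand, theta[-i], function(a, b) {
        dd <- abs(a - b); pmin(dd, 2 * pi - dd)
      })
      arg <- ch[i] * matrix(ch[-i], length(cand), n - 1, byrow = TRUE) -
        sh[i] * matrix(sh[-i], length(cand), n - 1, byrow = TRUE) * cos(dth)
      d <- acosh(pmax(arg, 1))
      p <- 1 / (1 + exp((d - R) / (2 * T_)))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- p
      ll[, a_i] <- log(p[, a_i, drop = FALSE])
      ll[, !a_i] <- log(1 - p[, !a_i, drop = FALSE])
      score <- rowSums(ll)
      best <- which.max(score)
      theta[i] <- cand[best]
    }
  }
  co$theta <- theta
  net_set(net, coords = co, params = list(R = R, T = T_, gamma = cfg$gamma))
}

#' Embed a network in the hyperbolic plane
#'
#' Full coordinate-inference pipeline: degree-rank radii, Laplacian-eigenmaps
#' angles, disk radius fitted to the observed mean degree, and (optionally)
#' likelihood refinement of the angles.
#'
#' @param net A connected \code{embedded_network} (no coordinates needed).
#' @param cfg An \code{\link{embedding_config}}.
#' @return The network with inferred coordinates and fitted parameters.
#' @export
embed_network <- function(net, cfg = embedding_config()) {
  r <- infer_radial_coordinates(net, cfg$gamma)
  theta <- infer_angular_coordinates(net)
  co <- data.frame(node = names(r), r = as.numeric(r),
                   theta = as.numeric(theta[names(r)]))
  kbar <- mean(igraph::degree(net$graph))
  R <- fit_disk_radius(co$r, co$theta, cfg$T, kbar)
  out <- net_set(net, coords = co,
                 params = list(gamma = cfg$gamma, T = cfg$T, R = R, zeta = 1,
                               N = igraph::vcount(net$graph)))
  if (cfg$refine) out <- refine_angles_likelihood(out, cfg)
  out
}

#' Circular correlation coefficient between two angle vectors
#'
#' Fisher-Lee T-linear association,
#' \deqn{r = \frac{\sum_{i<j} \sin(a_i - a_j)\sin(b_i - b_j)}
#'   {\sqrt{\sum_{i<j}\sin^2(a_i - a_j)\,\sum_{i<j}\sin^2(b_i - b_j)}},}
#' invariant under rotation of either vector and sign-flipped by reflection
#' (take the absolute value when either orientation is acceptable). Unlike
#' mean-direction-based variants it stays defined for angles spread uniformly
#' around the circle.
#'
#' @param a,b Angle vectors in radians (same length).
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
circular_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  sa <- outer(a, a, function(x, y) sin(x - y))
  sb <- outer(b, b, function(x, y) sin(x - y))
  num <- sum(sa[upper.tri(sa)] * sb[upper.tri(sb)])
  den <- sqrt(sum(sa[upper.tri(sa)]^2) * sum(sb[upper.tri(sb)]^2))
  num / den
}

#' Four-criterion evaluation of a hyperbolic map
#'
#' Checks the geometric self-consistency of an embedded network:
#' (i) the 20-bin empirical connection probability against the model curve;
#' (ii) the correlation of expected and actual degrees;
#' (iii) the global clustering coefficient against the mean over
#' \code{n_replicas} model networks with matched parameters;
#' (iv) greedy-routing success rate and median hop stretch against the same
#' replicas.
#'
#' @param net An \code{embedded_network} with coordinates and params.
#' @param n_replicas Model replicas for criteria (iii)-(iv); 0 skips them.
#' @param n_pairs,n_experiments Greedy-routing load for criterion (iv).
#' @param seed Integer seed for replica generation and routing draws.
#' @return List with fields \code{connection_prob_curve},
#'   \code{degree_agreement}, \code{clustering_observed},
#'   \code{clustering_psm_mean}, \code{gr_success_observed},
#'   \code{gr_success_psm}, \code{hop_stretch_observed},
#'   \code{hop_stretch_psm}.
#' @export
evaluate_embedding <- function(net, n_replicas = 10, n_pairs = 200,
                               n_experiments = 10, seed = 1L) {
  pa <- net_params(net)
  curve <- empirical_connection_probability(net, n_bins = 20)
  kk <- expected_degrees(net)
  deg <- igraph::degree(net$graph)[names(kk)]
  res <- list(
    connection_prob_curve = curve,
    degree_agreement = stats::cor(kk, deg),
    clustering_observed = igraph::transitivity(net$graph, type = "global"),
    clustering_psm_mean = NA_real_,
    gr_success_observed = NA_real_, gr_success_psm = NA_real_,
    hop_stretch_observed = NA_real_, hop_stretch_psm = NA_real_
  )
  cfg_r <- routing_config(n_pairs = n_pairs, n_experiments = n_experiments,
                          seed = seed)
  obs <- routing_efficiency(net, cfg_r)
  res$gr_success_observed <- stats::median(obs$efficiency)
  res$hop_stretch_observed <- stats::median(obs$hop_stretch)
  if (n_replicas > 0) {
    kbar <- mean(igraph::degree(net$graph))
    clus <- numeric(n_replicas)
    grs <- numeric(n_replicas)
    hs <- numeric(n_replicas)
    for (i in seq_len(n_replicas)) {
      rep_net <- generate_psm_network(psm_config(
        N = igraph::vcount(net$graph), gamma = pa$gamma, T_ = pa$T,
        target_mean_degree = kbar, seed = seed + i))
      clus[i] <- igraph::transitivity(rep_net$graph, type = "global")
      rep_lcc <- largest_component(rep_net)
      ro <- routing_efficiency(rep_lcc, routing_config(
        n_pairs = n_pairs, n_experiments = max(1, n_experiments %/% 2),
        seed = seed + i))
      grs[i] <- stats::median(ro$efficiency)
      hs[i] <- stats::median(ro$hop_stretch)
    }
    res$clustering_psm_mean <- mean(clus)
    res$gr_success_psm <- mean(grs)
    res$hop_stretch_psm <- mean(hs)
  }
  res
}
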