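#' @useDynLib hyperdm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import stats
#' @import utils
NULL

#' Minimal angular separation between two angles
#'
#' Angles are interpreted on the circle; inputs are normalised modulo
#' \eqn{2\pi} so any real value is accepted. The result is the shorter of the
#' two arcs between the angles, in \eqn{[0, \pi]}.
#'
#' @param theta_i,theta_j Numeric vectors of angles in radians (recycled).
#' @return Numeric vector of separations in \eqn{[0, \pi]}.
#' @examples
#' angular_separation(0.1, 2 * pi - 0.1) # 0.2
#' @export
angular_separation <- function(theta_i, theta_j) {
  d <- abs(normalize_angle(theta_i) - normalize_angle(theta_j))
  pmin(d, 2 * pi - d)
}

#' Normalise angles to [0, 2*pi)
#' @param theta Numeric vector of angles in radians.
#' @return Angles wrapped into \eqn{[0, 2\pi)}.
#' @export
normalize_angle <- function(theta) {
  theta %% (2 * pi)
}

#' Hyperbolic distance between points of the hyperbolic plane
#'
#' Distance between points given in native polar coordinates \eqn{(r, \theta)}
#' of the hyperbolic plane with curvature \eqn{K = -1}. The exact form is the
#' hyperbolic law of cosines,
#' \deqn{d = \mathrm{acosh}(\cosh r_i \cosh r_j -
#'       \sinh r_i \sinh r_j \cos\Delta\theta),}
#' and is the default throughout the package. The widely used large-radius
#' approximation \eqn{d \approx r_i + r_j + 2\ln(\Delta\theta / 2)} is
#' available as \code{mode = "approx"}; it diverges to \eqn{-\infty} as
#' \eqn{\Delta\theta \to 0}, so at \eqn{\Delta\theta = 0} it falls back to the
#' exact limit \eqn{|r_i - r_j|}.
#'
#' @param r_i,theta_i,r_j,theta_j Polar coordinates (vectors, recycled).
#'   Radii must be nonnegative.
#' @param mode "exact" (law of cosines, default) or "approx".
#' @return Numeric vector of distances.
#' @examples
#' hyperbolic_distance(10, 0, 10, pi)                  # exact
#' hyperbolic_distance(10, 0, 10, pi, mode = "approx") # 20 + 2*log(pi/2)
#' @export
hyperbolic_distance <- function(r_i, theta_i, r_j, theta_j,
                                mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  if (any(r_i < 0) || any(r_j < 0)) {
    stop("radial coordinates must be nonnegative")
  }
  dth <- angular_separation(theta_i, theta_j)
  if (mode == "exact") {
    arg <- cosh(r_i) * cosh(r_j) - sinh(r_i) * sinh(r_j) * cos(dth)
    # guard against arg sliply below 1 by rounding at dth ~ 0
    acosh(pmax(arg, 1))
  } else {
    out <- r_i + r_j + 2 * log(dth / 2)
    degenerate <- dth == 0
    if (any(degenerate)) {
      out[degenerate] <- abs(rep_len(r_i, length(out))[degenerate] -
                               rep_len(r_j, length(out))[degenerate])
    }
    out
  }
}

#' Fermi-Dirac connection probability
#'
#' Probability that two nodes at hyperbolic distance \code{x} are linked,
#' \deqn{p(x) = 1 / (1 + e^{(x - R) / (2T)}),}
#' where \code{R} is the radius of the hyperbolic disk and \code{T} the
#' network temperature. \code{T = 0} is the step-function limit (1 below
#' \code{R}, 0 above, 0.5 at \code{R}).
#'
#' @param x Nonnegative distances.
#' @param R Disk radius.
#' @param T_ Temperature, \code{>= 0}.
#' @return Probabilities in \eqn{[0, 1]}.
#' @examples
#' connection_probability(10, R = 10, T_ = 0.5) # 0.5 at x = R
#' @export
connection_probability <- function(x, R, T_) {
  if (any(x < 0)) stop("distances must be nonnegative")
  if (T_ < 0) stop("temperature must be nonnegative")
  if (T_ == 0) {
    p <- as.numeric(x < R)
    p[x == R] <- 0.5
    return(p)
  }
  1 / (1 + exp((x - R) / (2 * T_)))
}

#' Expected node degrees under the model
#'
#' For each node \eqn{i}, \eqn{\langle k_i\rangle = \sum_{j \ne i} p_{ij}}
#' with \eqn{p_{ij}} the Fermi-Dirac connection probability at the exact
#' hyperbolic distance between the nodes' coordinates.
#'
#' @param net An \code{\link{embedded_network}} with coordinates and model
#'   parameters (\code{R}, \code{T}).
#' @return Named numeric vector of expected degrees.
#' @export
expected_degrees <- function(net) {
  co <- net_coords(net)
  pa <- net_params(net)
  if (is.null(pa$R) || is.null(pa$T)) {
    stop("network parameters R and T are required")
  }
  k <- cpp_expected_degrees(co$r, co$theta, pa$R, pa$T)
  names(k) <- co$node
  k
}

#' Calibrate the hyperbolic disk radius to a target mean degree
#'
#' The mean expected degree \eqn{\bar{\langle k\rangle}} is strictly
#' increasing in the disk radius \code{R}; this solves for the \code{R} at
#' which it matches \code{target_mean_degree}, by monotone bisection to a
#' relative tolerance of \code{tol}.
#'
#' @param r,theta Node coordinates (same length, \code{>= 2} nodes).
#' @param T_ Temperature.
#' @param target_mean_degree Desired mean degree in \code{(0, N - 1)}.
#' @param tol Relative tolerance on the achieved mean degree.
#' @return The fitted radius \code{R}.
#' @export
fit_disk_radius <- function(r, theta, T_, target_mean_degree, tol = 1e-3) {
  n <- length(r)
  if (n < 2) stop("at least two coordinates are required")
  if (target_mean_degree <= 0 || target_mean_degree >= n - 1) {
    stop(sprintf(
      "target mean degree must lie in (0, %d); achievable range is (0, %d)",
      n - 1L, n - 1L
    ))
  }
  mean_deg <- function(R) cpp_mean_expected_degree(r, theta, R, T_)
  # bracket the target: mean degree -> 0 as R -> -Inf, -> N-1 as R -> Inf
  lo <- 0
  hi <- max(2 * max(r), 1)
  while (mean_deg(lo) > target_mean_degree) lo <- lo - hi
  while (mean_deg(hi) < target_mean_degree) hi <- hi * 2
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    val <- mean_deg(mid)
    if (abs(val - target_mean_degree) <= tol * target_mean_degree) {
      return(mid)
    }
    if (val < target_mean_degree) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
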