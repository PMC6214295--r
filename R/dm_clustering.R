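#' Mean nearest-neighbour distance between two modules
#'
#' For every node of A the minimum distance to any node of B, and vice versa;
#' the mean is taken over all \eqn{|A| + |B|} values. A node present in both
#' modules is at distance 0 from itself, so identical modules give 0.
#'
#' @param net An \code{embedded_network}.
#' @param A,B Character vectors of member node ids.
#' @param metric "hyperbolic" or "shortest_path".
#' @return The mean cross-module nearest distance.
#' @export
cross_nearest_mean <- function(net, A, B,
                               metric = c("hyperbolic", "shortest_path")) {
  metric <- match.arg(metric)
  A <- unique(as.character(A)); B <- unique(as.character(B))
  if (length(A) == 0 || length(B) == 0) stop("empty module")
  if (metric == "shortest_path") {
    d <- igraph::distances(net$graph, v = A, to = B)
  } else {
    co <- net_coords(net)
    ia <- match(A, co$node); ib <- match(B, co$node)
    if (anyNA(ia) || anyNA(ib)) stop("module member not in network")
    dth <- outer(co$theta[ia], co$theta[ib], function(a, b) {
      dd <- abs(a - b); pmin(dd, 2 * pi - dd)
    })
    arg <- outer(cosh(co$r[ia]), cosh(co$r[ib])) -
      outer(sinh(co$r[ia]), sinh(co$r[ib])) * cos(dth)
    d <- acosh(pmax(arg, 1))
    d[outer(A, B, "==")] <- 0
  }
  mean(c(apply(d, 1, min), apply(d, 2, min)))
}

#' Separation between two disease modules
#'
#' \deqn{s(A,B) = \langle d(A,B)\rangle -
#'   (\langle d(A,A)\rangle + \langle d(B,B)\rangle) / 2,}
#' where \eqn{\langle d(A,B)\rangle} is the mean nearest-neighbour distance
#' between the modules and \eqn{\langle d(A,A)\rangle} the mean distance of
#' each member to its nearest \emph{other} member. Negative values indicate
#' overlapping modules. The hyperbolic metric gives \eqn{s_H}, the
#' shortest-path metric the classical \eqn{s_s}.
#'
#' @param net An \code{embedded_network}.
#' @param A,B Member id vectors (each of size >= 2).
#' @param metric "hyperbolic" or "shortest_path".
#' @return The separation value.
#' @export
separation <- function(net, A, B, metric = c("hyperbolic", "shortest_path")) {
  metric <- match.arg(metric)
  if (length(unique(A)) < 2 || length(unique(B)) < 2) {
    stop("modules must have at least two members")
  }
  m <- if (metric == "hyperbolic") "hyperbolic" else "shortest_path"
  cross <- cross_nearest_mean(net, A, B, m)
  wa <- nearest_member_distances(net, A, m)$mean
  wb <- nearest_member_distances(net, B, m)$mean
  cross - (wa + wb) / 2
}

#' Jaccard distance between two sets
#' @param A,B Vectors (coerced to sets).
#' @return \eqn{1 - |A \cap B| / |A \cup B|}.
#' @export
jaccard_distance <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0) stop("both sets are empty")
  1 - length(intersect(A, B)) / u
}

#' Pairwise module dissimilarity matrix
#'
#' @param net An \code{embedded_network} (needs coordinates for
#'   \code{measure = "sH"}).
#' @param dms A \code{\link{disease_module_set}}.
#' @param measure "sH" (hyperbolic separation), "ss" (shortest-path
#'   separation) or "jaccard".
#' @return A symmetric matrix with the measure stored in attribute
#'   \code{"measure"}; s-measure diagonals hold
#'   \eqn{s(A,A) = -\langle d(A,A)\rangle}, the Jaccard diagonal is 0.
#' @export
separation_matrix <- function(net, dms, measure = c("sH", "ss", "jaccard")) {
  measure <- match.arg(measure)
  mods <- dms$modules
  ids <- names(mods)
  n <- length(mods)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (measure == "jaccard") {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- jaccard_distance(mods[[i]], mods[[j]])
      }
    }
  } else {
    metric <- if (measure == "sH") "hyperbolic" else "shortest_path"
    within <- vapply(mods, function(mm)
      nearest_member_distances(net, mm, metric)$mean, numeric(1))
    for (i in seq_len(n)) {
      m[i, i] <- -within[i]
      if (i < n) {
        for (j in (i + 1):n) {
          cross <- cross_nearest_mean(net, mods[[i]], mods[[j]], metric)
          m[i, j] <- m[j, i] <- cross - (within[i] + within[j]) / 2
        }
      }
    }
  }
  attr(m, "measure") <- measure
  m
}

# Separation values can be negative; MST and Ward need nonnegative
# dissimilarities. Rank-preserving shift by the most negative off-diagonal
# entry; diagonal forced to 0. No-op when already nonnegative.
shift_nonnegative <- function(m) {
  off <- m[row(m) != col(m)]
  if (length(off) > 0 && min(off) < 0) m <- m - min(off)
  diag(m) <- 0
  m
}

#' Non-centred minimum curvilinear embedding of a dissimilarity matrix
#'
#' Builds the minimum spanning tree of the complete weighted graph over the
#' samples, replaces every pairwise dissimilarity by the path length along
#' the tree (the minimum curvilinear distance), and decomposes that matrix by
#' singular value decomposition \emph{without centering}. Coordinates are the
#' left singular vectors scaled by the square roots of the singular values;
#' dimension 2 is the clustering axis. The sign of each singular vector is
#' fixed by making its largest-magnitude entry positive.
#'
#' @param dissimilarity Symmetric matrix (negative values are shifted).
#' @param n_dims Number of dimensions to return.
#' @return List with \code{ids}, \code{coords} (samples x dims) and
#'   \code{singular_values}.
#' @export
ncmce <- function(dissimilarity, n_dims = 2) {
  if (!isTRUE(all.equal(dissimilarity, t(dissimilarity),
                        check.attributes = FALSE))) {
    stop("dissimilarity matrix must be symmetric")
  }
  n <- nrow(dissimilarity)
  ids <- rownames(dissimilarity)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  m <- shift_nonnegative(unclass(dissimilarity))
  g <- igraph::make_full_graph(n)
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- m[cbind(el[, 1], el[, 2])]
  tree <- igraph::mst(g)
  D <- igraph::distances(tree, weights = igraph::E(tree)$weight)
  sv <- svd(D)
  keep <- seq_len(min(n_dims, n))
  u <- sv$u[, keep, drop = FALSE]
  for (k in seq_along(keep)) {
    if (u[which.max(abs(u[, k])), k] < 0) u[, k] <- -u[, k]
  }
  coords <- u * rep(sqrt(sv$d[keep]), each = n)
  dimnames(coords) <- list(ids, paste0("Dim", keep))
  list(ids = ids, coords = coords, singular_values = sv$d)
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' @param dissimilarity Symmetric matrix (negative values are shifted before
#'   clustering).
#' @param k Number of clusters for the cut.
#' @param method \code{hclust} linkage; Ward by default.
#' @return List with \code{labels} (named integer cluster ids) and
#'   \code{hclust} (the merge tree).
#' @export
ward_clustering <- function(dissimilarity, k, method = "ward.D2") {
  n <- nrow(dissimilarity)
  if (k > n) stop("k cannot exceed the number of modules")
  m <- shift_nonnegative(unclass(dissimilarity))
  hc <- stats::hclust(stats::as.dist(m), method = method)
  list(labels = stats::cutree(hc, k = k), hclust = hc)
}

#' Concordance score of category labels along one projection dimension
#'
#' Samples are ordered by their value on the dimension; \eqn{X} counts
#' adjacent pairs with differing labels. With \eqn{k} labels the best
#' achievable is \eqn{X_{min} = k - 1} (contiguous blocks) and the
#' random-ordering expectation is
#' \eqn{E_{rand} = (n-1)\,(1 - \sum_c n_c (n_c - 1) / (n (n - 1)))}.
#' The score \eqn{(E_{rand} - X) / (E_{rand} - X_{min})}, clamped to
#' \eqn{[0, 1]}, is 1 for a perfect ordering and about 0 for a random one.
#'
#' @param values Numeric vector (one projection coordinate per sample).
#' @param labels Category labels (>= 2 distinct).
#' @return A list with \code{score}, \code{x} (observed transitions),
#'   \code{x_min} and \code{e_rand}.
#' @export
c_score <- function(values, labels) {
  n <- length(values)
  stopifnot(length(labels) == n, n >= 3)
  labels <- as.character(labels)
  k <- length(unique(labels))
  if (k < 2) stop("C-score undefined for a single category")
  ord <- order(values)
  lab <- labels[ord]
  x <- sum(lab[-1] != lab[-n])
  x_min <- k - 1
  counts <- table(labels)
  e_rand <- (n - 1) * (1 - sum(counts * (counts - 1)) / (n * (n - 1)))
  score <- if (e_rand <= x_min) {
    as.numeric(x <= x_min)
  } else {
    min(max((e_rand - x) / (e_rand - x_min), 0), 1)
  }
  list(score = score, x = x, x_min = x_min, e_rand = e_rand)
}
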