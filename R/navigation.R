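#' Greedy-routing experiment configuration
#'
#' @param n_pairs Source-target pairs per experiment.
#' @param n_experiments Number of experiments.
#' @param n_faulty Faulty proteins injected per experiment (module
#'   experiments).
#' @param seed Integer seed for all pair and fault draws.
#' @return A \code{routing_config} list.
#' @export
routing_config <- function(n_pairs = 500, n_experiments = 100, n_faulty = 20,
                           seed = 1L) {
  stopifnot(n_pairs >= 1, n_experiments >= 1, n_faulty >= 0)
  structure(list(n_pairs = as.integer(n_pairs),
                 n_experiments = as.integer(n_experiments),
                 n_faulty = as.integer(n_faulty), seed = as.integer(seed)),
            class = "routing_config")
}

#' Greedy-route a single signal through the embedded network
#'
#' The current node forwards the signal to its neighbour with the smallest
#' hyperbolic distance to the target (the target itself, at distance 0,
#' always wins when adjacent; ties go to the lowest vertex index). Forwarding
#' to an already visited node (a loop) or to a faulty node (which drops the
#' signal) fails the routing.
#'
#' @param net An \code{embedded_network} with coordinates.
#' @param source,target Node ids; must differ and not be faulty.
#' @param faulty Character vector of faulty node ids.
#' @return List with \code{source}, \code{target}, \code{success},
#'   \code{path} (node ids, source first), \code{hops},
#'   \code{shortest_path_length} and \code{hop_stretch} (NA on failure).
#' @export
greedy_route <- function(net, source, target, faulty = character(0)) {
  if (source == target) stop("source and target must differ")
  if (source %in% faulty || target %in% faulty) {
    stop("endpoints must not be faulty")
  }
  co <- net_coords(net)
  nodes <- co$node
  s <- match(source, nodes); t <- match(target, nodes)
  if (is.na(s) || is.na(t)) stop("unknown source or target id")
  fset <- nodes %in% faulty
  g <- net$graph
  visited <- logical(length(nodes))
  visited[s] <- TRUE
  path <- s
  u <- s
  success <- FALSE
  repeat {
    nb <- as.integer(igraph::neighbors(g, u))
    if (length(nb) == 0) break
    d <- hyperbolic_distance(co$r[nb], co$theta[nb], co$r[t], co$theta[t])
    d[nb == t] <- 0
    best <- nb[which.min(d)]
    path <- c(path, best)
    if (best == t) { success <- TRUE; break }
    if (fset[best] || visited[best]) break
    visited[best] <- TRUE
    u <- best
  }
  hops <- length(path) - 1L
  sp <- as.integer(igraph::distances(g, v = source, to = target)[1, 1])
  list(source = source, target = target, success = success,
       path = nodes[path],
       hops = if (success) hops else NA_integer_,
       shortest_path_length = sp,
       hop_stretch = if (success) hops / sp else NA_real_)
}

# Draw n source-target pairs (1-based indices into the node order) from two
# pools, uniformly with replacement, rejecting self-pairs and faulty
# endpoints.
sample_pairs <- function(src_pool, tgt_pool, n, faulty_idx) {
  src_pool <- setdiff(src_pool, faulty_idx)
  tgt_pool <- setdiff(tgt_pool, faulty_idx)
  if (length(src_pool) < 1 || length(tgt_pool) < 1) {
    stop("routing pool empty after removing faulty nodes")
  }
  src <- sample(src_pool, n, replace = TRUE)
  tgt <- sample(tgt_pool, n, replace = TRUE)
  bad <- which(src == tgt)
  while (length(bad) > 0) {
    tgt[bad] <- sample(tgt_pool, length(bad), replace = TRUE)
    bad <- bad[src[bad] == tgt[bad]]
  }
  list(src = src, tgt = tgt)
}

# Shared batch driver: one experiment of n_pairs routings with a fixed
# faulty-index set. Returns efficiency and successful hop stretches.
run_experiment <- function(csr, co, src_pool, tgt_pool, n_pairs, faulty_idx) {
  fl <- logical(csr$n)
  fl[faulty_idx] <- TRUE
  pr <- sample_pairs(src_pool, tgt_pool, n_pairs, faulty_idx)
  res <- cpp_route_batch(csr$ptr, csr$idx, co$r, co$theta,
                         pr$src - 1L, pr$tgt - 1L, fl)
  ok <- which(res$success)
  hs <- numeric(0)
  if (length(ok) > 0) {
    sp <- cpp_bfs_pairs(csr$ptr, csr$idx, pr$src[ok] - 1L, pr$tgt[ok] - 1L)
    hs <- res$hops[ok] / sp
  }
  list(efficiency = length(ok) / n_pairs, hop_stretch = hs)
}

#' Greedy-routing efficiency over repeated experiments
#'
#' Runs \code{cfg$n_experiments} experiments of \code{cfg$n_pairs} randomly
#' drawn source-target pairs each; efficiency is the fraction of successful
#' routings per experiment, and hop stretch (greedy hops over shortest-path
#' length) is collected over successful routings only.
#'
#' @param net An \code{embedded_network} with coordinates.
#' @param cfg A \code{\link{routing_config}}.
#' @param faulty Character vector of faulty node ids (fixed across
#'   experiments).
#' @param source_pool,target_pool Optional node-id pools to draw from
#'   (default: all nodes).
#' @return List with \code{efficiency} (per-experiment vector) and
#'   \code{hop_stretch} (vector over all successful routings).
#' @export
routing_efficiency <- function(net, cfg = routing_config(),
                               faulty = character(0),
                               source_pool = NULL, target_pool = NULL) {
  co <- net_coords(net)
  nodes <- co$node
  csr <- net_csr(net)
  all_idx <- seq_along(nodes)
  sp <- if (is.null(source_pool)) all_idx else match(source_pool, nodes)
  tp <- if (is.null(target_pool)) all_idx else match(target_pool, nodes)
  if (anyNA(sp) || anyNA(tp)) stop("pool node not in network")
  fidx <- match(intersect(faulty, nodes), nodes)
  set.seed(cfg$seed)
  eff <- numeric(cfg$n_experiments)
  hs <- vector("list", cfg$n_experiments)
  for (e in seq_len(cfg$n_experiments)) {
    res <- run_experiment(csr, co, sp, tp, cfg$n_pairs, fidx)
    eff[e] <- res$efficiency
    hs[[e]] <- res$hop_stretch
  }
  list(efficiency = eff, hop_stretch = unlist(hs))
}

#' Degree-matched control pool for a node set
#'
#' Non-members falling in the same log2-degree bin as any member; when a
#' member's bin has no non-member, the nearest non-empty bin is used.
#'
#' @param net An \code{embedded_network}.
#' @param members Character vector of member node ids.
#' @return Character vector of control node ids.
#' @export
degree_matched_pool <- function(net, members) {
  deg <- igraph::degree(net$graph)
  nodes <- names(deg)
  bins <- floor(log2(pmax(deg, 1)))
  member_bins <- unique(bins[match(intersect(members, nodes), nodes)])
  non <- setdiff(nodes, members)
  pool <- character(0)
  for (b in member_bins) {
    cand <- non[bins[match(non, nodes)] == b]
    if (length(cand) == 0) {
      # nearest non-empty bin among non-members
      nb_bins <- sort(unique(bins[match(non, nodes)]))
      b2 <- nb_bins[which.min(abs(nb_bins - b))]
      cand <- non[bins[match(non, nodes)] == b2]
    }
    pool <- union(pool, cand)
  }
  pool
}

#' Navigability impact of a disease module's faulty proteins
#'
#' Runs \code{cfg$n_experiments} experiments (50 by default for impact runs);
#' in each, \code{cfg$n_faulty} faulty proteins are freshly drawn from the
#' module members and the greedy-routing efficiency over \code{cfg$n_pairs}
#' pairs is measured. The impact is the mean of these efficiencies minus the
#' reference efficiency of the fault-free network. The same protocol is
#' repeated drawing faults from a degree-matched non-member pool, and the two
#' per-experiment impact samples are compared with a one-sided Mann-Whitney U
#' test (module impacts lower).
#'
#' @param net An \code{embedded_network} with coordinates.
#' @param module Character vector of module member ids.
#' @param cfg A \code{\link{routing_config}}; use
#'   \code{routing_config(n_experiments = 50, n_faulty = 20)} for the
#'   standard protocol.
#' @param reference_efficiency Fault-free mean efficiency; computed on
#'   \code{net} with the same \code{cfg} when NULL.
#' @param alpha Significance level.
#' @return List with \code{impact}, \code{reference_efficiency},
#'   \code{mean_efficiency}, per-experiment \code{impacts_module} and
#'   \code{impacts_matched}, \code{p_value}, \code{significant} and
#'   \code{fault_frequency} (named counts over module draws).
#' @export
disease_impact <- function(net, module, cfg = routing_config(n_experiments = 50),
                           reference_efficiency = NULL, alpha = 0.05) {
  nodes <- net_nodes(net)
  module <- intersect(unique(as.character(module)), nodes)
  n_faulty <- cfg$n_faulty
  if (length(module) < n_faulty) {
    warning(sprintf("module smaller than n_faulty; lowering n_faulty to %d",
                    length(module)))
    n_faulty <- length(module)
  }
  if (is.null(reference_efficiency)) {
    ref <- routing_efficiency(net, routing_config(
      n_pairs = cfg$n_pairs, n_experiments = cfg$n_experiments,
      n_faulty = 0, seed = cfg$seed))
    reference_efficiency <- mean(ref$efficiency)
  }
  co <- net_coords(net)
  csr <- net_csr(net)
  all_idx <- seq_along(nodes)
  mod_idx <- match(module, nodes)
  matched <- match(degree_matched_pool(net, module), nodes)
  freq <- integer(length(nodes))
  run_condition <- function(pool_idx, count_faults) {
    eff <- numeric(cfg$n_experiments)
    nf <- min(n_faulty, length(pool_idx))
    for (e in seq_len(cfg$n_experiments)) {
      fidx <- if (nf > 0) sample(pool_idx, nf) else integer(0)
      if (count_faults) freq[fidx] <<- freq[fidx] + 1L
      eff[e] <- run_experiment(csr, co, all_idx, all_idx, cfg$n_pairs,
                               fidx)$efficiency
    }
    eff
  }
  set.seed(cfg$seed)
  eff_mod <- run_condition(mod_idx, TRUE)
  eff_mat <- run_condition(matched, FALSE)
  impacts_module <- eff_mod - reference_efficiency
  impacts_matched <- eff_mat - reference_efficiency
  pv <- stats::wilcox.test(impacts_module, impacts_matched,
                           alternative = "less", exact = FALSE)$p.value
  names(freq) <- nodes
  list(impact = mean(impacts_module),
       reference_efficiency = reference_efficiency,
       mean_efficiency = mean(eff_mod),
       impacts_module = impacts_module,
       impacts_matched = impacts_matched,
       p_value = pv, significant = pv < alpha,
       fault_frequency = freq[freq > 0])
}

#' Receptor-to-transcription-factor routing experiment
#'
#' Compares greedy-routing efficiency and hop stretch across three
#' conditions: random source-target pairs (reference), receptor sources to
#' transcription-factor targets, and a degree-matched control of
#' non-Rec/non-TF proteins. Pairwise Mann-Whitney U tests are reported on
#' per-experiment efficiencies and on hop-stretch distributions.
#'
#' @param net An \code{embedded_network} with coordinates.
#' @param annotations Named list node id -> classes (must contain "Rec" and
#'   "TF" members).
#' @param cfg A \code{\link{routing_config}}.
#' @param pool_size Number of receptors and of TFs drawn into the pools.
#' @return List of per-condition results and pairwise p-values.
#' @export
rec_tf_experiment <- function(net, annotations, cfg = routing_config(),
                              pool_size = 500) {
  nodes <- net_nodes(net)
  has <- function(cls) {
    ids <- names(annotations)[vapply(annotations, function(x) cls %in% x,
                                     logical(1))]
    intersect(ids, nodes)
  }
  recs <- has("Rec"); tfs <- has("TF")
  if (length(recs) == 0 || length(tfs) == 0) {
    stop("annotations must contain both Rec and TF members")
  }
  set.seed(cfg$seed)
  rec_pool <- if (length(recs) > pool_size) sample(recs, pool_size) else recs
  tf_pool <- if (length(tfs) > pool_size) sample(tfs, pool_size) else tfs
  neither <- setdiff(nodes, union(recs, tfs))
  ctrl_src <- intersect(degree_matched_pool(net, rec_pool), neither)
  ctrl_tgt <- intersect(degree_matched_pool(net, tf_pool), neither)
  if (length(ctrl_src) > pool_size) ctrl_src <- sample(ctrl_src, pool_size)
  if (length(ctrl_tgt) > pool_size) ctrl_tgt <- sample(ctrl_tgt, pool_size)
  reference <- routing_efficiency(net, cfg)
  rec_tf <- routing_efficiency(net, cfg, source_pool = rec_pool,
                               target_pool = tf_pool)
  control <- routing_efficiency(net, cfg, source_pool = ctrl_src,
                                target_pool = ctrl_tgt)
  mw <- function(a, b) stats::wilcox.test(a, b, exact = FALSE)$p.value
  list(
    reference = reference, rec_tf = rec_tf, control = control,
    p_efficiency = list(
      rec_tf_vs_reference = mw(rec_tf$efficiency, reference$efficiency),
      rec_tf_vs_control = mw(rec_tf$efficiency, control$efficiency)),
    p_hop_stretch = list(
      rec_tf_vs_reference = mw(rec_tf$hop_stretch, reference$hop_stretch),
      rec_tf_vs_control = mw(rec_tf$hop_stretch, control$hop_stretch))
  )
}

# Third quartile by R's default (type-7) quantile; e.g. {1,1,1,9} -> 3.
upper_quartile <- function(x) {
  unname(stats::quantile(x, 0.75, type = 7))
}

#' Frequent faulty proteins and their drug-target enrichment
#'
#' Proteins drawn as faulty more often than the upper quartile (type-7 Q3)
#' of the frequency distribution form the frequent set. Two one-sided
#' Fisher exact tests compare the proportion of FDA-approved and of potential
#' drug targets between frequent and infrequent faulty proteins.
#'
#' @param fault_frequency Named integer vector protein -> times drawn as
#'   faulty.
#' @param targets data.frame with columns \code{node}, \code{flag}
#'   (\code{"fda"} or \code{"potential"}); see
#'   \code{\link{read_target_flags}}.
#' @param alpha Significance level.
#' @return List with \code{frequent}, \code{infrequent}, \code{q3} and per
#'   flag the 2x2 table, p-value and significance.
#' @export
frequent_faulty <- function(fault_frequency, targets, alpha = 0.05) {
  if (length(fault_frequency) == 0) stop("empty fault-frequency table")
  q3 <- upper_quartile(fault_frequency)
  frequent <- names(fault_frequency)[fault_frequency > q3]
  infrequent <- setdiff(names(fault_frequency), frequent)
  if (length(frequent) == 0) {
    message("all fault frequencies at or below Q3; frequent set is empty")
  }
  test_flag <- function(flag) {
    flagged <- unique(targets$node[targets$flag == flag])
    tab <- matrix(c(
      sum(frequent %in% flagged), sum(!(frequent %in% flagged)),
      sum(infrequent %in% flagged), sum(!(infrequent %in% flagged))
    ), nrow = 2, byrow = TRUE,
    dimnames = list(c("frequent", "infrequent"), c("target", "not_target")))
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    list(table = tab, p_value = p, significant = p < alpha)
  }
  list(frequent = frequent, infrequent = infrequent, q3 = q3,
       fda = test_flag("fda"), potential = test_flag("potential"))
}
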