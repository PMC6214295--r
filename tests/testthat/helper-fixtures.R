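# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small PSM network (LCC) with ground-truth coordinates.
psm_small <- function() {
  cached("psm_small", largest_component(
    generate_psm_network(psm_config(300, 2.5, 0.3, 8, seed = 101))))
}

# Low-temperature PSM network for navigability / recovery tests.
psm_cold <- function() {
  cached("psm_cold", largest_component(
    generate_psm_network(psm_config(400, 2.5, 0.1, 8, seed = 202))))
}

# Path graph 1-2-...-10 as an embedded_network (no coordinates).
path10 <- function() {
  g <- igraph::make_ring(10, circular = FALSE)
  igraph::V(g)$name <- as.character(1:10)
  embedded_network(g)
}

# Collinear hyperbolic coordinates: with equal angles the exact distance
# between (r1, 0) and (r2, 0) is |r1 - r2|, so pairwise distances can be
# dictated by the radii.
collinear_net <- function(radii, edges = NULL) {
  n <- length(radii)
  ids <- paste0("v", seq_len(n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  embedded_network(g, coords = data.frame(node = ids, r = radii, theta = 0),
                   params = list(R = 10, T = 0.5))
}

expect_setequal_chr <- function(a, b) {
  expect_setequal(as.character(a), as.character(b))
}
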