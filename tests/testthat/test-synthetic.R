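test_that("generator is reproducible from its seed", {
  cfg <- psm_config(100, 2.5, 0.5, 6, seed = 77)
  n1 <- generate_psm_network(cfg)
  n2 <- generate_psm_network(cfg)
  expect_identical(igraph::as_edgelist(n1$graph), igraph::as_edgelist(n2$graph))
  expect_identical(net_coords(n1), net_coords(n2))
  n3 <- generate_psm_network(psm_config(100, 2.5, 0.5, 6, seed = 78))
  expect_false(identical(igraph::as_edgelist(n1$graph),
                         igraph::as_edgelist(n3$graph)))
})

test_that("generator calibrates the mean degree", {
  # scaled down from 20 seeds at N=2000 to keep the suite fast; the 5%
  # band is unchanged
  realized <- vapply(1:8, function(s) {
    net <- generate_psm_network(psm_config(1000, 2.5, 0.5, 10, seed = s))
    mean(igraph::degree(net$graph))
  }, numeric(1))
  expect_lt(abs(mean(realized) - 10) / 10, 0.05)
})

test_that("generator recovers the target degree exponent", {
  net <- generate_psm_network(psm_config(5000, 2.5, 0.3, 10, seed = 12))
  gamma_hat <- fit_power_law_gamma(igraph::degree(net$graph))
  expect_gt(gamma_hat, 2.2)
  expect_lt(gamma_hat, 2.8)
})

test_that("invalid generator configs are rejected", {
  expect_error(psm_config(100, gamma = 1.8))
  expect_error(psm_config(100, T_ = 0))
  expect_error(psm_config(100, target_mean_degree = 120))
})

test_that("empirical connection probability covers all pairs and edge cases", {
  # complete graph: every bin fraction 1
  g <- igraph::make_full_graph(8)
  igraph::V(g)$name <- paste0("v", 1:8)
  set.seed(5)
  co <- data.frame(node = paste0("v", 1:8), r = runif(8, 1, 5),
                   theta = runif(8, 0, 2 * pi))
  net <- embedded_network(g, coords = co)
  curve <- empirical_connection_probability(net, n_bins = 5)
  expect_equal(sum(curve$n_pairs), choose(8, 2))
  expect_true(all(curve$fraction[curve$n_pairs > 0] == 1))
  # edgeless graph: every fraction 0
  g0 <- igraph::make_empty_graph(8, directed = FALSE)
  igraph::V(g0)$name <- co$node
  curve0 <- empirical_connection_probability(embedded_network(g0, coords = co),
                                             n_bins = 5)
  expect_true(all(curve0$fraction[curve0$n_pairs > 0] == 0))
})

test_that("empirical connection probability tracks the model curve", {
  net <- generate_psm_network(psm_config(1000, 2.5, 0.5, 10, seed = 21))
  curve <- empirical_connection_probability(net, n_bins = 20)
  # each observed fraction within the 99% binomial CI of the model value at
  # the bin midpoint (midpoint approximation leaves a little slack; bins
  # with very few pairs are informationless)
  ok <- curve$n_pairs >= 30
  lo <- qbinom(0.005, curve$n_pairs[ok], pmin(pmax(curve$model_p[ok], 0), 1))
  hi <- qbinom(0.995, curve$n_pairs[ok], pmin(pmax(curve$model_p[ok], 0), 1))
  inside <- curve$n_connected[ok] >= lo & curve$n_connected[ok] <= hi
  expect_gt(mean(inside), 0.8)
})

test_that("planted modules honour concentration and background settings", {
  net <- psm_small()
  co <- net_coords(net)
  cfg <- synthetic_disease_config(
    n_diseases = 2, members_per_disease = c(10L, 10L),
    components_per_disease = c(1L, 1L), angular_concentration = 0.15,
    background_fraction = 0, seed = 31)
  dms <- plant_disease_modules(net, cfg)
  truth <- attr(dms, "truth")
  for (id in names(dms$modules)) {
    th <- co$theta[match(dms$modules[[id]], co$node)]
    sep <- angular_separation(th, truth[[id]]$centres[1])
    expect_true(all(sep <= 0.15 + 1e-9))
  }
  # reproducibility
  dms2 <- plant_disease_modules(net, cfg)
  expect_identical(dms$modules, dms2$modules)
})

test_that("diseases sharing centres overlap more than uniform sampling", {
  net <- psm_small()
  cfg <- synthetic_disease_config(
    n_diseases = 4, members_per_disease = c(15L, 15L),
    components_per_disease = c(2L, 2L), angular_concentration = 0.2,
    background_fraction = 0, n_categories = 2, seed = 8)
  dms <- plant_disease_modules(net, cfg)
  # diseases 1 and 3 share category block 1 (1-based index mod 2)
  obs <- 1 - jaccard_distance(dms$modules[[1]], dms$modules[[3]])
  # permutation oracle: Jaccard of size-matched uniform draws
  nodes <- net_nodes(net)
  set.seed(99)
  null <- replicate(200, {
    a <- sample(nodes, length(dms$modules[[1]]))
    b <- sample(nodes, length(dms$modules[[3]]))
    1 - jaccard_distance(a, b)
  })
  expect_gt(obs, quantile(null, 0.95))
})

test_that("full-background modules have uniform angles", {
  net <- psm_small()
  co <- net_coords(net)
  # large-sample Rayleigh test of circular uniformity
  rayleigh_p <- function(th) {
    n <- length(th)
    rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    exp(-n * rbar^2)
  }
  ps <- vapply(1:20, function(s) {
    dms <- plant_disease_modules(net, synthetic_disease_config(
      n_diseases = 1, members_per_disease = c(40L, 40L),
      background_fraction = 1, seed = s))
    rayleigh_p(co$theta[match(dms$modules[[1]], co$node)])
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("planted class annotations respect purity and sector membership", {
  net <- psm_small()
  co <- net_coords(net)
  sm <- default_sector_map()
  ann <- plant_class_annotations(net, sm, purity = 1, background_rate = 0,
                                 seed = 3)
  for (nd in names(ann)) {
    th <- co$theta[match(nd, co$node)]
    iv <- sm[[ann[[nd]]]]
    expect_true(th >= iv[1] && th < iv[2])
  }
  expect_error(
    plant_class_annotations(net, list(TF = c(0, 1), Rec = c(0.5, 1.5))),
    "disjoint")
})

test_that("synthetic outputs survive the TSV round trip", {
  net <- psm_small()
  dir <- withr::local_tempdir()
  write_edge_list(net, file.path(dir, "edges.tsv"))
  write_coords(net, file.path(dir, "coords.tsv"))
  back <- build_network(read_edge_list(file.path(dir, "edges.tsv")))
  back <- net_set(back, coords = read_coords(file.path(dir, "coords.tsv")))
  expect_setequal_chr(net_nodes(back), net_nodes(net))
  expect_equal(igraph::ecount(back$graph), igraph::ecount(net$graph))
  co1 <- net_coords(net); co2 <- net_coords(back)
  expect_equal(co2[match(co1$node, co2$node), "theta"], co1$theta,
               tolerance = 1e-12)
})
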