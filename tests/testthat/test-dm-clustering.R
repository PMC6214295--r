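test_that("cross-module nearest mean matches brute-force enumeration", {
  net <- psm_small()
  co <- net_coords(net)
  set.seed(23)
  for (i in 1:5) {
    A <- sample(co$node, 6)
    B <- sample(co$node, 4)
    got <- cross_nearest_mean(net, A, B, "hyperbolic")
    ia <- match(A, co$node); ib <- match(B, co$node)
    d <- hyperbolic_distance_matrix(co$r, co$theta)[ia, ib]
    d[outer(A, B, "==")] <- 0
    oracle <- mean(c(apply(d, 1, min), apply(d, 2, min)))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # identical modules: every nearest neighbour is the node itself
  A <- sample(co$node, 5)
  expect_equal(cross_nearest_mean(net, A, A, "hyperbolic"), 0)
  expect_equal(cross_nearest_mean(net, A, A, "shortest_path"), 0)
  # singleton pair at a known distance (collinear radii 1 and 8)
  cnet <- collinear_net(c(1, 8))
  expect_equal(cross_nearest_mean(cnet, "v1", "v2", "hyperbolic"), 7)
})

test_that("separation follows its defining formula", {
  cnet <- collinear_net(c(0, 1, 6, 7.5))
  A <- c("v1", "v2"); B <- c("v3", "v4")
  # hand enumeration: cross minima are v1->6, v2->5, v3->5, v4->6.5, so
  # <d(A,B)> = 5.625; within means are 1 (A) and 1.5 (B)
  expect_equal(cross_nearest_mean(cnet, A, B, "hyperbolic"), 5.625)
  got <- separation(cnet, A, B, "hyperbolic")
  expect_equal(got, 5.625 - (1 + 1.5) / 2)
  # A = B gives -<d(A,A)>
  expect_equal(separation(cnet, A, A, "hyperbolic"), -1)
  expect_error(separation(cnet, "v1", B), "two members")
})

test_that("separation matrices are symmetric with the stated diagonal", {
  net <- psm_small()
  dms <- plant_disease_modules(net, synthetic_disease_config(
    n_diseases = 4, members_per_disease = c(8L, 12L), seed = 3))
  for (measure in c("sH", "jaccard")) {
    m <- separation_matrix(net, dms, measure)
    expect_equal(m, t(m), ignore_attr = TRUE)
    if (measure == "jaccard") expect_true(all(diag(m) == 0))
    else expect_true(all(diag(m) <= 0))
  }
})

test_that("well-separated planted modules have positive separation", {
  net <- psm_small()
  co <- net_coords(net)
  near <- function(center, n) {
    ord <- order(angular_separation(co$theta, center))
    co$node[ord[seq_len(n)]]
  }
  A <- near(0.5, 10)
  B <- near(pi + 0.5, 10)
  expect_gt(separation(net, A, B, "hyperbolic"), 0)
  expect_equal(separation(net, A, B, "hyperbolic"),
               separation(net, B, A, "hyperbolic"))
})

test_that("jaccard distance satisfies its definition and triangle inequality", {
  expect_equal(jaccard_distance(1:4, 1:4), 0)
  expect_equal(jaccard_distance(1:3, 4:6), 1)
  expect_equal(jaccard_distance(1:5, 4:8), 0.75)  # |int|=2, |union|=8
  expect_error(jaccard_distance(character(0), character(0)), "empty")
  set.seed(15)
  for (i in 1:30) {
    A <- sample(letters, 8); B <- sample(letters, 8); C <- sample(letters, 8)
    expect_lte(jaccard_distance(A, B),
               jaccard_distance(A, C) + jaccard_distance(C, B) + 1e-12)
  }
})

test_that("ncmce reproduces the line geometry of collinear points", {
  # 3 collinear points with gaps 1 and 1: the MST is the path, so the
  # minimum curvilinear distances equal the input distances
  D <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  pr <- ncmce(D, n_dims = 3)
  # independent SVD oracle on the same matrix: the minimum curvilinear
  # distances along the path MST equal the input distances, so ncmce must
  # reproduce the plain SVD coordinates up to per-column sign
  sv <- svd(D)
  expect_equal(pr$singular_values, sv$d, tolerance = 1e-12)
  expect_equal(abs(pr$coords), abs(sv$u * rep(sqrt(sv$d), each = 3)),
               ignore_attr = TRUE, tolerance = 1e-10)
  # line ordering preserved (monotone along some dimension)
  dim2 <- pr$coords[, 2]
  expect_true(all(diff(dim2) > 0) || all(diff(dim2) < 0))
  expect_error(ncmce(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ncmce two-point embedding encodes the pair distance", {
  D <- matrix(c(0, 3, 3, 0), 2, 2)
  pr <- ncmce(D, n_dims = 2)
  expect_equal(pr$singular_values, c(3, 3), tolerance = 1e-12)
  # the two rows differ in exactly one dimension by sqrt(2 d); squared
  # row distance = 2 d
  expect_equal(sum((pr$coords[1, ] - pr$coords[2, ])^2), 2 * 3,
               tolerance = 1e-10)
})

test_that("ward clustering recovers blocks and is monotone", {
  set.seed(6)
  # two tight blocks with large between-block dissimilarity
  n <- 10
  m <- matrix(5, n, n)
  m[1:5, 1:5] <- 0.5
  m[6:10, 6:10] <- 0.5
  diag(m) <- 0
  m <- m + matrix(runif(n * n, 0, 0.05), n, n)
  m <- (m + t(m)) / 2; diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("d", 1:n)
  cl <- ward_clustering(m, k = 2)
  expect_equal(length(unique(cl$labels[1:5])), 1)
  expect_equal(length(unique(cl$labels[6:10])), 1)
  expect_false(cl$labels[1] == cl$labels[6])
  expect_true(all(diff(cl$hclust$height) >= -1e-9))
  cln <- ward_clustering(m, k = n)
  expect_equal(length(unique(cln$labels)), n)
  expect_error(ward_clustering(m, k = n + 1), "exceed")
})

test_that("c-score matches hand enumeration of the transition formula", {
  # AABB: X = 1 = X_min, E_rand = 2 -> score 1
  expect_equal(c_score(1:4, c("A", "A", "B", "B"))$score, 1)
  # ABAB: X = 3, clamp((2 - 3)/(2 - 1)) -> 0
  expect_equal(c_score(1:4, c("A", "B", "A", "B"))$score, 0)
  # perfect contiguous blocks of any sizes
  expect_equal(c_score(1:9, rep(c("x", "y", "z"), c(2, 4, 3)))$score, 1)
  expect_error(c_score(1:4, rep("A", 4)), "single")
})

test_that("random label permutations give c-scores near zero", {
  set.seed(123)
  labs <- rep(c("A", "B", "C"), each = 10)
  scores <- replicate(1000, c_score(1:30, sample(labs))$score)
  expect_gte(mean(scores), 0)
  expect_lte(mean(scores), 0.1)
})

test_that("hyperbolic separation clusters categories at least as well as jaccard", {
  net <- psm_small()
  dms <- plant_disease_modules(net, synthetic_disease_config(
    n_diseases = 9, members_per_disease = c(12L, 18L),
    angular_concentration = 0.2, background_fraction = 0,
    n_categories = 3, seed = 19))
  cats <- dms$categories
  score_for <- function(measure) {
    m <- separation_matrix(net, dms, measure)
    pr <- ncmce(m)
    c_score(pr$coords[, 2], cats[pr$ids])$score
  }
  s_h <- score_for("sH")
  s_j <- score_for("jaccard")
  expect_gte(s_h, s_j)
  expect_gt(s_h, 0.9)
})
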