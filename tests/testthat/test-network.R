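test_that("threshold sweep counts edges at or above each cutoff", {
  sc <- scores_fixture(c("a", "b", "c"), c("x", "y", "z"), c(10, 60, 70))
  sw <- threshold_sweep(sc, c(0, 60, 80))
  expect_equal(sw$n_edges, c(3L, 2L, 0L))
  expect_true(all(diff(sw$n_edges) <= 0))
  expect_equal(threshold_sweep(sc, 5)$n_edges, 3L)
})

test_that("build_network keeps exactly the qualifying edges, ties included", {
  sc <- scores_fixture(c("a", "b", "c", "d"), c("x", "y", "z", "w"),
                       c(59.9, 60, 75, 30))
  net <- build_network(sc, 60)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$t1, c("b", "c"))
  # threshold at the max keeps the tied top edge
  top <- build_network(sc, 75)
  expect_equal(nrow(top$edges), 1)
  expect_warning(empty <- build_network(sc, 100), "no edges")
  expect_equal(nrow(empty$edges), 0)
  # sweep count and network edge count agree at every threshold
  for (th in c(0, 30, 59.9, 60, 75))
    expect_equal(nrow(suppressWarnings(build_network(sc, th))$edges),
                 threshold_sweep(sc, th)$n_edges)
})

test_that("degree statistics match hand counts on small graphs", {
  tri <- build_network(
    scores_fixture(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1)), 1)
  ds <- degree_stats(tri)
  expect_equal(ds$n_nodes, 3)
  expect_equal(ds$degree_histogram$degree, 2L)
  expect_equal(ds$degree_histogram$count, 3L)
  star <- build_network(
    scores_fixture(rep("hub", 4), sprintf("l%d", 1:4), rep(1, 4)), 1)
  ds2 <- degree_stats(star)
  expect_equal(ds2$hubs, "hub")
  expect_equal(ds2$hub_degree, 4)
  expect_equal(ds2$fraction_degree1, 0.8)
  path2 <- build_network(scores_fixture("a", "b", 1), 1)
  expect_equal(degree_stats(path2)$fraction_degree1, 1)
  # tied hubs are all reported
  two_stars <- build_network(
    scores_fixture(c("h1", "h1", "h2", "h2"), c("p", "q", "r", "s"),
                   rep(1, 4)), 1)
  expect_setequal(degree_stats(two_stars)$hubs, c("h1", "h2"))
})

test_that("giant component size is the largest component's node count", {
  sc <- scores_fixture(c("a", "b", "d"), c("b", "c", "e"), c(1, 1, 1))
  expect_equal(giant_component(build_network(sc, 1)), 3)
  comps <- scores_fixture(
    c("a", "b", "c", "d", "f", "g", "h", "i", "k"),
    c("b", "c", "d", "e", "g", "h", "i", "j", "l"),
    rep(1, 9))   # components of sizes 5, 5, 2
  expect_equal(giant_component(build_network(comps, 1)), 5)
})

test_that("raising the threshold never grows the giant component", {
  set.seed(31)
  n <- 40
  pairs <- t(combn(sprintf("n%02d", 1:n), 2))
  keep <- sample(nrow(pairs), 120)
  sc <- scores_fixture(pairs[keep, 1], pairs[keep, 2],
                       runif(120, 0, 100))
  sizes <- vapply(c(0, 25, 50, 75), function(th)
    giant_component(suppressWarnings(build_network(sc, th))), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("gc significance uses the add-one estimator against G(n, m)", {
  # a dense clique has the largest possible giant component for its size:
  # every random network's giant component is <= observed, so p -> 1
  clique_pairs <- t(combn(sprintf("c%d", 1:8), 2))
  clique <- build_network(
    scores_fixture(clique_pairs[, 1], clique_pairs[, 2],
                   rep(1, nrow(clique_pairs))), 1)
  gs <- gc_significance(clique, n_replicates = 200, side = "smaller",
                        seed = 4)
  expect_equal(gs$p_value, 1)
  # an observation at the empirical rank r has p = (r + 1) / (n + 1)
  r <- sum(gs$replicate_sizes <= gs$observed)
  expect_equal(gs$p_value, (r + 1) / 201)
  # determinism under a fixed seed
  gs2 <- gc_significance(clique, n_replicates = 200, side = "smaller",
                         seed = 4)
  expect_identical(gs$replicate_sizes, gs2$replicate_sizes)
})

test_that("a fragmented observed network attains the p-value floor", {
  # 30 disjoint edges: giant component 2, essentially never matched by
  # G(60, 30) which concentrates around larger components
  sc <- scores_fixture(sprintf("u%02d", 1:30), sprintf("v%02d", 1:30),
                       rep(1, 30))
  net <- build_network(sc, 1)
  expect_equal(giant_component(net), 2)
  gs <- gc_significance(net, n_replicates = 500, side = "smaller", seed = 9)
  expect_equal(gs$p_value, 1 / 501)
})

test_that("an exact k^-2 histogram fits slope -2 with R^2 = 1", {
  k <- 1:8
  hist <- data.frame(degree = k, count = 1e6 * k^-2)
  fit <- powerlaw_fit(hist)
  expect_equal(fit$slope, -2, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("power-law fitting needs at least three distinct degrees", {
  expect_error(powerlaw_fit(data.frame(degree = c(1, 2), count = c(5, 3))),
               "insufficient")
})

test_that("noisy synthetic power-law degrees recover the exponent", {
  set.seed(77)
  k <- 1:12
  p <- k^-2.5 / sum(k^-2.5)
  deg <- sample(k, 4000, replace = TRUE, prob = p)
  hist <- as.data.frame(table(degree = deg))
  hist$degree <- as.integer(as.character(hist$degree))
  hist$count <- hist$Freq
  fit <- powerlaw_fit(hist[, c("degree", "count")])
  expect_lt(abs(fit$slope - (-2.5)), 0.3)
  expect_gt(fit$r2, 0.9)
})
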