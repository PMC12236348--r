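test_that("bridge expected influence sums signed cross-community weights", {
  w <- edge_matrix(letters[1:5], list(
    list("a", "b", 0.4),              # within community 1
    list("a", "c", 0.3),              # cross
    list("a", "d", -0.1),             # cross
    list("c", "d", 0.2)))             # within community 2
  memb <- c(1, 1, 2, 2, 2)
  bei <- bridge_expected_influence(w, memb)
  expect_equal(bei[["a"]], 0.3 - 0.1)
  expect_equal(bei[["b"]], 0)          # only within-community edges
  expect_equal(bei[["e"]], 0)          # no edges at all
  # handshake identity: total BEI = 2 * total signed cross weight
  cross <- outer(memb, memb, "!=")
  expect_equal(sum(bei), sum(w[cross]))
})

test_that("bridge closeness follows the inverse-mean-distance convention", {
  # a(C1) adjacent to b(C2) via weight 0.5 -> distance 2 -> BCL 0.5
  w <- edge_matrix(c("a", "b"), list(list("a", "b", 0.5)))
  expect_equal(bridge_closeness(w, c(1, 2))[["a"]], 0.5)

  # disconnected from all other communities -> 0
  w2 <- edge_matrix(letters[1:3], list(list("a", "b", 1)))
  expect_equal(bridge_closeness(w2, c(1, 1, 2))[["c"]], 0)
  expect_equal(bridge_closeness(w2, c(1, 1, 2))[["a"]], 0)

  # doubling all |weights| doubles BCL
  set.seed(5)
  w3 <- abs(random_pd_corr(6)); diag(w3) <- 0
  memb <- c(1, 1, 2, 2, 3, 3)
  expect_equal(bridge_closeness(2 * w3, memb),
               2 * bridge_closeness(w3, memb), tolerance = 1e-12)
})

test_that("bridge betweenness counts cross-community geodesics through a node", {
  # u(C1) - v(C1) - w(C2): the single cross-community geodesic passes v
  w <- edge_matrix(c("u", "v", "w"), list(list("u", "v", 1),
                                          list("v", "w", 1)))
  bbw <- bridge_betweenness(w, c(1, 1, 2))
  expect_equal(bbw[["v"]], 1)
  expect_equal(bbw[["u"]], 0)   # leaf
  expect_equal(bbw[["w"]], 0)

  # invariant to uniform positive rescaling of all weights
  set.seed(8)
  w2 <- abs(random_pd_corr(6)); diag(w2) <- 0
  w2[w2 < 0.15] <- 0
  memb <- c(1, 1, 2, 2, 3, 3)
  expect_equal(bridge_betweenness(w2, memb),
               bridge_betweenness(3 * w2, memb), tolerance = 1e-10)
})

test_that("bridge betweenness matches exhaustive path enumeration", {
  set.seed(909)
  for (rep in 1:6) {
    p <- sample(4:6, 1)
    w <- matrix(0, p, p, dimnames = rep(list(letters[1:p]), 2))
    idx <- which(upper.tri(w))
    on <- sample(idx, max(p, sample(length(idx), 1)))
    w[on] <- round(runif(length(on), 0.1, 0.9), 2)
    w <- w + t(w)
    memb <- sample(1:2, p, replace = TRUE)
    expect_equal(unname(bridge_betweenness(w, memb)),
                 oracle_bridge_betweenness(w, memb), tolerance = 1e-8)
  }
})

test_that("fractional counting splits tied geodesics", {
  # two equal-length 2-hop routes between a(C1) and d(C2)
  w <- edge_matrix(letters[1:4], list(
    list("a", "b", 1), list("b", "d", 1),
    list("a", "c", 1), list("c", "d", 1)))
  bbw <- bridge_betweenness(w, c(1, 1, 1, 2))
  expect_equal(bbw[["b"]], 0.5)
  expect_equal(bbw[["c"]], 0.5)
})

test_that("bridge metrics are invariant to community relabeling and a hub dominates", {
  gt <- make_ground_truth()
  tab <- simulate_subscales(gt, 500, seed = 31)
  net <- bootstrap_edge_selection(tab, n_boot = 150, seed = 31)
  memb <- instrument_blocks()
  relab <- c(3L, 1L, 2L)[memb]
  for (f in list(bridge_expected_influence, bridge_closeness,
                 bridge_betweenness)) {
    expect_equal(f(net, memb), f(net, relab))
  }

  # one node carrying every cross-community edge attains all three maxima
  w <- edge_matrix(letters[1:6], list(
    list("a", "b", 0.5), list("b", "c", 0.4),
    list("d", "e", 0.5), list("e", "f", 0.4),
    list("b", "e", 0.3)))
  memb2 <- c(1, 1, 1, 2, 2, 2)
  sc <- bridge_scores(w, memb2)
  hub <- which(sc$node == "b")
  expect_equal(which.max(sc$bei), hub)
  expect_equal(which.max(sc$bbw), hub)
  expect_true(sc$bcl[hub] >= max(sc$bcl[-c(hub, which(sc$node == "e"))]))
})

test_that("bridge difference test is seeded and flags a planted hub", {
  gt <- make_ground_truth()
  tab <- simulate_subscales(gt, 700, seed = 71)
  net <- bootstrap_edge_selection(tab, n_boot = 200, seed = 71)
  part <- fast_greedy(net)
  d1 <- bridge_difference_test(tab, net, part, metric = "bei",
                               n_boot = 150, seed = 5)
  d2 <- bridge_difference_test(tab, net, part, metric = "bei",
                               n_boot = 150, seed = 5)
  expect_identical(d1, d2)
  # significance is exactly "CI of the difference excludes zero"
  off <- !diag(9)
  expect_identical(d1$significant[off],
                   (d1$ci_lower[off] > 0 | d1$ci_upper[off] < 0))
  # SocProd carries the generating bridge edges; its BEI tops the table
  expect_equal(names(which.max(d1$estimate)), "SocProd")
})

test_that("exchangeable nodes are rarely flagged as different", {
  gt <- make_ground_truth(
    within_strength = c(0.25, 0.25),
    bridge_edges = data.frame(from = c("SocProd", "SocProd"),
                              to = c("Icon", "Metaph"),
                              weight = c(0.15, 0.15)))
  memb <- instrument_blocks()
  n_sig <- 0L
  n_sim <- 25L
  for (s in seq_len(n_sim)) {
    tab <- simulate_subscales(gt, 400, seed = 1000 + s)
    pc <- partial_correlations(spearman_correlations(subscale_matrix(tab)))
    diag(pc) <- 0
    # fixed mask: the generating support
    mask <- gt$pcor != 0; diag(mask) <- FALSE
    net <- structure(list(node_labels = node_labels(), pcor = pc,
                          weights = pc, included = mask, n = 400),
                     class = "estimated_network")
    d <- bridge_difference_test(tab, net, memb, metric = "bei",
                                n_boot = 150, seed = s)
    if (d$significant["Icon", "Metaph"]) n_sig <- n_sig + 1L
  }
  # nominal 5% rule; allow generous Monte-Carlo slack at 25 simulations
  expect_lte(n_sig / n_sim, 0.2)
})
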