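test_that("modularity matches its closed forms and igraph", {
  w <- edge_matrix(letters[1:6], list(
    list("a", "b", 1), list("a", "c", 1), list("b", "c", 1),
    list("d", "e", 1), list("d", "f", 1), list("e", "f", 1)))
  expect_equal(modularity_q(w, rep(1L, 6)), 0)
  expect_equal(modularity_q(w, c(1, 1, 1, 2, 2, 2)), 0.5)

  set.seed(77)
  rw <- abs(random_pd_corr(7)); diag(rw) <- 0
  rw <- (rw + t(rw)) / 2
  memb <- sample(1:3, 7, replace = TRUE)
  g <- igraph::graph_from_adjacency_matrix(rw, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(modularity_q(rw, memb),
               igraph::modularity(g, memb, weights = igraph::E(g)$weight),
               tolerance = 1e-12)

  expect_error(modularity_q(matrix(0, 3, 3), rep(1, 3)), "empty")
})

test_that("fast greedy separates disconnected cliques", {
  w <- edge_matrix(letters[1:6], list(
    list("a", "b", 1), list("a", "c", 1), list("b", "c", 1),
    list("d", "e", 1), list("d", "f", 1), list("e", "f", 1)))
  part <- fast_greedy(w)
  expect_equal(part$n_communities, 2)
  expect_equal(part$Q, 0.5)
  expect_equal(unname(part$membership), c(1, 1, 1, 2, 2, 2))
})

test_that("greedy modularity never exceeds the exhaustive-partition optimum", {
  set.seed(303)
  for (p in c(5, 6, 8)) {
    w <- matrix(0, p, p, dimnames = rep(list(letters[1:p]), 2))
    n_edges <- sample(p:(p * (p - 1) / 2), 1)
    idx <- sample(which(upper.tri(w)), n_edges)
    w[idx] <- runif(n_edges, 0.1, 1)
    w <- w + t(w)
    if (sum(w) == 0) next
    part <- fast_greedy(w)
    parts <- all_partitions(p)
    qs <- vapply(parts, function(m) modularity_q(w, m), numeric(1))
    qmax <- max(qs)
    expect_lte(part$Q, qmax + 1e-10)
    if (abs(part$Q - qmax) < 1e-10) {
      optima <- parts[qs > qmax - 1e-10]
      optima_canon <- lapply(optima, canonical_partition)
      expect_true(any(vapply(optima_canon, identical,
                             logical(1), canonical_partition(part$membership))))
    }
  }
})

test_that("fast greedy is deterministic and permutation-equivariant", {
  gt <- make_ground_truth()
  tab <- simulate_subscales(gt, 600, seed = 19)
  net <- bootstrap_edge_selection(tab, n_boot = 200, seed = 19)
  p1 <- fast_greedy(net)
  p2 <- fast_greedy(net)
  expect_identical(p1, p2)

  w <- abs(selected_weights(net))
  perm <- c(4, 9, 1, 6, 2, 8, 3, 7, 5)
  wp <- w[perm, perm]
  pp <- fast_greedy(wp)
  # same groups of labels, same Q, regardless of node order
  groups <- function(part) {
    unname(lapply(split(names(part$membership), part$membership), sort))
  }
  expect_equal(pp$Q, p1$Q, tolerance = 1e-12)
  expect_setequal(groups(pp), groups(fast_greedy(w)))
})

test_that("partition quality dominates the trivial partitions", {
  gt <- make_ground_truth()
  tab <- simulate_subscales(gt, 400, seed = 23)
  net <- bootstrap_edge_selection(tab, n_boot = 150, seed = 23)
  part <- fast_greedy(net)
  w <- abs(selected_weights(net))
  expect_gte(part$Q, modularity_q(w, seq_len(9)))
  expect_gte(part$Q, modularity_q(w, rep(1L, 9)))
  # Q recomputed from scratch on (network, assignment) matches
  expect_equal(part$Q, modularity_q(w, part$membership), tolerance = 1e-12)
})

test_that("isolated nodes stay in their own community and empty graphs fail", {
  w <- edge_matrix(letters[1:4], list(list("a", "b", 1), list("c", "d", 0)))
  w["c", "d"] <- w["d", "c"] <- 0
  part <- fast_greedy(w)
  expect_equal(part$membership[["c"]] == part$membership[["d"]], FALSE)
  expect_error(fast_greedy(matrix(0, 3, 3)), "empty")
})

test_that("our partition agrees with igraph fast greedy on the synthetic network", {
  gt <- make_ground_truth()
  tab <- simulate_subscales(gt, 800, seed = 3)
  net <- bootstrap_edge_selection(tab, n_boot = 300, seed = 3)
  part <- fast_greedy(net)
  w <- abs(selected_weights(net))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  ig <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  expect_equal(canonical_partition(unname(part$membership)),
               canonical_partition(unname(igraph::membership(ig))))
  expect_equal(part$Q, max(ig$modularity), tolerance = 1e-10)
})
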