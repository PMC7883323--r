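test_that("co-membership target pairs follow the one-class query semantics", {
  t1 <- comembership_target(c("q1", "q2"), "b1")
  expect_identical(nrow(t1), 3L)
  expect_identical(sum(t1$target == 1), 1L)
  expect_identical(sum(t1$target == -1), 2L)
  expect_error(comembership_target(c("q1", "q2"), character()), class = "psn_error")
  expect_error(comembership_target(c("q1", "b1"), c("b1")), class = "psn_error")
  # combinatorial counts for random sizes
  set.seed(2)
  for (rep in 1:5) {
    q <- sprintf("q%d", seq_len(sample(2:6, 1)))
    b <- sprintf("b%d", seq_len(sample(1:6, 1)))
    tt <- comembership_target(q, b)
    expect_equal(sum(tt$target == 1), choose(length(q), 2))
    expect_equal(sum(tt$target == -1), length(q) * length(b))
    expect_equal(nrow(tt), choose(length(q), 2) + length(q) * length(b))
  }
})

# 4-patient fixture: q1,q2 in the query, b1,b2 in the background.
aligned_fixture <- function(invert = FALSE) {
  e <- tibble::tibble(
    from = c("q1", "q1", "q2"),
    to = c("q2", "b1", "b2"),
    weight = if (invert) c(0.05, 0.9, 0.9) else c(0.9, 0.05, 0.05)
  )
  psn(e, nodes = c("q1", "q2", "b1", "b2"), name = "cand")
}

test_that("ridge solve matches the closed form and clips anti-aligned candidates", {
  net <- aligned_fixture()
  w <- solve_network_weights(list(cand = net), c("q1", "q2"), c("b1", "b2"),
                             ridge = 1)
  # closed-form oracle: intercept + single penalized regressor over the 5 pairs
  x <- c(0.9, 0.05, 0, 0.05, 0)  # q1q2, q1b1, q1b2, q2b2, q2b1 (any order)
  y <- c(1, -1, -1, -1, -1)
  lam <- 1 * sum(x^2)
  A <- rbind(c(length(x), sum(x)), c(sum(x), sum(x^2) + lam))
  expected <- solve(A, c(sum(y), sum(x * y)))[2]
  expect_gt(w$weight, 0)
  expect_equal(w$weight, expected, tolerance = 1e-12)

  w_anti <- solve_network_weights(list(cand = aligned_fixture(invert = TRUE)),
                                  c("q1", "q2"), c("b1", "b2"))
  expect_identical(w_anti$weight, 0)

  w2 <- solve_network_weights(list(a = net, b = net), c("q1", "q2"), c("b1", "b2"))
  expect_equal(w2$weight[1], w2$weight[2], tolerance = 1e-12)

  empty <- psn(tibble::tibble(from = character(), to = character(),
                              weight = numeric()),
               nodes = c("q1", "q2", "b1", "b2"), name = "none")
  expect_error(solve_network_weights(list(none = empty), c("q1", "q2"),
                                     c("b1", "b2")),
               class = "psn_error", regexp = "uninformative")
})

test_that("rescaling all candidates rescales weights by the inverse", {
  set.seed(6)
  nets <- list(a = random_psn(8, name = "a"), b = random_psn(8, name = "b"))
  ids <- psn_nodes(nets$a)
  q <- ids[1:3]; b <- ids[4:8]
  w1 <- solve_network_weights(nets, q, b)
  scaled <- lapply(nets, function(n) {
    e <- psn_edges(n); e$weight <- e$weight * 0.25
    psn(e, nodes = psn_nodes(n), name = psn_name(n))
  })
  w2 <- solve_network_weights(scaled, q, b)
  expect_equal(w2$weight, w1$weight / 0.25, tolerance = 1e-10)
})

test_that("network combination is the weighted edge sum over the node union", {
  net <- random_psn(5, name = "n1")
  one <- combine_networks(list(n1 = net), c(n1 = 1))
  expect_equal(psn_edges(one)[, c("from", "to", "weight")], psn_edges(net))
  half <- combine_networks(list(a = net, b = net), c(a = 0.5, b = 0.5))
  expect_equal(psn_edges(half)$weight, psn_edges(net)$weight)

  set.seed(12)
  n1 <- random_psn(5, name = "n1"); n2 <- random_psn(5, name = "n2")
  wts <- c(n1 = 0.3, n2 = 1.7)
  comb <- combine_networks(list(n1 = n1, n2 = n2), wts)
  ids <- sort(unique(c(psn_nodes(n1), psn_nodes(n2))))
  brute <- 0.3 * psn_matrix(n1, ids) + 1.7 * psn_matrix(n2, ids)
  expect_equal(psn_matrix(comb, ids), brute, tolerance = 1e-12)
})

test_that("label propagation matches a dense direct solve and the smoothing limits", {
  # edgeless graph: f equals the prior exactly
  iso <- psn(tibble::tibble(from = character(), to = character(), weight = numeric()),
             nodes = c("a", "b", "c"))
  pr <- c(a = 1, b = 0, c = 0.5)
  f <- propagate_labels(iso, pr)
  expect_equal(setNames(f$score, f$ID), pr[f$ID])

  # two nodes with an enormous edge weight: scores coalesce
  two <- psn(tibble::tibble(from = "a", to = "b", weight = 1e8))
  f2 <- propagate_labels(two, c(a = 1, b = 0))
  expect_lt(abs(diff(f2$score)), 1e-6)

  # 6-node fixture against the dense oracle
  set.seed(13)
  net <- random_psn(6)
  prior <- setNames(rbinom(6, 1, 0.5), psn_nodes(net))
  f3 <- propagate_labels(net, prior, lambda = 1.5)
  expect_equal(f3$score, dense_propagation(net, prior, 1.5), tolerance = 1e-8)
})

test_that("propagation satisfies the maximum principle and lambda monotonicity", {
  set.seed(14)
  for (rep in 1:10) {
    net <- random_psn(sample(4:12, 1))
    prior <- setNames(runif(length(psn_nodes(net))), psn_nodes(net))
    f <- propagate_labels(net, prior)
    expect_true(all(f$score >= min(prior) - 1e-8))
    expect_true(all(f$score <= max(prior) + 1e-8))
    # larger lambda pulls scores further from the prior
    res <- vapply(c(0.5, 1, 2, 4), function(l) {
      fl <- propagate_labels(net, prior, lambda = l)
      sum((fl$score - prior[fl$ID])^2)
    }, numeric(1))
    expect_true(all(diff(res) >= -1e-10))
  }
})
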