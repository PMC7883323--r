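test_that("pearson profile networks match correlation semantics", {
  ids <- c("a", "b", "c")
  m <- matrix(c(1, 2, 3, 4, 5,
                1, 2, 3, 4, 5,
                5, 4, 3, 2, 1), 5, 3,
              dimnames = list(paste0("g", 1:5), ids))
  net <- sim_pearson_profile(m, rownames(m), "f")
  e <- psn_edges(net)
  expect_equal(e$weight[e$from == "a" & e$to == "b"], 1)
  # perfectly anti-correlated pairs are clipped: no edge to c
  expect_false(any(e$from == "c" | e$to == "c"))
  expect_error(sim_pearson_profile(m, "g1", "solo"), class = "psn_error",
               regexp = "solo")
})

test_that("missing entries are handled by pairwise-complete correlation", {
  ids <- c("a", "b", "c")
  set.seed(11)
  m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("g", 1:4), ids))
  m[2, "b"] <- NA
  net <- sim_pearson_profile(m, rownames(m), "f")
  # brute-force oracle: correlation over shared observed measures per pair
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    shared <- which(!is.na(m[, pair[1]]) & !is.na(m[, pair[2]]))
    r <- cor(m[shared, pair[1]], m[shared, pair[2]])
    e <- psn_edges(net)
    row <- e[e$from == min(pair) & e$to == max(pair), ]
    if (r > 0) expect_equal(row$weight, r) else expect_identical(nrow(row), 0L)
  }
})

test_that("complete-data profile networks equal the textbook correlation", {
  set.seed(4)
  for (rep in 1:5) {
    m <- matrix(rnorm(8 * 6), 8, 6,
                dimnames = list(paste0("g", 1:8), paste0("p", 1:6)))
    net <- sim_pearson_profile(m, rownames(m), "f")
    r <- cor(m)
    e <- psn_edges(net)
    for (i in seq_len(nrow(e))) {
      expect_equal(e$weight[i], r[e$from[i], e$to[i]], tolerance = 1e-12)
    }
    # every positive correlation appears
    expect_identical(nrow(e), sum(r[upper.tri(r)] > 0))
  }
})

test_that("normalized difference follows its formula", {
  v <- c(a = 0, b = 5, c = 10)
  net <- sim_continuous(v, "normdiff", "age")
  e <- psn_edges(net)
  expect_equal(e$weight[e$from == "a" & e$to == "b"], 0.5)
  expect_equal(norm_diff(3, 3, 10), 1)
  expect_equal(norm_diff(0, 10, 10), 0)
  # extreme pair has similarity 0, hence no edge
  expect_identical(nrow(e[e$from == "a" & e$to == "c", ]), 0L)
  expect_error(sim_continuous(c(a = 2, b = 2), "normdiff", "flat"),
               class = "psn_error", regexp = "degenerate")
  # missing values are omitted, not imputed
  net2 <- sim_continuous(c(a = 0, b = 5, c = NA, d = 10), "normdiff", "age")
  expect_false("c" %in% psn_nodes(net2))
})

test_that("binary pathway networks are cliques over carriers with a floor", {
  ev <- tibble::tibble(
    ID = c(sprintf("p%d", 1:6), "p7"),
    gene = c(rep("G1", 3), rep("G2", 3), "OTHER")
  )
  net <- sim_binary_pathway(ev, c("G1", "G2"), "pw")
  expect_equal(nrow(psn_edges(net)), choose(6, 2))
  expect_true(all(psn_edges(net)$weight == 1))
  expect_setequal(psn_nodes(net), sprintf("p%d", 1:6))
  # 5 carriers under the default floor of 6: no network
  expect_null(sim_binary_pathway(ev[ev$ID != "p1", ], c("G1", "G2"), "pw"))
  expect_null(sim_binary_pathway(ev, "ABSENT_GENE", "pw"))
  # floor is tunable
  expect_s3_class(sim_binary_pathway(ev[1:3, ], "G1", "pw", min_carriers = 3), "psn")
})

test_that("sparsification keeps each node's strongest edges and is idempotent", {
  ids <- c("a", "b", "c", "d")
  pr <- t(combn(ids, 2))
  set.seed(8)
  for (rep in 1:20) {
    w <- sample(seq(0.1, 0.6, length.out = 6))  # distinct weights
    net <- psn(tibble::tibble(from = pr[, 1], to = pr[, 2], weight = w))
    sp <- sparsify_network(net, min_weight = 0, max_degree = 1)
    e <- psn_edges(sp)
    expect_gte(nrow(e), 2)
    expect_lte(nrow(e), 4)
    # each node's strongest incident edge survives
    for (id in ids) {
      inc <- net$edges[net$edges$from == id | net$edges$to == id, ]
      best <- inc[which.max(inc$weight), ]
      expect_true(any(e$from == best$from & e$to == best$to))
    }
    expect_identical(psn_edges(sparsify_network(sp, 0, 1)), e)
  }
  net <- random_psn(6)
  expect_identical(psn_edges(sparsify_network(net, 0, 10)), psn_edges(net))
  expect_identical(nrow(psn_edges(sparsify_network(net, 2, 10))), 0L)
})

test_that("edge weights are order-invariant and within [0, 1]", {
  set.seed(9)
  m <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("g", 1:5), paste0("p", 1:6)))
  perm <- sample(ncol(m))
  n1 <- sim_pearson_profile(m, rownames(m), "f")
  n2 <- sim_pearson_profile(m[, perm], rownames(m), "f")
  expect_equal(psn_edges(n1), psn_edges(n2))
  expect_true(all(psn_edges(n1)$weight >= 0 & psn_edges(n1)$weight <= 1))
  v <- setNames(rnorm(6), paste0("p", 1:6))
  c1 <- sim_continuous(v, "normdiff", "v")
  c2 <- sim_continuous(v[perm], "normdiff", "v")
  expect_equal(psn_edges(c1), psn_edges(c2))
  expect_true(all(psn_edges(c1)$weight >= 0 & psn_edges(c1)$weight <= 1))
})

test_that("build_feature_networks composes the per-metric operations", {
  ph <- tibble::tibble(ID = sprintf("p%d", 1:8), STATUS = rep(c("x", "y"), 4),
                       age = c(30, 40, 50, 60, 35, 45, 55, 65))
  set.seed(10)
  expr <- matrix(rnorm(64), 8, 8,
                 dimnames = list(paste0("g", 1:8), ph$ID))
  ds <- patient_dataset(ph, assays = list(expr = expr))
  rules <- list(expr = list(PW1 = paste0("g", 1:4), PW2 = paste0("g", 5:8)),
                clinical = list(age = "age"))
  nets <- build_feature_networks(ds, rules,
                                 list(expr = "pearson", clinical = "normdiff"))
  expect_setequal(names(nets), c("PW1", "PW2", "age"))
  expect_equal(psn_edges(nets$PW1),
               psn_edges(sim_pearson_profile(expr, paste0("g", 1:4), "PW1")))
  expect_equal(psn_edges(nets$age),
               psn_edges(sim_continuous(setNames(ph$age, ph$ID), "normdiff", "age")))

  # restriction: no held-out patient appears in any network
  train <- ph$ID[1:6]
  nets_tr <- build_feature_networks(ds, rules,
                                    list(expr = "pearson", clinical = "normdiff"),
                                    restrict_to = train)
  for (n in nets_tr) expect_true(all(psn_nodes(n) %in% train))

  # custom metric callables are honoured
  custom <- function(mat, group, name) {
    psn(tibble::tibble(from = colnames(mat)[1], to = colnames(mat)[2], weight = 1),
        name = name)
  }
  nets_c <- build_feature_networks(ds, list(expr = list(ONE = "g1")),
                                   list(expr = custom))
  expect_identical(psn_edges(nets_c$ONE)$weight, 1)
})
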