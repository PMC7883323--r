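test_that("a discriminative network outscores noise networks", {
  fix <- toy_two_class(n_per_class = 10, seed = 21)
  train <- fix$ds$pheno$ID
  nets <- build_feature_networks(fix$ds, fix$rules, fix$metrics)
  cl_a <- fix$ds$pheno$ID[fix$ds$pheno$STATUS == "A"]
  sc <- score_features(nets, cl_a, setdiff(train, cl_a),
                       feat_score_max = 3, seed = 31)
  expect_true(all(sc$score >= 0 & sc$score <= 3))
  expect_identical(sc$score[sc$feature == "SIGNAL"], 3L)
  sc1 <- score_features(nets, cl_a, setdiff(train, cl_a),
                        feat_score_max = 1, seed = 31)
  expect_true(all(sc1$score %in% c(0L, 1L)))
})

test_that("adding an all-zero candidate never changes other features' scores", {
  fix <- toy_two_class(n_per_class = 8, seed = 22)
  nets <- build_feature_networks(fix$ds, fix$rules, fix$metrics)
  cl_a <- fix$ds$pheno$ID[fix$ds$pheno$STATUS == "A"]
  bg <- setdiff(fix$ds$pheno$ID, cl_a)
  base <- score_features(nets, cl_a, bg, feat_score_max = 2, seed = 7)
  nets$ZERO <- psn(tibble::tibble(from = character(), to = character(),
                                  weight = numeric()),
                   nodes = fix$ds$pheno$ID, name = "ZERO")
  with_zero <- score_features(nets, cl_a, bg, feat_score_max = 2, seed = 7)
  expect_identical(
    with_zero$score[match(base$feature, with_zero$feature)], base$score)
  expect_identical(with_zero$score[with_zero$feature == "ZERO"], 0L)
})

test_that("consensus feature calling honours cutoff and pass fraction", {
  # score table shaped like a two-split run: three features scoring 2 and 2,
  # two scoring NA and 1
  tbl <- tibble::tibble(
    feature = c("PW_A", "PW_B", "PW_C", "age", "stage"),
    Split1 = c(2, 2, 2, NA, NA),
    Split2 = c(2, 2, 2, 1, 1)
  )
  expect_setequal(select_features(tbl, fs_cutoff = 2, fs_pct_pass = 1),
                  c("PW_A", "PW_B", "PW_C"))
  expect_setequal(select_features(tbl, fs_cutoff = 1, fs_pct_pass = 0),
                  tbl$feature)
  expect_identical(select_features(tbl[0, ], 1, 0), character())
  # missing entries count as below cutoff
  expect_setequal(select_features(tbl, fs_cutoff = 1, fs_pct_pass = 1),
                  c("PW_A", "PW_B", "PW_C"))
})

test_that("label bias takes its worked values", {
  labels <- setNames(rep(c("case", "control"), each = 5), sprintf("p%d", 1:10))
  expect_identical(label_bias(sprintf("p%d", 1:5), labels, "case"), 1)
  expect_identical(label_bias(sprintf("p%d", 6:10), labels, "case"), -1)
  expect_identical(label_bias(c("p1", "p2", "p6", "p7"), labels, "case"), 0)
  expect_true(is.na(label_bias(character(), labels, "case")))
})

test_that("enrichment p-values match exhaustive label-permutation enumeration", {
  # 8-patient cohort, 4 cases; 4-member network with 3 cases
  ids <- sprintf("p%d", 1:8)
  labels <- setNames(rep(c("case", "control"), each = 4), ids)
  members <- c("p1", "p2", "p3", "p5")
  net <- psn(tibble::tibble(from = rep(members[1], 3), to = members[2:4],
                            weight = 1), nodes = members, name = "pw")
  obs <- label_bias(members, labels, "case")
  # exact enumeration oracle: all placements of the 4 case labels
  combos <- combn(8, 4)
  exact <- mean(apply(combos, 2, function(pos) {
    lab <- setNames(ifelse(seq_len(8) %in% pos, "case", "control"), ids)
    label_bias(members, lab, "case") >= obs
  }))
  enr <- label_enrichment(list(pw = net), labels, "case",
                          num_perms = 4000, seed = 99)
  expect_equal(enr$bias, obs)
  expect_lt(abs(enr$p - exact), 0.02)
  expect_gt(enr$p, 0)  # +1 correction: never exactly zero
  expect_identical(enr$pass, enr$p < 0.07)
})

test_that("enrichment is deterministic given the seed and excludes empty networks", {
  ids <- sprintf("p%d", 1:8)
  labels <- setNames(rep(c("case", "control"), each = 4), ids)
  net <- psn(tibble::tibble(from = "p1", to = "p2", weight = 1), name = "pw")
  outside <- psn(tibble::tibble(from = "z1", to = "z2", weight = 1), name = "zz")
  e1 <- label_enrichment(list(pw = net), labels, "case", num_perms = 50, seed = 3)
  e2 <- label_enrichment(list(pw = net), labels, "case", num_perms = 50, seed = 3)
  expect_identical(e1, e2)
  expect_warning(
    e3 <- label_enrichment(list(pw = net, zz = outside), labels, "case",
                           num_perms = 20, seed = 3),
    regexp = "zz"
  )
  expect_identical(e3$network, "pw")
})

test_that("cumulative scores add across splits up to num_splits * feat_score_max", {
  threes <- lapply(1:3, function(i) tibble::tibble(feature = "PW", score = 3L))
  expect_identical(cumulative_scores(threes)$score, 9L)
  one <- list(tibble::tibble(feature = c("a", "b"), score = c(2L, 0L)))
  expect_equal(cumulative_scores(one) |> dplyr::arrange(feature),
               tibble::tibble(feature = c("a", "b"), score = c(2L, 0L)))
  tens <- lapply(1:3, function(i) tibble::tibble(feature = "PW", score = 10L))
  expect_identical(cumulative_scores(tens)$score, 30L)
  # features missing from a split contribute zero
  mixed <- list(tibble::tibble(feature = c("a", "b"), score = c(1L, 2L)),
                tibble::tibble(feature = "b", score = 3L))
  out <- cumulative_scores(mixed)
  expect_identical(out$score[out$feature == "a"], 1L)
  expect_identical(out$score[out$feature == "b"], 5L)
})

test_that("null enrichment p-values are super-uniform at the pass threshold", {
  set.seed(41)
  ids <- sprintf("p%02d", 1:20)
  labels <- setNames(rep(c("case", "control"), 10), ids)
  nets <- lapply(1:500, function(i) {
    members <- sample(ids, 6)
    psn(tibble::tibble(from = members[1], to = members[-1], weight = 1),
        nodes = members, name = paste0("n", i))
  })
  names(nets) <- paste0("n", 1:500)
  enr <- label_enrichment(nets, labels, "case", num_perms = 200, seed = 17)
  expect_lte(mean(enr$p < 0.05), 0.07)
})
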