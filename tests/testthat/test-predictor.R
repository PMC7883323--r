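test_that("the turnkey predictor returns the documented per-split components", {
  fix <- toy_two_class(n_per_class = 10, seed = 101)
  fit <- suppressWarnings(build_predictor(
    fix$ds, fix$rules, fix$metrics,
    num_splits = 2, feat_score_max = 2, feat_sel_cutoff = 1, seed = 5))
  expect_s3_class(fit, "psn_predictor")
  expect_length(fit$splits, 2)
  expect_setequal(fit$input_networks, c("SIGNAL", "NOISE"))
  for (sp in fit$splits) {
    expect_setequal(names(sp), c("assignment", "feature_scores", "selected",
                                 "predictions", "accuracy"))
    expect_setequal(names(sp$feature_scores), c("A", "B"))
    expect_identical(nrow(sp$predictions),
                     sum(sp$assignment$TT_STATUS == "TEST"))
  }
  # deterministic given the seed
  fit2 <- suppressWarnings(build_predictor(
    fix$ds, fix$rules, fix$metrics,
    num_splits = 2, feat_score_max = 2, feat_sel_cutoff = 1, seed = 5))
  expect_equal(fit$splits$Split1$predictions, fit2$splits$Split1$predictions)
  expect_identical(tidy(fit), tidy(fit2))
  # tidy/glance/feature_score_table shapes
  td <- tidy(fit)
  expect_setequal(names(td), c("split", "class", "feature", "score"))
  expect_identical(nrow(td), 2L * 2L * 2L)
  expect_identical(nrow(glance(fit)), 1L)
  fst <- feature_score_table(fit, "A")
  expect_setequal(names(fst), c("feature", "Split1", "Split2"))
})

test_that("the planted feature is recovered across splits", {
  fix <- toy_two_class(n_per_class = 10, seed = 102)
  fit <- suppressWarnings(build_predictor(
    fix$ds, fix$rules, fix$metrics,
    num_splits = 2, feat_score_max = 2, feat_sel_cutoff = 2, seed = 8))
  for (sp in fit$splits) {
    expect_true("SIGNAL" %in% sp$selected$A)
    expect_true("SIGNAL" %in% sp$selected$B)
  }
  sel <- select_features(feature_score_table(fit, "A"), fs_cutoff = 2,
                         fs_pct_pass = 1)
  expect_true("SIGNAL" %in% sel)
})

test_that("test patients cannot influence feature scores in their split", {
  fix <- toy_two_class(n_per_class = 10, seed = 103)
  fit <- suppressWarnings(build_predictor(
    fix$ds, fix$rules, fix$metrics,
    num_splits = 1, feat_score_max = 2, feat_sel_cutoff = 1, seed = 5))
  test_ids <- with(fit$splits$Split1$assignment, ID[TT_STATUS == "TEST"])
  # perturb only test patients' assay values and re-fit
  ds2 <- fix$ds
  ds2$assays$expr[, test_ids] <- ds2$assays$expr[, test_ids] + 100
  fit2 <- suppressWarnings(build_predictor(
    ds2, fix$rules, fix$metrics,
    num_splits = 1, feat_score_max = 2, feat_sel_cutoff = 1, seed = 5))
  expect_identical(fit$splits$Split1$feature_scores,
                   fit2$splits$Split1$feature_scores)
})

test_that("holdout scoring requires enough training members per class", {
  fix <- toy_two_class(n_per_class = 4, seed = 104)
  expect_error(
    build_predictor(fix$ds, fix$rules, fix$metrics, num_splits = 1,
                    feat_score_max = 10, feat_sel_cutoff = 1, seed = 2),
    class = "psn_error", regexp = "montecarlo"
  )
})

test_that("the sparse predictor scores, filters and sweeps cutoffs coherently", {
  sd <- simulate_sparse_events(n_patients = 240, seed = 31)
  fit_off <- build_predictor_sparse(sd$pheno, sd$events, sd$sets, "case",
                                    num_splits = 3, feat_score_max = 3,
                                    enrich_labels = FALSE, seed = 11)
  fit_on <- build_predictor_sparse(sd$pheno, sd$events, sd$sets, "case",
                                   num_splits = 3, feat_score_max = 3,
                                   enrich_labels = TRUE, num_perms = 50,
                                   seed = 11)
  # enrichment only removes candidates
  expect_true(all(fit_on$cumulative_scores$feature %in%
                    fit_off$cumulative_scores$feature))
  # scores bounded by num_splits * feat_score_max; enriched pathways near the top
  expect_true(all(fit_on$cumulative_scores$score <= 9))
  top <- fit_on$cumulative_scores$feature[1:2]
  expect_true(any(top %in% sd$truth$pathway[sd$truth$enriched]))
  # performance table spans every cumulative cutoff with fixed marginals
  expect_identical(nrow(fit_on$performance), 9L)
  expect_true(all(fit_on$performance$tp + fit_on$performance$fn ==
                    sum(sd$pheno$STATUS == "case")))
  expect_true(fit_on$auc > 0.5)
  expect_equal(glance(fit_on)$max_score, 9)
  # deterministic
  fit_on2 <- build_predictor_sparse(sd$pheno, sd$events, sd$sets, "case",
                                    num_splits = 3, feat_score_max = 3,
                                    enrich_labels = TRUE, num_perms = 50,
                                    seed = 11)
  expect_identical(fit_on$cumulative_scores, fit_on2$cumulative_scores)
})

test_that("a strongly case-enriched pathway drives high sparse-workflow AUROC", {
  sd <- simulate_sparse_events(n_patients = 300, case_rate = 0.6,
                               control_rate = 0.02, seed = 32)
  fit <- build_predictor_sparse(sd$pheno, sd$events, sd$sets, "case",
                                num_splits = 3, feat_score_max = 3,
                                enrich_labels = TRUE, num_perms = 50, seed = 13)
  expect_gt(fit$auc, 0.75)
})
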