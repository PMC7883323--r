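#' Build a patient classifier over multiple train/test splits
#'
#' The turnkey predictor loop. For each of `num_splits` random stratified
#' train/test splits it (1) builds train-only feature networks, (2) scores
#' every feature per class by `feat_score_max` integration queries on
#' training subsamples ([score_features()]), (3) keeps features scoring at
#' least `feat_sel_cutoff`, and (4) classifies the held-out test patients by
#' label propagation on the integrated selected networks
#' ([classify_by_propagation()]). Test patients never influence feature
#' scores in their split. The run is deterministic given `seed`.
#'
#' When a class has no feature at the cutoff, classification for that split
#' proceeds with the class's best-scoring feature(s) and a warning - the
#' documented fallback, preferable to aborting a whole split.
#'
#' @param ds a [patient_dataset()].
#' @param rules grouping rules (see [validate_dataset()]).
#' @param metrics per-layer metric assignment (see [build_feature_networks()]).
#' @param num_splits number of train/test splits.
#' @param feat_score_max queries per class and split (maximum feature score).
#' @param feat_sel_cutoff minimum score for a feature to be used in
#'   classification, in `[1, feat_score_max]`.
#' @param train_fraction per-class training fraction (default 0.8).
#' @param scheme resampling scheme for queries, `"holdout"` or `"montecarlo"`.
#' @param mc_fraction Monte Carlo sampling fraction.
#' @param lambda label-propagation smoothing strength.
#' @param ridge relative ridge penalty of the weight solve.
#' @param sparsify sparsify continuous-variable networks
#'   (see [build_feature_networks()]).
#' @param min_carriers carrier floor for binary features.
#' @param seed integer seed driving splits and subsampling.
#' @return object of class `psn_predictor`: list with `input_networks` (the
#'   feature inventory), `splits` (per split: `assignment`, `feature_scores`,
#'   `selected`, `predictions`, `accuracy`) and `config`. Use [tidy()] for the
#'   long score table, [glance()] for a one-row summary and
#'   [feature_score_table()] + [select_features()] for consensus calling.
#' @export
build_predictor <- function(ds, rules, metrics, num_splits = 10L,
                            feat_score_max = 10L, feat_sel_cutoff = 9L,
                            train_fraction = 0.8, scheme = "holdout",
                            mc_fraction = 0.8, lambda = 1, ridge = 1,
                            sparsify = FALSE, min_carriers = 6L, seed = 42L) {
  stopifnot(num_splits >= 1, feat_score_max >= 1,
            feat_sel_cutoff >= 1, feat_sel_cutoff <= feat_score_max)
  validate_dataset(ds, rules, strict = TRUE)
  classes <- sort(unique(ds$pheno$STATUS))
  inventory <- names(build_feature_networks(
    ds, rules, metrics, sparsify = sparsify, min_carriers = min_carriers))
  splits <- list()
  for (k in seq_len(num_splits)) {
    split_seed <- seed + k
    assignment <- split_train_test(ds, train_fraction, seed = split_seed)
    train_ids <- assignment$ID[assignment$TT_STATUS == "TRAIN"]
    nets_train <- build_feature_networks(
      ds, rules, metrics, restrict_to = train_ids,
      sparsify = sparsify, min_carriers = min_carriers)
    if (length(nets_train) == 0) {
      abort(sprintf("split %d: no feature network could be built on training data", k),
            class = "psn_error")
    }
    scores <- list()
    selected <- list()
    for (cl in classes) {
      cl_train <- assignment$ID[assignment$TT_STATUS == "TRAIN" &
                                  assignment$STATUS == cl]
      if (scheme == "holdout" && length(cl_train) < feat_score_max) {
        abort(sprintf(
          "split %d, class '%s': %d training members < feat_score_max = %d under holdout resampling; use scheme = \"montecarlo\"",
          k, cl, length(cl_train), feat_score_max), class = "psn_error")
      }
      sc <- score_features(nets_train, cl_train, setdiff(train_ids, cl_train),
                           feat_score_max, scheme, seed = split_seed,
                           ridge = ridge, mc_fraction = mc_fraction)
      scores[[cl]] <- sc
      sel <- sc$feature[sc$score >= feat_sel_cutoff]
      if (length(sel) == 0) {
        sel <- sc$feature[sc$score == max(sc$score)]
        warn(sprintf("split %d, class '%s': no feature reached the cutoff; falling back to best-scoring feature(s)",
                     k, cl))
      }
      selected[[cl]] <- sel
    }
    predictions <- classify_by_propagation(
      ds, rules, metrics, selected, assignment, lambda = lambda,
      sparsify = sparsify, min_carriers = min_carriers)
    splits[[sprintf("Split%d", k)]] <- list(
      assignment = assignment,
      feature_scores = scores,
      selected = selected,
      predictions = predictions,
      accuracy = mean(predictions$PRED_CLASS == predictions$STATUS)
    )
  }
  structure(list(
    input_networks = inventory,
    splits = splits,
    classes = classes,
    config = list(num_splits = num_splits, feat_score_max = feat_score_max,
                  feat_sel_cutoff = feat_sel_cutoff,
                  train_fraction = train_fraction, scheme = scheme,
                  mc_fraction = mc_fraction, lambda = lambda, ridge = ridge,
                  sparsify = sparsify, min_carriers = min_carriers, seed = seed)
  ), class = "psn_predictor")
}

#' @export
print.psn_predictor <- function(x, ...) {
  cat(sprintf("<psn_predictor> %d input networks, %d split(s), classes: %s\n",
              length(x$input_networks), length(x$splits),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("accuracy per split: %s\n",
              paste(sprintf("%.3f", vapply(x$splits, `[[`, numeric(1), "accuracy")),
                    collapse = " ")))
  invisible(x)
}

#' Long feature-score table of a fitted predictor
#'
#' `tidy()` returns one row per split, class and feature with the integer
#' score; `glance()` a one-row summary with mean test accuracy.
#'
#' @param x a `psn_predictor`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.psn_predictor <- function(x, ...) {
  rows <- list()
  for (k in seq_along(x$splits)) {
    for (cl in names(x$splits[[k]]$feature_scores)) {
      sc <- x$splits[[k]]$feature_scores[[cl]]
      rows[[length(rows) + 1]] <- dplyr::mutate(sc, split = k, class = cl)
    }
  }
  dplyr::bind_rows(rows)[, c("split", "class", "feature", "score")]
}

#' @rdname tidy.psn_predictor
#' @export
glance.psn_predictor <- function(x, ...) {
  acc <- vapply(x$splits, `[[`, numeric(1), "accuracy")
  tibble(
    num_splits = length(x$splits),
    n_input_networks = length(x$input_networks),
    mean_accuracy = mean(acc),
    min_accuracy = min(acc),
    max_accuracy = max(acc)
  )
}

#' Feature-by-split score table for one class
#'
#' Reshapes a fitted predictor's scores for one class into the wide
#' feature-by-split form consumed by [select_features()]. Features never
#' scored in a split carry `NA`.
#'
#' @param x a `psn_predictor`.
#' @param class class label.
#' @return tibble with `feature` and one `Split<i>` column per split.
#' @export
feature_score_table <- function(x, class) {
  stopifnot(inherits(x, "psn_predictor"), class %in% x$classes)
  tidy(x) |>
    dplyr::filter(.data$class == !!class) |>
    dplyr::mutate(split = sprintf("Split%d", .data$split)) |>
    tidyr::pivot_wider(id_cols = "feature", names_from = "split",
                       values_from = "score")
}

#' Prediction tables of a fitted predictor
#'
#' @param x a `psn_predictor`.
#' @return list of per-split prediction tibbles, ready for
#'   [evaluate_predictions()].
#' @export
prediction_tables <- function(x) {
  stopifnot(inherits(x, "psn_predictor"))
  lapply(x$splits, `[[`, "predictions")
}

#' Build a classifier from sparse genetic events
#'
#' The sparse-genetic workflow: pathway-level features with binary similarity
#' (a clique over each pathway's carriers), an optional permutation-based
#' label-enrichment filter, cumulative feature scoring over `num_splits`
#' rounds on independent held-out fractions, and a pathway-membership decision
#' rule swept over all cumulative-score cutoffs to produce a ROC.
#'
#' Each round trains on `(num_splits - 1) / num_splits` of the cohort
#' (stratified folds). Within a round, features are scored `0..feat_score_max`
#' exactly as in the dense workflow; scores are then summed across rounds, so
#' a feature can reach `num_splits * feat_score_max`. At a given cumulative
#' cutoff a patient is called a case if they carry an event in at least one
#' pathway scoring at or above the cutoff.
#'
#' @param pheno metadata tibble with `ID` and `STATUS`.
#' @param events patient events, tibble with `ID`, `gene` (one row per event).
#' @param sets named list of pathway gene sets (e.g. from [read_gmt()]).
#' @param predict_class the label to predict (must be present in `STATUS`).
#' @param num_splits number of feature-selection rounds (independent held-out
#'   fractions).
#' @param feat_score_max per-round maximum feature score.
#' @param enrich_labels apply the label-enrichment filter before scoring.
#' @param num_perms permutations for label enrichment.
#' @param enrich_threshold p-value threshold for enrichment (default 0.07).
#' @param min_carriers carrier floor for pathway networks.
#' @param ridge relative ridge penalty of the weight solve.
#' @param seed integer seed.
#' @return object of class `psn_sparse_predictor`: list with
#'   `cumulative_scores`, `per_split_scores`, `enrichment` (per round),
#'   `performance` (per-cutoff tp/fp/tn/fn), `auc`, `prauc` and `config`.
#' @export
build_predictor_sparse <- function(pheno, events, sets, predict_class = "case",
                                   num_splits = 3L, feat_score_max = 3L,
                                   enrich_labels = TRUE, num_perms = 20L,
                                   enrich_threshold = 0.07, min_carriers = 6L,
                                   ridge = 1, seed = 42L) {
  pheno <- as_tibble(pheno)
  stopifnot(all(c("ID", "STATUS") %in% names(pheno)), num_splits >= 1)
  if (!predict_class %in% pheno$STATUS) {
    abort(sprintf("predict_class '%s' not present in STATUS", predict_class),
          class = "psn_error")
  }
  labels <- setNames(pheno$STATUS, pheno$ID)
  # stratified folds: round k trains on everything outside fold k
  folds <- with_seed(seed, {
    f <- integer(nrow(pheno))
    names(f) <- pheno$ID
    for (cl in unique(pheno$STATUS)) {
      idsc <- sample(pheno$ID[pheno$STATUS == cl])
      f[idsc] <- rep_len(seq_len(num_splits), length(idsc))
    }
    f
  })
  per_split <- list()
  enrichment <- list()
  for (k in seq_len(num_splits)) {
    train_ids <- names(folds)[folds != k | num_splits == 1]
    train_events <- events[events$ID %in% train_ids, ]
    nets <- compact(lapply(names(sets), function(nm) {
      sim_binary_pathway(train_events, sets[[nm]], nm, min_carriers)
    }))
    names(nets) <- vapply(nets, psn_name, character(1))
    if (length(nets) == 0) {
      abort(sprintf("round %d: no pathway reached the carrier floor on training data", k),
            class = "psn_error")
    }
    if (enrich_labels) {
      enr <- label_enrichment(nets, labels[train_ids], predict_class,
                              num_perms = num_perms,
                              threshold = enrich_threshold, seed = seed + k)
      enrichment[[k]] <- enr
      nets <- nets[enr$network[enr$pass]]
      if (length(nets) == 0) {
        abort(sprintf("round %d: label enrichment eliminated every network; lower the threshold or increase num_perms", k),
              class = "psn_error")
      }
    }
    cl_train <- train_ids[labels[train_ids] == predict_class]
    bg_train <- setdiff(train_ids, cl_train)
    per_split[[k]] <- score_features(nets, cl_train, bg_train, feat_score_max,
                                     scheme = "holdout", seed = seed + k,
                                     ridge = ridge)
  }
  cum <- cumulative_scores(per_split)
  max_score <- num_splits * feat_score_max
  cutoffs <- seq_len(max_score)
  selected_by_cutoff <- setNames(
    lapply(cutoffs, function(s) cum$feature[cum$score >= s]),
    cutoffs
  )
  perf <- sparse_pathway_classify(events, selected_by_cutoff, sets, labels,
                                  positive_label = predict_class)
  stats <- perf_calc(perf)
  structure(list(
    cumulative_scores = cum,
    per_split_scores = per_split,
    enrichment = enrichment,
    selected_by_cutoff = selected_by_cutoff,
    performance = stats$stats,
    auc = stats$auc,
    prauc = stats$prauc,
    folds = folds,
    config = list(predict_class = predict_class, num_splits = num_splits,
                  feat_score_max = feat_score_max,
                  enrich_labels = enrich_labels, num_perms = num_perms,
                  enrich_threshold = enrich_threshold,
                  min_carriers = min_carriers, ridge = ridge, seed = seed)
  ), class = "psn_sparse_predictor")
}

#' @export
print.psn_sparse_predictor <- function(x, ...) {
  cat(sprintf("<psn_sparse_predictor> %d round(s), max cumulative score %d\n",
              x$config$num_splits, x$config$num_splits * x$config$feat_score_max))
  cat(sprintf("AUROC %.3f, AUPR %.3f\n", x$auc, x$prauc))
  invisible(x)
}

#' @rdname tidy.psn_predictor
#' @export
tidy.psn_sparse_predictor <- function(x, ...) x$cumulative_scores

#' @rdname tidy.psn_predictor
#' @export
glance.psn_sparse_predictor <- function(x, ...) {
  tibble(
    num_splits = x$config$num_splits,
    max_score = x$config$num_splits * x$config$feat_score_max,
    n_features_scored = nrow(x$cumulative_scores),
    auc = x$auc,
    prauc = x$prauc
  )
}
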