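#' Classify held-out patients by label propagation
#'
#' For each class, rebuilds that class's selected feature networks over the
#' train+test cohort, integrates them with equal weights (weights are not
#' re-fit once test patients are present, which would leak test labels), and
#' propagates a prior of 1 on the class's training members. A test patient's
#' score for the class is the normalized rank of their propagation score among
#' test patients (`rank / n_test`, ties averaged), making classes with
#' different network densities comparable. The predicted class is the argmax;
#' exact ties go to the lexicographically first class. A test patient absent
#' from every selected network of a class scores 0 for that class with a
#' warning - the missing-data contract, not an error.
#'
#' @param ds a [patient_dataset()] containing train and test patients.
#' @param rules grouping rules for the full feature inventory.
#' @param metrics per-layer metric assignment; see [build_feature_networks()].
#' @param selected named list mapping each class label to its selected feature
#'   names (each class needs at least one).
#' @param split tibble from [split_train_test()] (`ID`, `STATUS`, `TT_STATUS`).
#' @param lambda propagation smoothing strength.
#' @param ... further arguments to [build_feature_networks()] (sparsification,
#'   carrier floor).
#' @return tibble with one row per test patient: `ID`, `STATUS` (truth),
#'   `TT_STATUS`, one `<class>_SCORE` column per class, `PRED_CLASS`.
#' @export
classify_by_propagation <- function(ds, rules, metrics, selected, split,
                                    lambda = 1, ...) {
  classes <- sort(names(selected))
  train_ids <- split$ID[split$TT_STATUS == "TRAIN"]
  test_ids <- split$ID[split$TT_STATUS == "TEST"]
  stopifnot(length(test_ids) >= 1)
  if (any(lengths(selected) == 0)) {
    abort("every class needs at least one selected feature", class = "psn_error")
  }
  score_cols <- list()
  for (cl in classes) {
    cl_train <- split$ID[split$TT_STATUS == "TRAIN" & split$STATUS == cl]
    if (length(cl_train) == 0) {
      abort(sprintf("class '%s' has no training members", cl), class = "psn_error")
    }
    nets <- build_feature_networks(
      ds, filter_rules(rules, selected[[cl]]), metrics,
      restrict_to = c(train_ids, test_ids), ...
    )
    if (length(nets) == 0) {
      abort(sprintf("class '%s': no selected feature produced a network", cl),
            class = "psn_error")
    }
    integrated <- combine_networks(nets, name = sprintf("integrated_%s", cl))
    nodes <- psn_nodes(integrated)
    prior <- setNames(as.numeric(nodes %in% cl_train), nodes)
    f <- propagate_labels(integrated, prior, lambda = lambda)
    present <- intersect(test_ids, f$ID)
    absent <- setdiff(test_ids, present)
    if (length(absent)) {
      warn(sprintf("class '%s': %d test patient(s) absent from every selected network; scored 0 (%s)",
                   cl, length(absent), paste(head(absent, 5), collapse = ", ")))
    }
    sc <- setNames(rep(0, length(test_ids)), test_ids)
    if (length(present)) {
      raw <- setNames(f$score, f$ID)[present]
      sc[present] <- rank(raw, ties.method = "average") / length(present)
    }
    score_cols[[cl]] <- unname(sc)
  }
  scores <- as.matrix(as.data.frame(score_cols, check.names = FALSE))
  pred <- classes[apply(scores, 1, which.max)]  # which.max: first max = lexicographic tie-break
  out <- tibble(
    ID = test_ids,
    STATUS = split$STATUS[match(test_ids, split$ID)],
    TT_STATUS = "TEST"
  )
  for (cl in classes) out[[paste0(cl, "_SCORE")]] <- unname(scores[, cl])
  out$PRED_CLASS <- pred
  out
}

filter_rules <- function(rules, keep) {
  out <- lapply(rules, function(grp) grp[names(grp) %in% keep])
  out[lengths(out) > 0]
}

#' Classify patients by pathway membership at feature-score cutoffs
#'
#' The sparse-genetic decision rule: at a given feature-score cutoff, a
#' patient is called a case if they have a genetic event in at least one
#' pathway passing feature selection at that cutoff; otherwise they are a
#' control at that cutoff. Sweeping the cutoff yields the counts from which
#' the workflow's ROC curve is computed.
#'
#' @param events patient events (data frame `ID`/`gene` or named list); see
#'   [sim_binary_pathway()].
#' @param selected_by_cutoff named list mapping each score cutoff to the
#'   pathway names selected at that cutoff (higher cutoffs select subsets).
#' @param sets named list of pathway gene sets.
#' @param labels named character vector of true labels over the cohort.
#' @param positive_label label treated as "case".
#' @return tibble with one row per cutoff: `score`, `tp`, `fp`, `tn`, `fn`;
#'   `tp + fn` equals the number of true cases in every row.
#' @export
sparse_pathway_classify <- function(events, selected_by_cutoff, sets, labels,
                                    positive_label = "case") {
  ev <- as_event_list(events)
  ids <- names(labels)
  truth_pos <- labels == positive_label
  rows <- lapply(names(selected_by_cutoff), function(cut) {
    paths <- selected_by_cutoff[[cut]]
    genes <- unique(unlist(sets[intersect(paths, names(sets))]))
    called <- vapply(ids, function(id) {
      g <- ev[[id]]
      length(g) > 0 && any(g %in% genes)
    }, logical(1))
    tibble(
      score = as.numeric(cut),
      tp = sum(called & truth_pos), fp = sum(called & !truth_pos),
      tn = sum(!called & !truth_pos), fn = sum(!called & truth_pos)
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$score)
}
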