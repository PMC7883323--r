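#' Score features for one class on one training split
#'
#' Runs `feat_score_max` integration queries for a class. Each query takes a
#' different subsample of the class's training patients ([resample_training()]),
#' solves non-negative network weights against the co-membership target
#' ([solve_network_weights()]), and increments the score of every network that
#' receives a positive weight. A feature's score for the split is therefore an
#' integer in `[0, feat_score_max]`: the number of queries it helped explain.
#'
#' @param networks named list of train-only candidate [psn()]s.
#' @param class_ids training patients of the class being scored.
#' @param background_ids the remaining training patients.
#' @param feat_score_max number of queries (maximum attainable score).
#' @param scheme,mc_fraction resampling scheme; see [resample_training()].
#' @param seed integer seed for the split's subsampling.
#' @param ridge relative ridge penalty for the weight solve.
#' @return tibble with columns `feature`, `score`.
#' @export
score_features <- function(networks, class_ids, background_ids,
                           feat_score_max, scheme = "holdout", seed = 42L,
                           ridge = 1, mc_fraction = 0.8) {
  counts <- setNames(integer(length(networks)), names(networks))
  for (i in seq_len(feat_score_max)) {
    query <- resample_training(class_ids, scheme, feat_score_max, i, seed,
                               mc_fraction)
    w <- tryCatch(
      solve_network_weights(networks, query, background_ids, ridge),
      psn_error = function(e) {
        abort(sprintf("query %d: %s", i, conditionMessage(e)), class = "psn_error")
      }
    )
    hit <- w$network[w$weight > 0]
    counts[hit] <- counts[hit] + 1L
  }
  tibble(feature = names(counts), score = unname(counts))
}

#' Call consensus features across train/test splits
#'
#' A feature passes selection when it scores at least `fs_cutoff` in at least
#' `fs_pct_pass` of the splits; `fs_pct_pass = 0` means "in at least one
#' split". Missing entries (a feature never weighted in a split) count as
#' below cutoff. With features scored out of 10, a reasonable consensus
#' setting is `fs_cutoff = 9`, `fs_pct_pass = 0.7`.
#'
#' @param scores data frame with a `feature` column and one numeric column per
#'   split (`NA` allowed).
#' @param fs_cutoff minimum per-split score, `>= 1`.
#' @param fs_pct_pass minimum fraction of splits meeting the cutoff, in
#'   `[0, 1]`.
#' @return character vector of selected feature names.
#' @export
select_features <- function(scores, fs_cutoff = 1L, fs_pct_pass = 0) {
  stopifnot(fs_cutoff >= 1, fs_pct_pass >= 0, fs_pct_pass <= 1)
  if (nrow(scores) == 0) return(character())
  split_cols <- setdiff(names(scores), "feature")
  if (length(split_cols) == 0) abort("no split columns in score table",
                                     class = "psn_error")
  m <- as.matrix(scores[, split_cols, drop = FALSE])
  npass <- rowSums(!is.na(m) & m >= fs_cutoff)
  need <- if (fs_pct_pass == 0) 1L else fs_pct_pass * length(split_cols)
  scores$feature[npass >= need]
}

#' Label bias of a network's membership
#'
#' The bias of a network toward a label, computed over its member patients:
#' a network whose members are all cases scores +1, all controls scores -1,
#' and an equal number of both scores 0.
#'
#' @param members character vector of member patient ids.
#' @param labels named character vector of cohort labels.
#' @param positive_label the label counted as positive (e.g. `"case"`).
#' @return bias in `[-1, 1]`, or `NA` for an empty membership.
#' @export
label_bias <- function(members, labels, positive_label) {
  members <- intersect(members, names(labels))
  if (length(members) == 0) return(NA_real_)
  npos <- sum(labels[members] == positive_label)
  (npos - (length(members) - npos)) / length(members)
}

#' Permutation-based label enrichment of binary feature networks
#'
#' Binary similarity lets a pathway network earn a high feature score from a
#' single case member, so networks are first filtered for enrichment of the
#' predicted label. Each network's observed [label_bias()] is compared against
#' its bias under label permutations (labels shuffled over the full cohort,
#' network membership fixed), and the empirical p-value is the proportion of
#' permutations with bias at least as high as observed, with a +1 correction
#' so p is never exactly zero. Networks with `p < threshold` pass.
#'
#' @param networks named list of [psn()]s (members = node sets).
#' @param labels named character vector over the cohort.
#' @param positive_label the predicted class.
#' @param num_perms number of label permutations, `>= 1`.
#' @param threshold pass threshold on the empirical p-value (default 0.07).
#' @param seed integer seed for the permutations.
#' @return tibble with columns `network`, `n_members`, `bias`, `p`, `pass`;
#'   networks without members in the cohort are excluded with a warning.
#' @export
label_enrichment <- function(networks, labels, positive_label, num_perms = 50L,
                             threshold = 0.07, seed = 42L) {
  stopifnot(num_perms >= 1)
  if (!positive_label %in% labels || all(labels == positive_label)) {
    abort("cohort must contain both the positive label and at least one other",
          class = "psn_error")
  }
  perm_labels <- with_seed(seed, {
    replicate(num_perms, sample(unname(labels)))
  })
  rownames(perm_labels) <- NULL
  ids <- names(labels)
  rows <- lapply(names(networks), function(nm) {
    members <- intersect(psn_nodes(networks[[nm]]), ids)
    if (length(members) == 0) {
      warn(sprintf("network '%s' has no members in the cohort; excluded", nm))
      return(NULL)
    }
    obs <- label_bias(members, labels, positive_label)
    idx <- match(members, ids)
    pb <- colSums(perm_labels[idx, , drop = FALSE] == positive_label)
    perm_bias <- (2 * pb - length(members)) / length(members)
    p <- (1 + sum(perm_bias >= obs)) / (num_perms + 1)
    tibble(network = nm, n_members = length(members), bias = obs, p = p,
           pass = p < threshold)
  })
  dplyr::bind_rows(compact(rows))
}

#' Sum feature scores across splits
#'
#' In the sparse-genetic workflow feature scores are added across the
#' `num_splits` feature-selection rounds, so a feature can score as high as
#' `num_splits * feat_score_max` (e.g. 9 over 3 splits scored out of 3, or 30
#' over 3 splits scored out of 10). Features missing from a split contribute 0.
#'
#' @param per_split list of per-split score tibbles (`feature`, `score`).
#' @return tibble with columns `feature`, `score`, sorted by decreasing score.
#' @export
cumulative_scores <- function(per_split) {
  stopifnot(length(per_split) >= 1)
  dplyr::bind_rows(per_split) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(score = sum(.data$score, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$feature)
}
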