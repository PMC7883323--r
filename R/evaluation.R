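#' ROC curve from continuous scores
#'
#' Sweeps a decision threshold over the positive-class score, grouping tied
#' scores, and returns (FPR, TPR) points anchored at (0,0) and (1,1). The
#' trapezoidal area under these points equals the Mann-Whitney U statistic
#' divided by `n_pos * n_neg` (ties counted half).
#'
#' @param score numeric scores, higher = more positive.
#' @param truth logical vector, `TRUE` for the positive class.
#' @return tibble with columns `fpr`, `tpr`, sorted by `fpr`.
#' @export
roc_curve <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  npos <- sum(truth)
  nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) {
    abort("ROC undefined: only one class present", class = "psn_degenerate_error")
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t)
  fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(
    fpr = c(0, fp[last] / nneg),
    tpr = c(0, tp[last] / npos)
  )
}

#' Precision-recall curve from continuous scores
#'
#' Threshold sweep companion of [roc_curve()]; points are reported per tied
#' score group and the curve is summarised by step interpolation (area =
#' sum of recall increments times precision at that threshold).
#'
#' @inheritParams roc_curve
#' @return tibble with columns `recall`, `precision`, sorted by `recall`.
#' @export
pr_curve <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  npos <- sum(truth)
  if (npos == 0) abort("PR undefined: no positives", class = "psn_degenerate_error")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  t <- truth[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t)
  fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)
  tibble(
    recall = tp[last] / npos,
    precision = tp[last] / (tp[last] + fp[last])
  )
}

#' Area under a curve by trapezoidal rule
#' @param x,y curve coordinates (x need not be sorted).
#' @return numeric area.
#' @export
auc_trapezoid <- function(x, y) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

auc_step <- function(recall, precision) {
  ord <- order(recall)
  r <- c(0, recall[ord])
  p <- precision[ord]
  sum(diff(r) * p)
}

#' Evaluate prediction tables across train/test splits
#'
#' Computes per-split accuracy (overall and per class), confusion counts, ROC
#' and precision-recall curves on the positive-class score, AUROC/AUPR per
#' split, and mean curves by vertical averaging over splits. Splits whose test
#' set contains a single true class have no defined ROC; they are flagged and
#' excluded from curve averages (accuracy is still reported).
#'
#' @param tables a prediction tibble from [classify_by_propagation()] or a
#'   list of them (one per split).
#' @param positive_class class whose `<class>_SCORE` column drives the curves.
#' @param grid_size number of grid points for vertical curve averaging.
#' @return object of class `psn_performance`; see [glance.psn_performance()].
#' @export
evaluate_predictions <- function(tables, positive_class, grid_size = 101L) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  score_col <- paste0(positive_class, "_SCORE")
  summ <- list(); rocs <- list(); prs <- list(); cls_acc <- list(); conf <- list()
  for (k in seq_along(tables)) {
    tb <- tables[[k]]
    if (!score_col %in% names(tb)) {
      abort(sprintf("score column '%s' missing from split %d", score_col, k),
            class = "psn_error")
    }
    acc <- mean(tb$PRED_CLASS == tb$STATUS)
    truth <- tb$STATUS == positive_class
    ok <- length(unique(truth)) == 2
    auroc <- aupr <- NA_real_
    if (ok) {
      rc <- roc_curve(tb[[score_col]], truth)
      pc <- pr_curve(tb[[score_col]], truth)
      auroc <- auc_trapezoid(rc$fpr, rc$tpr)
      aupr <- auc_step(pc$recall, pc$precision)
      rocs[[k]] <- dplyr::mutate(rc, split = k)
      prs[[k]] <- dplyr::mutate(pc, split = k)
    }
    summ[[k]] <- tibble(split = k, n = nrow(tb), accuracy = acc,
                        auroc = auroc, aupr = aupr, roc_ok = ok)
    cls_acc[[k]] <- tb |>
      dplyr::group_by(class = .data$STATUS) |>
      dplyr::summarise(accuracy = mean(.data$PRED_CLASS == .data$STATUS),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(split = k)
    conf[[k]] <- tb |>
      dplyr::count(.data$STATUS, .data$PRED_CLASS) |>
      dplyr::mutate(split = k)
  }
  roc_tbl <- dplyr::bind_rows(rocs)
  pr_tbl <- dplyr::bind_rows(prs)
  grid <- seq(0, 1, length.out = grid_size)
  mean_roc <- mean_pr <- NULL
  if (nrow(roc_tbl) > 0) {
    tprs <- vapply(split(roc_tbl, roc_tbl$split), function(d) {
      stats::approx(d$fpr, d$tpr, xout = grid, ties = max, rule = 2)$y
    }, numeric(grid_size))
    mean_roc <- tibble(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
    precs <- vapply(split(pr_tbl, pr_tbl$split), function(d) {
      stats::approx(c(0, d$recall), c(d$precision[1], d$precision),
                    xout = grid, ties = max, rule = 2)$y
    }, numeric(grid_size))
    mean_pr <- tibble(recall = grid, precision = rowMeans(as.matrix(precs)))
  }
  structure(list(
    positive_class = positive_class,
    summary = dplyr::bind_rows(summ),
    class_accuracy = dplyr::bind_rows(cls_acc),
    confusion = dplyr::bind_rows(conf),
    roc = roc_tbl, pr = pr_tbl,
    mean_roc = mean_roc, mean_pr = mean_pr
  ), class = "psn_performance")
}

#' @export
print.psn_performance <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<psn_performance> %d split(s); mean accuracy %.3f; mean AUROC %.3f; mean AUPR %.3f\n",
              g$n_splits, g$mean_accuracy, g$mean_auroc, g$mean_aupr))
  invisible(x)
}

#' Tidy and summarise performance objects
#'
#' `tidy()` returns the per-split summary (accuracy, AUROC, AUPR); `glance()`
#' returns a one-row summary with means over the splits where curves are
#' defined.
#'
#' @param x a `psn_performance` object.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.psn_performance <- function(x, ...) x$summary

#' @rdname tidy.psn_performance
#' @export
glance.psn_performance <- function(x, ...) {
  tibble(
    n_splits = nrow(x$summary),
    mean_accuracy = mean(x$summary$accuracy),
    mean_auroc = mean(x$summary$auroc, na.rm = TRUE),
    mean_aupr = mean(x$summary$aupr, na.rm = TRUE)
  )
}

#' Plot ROC and precision-recall curves
#'
#' Per-split curves in grey, vertically-averaged curves in blue, one panel
#' per curve type.
#'
#' @param object a `psn_performance` object.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.psn_performance <- function(object, ...) {
  roc <- dplyr::mutate(object$roc, panel = "ROC", x = .data$fpr, y = .data$tpr)
  pr <- dplyr::mutate(object$pr, panel = "Precision-recall",
                      x = .data$recall, y = .data$precision)
  per_split <- dplyr::bind_rows(roc, pr)
  avg <- dplyr::bind_rows(
    dplyr::mutate(object$mean_roc, panel = "ROC", x = .data$fpr, y = .data$tpr),
    dplyr::mutate(object$mean_pr, panel = "Precision-recall",
                  x = .data$recall, y = .data$precision)
  )
  ggplot2::ggplot(per_split, ggplot2::aes(.data$x, .data$y, group = .data$split)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_line(data = avg, ggplot2::aes(group = NULL), colour = "blue") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}

#' Performance from classification counts
#'
#' Given per-cutoff confusion counts (as produced by
#' [sparse_pathway_classify()]), computes TPR, FPR and precision per row
#' (precision at `tp + fp = 0` is defined as 1), anchors the ROC at (0,0) and
#' (1,1), and returns trapezoidal AUROC and step-interpolated area under the
#' precision-recall curve.
#'
#' @param counts data frame with columns `score`, `tp`, `fp`, `tn`, `fn`;
#'   `tp + fn` and `fp + tn` must be constant across rows.
#' @return list with `stats` (the input plus `tpr`, `fpr`, `precision`),
#'   `auc` and `prauc`.
#' @export
perf_calc <- function(counts) {
  req <- c("score", "tp", "fp", "tn", "fn")
  stopifnot(all(req %in% names(counts)))
  pos <- unique(counts$tp + counts$fn)
  neg <- unique(counts$fp + counts$tn)
  if (length(pos) != 1 || length(neg) != 1 || pos <= 0 || neg <= 0 ||
      any(counts[req[-1]] < 0)) {
    abort("invalid count table: tp+fn and fp+tn must be constant positive marginals",
          class = "psn_error")
  }
  stats_tbl <- as_tibble(counts) |>
    dplyr::mutate(
      tpr = .data$tp / pos,
      fpr = .data$fp / neg,
      precision = ifelse(.data$tp + .data$fp == 0, 1,
                         .data$tp / (.data$tp + .data$fp))
    )
  auc <- auc_trapezoid(c(0, stats_tbl$fpr, 1), c(0, stats_tbl$tpr, 1))
  prauc <- auc_step(stats_tbl$tpr, stats_tbl$precision)
  list(stats = stats_tbl, auc = auc, prauc = prauc)
}
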