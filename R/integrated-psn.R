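#' Aggregate selected feature networks into an integrated patient network
#'
#' Combines the networks that passed feature selection into one network by
#' taking, per patient pair, the mean of the edge weights (`"MEAN"`; a pair
#' absent from a network contributes 0 to that network's term, and the
#' denominator is the number of networks aggregated) or the maximum (`"MAX"`).
#' Optionally prunes to the strongest edges: `top_x = 0.05` keeps the top 5%
#' of edges by weight network-wide.
#'
#' @param networks named list of [psn()]s (at least one).
#' @param agg_fun `"MEAN"` or `"MAX"`.
#' @param top_x fraction of edges retained after aggregation, in `(0, 1]`;
#'   `ceiling(top_x * n_edges)` edges are kept, ties broken deterministically.
#' @param name name for the integrated network.
#' @return a [psn()] over the union of the input node sets.
#' @export
aggregate_networks <- function(networks, agg_fun = c("MEAN", "MAX"), top_x = 1,
                               name = "integrated") {
  agg_fun <- match.arg(agg_fun)
  stopifnot(length(networks) >= 1, top_x > 0, top_x <= 1)
  nodes <- sort(unique(unlist(lapply(networks, psn_nodes))))
  all_e <- dplyr::bind_rows(lapply(networks, psn_edges))
  if (nrow(all_e) == 0) return(psn(empty_edges(), nodes = nodes, name = name))
  agg <- all_e |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = if (agg_fun == "MEAN")
      sum(.data$weight) / length(networks) else max(.data$weight),
      .groups = "drop")
  if (top_x < 1) {
    keep_n <- ceiling(top_x * nrow(agg))
    agg <- agg[order(-agg$weight, agg$from, agg$to)[seq_len(keep_n)], ]
  }
  psn(agg, nodes = nodes, name = name)
}

#' Within- versus between-class shortest-path statistics
#'
#' Tests whether patients of the same class sit closer together in the
#' integrated network than patients of different classes. Edge length is taken
#' as `1 / weight` (stronger similarity, shorter path) and all-pairs shortest
#' paths are computed by Dijkstra's algorithm. Pairwise distances are
#' partitioned into within-class (per class) and between-class samples, and a
#' one-sided Wilcoxon-Mann-Whitney test assesses whether within-class
#' distances are smaller. Unreachable pairs are excluded and counted.
#'
#' @param net a [psn()], typically from [aggregate_networks()].
#' @param labels named character vector of class labels over (a superset of)
#'   the network's nodes; at least two classes must be present among nodes.
#' @return object of class `psn_separation`: list with `samples` (tibble
#'   `group`, `distance`), `tests` (tibble `comparison`, `n_within`,
#'   `n_between`, `p`, `skipped`) and `unreachable` (tibble `group`, `n`).
#' @export
class_separation <- function(net, labels) {
  nodes <- intersect(psn_nodes(net), names(labels))
  lab <- labels[nodes]
  if (length(unique(lab)) < 2) {
    abort("need at least 2 classes among network nodes", class = "psn_error")
  }
  e <- psn_edges(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to, weight = 1 / e$weight),
    directed = FALSE, vertices = data.frame(name = psn_nodes(net))
  )
  D <- igraph::distances(g, v = nodes, to = nodes, algorithm = "dijkstra")
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ut]
  same <- lab[ut[, 1]] == lab[ut[, 2]]
  grp <- unname(ifelse(same, paste0("within_", lab[ut[, 1]]), "between"))
  finite <- is.finite(d)
  samples <- tibble(group = grp[finite], distance = d[finite])
  unreachable <- tibble(group = grp[!finite]) |>
    dplyr::count(.data$group, name = "n")
  between <- samples$distance[samples$group == "between"]
  tests <- lapply(sort(unique(lab)), function(cl) {
    within <- samples$distance[samples$group == paste0("within_", cl)]
    skipped <- length(within) < 2 || length(between) < 2
    p <- if (skipped) NA_real_ else
      suppressWarnings(wilcox.test(within, between, alternative = "less")$p.value)
    tibble(comparison = sprintf("within_%s vs between", cl),
           n_within = length(within), n_between = length(between),
           p = p, skipped = skipped)
  })
  structure(list(samples = samples, tests = dplyr::bind_rows(tests),
                 unreachable = unreachable),
            class = "psn_separation")
}

#' @export
print.psn_separation <- function(x, ...) {
  cat("<psn_separation>\n")
  print(x$tests)
  invisible(x)
}

#' Violin plot of within- and between-class shortest-path distances
#'
#' @param object a `psn_separation` object from [class_separation()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.psn_separation <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(.data$group, .data$distance, fill = .data$group)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "shortest-path distance") +
    ggplot2::theme_bw()
}
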