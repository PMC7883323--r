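#' Pearson-profile similarity network
#'
#' Builds one feature network from a group of measures (typically one
#' pathway's genes) in a measure-by-patient matrix. The weight of the edge
#' between two patients is their Pearson correlation over pairwise-complete
#' observations of the group's measures, clipped at zero: network integration
#' and label propagation assume non-negative affinities, and a negative
#' correlation is treated as "no similarity". Pairs with an undefined
#' correlation (zero variance, fewer than two shared observed measures)
#' receive no edge. Missing entries are handled by the metric itself, so
#' patients missing some measures still enter the network.
#'
#' @param mat numeric matrix, measures in rows and patients in columns.
#' @param group character vector of measure (row) identifiers; measures absent
#'   from `mat` are dropped, but at least two must remain.
#' @param name feature identifier.
#' @param clip_negative clip negative correlations to zero (default) rather
#'   than keeping them; clipped/zero-weight pairs are omitted from the edge
#'   list.
#' @return a [psn()] whose nodes are the patients with at least two observed
#'   measures in the group.
#' @export
sim_pearson_profile <- function(mat, group, name, clip_negative = TRUE) {
  rows <- intersect(group, rownames(mat))
  if (length(rows) < 2) {
    abort(sprintf("feature '%s': group resolves to %d measure(s); need >= 2",
                  name, length(rows)), class = "psn_error")
  }
  sub <- mat[rows, , drop = FALSE]
  nobs <- colSums(!is.na(sub))
  sub <- sub[, nobs >= 2, drop = FALSE]
  if (ncol(sub) < 2) return(psn(empty_edges(), nodes = colnames(sub), name = name))
  r <- suppressWarnings(cor(sub, use = "pairwise.complete.obs"))
  ut <- which(upper.tri(r), arr.ind = TRUE)
  w <- r[ut]
  if (clip_negative) w[w < 0] <- 0
  keep <- is.finite(w) & w > 0
  edges <- tibble(
    from = colnames(sub)[ut[keep, 1]],
    to = colnames(sub)[ut[keep, 2]],
    weight = pmin(w[keep], 1)
  )
  psn(edges, nodes = colnames(sub), name = name)
}

empty_edges <- function() {
  tibble(from = character(), to = character(), weight = numeric())
}

#' Similarity network for a single continuous variable
#'
#' For clinical variables each variable is its own feature. Two metrics are
#' built in:
#' \describe{
#'   \item{normdiff}{normalized difference,
#'     `w(a,b) = 1 - |x_a - x_b| / (max - min)`, the range taken over the
#'     observed cohort at build time.}
#'   \item{scaled_euclidean}{`w(a,b) = 1 - d(a,b) / max d`, the distance
#'     scaled by the largest pairwise distance in the cohort. For a single
#'     variable this coincides with normalized difference.}
#' }
#' Patients with missing values are omitted from the network, not imputed.
#'
#' @param values named numeric vector, one value per patient.
#' @param metric `"normdiff"` or `"scaled_euclidean"`.
#' @param name feature identifier.
#' @return a [psn()] over the patients with observed values; pairs whose
#'   similarity is exactly zero (the cohort extremes) carry no edge.
#' @export
sim_continuous <- function(values, metric = c("normdiff", "scaled_euclidean"),
                           name) {
  metric <- match.arg(metric)
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort(sprintf("feature '%s': fewer than 2 patients with observed values", name),
          class = "psn_error")
  }
  rng <- max(values) - min(values)
  if (rng == 0) {
    abort(sprintf("feature '%s': degenerate range (all values identical)", name),
          class = "psn_error")
  }
  ids <- names(values)
  pr <- which(upper.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  d <- abs(values[pr[, 1]] - values[pr[, 2]])
  w <- 1 - d / rng
  keep <- w > 0
  psn(tibble(from = ids[pr[keep, 1]], to = ids[pr[keep, 2]], weight = w[keep]),
      nodes = ids, name = name)
}

#' Normalized-difference similarity
#'
#' The scalar form of the `normdiff` metric: `1 - |a - b| / rng`.
#'
#' @param a,b numeric values.
#' @param rng the observed cohort range (`max - min`), must be positive.
#' @return similarity in `[0, 1]` when `a` and `b` lie in the cohort range.
#' @export
norm_diff <- function(a, b, rng) {
  stopifnot(rng > 0)
  1 - abs(a - b) / rng
}

#' Binary pathway similarity network from sparse genetic events
#'
#' Two patients that share a genetic event (mutation, CNV) in genes of the
#' same pathway have similarity one for that pathway; otherwise zero. The
#' network is therefore the complete graph (all weights 1) over the pathway's
#' carriers. Pathways with fewer carriers than `min_carriers` (default 6) do
#' not generate a feature at all, which keeps near-empty cliques out of
#' feature selection.
#'
#' @param events patient events: either a data frame with columns `ID` and
#'   `gene` (one row per event) or a named list mapping patient id to a
#'   character vector of event genes.
#' @param gene_set character vector of the pathway's genes.
#' @param name feature identifier.
#' @param min_carriers minimum number of carriers to emit a network.
#' @return a [psn()] clique over the carriers, or `NULL` when fewer than
#'   `min_carriers` patients carry an event in the set.
#' @export
sim_binary_pathway <- function(events, gene_set, name, min_carriers = 6L) {
  ev <- as_event_list(events)
  carriers <- names(ev)[vapply(ev, function(g) any(g %in% gene_set), logical(1))]
  if (length(carriers) < min_carriers) return(NULL)
  carriers <- sort(carriers)
  pr <- t(combn(carriers, 2))
  psn(tibble(from = pr[, 1], to = pr[, 2], weight = 1),
      nodes = carriers, name = name)
}

as_event_list <- function(events) {
  if (is.data.frame(events)) {
    stopifnot(all(c("ID", "gene") %in% names(events)))
    split(as.character(events$gene), as.character(events$ID))
  } else {
    events
  }
}

#' Sparsify a similarity network
#'
#' Drops edges below a weight floor, then keeps, for each node, only its
#' `max_degree` strongest incident edges; an edge survives if either endpoint
#' retains it. The operation is idempotent. Dense all-pairs networks (e.g.
#' normalized-difference features) are sparsified before integration to keep
#' memory and solve time proportional to meaningful similarity.
#'
#' @param net a [psn()].
#' @param min_weight minimum edge weight retained (default 0.3).
#' @param max_degree per-node cap on retained incident edges (default 50).
#' @return a [psn()] over the same node set.
#' @export
sparsify_network <- function(net, min_weight = 0.3, max_degree = 50L) {
  stopifnot(min_weight >= 0, max_degree >= 1)
  e <- net$edges[net$edges$weight >= min_weight, , drop = FALSE]
  if (nrow(e) > 0) {
    # rank an edge within each endpoint's incidence list (ties by pair order
    # for determinism); keep edges ranked within max_degree by either endpoint
    long <- rbind(
      data.frame(node = e$from, idx = seq_len(nrow(e)), weight = e$weight),
      data.frame(node = e$to, idx = seq_len(nrow(e)), weight = e$weight)
    )
    long <- long[order(long$node, -long$weight, long$idx), ]
    rk <- stats::ave(seq_along(long$idx), long$node, FUN = seq_along)
    keep_idx <- unique(long$idx[rk <= max_degree])
    e <- e[sort(keep_idx), , drop = FALSE]
  }
  psn(e, nodes = net$nodes, name = net$name)
}

#' Build all feature networks for a dataset
#'
#' Converts grouped patient data into one similarity network per feature
#' group, dispatching on a per-layer metric assignment. Binary features may be
#' absent when they fail the carrier floor. Restricting to a patient subset
#' (e.g. the training set during feature selection) subsets the data before
#' any cohort statistic (correlation, range) is computed, so held-out patients
#' cannot leak into training networks.
#'
#' @param ds a [patient_dataset()].
#' @param rules grouping rules as in [validate_dataset()].
#' @param metrics named vector/list mapping each rule layer to `"pearson"`,
#'   `"normdiff"`, `"scaled_euclidean"`, `"binary"`, or a custom function
#'   `f(layer_matrix, group, name)` returning a [psn()] or `NULL`.
#' @param restrict_to optional patient ids to restrict all networks to.
#' @param sparsify logical; apply [sparsify_network()] to continuous-variable
#'   networks (mirrors common practice for dense clinical features).
#' @param min_weight,max_degree sparsification parameters.
#' @param min_carriers carrier floor for binary features.
#' @return named list of [psn()] objects (one per emitted feature).
#' @export
build_feature_networks <- function(ds, rules, metrics, restrict_to = NULL,
                                   sparsify = FALSE, min_weight = 0.3,
                                   max_degree = 50L, min_carriers = 6L) {
  stopifnot(inherits(ds, "patient_dataset"))
  miss <- setdiff(names(rules), names(metrics))
  if (length(miss)) {
    abort(sprintf("no metric assigned for layer(s): %s", paste(miss, collapse = ", ")),
          class = "psn_error")
  }
  nets <- list()
  for (ly in names(rules)) {
    mat <- ds$assays[[ly]]
    if (is.null(mat)) abort(sprintf("layer '%s' not found in dataset", ly),
                            class = "psn_error")
    if (!is.null(restrict_to)) {
      mat <- mat[, colnames(mat) %in% restrict_to, drop = FALSE]
    }
    metric <- metrics[[ly]]
    for (feat in names(rules[[ly]])) {
      grp <- rules[[ly]][[feat]]
      net <- build_one_network(mat, grp, feat, metric, min_carriers)
      if (is.null(net)) next
      if (sparsify && !is.function(metric) &&
          metric %in% c("normdiff", "scaled_euclidean")) {
        net <- sparsify_network(net, min_weight, max_degree)
      }
      if (feat %in% names(nets)) {
        abort(sprintf("duplicate feature name across layers: '%s'", feat),
              class = "psn_error")
      }
      nets[[feat]] <- net
    }
  }
  nets
}

build_one_network <- function(mat, grp, feat, metric, min_carriers) {
  if (is.function(metric)) return(metric(mat, grp, feat))
  switch(metric,
    pearson = sim_pearson_profile(mat, grp, feat),
    normdiff = ,
    scaled_euclidean = {
      if (length(intersect(grp, rownames(mat))) != 1) {
        abort(sprintf("feature '%s': continuous-variable metrics take exactly one measure",
                      feat), class = "psn_error")
      }
      v <- mat[intersect(grp, rownames(mat)), ]
      sim_continuous(setNames(as.numeric(v), colnames(mat)), metric, feat)
    },
    binary = {
      bm <- mat[intersect(grp, rownames(mat)), , drop = FALSE]
      ev <- apply(bm, 2, function(col) rownames(bm)[which(!is.na(col) & col != 0)],
                  simplify = FALSE)
      sim_binary_pathway(ev, rownames(bm), feat, min_carriers)
    },
    abort(sprintf("unknown metric '%s'", metric), class = "psn_error")
  )
}
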