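#' Pairwise co-membership regression target
#'
#' Feature selection integrates candidate networks by regressing a
#' label-derived target on candidate edge weights. For a one-class query the
#' target over unordered patient pairs is +1 when both patients belong to the
#' query class sample, -1 when exactly one does, and pairs entirely within the
#' background are excluded from the fit (only same-vs-different class
#' information is used).
#'
#' @param query_ids training patients of the current class (the query sample).
#' @param background_ids the other training patients.
#' @return tibble with columns `from`, `to`, `target`.
#' @export
comembership_target <- function(query_ids, background_ids) {
  if (length(query_ids) == 0 || length(background_ids) == 0) {
    abort("query and background must both be non-empty", class = "psn_error")
  }
  if (length(intersect(query_ids, background_ids))) {
    abort("query and background sets overlap", class = "psn_error")
  }
  qq <- if (length(query_ids) >= 2) {
    pr <- t(combn(sort(query_ids), 2))
    tibble(from = pr[, 1], to = pr[, 2], target = 1)
  } else empty_target()
  qb <- tidyr::expand_grid(from = query_ids, to = background_ids)
  qb$target <- -1
  out <- dplyr::bind_rows(qq, qb)
  swap <- out$from > out$to
  tmp <- out$from[swap]; out$from[swap] <- out$to[swap]; out$to[swap] <- tmp
  out[order(out$from, out$to), ]
}

empty_target <- function() tibble(from = character(), to = character(), target = numeric())

#' Solve non-negative network weights by regularized regression
#'
#' Fits the co-membership target (+1 within the query class, -1 across) on
#' the candidate networks' edge weights by ridge-regularized least squares,
#' treating absent edges as weight zero. The fit includes an unpenalized
#' intercept (a constant bias network), so a candidate's weight reflects the
#' covariance between its edge weights and the target rather than their raw
#' inner product - without it, a network that connects training patients of
#' every class coherently would be penalized for its edges to the held-out
#' members of the query class. Negative coefficients are clipped to zero and
#' the system re-solved on the surviving candidates until all weights are
#' non-negative. Networks with a positive weight are the ones whose feature
#' score is incremented for this query.
#'
#' The ridge penalty is applied relative to the candidate scale
#' (`ridge * mean(diag(X'X))` over active candidates) and never to the
#' intercept, so rescaling all networks by a common positive constant
#' rescales the weights by its inverse.
#'
#' @param networks named list of [psn()] candidates.
#' @param query_ids,background_ids disjoint, non-empty training patient sets;
#'   see [comembership_target()].
#' @param ridge relative ridge penalty, `>= 0`; default 1.
#' @return tibble with columns `network`, `weight` (all `>= 0`, one row per
#'   candidate) and attribute `residual` (the fit's residual norm).
#' @export
solve_network_weights <- function(networks, query_ids, background_ids, ridge = 1) {
  stopifnot(length(networks) >= 1, ridge >= 0)
  if (is.null(names(networks)) || anyDuplicated(names(networks))) {
    abort("candidate networks must be uniquely named", class = "psn_error")
  }
  tgt <- comembership_target(query_ids, background_ids)
  ids <- sort(unique(c(query_ids, background_ids)))
  i <- match(tgt$from, ids)
  j <- match(tgt$to, ids)
  X <- vapply(networks, function(net) psn_matrix(net, ids)[cbind(i, j)],
              numeric(nrow(tgt)))
  X <- matrix(X, nrow = nrow(tgt), dimnames = list(NULL, names(networks)))
  y <- tgt$target
  active <- which(colSums(abs(X)) > 0)
  if (length(active) == 0) {
    abort("uninformative query: no candidate network touches any fit pair",
          class = "psn_error")
  }
  w <- setNames(numeric(ncol(X)), colnames(X))
  intercept <- 0
  repeat {
    Xa <- cbind(1, X[, active, drop = FALSE])
    A <- crossprod(Xa)
    lam <- ridge * mean(diag(crossprod(X[, active, drop = FALSE])))
    pen <- diag(c(0, rep(lam, length(active))), nrow = nrow(A))
    wa <- solve(A + pen, crossprod(Xa, y))
    intercept <- wa[1]
    wnet <- wa[-1]
    if (all(wnet >= 0) || length(active) == 1) {
      wnet[wnet < 0] <- 0
      w[active] <- wnet
      break
    }
    active <- active[wnet > 0]
    if (length(active) == 0) break
  }
  fit <- intercept + X %*% w
  out <- tibble(network = names(networks), weight = unname(w))
  attr(out, "residual") <- sqrt(sum((y - fit)^2))
  attr(out, "intercept") <- unname(intercept)
  out
}

#' Integrate networks into one weighted network
#'
#' Edge weight of the integrated network is the weighted sum of the candidate
#' networks' weights over the union of their node sets; zero-weight networks
#' contribute nothing.
#'
#' @param networks named list of [psn()].
#' @param weights named numeric weights covering all networks, or a tibble as
#'   returned by [solve_network_weights()]; `NULL` means equal weights
#'   `1/length(networks)` (used when integrating selected features for
#'   classification, where weights are not re-fit on train+test data).
#' @param name name of the integrated network.
#' @return a [psn()].
#' @export
combine_networks <- function(networks, weights = NULL, name = "integrated") {
  if (is.data.frame(weights)) weights <- setNames(weights$weight, weights$network)
  if (is.null(weights)) {
    weights <- setNames(rep(1 / length(networks), length(networks)), names(networks))
  }
  if (!all(names(networks) %in% names(weights))) {
    abort("weights must cover all provided networks", class = "psn_error")
  }
  nodes <- sort(unique(unlist(lapply(networks, psn_nodes))))
  pieces <- lapply(names(networks), function(nm) {
    if (weights[[nm]] == 0) return(empty_edges())
    e <- networks[[nm]]$edges
    e$weight <- e$weight * weights[[nm]]
    e
  })
  all_e <- dplyr::bind_rows(pieces)
  if (nrow(all_e)) {
    all_e <- all_e |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
      dplyr::filter(.data$weight > 0)
  }
  psn(all_e, nodes = nodes, name = name)
}

#' Propagate labels over a similarity network
#'
#' Diffuses training-class membership over the integrated network by solving
#' the graph-regularized linear system `(I + lambda * L) f = prior`, where `L`
#' is the combinatorial graph Laplacian. The system is symmetric positive
#' definite, so the solution is unique; it is computed by conjugate gradients
#' on the sparse operator and satisfies the maximum principle
#' `min(prior) <= f <= max(prior)` up to solver tolerance. On an edgeless
#' network `f` equals the prior exactly; as `lambda` (or an edge weight) grows,
#' scores of connected patients are pulled together.
#'
#' @param net a [psn()] with at least one node.
#' @param prior named numeric vector over all nodes of `net`; for
#'   classification, 1 for the positive class's training patients, 0 otherwise.
#' @param lambda smoothing strength, `> 0`; default 1.
#' @param tol relative residual tolerance of the solver.
#' @param max_iter iteration cap.
#' @return tibble with columns `ID`, `score`; attributes `iterations` and
#'   `residual` carry solver metadata.
#' @export
propagate_labels <- function(net, prior, lambda = 1, tol = 1e-10,
                             max_iter = 10000L) {
  stopifnot(lambda > 0)
  nodes <- psn_nodes(net)
  if (length(nodes) == 0) abort("network has no nodes", class = "psn_error")
  if (!all(nodes %in% names(prior))) {
    abort("prior must be defined on all network nodes", class = "psn_error")
  }
  y <- as.numeric(prior[nodes])
  if (any(!is.finite(y))) abort("prior values must be finite", class = "psn_error")
  e <- net$edges
  n <- length(nodes)
  if (nrow(e)) {
    W <- Matrix::sparseMatrix(
      i = match(e$from, nodes), j = match(e$to, nodes), x = e$weight,
      dims = c(n, n), symmetric = TRUE
    )
    d <- Matrix::rowSums(W)
    amul <- function(v) as.numeric(v + lambda * (d * v - W %*% v))
  } else {
    amul <- identity
  }
  sol <- cg_solve(amul, y, x0 = y, tol = tol, max_iter = max_iter)
  out <- tibble(ID = nodes, score = sol$x)
  attr(out, "iterations") <- sol$iterations
  attr(out, "residual") <- sol$residual
  out
}

# Conjugate gradients for a symmetric positive definite operator.
cg_solve <- function(amul, b, x0, tol, max_iter) {
  x <- x0
  r <- b - amul(x)
  p <- r
  rs <- sum(r * r)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) bnorm <- 1
  it <- 0L
  while (sqrt(rs) / bnorm > tol && it < max_iter) {
    Ap <- amul(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs2 <- sum(r * r)
    p <- r + (rs2 / rs) * p
    rs <- rs2
    it <- it + 1L
  }
  list(x = x, iterations = it, residual = sqrt(rs) / bnorm)
}
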