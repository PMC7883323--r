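# Shared fixture builders; everything is generated in code.

# Small dataset with one perfectly discriminative expression feature and one
# noise feature. Class "A" patients share one profile pattern, class "B"
# another; feature NOISE is iid normal.
toy_two_class <- function(n_per_class = 10, group_size = 6, seed = 1) {
  n <- 2 * n_per_class
  ids <- sprintf("T%02d", seq_len(n))
  status <- rep(c("A", "B"), each = n_per_class)
  set.seed(seed)
  patt_a <- rnorm(group_size)
  patt_b <- rnorm(group_size)
  x <- matrix(rnorm(2 * group_size * n, sd = 0.2), 2 * group_size, n,
              dimnames = list(sprintf("g%02d", seq_len(2 * group_size)), ids))
  sig_rows <- seq_len(group_size)
  x[sig_rows, status == "A"] <- x[sig_rows, status == "A"] + 2 * patt_a
  x[sig_rows, status == "B"] <- x[sig_rows, status == "B"] + 2 * patt_b
  list(
    ds = patient_dataset(tibble::tibble(ID = ids, STATUS = status),
                         assays = list(expr = x)),
    rules = list(expr = list(
      SIGNAL = rownames(x)[sig_rows],
      NOISE = rownames(x)[-sig_rows]
    )),
    metrics = list(expr = "pearson")
  )
}

# Random sparse similarity network over n nodes (for property tests).
random_psn <- function(n, p_edge = 0.4, name = "rnd") {
  ids <- sprintf("N%02d", seq_len(n))
  pr <- t(combn(ids, 2))
  keep <- runif(nrow(pr)) < p_edge
  psn(tibble::tibble(from = pr[keep, 1], to = pr[keep, 2],
                     weight = runif(sum(keep), 0.1, 1)),
      nodes = ids, name = name)
}

# Dense direct solve of (I + lambda * L) f = y: the independent propagation
# oracle (base linear algebra only).
dense_propagation <- function(net, prior, lambda = 1) {
  ids <- psn_nodes(net)
  W <- psn_matrix(net, ids)
  L <- diag(rowSums(W)) - W
  as.numeric(solve(diag(length(ids)) + lambda * L, prior[ids]))
}
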