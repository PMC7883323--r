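#' Patient similarity networks
#'
#' A patient similarity network (PSN) is a weighted undirected graph whose
#' nodes are patients and whose edge weights quantify pairwise similarity
#' under one feature's data (one pathway's expression profile, one clinical
#' variable, shared pathway mutations, ...). `psn()` constructs one from an
#' edge table; the constructor canonicalizes unordered pairs, forbids
#' self-edges and requires finite non-negative weights.
#'
#' @param edges data frame with columns `from`, `to`, `weight` (one row per
#'   unordered patient pair).
#' @param nodes optional character vector of member patients; defaults to the
#'   patients appearing in `edges`. Nodes without edges are allowed.
#' @param name feature identifier.
#'
#' @return An object of class `psn`: a list with elements `name`, `edges`
#'   (tibble, pairs stored with `from < to`) and `nodes`.
#' @export
#' @examples
#' net <- psn(data.frame(from = "P2", to = "P1", weight = 0.5), name = "toy")
#' psn_edges(net)
psn <- function(edges, nodes = NULL, name = "psn") {
  edges <- as_tibble(edges)
  req <- c("from", "to", "weight")
  if (!all(req %in% names(edges))) {
    abort("`edges` must have columns from, to, weight", class = "psn_error")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$from == edges$to)) {
    abort("self-edges are not allowed in a similarity network", class = "psn_error")
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0)) {
    abort("edge weights must be finite and >= 0", class = "psn_error")
  }
  # canonical unordered pairs
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicate patient pairs in edge list", class = "psn_error")
  }
  edges <- edges[order(edges$from, edges$to), req]
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(name = name, edges = edges, nodes = nodes), class = "psn")
}

#' @export
print.psn <- function(x, ...) {
  cat(sprintf(
    "<psn> %s: %d nodes, %d edges\n", x$name, length(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' @rdname psn
#' @param net a `psn` object.
#' @export
psn_edges <- function(net) net$edges

#' @rdname psn
#' @export
psn_nodes <- function(net) net$nodes

#' @rdname psn
#' @export
psn_name <- function(net) net$name

#' @export
as_tibble.psn <- function(x, ...) x$edges

#' Dense weight matrix of a network over a fixed patient order
#'
#' Pairs without an edge get weight 0. Used internally by the integration
#' engine, where absent edges enter the regression as zeros.
#'
#' @param net a `psn`.
#' @param ids patient identifiers indexing rows/columns of the result.
#' @return symmetric numeric matrix `length(ids) x length(ids)`.
#' @export
psn_matrix <- function(net, ids = psn_nodes(net)) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- net$edges[net$edges$from %in% ids & net$edges$to %in% ids, ]
  if (nrow(e)) {
    i <- match(e$from, ids)
    j <- match(e$to, ids)
    m[cbind(i, j)] <- e$weight
    m[cbind(j, i)] <- e$weight
  }
  m
}

#' Restrict a network to a subset of patients
#'
#' Keeps the induced subgraph on `ids`. Used to build train-only networks
#' during feature selection so that held-out patients cannot influence
#' feature scores.
#'
#' @inheritParams psn_matrix
#' @return a `psn`.
#' @export
psn_restrict <- function(net, ids) {
  keep <- net$edges$from %in% ids & net$edges$to %in% ids
  psn(net$edges[keep, ], nodes = intersect(net$nodes, ids), name = net$name)
}

#' Read and write similarity networks as edge lists
#'
#' Networks serialize as tab-delimited `from<TAB>to<TAB>weight` with weights
#' printed at 6 significant digits, one file per feature.
#'
#' @param net a `psn`.
#' @param path file path.
#' @param name feature name for the network read back (defaults to the file
#'   name without extension).
#' @return `write_psn()` returns `path` invisibly; `read_psn()` returns a
#'   `psn`.
#' @export
write_psn <- function(net, path) {
  e <- net$edges
  out <- data.frame(e$from, e$to, signif(e$weight, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_psn
#' @export
read_psn <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  e <- utils::read.delim(path, header = FALSE, as.is = TRUE,
                         col.names = c("from", "to", "weight"))
  psn(e, name = name)
}
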