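#' Smooth binary mutation profiles over a gene interaction network
#'
#' Infers "indirect mutations" by random walk with restart: a patient's direct
#' somatic mutations are propagated over a binary, symmetric gene-gene
#' interaction network onto neighbouring genes, yielding a continuous score
#' per gene in `[0, 1]` that reflects network proximity to the patient's
#' mutations. Each patient's seed vector is the mutation profile normalized to
#' sum 1, and the walk iterates `F <- (1 - restart) * W %*% F + restart * F0`
#' with `W` the column-normalized adjacency; isolated genes keep their own
#' mass via a self-loop, so per-patient score mass is conserved at every
#' iteration.
#'
#' @param geno binary gene-by-patient mutation matrix (entry 1 = somatic
#'   mutation); gene names must all appear in the interaction network.
#'   Patients without any mutation are passed through as all-zero columns with
#'   a warning.
#' @param net binary symmetric gene-by-gene interaction matrix with zero
#'   diagonal.
#' @param restart restart probability in `(0, 1]`; default 0.5.
#' @param tol convergence tolerance on the largest entry change (default 1e-6).
#' @param max_iter iteration cap.
#' @return gene-by-patient matrix of propagation scores over the network's
#'   genes, with attribute `iterations`.
#' @export
smooth_mutations <- function(geno, net, restart = 0.5, tol = 1e-6,
                             max_iter = 1000L) {
  stopifnot(restart > 0, restart <= 1)
  net <- as.matrix(net)
  if (is.null(rownames(net)) || !identical(rownames(net), colnames(net))) {
    abort("interaction network must have matching gene row/column names",
          class = "psn_error")
  }
  if (!isSymmetric(unname(net))) {
    abort("interaction network must be symmetric", class = "psn_error")
  }
  if (!all(net %in% c(0, 1))) {
    abort("interaction network must be binary (0/1)", class = "psn_error")
  }
  if (any(diag(net) != 0)) {
    abort("interaction network must have a zero diagonal", class = "psn_error")
  }
  geno <- as.matrix(geno)
  missing_genes <- setdiff(rownames(geno), rownames(net))
  if (length(missing_genes)) {
    abort(sprintf("%d mutated gene(s) absent from the interaction network (%s)",
                  length(missing_genes), paste(head(missing_genes, 5), collapse = ", ")),
          class = "psn_error")
  }
  genes <- rownames(net)
  deg <- colSums(net)
  W <- sweep(net, 2, pmax(deg, 1), "/")
  iso <- which(deg == 0)
  if (length(iso)) W[cbind(iso, iso)] <- 1  # self-retention for isolated genes
  F0 <- matrix(0, length(genes), ncol(geno),
               dimnames = list(genes, colnames(geno)))
  F0[rownames(geno), ] <- geno
  mass <- colSums(F0)
  if (any(mass == 0)) {
    warn(sprintf("%d patient(s) have no mutations; returned as all-zero columns",
                 sum(mass == 0)))
  }
  F0 <- sweep(F0, 2, pmax(mass, 1), "/")
  Fm <- F0
  it <- 0L
  WS <- Matrix::Matrix(W, sparse = TRUE)
  repeat {
    Fn <- as.matrix((1 - restart) * (WS %*% Fm) + restart * F0)
    it <- it + 1L
    if (max(abs(Fn - Fm)) < tol || it >= max_iter) break
    Fm <- Fn
  }
  dimnames(Fn) <- dimnames(F0)
  attr(Fn, "iterations") <- it
  Fn
}

#' Binarize smoothed mutation scores
#'
#' Ranks each patient's propagation scores and sets the top-ranked fraction of
#' genes to one (default 3%), restricted to genes with a positive score; ties
#' at the cutoff are broken by gene-name order for determinism. The patient's
#' original (direct) mutations are always kept, so the result - the "direct
#' plus inferred" mutation matrix - is never sparser than the input. The
#' binarization confines inferred mutation to genes closest to the observed
#' ones: distant genes receive low propagation values and are thresholded back
#' to zero.
#'
#' @param smoothed gene-by-patient score matrix from [smooth_mutations()].
#' @param original the input binary mutation matrix (genes must be a subset of
#'   the smoothed matrix's genes, patients identical).
#' @param fraction fraction of genes set per patient, in `(0, 1]`; the number
#'   set is `ceiling(fraction * n_genes)` capped at the positive-score count.
#' @return binary gene-by-patient matrix over the smoothed matrix's genes.
#' @export
binarize_smoothed <- function(smoothed, original, fraction = 0.03) {
  if (!(fraction > 0 && fraction <= 1)) {
    abort("fraction must be in (0, 1]", class = "psn_error")
  }
  original <- as.matrix(original)
  if (!all(rownames(original) %in% rownames(smoothed)) ||
      !identical(colnames(original), colnames(smoothed))) {
    abort("original matrix must match smoothed genes (subset) and patients",
          class = "psn_error")
  }
  genes <- rownames(smoothed)
  k <- ceiling(fraction * length(genes))
  out <- matrix(0L, nrow(smoothed), ncol(smoothed), dimnames = dimnames(smoothed))
  for (j in seq_len(ncol(smoothed))) {
    s <- smoothed[, j]
    elig <- which(s > 0)
    if (length(elig)) {
      o <- elig[order(-s[elig], genes[elig])]  # ties at the cutoff: gene-name order
      out[o[seq_len(min(k, length(o)))], j] <- 1L
    }
  }
  idx <- which(original > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    out[cbind(match(rownames(original)[idx[, 1]], genes), idx[, 2])] <- 1L
  }
  out
}

#' Read a binary gene interaction network
#'
#' Reads the tab-delimited square-matrix format (header row and first column
#' both carrying gene names).
#'
#' @param path file path.
#' @return binary symmetric gene-by-gene matrix.
#' @export
read_interaction_network <- function(path) {
  m <- as.matrix(utils::read.delim(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "numeric"
  m
}
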