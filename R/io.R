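#' Read gene sets in GMT format
#'
#' Parses tab-delimited GMT (set name, description, then member genes, one set
#' per line), deduplicates genes within a set, and drops sets whose size after
#' deduplication falls outside `[min_size, max_size]` - the usual pathway-size
#' filter that removes sets too small to form networks and too broad to be
#' interpretable.
#'
#' @param path GMT file path.
#' @param min_size,max_size inclusive size filter (defaults 10 and 200).
#' @return named list of gene character vectors, with attributes
#'   `descriptions` (named character) and `report` (tibble with `read`,
#'   `excluded`, `kept`).
#' @export
read_gmt <- function(path, min_size = 10L, max_size = 200L) {
  stopifnot(min_size <= max_size)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("line %d: GMT records need >= 3 tab-separated fields", i),
            class = "psn_io_error")
    }
    nm <- f[1]
    if (nm %in% names(sets)) {
      abort(sprintf("line %d: duplicate set name '%s'", i, nm),
            class = "psn_io_error")
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    sets[[nm]] <- genes
    desc[nm] <- f[2]
  }
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  out <- sets[keep]
  attr(out, "descriptions") <- desc[keep]
  attr(out, "report") <- tibble(read = length(sets),
                                excluded = sum(!keep), kept = sum(keep))
  out
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @param descriptions optional named descriptions (set name reused when
#'   absent).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- descriptions[nm] %||% nm
    if (is.na(d)) d <- nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic event intervals
#'
#' Reads patient genomic events (e.g. CNV calls) into the internal 1-based,
#' closed coordinate convention. Two dialects are accepted:
#' \describe{
#'   \item{onebased_closed}{tab-delimited with a header; columns `ID`,
#'     `seqnames` (or `chrom`), `start`, `end` and optionally `Gene_symbols`
#'     (comma-separated). Coordinates pass through unchanged.}
#'   \item{bed}{headerless BED4+: chrom, start, end, name (the patient ID),
#'     optional fifth column of comma-separated gene symbols. The 0-based
#'     half-open coordinates are converted (`start + 1`, `end`).}
#' }
#' Rows with `start > end` (after conversion) are rejected with their row
#' number.
#'
#' @param path file path.
#' @param dialect `"onebased_closed"` or `"bed"`.
#' @return tibble with columns `ID`, `chrom`, `start`, `end`, `genes`.
#' @export
read_intervals <- function(path, dialect = c("onebased_closed", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "onebased_closed") {
    d <- utils::read.delim(path, sep = "\t", header = TRUE, as.is = TRUE)
    chrom_col <- intersect(c("seqnames", "chrom"), names(d))[1]
    if (is.na(chrom_col) || !all(c("ID", "start", "end") %in% names(d))) {
      abort("expected header with ID, seqnames/chrom, start, end",
            class = "psn_io_error")
    }
    out <- tibble(ID = as.character(d$ID), chrom = as.character(d[[chrom_col]]),
                  start = d$start, end = d$end,
                  genes = if ("Gene_symbols" %in% names(d))
                    as.character(d$Gene_symbols) else NA_character_)
  } else {
    d <- utils::read.delim(path, sep = "\t", header = FALSE, as.is = TRUE)
    if (ncol(d) < 4) abort("BED dialect needs >= 4 columns (patient ID in column 4)",
                           class = "psn_io_error")
    out <- tibble(ID = as.character(d[[4]]), chrom = as.character(d[[1]]),
                  start = d[[2]] + 1L, end = d[[3]],
                  genes = if (ncol(d) >= 5) as.character(d[[5]]) else NA_character_)
  }
  bad <- which(!is.finite(out$start) | !is.finite(out$end) |
                 out$start > out$end | !nzchar(out$chrom))
  if (length(bad)) {
    abort(sprintf("malformed coordinates in row(s): %s",
                  paste(head(bad, 10), collapse = ", ")), class = "psn_io_error")
  }
  out
}

intervals_to_granges <- function(x, names = NULL) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

#' Map patient intervals to genes and gene sets
#'
#' `events_from_intervals()` returns the patient-gene events implied by
#' interval overlap: an interval hits a gene when they overlap by at least one
#' base on the same chromosome (1-based closed arithmetic, strand ignored).
#' `map_intervals_to_sets()` additionally groups hits by gene set, counting,
#' per patient, the number of their intervals that hit any gene of the set.
#'
#' @param intervals tibble from [read_intervals()] (columns `ID`, `chrom`,
#'   `start`, `end`).
#' @param gene_extents tibble with columns `gene`, `chrom`, `start`, `end`
#'   (one extent per gene).
#' @param sets named list of gene sets; genes without an extent are ignored
#'   with a warning.
#' @return `events_from_intervals()`: tibble `ID`, `gene`;
#'   `map_intervals_to_sets()`: tibble `ID`, `set`, `n_events`.
#' @export
events_from_intervals <- function(intervals, gene_extents) {
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(intervals),
    GenomicRanges::GRanges(gene_extents$chrom,
                           IRanges::IRanges(gene_extents$start, gene_extents$end)),
    minoverlap = 1L
  )
  tibble(
    ID = intervals$ID[S4Vectors::queryHits(hits)],
    gene = gene_extents$gene[S4Vectors::subjectHits(hits)]
  ) |> dplyr::distinct()
}

#' @rdname events_from_intervals
#' @export
map_intervals_to_sets <- function(intervals, gene_extents, sets) {
  uncovered <- setdiff(unique(unlist(sets)), gene_extents$gene)
  if (length(uncovered)) {
    warn(sprintf("%d set gene(s) have no extent and are ignored", length(uncovered)))
  }
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(intervals),
    GenomicRanges::GRanges(gene_extents$chrom,
                           IRanges::IRanges(gene_extents$start, gene_extents$end)),
    minoverlap = 1L
  )
  hit_tbl <- tibble(row = S4Vectors::queryHits(hits),
                    gene = gene_extents$gene[S4Vectors::subjectHits(hits)])
  rows <- lapply(names(sets), function(nm) {
    h <- hit_tbl[hit_tbl$gene %in% sets[[nm]], ]
    if (nrow(h) == 0) return(NULL)
    tibble(ID = intervals$ID[unique(h$row)]) |>
      dplyr::count(.data$ID, name = "n_events") |>
      dplyr::mutate(set = nm)
  })
  out <- dplyr::bind_rows(compact(rows))
  if (nrow(out) == 0) return(tibble(ID = character(), set = character(),
                                    n_events = integer()))
  out[, c("ID", "set", "n_events")]
}

#' Read and write assay matrices and metadata tables
#'
#' Assay matrices are tab-delimited with the first column holding the measure
#' name and remaining columns named by patient ID. Metadata tables are
#' tab-delimited with a header and mandatory `ID` and `STATUS` columns; extra
#' columns are preserved as clinical variables.
#'
#' @param path file path.
#' @param mat numeric matrix to write.
#' @return `read_assay_matrix()`: numeric matrix; `read_metadata()`: tibble.
#' @export
read_assay_matrix <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_assay_matrix
#' @export
write_assay_matrix <- function(mat, path) {
  d <- data.frame(measure = rownames(mat), mat, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_assay_matrix
#' @export
read_metadata <- function(path) {
  d <- as_tibble(utils::read.delim(path, sep = "\t", header = TRUE, as.is = TRUE))
  if (!all(c("ID", "STATUS") %in% names(d))) {
    abort("metadata table must have ID and STATUS columns", class = "psn_io_error")
  }
  d$ID <- as.character(d$ID)
  d
}
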