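#' Assemble a patient dataset
#'
#' Bundles patient metadata with named assay matrices. The metadata table must
#' carry an `ID` column (unique patient identifiers) and a `STATUS` column
#' (class labels). Any additional numeric metadata columns are exposed as the
#' reserved `clinical` assay layer (one row per variable, one column per
#' patient), so clinical variables can be grouped into features like any other
#' layer.
#'
#' Patients may be absent from some assay layers; this is the supported
#' missing-data case and downstream similarity/integration steps simply use
#' the layers in which a patient is present. Every assay column name must be
#' one of the metadata IDs.
#'
#' @param pheno data frame with columns `ID` and `STATUS`; extra numeric
#'   columns become clinical variables.
#' @param assays named list of numeric matrices, measures in rows and patients
#'   in columns (`NA` entries allowed).
#' @return A `patient_dataset`: list with `pheno` (tibble), `assays` (named
#'   list of matrices, including `clinical` when present).
#' @export
#' @examples
#' ph <- data.frame(ID = c("a", "b", "c"), STATUS = c("case", "case", "control"),
#'                  age = c(40, 52, 61))
#' x <- matrix(rnorm(9), 3, 3, dimnames = list(paste0("g", 1:3), ph$ID))
#' ds <- patient_dataset(ph, assays = list(expr = x))
#' names(ds$assays)
patient_dataset <- function(pheno, assays = list()) {
  pheno <- as_tibble(pheno)
  if (!all(c("ID", "STATUS") %in% names(pheno))) {
    abort("metadata must have ID and STATUS columns", class = "psn_validation_error")
  }
  pheno$ID <- as.character(pheno$ID)
  pheno$STATUS <- as.character(pheno$STATUS)
  extra <- setdiff(names(pheno), c("ID", "STATUS"))
  num <- extra[vapply(pheno[extra], is.numeric, logical(1))]
  if (length(num) && !"clinical" %in% names(assays)) {
    cl <- t(as.matrix(pheno[, num, drop = FALSE]))
    colnames(cl) <- pheno$ID
    rownames(cl) <- num
    assays$clinical <- cl
  }
  structure(list(pheno = pheno, assays = assays), class = "patient_dataset")
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf("<patient_dataset> %d patients, %d classes, %d assay layer(s)\n",
              nrow(x$pheno), length(unique(x$pheno$STATUS)), length(x$assays)))
  invisible(x)
}

#' Validate a dataset against grouping rules
#'
#' Checks the ID/STATUS conventions and the name-matching contract between
#' grouping rules and assay layers. Fatal problems are duplicate patient IDs,
#' missing/empty labels, rule layer names that match no assay, and empty
#' feature groups. Measures named in a rule but absent from the layer matrix
#' are a warning only: the feature is built from the measures that are present.
#'
#' @param ds a [patient_dataset()].
#' @param rules grouping rules: named list (one entry per layer) of named
#'   lists of measure-identifier vectors, each inner entry defining one
#'   feature.
#' @param strict if `TRUE` (default) fatal problems raise a
#'   `psn_validation_error`; otherwise they are returned in the report.
#' @return tibble with columns `severity` (`"error"`/`"warning"`), `field`,
#'   `message`; zero rows when all conventions are met.
#' @export
validate_dataset <- function(ds, rules = list(), strict = TRUE) {
  stopifnot(inherits(ds, "patient_dataset"))
  rep <- list()
  add <- function(sev, field, msg) {
    rep[[length(rep) + 1]] <<- tibble(severity = sev, field = field, message = msg)
  }
  ids <- ds$pheno$ID
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add("error", "ID", sprintf("duplicate patient ID: %s", d))
  bad <- ids[is.na(ds$pheno$STATUS) | ds$pheno$STATUS == ""]
  for (b in bad) add("error", "STATUS", sprintf("empty label for patient %s", b))
  if (nrow(ds$pheno) == 0) add("error", "ID", "no patients in dataset")
  for (ly in names(ds$assays)) {
    unk <- setdiff(colnames(ds$assays[[ly]]), ids)
    if (length(unk)) {
      add("error", ly, sprintf("assay columns not in metadata IDs: %s",
                               paste(unk, collapse = ", ")))
    }
  }
  for (ly in names(rules)) {
    if (!ly %in% names(ds$assays)) {
      add("error", "rules", sprintf("rule layer '%s' matches no assay layer", ly))
      next
    }
    grp <- rules[[ly]]
    if (is.null(names(grp)) || anyDuplicated(names(grp))) {
      add("error", "rules", sprintf("feature names in layer '%s' must be unique", ly))
    }
    for (g in names(grp)) {
      if (length(grp[[g]]) == 0) {
        add("error", "rules", sprintf("feature '%s' (layer '%s') has an empty group", g, ly))
        next
      }
      miss <- setdiff(grp[[g]], rownames(ds$assays[[ly]]))
      if (length(miss)) {
        add("warning", "rules",
            sprintf("feature '%s': %d measure(s) absent from layer '%s' (%s); group built from present measures",
                    g, length(miss), ly, paste(head(miss, 5), collapse = ", ")))
      }
    }
  }
  out <- if (length(rep)) dplyr::bind_rows(rep) else
    tibble(severity = character(), field = character(), message = character())
  if (strict && any(out$severity == "error")) {
    abort(paste(out$message[out$severity == "error"], collapse = "; "),
          class = "psn_validation_error")
  }
  out
}

#' Drop duplicate patient records
#'
#' Keeps the first record per `ID`. Duplicate IDs are otherwise a fatal
#' validation error; event tables (one row per genomic event) are not
#' affected by this helper.
#'
#' @param pheno metadata data frame with an `ID` column.
#' @return tibble with one row per patient.
#' @export
dedupe_patients <- function(pheno) {
  pheno <- as_tibble(pheno)
  pheno[!duplicated(pheno$ID), ]
}

# Run expr under a fixed RNG seed without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Stratified train/test split
#'
#' Randomly partitions labelled patients into training and test groups,
#' stratified by class so that each class contributes
#' `round(train_fraction * class size)` training patients (adjusted by at most
#' one to keep both sides of every class non-empty and per-class proportions
#' within one patient of the target).
#'
#' @param ds a [patient_dataset()] or a metadata data frame with `ID`/`STATUS`.
#' @param train_fraction fraction of each class assigned to TRAIN; default 0.8
#'   (an 80:20 split).
#' @param seed integer seed; the same seed always yields the same assignment.
#' @return tibble with columns `ID`, `STATUS`, `TT_STATUS` (`"TRAIN"`/`"TEST"`).
#' @export
split_train_test <- function(ds, train_fraction = 0.8, seed = 42L) {
  pheno <- if (inherits(ds, "patient_dataset")) ds$pheno else as_tibble(ds)
  stopifnot(train_fraction > 0, train_fraction < 1)
  cls <- split(pheno$ID, pheno$STATUS)
  small <- names(cls)[lengths(cls) < 2]
  if (length(small)) {
    abort(sprintf("class(es) with fewer than 2 members: %s",
                  paste(small, collapse = ", ")), class = "psn_error")
  }
  train <- with_seed(seed, {
    unlist(lapply(names(cls), function(cl) {
      idsc <- cls[[cl]]
      k <- round(train_fraction * length(idsc))
      k <- min(max(k, 1L), length(idsc) - 1L)
      sample(idsc, k)
    }), use.names = FALSE)
  })
  tibble(
    ID = pheno$ID, STATUS = pheno$STATUS,
    TT_STATUS = ifelse(pheno$ID %in% train, "TRAIN", "TEST")
  )
}

#' Subsample a class's training patients for one feature-scoring query
#'
#' Feature scoring runs `feat_score_max` integration queries per class, each
#' on a different subsample of that class's training patients. Two schemes are
#' supported:
#' \describe{
#'   \item{holdout}{the ids are shuffled once (with `seed`) and cut into
#'     `feat_score_max` nearly equal contiguous blocks; query `iteration`
#'     omits the `iteration`-th block, so each query uses roughly
#'     `1 - 1/feat_score_max` of the class. With `feat_score_max = 1` the
#'     single query is the full class.}
#'   \item{montecarlo}{each query draws `mc_fraction` of the class without
#'     replacement, allowing feature scores with a higher ceiling than the
#'     class size supports under block holdout.}
#' }
#'
#' @param ids training patient ids of one class.
#' @param scheme `"holdout"` or `"montecarlo"`.
#' @param feat_score_max number of queries (maximum feature score).
#' @param iteration which query, in `1:feat_score_max`.
#' @param seed integer seed shared by all iterations of one split.
#' @param mc_fraction Monte Carlo sampling fraction (default 0.8).
#' @return character vector of query ids.
#' @export
resample_training <- function(ids, scheme = c("holdout", "montecarlo"),
                              feat_score_max, iteration, seed = 42L,
                              mc_fraction = 0.8) {
  scheme <- match.arg(scheme)
  if (length(ids) == 0) abort("empty class: no training ids to subsample",
                              class = "psn_error")
  stopifnot(feat_score_max >= 1, iteration >= 1, iteration <= feat_score_max)
  if (scheme == "holdout") {
    if (feat_score_max == 1) return(ids)
    shuffled <- with_seed(seed, sample(ids))
    block <- sort(rep_len(seq_len(feat_score_max), length(ids)))
    shuffled[block != iteration]
  } else {
    k <- max(1L, round(mc_fraction * length(ids)))
    with_seed(seed, {
      q <- NULL
      for (i in seq_len(iteration)) q <- sample(ids, k)
      q
    })
  }
}
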