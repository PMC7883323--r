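#' Simulate a multi-layer patient dataset with planted class structure
#'
#' Generates a two-or-more-class cohort with one continuous assay layer whose
#' measures are grouped into features, a designated number of which are
#' discriminative. Noise measures are standard normal. Each discriminative
#' group carries a class-specific measure pattern: class `k` patients receive
#' `effect_size` times a pattern vector drawn once per class on top of unit
#' noise, so patients of the same class have correlated profiles over the
#' group while patients of different classes do not. This is exactly the
#' structure the Pearson-profile similarity is designed to detect; with
#' `effect_size = 0` the dataset is pure noise and the downstream pipeline
#' should perform at chance.
#'
#' @param n_patients cohort size.
#' @param class_labels class names (default case/control).
#' @param class_proportions class mixing proportions (default equal).
#' @param n_features number of feature groups in the continuous layer.
#' @param group_size measures per group.
#' @param n_discriminative number of groups with planted class structure.
#' @param effect_size pattern amplitude relative to unit noise (2 = strong).
#' @param missing_rate fraction of assay entries masked to `NA` at random.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list with `dataset` (a [patient_dataset()]), `rules`, `metrics`
#'   (ready for [build_feature_networks()]) and `truth` (tibble naming the
#'   planted features).
#' @export
simulate_patient_data <- function(n_patients = 200L,
                                  class_labels = c("case", "control"),
                                  class_proportions = NULL,
                                  n_features = 20L, group_size = 10L,
                                  n_discriminative = 1L, effect_size = 2,
                                  missing_rate = 0, seed = 42L) {
  stopifnot(n_patients > 0, n_features >= 1, group_size >= 2,
            n_discriminative >= 0, n_discriminative <= n_features,
            missing_rate >= 0, missing_rate < 1)
  k <- length(class_labels)
  if (is.null(class_proportions)) class_proportions <- rep(1 / k, k)
  stopifnot(length(class_proportions) == k)
  with_seed(seed, {
    counts <- round(class_proportions / sum(class_proportions) * n_patients)
    counts[1] <- n_patients - sum(counts[-1])
    status <- rep(class_labels, counts)
    ids <- sprintf("P%03d", seq_len(n_patients))
    n_meas <- n_features * group_size
    x <- matrix(rnorm(n_meas * n_patients), n_meas, n_patients,
                dimnames = list(sprintf("g%04d", seq_len(n_meas)), ids))
    groups <- split(rownames(x), rep(seq_len(n_features), each = group_size))
    names(groups) <- sprintf("FEATURE_%02d", seq_len(n_features))
    disc <- names(groups)[seq_len(n_discriminative)]
    for (f in disc) {
      rows <- groups[[f]]
      patterns <- matrix(rnorm(group_size * k), group_size, k)
      for (ci in seq_len(k)) {
        cols <- which(status == class_labels[ci])
        x[rows, cols] <- x[rows, cols] + effect_size * patterns[, ci]
      }
    }
    if (missing_rate > 0) {
      mask <- runif(length(x)) < missing_rate
      x[mask] <- NA
    }
    ds <- patient_dataset(tibble(ID = ids, STATUS = status),
                          assays = list(expr = x))
    list(
      dataset = ds,
      rules = list(expr = groups),
      metrics = list(expr = "pearson"),
      truth = tibble(feature = names(groups), layer = "expr",
                     discriminative = names(groups) %in% disc)
    )
  })
}

#' Simulate sparse genetic events with case-enriched pathways
#'
#' Generates a case/control cohort with per-patient gene-level events placed
#' in disjoint synthetic pathways. In the designated enriched pathways, cases
#' carry an event at `case_rate` and controls at `control_rate`; in all other
#' pathways both classes carry events at `background_rate`. Each event hits
#' one random gene of its pathway. This emulates the rare-variant setting
#' (e.g. CNV burden converging on pathways) that the binary-similarity
#' workflow and label enrichment were designed for.
#'
#' @param n_patients cohort size.
#' @param case_fraction fraction of cases.
#' @param n_pathways number of synthetic pathways.
#' @param genes_per_pathway genes per pathway (disjoint across pathways).
#' @param n_enriched number of case-enriched pathways.
#' @param case_rate,control_rate event probability in enriched pathways for
#'   cases and controls.
#' @param background_rate event probability in non-enriched pathways.
#' @param seed integer seed.
#' @return list with `pheno` (tibble `ID`, `STATUS`), `events` (tibble `ID`,
#'   `gene`), `sets` (named list of pathway genes) and `truth` (tibble naming
#'   enriched pathways).
#' @export
simulate_sparse_events <- function(n_patients = 300L, case_fraction = 0.5,
                                   n_pathways = 20L, genes_per_pathway = 10L,
                                   n_enriched = 2L, case_rate = 0.4,
                                   control_rate = 0.05, background_rate = 0.05,
                                   seed = 42L) {
  stopifnot(n_enriched <= n_pathways)
  with_seed(seed, {
    n_case <- round(case_fraction * n_patients)
    ids <- sprintf("S%03d", seq_len(n_patients))
    status <- c(rep("case", n_case), rep("control", n_patients - n_case))
    sets <- lapply(seq_len(n_pathways), function(p) {
      sprintf("PW%02d_G%02d", p, seq_len(genes_per_pathway))
    })
    names(sets) <- sprintf("PATHWAY_%02d", seq_len(n_pathways))
    enriched <- names(sets)[seq_len(n_enriched)]
    rows <- list()
    for (p in names(sets)) {
      rate <- if (p %in% enriched) {
        ifelse(status == "case", case_rate, control_rate)
      } else rep(background_rate, n_patients)
      hit <- runif(n_patients) < rate
      if (any(hit)) {
        rows[[p]] <- tibble(ID = ids[hit],
                            gene = sample(sets[[p]], sum(hit), replace = TRUE))
      }
    }
    list(
      pheno = tibble(ID = ids, STATUS = status),
      events = dplyr::bind_rows(rows),
      sets = sets,
      truth = tibble(pathway = names(sets), enriched = names(sets) %in% enriched)
    )
  })
}
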