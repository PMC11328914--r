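#' Per-core composition profile
#'
#' Counts, proportions (count / total cells), densities (count / tissue
#' area, cells per mm^2), per-channel mean intensities (over all cells,
#' with per-type means retained), and the coverage-adjusted Shannon
#' entropy of the phenotype counts.
#'
#' @param cells cells data.frame for one core (phenotypes assigned).
#' @param tissue_area core tissue area in mm^2.
#' @param phenotypes label universe; defaults to the labels present.
#' @param channels intensity columns to average; defaults to all numeric
#'   marker columns present.
#' @return list of class `composition_profile`: `counts`, `proportion`,
#'   `density`, `mean_intensity`, `mean_intensity_by_type`, `entropy`,
#'   `n_cells`, `tissue_area`, `empty` flag.
#' @export
compute_composition <- function(cells, tissue_area,
                                phenotypes = NULL, channels = NULL) {
  stopifnot(tissue_area > 0)
  if (is.null(phenotypes))
    phenotypes <- sort(unique(cells$phenotype))
  n <- nrow(cells)
  if (n == 0L) {
    return(structure(list(counts = integer(), proportion = numeric(),
                          density = numeric(), mean_intensity = numeric(),
                          mean_intensity_by_type = NULL,
                          entropy = NA_real_, n_cells = 0L,
                          tissue_area = tissue_area, empty = TRUE),
                     class = "composition_profile"))
  }
  counts <- table(factor(cells$phenotype, levels = phenotypes))
  counts <- stats::setNames(as.integer(counts), phenotypes)
  proportion <- counts / n
  density <- counts / tissue_area
  if (is.null(channels)) {
    skip <- c("x", "y")
    channels <- names(cells)[vapply(cells, is.numeric, logical(1))]
    channels <- setdiff(channels, skip)
  }
  mean_int <- vapply(channels, function(ch)
    mean(cells[[ch]], na.rm = TRUE), numeric(1))
  by_type <- NULL
  if (length(channels)) {
    by_type <- do.call(rbind, lapply(phenotypes, function(t) {
      sel <- cells$phenotype == t
      vapply(channels, function(ch)
        if (any(sel)) mean(cells[[ch]][sel], na.rm = TRUE) else NA_real_,
        numeric(1))
    }))
    rownames(by_type) <- phenotypes
  }
  structure(list(counts = counts, proportion = proportion, density = density,
                 mean_intensity = mean_int,
                 mean_intensity_by_type = by_type,
                 entropy = chao_shen_entropy(counts),
                 n_cells = n, tissue_area = tissue_area, empty = FALSE),
            class = "composition_profile")
}

#' Chao-Shen coverage-adjusted Shannon entropy
#'
#' Entropy of a multinomial sample corrected for unseen categories: with
#' total count n and f1 singleton categories, the estimated sample
#' coverage is C = 1 - f1/n; category probabilities are shrunk to
#' p~ = C p and each term is inflated by the Horvitz-Thompson inclusion
#' probability, giving H = -sum p~ log(p~) / (1 - (1 - p~)^n). Natural
#' logarithm. Reduces to (slightly above) the plug-in entropy when no
#' category is a singleton; a single observed category gives exactly 0.
#'
#' @param counts nonnegative integer counts per category.
#' @return entropy in nats (`NaN`, with a warning, in the degenerate
#'   all-singletons case where estimated coverage is zero).
#' @export
chao_shen_entropy <- function(counts) {
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) stop("counts must be nonnegative")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) stop("all-zero counts: entropy undefined")
  f1 <- sum(counts == 1)
  C <- 1 - f1 / n
  if (C == 0) {
    warning("all categories are singletons; coverage 0, entropy undefined")
    return(NaN)
  }
  p <- counts / n
  pa <- C * p
  sum(-pa * log(pa) / (1 - (1 - pa)^n))
}

#' Aggregate core profiles to the patient level
#'
#' Unweighted means across a patient's cores of proportions, densities,
#' mean intensities and entropy. Entropy is reported only for patients
#' with at least two cores (`entropy = NA` otherwise, with
#' `entropy_evaluable = FALSE`). Densities are additionally stored as
#' log1p-transformed copies (`log_density`), the transform applied before
#' any statistical testing downstream.
#'
#' @param profiles list of `composition_profile` for one patient's cores.
#' @return list of class `patient_profile`.
#' @export
aggregate_patient <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  profiles <- Filter(function(p) !isTRUE(p$empty), profiles)
  if (!length(profiles)) stop("no non-empty cores for patient")
  avg <- function(field) {
    m <- do.call(rbind, lapply(profiles, function(p) p[[field]]))
    colMeans(m)
  }
  ent <- vapply(profiles, function(p) p$entropy, numeric(1))
  evaluable <- length(profiles) >= 2L
  structure(list(
    n_cores = length(profiles),
    proportion = avg("proportion"),
    density = avg("density"),
    log_density = log1p(avg("density")),
    mean_intensity = avg("mean_intensity"),
    entropy = if (evaluable) mean(ent, na.rm = TRUE) else NA_real_,
    entropy_evaluable = evaluable),
    class = "patient_profile")
}

#' Split patients into heterogeneity groups by entropy quantiles
#'
#' Patients strictly above the 0.6 empirical quantile of entropy are
#' "high", strictly below the 0.4 quantile "low", the rest "middle"
#' (excluded from two-group survival comparison). Type-7 quantiles.
#'
#' @param patient_entropy named numeric, patient -> mean entropy.
#' @param lo,hi quantile cut points (default 0.4 / 0.6).
#' @return named character vector of labels in `{high, low, middle}`.
#' @export
heterogeneity_groups <- function(patient_entropy, lo = 0.4, hi = 0.6) {
  quantile_groups(patient_entropy, lo = lo, hi = hi,
                  labels = c("low", "middle", "high"))
}

#' Within- vs between-patient core correlation
#'
#' Pearson correlation of per-core cell-type density vectors for every
#' pair of cores, partitioned into pairs from the same patient and pairs
#' from different patients; reports the two means and a two-sided
#' Wilcoxon rank-sum test between the two sets of coefficients. Cores
#' whose density vector has zero variance are skipped.
#'
#' @param density_by_core matrix, cores x phenotypes, of densities.
#' @param patient_of named map core -> patient (character vector aligned
#'   with `rownames(density_by_core)`).
#' @return list: `mean_within`, `mean_between`, `p_value`, `n_within`,
#'   `n_between`.
#' @export
core_correlation_summary <- function(density_by_core, patient_of) {
  stopifnot(nrow(density_by_core) >= 2L)
  keep <- apply(density_by_core, 1, stats::sd) > 0
  if (any(!keep)) {
    message(sum(!keep), " zero-variance cores skipped")
    density_by_core <- density_by_core[keep, , drop = FALSE]
    patient_of <- patient_of[keep]
  }
  cm <- stats::cor(t(density_by_core))
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[idx]
  same <- patient_of[idx[, 1]] == patient_of[idx[, 2]]
  if (!any(same) || all(same))
    stop("need both within- and between-patient core pairs")
  test <- stats::wilcox.test(r[same], r[!same], exact = FALSE)
  list(mean_within = mean(r[same]), mean_between = mean(r[!same]),
       p_value = test$p.value,
       n_within = sum(same), n_between = sum(!same))
}

#' Per-core composition table for a cohort
#'
#' Convenience wrapper: computes one `composition_profile` per core (one
#' panel at a time) and returns proportions/densities as matrices.
#'
#' @param cohort an `mif_cohort`.
#' @param panel_id which panel's cells to profile.
#' @param phenotypes label universe (defaults to that panel's labels).
#' @return list: `profiles` (named list per core), `proportion`, `density`
#'   (matrices cores x phenotypes), `entropy` (named vector).
#' @export
cohort_composition <- function(cohort, panel_id = "panel1",
                               phenotypes = NULL) {
  panel <- cohort$panels[[panel_id]]
  if (is.null(phenotypes)) phenotypes <- panel_labels(panel)
  cells <- cohort$cells[cohort$cells$panel_id == panel_id, , drop = FALSE]
  ids <- cohort$cores$core_id
  profs <- lapply(ids, function(i) {
    compute_composition(cells[cells$core_id == i, , drop = FALSE],
                        cohort$cores$tissue_area[cohort$cores$core_id == i],
                        phenotypes = phenotypes)
  })
  names(profs) <- ids
  nonempty <- !vapply(profs, function(p) isTRUE(p$empty), logical(1))
  prop <- do.call(rbind, lapply(profs[nonempty], `[[`, "proportion"))
  dens <- do.call(rbind, lapply(profs[nonempty], `[[`, "density"))
  ent <- vapply(profs[nonempty], `[[`, numeric(1), "entropy")
  list(profiles = profs, proportion = prop, density = dens, entropy = ent)
}
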