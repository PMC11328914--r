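#' Radius neighbor composition vectors
#'
#' For each index cell, the composition of phenotypes among cells within a
#' fixed Euclidean radius of it, the index cell included in its own
#' neighborhood (so an isolated cell's vector is the indicator of its own
#' type). Vectors lie on the simplex (counts divided by neighborhood
#' size); set `mode = "counts"` for raw counts.
#'
#' @param cells cells data.frame for one core with `x`, `y`, `phenotype`.
#' @param radius neighborhood radius in micrometres (the analyses here use
#'   40, 50 and 60 um).
#' @param phenotypes label universe (columns of the result).
#' @param mode `"frequency"` (default) or `"counts"`.
#' @return numeric matrix, cells x phenotypes; rows sum to 1 in
#'   frequency mode.
#' @export
neighbor_vectors <- function(cells, radius, phenotypes = NULL,
                             mode = c("frequency", "counts")) {
  mode <- match.arg(mode)
  if (is.null(phenotypes)) phenotypes <- sort(unique(cells$phenotype))
  n <- nrow(cells)
  ph <- factor(cells$phenotype, levels = phenotypes)
  xy <- cbind(cells$x, cells$y)
  out <- matrix(0, n, length(phenotypes),
                dimnames = list(cells$cell_id, phenotypes))
  k <- min(n, 64L)
  repeat {
    nn <- RANN::nn2(xy, xy, k = k, searchtype = "radius", radius = radius)
    saturated <- nn$nn.idx[, k] != 0
    if (!any(saturated) || k == n) break
    k <- min(n, 2L * k)
  }
  code <- as.integer(ph)
  for (i in seq_len(n)) {
    nb <- nn$nn.idx[i, ]
    nb <- nb[nb != 0L]
    tab <- tabulate(code[nb], nbins = length(phenotypes))
    out[i, ] <- tab
  }
  if (mode == "frequency") out <- out / rowSums(out)
  out
}

#' Fit a cellular-neighborhood (CN) model
#'
#' K-means clustering of pooled radius neighbor vectors; every cell is
#' assigned the CN of its nearest centroid. The fit is deterministic given
#' the seed (multiple random starts, best inertia kept).
#'
#' @param vectors matrix of neighbor vectors pooled across cores (rows =
#'   cells), as from [neighbor_vectors()].
#' @param K number of neighborhoods (the mesothelioma analysis uses 6,
#'   chosen by elbow; see [cn_elbow_scan()]).
#' @param seed RNG seed for the k-means starts (default 0).
#' @param radius the radius the vectors were built with (recorded).
#' @param nstart,iter.max passed to [stats::kmeans()].
#' @return object of class `cn_model`: `radius`, `K`, `centroids`,
#'   `cell_cn` (integer labels named by row), `inertia` (total
#'   within-cluster sum of squares), `size`.
#' @export
fit_cn_model <- function(vectors, K, seed = 0, radius = NA_real_,
                         nstart = 10L, iter.max = 100L) {
  stopifnot(is.matrix(vectors))
  if (K > nrow(vectors)) stop("K exceeds the number of vectors")
  set.seed(seed)
  km <- stats::kmeans(vectors, centers = K, nstart = nstart,
                      iter.max = iter.max)
  structure(list(radius = radius, K = K, seed = seed,
                 centroids = km$centers,
                 cell_cn = stats::setNames(km$cluster, rownames(vectors)),
                 inertia = km$tot.withinss, size = km$size),
            class = "cn_model")
}

#' @export
print.cn_model <- function(x, ...) {
  cat("<cn_model> K =", x$K, " radius =", x$radius, "um, ",
      length(x$cell_cn), "cells, inertia", signif(x$inertia, 4), "\n")
  invisible(x)
}

#' Elbow diagnostic for the number of neighborhoods
#'
#' Inertia (total within-cluster sum of squares) over a range of K, with a
#' maximum-curvature (kneedle-style) suggestion from the normalized
#' inertia curve. The suggestion is advisory; K remains user-set.
#'
#' @param vectors neighbor-vector matrix.
#' @param K_range candidate K values (default 2:10).
#' @param seed RNG seed.
#' @return data.frame `K`, `inertia`; attribute `suggested_K`.
#' @export
cn_elbow_scan <- function(vectors, K_range = 2:10, seed = 0) {
  inertia <- vapply(K_range, function(k)
    fit_cn_model(vectors, k, seed = seed)$inertia, numeric(1))
  out <- data.frame(K = K_range, inertia = inertia)
  if (length(K_range) >= 3L) {
    xs <- (K_range - min(K_range)) / diff(range(K_range))
    ys <- (inertia - min(inertia)) / diff(range(inertia))
    # kneedle: farthest point below the chord from first to last
    chord <- ys[1] + (ys[length(ys)] - ys[1]) * xs
    attr(out, "suggested_K") <- K_range[which.max(chord - ys)]
  }
  out
}

#' CN enrichment matrix (log odds ratios)
#'
#' Enrichment of each phenotype in each neighborhood: the log odds ratio
#' of the cluster centroid frequency against the global frequency of that
#' phenotype, `log(odds(c_kt) / odds(g_t))` with `odds(p) = p/(1-p)`.
#' Centroid or global frequencies of exactly 0 or 1 are smoothed with half
#' a pseudo-count before the odds. Values are brought to the [-5, 5]
#' display range either by symmetric clipping (default: values beyond
#' +/-5 saturate, everything else untouched) or by linear rescaling of
#' the largest magnitude onto 5 (`mode = "rescale"`); both are monotone
#' and sign-preserving.
#'
#' @param model a `cn_model`.
#' @param global_freq named global phenotype frequencies (defaults to the
#'   size-weighted mean of the centroids, i.e. the pooled training
#'   frequencies).
#' @param mode `"clip"` (default) or `"rescale"`.
#' @param bound range bound (default 5).
#' @return list: `raw` and `normalized` K x T matrices.
#' @export
cn_enrichment <- function(model, global_freq = NULL,
                          mode = c("clip", "rescale"), bound = 5) {
  mode <- match.arg(mode)
  cen <- model$centroids
  if (is.null(global_freq))
    global_freq <- colSums(cen * model$size) / sum(model$size)
  global_freq <- global_freq[colnames(cen)]
  smooth <- function(p, n) {
    eps <- 0.5 / (n + 1)
    pmin(pmax(p, eps), 1 - eps)
  }
  odds <- function(p) p / (1 - p)
  raw <- cen
  for (k in seq_len(nrow(cen))) {
    pc <- smooth(cen[k, ], model$size[k])
    pg <- smooth(global_freq, sum(model$size))
    raw[k, ] <- log(odds(pc) / odds(pg))
  }
  norm <- raw
  if (mode == "clip") {
    norm <- pmin(pmax(raw, -bound), bound)
  } else {
    m <- max(abs(raw))
    if (m > 0) norm <- raw / m * bound
  }
  list(raw = raw, normalized = norm)
}

#' Per-sample CN prevalence and group medians
#'
#' Fraction of each sample's cells assigned to each CN (fractions per
#' sample sum to 1), with the per-group median across samples.
#'
#' @param model a `cn_model`.
#' @param sample_of named map cell id -> sample (core or patient id),
#'   aligned with `names(model$cell_cn)`.
#' @param grouping optional named map sample -> group; when given, group
#'   medians are reported.
#' @return list: `prevalence` (samples x K matrix), `group_median`
#'   (groups x K, or NULL).
#' @export
cn_prevalence <- function(model, sample_of, grouping = NULL) {
  sample_of <- sample_of[names(model$cell_cn)]
  tab <- table(sample_of, factor(model$cell_cn, levels = seq_len(model$K)))
  prev <- prop.table(as.matrix(tab), margin = 1)
  colnames(prev) <- paste0("CN", seq_len(model$K))
  gm <- NULL
  if (!is.null(grouping)) {
    g <- grouping[rownames(prev)]
    gm <- do.call(rbind, lapply(unique(stats::na.omit(g)), function(lev)
      apply(prev[which(g == lev), , drop = FALSE], 2, stats::median)))
    rownames(gm) <- unique(stats::na.omit(g))
  }
  list(prevalence = prev, group_median = gm)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions of the same items; 1 for
#' identical partitions (up to label renaming), about 0 for independent
#' ones. Used by the radius-robustness harness and the planted-region
#' recovery checks.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (maxi - expected)
}

#' Radius-robustness of CN labelings
#'
#' Fits a CN model at each radius on the same core and reports the ARI
#' between labelings at adjacent radii — the check behind the claim that
#' neighborhood structure is consistent across 40/50/60 um.
#'
#' @param cells one core's cells (phenotypes assigned).
#' @param radii radii to compare (default c(40, 50, 60)).
#' @param K number of neighborhoods.
#' @param seed RNG seed.
#' @param phenotypes label universe.
#' @return data.frame `radius_a`, `radius_b`, `ari`.
#' @export
cn_radius_robustness <- function(cells, radii = c(40, 50, 60), K, seed = 0,
                                 phenotypes = NULL) {
  labelings <- lapply(radii, function(r) {
    v <- neighbor_vectors(cells, r, phenotypes = phenotypes)
    fit_cn_model(v, K, seed = seed, radius = r)$cell_cn
  })
  out <- data.frame()
  for (i in seq_len(length(radii) - 1L)) {
    out <- rbind(out, data.frame(
      radius_a = radii[i], radius_b = radii[i + 1L],
      ari = adjusted_rand_index(labelings[[i]], labelings[[i + 1L]])))
  }
  out
}
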