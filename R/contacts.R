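#' Delaunay triangulation edges
#'
#' Undirected first-tier neighbor edges of the Delaunay triangulation of
#' the cell centroids. Exact duplicate coordinates are jittered by 0.01 um
#' (deterministically, fixed internal seed) before triangulation, since
#' the triangulation is undefined on coincident points.
#'
#' @param x,y coordinates in micrometres.
#' @param max_edge_length optional pruning threshold in um; edges longer
#'   than this are dropped (off by default: the contact construction uses
#'   the full first tier).
#' @return two-column integer matrix of vertex indices (`i < j`), one row
#'   per undirected edge.
#' @export
delaunay_edges <- function(x, y, max_edge_length = Inf) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3L) stop("degenerate geometry: need at least 3 points")
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    old <- .Random.seed_save()
    set.seed(20240601L)
    x[dup] <- x[dup] + stats::runif(sum(dup), -0.01, 0.01)
    y[dup] <- y[dup] + stats::runif(sum(dup), -0.01, 0.01)
    .Random.seed_restore(old)
  }
  # collinearity check: triangulation undefined on a line
  cross <- abs((x[2] - x[1]) * (y - y[1]) - (y[2] - y[1]) * (x - x[1]))
  if (max(cross) < 1e-9 * max(diff(range(x)), diff(range(y)), 1))
    stop("degenerate geometry: all points collinear")
  tri <- deldir::deldir(x, y, suppressMsge = TRUE)
  e <- cbind(pmin(tri$delsgs$ind1, tri$delsgs$ind2),
             pmax(tri$delsgs$ind1, tri$delsgs$ind2))
  e <- unique(e)
  if (is.finite(max_edge_length)) {
    len <- sqrt((x[e[, 1]] - x[e[, 2]])^2 + (y[e[, 1]] - y[e[, 2]])^2)
    e <- e[len <= max_edge_length, , drop = FALSE]
  }
  colnames(e) <- c("i", "j")
  e
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Cell-cell contact score matrix for one core
#'
#' Builds the Delaunay graph on the core's cells and scores each phenotype
#' pair (A, B) by the log odds of observed first-tier adjacency against
#' the frequency expected by chance. Adjacency is counted over ordered
#' pairs (each undirected edge contributes to both directions, and a
#' same-type edge contributes twice to its diagonal entry), so the total
#' ordered count is twice the edge count and the chance expectation is
#' exactly p_A p_B, the product of the type proportions; the score is then
#' mean-zero under complete spatial randomness. The observed frequency is
#' the mean of a Beta(alpha, total - alpha) posterior; with Jeffreys-style
#' smoothing (alpha + 1/2)/(total + 1) zero-adjacency pairs get a finite
#' score.
#'
#' @param cells cells data.frame for one core with `x`, `y`, `phenotype`.
#' @param phenotypes label universe of the matrix (default: labels
#'   present in the core).
#' @param smoothing `TRUE` (default) for the smoothed observed frequency;
#'   `FALSE` gives the raw alpha/total ratio (log 0 for absent contacts).
#' @param max_edge_length optional Delaunay edge pruning, passed through.
#' @return object of class `contact_matrix`: `labels`, `alpha` (ordered
#'   adjacency counts, symmetric), `total_connections`, `proportion`
#'   (type proportions), `raw_score` (symmetric matrix; `NA` where either
#'   type is absent from the core), `n_cells`, `n_edges`.
#' @export
contact_score_matrix <- function(cells, phenotypes = NULL, smoothing = TRUE,
                                 max_edge_length = Inf) {
  stopifnot(all(c("x", "y", "phenotype") %in% names(cells)))
  if (is.null(phenotypes)) phenotypes <- sort(unique(cells$phenotype))
  ph <- factor(cells$phenotype, levels = phenotypes)
  e <- delaunay_edges(cells$x, cells$y, max_edge_length = max_edge_length)
  t1 <- ph[e[, 1]]; t2 <- ph[e[, 2]]
  T <- length(phenotypes)
  tab <- matrix(as.numeric(table(t1, t2)), T, T)
  alpha <- tab + t(tab)  # ordered counting: each edge feeds both directions
  dimnames(alpha) <- list(phenotypes, phenotypes)
  total <- 2L * nrow(e)
  p <- as.numeric(table(ph)) / length(ph)
  names(p) <- phenotypes
  present <- p > 0
  obs <- if (smoothing) (alpha + 0.5) / (total + 1) else alpha / total
  theo <- outer(p, p)
  raw <- log(obs / theo)
  raw[!present, ] <- NA
  raw[, !present] <- NA
  structure(list(labels = phenotypes, alpha = alpha,
                 total_connections = total, proportion = p,
                 raw_score = raw, n_cells = nrow(cells), n_edges = nrow(e)),
            class = "contact_matrix")
}

#' Min-max normalize contact scores within a core
#'
#' Rescales the defined raw scores of one contact matrix linearly to
#' [0, 1] across all phenotype pairs of that core. A core whose defined
#' scores are all equal (including the single-pair case) maps to 0.5 by
#' convention. With `scope = "cohort"` the min and max are taken across
#' all supplied cores instead.
#'
#' @param matrices one `contact_matrix` or a list of them.
#' @param scope `"core"` (default) or `"cohort"`.
#' @return the input with a `norm_score` matrix added (same shape as
#'   `raw_score`).
#' @export
minmax_normalize <- function(matrices, scope = c("core", "cohort")) {
  scope <- match.arg(scope)
  single <- inherits(matrices, "contact_matrix")
  if (single) matrices <- list(matrices)
  rescale <- function(m, lo, hi) {
    out <- m
    if (!is.finite(lo) || !is.finite(hi) || hi == lo) out[!is.na(out)] <- 0.5
    else out <- (m - lo) / (hi - lo)
    out
  }
  if (scope == "cohort") {
    allv <- unlist(lapply(matrices, function(cm) cm$raw_score))
    lo <- suppressWarnings(min(allv, na.rm = TRUE))
    hi <- suppressWarnings(max(allv, na.rm = TRUE))
    matrices <- lapply(matrices, function(cm) {
      cm$norm_score <- rescale(cm$raw_score, lo, hi); cm })
  } else {
    matrices <- lapply(matrices, function(cm) {
      v <- cm$raw_score[!is.na(cm$raw_score)]
      lo <- suppressWarnings(min(v)); hi <- suppressWarnings(max(v))
      cm$norm_score <- rescale(cm$raw_score, lo, hi); cm })
  }
  if (single) matrices[[1]] else matrices
}

#' Mean nearest-neighbor distances between phenotype pairs
#'
#' For every cell of the from-type, the Euclidean distance to its nearest
#' cell of the to-type (excluding the cell itself for same-type queries),
#' averaged per ordered pair. Uses a kd-tree.
#'
#' @param cells cells data.frame for one core with `x`, `y`, `phenotype`.
#' @param phenotypes label universe (default: labels present).
#' @return matrix from-type x to-type of mean distances (um); `NA` where
#'   a query is undefined (to-type absent, or a lone cell of its own
#'   type).
#' @export
nn_distances <- function(cells, phenotypes = NULL) {
  if (is.null(phenotypes)) phenotypes <- sort(unique(cells$phenotype))
  T <- length(phenotypes)
  out <- matrix(NA_real_, T, T, dimnames = list(phenotypes, phenotypes))
  xy <- cbind(cells$x, cells$y)
  idx <- split(seq_len(nrow(cells)),
               factor(cells$phenotype, levels = phenotypes))
  for (a in phenotypes) for (b in phenotypes) {
    ia <- idx[[a]]; ib <- idx[[b]]
    if (!length(ia) || !length(ib)) next
    if (a == b) {
      if (length(ia) < 2L) next
      nn <- FNN::get.knn(xy[ia, , drop = FALSE], k = 1)
      out[a, b] <- mean(nn$nn.dist[, 1])
    } else {
      nn <- FNN::get.knnx(xy[ib, , drop = FALSE], xy[ia, , drop = FALSE],
                          k = 1)
      out[a, b] <- mean(nn$nn.dist[, 1])
    }
  }
  out
}

#' Compare contact scores between two groups of cores
#'
#' One-sided Mann-Whitney U test per phenotype pair on per-core
#' normalized contact scores, with Benjamini-Hochberg adjustment across
#' pairs. Pairs defined in fewer than `min_per_group` cores of either
#' group are skipped (and listed).
#'
#' @param matrices named list of `contact_matrix` with `norm_score` (see
#'   [minmax_normalize()]); names are core ids.
#' @param grouping named character/factor, core id -> group (two levels).
#' @param direction `"greater"` tests group1 > group2 (first factor
#'   level), `"less"` the reverse, `"two.sided"` available.
#' @param fdr_threshold significance cut on the adjusted q value
#'   (default 0.15; 0.1 is the stricter figure-level choice).
#' @param min_per_group minimum cores per group with the pair defined.
#' @return data.frame: type_a, type_b, n1, n2, statistic, p, q,
#'   significant; attribute `skipped` lists pairs not testable.
#' @export
contact_group_test <- function(matrices, grouping,
                               direction = c("greater", "less", "two.sided"),
                               fdr_threshold = 0.15, min_per_group = 2L) {
  direction <- match.arg(direction)
  grouping <- grouping[names(matrices)]
  lev <- unique(stats::na.omit(as.character(grouping)))
  if (length(lev) != 2L) stop("grouping must have exactly two levels")
  labels <- matrices[[1]]$labels
  pairs <- which(upper.tri(matrix(0, length(labels), length(labels)),
                           diag = TRUE), arr.ind = TRUE)
  rows <- list(); skipped <- character()
  for (r in seq_len(nrow(pairs))) {
    a <- labels[pairs[r, 1]]; b <- labels[pairs[r, 2]]
    v <- vapply(matrices, function(cm) cm$norm_score[a, b], numeric(1))
    g1 <- v[grouping == lev[1]]; g2 <- v[grouping == lev[2]]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    if (length(g1) < min_per_group || length(g2) < min_per_group) {
      skipped <- c(skipped, paste(a, b, sep = "~"))
      next
    }
    wt <- stats::wilcox.test(g1, g2, alternative = direction, exact = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      type_a = a, type_b = b, n1 = length(g1), n2 = length(g2),
      statistic = unname(wt$statistic), p = wt$p.value,
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message(length(skipped), " pair(s) skipped: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable phenotype pairs")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr_threshold
  attr(out, "skipped") <- skipped
  attr(out, "groups") <- lev
  out
}
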