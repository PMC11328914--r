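# Independent oracles, kept deliberately naive: these re-derive expected
# values by brute force or literal formula transcription, and must not
# share code with the implementation they check.

# Delaunay edge oracle: (i, j) is a Delaunay edge iff some circle through
# the two points contains no other point. For points in general position it
# suffices to check, for every third point k, whether any empty circumcircle
# through i, j exists; we test the stronger local-Delaunay characterization
# by scanning all circumcircles of triangles (i, j, k). O(n^4) — tiny n only.
oracle_delaunay_edges <- function(x, y) {
  n <- length(x)
  circum <- function(i, j, k) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  edges <- matrix(integer(), 0, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    found <- FALSE
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      cc <- circum(i, j, k)
      if (is.null(cc)) next
      others <- setdiff(seq_len(n), c(i, j, k))
      d2 <- (x[others] - cc[1])^2 + (y[others] - cc[2])^2
      if (all(d2 > cc[3]^2 * (1 + 1e-9))) { found <- TRUE; break }
    }
    if (found) edges <- rbind(edges, c(i, j))
  }
  edges
}

# Literal transcription of the coverage-adjusted entropy formula.
oracle_chao_shen <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  f1 <- sum(counts == 1)
  C <- 1 - f1 / n
  p_tilde <- C * counts / n
  H <- 0
  for (pa in p_tilde) H <- H - pa * log(pa) / (1 - (1 - pa)^n)
  H
}

# O(n^2) nearest-neighbor scan.
oracle_nn_distances <- function(cells, phenotypes) {
  T <- length(phenotypes)
  out <- matrix(NA_real_, T, T, dimnames = list(phenotypes, phenotypes))
  for (a in phenotypes) for (b in phenotypes) {
    ia <- which(cells$phenotype == a)
    ib <- which(cells$phenotype == b)
    if (!length(ia) || !length(ib)) next
    dists <- numeric(0)
    for (i in ia) {
      cand <- setdiff(ib, i)
      if (!length(cand)) next
      d <- sqrt((cells$x[cand] - cells$x[i])^2 +
                  (cells$y[cand] - cells$y[i])^2)
      dists <- c(dists, min(d))
    }
    if (length(dists) == length(ia)) out[a, b] <- mean(dists)
  }
  out
}

# Ordered adjacency recount from an explicit edge list.
oracle_alpha_recount <- function(edges, phenotype, labels) {
  T <- length(labels)
  alpha <- matrix(0, T, T, dimnames = list(labels, labels))
  for (r in seq_len(nrow(edges))) {
    a <- phenotype[edges[r, 1]]; b <- phenotype[edges[r, 2]]
    alpha[a, b] <- alpha[a, b] + 1
    alpha[b, a] <- alpha[b, a] + 1
  }
  alpha
}

# Brute-force radius neighbor composition (index cell included).
oracle_neighbor_vectors <- function(cells, radius, phenotypes) {
  n <- nrow(cells)
  out <- matrix(0, n, length(phenotypes),
                dimnames = list(cells$cell_id, phenotypes))
  for (i in seq_len(n)) {
    d2 <- (cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2
    nb <- which(d2 <= radius^2)
    tab <- table(factor(cells$phenotype[nb], levels = phenotypes))
    out[i, ] <- as.numeric(tab) / length(nb)
  }
  out
}

# Small labeled core on CSR points, for spatial tests.
make_labeled_core <- function(n, types, probs, seed, radius = 300) {
  set.seed(seed)
  r <- radius * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  data.frame(cell_id = paste0("c", seq_len(n)),
             x = radius + r * cos(a), y = radius + r * sin(a),
             phenotype = sample(types, n, replace = TRUE, prob = probs),
             stringsAsFactors = FALSE)
}
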