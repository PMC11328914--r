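test_that("neighbor vectors are simplex compositions with self-inclusion", {
  # isolated cell: vector is the indicator of its own type
  cells <- data.frame(cell_id = c("a", "b"), x = c(0, 1000), y = c(0, 0),
                      phenotype = c("Tumor", "CD8 T"))
  v <- neighbor_vectors(cells, radius = 50,
                        phenotypes = c("Tumor", "CD8 T"))
  expect_equal(v["a", ], c(Tumor = 1, "CD8 T" = 0))
  expect_equal(v["b", ], c(Tumor = 0, "CD8 T" = 1))

  # hand count: index Tumor cell with 3 CD8 and 1 Tumor neighbor
  cells <- data.frame(
    cell_id = paste0("c", 1:5),
    x = c(0, 10, -10, 0, 0), y = c(0, 0, 0, 10, -10),
    phenotype = c("Tumor", "CD8 T", "CD8 T", "CD8 T", "Tumor"))
  v <- neighbor_vectors(cells, radius = 20,
                        phenotypes = c("CD8 T", "Tumor"))
  expect_equal(v["c1", ], c("CD8 T" = 0.6, Tumor = 0.4))

  for (seed in 1:3) {
    core <- make_labeled_core(300, c("A", "B", "C"), c(0.4, 0.4, 0.2), seed)
    v <- neighbor_vectors(core, 50, phenotypes = c("A", "B", "C"))
    expect_equal(unname(rowSums(v)), rep(1, nrow(core)))
    expect_true(all(v >= 0))
    want <- oracle_neighbor_vectors(core, 50, c("A", "B", "C"))
    expect_equal(v, want, tolerance = 1e-12)
  }
})

test_that("k-means CN fit honours seed, K=1, and parameter checks", {
  core <- make_labeled_core(500, c("A", "B"), c(0.5, 0.5), 9)
  v <- neighbor_vectors(core, 50, phenotypes = c("A", "B"))
  m1 <- fit_cn_model(v, K = 3, seed = 4)
  m2 <- fit_cn_model(v, K = 3, seed = 4)
  expect_identical(m1$cell_cn, m2$cell_cn)

  m0 <- fit_cn_model(v, K = 1, seed = 0)
  expect_true(all(m0$cell_cn == 1))
  tot_var <- sum(scale(v, scale = FALSE)^2)
  expect_equal(m0$inertia, tot_var, tolerance = 1e-9)

  expect_error(fit_cn_model(v[1:3, ], K = 5), "exceeds")
})

test_that("planted two-region cores are recovered with high ARI", {
  spec <- sim_spec(n_cells_per_core = 3000)
  regions <- list(
    list(halfplane = "left", composition = c(Tumor = 0.8, "CD8 T" = 0.2)),
    list(halfplane = "right", composition = c(Tumor = 0.2, "CD8 T" = 0.8)))
  g <- plant_neighborhoods(spec, regions, seed = 42,
                           panels = default_panels()["panel1"])
  cells <- g$cells
  cells$phenotype <- g$truth$true_phenotype
  v <- neighbor_vectors(cells, 50, phenotypes = c("Tumor", "CD8 T"))
  m <- fit_cn_model(v, K = 2, seed = 0, radius = 50)
  ari <- adjusted_rand_index(m$cell_cn, g$truth$region)
  expect_gte(ari, 0.9)
})

test_that("CN labels are stable under phenotype column permutation", {
  core <- make_labeled_core(800, c("A", "B", "C"), c(0.4, 0.4, 0.2), 33)
  v <- neighbor_vectors(core, 50, phenotypes = c("A", "B", "C"))
  m1 <- fit_cn_model(v, K = 3, seed = 1)
  m2 <- fit_cn_model(v[, c("C", "A", "B")], K = 3, seed = 1)
  expect_equal(adjusted_rand_index(m1$cell_cn, m2$cell_cn), 1)
})

test_that("adjusted Rand index agrees with the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(10)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("enrichment log odds ratios follow the odds arithmetic", {
  cen <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  colnames(cen) <- c("Tumor", "CD8 T")
  model <- structure(list(centroids = cen, size = c(100, 100), K = 2),
                     class = "cn_model")
  enr <- cn_enrichment(model, global_freq = c(Tumor = 0.2, "CD8 T" = 0.8))
  expect_equal(unname(enr$raw[1, "Tumor"]), log(4 / 0.25), tolerance = 1e-12)
  expect_equal(unname(enr$raw[2, "Tumor"]), 0, tolerance = 1e-12)

  # centroid equal to global -> zero everywhere
  eq <- cn_enrichment(model, global_freq = c(Tumor = 0.8, "CD8 T" = 0.2))
  expect_equal(unname(eq$raw[1, ]), c(0, 0), tolerance = 1e-12)

  # degenerate centroid frequencies are smoothed, not infinite
  cen2 <- rbind(c(1, 0), c(0.5, 0.5))
  colnames(cen2) <- c("Tumor", "CD8 T")
  model2 <- structure(list(centroids = cen2, size = c(50, 50), K = 2),
                      class = "cn_model")
  enr2 <- cn_enrichment(model2)
  expect_true(all(is.finite(enr2$raw)))

  # clip mode saturates; rescale mode pins the extreme to +/-5
  extreme <- cn_enrichment(model2, mode = "clip", bound = 0.5)
  expect_true(all(abs(extreme$normalized) <= 0.5))
  res <- cn_enrichment(model2, mode = "rescale")
  expect_equal(max(abs(res$normalized)), 5)
  expect_true(all(sign(res$normalized) == sign(res$raw) |
                    res$raw == 0))
  # monotone: raw ordering preserved
  o1 <- order(enr2$raw); o2 <- order(res$normalized[o1])
  expect_true(!is.unsorted(res$normalized[o1]))
})

test_that("CN prevalence partitions each sample and ranks planted groups", {
  spec <- sim_spec(n_cells_per_core = 800)
  mk_core <- function(seed, p_left) {
    regions <- list(
      list(halfplane = "left", composition = c(Tumor = 0.9, "CD8 T" = 0.1)),
      list(halfplane = "right", composition = c(Tumor = 0.1, "CD8 T" = 0.9)))
    g <- plant_neighborhoods(spec, regions, seed = seed,
                             panels = default_panels()["panel1"])
    cells <- g$cells
    cells$phenotype <- g$truth$true_phenotype
    # keep p_left of the left side to skew region-1 prevalence
    keep <- cells$x > 300 | runif(nrow(cells)) < p_left
    cells[keep, ]
  }
  cores <- c(lapply(1:4, function(s) mk_core(s, 1.0)),      # group A
             lapply(5:8, function(s) mk_core(s, 0.15)))     # group B
  for (i in seq_along(cores)) {
    cores[[i]]$core_id <- paste0("core", i)
    cores[[i]]$cell_id <- paste0("core", i, "_", cores[[i]]$cell_id)
  }
  cells <- do.call(rbind, cores)
  v <- neighbor_vectors(cells, 50, phenotypes = c("Tumor", "CD8 T"))
  m <- fit_cn_model(v, K = 2, seed = 0)
  sample_of <- setNames(cells$core_id, cells$cell_id)
  grouping <- setNames(rep(c("A", "B"), each = 4), paste0("core", 1:8))
  pr <- cn_prevalence(m, sample_of, grouping)
  expect_equal(unname(rowSums(pr$prevalence)), rep(1, 8), tolerance = 1e-12)
  # the tumor-rich CN (centroid highest in Tumor) dominates group A
  cn_tumor <- which.max(m$centroids[, "Tumor"])
  expect_gt(pr$group_median["A", cn_tumor], pr$group_median["B", cn_tumor])
})

test_that("CN labelings are consistent across 40/50/60 um radii", {
  spec <- sim_spec(n_cells_per_core = 2500)
  regions <- list(
    list(halfplane = "left", composition = c(Tumor = 0.8, "CD8 T" = 0.2)),
    list(halfplane = "right", composition = c(Tumor = 0.2, "CD8 T" = 0.8)))
  g <- plant_neighborhoods(spec, regions, seed = 77,
                           panels = default_panels()["panel1"])
  cells <- g$cells
  cells$phenotype <- g$truth$true_phenotype
  rr <- cn_radius_robustness(cells, radii = c(40, 50, 60), K = 2, seed = 0,
                             phenotypes = c("Tumor", "CD8 T"))
  expect_true(all(rr$ari >= 0.8))
})

test_that("elbow scan reports decreasing inertia and a suggestion", {
  set.seed(5)
  blob <- function(cx, cy) cbind(rnorm(150, cx, 0.05), rnorm(150, cy, 0.05))
  v <- rbind(blob(0, 0), blob(1, 0), blob(0, 1))
  colnames(v) <- c("f1", "f2")
  scan <- cn_elbow_scan(v, K_range = 2:7, seed = 0)
  expect_true(all(diff(scan$inertia) <= 1e-8))
  expect_equal(attr(scan, "suggested_K"), 3)
})
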