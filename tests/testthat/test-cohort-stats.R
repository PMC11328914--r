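test_that("quantile grouping follows top-40/bottom-40 stratification", {
  vals <- setNames(as.numeric(1:10), paste0("P", 1:10))
  grp <- quantile_groups(vals)
  expect_setequal(names(grp)[grp == "high"], paste0("P", 7:10))
  expect_setequal(names(grp)[grp == "low"], paste0("P", 1:4))

  # median split: lo = hi = 0.5 leaves no middle except exact ties
  even <- setNames(c(1, 2, 3, 4, 10, 11, 12, 13), paste0("P", 1:8))
  g2 <- quantile_groups(even, lo = 0.5, hi = 0.5)
  expect_equal(sum(g2 == "middle"), 0)
  expect_equal(sum(g2 == "high"), 4)

  expect_warning(quantile_groups(setNames(rep(2, 6), 1:6)), "empty")
})

test_that("log-rank is symmetric, null-calibrated, and powered", {
  set.seed(123)
  tt <- rexp(40); ev <- rep(TRUE, 40)
  grp <- rep(c("a", "b"), each = 20)
  # identical survival in both groups: duplicate every subject
  r <- km_logrank(c(tt[1:20], tt[1:20]), rep(ev[1:20], 2), grp)
  expect_lt(r$chisq, 1e-10)
  expect_equal(r$p, 1, tolerance = 1e-6)

  # label swap leaves p unchanged
  r1 <- km_logrank(tt, ev, grp)
  r2 <- km_logrank(tt, ev, rev(grp))
  expect_equal(r1$p, r2$p, tolerance = 1e-12)

  # KM curve starts at 1 and is non-increasing
  s <- summary(r1$fit)
  expect_true(all(s$surv <= 1 + 1e-12))
  expect_true(all(tapply(s$surv, s$strata, function(v) !is.unsorted(-v))))

  # power at hazard ratio 3
  set.seed(31)
  rej <- mean(replicate(100, {
    sv1 <- simulate_survival(rep(0, 100))
    sv2 <- simulate_survival(rep(log(3), 100))
    km_logrank(c(sv1$time, sv2$time), c(sv1$event, sv2$event),
               rep(c("a", "b"), each = 100))$p < 0.05
  }))
  expect_gte(rej, 0.9)

  # group with no events is flagged, not dropped
  r3 <- km_logrank(c(tt[1:10], 1:10), c(ev[1:10], rep(FALSE, 10)),
                   rep(c("a", "b"), each = 10))
  expect_equal(r3$no_event_groups, "b")
})

test_that("Cox univariate estimates are unbiased and guarded", {
  set.seed(7)
  betas <- replicate(100, {
    x <- runif(120)
    sv <- simulate_survival(rep(0, 120))
    cox_univariate(sv$time, sv$event, x)$coef
  })
  expect_lt(abs(mean(betas)), 0.15)

  expect_error(cox_univariate(rexp(20), rep(TRUE, 20), rep(1, 20)),
               "zero variance")

  # affine time rescaling leaves the estimate unchanged
  x <- runif(60); sv <- simulate_survival(0.7 * x)
  c1 <- cox_univariate(sv$time, sv$event, x)
  c2 <- cox_univariate(sv$time * 12.5, sv$event, x)
  expect_equal(c1$coef, c2$coef, tolerance = 1e-8)
  expect_gt(c1$hr, 0)
  expect_lte(c1$ci_lower, c1$hr)
  expect_gte(c1$ci_upper, c1$hr)
})

test_that("Cox recovers a planted effect through the cohort generator", {
  spec <- sim_spec(n_cells_per_core = 150, cores_per_patient = 2,
                   patient_effect_sd = 0.8,
                   survival_model = list(rate = log(2) / 12,
                                         beta = c("CD4 T" = -3),
                                         censor_frac = 0.3))
  gc <- generate_cohort(spec, 150, seed = 55)
  x <- gc$patient_truth$`prop_CD4 T`
  cl <- gc$cohort$clinical
  fit <- cox_univariate(cl$survival_months, cl$event, x)
  expect_lt(fit$coef, 0)
  expect_true(fit$ci_lower < -3 && -3 < fit$ci_upper || abs(fit$coef + 3) < 2)
})

test_that("Spearman association handles monotone, null and constant input", {
  x <- runif(30)
  expect_equal(spearman_assoc(x, exp(3 * x))$rho, 1, tolerance = 1e-12)
  set.seed(14)
  rhos <- replicate(200, spearman_assoc(runif(20), runif(20))$rho)
  expect_lt(abs(mean(rhos)), 0.05)
  expect_warning(r <- spearman_assoc(rep(1, 10), runif(10)), "constant")
  expect_true(is.na(r$rho))
  expect_error(spearman_assoc(1:3, 1:3), "5")
})

test_that("planted BAP1/CD8 coupling is recovered at rho <= -0.4", {
  spec <- sim_spec(n_cells_per_core = 600,
                   tsg_model = list(meanlog = log(5), between_sd = 0.15,
                                    within_sd = 0.3, cd8_coupling = -12))
  bap1 <- cd8 <- numeric(40)
  for (i in 1:40) {
    g <- generate_core(spec, seed = 700 + i)
    p2 <- g$cells[g$cells$panel_id == "panel2", ]
    p1 <- g$cells[g$cells$panel_id == "panel1", ]
    bap1[i] <- mean(p2$BAP1)
    cd8[i] <- mean(p1$CD8)
  }
  expect_lte(spearman_assoc(bap1, cd8)$rho, -0.4)
})

test_that("tumor-enriched filter applies a strict 20 percent cut", {
  pm <- matrix(c(0.20, 0.21, 1.0, 0.05), ncol = 1,
               dimnames = list(paste0("core", 1:4), "Tumor"))
  kept <- tumor_enriched_filter(pm)
  expect_setequal(kept, c("core2", "core3"))

  spec <- sim_spec(n_cells_per_core = 200, cores_per_patient = 2,
                   patient_effect_sd = 0.9)
  gc <- generate_cohort(spec, 8, seed = 77)
  gc$cohort$cells$phenotype <- gc$truth$true_phenotype[
    match(gc$cohort$cells$cell_id, gc$truth$cell_id)]
  cc <- cohort_composition(gc$cohort, phenotypes = names(spec$composition))
  kept <- tumor_enriched_filter(cc$proportion)
  manual <- rownames(cc$proportion)[cc$proportion[, "Tumor"] > 0.2]
  expect_setequal(kept, manual)
})

test_that("cohort summary reproduces printed-style percentages", {
  clin <- data.frame(
    patient_id = paste0("P", 1:115),
    sex = rep(c("male", "female", "unknown"), c(81, 24, 10)),
    site = rep(c("MPM", "MPeM", "other"), c(88, 25, 2)),
    histology = rep(c("Epithelioid", "Biphasic", "other"), c(69, 22, 24)),
    survival_months = rep(12, 115), event = TRUE,
    stringsAsFactors = FALSE)
  tab <- cohort_summary_table(clin, fields = c("sex", "site", "histology"))
  ct <- tab$categorical
  pick <- function(f, l) ct$percent[ct$field == f & ct$level == l &
                                      ct$subgroup == "Total"]
  expect_equal(pick("sex", "male"), 70)
  expect_equal(pick("sex", "female"), 21)
  expect_equal(pick("sex", "unknown"), 8.7)
  expect_equal(pick("site", "MPM"), 77)
  expect_equal(pick("site", "MPeM"), 22)
  expect_equal(pick("site", "other"), 1.7)
  expect_equal(pick("histology", "Epithelioid"), 60)

  # per-field percentages sum to ~100 within rounding slack
  for (f in unique(ct$field)) {
    s <- sum(ct$percent[ct$field == f & ct$subgroup == "Total"])
    expect_lt(abs(s - 100), length(unique(ct$level[ct$field == f])))
  }
  expect_equal(tab$survival$median[1], 12)
})

test_that("marker association table covers all channel-marker pairs", {
  set.seed(3)
  ch <- matrix(runif(40), 20, 2,
               dimnames = list(paste0("s", 1:20), c("BAP1", "NF2")))
  mk <- matrix(runif(40), 20, 2,
               dimnames = list(paste0("s", 1:20), c("CD8", "CD68")))
  grp <- setNames(rep(c("MPM", "MPeM"), each = 10), paste0("s", 1:20))
  tab <- marker_association_table(ch, mk, grp)
  expect_equal(nrow(tab), 2 * 2 * 2)
  expect_true(all(abs(tab$rho) <= 1))
})
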