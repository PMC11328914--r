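#' Simulation specification for synthetic mIF cohorts
#'
#' Describes the generative model used for validation: circular 0.6 mm
#' cores; a 9-phenotype composition (the eight marker-defined types plus
#' "unidentified"); cell placement either completely spatially random (CSR)
#' or via a Thomas (Poisson cluster) process with tunable within-type
#' aggregation; per-channel two-component log-normal intensity mixtures
#' driven by each type's positivity signature; per-core means with
#' cell-level noise for the continuous protein channels (BAP1, NF2, MTAP,
#' LAG3); 1-9 cores per patient; and exponential survival with log-hazard
#' coefficients on realized per-patient covariates and independent
#' exponential censoring (about 30 percent censored at baseline).
#'
#' @param composition named probabilities over phenotypes, summing to 1.
#' @param n_cells_per_core Poisson mean of the per-core cell count (applies
#'   to each staining panel's segmentation independently).
#' @param core_radius_um core radius, micrometres.
#' @param clustering `list(type = "CSR")` or `list(type = "thomas",
#'   sigma = 30, mu = 30, clustered_types = <character>, shared_groups =
#'   <list of character vectors>)`. Types in a shared group are placed
#'   around one common parent set, which plants positive contact
#'   enrichment between them; other clustered types get their own parents.
#' @param intensity_model `list(neg_meanlog, pos_meanlog, sdlog)` for the
#'   log-normal negative/positive components (defaults: medians 1 and 10,
#'   common log-scale 0.35, chosen for clean threshold gating).
#' @param tsg_model per-continuous-channel model: `list(meanlog, between_sd,
#'   within_sd, cd8_coupling)`; each core draws a channel mean on the log
#'   scale (optionally shifted by `cd8_coupling` times the core's
#'   centred CD8 fraction, to plant marker/infiltration correlations) and
#'   cells add log-normal noise.
#' @param cores_per_patient integer vector to sample the per-patient core
#'   count from (default 1:9).
#' @param patient_effect_sd log-scale SD of the per-patient composition
#'   perturbation (drives within- vs between-patient core correlation).
#' @param survival_model `list(rate, beta, censor_frac)`: baseline
#'   exponential hazard (default median 12 months), named log-hazard
#'   coefficients on realized per-patient phenotype proportions, and the
#'   target censoring fraction at baseline hazard.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(composition = c(Tumor = 0.33, "CD8 T" = 0.12,
                                     "CD4 T" = 0.10, Treg = 0.03,
                                     Macrophage = 0.12, B = 0.04,
                                     DC = 0.05, NK = 0.03,
                                     unidentified = 0.18),
                     n_cells_per_core = 2000,
                     core_radius_um = 300,
                     clustering = list(type = "CSR"),
                     intensity_model = list(neg_meanlog = 0,
                                            pos_meanlog = log(10),
                                            sdlog = 0.35),
                     tsg_model = list(meanlog = log(5), between_sd = 0.5,
                                      within_sd = 0.3, cd8_coupling = 0),
                     cores_per_patient = 1:9,
                     patient_effect_sd = 0.25,
                     survival_model = list(rate = log(2) / 12, beta = NULL,
                                           censor_frac = 0.3)) {
  if (abs(sum(composition) - 1) > 1e-8)
    stop("composition must sum to 1")
  if (any(composition < 0 | composition > 1))
    stop("composition probabilities must lie in [0, 1]")
  if (core_radius_um <= 0) stop("core_radius_um must be positive")
  if (identical(clustering$type, "thomas") &&
      (is.null(clustering$sigma) || clustering$sigma <= 0))
    stop("thomas clustering requires sigma > 0")
  structure(list(composition = composition,
                 n_cells_per_core = n_cells_per_core,
                 core_radius_um = core_radius_um,
                 clustering = clustering,
                 intensity_model = intensity_model,
                 tsg_model = tsg_model,
                 cores_per_patient = cores_per_patient,
                 patient_effect_sd = patient_effect_sd,
                 survival_model = survival_model),
            class = "sim_spec")
}

# positive-marker signature of each phenotype
.signatures <- list(
  Tumor = "panCK", "CD4 T" = "CD4", Treg = c("CD4", "FOXP3"),
  "CD8 T" = "CD8", B = "CD20", Macrophage = "CD68",
  DC = "CD11c", NK = "CD56", unidentified = character())

#' Default gating thresholds for synthetic intensities
#'
#' Thresholds at the geometric mean of the two mixture medians, the
#' midpoint on the log scale.
#'
#' @param spec a `sim_spec`.
#' @param panel `marker_panel` whose rule markers need thresholds.
#' @return a [gating_config()].
#' @export
default_gating <- function(spec = sim_spec(), panel) {
  im <- spec$intensity_model
  thr <- exp((im$neg_meanlog + im$pos_meanlog) / 2)
  rule_markers <- unique(unlist(lapply(panel$rules,
                                       function(r) c(r$require, r$forbid))))
  gating_config(stats::setNames(rep(thr, length(rule_markers)), rule_markers))
}

.runif_disc <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  cbind(x = radius + r * cos(a), y = radius + r * sin(a))
}

# Thomas-process positions for n points inside the disc; parents uniform,
# offspring Gaussian around parents, resampled until inside the core.
.thomas_disc <- function(n, radius, sigma, mu, parents = NULL) {
  if (n == 0L) return(cbind(x = numeric(), y = numeric()))
  if (is.null(parents)) {
    np <- max(1L, stats::rpois(1, n / mu))
    parents <- .runif_disc(np, radius)
  }
  idx <- sample.int(nrow(parents), n, replace = TRUE)
  pos <- matrix(NA_real_, n, 2)
  centre <- c(radius, radius)
  for (i in seq_len(n)) {
    for (trial in 1:200) {
      p <- parents[idx[i], ] + stats::rnorm(2, 0, sigma)
      if (sum((p - centre)^2) <= radius^2) break
      if (trial == 200) p <- centre  # pathological sigma; keep inside
    }
    pos[i, ] <- p
  }
  colnames(pos) <- c("x", "y")
  pos
}

.place_cells <- function(types, spec) {
  n <- length(types)
  radius <- spec$core_radius_um
  cl <- spec$clustering
  pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  if (!identical(cl$type, "thomas")) {
    pos[] <- .runif_disc(n, radius)
    return(pos)
  }
  clustered <- cl$clustered_types %||% unique(types)
  groups <- cl$shared_groups %||% list()
  grouped_types <- unlist(groups)
  units <- c(groups, as.list(setdiff(intersect(clustered, unique(types)),
                                     grouped_types)))
  done <- rep(FALSE, n)
  for (u in units) {
    sel <- types %in% u
    if (!any(sel)) next
    pos[sel, ] <- .thomas_disc(sum(sel), radius, cl$sigma, cl$mu %||% 30)
    done[sel] <- TRUE
  }
  if (any(!done)) pos[!done, ] <- .runif_disc(sum(!done), radius)
  pos
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.draw_intensities <- function(types, panel, spec, tsg_shift = 0) {
  im <- spec$intensity_model
  n <- length(types)
  out <- list()
  for (m in setdiff(panel$markers, panel$continuous_channels)) {
    posflag <- vapply(types, function(t) m %in% .signatures[[t]], logical(1))
    meanlog <- ifelse(posflag, im$pos_meanlog, im$neg_meanlog)
    out[[m]] <- stats::rlnorm(n, meanlog, im$sdlog)
  }
  tm <- spec$tsg_model
  for (ch in panel$continuous_channels) {
    core_meanlog <- tm$meanlog + stats::rnorm(1, 0, tm$between_sd) +
      (if (ch == "BAP1") tsg_shift else 0)
    out[[ch]] <- stats::rlnorm(n, core_meanlog, tm$within_sd)
  }
  out
}

.panel_cells <- function(types, pos, core_id, panel, spec, tsg_shift = 0) {
  n <- length(types)
  cells <- data.frame(
    cell_id = paste0(core_id, "_", panel$panel_id, "_", seq_len(n)),
    core_id = core_id, panel_id = panel$panel_id,
    x = pos[, "x"], y = pos[, "y"], stringsAsFactors = FALSE)
  for (m in names(ints <- .draw_intensities(types, panel, spec, tsg_shift)))
    cells[[m]] <- ints[[m]]
  cells
}

#' Generate one synthetic core
#'
#' Draws a Poisson cell count, true phenotypes from the composition,
#' positions from the configured point process, and channel intensities
#' from the type-conditional mixtures, independently for each staining
#' panel. Deterministic given `(spec, seed)`.
#'
#' @param spec a `sim_spec`.
#' @param seed integer seed.
#' @param core_id identifier for the generated core.
#' @param composition optional override of `spec$composition`.
#' @param panels staining panels to simulate (default both; pass
#'   `default_panels()["panel1"]` for lineage-panel-only studies).
#' @return list: `cells` (both panels pooled), `truth` (cell_id,
#'   true_phenotype, region = NA), `tissue_area` (mm^2 of the disc).
#' @export
generate_core <- function(spec, seed, core_id = "core1", composition = NULL,
                          panels = default_panels()) {
  set.seed(seed)
  comp <- composition %||% spec$composition
  if (abs(sum(comp) - 1) > 1e-8) stop("composition must sum to 1")
  cells <- NULL; truth <- NULL
  cd8_frac <- NA_real_
  for (panel in panels) {
    n <- stats::rpois(1, spec$n_cells_per_core)
    types <- sample(names(comp), n, replace = TRUE, prob = comp)
    if (panel$panel_id == "panel1")
      cd8_frac <- mean(types == "CD8 T")
    pos <- .place_cells(types, spec)
    shift <- if (panel$panel_id == "panel2" &&
                 !is.null(spec$tsg_model$cd8_coupling) &&
                 spec$tsg_model$cd8_coupling != 0 && is.finite(cd8_frac))
      spec$tsg_model$cd8_coupling *
        (cd8_frac - (if ("CD8 T" %in% names(comp)) comp[["CD8 T"]] else 0))
    else 0
    pc <- .panel_cells(types, pos, core_id, panel, spec, tsg_shift = shift)
    cells <- if (is.null(cells)) pc else
      merge_rows(cells, pc)
    truth <- rbind(truth, data.frame(cell_id = pc$cell_id,
                                     true_phenotype = types,
                                     region = NA_integer_,
                                     stringsAsFactors = FALSE))
  }
  list(cells = cells, truth = truth,
       tissue_area = core_disc_area(spec$core_radius_um))
}

# rbind two cell tables with different channel columns, padding with NA
merge_rows <- function(a, b) {
  for (cn in setdiff(names(b), names(a))) a[[cn]] <- NA_real_
  for (cn in setdiff(names(a), names(b))) b[[cn]] <- NA_real_
  rbind(a, b[names(a)])
}

#' Generate a core with planted spatial neighborhoods
#'
#' Cells are placed uniformly over the disc; each falls into at most one of
#' the supplied regions and draws its phenotype from that region's
#' composition (background cells use `spec$composition`). The true region
#' label is recorded per cell, giving ground truth for
#' cellular-neighborhood recovery tests.
#'
#' @param spec a `sim_spec`.
#' @param regions list of `list(center = c(x, y), radius = r, composition =
#'   <named probabilities>)` or `list(halfplane = "left"/"right",
#'   composition = ...)` splitting the core at the vertical midline.
#'   Regions must not overlap.
#' @param seed integer seed.
#' @param panels staining panels to simulate (default both).
#' @return list as in [generate_core()] with `truth$region` set (0 =
#'   background).
#' @export
plant_neighborhoods <- function(spec, regions, seed,
                                panels = default_panels()) {
  set.seed(seed)
  R <- spec$core_radius_um
  discs <- Filter(function(r) !is.null(r$center), regions)
  if (length(discs) > 1) {
    for (i in seq_len(length(discs) - 1)) for (j in (i + 1):length(discs)) {
      d <- sqrt(sum((discs[[i]]$center - discs[[j]]$center)^2))
      if (d < discs[[i]]$radius + discs[[j]]$radius)
        stop("overlapping regions: ambiguous ground truth")
    }
  }
  for (r in regions) if (abs(sum(r$composition) - 1) > 1e-8)
    stop("region composition must sum to 1")

  cells <- NULL; truth <- NULL
  for (panel in panels) {
    n <- stats::rpois(1, spec$n_cells_per_core)
    pos <- .runif_disc(n, R)
    region <- rep(0L, n)
    for (k in seq_along(regions)) {
      rg <- regions[[k]]
      inside <- if (!is.null(rg$halfplane)) {
        if (rg$halfplane == "left") pos[, "x"] <= R else pos[, "x"] > R
      } else {
        (pos[, "x"] - rg$center[1])^2 + (pos[, "y"] - rg$center[2])^2 <=
          rg$radius^2
      }
      region[inside & region == 0L] <- k
    }
    types <- character(n)
    bg <- region == 0L
    if (any(bg)) types[bg] <- sample(names(spec$composition), sum(bg),
                                     replace = TRUE, prob = spec$composition)
    for (k in seq_along(regions)) {
      sel <- region == k
      if (any(sel)) {
        comp <- regions[[k]]$composition
        types[sel] <- sample(names(comp), sum(sel), replace = TRUE,
                             prob = comp)
      }
    }
    pc <- .panel_cells(types, pos, "core1", panel, spec)
    cells <- if (is.null(cells)) pc else merge_rows(cells, pc)
    truth <- rbind(truth, data.frame(cell_id = pc$cell_id,
                                     true_phenotype = types, region = region,
                                     stringsAsFactors = FALSE))
  }
  list(cells = cells, truth = truth,
       tissue_area = core_disc_area(spec$core_radius_um))
}

#' Simulate survival times with exponential hazard and censoring
#'
#' Event times are exponential with hazard `rate * exp(lp)`; censoring
#' times are independent exponential with rate chosen so that a fraction
#' `censor_frac` of baseline-hazard subjects is censored.
#'
#' @param lp numeric linear predictor (log relative hazard) per subject.
#' @param rate baseline hazard (1/months).
#' @param censor_frac target censoring fraction at baseline.
#' @return data.frame `time`, `event` (logical).
#' @export
simulate_survival <- function(lp, rate = log(2) / 12, censor_frac = 0.3) {
  n <- length(lp)
  t_event <- stats::rexp(n, rate * exp(lp))
  rate_c <- rate * censor_frac / (1 - censor_frac)
  t_cens <- if (censor_frac > 0) stats::rexp(n, rate_c) else rep(Inf, n)
  data.frame(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

.sample_clinical <- function(patient_id) {
  data.frame(
    patient_id = patient_id,
    site = sample(c("MPM", "MPeM", "other"), 1, prob = c(0.77, 0.21, 0.02)),
    histology = sample(c("Epithelioid", "Biphasic", "Sarcomatoid", "other"),
                       1, prob = c(0.60, 0.19, 0.07, 0.14)),
    grade = sample(c("high", "intermediate", "low", "unknown"), 1,
                   prob = c(0.40, 0.15, 0.07, 0.38)),
    sex = sample(c("male", "female", "unknown"), 1,
                 prob = c(0.70, 0.21, 0.09)),
    age_bin = sample(c("31-40", "41-50", "51-60", "61-70", "71-80", "81-90"),
                     1, prob = c(0.035, 0.07, 0.22, 0.41, 0.23, 0.035)),
    asbestos = sample(c("yes", "no", "unknown"), 1,
                      prob = c(0.33, 0.05, 0.62)),
    smoking = sample(c("current", "never", "previous", "unknown"), 1,
                     prob = c(0.11, 0.29, 0.33, 0.27)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Patients receive a log-normal perturbation of the base composition
#' (within-patient cores then share a composition, giving higher
#' within-patient than between-patient core correlation), 1-9 cores each,
#' and exponential survival whose log-hazard is `beta` applied to the
#' realized per-patient true phenotype proportions.
#'
#' @param spec a `sim_spec`.
#' @param n_patients number of patients.
#' @param seed integer seed.
#' @return list: `cohort` (an [mif_cohort()]), `truth` (per-cell table plus
#'   attributes), `patient_truth` (realized proportions and true log-hazard
#'   per patient).
#' @export
generate_cohort <- function(spec, n_patients, seed) {
  stopifnot(n_patients >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  all_cells <- list(); all_truth <- list(); cores <- list()
  clin <- list(); ptruth <- list()
  beta <- spec$survival_model$beta
  for (p in seq_len(n_patients)) {
    set.seed(sub_seeds[p])
    pid <- sprintf("P%03d", p)
    n_cores <- sample(spec$cores_per_patient, 1)
    w <- spec$composition *
      exp(stats::rnorm(length(spec$composition), 0, spec$patient_effect_sd))
    comp_p <- w / sum(w)
    core_seeds <- sample.int(.Machine$integer.max - 1L, n_cores)
    ptypes <- character()
    for (k in seq_len(n_cores)) {
      cid <- sprintf("%s_c%d", pid, k)
      g <- generate_core(spec, core_seeds[k], core_id = cid,
                         composition = comp_p)
      all_cells[[cid]] <- g$cells
      all_truth[[cid]] <- g$truth
      cores[[cid]] <- data.frame(core_id = cid, patient_id = pid,
                                 tissue_area = g$tissue_area,
                                 stringsAsFactors = FALSE)
      ptypes <- c(ptypes, g$truth$true_phenotype)
    }
    set.seed(sub_seeds[p] %% 1000000L + p)  # clinical + survival draws
    cl <- .sample_clinical(pid)
    props <- prop.table(table(factor(ptypes, levels = names(spec$composition))))
    lp <- 0
    if (!is.null(beta))
      lp <- sum(beta * as.numeric(props[names(beta)]))
    sv <- simulate_survival(lp, rate = spec$survival_model$rate,
                            censor_frac = spec$survival_model$censor_frac)
    cl$survival_months <- sv$time
    cl$event <- sv$event
    clin[[pid]] <- cl
    pt <- data.frame(patient_id = pid, true_lp = lp,
                     stringsAsFactors = FALSE)
    for (t in names(props)) pt[[paste0("prop_", t)]] <- as.numeric(props[[t]])
    ptruth[[pid]] <- pt
  }
  cells <- Reduce(merge_rows, all_cells)
  cohort <- mif_cohort(cells, do.call(rbind, cores),
                       clinical = do.call(rbind, clin))
  rownames(cohort$clinical) <- NULL
  list(cohort = cohort, truth = do.call(rbind, all_truth),
       patient_truth = do.call(rbind, ptruth))
}
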