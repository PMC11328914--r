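#' Quantile-stratified grouping
#'
#' Splits samples on empirical quantiles of a score: strictly above the
#' `hi` quantile -> "high", strictly below the `lo` quantile -> "low",
#' everything else "middle" (excluded from two-group tests). With the
#' default 0.4/0.6 cut this is the top-40 / bottom-40 percent
#' stratification used for the survival comparisons. Type-7 empirical
#' quantiles, strict inequalities.
#'
#' @param values named numeric vector (names are sample ids).
#' @param lo,hi quantile cut points.
#' @param labels labels for (low, middle, high).
#' @return named character vector of group labels.
#' @export
quantile_groups <- function(values, lo = 0.4, hi = 0.6,
                            labels = c("low", "middle", "high")) {
  stopifnot(length(values) >= 5L, lo <= hi)
  qlo <- stats::quantile(values, lo, type = 7, names = FALSE)
  qhi <- stats::quantile(values, hi, type = 7, names = FALSE)
  out <- rep(labels[2], length(values))
  out[values < qlo] <- labels[1]
  out[values > qhi] <- labels[3]
  if (all(out == labels[2]))
    warning("all values in the middle band; high/low groups empty")
  stats::setNames(out, names(values))
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimate per group and the two-sided log-rank
#' test between groups.
#'
#' @param time follow-up time (months).
#' @param event event indicator (TRUE/1 = death).
#' @param group group labels (two or more levels).
#' @return list of class `km_result`: `fit` ([survival::survfit()]
#'   object), `chisq`, `df`, `p`, `n_per_group`, `no_event_groups`
#'   (levels with zero events, flagged not dropped).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("need at least two groups")
  d <- data.frame(time = time, event = as.integer(event),
                  group = droplevels(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd$n) - 1L
  p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  ev <- tapply(d$event, d$group, sum)
  structure(list(fit = fit, chisq = unname(sd$chisq), df = df, p = p,
                 n_per_group = table(d$group),
                 no_event_groups = names(ev)[ev == 0]),
            class = "km_result")
}

#' Univariate Cox proportional-hazards fit
#'
#' Single-covariate partial-likelihood fit (Efron tie handling) reporting
#' the hazard ratio, its 95 percent Wald confidence interval and p value.
#'
#' @param time follow-up time.
#' @param event event indicator.
#' @param covariate numeric covariate (e.g. a cell-type proportion or CN
#'   prevalence); must have positive variance.
#' @param name covariate name for the report.
#' @return list of class `cox_result`: `name`, `coef`, `hr`, `ci_lower`,
#'   `ci_upper`, `se`, `p`, `n`, `converged`.
#' @export
cox_univariate <- function(time, event, covariate, name = "covariate") {
  if (stats::var(covariate, na.rm = TRUE) == 0)
    stop("covariate has zero variance")
  d <- data.frame(time = time, event = as.integer(event), x = covariate)
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  s <- summary(fit)
  conv <- is.finite(s$coefficients[1, "se(coef)"]) &&
    s$coefficients[1, "se(coef)"] < 50
  structure(list(name = name,
                 coef = unname(stats::coef(fit)[1]),
                 hr = unname(exp(stats::coef(fit)[1])),
                 ci_lower = unname(s$conf.int[1, "lower .95"]),
                 ci_upper = unname(s$conf.int[1, "upper .95"]),
                 se = unname(s$coefficients[1, "se(coef)"]),
                 p = unname(s$coefficients[1, "Pr(>|z|)"]),
                 n = s$n, converged = conv),
            class = "cox_result")
}

#' Spearman association between marker intensities
#'
#' Rank correlation (tie-corrected) between two per-sample intensity
#' summaries, e.g. a tumor-suppressor channel against an immune marker.
#'
#' @param x,y paired numeric vectors (n >= 5).
#' @return list: `rho`, `p`, `n`; `rho` is `NA` with a warning when either
#'   vector is constant.
#' @export
spearman_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Association table of continuous channels vs marker intensities
#'
#' All (channel x marker) Spearman correlations of per-sample mean
#' intensities, optionally within site groups.
#'
#' @param channel_means samples x channels matrix (e.g. BAP1, NF2, MTAP,
#'   LAG3 per-core means).
#' @param marker_means samples x markers matrix.
#' @param grouping optional named map sample -> group.
#' @return data.frame: group, channel, marker, rho, p, n.
#' @export
marker_association_table <- function(channel_means, marker_means,
                                     grouping = NULL) {
  stopifnot(nrow(channel_means) == nrow(marker_means))
  samples <- rownames(channel_means)
  groups <- if (is.null(grouping)) list(all = samples) else
    split(samples, grouping[samples])
  out <- list()
  for (g in names(groups)) {
    sel <- groups[[g]]
    for (ch in colnames(channel_means)) for (m in colnames(marker_means)) {
      r <- spearman_assoc(channel_means[sel, ch], marker_means[sel, m])
      out[[length(out) + 1L]] <- data.frame(
        group = g, channel = ch, marker = m,
        rho = r$rho, p = r$p, n = r$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Tumor-enriched core filter
#'
#' Retains cores whose tumor (pan-CK) proportion strictly exceeds the
#' threshold (default 20 percent); a core exactly at the threshold is
#' excluded.
#'
#' @param proportion_matrix cores x phenotypes proportion matrix.
#' @param tumor_label column holding the tumor proportion.
#' @param threshold minimum proportion, exclusive (default 0.20).
#' @return character vector of retained core ids.
#' @export
tumor_enriched_filter <- function(proportion_matrix, tumor_label = "Tumor",
                                  threshold = 0.20) {
  stopifnot(tumor_label %in% colnames(proportion_matrix))
  rownames(proportion_matrix)[proportion_matrix[, tumor_label] > threshold]
}

.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Format a percentage the way clinical summary tables print it
#'
#' Two significant figures, half-up: at or above 10 percent an integer,
#' below 10 percent one decimal (so 81/115 prints 70, 10/115 prints 8.7).
#'
#' @param count,total integers.
#' @return numeric percentage.
#' @export
summary_percent <- function(count, total) {
  pct <- 100 * count / total
  ifelse(pct >= 10 | pct == 0, .round_half_up(pct, 0), .round_half_up(pct, 1))
}

#' Cohort characteristics summary table
#'
#' Per-level counts and printed-style percentages for each categorical
#' clinical field, overall and per subgroup, plus median (IQR) of
#' survival months.
#'
#' @param clinical clinical data.frame (see [read_clinical()]).
#' @param fields categorical columns to summarize.
#' @param by optional subgroup column (e.g. contributing site).
#' @return list: `categorical` (data.frame subgroup, field, level, n,
#'   percent), `survival` (data.frame subgroup, median, q1, q3).
#' @export
cohort_summary_table <- function(clinical,
                                 fields = c("sex", "age_bin", "asbestos",
                                            "smoking", "site", "histology",
                                            "grade"),
                                 by = NULL) {
  fields <- intersect(fields, names(clinical))
  subsets <- list(Total = clinical)
  if (!is.null(by) && by %in% names(clinical))
    subsets <- c(subsets, split(clinical, clinical[[by]]))
  cat_rows <- list()
  surv_rows <- list()
  for (sg in names(subsets)) {
    d <- subsets[[sg]]
    total <- nrow(d)
    for (f in fields) {
      tab <- table(d[[f]])
      for (lev in names(tab)) {
        cnt <- as.integer(tab[[lev]])
        cat_rows[[length(cat_rows) + 1L]] <- data.frame(
          subgroup = sg, field = f, level = lev, n = cnt,
          percent = summary_percent(cnt, total), stringsAsFactors = FALSE)
      }
    }
    if ("survival_months" %in% names(d)) {
      q <- stats::quantile(d$survival_months, c(0.25, 0.5, 0.75),
                           na.rm = TRUE, type = 7)
      surv_rows[[length(surv_rows) + 1L]] <- data.frame(
        subgroup = sg, median = unname(q[2]), q1 = unname(q[1]),
        q3 = unname(q[3]))
    }
  }
  list(categorical = do.call(rbind, cat_rows),
       survival = if (length(surv_rows)) do.call(rbind, surv_rows) else NULL)
}
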