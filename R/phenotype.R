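#' Gate marker positivity by intensity threshold
#'
#' Adds one logical `pos_<marker>` column per thresholded channel:
#' a cell is positive when its intensity is strictly above the threshold
#' (a cell exactly at threshold is negative). Idempotent.
#'
#' @param cells cells data.frame with intensity columns.
#' @param gating a [gating_config()]; every marker used by the panel's
#'   rules must have a threshold.
#' @param panel `marker_panel` the cells belong to; defaults to gating all
#'   thresholded channels present in `cells`.
#' @return `cells` with `pos_*` columns added/overwritten.
#' @export
gate_positivity <- function(cells, gating, panel = NULL) {
  stopifnot(inherits(gating, "gating_config"))
  thr <- gating$thresholds
  if (!is.null(panel)) {
    need <- unique(unlist(lapply(panel$rules,
                                 function(r) c(r$require, r$forbid))))
    miss <- setdiff(need, names(thr))
    if (length(miss))
      stop("missing gating threshold for marker(s): ",
           paste(miss, collapse = ", "))
  }
  for (m in intersect(names(thr), names(cells)))
    cells[[paste0("pos_", m)]] <- !is.na(cells[[m]]) & cells[[m]] > thr[[m]]
  cells
}

#' Assign phenotypes from positivity calls
#'
#' Implements the marker-priority scheme used for the first-round lineage
#' panel: a cell positive for a single rule marker takes that rule's
#' label; composite co-positivity rules (CD4+FOXP3+ Treg, CD4+FOXP3- CD4 T)
#' are evaluated before the generic multi-positive resolution; a cell
#' positive for several markers takes the label of its highest-intensity
#' positive marker, excluding the tumor marker (pan-CK) from that argmax;
#' a cell positive only for the tumor marker is "Tumor"; a cell with no
#' positive rule marker is "unidentified". Intensity ties are broken by
#' panel marker order, so the result does not depend on column order.
#'
#' @param cells cells data.frame with `pos_*` columns (see
#'   [gate_positivity()]).
#' @param panel a `marker_panel`.
#' @return `cells` with a `phenotype` column.
#' @export
assign_cell_types <- function(cells, panel) {
  rule_single <- list()   # marker -> label; enters the intensity argmax
  rule_comp <- list()     # co-positivity rules, evaluated first
  for (r in panel$rules) {
    if (length(r$require) == 1L)
      rule_single[[r$require]] <- r$label
    else rule_comp[[length(rule_comp) + 1L]] <- r
  }
  markers <- panel$markers
  posmat <- sapply(markers, function(m) {
    cn <- paste0("pos_", m)
    if (cn %in% names(cells)) cells[[cn]] else rep(FALSE, nrow(cells))
  })
  if (is.null(dim(posmat))) posmat <- matrix(posmat, nrow = nrow(cells))
  colnames(posmat) <- markers
  intmat <- sapply(markers, function(m)
    if (m %in% names(cells)) cells[[m]] else rep(NA_real_, nrow(cells)))
  if (is.null(dim(intmat))) intmat <- matrix(intmat, nrow = nrow(cells))
  colnames(intmat) <- markers

  n <- nrow(cells)
  ph <- rep(NA_character_, n)

  # composite rules take precedence (co-positivity defines the type)
  for (r in rule_comp) {
    hit <- rep(TRUE, n)
    for (m in r$require) hit <- hit & posmat[, m]
    for (m in r$forbid) hit <- hit & !posmat[, m]
    ph[is.na(ph) & hit] <- r$label
  }

  rule_markers <- names(rule_single)
  argmax_markers <- setdiff(rule_markers, panel$tumor_marker)
  open <- which(is.na(ph))
  for (i in open) {
    pos_rule <- rule_markers[posmat[i, rule_markers]]
    if (length(pos_rule) == 0L) { ph[i] <- "unidentified"; next }
    cand <- intersect(argmax_markers, pos_rule)
    if (length(cand) == 0L) {
      # only the tumor marker is positive among rule markers
      ph[i] <- rule_single[[pos_rule[1]]]
    } else {
      best <- cand[which.max(intmat[i, cand])]  # first index wins ties:
      ph[i] <- rule_single[[best]]              # panel order is stable
    }
  }
  cells$phenotype <- ph
  cells
}

#' Merge the two staining panels' compositions
#'
#' The NK (CD56) and DC (CD11c) markers sit on the second panel, whose
#' cells are segmented independently of the first. The combined per-core
#' composition keeps panel 1's proportions, appends panel 2's NK and DC
#' proportions, and subtracts them from panel 1's "unidentified" share
#' (clamped at zero on noisy cores, with a warning); the result is
#' renormalized to sum to 1.
#'
#' @param p1 named proportions from panel 1, containing "unidentified".
#' @param p2 named proportions from panel 2 with entries `NK` and `DC`.
#' @return named numeric composition over panel-1 types plus NK and DC,
#'   summing to 1.
#' @export
merge_panel_compositions <- function(p1, p2) {
  if (any(c(p1, p2) < 0)) stop("proportions must be nonnegative")
  if (!"unidentified" %in% names(p1))
    stop("p1 must contain an 'unidentified' entry")
  nk <- if ("NK" %in% names(p2)) p2[["NK"]] else 0
  dc <- if ("DC" %in% names(p2)) p2[["DC"]] else 0
  adj <- p1[["unidentified"]] - nk - dc
  if (adj < 0) {
    warning("NK + DC proportions exceed panel-1 'unidentified'; clamped to 0")
    adj <- 0
  }
  out <- p1
  out[["unidentified"]] <- adj
  out[["NK"]] <- nk
  out[["DC"]] <- dc
  out / sum(out)
}
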