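#' Construct a marker panel
#'
#' A marker panel names the fluorescence channels measured in one staining
#' round and the positivity rules that translate marker calls into cell
#' phenotypes. Rules may require several markers to be simultaneously
#' positive and others negative (e.g. Tregs are CD4+FOXP3+, CD4 T cells are
#' CD4+FOXP3-). The tumor marker (pan-CK by convention) is recorded so that
#' downstream phenotype assignment can exclude it from intensity
#' tie-breaking among immune markers.
#'
#' @param panel_id character scalar identifying the panel.
#' @param markers character vector of channel names, in panel order. The
#'   order is meaningful: intensity ties during phenotype assignment are
#'   broken by panel order.
#' @param rules list of rules created by [phenotype_rule()]. Labels must be
#'   unique and every referenced marker must be in `markers`.
#' @param tumor_marker channel excluded from the highest-intensity
#'   tie-break, or `NA` if the panel carries no tumor marker.
#' @param continuous_channels channels measured for their intensity only
#'   (no positivity rule), e.g. tumor-suppressor protein stains.
#' @return An object of class `marker_panel`.
#' @seealso [default_panels()] for the two-round mesothelioma panel set.
#' @export
marker_panel <- function(panel_id, markers, rules, tumor_marker = NA_character_,
                         continuous_channels = character()) {
  stopifnot(is.character(panel_id), length(panel_id) == 1L,
            is.character(markers), length(markers) >= 1L,
            !anyDuplicated(markers))
  labels <- vapply(rules, function(r) r$label, character(1))
  if (anyDuplicated(labels))
    stop("phenotype labels must be unique within a panel")
  for (r in rules) {
    bad <- setdiff(c(r$require, r$forbid), markers)
    if (length(bad))
      stop("rule '", r$label, "' references markers not in the panel: ",
           paste(bad, collapse = ", "))
  }
  if (!is.na(tumor_marker) && !tumor_marker %in% markers)
    stop("tumor_marker must be one of the panel markers")
  if (length(bad <- setdiff(continuous_channels, markers)))
    stop("continuous channels not in panel: ", paste(bad, collapse = ", "))
  structure(list(panel_id = panel_id, markers = markers, rules = rules,
                 tumor_marker = tumor_marker,
                 continuous_channels = continuous_channels),
            class = "marker_panel")
}

#' Define one phenotype rule
#'
#' @param label phenotype name the rule assigns.
#' @param require markers that must be positive.
#' @param forbid markers that must be negative.
#' @return A list with elements `label`, `require`, `forbid`.
#' @export
phenotype_rule <- function(label, require, forbid = character()) {
  stopifnot(is.character(label), length(label) == 1L, length(require) >= 1L)
  list(label = label, require = require, forbid = forbid)
}

#' The two-round mesothelioma mIF panel set
#'
#' Panel 1 carries the six lineage markers scored in the first staining
#' round (pan-CK tumor cells, CD20 B cells, CD4 and CD8 T cells, FOXP3 for
#' Tregs, CD68 macrophages); panel 2 carries the dendritic-cell and NK
#' markers (CD11c, CD56) together with four continuous protein channels
#' (BAP1, NF2, MTAP, LAG3) that receive no phenotype rule.
#'
#' @return Named list with elements `panel1` and `panel2`.
#' @export
default_panels <- function() {
  p1 <- marker_panel(
    panel_id = "panel1",
    markers = c("panCK", "CD20", "CD4", "CD8", "FOXP3", "CD68"),
    rules = list(
      phenotype_rule("Treg",       require = c("CD4", "FOXP3")),
      phenotype_rule("CD4 T",      require = "CD4", forbid = "FOXP3"),
      phenotype_rule("CD8 T",      require = "CD8"),
      phenotype_rule("B",          require = "CD20"),
      phenotype_rule("Macrophage", require = "CD68"),
      phenotype_rule("Tumor",      require = "panCK")
    ),
    tumor_marker = "panCK")
  p2 <- marker_panel(
    panel_id = "panel2",
    markers = c("CD11c", "CD56", "BAP1", "NF2", "MTAP", "LAG3"),
    rules = list(
      phenotype_rule("DC", require = "CD11c"),
      phenotype_rule("NK", require = "CD56")
    ),
    continuous_channels = c("BAP1", "NF2", "MTAP", "LAG3"))
  list(panel1 = p1, panel2 = p2)
}

#' Phenotype labels a panel can assign
#'
#' @param panel a `marker_panel`.
#' @param unidentified include the fallback label for cells with no
#'   positive marker.
#' @return character vector of labels.
#' @export
panel_labels <- function(panel, unidentified = TRUE) {
  lab <- vapply(panel$rules, function(r) r$label, character(1))
  if (unidentified) c(lab, "unidentified") else lab
}

#' Gating configuration
#'
#' Intensity thresholds per channel; a cell is positive for a marker when
#' its intensity is strictly above the threshold.
#'
#' @param thresholds named numeric vector, channel -> nonnegative threshold.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(thresholds) {
  stopifnot(is.numeric(thresholds), !is.null(names(thresholds)),
            all(thresholds >= 0))
  structure(list(thresholds = thresholds), class = "gating_config")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>", x$panel_id, "\n markers:",
      paste(x$markers, collapse = ", "), "\n rules:",
      paste(vapply(x$rules, `[[`, character(1), "label"), collapse = ", "),
      "\n")
  invisible(x)
}
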