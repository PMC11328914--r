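#' Assemble an mIF cohort
#'
#' The cohort is the unit every pipeline stage consumes: a per-cell table
#' pooled across cores and staining panels, per-core metadata, the clinical
#' table, and the panel definitions.
#'
#' @param cells data.frame with one row per segmented cell: `cell_id`,
#'   `core_id`, `panel_id`, centroid `x`, `y` (micrometres, origin at the
#'   core bounding-box corner), one intensity column per channel, and
#'   optionally `phenotype` and logical `pos_<marker>` columns.
#' @param cores data.frame: `core_id`, `patient_id`, `tissue_area` (mm^2).
#' @param clinical data.frame of per-patient covariates and outcome, as
#'   returned by [read_clinical()]; may be `NULL` for core-only work.
#' @param panels named list of [marker_panel()] objects.
#' @return An object of class `mif_cohort`.
#' @export
mif_cohort <- function(cells, cores, clinical = NULL, panels = default_panels()) {
  need <- c("cell_id", "core_id", "panel_id", "x", "y")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
    stop("cell coordinates must be finite")
  miss <- setdiff(c("core_id", "patient_id", "tissue_area"), names(cores))
  if (length(miss)) stop("cores table lacks columns: ", paste(miss, collapse = ", "))
  if (any(cores$tissue_area <= 0)) stop("tissue_area must be positive")
  if (anyDuplicated(cores$core_id)) stop("duplicate core_id in cores table")
  structure(list(cells = cells, cores = cores, clinical = clinical,
                 panels = panels),
            class = "mif_cohort")
}

#' @export
print.mif_cohort <- function(x, ...) {
  cat("<mif_cohort>", nrow(x$cells), "cells,", nrow(x$cores), "cores,",
      if (is.null(x$clinical)) 0L else nrow(x$clinical), "patients\n")
  invisible(x)
}

#' Area of the default circular TMA core
#'
#' @param radius_um core radius in micrometres (default 300, i.e. the
#'   0.6 mm punch used on the arrays this pipeline targets).
#' @return area in mm^2.
#' @export
core_disc_area <- function(radius_um = 300) pi * (radius_um / 1000)^2

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(",")
  if (lengths(regmatches(first, gregexpr("\t", first))) >
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read a per-cell measurement table
#'
#' Reads a delimited text export (comma- or tab-separated, auto-detected)
#' with one row per segmented cell. Column names are mapped through
#' `dialect` so that real phenotyping-software exports and synthetic
#' fixtures share one reader. Rows are never silently dropped: the returned
#' table has exactly one row per input row.
#'
#' @param path file path.
#' @param panel `marker_panel` whose markers name the intensity columns.
#' @param dialect named character vector mapping canonical names
#'   (`cell_id`, `core_id`, `x`, `y`, marker names, optionally `phenotype`,
#'   `tissue_area`) to the file's column names. Defaults to the identity.
#' @param tissue_area fallback area (mm^2) per core when the file has no
#'   area column; default is the 0.6 mm disc area.
#' @return list with `cells` (data.frame) and `cores` (data.frame with
#'   core_id, tissue_area); phenotype strings not in the panel vocabulary
#'   are mapped to "unidentified" with a warning.
#' @export
read_cell_table <- function(path, panel, dialect = NULL,
                            tissue_area = core_disc_area()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty input: ", path)

  canon <- c("cell_id", "core_id", "x", "y", panel$markers)
  map <- stats::setNames(canon, canon)
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  mandatory <- c("cell_id", "core_id", "x", "y", panel$markers)
  for (cn in mandatory) {
    if (!map[[cn]] %in% names(raw))
      stop("missing mandatory column: ", cn, " (file column '", map[[cn]], "')")
  }
  get <- function(cn) raw[[map[[cn]]]]

  for (cn in c("x", "y")) {
    v <- suppressWarnings(as.numeric(get(cn)))
    bad <- which(is.na(v) & !is.na(get(cn)) | !is.finite(v))
    if (length(bad))
      stop("non-numeric ", cn, " coordinate at row ", bad[1])
  }

  cells <- data.frame(cell_id = as.character(get("cell_id")),
                      core_id = as.character(get("core_id")),
                      panel_id = panel$panel_id,
                      x = as.numeric(get("x")), y = as.numeric(get("y")),
                      stringsAsFactors = FALSE)
  for (m in panel$markers) {
    v <- as.numeric(get(m))
    if (any(v < 0, na.rm = TRUE)) stop("negative intensity in channel ", m)
    cells[[m]] <- v
  }
  ph_col <- if (!is.null(dialect) && "phenotype" %in% names(dialect))
    dialect[["phenotype"]] else "phenotype"
  if (ph_col %in% names(raw)) {
    ph <- as.character(raw[[ph_col]])
    known <- panel_labels(panel)
    unk <- !(ph %in% known)
    if (any(unk)) {
      warning(sum(unk), " cells with phenotype outside the panel vocabulary",
              " mapped to 'unidentified'")
      ph[unk] <- "unidentified"
    }
    cells$phenotype <- ph
  }

  area_col <- if (!is.null(dialect) && "tissue_area" %in% names(dialect))
    dialect[["tissue_area"]] else "tissue_area"
  ids <- unique(cells$core_id)
  if (area_col %in% names(raw)) {
    area <- vapply(ids, function(i)
      as.numeric(raw[[area_col]][match(i, cells$core_id)]), numeric(1))
  } else {
    area <- rep(tissue_area, length(ids))
  }
  cores <- data.frame(core_id = ids, tissue_area = area,
                      stringsAsFactors = FALSE)
  list(cells = cells, cores = cores)
}

#' Write a per-cell table as CSV
#'
#' Inverse of [read_cell_table()]: columns are written under their
#' canonical names so the round trip is the identity up to floating-point
#' formatting (full precision is kept).
#'
#' @param cells cells data.frame (one panel).
#' @param path output file.
#' @param cores optional cores data.frame; when given, a `tissue_area`
#'   column is added.
#' @export
write_cell_table <- function(cells, path, cores = NULL) {
  out <- cells
  out$panel_id <- NULL
  if (!is.null(cores))
    out$tissue_area <- cores$tissue_area[match(out$core_id, cores$core_id)]
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.site_vocab <- c(MPM = "MPM", Pleural = "MPM", pleural = "MPM",
                 MPeM = "MPeM", Peritoneal = "MPeM", peritoneal = "MPeM")

#' Read the clinical metadata table
#'
#' One row per patient: site of origin (pleural/peritoneal/other),
#' histology, grade, sex, age bin, asbestos exposure, smoking status,
#' overall survival in months and the event indicator. Unknown categorical
#' values are kept as "unknown"; site synonyms (Pleural/Peritoneal) are
#' normalized to MPM/MPeM.
#'
#' @param path CSV file with a `patient_id` column.
#' @return data.frame of class `mif_clinical`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(d)) stop("missing mandatory column: patient_id")
  d$patient_id <- as.character(d$patient_id)
  if (anyDuplicated(d$patient_id))
    stop("duplicate patient_id: ",
         d$patient_id[duplicated(d$patient_id)][1])
  if ("site" %in% names(d)) {
    mapped <- .site_vocab[d$site]
    d$site <- ifelse(is.na(mapped),
                     ifelse(d$site %in% "other", "other", "other"), mapped)
  }
  for (cn in c("histology", "grade", "sex", "age_bin", "asbestos", "smoking"))
    if (cn %in% names(d)) {
      v <- as.character(d[[cn]])
      v[is.na(v) | v == ""] <- "unknown"
      d[[cn]] <- v
    }
  if ("survival_months" %in% names(d)) {
    d$survival_months <- as.numeric(d$survival_months)
    if (any(d$survival_months < 0, na.rm = TRUE))
      stop("negative survival_months")
  }
  if ("event" %in% names(d)) d$event <- as.logical(as.integer(d$event))
  class(d) <- c("mif_clinical", "data.frame")
  d
}

#' Write the clinical table as CSV
#' @param clinical clinical data.frame.
#' @param path output file.
#' @export
write_clinical <- function(clinical, path) {
  out <- as.data.frame(clinical)
  out$event <- as.integer(out$event)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a cohort before spatial analysis
#'
#' Report-only consistency check: cores whose patient has no clinical
#' record, cores below the minimum cell count at which the spatial stages
#' (Delaunay triangulation, neighborhood k-means) are reliable, and
#' duplicated cell coordinates within a core. Flagged cores are not
#' removed; callers decide.
#'
#' @param cohort an `mif_cohort`.
#' @param min_cells minimum cells per core for spatial stages (default 50).
#' @return data.frame with columns `issue`, `core_id`, `detail`; zero rows
#'   when the cohort is fully consistent.
#' @export
validate_cohort <- function(cohort, min_cells = 50) {
  out <- data.frame(issue = character(), core_id = character(),
                    detail = character(), stringsAsFactors = FALSE)
  add <- function(issue, core_id, detail)
    rbind(out, data.frame(issue = issue, core_id = core_id, detail = detail,
                          stringsAsFactors = FALSE))
  if (!is.null(cohort$clinical)) {
    orphan <- setdiff(cohort$cores$patient_id, cohort$clinical$patient_id)
    for (p in orphan) {
      ids <- cohort$cores$core_id[cohort$cores$patient_id == p]
      for (i in ids) out <- add("orphan_core", i, paste("patient", p, "absent"))
    }
  }
  tab <- table(cohort$cells$core_id)
  for (i in cohort$cores$core_id) {
    n <- if (i %in% names(tab)) as.integer(tab[[i]]) else 0L
    if (n < min_cells)
      out <- add("low_cell_count", i, paste0(n, " cells (< ", min_cells, ")"))
  }
  for (i in unique(cohort$cells$core_id)) {
    sub <- cohort$cells[cohort$cells$core_id == i, c("x", "y")]
    if (anyDuplicated(sub))
      out <- add("duplicate_coordinates", i,
                 paste(sum(duplicated(sub)), "duplicated positions"))
  }
  out
}
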