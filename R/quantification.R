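# Per-patient, compartment-resolved densities and marker-positive fractions.
# Patient aggregation is pooled over fields: (sum of counts) / (sum of
# areas), never a mean of per-field densities. Cells in compartment "other"
# never enter numerators or denominators.

.density_compartments <- c("epithelium", "stroma")
.fraction_parents <- c("T", "Th", "Treg", "CD8T")
.fraction_markers <- c("Ki67", "GrB")

.require_gated <- function(cells) {
  missing <- setdiff(c(phenotype_categories(), "grb_pos"), names(cells))
  if (length(missing) > 0) {
    stop(sprintf("cells are not gated (missing column(s) %s); call gate_cohort() first",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(cells)
}

.area_col <- function(compartment) paste0("area_", compartment)

#' Density of a phenotype category in one compartment of one patient
#'
#' Pools the patient's fields: density = (total cells of `category` lying in
#' `compartment`) / (total `compartment` area over the fields), in cells/mm^2.
#'
#' @param cells Gated cell table (see [gate_cohort()]).
#' @param fields Field summary table (see [read_field_summary()]).
#' @param category One of [phenotype_categories()].
#' @param compartment `"epithelium"` or `"stroma"`.
#' @param patient Patient ID.
#' @return Density in cells/mm^2, or `NA` (with a `"reason"` attribute
#'   `"zero_area"`) when the pooled compartment area is zero.
#' @export
compute_density <- function(cells, fields, category, compartment, patient) {
  .require_gated(cells)
  stopifnot(category %in% phenotype_categories(),
            compartment %in% .density_compartments)
  f <- fields[fields$patient_id == patient, , drop = FALSE]
  area <- sum(f[[.area_col(compartment)]])
  cc <- cells[cells$patient_id == patient & cells$compartment == compartment, ,
              drop = FALSE]
  count <- sum(cc[[category]])
  if (!(area > 0)) {
    out <- NA_real_
    attr(out, "reason") <- "zero_area"
    return(out)
  }
  count / area
}

#' Marker-positive fraction within a parent category
#'
#' Percentage of `parent`-category cells in `compartment` that are positive
#' for `marker` (`"Ki67"` or `"GrB"`), pooled over the patient's fields.
#'
#' @inheritParams compute_density
#' @param parent Parent category (one of `T`, `Th`, `Treg`, `CD8T`).
#' @param marker `"Ki67"` or `"GrB"`.
#' @return Percentage in `[0, 100]`, or `NA` (with `"reason"` attribute
#'   `"no_parent_cells"`) when the parent count is zero.
#' @export
compute_fraction <- function(cells, parent, marker, compartment, patient) {
  .require_gated(cells)
  stopifnot(parent %in% phenotype_categories(),
            marker %in% .fraction_markers,
            compartment %in% .density_compartments)
  cc <- cells[cells$patient_id == patient & cells$compartment == compartment, ,
              drop = FALSE]
  in_parent <- cc[[parent]]
  n_parent <- sum(in_parent)
  if (n_parent == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no_parent_cells"
    return(out)
  }
  pos <- if (marker == "Ki67") cc$ki67 else cc$grb_pos
  100 * sum(in_parent & pos) / n_parent
}

#' Full per-patient metric table: densities and fractions
#'
#' Computes the complete grid of densities (all ten categories x
#' epithelium/stroma x patients) and marker-positive fractions (parents
#' `T`, `Th`, `Treg`, `CD8T` x markers Ki67/GrB x compartments x patients).
#' Undefined combinations are kept with `NA` values and a reason code,
#' never dropped.
#'
#' @inheritParams compute_density
#' @return A list with two data frames:
#' \describe{
#'   \item{density}{`patient_id`, `category`, `compartment`, `count`,
#'     `area_mm2`, `density` (cells/mm^2), `reason`.}
#'   \item{fraction}{`patient_id`, `parent`, `marker`, `compartment`,
#'     `n_parent`, `n_positive`, `percent`, `reason`.}
#' }
#' @export
build_metric_table <- function(cells, fields) {
  .require_gated(cells)
  patients <- sort(unique(fields$patient_id))
  cats <- phenotype_categories()

  dens <- expand.grid(patient_id = patients, category = cats,
                      compartment = .density_compartments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(dens) > 0) {
    area_by <- lapply(.density_compartments, function(cp) {
      tapply(fields[[.area_col(cp)]], fields$patient_id, sum)
    })
    names(area_by) <- .density_compartments
    keep <- cells$compartment %in% .density_compartments
    cc <- cells[keep, , drop = FALSE]
    dens$count <- mapply(function(p, cat, cp) {
      sum(cc[[cat]][cc$patient_id == p & cc$compartment == cp])
    }, dens$patient_id, dens$category, dens$compartment)
    dens$area_mm2 <- mapply(function(p, cp) {
      a <- area_by[[cp]][p]
      if (is.na(a)) 0 else unname(a)
    }, dens$patient_id, dens$compartment)
    dens$density <- ifelse(dens$area_mm2 > 0, dens$count / dens$area_mm2, NA_real_)
    dens$reason <- ifelse(dens$area_mm2 > 0, "", "zero_area")
  } else {
    dens$count <- integer(0); dens$area_mm2 <- numeric(0)
    dens$density <- numeric(0); dens$reason <- character(0)
  }

  frac <- expand.grid(patient_id = patients, parent = .fraction_parents,
                      marker = .fraction_markers,
                      compartment = .density_compartments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(frac) > 0) {
    res <- mapply(function(p, parent, marker, cp) {
      cc <- cells[cells$patient_id == p & cells$compartment == cp, , drop = FALSE]
      in_parent <- cc[[parent]]
      pos <- if (marker == "Ki67") cc$ki67 else cc$grb_pos
      c(sum(in_parent), sum(in_parent & pos))
    }, frac$patient_id, frac$parent, frac$marker, frac$compartment)
    frac$n_parent <- res[1, ]
    frac$n_positive <- res[2, ]
    frac$percent <- ifelse(frac$n_parent > 0,
                           100 * frac$n_positive / frac$n_parent, NA_real_)
    frac$reason <- ifelse(frac$n_parent > 0, "", "no_parent_cells")
  } else {
    frac$n_parent <- integer(0); frac$n_positive <- integer(0)
    frac$percent <- numeric(0); frac$reason <- character(0)
  }

  list(density = dens, fraction = frac)
}

#' Reshape a long density table to a patient-by-metric matrix
#'
#' Metric columns are named `density_<category>_<compartment>`. Used to feed
#' the inter-metric and metric-expression correlation analyses.
#'
#' @param density Long density table from [build_metric_table()].
#' @return Numeric matrix, patients in rows, metrics in columns.
#' @export
density_wide <- function(density) {
  patients <- sort(unique(density$patient_id))
  key <- paste0("density_", density$category, "_", density$compartment)
  cols <- unique(key)
  out <- matrix(NA_real_, nrow = length(patients), ncol = length(cols),
                dimnames = list(patients, cols))
  out[cbind(match(density$patient_id, patients), match(key, cols))] <- density$density
  out
}
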