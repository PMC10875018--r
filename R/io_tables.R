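# Tabular IO. Canonical dialect for every reader/writer: TSV, UTF-8, "."
# decimal, mandatory header row. Numerics are serialized with 17 significant
# digits so write -> read reproduces doubles exactly.

.compartments <- c("epithelium", "stroma", "other")

.cell_cols <- c("patient_id", "field_id", "x", "y", "compartment",
                "cd3", "cd8", "foxp3", "ki67", "ck", "grb_intensity")
.field_cols <- c("patient_id", "field_id", "area_epithelium", "area_stroma",
                 "area_other", "epithelium_fraction")
.clinical_cols <- c("patient_id", "os_time", "os_event", "pfs_time",
                    "pfs_event", "age", "sex", "side", "adjuvant", "ajcc",
                    "msi", "cms", "icr")
.clinical_enums <- list(
  sex  = c("male", "female"),
  side = c("right", "left"),
  ajcc = c("I", "II", "III", "IV"),
  msi  = c("MSI-H", "MSS"),
  cms  = c("CMS1", "CMS2", "CMS3", "CMS4", "Mixed"),
  icr  = c("Low", "Medium", "High")
)

.read_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
}

.check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

.as_num <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop(sprintf("validation error in %s: column '%s' non-numeric at row %d",
                 path, col, bad[1]), call. = FALSE)
  }
  out
}

.as_bool <- function(x, col, path) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "0")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("validation error in %s: column '%s' not boolean at row %d",
                 path, col, bad[1]), call. = FALSE)
  }
  as.logical(out)
}

.check_enum <- function(x, allowed, col, path) {
  bad <- which(!(x %in% allowed))
  if (length(bad) > 0) {
    stop(sprintf(
      "validation error in %s: column '%s' value '%s' at row %d not in {%s}",
      path, col, x[bad[1]], bad[1], paste(allowed, collapse = ", ")),
      call. = FALSE)
  }
  x
}

.check_range <- function(x, lo, hi, col, path, finite = TRUE) {
  bad <- which((finite & !is.finite(x)) | x < lo | x > hi)
  if (length(bad) > 0) {
    stop(sprintf("validation error in %s: column '%s' value %s at row %d outside [%g, %g]",
                 path, col, format(x[bad[1]]), bad[1], lo, hi), call. = FALSE)
  }
  x
}

.write_tsv <- function(df, path) {
  df2 <- df
  for (col in names(df2)) {
    if (is.numeric(df2[[col]]) && !is.integer(df2[[col]])) {
      df2[[col]] <- sprintf("%.17g", df2[[col]])
      df2[[col]][is.na(df[[col]])] <- "NA"
    }
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-cell segmentation table
#'
#' Reads a TSV with one row per segmented cell. Required columns:
#' `patient_id`, `field_id`, `x`, `y` (coordinates in micrometres, origin at
#' the top-left of each field, y increasing downward), `compartment`
#' (`epithelium`/`stroma`/`other`), logical marker calls `cd3`, `cd8`,
#' `foxp3`, `ki67`, `ck`, and `grb_intensity` in `[0, 1]`. Every malformed
#' row raises a located error; rows are never dropped silently.
#'
#' @param path Path to the TSV file.
#' @param coord_scale Multiplier applied to `x` and `y` on read (e.g. a
#'   pixel-to-micrometre factor for exports in pixels). Default 1 (already µm).
#' @return A validated `data.frame` of cells.
#' @export
read_cell_table <- function(path, coord_scale = 1) {
  df <- .read_tsv(path)
  .check_columns(df, .cell_cols, path)
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    field_id = as.character(df$field_id),
    x = .as_num(df$x, "x", path) * coord_scale,
    y = .as_num(df$y, "y", path) * coord_scale,
    compartment = .check_enum(df$compartment, .compartments, "compartment", path),
    stringsAsFactors = FALSE
  )
  for (col in c("cd3", "cd8", "foxp3", "ki67", "ck")) {
    out[[col]] <- .as_bool(df[[col]], col, path)
  }
  out$grb_intensity <- .check_range(.as_num(df$grb_intensity, "grb_intensity", path),
                                    0, 1, "grb_intensity", path)
  .check_range(out$x, 0, Inf, "x", path)
  .check_range(out$y, 0, Inf, "y", path)
  out
}

#' Write a per-cell table
#' @param cells Cell table as returned by [read_cell_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  .write_tsv(cells[, .cell_cols], path)
}

#' Read a per-field compartment area table
#'
#' Required columns: `patient_id`, `field_id`, `area_epithelium`,
#' `area_stroma`, `area_other` (mm^2) and `epithelium_fraction`, which must
#' equal `area_epithelium / (sum of the three areas)` within 1e-9.
#'
#' @param path Path to the TSV file.
#' @return A validated `data.frame` of field summaries.
#' @export
read_field_summary <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, .field_cols, path)
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    field_id = as.character(df$field_id),
    stringsAsFactors = FALSE
  )
  for (col in c("area_epithelium", "area_stroma", "area_other")) {
    out[[col]] <- .check_range(.as_num(df[[col]], col, path), 0, Inf, col, path)
  }
  out$epithelium_fraction <- .check_range(
    .as_num(df$epithelium_fraction, "epithelium_fraction", path),
    0, 1, "epithelium_fraction", path)
  total <- out$area_epithelium + out$area_stroma + out$area_other
  expected <- ifelse(total > 0, out$area_epithelium / total, 0)
  bad <- which(abs(expected - out$epithelium_fraction) > 1e-9)
  if (length(bad) > 0) {
    stop(sprintf("validation error in %s: epithelium_fraction inconsistent with areas at row %d (expected %.12g, got %.12g)",
                 path, bad[1], expected[bad[1]], out$epithelium_fraction[bad[1]]),
         call. = FALSE)
  }
  out
}

#' Write a per-field summary table
#' @param fields Field table as returned by [read_field_summary()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_field_summary <- function(fields, path) {
  .write_tsv(fields[, .field_cols], path)
}

#' Read a gene-by-patient expression matrix
#'
#' First column holds gene symbols; every remaining column is one patient.
#' Duplicate gene symbols are an error.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows (rownames = symbols), patients in
#'   columns (colnames = patient IDs).
#' @export
read_expression_matrix <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) {
    stop(sprintf("schema error in %s: need a gene column plus >=1 patient column", path),
         call. = FALSE)
  }
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop(sprintf("validation error in %s: duplicate gene symbol(s): %s",
                 path, paste(dup, collapse = ", ")), call. = FALSE)
  }
  vals <- sapply(names(df)[-1], function(col) .as_num(df[[col]], col, path))
  vals <- matrix(vals, nrow = length(genes),
                 dimnames = list(genes, names(df)[-1]))
  vals
}

#' Write a gene-by-patient expression matrix
#' @param expr Numeric matrix with gene rownames and patient colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), stringsAsFactors = FALSE)
  for (p in colnames(expr)) df[[p]] <- expr[, p]
  .write_tsv(df, path)
}

#' Read a clinical/outcome table
#'
#' Required columns: `patient_id`; `os_time`, `pfs_time` (years, strictly
#' positive); `os_event`, `pfs_event`, `adjuvant` (logical); `age` (years);
#' and closed enums `sex` (male/female), `side` (right/left), `ajcc`
#' (I--IV), `msi` (MSI-H/MSS), `cms` (CMS1--CMS4/Mixed), `icr`
#' (Low/Medium/High).
#'
#' @param path Path to the TSV file.
#' @return A validated `data.frame` of clinical records.
#' @export
read_clinical_table <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, .clinical_cols, path)
  out <- data.frame(patient_id = as.character(df$patient_id),
                    stringsAsFactors = FALSE)
  for (col in c("os_time", "pfs_time")) {
    v <- .as_num(df[[col]], col, path)
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0) {
      stop(sprintf("validation error in %s: column '%s' must be > 0 at row %d",
                   path, col, bad[1]), call. = FALSE)
    }
    out[[col]] <- v
  }
  for (col in c("os_event", "pfs_event", "adjuvant")) {
    out[[col]] <- .as_bool(df[[col]], col, path)
  }
  out$age <- .check_range(.as_num(df$age, "age", path), 0, 150, "age", path)
  for (col in names(.clinical_enums)) {
    out[[col]] <- .check_enum(as.character(df[[col]]), .clinical_enums[[col]], col, path)
  }
  out[, .clinical_cols]
}

#' Write a clinical table
#' @param clinical Clinical table as returned by [read_clinical_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  .write_tsv(clinical[, .clinical_cols], path)
}
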