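# Nearest-neighbor distance machinery. All distances are within-field
# Euclidean distances in micrometres; fields are separate images, so
# distances never cross field boundaries. The per-patient summary is the
# median of per-cell distances POOLED across the patient's fields.

#' Pairwise Euclidean distance matrix for one field
#'
#' @param x,y Coordinate vectors (µm) of cells from a single field.
#' @param field_id Optional vector of field IDs; an error is raised if more
#'   than one field is present (cross-field distances are undefined).
#' @return Symmetric matrix of Euclidean distances with zero diagonal.
#' @export
pairwise_distances <- function(x, y, field_id = NULL) {
  if (length(x) == 0) stop("need at least one point", call. = FALSE)
  stopifnot(length(x) == length(y))
  if (!is.null(field_id) && length(unique(field_id)) > 1) {
    stop("points from multiple fields; cross-field distances are undefined",
         call. = FALSE)
  }
  as.matrix(stats::dist(cbind(x, y)))
}

# Vectorized nearest-neighbor core for one field. Computes, for each source
# point, the distance to the nearest target point, optionally excluding the
# target with the same cell id (self-exclusion when categories overlap).
# Chunked so memory stays bounded for large fields.
.nn_core <- function(sx, sy, tx, ty, source_ids = NULL, target_ids = NULL,
                     chunk = 512L) {
  ns <- length(sx)
  nt <- length(tx)
  if (ns == 0) return(numeric(0))
  out <- rep(NA_real_, ns)
  if (nt == 0) return(out)
  exclude_self <- !is.null(source_ids) && !is.null(target_ids)
  for (start in seq(1L, ns, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ns)
    d2 <- outer(sx[idx], tx, "-")^2 + outer(sy[idx], ty, "-")^2
    if (exclude_self) {
      self <- outer(source_ids[idx], target_ids, "==")
      d2[self] <- Inf
    }
    m <- apply(d2, 1, min)
    out[idx] <- ifelse(is.finite(m), sqrt(m), NA_real_)
  }
  out
}

#' Nearest-neighbor distances from source points to target points
#'
#' For each source point, the Euclidean distance to the nearest target point
#' in the same field. A cell present in both sets (matching `source_ids` /
#' `target_ids`) is never its own nearest neighbor: the distance to the
#' nearest *other* target is used, and the value is `NA` when no other
#' target exists.
#'
#' @param sx,sy Source coordinates (µm).
#' @param tx,ty Target coordinates (µm), same field.
#' @param source_ids,target_ids Optional cell identifiers used for
#'   self-exclusion when the source and target categories overlap.
#' @return Numeric vector, one nearest distance per source point (`NA` when
#'   no eligible target exists).
#' @export
nn_distance <- function(sx, sy, tx, ty, source_ids = NULL, target_ids = NULL) {
  stopifnot(length(sx) == length(sy), length(tx) == length(ty))
  .nn_core(sx, sy, tx, ty, source_ids, target_ids)
}

# Per-cell NN distances for one patient between two gated categories,
# field by field. Returns a numeric vector pooled over fields.
.patient_nn <- function(cells, patient, source_category, target_category,
                        source_filter = NULL) {
  pc <- cells[cells$patient_id == patient, , drop = FALSE]
  out <- numeric(0)
  for (fid in unique(pc$field_id)) {
    fc <- pc[pc$field_id == fid, , drop = FALSE]
    ids <- seq_len(nrow(fc))
    src <- which(fc[[source_category]] &
                   (if (is.null(source_filter)) TRUE else source_filter(fc)))
    tgt <- which(fc[[target_category]])
    if (length(src) == 0 || length(tgt) == 0) next
    d <- .nn_core(fc$x[src], fc$y[src], fc$x[tgt], fc$y[tgt],
                  source_ids = ids[src], target_ids = ids[tgt])
    out <- c(out, d[!is.na(d)])
  }
  out
}

#' Nearest-tumor-cell distances for non-intraepithelial source cells
#'
#' Per-cell distances from cells of `source_category` to the nearest tumor
#' (CK+) cell in the same field. Only source cells whose centroid lies
#' *outside* the tumor epithelium contribute (intraepithelial T cells are
#' excluded because their tumor distances are dominated by being inside the
#' epithelium); target tumor cells are used regardless of compartment.
#' Fields without tumor cells contribute nothing.
#'
#' @param cells Gated cell table for the cohort.
#' @param patient Patient ID.
#' @param source_category Source phenotype category.
#' @return Numeric vector of per-cell distances (µm), pooled over the
#'   patient's fields; length 0 if no field qualifies.
#' @export
nn_to_tumor <- function(cells, patient, source_category) {
  .require_gated(cells)
  .patient_nn(cells, patient, source_category, "Tumor",
              source_filter = function(fc) fc$compartment != "epithelium")
}

#' Nearest-neighbor distances between two T-cell categories
#'
#' Per-cell distances from `source_category` cells to the nearest
#' `target_category` cell in the same field, with self-exclusion when the
#' categories overlap. No compartment restriction is applied.
#'
#' @inheritParams nn_to_tumor
#' @param target_category Target phenotype category.
#' @return Numeric vector of per-cell distances (µm), pooled over fields.
#' @export
nn_between <- function(cells, patient, source_category, target_category) {
  .require_gated(cells)
  .patient_nn(cells, patient, source_category, target_category)
}

#' Per-patient median nearest-neighbor distance summaries
#'
#' Builds the long table of per-patient median NN distances for every
#' requested (source, target) pair. The patient value is the median of the
#' per-cell distances pooled across that patient's fields; patients with no
#' contributing cells carry `NA` with a reason code.
#'
#' @param cells Gated cell table.
#' @param pairs Data frame with columns `source` and `target` (category
#'   names; target `"Tumor"` applies the non-intraepithelial restriction).
#'   Defaults to all nine T-cell categories vs `Tumor` plus the
#'   Treg/Th/CD8T inter-subset pairs.
#' @return Data frame: `patient_id`, `source`, `target`, `n_source_cells`,
#'   `median_distance` (µm), `reason`.
#' @export
summarize_patient_distances <- function(cells, pairs = default_distance_pairs()) {
  .require_gated(cells)
  patients <- sort(unique(cells$patient_id))
  out <- expand.grid(patient_id = patients, pair = seq_len(nrow(pairs)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$source <- pairs$source[out$pair]
  out$target <- pairs$target[out$pair]
  out$pair <- NULL
  res <- mapply(function(p, s, t) {
    d <- if (t == "Tumor") nn_to_tumor(cells, p, s) else nn_between(cells, p, s, t)
    c(length(d), if (length(d) > 0) stats::median(d) else NA_real_)
  }, out$patient_id, out$source, out$target)
  out$n_source_cells <- as.integer(res[1, ])
  out$median_distance <- res[2, ]
  out$reason <- ifelse(out$n_source_cells > 0, "", "no_contributing_cells")
  out[order(out$source, out$target, out$patient_id), ]
}

#' Default (source, target) pairs for distance summaries
#'
#' All nine T-cell categories to tumor cells, plus the regulatory/helper/
#' cytotoxic inter-subset pairs highlighted in downstream survival analysis.
#'
#' @return Data frame with columns `source` and `target`.
#' @export
default_distance_pairs <- function() {
  rbind(
    data.frame(source = tcell_categories(), target = "Tumor",
               stringsAsFactors = FALSE),
    data.frame(source = c("Treg", "Treg", "CD8T", "Th", "aCD8T", "Treg"),
               target = c("Th", "CD8T", "Treg", "CD8T", "Treg", "aCD8T"),
               stringsAsFactors = FALSE)
  )
}

#' Overall nearest radius: cohort-level T-cell-to-tumor distance
#'
#' The median over patients of the per-patient median nearest distance from
#' CD3+ T cells to tumor cells. This single micrometre scalar summarizes how
#' close T cells come to tumor cells across the cohort.
#'
#' @param distance_summary Output of [summarize_patient_distances()].
#' @param source,target Pair to summarize (defaults `"T"` -> `"Tumor"`).
#' @return Median of patient medians (µm); `NA` if no patient has a value.
#' @export
overall_nearest_radius <- function(distance_summary, source = "T", target = "Tumor") {
  v <- distance_summary$median_distance[
    distance_summary$source == source & distance_summary$target == target]
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  stats::median(v)
}

#' Reshape a long distance summary to a patient-by-metric matrix
#'
#' Metric columns are named `distance_<source>_to_<target>`.
#'
#' @param distance_summary Output of [summarize_patient_distances()].
#' @return Numeric matrix, patients in rows, distance metrics in columns.
#' @export
distance_wide <- function(distance_summary) {
  patients <- sort(unique(distance_summary$patient_id))
  key <- paste0("distance_", distance_summary$source, "_to_", distance_summary$target)
  cols <- unique(key)
  out <- matrix(NA_real_, nrow = length(patients), ncol = length(cols),
                dimnames = list(patients, cols))
  out[cbind(match(distance_summary$patient_id, patients), match(key, cols))] <-
    distance_summary$median_distance
  out
}

#' Inter-metric correlation matrix
#'
#' Correlations between per-patient metrics (densities and/or distance
#' medians) across patients, using pairwise-complete observations.
#'
#' @param metrics Numeric matrix, patients in rows, metrics in columns (see
#'   [density_wide()], [distance_wide()]).
#' @param method `"spearman"` (default, rank-based) or `"pearson"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
metric_correlation_matrix <- function(metrics, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  # a zero-variance metric (e.g. a category absent in every patient) has no
  # defined correlation: NA off-diagonal, without a warning per pair
  r <- suppressWarnings(
    stats::cor(metrics, method = method, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}
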