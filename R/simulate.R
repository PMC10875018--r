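# Seeded synthetic cohort generator. Emulates the study geometry: 4 fields
# per patient, an epithelium mask built from random discs and rejected until
# the epithelium fraction reaches 0.30, tumor cells as a homogeneous Poisson
# process on the mask, T-cell subsets as Thomas cluster processes with
# compartment-specific intensities scaled by a per-patient latent
# immune-activity factor that also drives the gene panels, and survival
# times from an exponential proportional-hazards model with a planted
# log-hazard ratio on a median-split spatial covariate.

.base_subtypes <- c("Th", "Treg", "CD8T")

.subtype_matrix <- function(th, treg, cd8t) {
  m <- rbind(Th = th, Treg = treg, CD8T = cd8t)
  colnames(m) <- c("epithelium", "stroma", "other")
  m
}

#' Simulation parameters with study-condition defaults
#'
#' Defaults encode the emulated study conditions: 90 patients, 4 fields per
#' patient, 669 x 500 µm fields, epithelium fraction at least 0.30, helper
#' T-cell base densities of 89.6 (epithelium) and 595.2 (stroma) cells/mm^2
#' with regulatory and cytotoxic subsets at similar, lower densities,
#' epithelial Ki67 fractions of 33.7% (helper) and 14.8% (cytotoxic), a GrB
#' cut-off-separated intensity mixture, a latent immune-activity factor
#' loading on both densities and a gene panel (target correlation 0.7), and
#' a planted hazard ratio of 0.281 on the high-vs-low median split of the
#' regulatory-to-helper T-cell nearest-neighbor distance.
#'
#' @param ... Named overrides of any default listed below.
#' @return Named list of simulation parameters.
#' @export
sim_params <- function(...) {
  p <- list(
    n_patients = 90L,
    fields_per_patient = 4L,
    field_width_um = 669, field_height_um = 500,
    epithelium_fraction_min = 0.30,
    n_epi_discs = 8L, epi_disc_radius_um = c(60, 140),
    n_other_discs = 3L, other_disc_radius_um = c(15, 40),
    mask_grid_um = 2, mask_retry_budget = 50L,
    tumor_intensity = 1500,                      # CK+ cells/mm^2 on the mask
    base_intensity = .subtype_matrix(             # cells/mm^2 by compartment
      th   = c(89.6, 595.2, 30),
      treg = c(40, 150, 8),
      cd8t = c(45, 160, 10)),
    ki67_prob = .subtype_matrix(
      th   = c(0.337, 0.20, 0.15),
      treg = c(0.20, 0.12, 0.10),
      cd8t = c(0.148, 0.10, 0.08)),
    tumor_ki67_prob = 0.30,
    grb_pos_prob = .subtype_matrix(
      th   = c(0.02, 0.02, 0.02),
      treg = c(0.02, 0.02, 0.02),
      cd8t = c(0.35, 0.20, 0.15)),
    grb_cutoff = 0.25,
    cluster_parent_intensity = 20,               # Thomas parents / mm^2
    cluster_sd_um = 25,
    share_parents = TRUE,
    treg_offset_um = 0,                          # planted Treg cluster shift
    latent_sd = 1,
    density_loading = 0.4,                       # intensity ~ exp(loading * latent)
    expression_corr = 0.7,                       # target corr(latent, gene)
    expression_noise_sd = 1,
    expression_baseline = 5,
    baseline_hazard = log(2) / 4,                # events / year (median OS 4 y)
    pfs_hazard_multiplier = 1.4,
    planted_log_hr = log(0.281),                 # on high-vs-low split
    survival_source = "Treg", survival_target = "Th",
    censoring_rate = 0.12                        # / year, exponential
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) {
    stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  p
}

# Disc-union membership test: TRUE where (x, y) falls in any disc.
.in_discs <- function(x, y, discs) {
  inside <- rep(FALSE, length(x))
  if (is.null(discs) || nrow(discs) == 0) return(inside)
  for (i in seq_len(nrow(discs))) {
    inside <- inside |
      ((x - discs$cx[i])^2 + (y - discs$cy[i])^2 <= discs$r[i]^2)
  }
  inside
}

.draw_discs <- function(n, w, h, r_range) {
  data.frame(cx = stats::runif(n, 0, w), cy = stats::runif(n, 0, h),
             r = stats::runif(n, r_range[1], r_range[2]))
}

# Compartment of continuous points: epithelium mask wins; "other" holes are
# punched out of the remaining stroma.
.compartment_of <- function(x, y, epi_discs, other_discs) {
  epi <- .in_discs(x, y, epi_discs)
  oth <- !epi & .in_discs(x, y, other_discs)
  ifelse(epi, "epithelium", ifelse(oth, "other", "stroma"))
}

# Unbiased jittered-grid estimate of the compartment areas (mm^2): a square
# grid with a uniformly random offset makes each area estimate exactly
# unbiased for the true mask area.
.estimate_areas <- function(epi_discs, other_discs, w, h, grid_um) {
  ox <- stats::runif(1, 0, grid_um)
  oy <- stats::runif(1, 0, grid_um)
  gx <- seq(ox, w, by = grid_um)
  gy <- seq(oy, h, by = grid_um)
  pts <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  comp <- .compartment_of(pts$x, pts$y, epi_discs, other_discs)
  cell_mm2 <- grid_um^2 / 1e6
  c(epithelium = sum(comp == "epithelium") * cell_mm2,
    stroma = sum(comp == "stroma") * cell_mm2,
    other = sum(comp == "other") * cell_mm2)
}

# GrB cytoplasmic intensity mixture: the negative component lives on
# [0, cutoff), the positive component on [cutoff, 1], so the cut-off
# separates them exactly.
.draw_grb <- function(positive, cutoff) {
  n <- length(positive)
  out <- numeric(n)
  npos <- sum(positive)
  out[positive] <- cutoff + (1 - cutoff) * stats::rbeta(npos, 2, 2)
  out[!positive] <- cutoff * stats::rbeta(n - npos, 2, 5) * 0.999
  out
}

# Offspring of one Thomas category in one field: parents are Poisson over a
# buffered box (4 cluster-sd margin), offspring counts Poisson(mu) with
# isotropic Gaussian displacement; only offspring inside the field are kept.
.thomas_points <- function(parents, mu, sigma, w, h) {
  if (nrow(parents) == 0 || mu <= 0) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  n_off <- stats::rpois(nrow(parents), mu)
  tot <- sum(n_off)
  if (tot == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  px <- rep(parents$x, n_off)
  py <- rep(parents$y, n_off)
  x <- px + stats::rnorm(tot, 0, sigma)
  y <- py + stats::rnorm(tot, 0, sigma)
  keep <- x >= 0 & x <= w & y >= 0 & y <= h
  data.frame(x = x[keep], y = y[keep])
}

#' Generate one imaging field
#'
#' Builds the epithelium mask (union of random discs, rejection-sampled
#' until the epithelium fraction reaches the 0.30 minimum), places tumor
#' cells as a homogeneous Poisson process on the mask, and each T-cell base
#' subtype (helper, regulatory, cytotoxic) as a Thomas cluster process with
#' compartment-specific intensity scaled by `exp(loading * latent)`, so a
#' median patient (latent 0) has exactly the base intensities.
#' Marker booleans are consistent with the generating subtype; GrB
#' intensities come from a two-component mixture separated at the cut-off.
#'
#' Uses the current RNG state; seed control belongs to the caller (see
#' [generate_cohort()]).
#'
#' @param params Parameter list from [sim_params()].
#' @param latent Patient latent immune-activity factor (standard normal
#'   scale).
#' @param patient_id,field_id Identifiers stamped on the output rows.
#' @return List with `cells` (cell table rows) and `field` (one field
#'   summary row).
#' @export
generate_field <- function(params, latent = 0, patient_id = "P1",
                           field_id = "F1") {
  w <- params$field_width_um; h <- params$field_height_um
  for (try in seq_len(params$mask_retry_budget)) {
    epi_discs <- .draw_discs(params$n_epi_discs, w, h, params$epi_disc_radius_um)
    other_discs <- .draw_discs(params$n_other_discs, w, h,
                               params$other_disc_radius_um)
    areas <- .estimate_areas(epi_discs, other_discs, w, h, params$mask_grid_um)
    frac <- areas[["epithelium"]] / sum(areas)
    if (frac >= params$epithelium_fraction_min) break
    if (try == params$mask_retry_budget) {
      stop("epithelium mask rejection exceeded retry budget", call. = FALSE)
    }
  }

  # lognormal latent scaling anchored at the median patient: latent = 0
  # reproduces the base intensities exactly
  scale <- exp(params$density_loading * latent)

  # tumor cells: homogeneous Poisson over the field, thinned to the mask
  a_field <- w * h / 1e6
  n_t <- stats::rpois(1, params$tumor_intensity * a_field)
  tx <- stats::runif(n_t, 0, w); ty <- stats::runif(n_t, 0, h)
  keep <- .in_discs(tx, ty, epi_discs)
  tumor <- data.frame(x = tx[keep], y = ty[keep])

  # Thomas processes per compartment, parents optionally shared across
  # subtypes so their densities co-fluctuate within the field
  sigma <- params$cluster_sd_um
  buf <- 4 * sigma
  a_buf <- (w + 2 * buf) * (h + 2 * buf) / 1e6
  kappa <- params$cluster_parent_intensity
  cell_rows <- list()
  for (comp in c("epithelium", "stroma", "other")) {
    shared <- data.frame(
      x = numeric(0), y = numeric(0))
    if (params$share_parents) {
      n_par <- stats::rpois(1, kappa * a_buf)
      shared <- data.frame(x = stats::runif(n_par, -buf, w + buf),
                           y = stats::runif(n_par, -buf, h + buf))
    }
    for (st in .base_subtypes) {
      lambda <- params$base_intensity[st, comp] * scale
      if (lambda <= 0) next
      parents <- if (params$share_parents) shared else {
        n_par <- stats::rpois(1, kappa * a_buf)
        data.frame(x = stats::runif(n_par, -buf, w + buf),
                   y = stats::runif(n_par, -buf, h + buf))
      }
      if (st == "Treg" && params$treg_offset_um > 0 && nrow(parents) > 0) {
        ang <- stats::runif(nrow(parents), 0, 2 * pi)
        parents$x <- parents$x + params$treg_offset_um * cos(ang)
        parents$y <- parents$y + params$treg_offset_um * sin(ang)
      }
      pts <- .thomas_points(parents, lambda / kappa, sigma, w, h)
      if (nrow(pts) == 0) next
      comp_of <- .compartment_of(pts$x, pts$y, epi_discs, other_discs)
      pts <- pts[comp_of == comp, , drop = FALSE]
      if (nrow(pts) == 0) next
      n <- nrow(pts)
      ki67 <- stats::runif(n) < params$ki67_prob[st, comp]
      grb_pos <- stats::runif(n) < params$grb_pos_prob[st, comp]
      cell_rows[[length(cell_rows) + 1]] <- data.frame(
        x = pts$x, y = pts$y, compartment = comp,
        cd3 = TRUE, cd8 = st == "CD8T", foxp3 = st == "Treg",
        ki67 = ki67, ck = FALSE,
        grb_intensity = .draw_grb(grb_pos, params$grb_cutoff),
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(tumor) > 0) {
    n <- nrow(tumor)
    cell_rows[[length(cell_rows) + 1]] <- data.frame(
      x = tumor$x, y = tumor$y, compartment = "epithelium",
      cd3 = FALSE, cd8 = FALSE, foxp3 = FALSE,
      ki67 = stats::runif(n) < params$tumor_ki67_prob, ck = TRUE,
      grb_intensity = .draw_grb(rep(FALSE, n), params$grb_cutoff),
      stringsAsFactors = FALSE)
  }
  cells <- if (length(cell_rows) > 0) do.call(rbind, cell_rows) else
    data.frame(x = numeric(0), y = numeric(0), compartment = character(0),
               cd3 = logical(0), cd8 = logical(0), foxp3 = logical(0),
               ki67 = logical(0), ck = logical(0), grb_intensity = numeric(0),
               stringsAsFactors = FALSE)
  cells <- cbind(data.frame(patient_id = rep(patient_id, nrow(cells)),
                            field_id = rep(field_id, nrow(cells)),
                            stringsAsFactors = FALSE), cells)

  total <- sum(areas)
  field <- data.frame(
    patient_id = patient_id, field_id = field_id,
    area_epithelium = areas[["epithelium"]],
    area_stroma = areas[["stroma"]],
    area_other = areas[["other"]],
    epithelium_fraction = areas[["epithelium"]] / total,
    stringsAsFactors = FALSE)
  list(cells = cells, field = field)
}

#' Generate latent-driven panel gene expression
#'
#' Each panel gene g is `baseline + b * latent + noise` with `b` chosen so
#' the population correlation between the latent factor and the gene equals
#' `params$expression_corr`.
#'
#' @param latent Named numeric vector of per-patient latent factors.
#' @param params Parameter list from [sim_params()].
#' @param genes Gene symbols to generate (default: the union of the three
#'   shipped panels).
#' @return Gene-by-patient numeric matrix.
#' @export
generate_expression <- function(latent, params = sim_params(), genes = NULL) {
  if (is.null(genes)) {
    genes <- unique(c(icr_panel(), gene_panel("chemokine"),
                      gene_panel("cell_cell_interaction")))
  }
  r <- params$expression_corr
  sd_e <- params$expression_noise_sd
  b <- r / sqrt(1 - r^2) * sd_e / params$latent_sd
  vals <- vapply(seq_along(genes), function(i) {
    params$expression_baseline + b * latent +
      stats::rnorm(length(latent), 0, sd_e)
  }, numeric(length(latent)))
  t(matrix(vals, nrow = length(latent), dimnames = list(names(latent), genes)))
}

#' Simulate survival times under exponential proportional hazards
#'
#' Event times are exponential with rate `baseline_hazard * exp(linpred)`;
#' censoring is independent exponential with rate `censoring_rate`.
#'
#' @param linpred Linear predictor (planted log-hazard contribution) per
#'   subject.
#' @param baseline_hazard Baseline event rate per year.
#' @param censoring_rate Exponential censoring rate per year.
#' @return List with `time` (years) and `event` (logical).
#' @export
simulate_survival <- function(linpred, baseline_hazard, censoring_rate) {
  n <- length(linpred)
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(linpred))
  t_cens <- stats::rexp(n, rate = censoring_rate)
  list(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

#' Generate a complete synthetic cohort with planted ground truth
#'
#' Draws per-patient latent immune-activity factors, generates each
#' patient's imaging fields ([generate_field()]), panel gene expression
#' ([generate_expression()]), clinical covariates, and survival outcomes in
#' which the planted log-hazard ratio acts on the high-vs-low median split
#' of the configured spatial covariate (computed from the generated cells
#' with the package's own gating and distance machinery). Identical
#' `(params, seed)` give identical output, byte for byte.
#'
#' @param params Parameter list from [sim_params()].
#' @param seed Integer seed controlling all randomness.
#' @return List with `cells`, `fields`, `expression`, `clinical`,
#'   `ground_truth` (per-patient latent/metric/group plus the planted
#'   parameters), and the `params`/`seed` used.
#' @export
generate_cohort <- function(params = sim_params(), seed = 1L) {
  set.seed(seed)
  n <- params$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  latent <- stats::rnorm(n, 0, params$latent_sd)
  names(latent) <- ids

  cells_list <- vector("list", n * params$fields_per_patient)
  fields_list <- vector("list", n * params$fields_per_patient)
  k <- 0
  for (i in seq_len(n)) {
    for (f in seq_len(params$fields_per_patient)) {
      k <- k + 1
      fl <- generate_field(params, latent = latent[i], patient_id = ids[i],
                           field_id = sprintf("%s_F%d", ids[i], f))
      cells_list[[k]] <- fl$cells
      fields_list[[k]] <- fl$field
    }
  }
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL
  fields <- do.call(rbind, fields_list)
  rownames(fields) <- NULL

  expr <- generate_expression(latent, params)

  # planted prognostic spatial covariate, computed with the real pipeline
  gated <- gate_cohort(cells, grb_cutoff = params$grb_cutoff)
  pair <- data.frame(source = params$survival_source,
                     target = params$survival_target,
                     stringsAsFactors = FALSE)
  ds <- summarize_patient_distances(gated, pairs = pair)
  metric <- stats::setNames(ds$median_distance, ds$patient_id)[ids]
  metric_name <- paste0("distance_", params$survival_source, "_to_",
                        params$survival_target)
  split <- tryCatch(median_split(metric, metric_name = metric_name),
                    error = function(e) NULL)
  group <- rep(NA_character_, n); names(group) <- ids
  if (!is.null(split)) group[names(split$group)] <- split$group
  linpred <- ifelse(!is.na(group) & group == "high", params$planted_log_hr, 0)

  os <- simulate_survival(linpred, params$baseline_hazard, params$censoring_rate)
  pfs <- simulate_survival(linpred,
                           params$baseline_hazard * params$pfs_hazard_multiplier,
                           params$censoring_rate)

  icr <- cut(rank(latent, ties.method = "first"),
             breaks = 3, labels = c("Low", "Medium", "High"))
  clinical <- data.frame(
    patient_id = ids,
    os_time = os$time, os_event = os$event,
    pfs_time = pfs$time, pfs_event = pfs$event,
    age = pmin(95, pmax(30, round(stats::rnorm(n, 68, 10)))),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.55, 0.45)),
    side = sample(c("right", "left"), n, replace = TRUE),
    adjuvant = stats::runif(n) < 0.3,
    ajcc = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.15, 0.35, 0.35, 0.15)),
    msi = sample(c("MSI-H", "MSS"), n, replace = TRUE, prob = c(0.25, 0.75)),
    cms = sample(c("CMS1", "CMS2", "CMS3", "CMS4", "Mixed"), n, replace = TRUE,
                 prob = c(0.15, 0.35, 0.15, 0.25, 0.10)),
    icr = as.character(icr),
    stringsAsFactors = FALSE)

  ground_truth <- list(
    per_patient = data.frame(
      patient_id = ids, latent = unname(latent),
      survival_metric = unname(metric), survival_group = unname(group),
      stringsAsFactors = FALSE),
    planted_log_hr = params$planted_log_hr,
    survival_metric_name = metric_name,
    median_cutoff = if (!is.null(split)) split$cutoff else NA_real_,
    expression_corr = params$expression_corr,
    density_loading = params$density_loading,
    treg_offset_um = params$treg_offset_um,
    base_intensity = params$base_intensity,
    tumor_intensity = params$tumor_intensity)

  list(cells = cells, fields = fields, expression = expr, clinical = clinical,
       ground_truth = ground_truth, params = params, seed = seed)
}
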