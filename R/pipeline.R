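# End-to-end pipeline: simulate (or read) -> gate -> quantify -> spatial ->
# associate -> survive, with a config echo and a hashed output manifest so
# identical (inputs, config, seed) runs are byte-identical.

#' Default pipeline configuration
#'
#' @param ... Named overrides. Keys: `simulate` (named list of [sim_params()]
#'   overrides, or `NULL` to read inputs from files), `cells`, `fields`,
#'   `expression`, `clinical` (input paths when not simulating), `seed`,
#'   `grb_cutoff`, `tumor_excludes_cd3`, `t_excludes_ck`, `panels`,
#'   `metric_corr_method` (inter-metric correlations, default Spearman),
#'   `gene_corr_method` (metric-expression correlations, default Pearson),
#'   `run_survival`, `survival_endpoints`, `km_metric` (metric whose
#'   median-split Kaplan-Meier curves are written).
#' @return Named configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    simulate = list(),
    cells = NULL, fields = NULL, expression = NULL, clinical = NULL,
    seed = 1L,
    grb_cutoff = 0.25,
    tumor_excludes_cd3 = TRUE,
    t_excludes_ck = TRUE,
    panels = c("icr", "chemokine", "cell_cell_interaction"),
    metric_corr_method = "spearman",
    gene_corr_method = "pearson",
    run_survival = TRUE,
    survival_endpoints = c("os", "pfs"),
    km_metric = "distance_Treg_to_Th"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected, never ignored.
#'
#' @param path YAML file path.
#' @return Configuration list (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# Binary/derived covariate codings for the Cox covariate panel.
.clinical_covariates <- function(clinical, endpoint) {
  data.frame(
    time = clinical[[paste0(endpoint, "_time")]],
    event = clinical[[paste0(endpoint, "_event")]],
    age = clinical$age,
    sex_male = as.integer(clinical$sex == "male"),
    side_right = as.integer(clinical$side == "right"),
    adjuvant = as.integer(clinical$adjuvant),
    ajcc_3_4 = as.integer(clinical$ajcc %in% c("III", "IV")),
    msi_h = as.integer(clinical$msi == "MSI-H"),
    cms1 = as.integer(clinical$cms == "CMS1"),
    icr_med_high = as.integer(clinical$icr %in% c("Medium", "High")),
    row.names = clinical$patient_id)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (simulate/read inputs, gate, quantify,
#' spatial, associate, survive), writes every result table in the canonical
#' TSV dialect to `out_dir`, echoes the effective configuration, and writes
#' a `manifest.tsv` listing every output with its MD5 content hash. Any
#' stage failure aborts with a located error; nothing is written on
#' configuration errors.
#'
#' @param config Configuration list ([pipeline_config()]) or path to a YAML
#'   file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`cells`, `fields`,
#'   `metrics`, `distance_summary`, `metric_wide`, `overall_radius`,
#'   `correlations`, `survival`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  simulate <- !is.null(config$simulate)
  if (!simulate) {
    for (key in c("cells", "fields", "expression")) {
      if (is.null(config[[key]])) {
        stop(sprintf("config error: '%s' input path required when not simulating", key),
             call. = FALSE)
      }
    }
    if (isTRUE(config$run_survival) && is.null(config$clinical)) {
      stop("config error: survival requested but no clinical table configured",
           call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    written <<- c(written, p)
    p
  }

  if (simulate) {
    params <- do.call(sim_params, config$simulate)
    cohort <- generate_cohort(params, seed = config$seed)
    cells <- cohort$cells; fields <- cohort$fields
    expr <- cohort$expression; clinical <- cohort$clinical
    emit(cells, "cells.tsv"); emit(fields, "fields.tsv")
    emit(clinical, "clinical.tsv")
    write_expression_matrix(expr, file.path(out_dir, "expression.tsv"))
    written <- c(written, file.path(out_dir, "expression.tsv"))
    emit(cohort$ground_truth$per_patient, "ground_truth.tsv")
  } else {
    cells <- read_cell_table(config$cells)
    fields <- read_field_summary(config$fields)
    expr <- read_expression_matrix(config$expression)
    clinical <- if (!is.null(config$clinical)) read_clinical_table(config$clinical)
  }

  # gate
  gated <- gate_cohort(cells, grb_cutoff = config$grb_cutoff,
                       tumor_excludes_cd3 = config$tumor_excludes_cd3,
                       t_excludes_ck = config$t_excludes_ck)

  # quantify
  metrics <- build_metric_table(gated, fields)
  emit(metrics$density, "metrics_density.tsv")
  emit(metrics$fraction, "metrics_fraction.tsv")

  # spatial
  dsum <- summarize_patient_distances(gated)
  emit(dsum, "metrics_distance.tsv")
  dw <- distance_wide(dsum)
  denw <- density_wide(metrics$density)
  metric_wide <- cbind(denw[rownames(dw), , drop = FALSE], dw)
  radius <- overall_nearest_radius(dsum)
  mcor <- metric_correlation_matrix(metric_wide, method = config$metric_corr_method)
  mcor_df <- data.frame(metric = rownames(mcor), mcor, check.names = FALSE)
  emit(mcor_df, paste0("metric_correlation_", config$metric_corr_method, ".tsv"))
  emit(data.frame(quantity = "overall_nearest_radius_um", value = radius),
       "overall_nearest_radius.tsv")

  # associate
  correlations <- list()
  for (panel in config$panels) {
    symbols <- gene_panel(panel)
    tab_d <- correlate_panel(denw, expr, symbols, metric_kind = "density",
                             method = config$gene_corr_method)
    tab_x <- correlate_panel(dw, expr, symbols, metric_kind = "distance",
                             method = config$gene_corr_method)
    tab <- rbind(tab_d, tab_x)
    correlations[[panel]] <- tab
    emit(tab, paste0("correlation_", panel, ".tsv"))
  }

  # survive
  surv_res <- NULL
  if (isTRUE(config$run_survival)) {
    if (is.null(clinical)) {
      stop("config error: survival requested but no clinical data available",
           call. = FALSE)
    }
    surv_res <- list()
    for (endpoint in config$survival_endpoints) {
      base <- .clinical_covariates(clinical, endpoint)
      spatial_cols <- colnames(metric_wide)
      uni_rows <- list()
      for (mcol in spatial_cols) {
        vals <- stats::setNames(metric_wide[, mcol], rownames(metric_wide))
        split <- tryCatch(median_split(vals, metric_name = mcol),
                          error = function(e) NULL)
        if (is.null(split)) next
        dat <- base[names(split$group), , drop = FALSE]
        dat$group_high <- as.integer(split$group == "high")
        fit <- tryCatch(cox_fit(dat, "time", "event", "group_high"),
                        error = function(e) NULL)
        if (is.null(fit)) next
        row <- fit$table
        row$covariate <- mcol
        uni_rows[[mcol]] <- row
      }
      spatial_uni <- do.call(rbind, uni_rows)
      clin_cov <- c("age", "sex_male", "side_right", "adjuvant", "ajcc_3_4",
                    "msi_h", "cms1", "icr_med_high")
      sg <- .spatial_groups(metric_wide, config$km_metric)
      res <- cox_univariate_multivariate(
        cbind(base, sg[rownames(base), , drop = FALSE]),
        "time", "event", c(clin_cov, "spatial_group_high"))
      surv_res[[endpoint]] <- list(spatial_univariate = spatial_uni,
                                   table1 = res)
      emit(spatial_uni, paste0("survival_cox_spatial_", endpoint, ".tsv"))
      emit(res$univariate, paste0("survival_cox_univariate_", endpoint, ".tsv"))
      if (!is.null(res$multivariate)) {
        emit(res$multivariate$table,
             paste0("survival_cox_multivariate_", endpoint, ".tsv"))
      }
      # KM curves for the configured headline metric
      if (config$km_metric %in% colnames(metric_wide)) {
        vals <- stats::setNames(metric_wide[, config$km_metric],
                                rownames(metric_wide))
        split <- tryCatch(median_split(vals), error = function(e) NULL)
        if (!is.null(split)) {
          km_rows <- do.call(rbind, lapply(c("high", "low"), function(g) {
            ids <- names(split$group)[split$group == g]
            dat <- base[ids, , drop = FALSE]
            km <- km_estimate(dat$time, dat$event)
            km$group <- g
            km
          }))
          dat <- base[names(split$group), , drop = FALSE]
          lr <- logrank_test(dat$time, dat$event, split$group[rownames(dat)])
          km_rows$logrank_p <- lr$p
          emit(km_rows, paste0("survival_km_", config$km_metric, "_",
                               endpoint, ".tsv"))
        }
      }
    }
  }

  # config echo + manifest
  cfg_path <- file.path(out_dir, "config_echo.yaml")
  yaml::write_yaml(config, cfg_path)
  written <- c(written, cfg_path)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  .write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(cells = gated, fields = fields, metrics = metrics,
                 distance_summary = dsum, metric_wide = metric_wide,
                 overall_radius = radius, correlations = correlations,
                 survival = surv_res, manifest = manifest))
}

.spatial_groups <- function(metric_wide, metric) {
  if (!(metric %in% colnames(metric_wide))) {
    stop(sprintf("config error: km_metric '%s' not among computed metrics", metric),
         call. = FALSE)
  }
  vals <- stats::setNames(metric_wide[, metric], rownames(metric_wide))
  split <- median_split(vals, metric_name = metric)
  out <- data.frame(spatial_group_high = rep(NA_integer_, nrow(metric_wide)),
                    row.names = rownames(metric_wide))
  out[names(split$group), "spatial_group_high"] <-
    as.integer(split$group == "high")
  out
}
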