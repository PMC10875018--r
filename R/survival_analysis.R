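# Median-split stratification, Kaplan-Meier / log-rank, and univariate ->
# multivariate Cox with Wald tests. Estimation is delegated to the survival
# package (product-limit via survfit, Mantel-Cox via survdiff, partial
# likelihood with Efron tie handling via coxph); this module owns the
# stratification convention, the selection rule and the result contracts.

#' Median-split stratification of a per-patient metric
#'
#' Patients strictly above the cohort median are `"high"`; patients at or
#' below it (including ties at the median) are `"low"`. Missing values are
#' excluded with a reason, never silently dropped.
#'
#' @param values Named numeric vector (names = patient IDs).
#' @return A list with `group` (named character vector, `"high"`/`"low"`),
#'   `cutoff` (the median), `excluded` (IDs with missing values), and
#'   `metric` (optional metric name carried through).
#' @param metric_name Optional label for the stratifying metric.
#' @export
median_split <- function(values, metric_name = NA_character_) {
  stopifnot(!is.null(names(values)))
  ok <- is.finite(values)
  v <- values[ok]
  if (length(v) < 2) stop("need >= 2 non-missing values to stratify", call. = FALSE)
  if (max(v) == min(v)) {
    stop("degenerate stratification: all metric values identical", call. = FALSE)
  }
  cutoff <- stats::median(v)
  group <- ifelse(v > cutoff, "high", "low")
  names(group) <- names(v)
  list(group = group, cutoff = cutoff,
       excluded = names(values)[!ok], metric = metric_name)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times Follow-up times (> 0).
#' @param events Logical event indicators (`FALSE` = censored).
#' @return Data frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (non-increasing, in `[0, 1]`).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @param group Two-level grouping vector.
#' @return List with `chisq` (1 df statistic) and `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("log-rank comparison needs exactly two groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  chisq <- sd$chisq
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with Wald tests
#'
#' Partial-likelihood maximization with Efron handling of tied event times.
#' Reports, per covariate: hazard ratio, 95% CI (`exp(beta +/- 1.96 se)`)
#' and the Wald p-value. Non-convergence, separation (unbounded
#' coefficients) and collinearity (aliased covariates) are flagged in the
#' result, never silent. Schoenfeld-residual proportional-hazards
#' diagnostics are attached when computable but never alter the estimates.
#'
#' @param data Data frame of covariates plus time/event columns.
#' @param time_col,event_col Column names for follow-up time and event flag.
#' @param covariates Character vector of covariate column names.
#' @return List with `table` (data frame: `covariate`, `beta`, `se`, `hr`,
#'   `ci_low`, `ci_high`, `p`, `flag`), `flags` (fit-level flags),
#'   `n`, `n_events`, `ph_test` (Schoenfeld global p or `NA`), and the
#'   underlying `coxph` object as `fit`.
#' @export
cox_fit <- function(data, time_col, event_col, covariates) {
  stopifnot(all(c(time_col, event_col, covariates) %in% names(data)))
  n_events <- sum(as.logical(data[[event_col]]))
  if (n_events < length(covariates) + 1) {
    stop(sprintf("too few events (%d) for %d covariate(s)", n_events,
                 length(covariates)), call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", as.integer(", event_col, ")) ~ ",
    paste(covariates, collapse = " + ")))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))[seq_along(beta)]
  se <- ifelse(is.na(beta), NA_real_, se)
  tab <- data.frame(
    covariate = names(beta),
    beta = unname(beta),
    se = unname(se),
    hr = exp(unname(beta)),
    ci_low = exp(unname(beta) - 1.96 * unname(se)),
    ci_high = exp(unname(beta) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE
  )
  tab$flag <- ""
  aliased <- is.na(beta)
  if (any(aliased)) {
    tab$flag[aliased] <- "aliased_collinear"
    flags <- c(flags, "collinearity: aliased covariate(s) dropped")
  }
  big <- !aliased & (abs(beta) > 15 | se > 15)
  if (any(big, na.rm = TRUE)) {
    tab$flag[big] <- "possible_separation"
    flags <- c(flags, "possible separation: unbounded coefficient")
  }
  if (any(grepl("Ran out of iterations|did not converge", flags))) {
    flags <- c(flags, "non_convergence")
  }
  ph_p <- tryCatch({
    z <- survival::cox.zph(fit)
    unname(z$table["GLOBAL", "p"])
  }, error = function(e) NA_real_)
  list(table = tab, flags = unique(flags), n = fit$n, n_events = fit$nevent,
       ph_test = ph_p, fit = fit)
}

#' Select covariates for the multivariate Cox model
#'
#' Keeps exactly the covariates whose univariate Wald p-value is strictly
#' below `alpha` (a boundary p equal to `alpha` is excluded).
#'
#' @param univariate_p Named numeric vector of univariate Wald p-values.
#' @param alpha Selection threshold, default 0.05.
#' @return Character vector of selected covariate names (possibly empty).
#' @export
select_multivariate <- function(univariate_p, alpha = 0.05) {
  stopifnot(!is.null(names(univariate_p)))
  names(univariate_p)[!is.na(univariate_p) & univariate_p < alpha]
}

#' Univariate-then-multivariate Cox analysis over a covariate set
#'
#' Fits one univariate Cox model per covariate, selects those with Wald
#' p < `alpha`, and fits the multivariate model on the selected set (skipped
#' with a message when the set is empty).
#'
#' @inheritParams cox_fit
#' @param alpha Univariate selection threshold, default 0.05.
#' @return List with `univariate` (stacked per-covariate tables),
#'   `selected` (covariate names) and `multivariate` (a [cox_fit()] result
#'   or `NULL`).
#' @export
cox_univariate_multivariate <- function(data, time_col, event_col, covariates,
                                        alpha = 0.05) {
  uni <- do.call(rbind, lapply(covariates, function(cv) {
    t <- cox_fit(data, time_col, event_col, cv)$table
    t$term <- t$covariate
    t$covariate <- cv
    t
  }))
  # selection is per input covariate: a factor covariate is selected when any
  # of its terms is significant
  p_by_cov <- tapply(uni$p, uni$covariate, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0) NA_real_ else min(p)
  })
  selected <- select_multivariate(p_by_cov[covariates], alpha = alpha)
  multi <- NULL
  if (length(selected) > 0) {
    multi <- cox_fit(data, time_col, event_col, selected)
  } else {
    message("no covariate reached univariate p < ", alpha,
            "; multivariate model skipped")
  }
  list(univariate = uni, selected = selected, multivariate = multi)
}
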