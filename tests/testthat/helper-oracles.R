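# Independent oracles and fixture builders. Everything here is deliberately
# naive (double loops, closed forms) and shares no code with the package
# internals it checks.

# O(n^2) double-loop nearest-neighbor oracle with optional self-exclusion.
nn_brute <- function(sx, sy, tx, ty, source_ids = NULL, target_ids = NULL) {
  out <- rep(NA_real_, length(sx))
  for (i in seq_along(sx)) {
    best <- Inf
    for (j in seq_along(tx)) {
      if (!is.null(source_ids) && !is.null(target_ids) &&
          source_ids[i] == target_ids[j]) next
      d <- sqrt((sx[i] - tx[j])^2 + (sy[i] - ty[j])^2)
      if (d < best) best <- d
    }
    if (is.finite(best)) out[i] <- best
  }
  out
}

# Double-loop pairwise distance oracle.
pairwise_brute <- function(x, y) {
  n <- length(x)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    }
  }
  m
}

# Random ungated cell table with arbitrary marker states (not generator
# output: markers here are independent coin flips, so every combination,
# including implausible ones, is exercised).
random_cells <- function(n, n_patients = 2, n_fields = 2, w = 600, h = 500) {
  pid <- sprintf("P%02d", sample.int(n_patients, n, replace = TRUE))
  data.frame(
    patient_id = pid,
    field_id = paste0(pid, "_F", sample.int(n_fields, n, replace = TRUE)),
    x = runif(n, 0, w), y = runif(n, 0, h),
    compartment = sample(c("epithelium", "stroma", "other"), n, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)),
    cd3 = runif(n) < 0.5, cd8 = runif(n) < 0.4, foxp3 = runif(n) < 0.25,
    ki67 = runif(n) < 0.3, ck = runif(n) < 0.35,
    grb_intensity = runif(n),
    stringsAsFactors = FALSE)
}

# Field summary consistent with a set of random areas.
random_fields <- function(cells) {
  key <- unique(cells[, c("patient_id", "field_id")])
  n <- nrow(key)
  a <- matrix(runif(3 * n, 0.05, 0.3), ncol = 3)
  data.frame(
    patient_id = key$patient_id, field_id = key$field_id,
    area_epithelium = a[, 1], area_stroma = a[, 2], area_other = a[, 3],
    epithelium_fraction = a[, 1] / rowSums(a),
    stringsAsFactors = FALSE)
}

# Naive per-cell membership re-count, straight from the category
# definitions (independent of gate_markers).
count_category_brute <- function(cells, category, compartment = NULL,
                                 grb_cutoff = 0.25) {
  n <- 0
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, ]
    if (!is.null(compartment) && r$compartment != compartment) next
    t <- r$cd3 && !r$ck
    grb <- r$grb_intensity >= grb_cutoff
    member <- switch(category,
      "T" = t,
      "pT" = t && r$ki67,
      "Th" = t && !r$cd8 && !r$foxp3,
      "pTh" = t && !r$cd8 && !r$foxp3 && r$ki67,
      "Treg" = t && r$foxp3,
      "pTreg" = t && r$foxp3 && r$ki67,
      "CD8T" = t && r$cd8,
      "pCD8T" = t && r$cd8 && r$ki67,
      "aCD8T" = t && r$cd8 && grb,
      "Tumor" = r$ck && !r$cd3)
    if (member) n <- n + 1
  }
  n
}

# Naive product-limit estimator: loop over distinct times in order.
km_brute <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (k in seq_along(ut)) {
    at_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events)
    if (at_risk > 0) s <- s * (1 - d / at_risk)
    out$surv[k] <- s
  }
  out
}

# Mantel-Cox log-rank oracle from the O-E table, 1 df.
logrank_brute <- function(times, events, group) {
  g <- as.integer(as.factor(group)) # 1/2
  ut <- sort(unique(times[events]))
  O <- 0; E <- 0; V <- 0
  for (t in ut) {
    n1 <- sum(times >= t & g == 1)
    n2 <- sum(times >= t & g == 2)
    d1 <- sum(times == t & events & g == 1)
    d2 <- sum(times == t & events & g == 2)
    n <- n1 + n2; d <- d1 + d2
    if (n == 0) next
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Efron negative log partial likelihood for one binary covariate; used to
# re-maximize independently of coxph.
efron_nll <- function(beta, times, events, z) {
  nll <- 0
  for (t in unique(times[events])) {
    D <- which(times == t & events)
    R <- which(times >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * z[R]))
    sum_d <- sum(exp(beta * z[D]))
    nll <- nll - beta * sum(z[D])
    for (l in seq_len(d) - 1) {
      nll <- nll + log(sum_r - (l / d) * sum_d)
    }
  }
  nll
}

# Textbook product-moment correlation.
pearson_brute <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Tiny hand-checkable gated cohort builder: explicit rows, then gate.
make_cells <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    defaults <- list(patient_id = "P1", field_id = "P1_F1", x = 0, y = 0,
                     compartment = "stroma", cd3 = FALSE, cd8 = FALSE,
                     foxp3 = FALSE, ki67 = FALSE, ck = FALSE,
                     grb_intensity = 0)
    defaults[names(r)] <- r
    as.data.frame(defaults, stringsAsFactors = FALSE)
  }))
  df
}
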