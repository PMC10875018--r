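# Correlation of per-patient spatial metrics with immune gene-expression
# panels. Sign convention for distance metrics: the metric is negated before
# correlating, so a positive coefficient always reads "higher expression,
# shorter distance" (and, for densities, "higher expression, higher
# density").

#' The 20-gene immunologic constant of rejection (ICR) panel
#'
#' Th1 signaling (IFNG, TBX21, CD8A, CD8B, IL12B, STAT1, IRF1), CXCR3/CCR5
#' chemoattraction (CXCL9, CXCL10, CCL5), cytotoxic function (GNLY, PRF1,
#' GZMA, GZMB, GZMH) and immune regulation (IDO1, CTLA4, CD274, PDCD1,
#' FOXP3). Symbols follow HGNC: the perforin gene is `PRF1` and the CD8
#' module is expanded to `CD8A` and `CD8B`.
#'
#' @return Character vector of 20 HGNC symbols.
#' @export
icr_panel <- function() {
  c("IFNG", "TBX21", "CD8A", "CD8B", "IL12B", "STAT1", "IRF1",
    "CXCL9", "CXCL10", "CCL5",
    "GNLY", "PRF1", "GZMA", "GZMB", "GZMH",
    "IDO1", "CTLA4", "CD274", "PDCD1", "FOXP3")
}

#' Load a named gene panel
#'
#' `"icr"` is built in (see [icr_panel()]); `"chemokine"` and
#' `"cell_cell_interaction"` are read from editable plain-text symbol lists
#' shipped with the package (one symbol per line, `#` comments allowed).
#' Any other value is treated as a path to such a file.
#'
#' @param name Panel name or path to a symbol list file.
#' @return Character vector of gene symbols.
#' @export
gene_panel <- function(name) {
  if (identical(name, "icr")) return(icr_panel())
  path <- if (name %in% c("chemokine", "cell_cell_interaction")) {
    system.file("extdata", paste0("panel_", name, ".txt"), package = "tmespat",
                mustWork = TRUE)
  } else name
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Pearson or Spearman correlation with pairwise-complete handling
#'
#' Drops incomplete pairs, then computes the coefficient. Returns `NA` with
#' a `"reason"` attribute when fewer than 3 complete pairs remain
#' (`"insufficient_n"`) or either vector is constant (`"zero_variance"`).
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient with attribute `"n"` (pairs used), or
#'   `NA` with a `"reason"` attribute.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) {
    out <- NA_real_
    attr(out, "reason") <- "insufficient_n"
    attr(out, "n") <- n
    return(out)
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    out <- NA_real_
    attr(out, "reason") <- "zero_variance"
    attr(out, "n") <- n
    return(out)
  }
  out <- stats::cor(x[ok], y[ok], method = method)
  attr(out, "n") <- n
  out
}

#' Correlate a gene panel with per-patient spatial metrics
#'
#' For every (gene, metric) pair, correlates expression with the metric
#' across the overlapping patients. For `metric_kind = "distance"` the
#' metric is negated before correlation (when `flip_distance_sign` is
#' `TRUE`), so that r > 0 means higher expression is associated with
#' *shorter* distance; density metrics are never transformed. Panel genes
#' absent from the expression matrix are emitted as missing rows, not
#' dropped.
#'
#' @param metrics Numeric matrix, patients in rows, metrics in columns
#'   ([density_wide()] or [distance_wide()]).
#' @param expr Gene-by-patient expression matrix ([read_expression_matrix()]).
#' @param panel Character vector of gene symbols (see [gene_panel()]).
#' @param metric_kind `"density"` or `"distance"`.
#' @param method Correlation method, default `"pearson"`.
#' @param flip_distance_sign Apply the distance sign convention (default
#'   `TRUE`). Disabling it returns exactly the negated coefficients for
#'   distance metrics.
#' @return Data frame: `gene`, `metric`, `r`, `n`, `p`, `reason`, plus a
#'   `"distance_sign_flipped"` attribute.
#' @export
correlate_panel <- function(metrics, expr, panel,
                            metric_kind = c("density", "distance"),
                            method = c("pearson", "spearman"),
                            flip_distance_sign = TRUE) {
  metric_kind <- match.arg(metric_kind)
  method <- match.arg(method)
  common <- intersect(rownames(metrics), colnames(expr))
  if (length(common) < 3) {
    stop(sprintf("only %d overlapping patients between metrics and expression; need >= 3",
                 length(common)), call. = FALSE)
  }
  m <- metrics[common, , drop = FALSE]
  if (metric_kind == "distance" && flip_distance_sign) m <- -m
  out <- expand.grid(gene = panel, metric = colnames(metrics),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- NA_real_; out$n <- 0L; out$p <- NA_real_; out$reason <- ""
  for (i in seq_len(nrow(out))) {
    g <- out$gene[i]
    if (!(g %in% rownames(expr))) {
      out$reason[i] <- "gene_absent"
      next
    }
    r <- correlate(m[, out$metric[i]], expr[g, common], method = method)
    out$n[i] <- attr(r, "n")
    if (is.na(r)) {
      out$reason[i] <- attr(r, "reason")
    } else {
      out$r[i] <- as.numeric(r)
      # two-sided t-test p for the coefficient (pearson) / rank version
      nn <- out$n[i]
      if (abs(out$r[i]) < 1) {
        tstat <- out$r[i] * sqrt((nn - 2) / (1 - out$r[i]^2))
        out$p[i] <- 2 * stats::pt(-abs(tstat), df = nn - 2)
      } else out$p[i] <- 0
    }
  }
  attr(out, "distance_sign_flipped") <- metric_kind == "distance" && flip_distance_sign
  out
}

#' Benjamini-Hochberg adjustment utility for a correlation table
#'
#' Adds a `p_adj` column (BH across all non-missing p-values). Provided as
#' an opt-in convenience: no correction is applied by default anywhere in
#' the package, and the raw `r`, `n`, `p` columns are always preserved.
#'
#' @param correlation_table Output of [correlate_panel()].
#' @return The table with an additional `p_adj` column.
#' @export
adjust_correlation_table <- function(correlation_table) {
  correlation_table$p_adj <- stats::p.adjust(correlation_table$p, method = "BH")
  correlation_table
}
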