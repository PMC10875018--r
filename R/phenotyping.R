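#' Phenotype category names
#'
#' The ten cell phenotype categories used throughout the package. The nine
#' T-cell categories are *memberships*, not a partition: a proliferating
#' cytotoxic T cell belongs to `T`, `pT`, `CD8T` and `pCD8T` at once.
#'
#' * `T`      -- CD3+ (all T cells)
#' * `pT`     -- CD3+Ki67+ (proliferating T cells)
#' * `Th`     -- CD3+CD8-FoxP3- (helper T cells)
#' * `pTh`    -- CD3+CD8-FoxP3-Ki67+
#' * `Treg`   -- CD3+FoxP3+ (regulatory T cells)
#' * `pTreg`  -- CD3+FoxP3+Ki67+
#' * `CD8T`   -- CD3+CD8+ (cytotoxic T cells)
#' * `pCD8T`  -- CD3+CD8+Ki67+
#' * `aCD8T`  -- CD3+CD8+GrB+ (active cytotoxic T cells)
#' * `Tumor`  -- CK+ (tumor epithelial cells)
#'
#' @return Character vector of the ten category names, in canonical order.
#' @export
phenotype_categories <- function() {
  c("T", "pT", "Th", "pTh", "Treg", "pTreg", "CD8T", "pCD8T", "aCD8T", "Tumor")
}

#' T-cell phenotype categories (excluding Tumor)
#' @return Character vector of the nine T-cell category names.
#' @export
tcell_categories <- function() {
  setdiff(phenotype_categories(), "Tumor")
}

#' Granzyme-B positivity call from cytoplasmic mean intensity
#'
#' A cell is GrB-positive when its cytoplasmic mean intensity (on a 0--1
#' scale) is at or above the cut-off. The default cut-off is 0.25; the
#' boundary is inclusive (intensity equal to the cut-off is positive).
#'
#' @param grb_intensity Numeric vector of intensities in `[0, 1]`.
#' @param cutoff Positivity threshold, default `0.25`.
#' @return Logical vector of positivity calls.
#' @export
call_grb_positive <- function(grb_intensity, cutoff = 0.25) {
  if (!is.numeric(grb_intensity)) {
    stop("grb_intensity must be numeric", call. = FALSE)
  }
  bad <- which(!is.finite(grb_intensity) | grb_intensity < 0 | grb_intensity > 1)
  if (length(bad) > 0) {
    stop(sprintf("grb_intensity outside [0, 1] at position(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  grb_intensity >= cutoff
}

#' Phenotype memberships for one cell
#'
#' Maps one cell's marker state to its set of phenotype categories.
#' Memberships respect the subset lattice: `pT`, `Th`, `Treg`, `CD8T` are
#' subsets of `T`; `pTh` of `Th`; `pTreg` of `Treg`; `pCD8T` and `aCD8T` of
#' `CD8T`. A cell negative for both CD3 and CK receives the empty set.
#'
#' @param cd3,cd8,foxp3,ki67,ck Logical marker calls (length 1).
#' @param grb_intensity Cytoplasmic GrB mean intensity in `[0, 1]`.
#' @param grb_cutoff GrB positivity cut-off, default `0.25`.
#' @param tumor_excludes_cd3 If `TRUE` (default) a CK+CD3+ cell is not
#'   counted as `Tumor` (segmentation-artifact guard).
#' @param t_excludes_ck If `TRUE` (default) a CD3+CK+ cell is excluded from
#'   the T-cell categories.
#' @return Character vector: the subset of [phenotype_categories()] the cell
#'   belongs to.
#' @export
assign_memberships <- function(cd3, cd8, foxp3, ki67, ck, grb_intensity,
                               grb_cutoff = 0.25,
                               tumor_excludes_cd3 = TRUE,
                               t_excludes_ck = TRUE) {
  m <- gate_markers(
    cd3 = cd3, cd8 = cd8, foxp3 = foxp3, ki67 = ki67, ck = ck,
    grb_intensity = grb_intensity, grb_cutoff = grb_cutoff,
    tumor_excludes_cd3 = tumor_excludes_cd3, t_excludes_ck = t_excludes_ck
  )
  phenotype_categories()[unlist(m[1, phenotype_categories()])]
}

# Vectorized gating core: logical marker vectors in, one logical column per
# category out. All membership definitions live here.
gate_markers <- function(cd3, cd8, foxp3, ki67, ck, grb_intensity,
                         grb_cutoff = 0.25,
                         tumor_excludes_cd3 = TRUE,
                         t_excludes_ck = TRUE) {
  grb <- call_grb_positive(grb_intensity, grb_cutoff)
  tt <- if (t_excludes_ck) cd3 & !ck else cd3
  out <- data.frame(
    T     = tt,
    pT    = tt & ki67,
    Th    = tt & !cd8 & !foxp3,
    pTh   = tt & !cd8 & !foxp3 & ki67,
    Treg  = tt & foxp3,
    pTreg = tt & foxp3 & ki67,
    CD8T  = tt & cd8,
    pCD8T = tt & cd8 & ki67,
    aCD8T = tt & cd8 & grb,
    Tumor = if (tumor_excludes_cd3) ck & !cd3 else ck,
    check.names = FALSE
  )
  out
}

#' Gate a cohort of cells into phenotype categories
#'
#' Annotates a cell table (see [read_cell_table()]) with one logical column
#' per phenotype category. Idempotent: gating an already gated table replaces
#' the membership columns. The number of CK+CD3+ co-positive cells excluded
#' from `Tumor` is recorded in the `"n_ck_cd3_copositive"` attribute.
#'
#' @param cells Cell table with the marker columns `cd3`, `cd8`, `foxp3`,
#'   `ki67`, `ck` (logical) and `grb_intensity` (numeric in `[0, 1]`).
#' @inheritParams assign_memberships
#' @return `cells` with ten additional logical membership columns named as
#'   [phenotype_categories()], plus a `grb_pos` column with the GrB call.
#' @export
gate_cohort <- function(cells, grb_cutoff = 0.25,
                        tumor_excludes_cd3 = TRUE, t_excludes_ck = TRUE) {
  stopifnot(is.data.frame(cells))
  cats <- phenotype_categories()
  cells <- cells[, setdiff(names(cells), c(cats, "grb_pos")), drop = FALSE]
  if (nrow(cells) == 0) {
    for (cat in cats) cells[[cat]] <- logical(0)
    cells$grb_pos <- logical(0)
    attr(cells, "n_ck_cd3_copositive") <- 0L
    attr(cells, "grb_cutoff") <- grb_cutoff
    return(cells)
  }
  m <- gate_markers(
    cd3 = cells$cd3, cd8 = cells$cd8, foxp3 = cells$foxp3,
    ki67 = cells$ki67, ck = cells$ck, grb_intensity = cells$grb_intensity,
    grb_cutoff = grb_cutoff, tumor_excludes_cd3 = tumor_excludes_cd3,
    t_excludes_ck = t_excludes_ck
  )
  for (cat in cats) cells[[cat]] <- m[[cat]]
  cells$grb_pos <- call_grb_positive(cells$grb_intensity, grb_cutoff)
  attr(cells, "n_ck_cd3_copositive") <- sum(cells$ck & cells$cd3)
  attr(cells, "grb_cutoff") <- grb_cutoff
  cells
}
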