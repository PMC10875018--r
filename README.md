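# tmespat

Spatial T-cell contexture analysis for multiplex-immunofluorescence (mIF)
cell tables.

## The problem

Multiplexed immunofluorescence of tumor sections yields, after segmentation
and marker classification, a table of cells: coordinates within each imaged
field, a tissue compartment (tumor epithelium / stroma / other), binary
calls for CD3, CD8, FoxP3, Ki67 and cytokeratin (CK), and a Granzyme-B (GrB)
cytoplasmic intensity. Turning that table into tumor-immune contexture
metrics — *which* T-cell subsets are present, *where* (epithelium vs
stroma), *how close* they come to tumor cells and to each other, how those
metrics track immune gene expression, and whether they stratify patient
survival — involves a chain of conventions that are easy to get subtly
wrong. `tmespat` implements that chain as tested, reusable functions for
researchers analyzing Vectra/inForm-style cell-segmentation exports.

## What it computes

* **Gating** into ten phenotype categories — T = CD3⁺, pT = CD3⁺Ki67⁺,
  Th = CD3⁺CD8⁻FoxP3⁻, pTh, Treg = CD3⁺FoxP3⁺, pTreg, CD8T = CD3⁺CD8⁺,
  pCD8T, aCD8T = CD3⁺CD8⁺GrB⁺, Tumor = CK⁺ — with GrB⁺ defined by
  intensity ≥ 0.25 (inclusive). Categories are memberships, not a
  partition: pCD8T ⊆ CD8T ⊆ T by construction.
* **Densities** per patient, category and compartment in cells/mm²,
  pooling each patient's fields as (Σ counts)/(Σ compartment areas), and
  Ki67⁺/GrB⁺ **fractions** within parent subsets.
* **Nearest-neighbor distances**: for source category A and target B, each
  A-cell's Euclidean distance (µm) to the nearest B-cell in the same field,
  with self-exclusion when categories overlap; per-patient medians over
  pooled cells; T→Tumor distances restricted to non-intraepithelial
  sources; and the cohort "overall nearest radius" (median over patients
  of median CD3⁺→Tumor distance).
* **Association** of metrics with gene panels (the 20-gene ICR signature,
  chemokines, cell–cell interaction molecules) by Pearson/Spearman
  correlation; distance metrics are sign-flipped so r > 0 always reads
  "higher expression, shorter distance".
* **Survival**: median-split stratification (above median = high),
  Kaplan–Meier + log-rank (Mantel–Cox), univariate → multivariate Cox
  (Efron ties, Wald tests, selection at p < 0.05), with hazard ratios and
  95% CIs as exp(β ± 1.96·se).
* A **seeded synthetic cohort generator** (4 fields/patient, disc-union
  epithelium masks with ≥ 30% epithelium, Poisson tumor cells, Thomas
  cluster T cells driven by a latent immune-activity factor that also
  drives the gene panels, planted survival effects) for validation and
  demonstration.

## Worked example

Generate a 40-patient synthetic cohort and run the analysis:

```r
library(tmespat)

co    <- generate_cohort(sim_params(n_patients = 40L), seed = 42)
gated <- gate_cohort(co$cells)                  # adds membership columns
mt    <- build_metric_table(gated, co$fields)   # densities + fractions
ds    <- summarize_patient_distances(gated)     # per-patient NN medians

median(subset(mt$density, category == "Th" & compartment == "stroma")$density)
#> [1] 557.1012
overall_nearest_radius(ds)
#> [1] 66.8514
```

557 cells/mm² is the cohort's median stromal helper-T density (the
generator's base condition is 595.2, scaled per patient by the latent
factor); 66.9 µm is the median-over-patients median distance from a CD3⁺
cell to the nearest tumor cell.

Stratify patients at the median regulatory→helper T-cell distance and fit a
Cox model on progression-free survival:

```r
dw   <- distance_wide(ds)
vals <- setNames(dw[, "distance_Treg_to_Th"], rownames(dw))
sp   <- median_split(vals)            # above median -> "high"
cl   <- co$clinical; rownames(cl) <- cl$patient_id
dat  <- data.frame(time  = cl[names(sp$group), "pfs_time"],
                   event = cl[names(sp$group), "pfs_event"],
                   high  = as.integer(sp$group == "high"))
cox_fit(dat, "time", "event", "high")$table[, c("covariate", "hr", "ci_low", "ci_high", "p")]
#>  covariate        hr     ci_low   ci_high           p
#>       high 0.1560518 0.04962529 0.4907209 0.001483677
logrank_test(dat$time, dat$event, sp$group)$p
#> [1] 0.000379189
```

The fitted hazard ratio 0.156 (95% CI 0.050–0.491) recovers the direction
and magnitude of the generator's planted protective effect (HR 0.281 for
the high-distance group) at this cohort size; the log-rank test agrees
(p = 4e-4).

The same chain runs end-to-end, with every table written as TSV plus a
hashed manifest, via:

```r
run_pipeline(pipeline_config(simulate = list(n_patients = 40L), seed = 42),
             out_dir = "results/run1")
```

or from a shell through the thin wrapper `inst/cli/tmespat.R`
(`simulate` and `all` subcommands).

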