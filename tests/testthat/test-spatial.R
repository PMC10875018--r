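test_that("pairwise distances: 3-4-5 triangle, singleton, field guard, oracle", {
  expect_equal(pairwise_distances(c(0, 3), c(0, 4))[1, 2], 5)
  expect_equal(pairwise_distances(5, 7), matrix(0, 1, 1, dimnames = list("1", "1")),
               ignore_attr = TRUE)
  expect_error(pairwise_distances(c(0, 1), c(0, 1), field_id = c("F1", "F2")),
               "multiple fields")
  set.seed(41)
  x <- runif(50, 0, 100); y <- runif(50, 0, 100)
  expect_equal(unname(pairwise_distances(x, y)), pairwise_brute(x, y),
               tolerance = 1e-12)
})

test_that("nearest-neighbor distances match the brute-force oracle", {
  expect_equal(nn_distance(0, 0, c(3, 10), c(4, 0)), 5)
  # sole cell that is its own only target: missing, never zero
  expect_true(is.na(nn_distance(1, 1, 1, 1, source_ids = 1, target_ids = 1)))
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    sx <- runif(n, 0, 600); sy <- runif(n, 0, 500)
    m <- sample(20:100, 1)
    tx <- runif(m, 0, 600); ty <- runif(m, 0, 500)
    expect_equal(nn_distance(sx, sy, tx, ty), nn_brute(sx, sy, tx, ty),
                 tolerance = 1e-9)
    # overlapping source/target with shared ids
    ids <- seq_len(n)
    expect_equal(nn_distance(sx, sy, sx, sy, ids, ids),
                 nn_brute(sx, sy, sx, sy, ids, ids), tolerance = 1e-9)
  }
})

test_that("translation and rotation leave distance statistics unchanged", {
  set.seed(43)
  sx <- runif(80, 100, 400); sy <- runif(80, 100, 400)
  tx <- runif(40, 100, 400); ty <- runif(40, 100, 400)
  base <- nn_distance(sx, sy, tx, ty)
  expect_equal(nn_distance(sx + 57, sy - 13, tx + 57, ty - 13), base,
               tolerance = 1e-9)
  th <- 0.7
  rot <- function(x, y) list(x = x * cos(th) - y * sin(th),
                             y = x * sin(th) + y * cos(th))
  s <- rot(sx, sy); t <- rot(tx, ty)
  expect_equal(nn_distance(s$x, s$y, t$x, t$y), base, tolerance = 1e-9)
})

test_that("tumor distances use only non-intraepithelial sources and all tumor targets", {
  cells <- gate_cohort(make_cells(
    list(cd3 = TRUE, x = 0, y = 0, compartment = "stroma"),
    list(ck = TRUE, x = 6, y = 8, compartment = "epithelium")))
  expect_equal(nn_to_tumor(cells, "P1", "Th"), 10)

  # an intraepithelial source contributes nothing
  cells2 <- gate_cohort(make_cells(
    list(cd3 = TRUE, x = 0, y = 0, compartment = "epithelium"),
    list(ck = TRUE, x = 6, y = 8, compartment = "epithelium")))
  expect_length(nn_to_tumor(cells2, "P1", "Th"), 0)

  # no tumor cells: field contributes nothing
  cells3 <- gate_cohort(make_cells(
    list(cd3 = TRUE, x = 0, y = 0, compartment = "stroma")))
  expect_length(nn_to_tumor(cells3, "P1", "Th"), 0)

  # oracle: filter then brute-force on a random cohort
  set.seed(44)
  rc <- gate_cohort(random_cells(300, n_patients = 2, n_fields = 2))
  for (p in unique(rc$patient_id)) {
    got <- sort(nn_to_tumor(rc, p, "T"))
    want <- numeric(0)
    pc <- rc[rc$patient_id == p, ]
    for (f in unique(pc$field_id)) {
      fc <- pc[pc$field_id == f, ]
      src <- fc$T & fc$compartment != "epithelium"
      tgt <- fc$Tumor
      if (!any(src) || !any(tgt)) next
      want <- c(want, nn_brute(fc$x[src], fc$y[src], fc$x[tgt], fc$y[tgt]))
    }
    expect_equal(got, sort(want), tolerance = 1e-9)
  }
})

test_that("adding tumor cells never increases a tumor distance", {
  set.seed(45)
  cells <- random_cells(150, n_patients = 1, n_fields = 1)
  cells$cd3[1:30] <- TRUE; cells$ck[1:30] <- FALSE
  cells$compartment[1:30] <- "stroma"
  base <- gate_cohort(cells)
  d0 <- nn_to_tumor(base, "P01", "T")
  extra <- cells[1, ]
  extra$cd3 <- FALSE; extra$ck <- TRUE
  extra$x <- 300; extra$y <- 250; extra$compartment <- "epithelium"
  d1 <- nn_to_tumor(gate_cohort(rbind(cells, extra)), "P01", "T")
  expect_length(d1, length(d0))
  expect_true(all(d1 <= d0 + 1e-12))
})

test_that("patient summaries pool per-cell distances across fields (median conventions)", {
  # distances to a single tumor cell per field: [1,2,3] pooled -> median 2;
  # adding a fourth (even count) -> mid-mean 2.5
  mk <- function(ds) {
    rows <- list()
    for (i in seq_along(ds)) {
      fid <- paste0("P1_F", i)
      rows[[length(rows) + 1]] <- list(cd3 = TRUE, x = 0, y = 0,
                                       compartment = "stroma", field_id = fid)
      rows[[length(rows) + 1]] <- list(ck = TRUE, x = ds[i], y = 0,
                                       compartment = "epithelium", field_id = fid)
    }
    gate_cohort(do.call(make_cells, rows))
  }
  pairs <- data.frame(source = "T", target = "Tumor", stringsAsFactors = FALSE)
  s3 <- summarize_patient_distances(mk(c(1, 2, 3)), pairs)
  expect_equal(s3$median_distance, 2)
  expect_equal(s3$n_source_cells, 3L)
  s4 <- summarize_patient_distances(mk(c(1, 2, 3, 4)), pairs)
  expect_equal(s4$median_distance, 2.5)
  # patient with no contributing cells carries a reason, not a silent drop
  none <- summarize_patient_distances(
    gate_cohort(make_cells(list(cd3 = TRUE, compartment = "epithelium"))), pairs)
  expect_true(is.na(none$median_distance))
  expect_equal(none$reason, "no_contributing_cells")
})

test_that("overall nearest radius is the median of patient medians", {
  ds <- data.frame(patient_id = c("P1", "P2", "P3"), source = "T",
                   target = "Tumor", n_source_cells = 5L,
                   median_distance = c(10, 20, 30), reason = "",
                   stringsAsFactors = FALSE)
  expect_equal(overall_nearest_radius(ds), 20)
  expect_equal(overall_nearest_radius(ds[1, ]), 10)
  ds$median_distance[2] <- NA
  expect_equal(overall_nearest_radius(ds), 20)
})

test_that("nearest-distance mean matches the Poisson closed form 1/(2*sqrt(lambda))", {
  set.seed(46)
  lambda <- 0.01                      # targets per um^2
  w <- 1000; h <- 1000
  n_t <- rpois(1, lambda * w * h)
  tx <- runif(n_t, 0, w); ty <- runif(n_t, 0, h)
  # sources away from the border so edge effects are negligible
  sx <- runif(4000, 100, w - 100); sy <- runif(4000, 100, h - 100)
  d <- nn_distance(sx, sy, tx, ty)
  expect_equal(mean(d), 1 / (2 * sqrt(lambda)), tolerance = 0.05)
})

test_that("inter-metric correlations: unit diagonal, exact small cases, formula oracle", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(3, 2, 1, 0), c = c(2, 4, 6, 9))
  r <- metric_correlation_matrix(m, method = "pearson")
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], -1)
  expect_equal(r, t(r))
  rs <- metric_correlation_matrix(m, method = "spearman")
  expect_equal(rs["a", "b"], -1)
  expect_equal(rs["a", "c"], 1)
  set.seed(47)
  x <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("m1", "m2", "m3")))
  rp <- metric_correlation_matrix(x, method = "pearson")
  expect_equal(rp["m1", "m2"], pearson_brute(x[, 1], x[, 2]), tolerance = 1e-12)
  expect_equal(rp["m2", "m3"], pearson_brute(x[, 2], x[, 3]), tolerance = 1e-12)
})
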