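grid_from <- function(doses) {
  voxel_grid(array(doses, c(length(doses), 1, 1)), c(1, 1, 1))
}
all_mask <- function(n) array(TRUE, c(n, 1, 1))

test_that("DVH curves are non-increasing, bounded, and match exhaustive counting", {
  g <- grid_from(rep(10, 50))
  curve <- dvh(g, all_mask(50))
  expect_equal(curve$volume_pct[curve$dose == 0], 100)
  expect_equal(curve$volume_pct[curve$dose == 10], 100)
  expect_equal(curve$volume_pct[nrow(curve)], 0)

  g2 <- grid_from(c(rep(10, 25), rep(20, 25)))
  c2 <- dvh(g2, all_mask(50))
  expect_equal(c2$volume_pct[c2$dose == 10], 100)
  expect_equal(c2$volume_pct[c2$dose == 20], 50)

  set.seed(21)
  d <- runif(400, 0, 80)
  c3 <- dvh(grid_from(d), all_mask(400))
  expect_true(all(diff(c3$volume_pct) <= 0))
  expect_true(all(c3$volume_pct >= 0 & c3$volume_pct <= 100))
  for (k in sample(nrow(c3), 20))
    expect_equal(c3$volume_pct[k], 100 * sum(d >= c3$dose[k]) / 400)
  expect_error(dvh(g, array(FALSE, c(50, 1, 1))), "empty")
})

test_that("dose metrics follow the hottest-volume convention and the sort oracle", {
  g <- grid_from(1:100)
  m <- all_mask(100)
  expect_equal(dose_metric(g, m, "Dpct", 98), 3)
  expect_equal(dose_metric(g, m, "Dpct", 2), 99)
  expect_equal(dose_metric(g, m, "Dmax"), 100)
  expect_equal(dose_metric(g, m, "Dmean"), 50.5)
  expect_equal(dose_metric(g, m, "VGy", 20), 81)

  gu <- grid_from(rep(10, 40))
  mu <- all_mask(40)
  for (met in c("Dmax", "Dmean")) expect_equal(dose_metric(gu, mu, met), 10)
  expect_equal(dose_metric(gu, mu, "Dpct", 2), 10)
  expect_equal(dose_metric(gu, mu, "Dpct", 98), 10)

  set.seed(31)
  for (rep in 1:20) {
    n <- sample(50:5000, 1)
    d <- round(runif(n, 0, 120), 3)
    gg <- grid_from(d); mm <- all_mask(n)
    x <- runif(1, 1, 99)
    expect_equal(dose_metric(gg, mm, "Dpct", x), metric_sort_oracle(d, "Dpct", x))
    dd <- runif(1, 0, 120)
    expect_equal(dose_metric(gg, mm, "VGy", dd), metric_sort_oracle(d, "VGy", dd))
    # absolute-volume metric against whole-voxel counting (1 mm3 voxels)
    vol_cc <- runif(1, 0.001, n / 1000)
    expect_equal(dose_metric(gg, mm, "Dcc", vol_cc, interpolate = FALSE),
                 metric_sort_oracle(d, "Dcc", vol_cc, voxel_cc = 1e-3))
  }
  # D98 <= Dmean <= D2 <= Dmax ordering
  d <- runif(500, 0, 60); gg <- grid_from(d); mm <- all_mask(500)
  expect_lte(dose_metric(gg, mm, "Dpct", 98), dose_metric(gg, mm, "Dmean"))
  expect_lte(dose_metric(gg, mm, "Dmean"), dose_metric(gg, mm, "Dpct", 2))
  expect_lte(dose_metric(gg, mm, "Dpct", 2), dose_metric(gg, mm, "Dmax"))
  expect_error(dose_metric(gg, mm, "Dcc", 10), "exceeds")
})

test_that("interpolated absolute-volume metrics bracket the step convention", {
  d <- c(10, 20, 30, 40)
  g <- voxel_grid(array(d, c(4, 1, 1)), c(10, 10, 10))  # 1 cm3 voxels
  m <- array(TRUE, c(4, 1, 1))
  step <- dose_metric(g, m, "Dcc", 1.5, interpolate = FALSE)
  interp <- dose_metric(g, m, "Dcc", 1.5, interpolate = TRUE)
  expect_equal(step, 30)
  expect_equal(interp, 35)  # halfway between the 1st and 2nd hottest voxel
})

test_that("EUD and EQD2 maps reduce to the scalar formulas on simple fields", {
  ph <- tiny_phantom()
  reg <- read_tissue_table()
  # no beams: all-zero maps
  sim0 <- simulate_plan(ph$density, list(),
                        voxels = ph$structures$masks$ptv_gbm_cavity)
  e0 <- eud_map(sim0, ph$structures, reg)
  expect_true(all(e0$values == 0))
  expect_true(all(eqd2_map(e0, ph$structures, reg)$values == 0))

  # uniform 20 Gy EUD map with alpha/beta = 3: every voxel converts to 92 Gy
  vals <- array(0, dim(ph$density$values))
  vals[ph$structures$masks$ptv_gbm_cavity] <- 20
  em <- voxel_grid(vals, ph$density$spacing)
  reg3 <- list(ptv_gbm_cavity = tissue_params("ptv_gbm_cavity", alpha = 0.0585,
                                              beta = 0.0195),
               default = default_tissue_params())
  q <- eqd2_map(em, ph$structures, reg3, priority = "ptv_gbm_cavity")
  expect_equal(unique(q$values[ph$structures$masks$ptv_gbm_cavity]), 92)
  expect_true(all(q$values[!ph$structures$masks$ptv_gbm_cavity] == 0))

  # clinical map at the reference fractionation is unchanged
  vals60 <- array(60, dim(ph$density$values))
  g60 <- voxel_grid(vals60, ph$density$spacing)
  q60 <- eqd2_map(g60, ph$structures, reg, single_fraction = FALSE, fractions = 30)
  expect_equal(q60$values, vals60)
  expect_error(eqd2_map(g60, ph$structures, reg, single_fraction = FALSE),
               "fraction scheme")
})

test_that("out-of-field voxels with homogeneous scatter reduce to the scatter sum", {
  # a voxel receiving only uniform scatter from each field: its EUD is the
  # plain sum of the per-field scatter doses
  g <- voxel_grid(array(1, c(5, 5, 1)), c(2, 2, 2))
  iso <- c(5, 5, 1)
  px <- matrix(TRUE, 2, 2)
  fm <- field_mask(px, c(1, 1), -1, -1)   # tiny aperture around the isocenter
  b1 <- beam_spec(0, 100, isocenter = iso, field_mask = fm, scatter_fraction = 0.02)
  b2 <- beam_spec(90, 100, isocenter = iso, field_mask = fm, scatter_fraction = 0.02)
  blk <- sample_subvoxel_doses(c(1, 5, 1), list(b1, b2), g, collapse_z = TRUE)
  spread <- diff(range(blk$sample_doses)) / mean(blk$sample_doses)
  expect_lt(spread, 0.05)   # near-homogeneous scatter bath
  h <- build_histogram(blk)
  e <- eud_from_histogram(h, default_tissue_params())
  expect_equal(e, mean(blk$sample_doses), tolerance = 1e-3)
})

test_that("D98 normalization hits the reference and is idempotent", {
  ph <- tiny_phantom()
  reg <- read_tissue_table()
  tgt <- ph$structures$masks$ptv_gbm_cavity
  sim <- simulate_plan(ph$density, tiny_beams(ph), voxels = tgt)
  ans <- normalize_to_reference_d98(sim, 50, tgt, ph$structures, reg)
  expect_equal(ans$achieved_d98, 50, tolerance = 50 * 1e-3)
  q <- eqd2_map(eud_map(ans$sim, ph$structures, reg), ph$structures, reg)
  expect_equal(dose_metric(q, tgt, "Dpct", 98), 50, tolerance = 50 * 1e-3)
  ans2 <- normalize_to_reference_d98(ans$sim, 50, tgt, ph$structures, reg)
  expect_equal(ans2$factor, 1, tolerance = 1e-3)

  # independent bisection on the scalar factor reaches the same scale
  f_oracle <- local({
    d98 <- function(s) {
      m <- eqd2_map(eud_map(scale_plan(sim, s), ph$structures, reg),
                    ph$structures, reg)
      dose_metric(m, tgt, "Dpct", 98)
    }
    lo <- 1e-3; hi <- 100
    for (i in 1:60) {
      mid <- sqrt(lo * hi)
      if (d98(mid) < 50) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  })
  expect_equal(ans$factor, f_oracle, tolerance = 1e-3)
})

test_that("constraint reports flag exactly the comparator violations", {
  cs <- list(constraint_spec("brain_stem", "Dmax", 54),
             constraint_spec("cochlea", "Dmax", 45),
             constraint_spec("lung", "VGy", 20, arg = 20))
  rep1 <- constraint_report(cs, c("brain_stem:Dmax" = 51.49,
                                  "cochlea:Dmax" = 39.97,
                                  "lung:VGy:20" = 5.12))
  expect_true(all(rep1$pass))
  rep2 <- constraint_report(cs, c("brain_stem:Dmax" = 65.79,
                                  "cochlea:Dmax" = 65.92,
                                  "lung:VGy:20" = 5.12))
  expect_equal(rep2$pass, c(FALSE, FALSE, TRUE))
  # boundary: strict comparator fails at equality, <= passes
  eq <- list(constraint_spec("s", "Dmax", 54, comparator = "<"),
             constraint_spec("s", "Dmean", 54, comparator = "<="))
  r <- constraint_report(eq, c("s:Dmax" = 54, "s:Dmean" = 54))
  expect_equal(r$pass, c(FALSE, TRUE))
  expect_equal(nrow(constraint_report(list(), numeric(0))), 0)
  expect_error(constraint_report(cs, c("brain_stem:Dmax" = 1)), "no achieved")
})

test_that("plan metrics feed the constraint machinery end to end", {
  ph <- tiny_phantom()
  vals <- array(0, dim(ph$density$values))
  vals[ph$structures$masks$brain_stem] <- 30
  g <- voxel_grid(vals, ph$density$spacing)
  cs <- list(constraint_spec("brain_stem", "Dmax", 54),
             constraint_spec("brain_stem", "Dmean", 26))
  rep <- evaluate_constraints(g, ph$structures, cs)
  expect_equal(rep$achieved, c(30, 30))
  expect_equal(rep$pass, c(TRUE, FALSE))  # 30 Gy mean exceeds the 26 Gy limit
  expect_error(plan_metrics(g, ph$structures,
                            list(constraint_spec("nope", "Dmax", 5))),
               "not in the structure set")
})
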