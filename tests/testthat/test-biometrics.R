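test_that("MTT viability percentages", {
  expect_equal(cell_viability_percent(viability_plate(0.6, 0.1, 1.1)), 50)
  expect_equal(cell_viability_percent(viability_plate(1.1, 0.1, 1.1)), 100)
  expect_equal(cell_viability_percent(viability_plate(0.1, 0.1, 1.1)), 0)
  expect_error(viability_plate(0.5, 0.2, 0.1), "invalid assay")
})

test_that("apparent permeability arithmetic and unit handling", {
  # toy flux chosen so Papp = 1e-6 cm/s on the standard 1.13 cm^2 insert
  a <- permeability_assay(flux = 1e-6 * 1.13 * 100 * 60, area = 1.13,
                          initial_conc = 100, time_unit = "min")
  expect_equal(apparent_permeability(a), 1e-6)
  expect_equal(apparent_permeability(
    permeability_assay(0, initial_conc = 10)), 0)
  # doubling C0 halves Papp
  a2 <- permeability_assay(5, 1.13, 200, "s")
  a1 <- permeability_assay(5, 1.13, 100, "s")
  expect_equal(apparent_permeability(a2), apparent_permeability(a1) / 2)
  expect_error(permeability_assay(1, area = 0, initial_conc = 1), "area")
  expect_error(permeability_assay(1, initial_conc = 0), "initial_conc")
})

test_that("withdrawal correction follows the cumulative recursion", {
  p <- dissolution_profile(1:3, c(10, 10, 10), medium_volume = 500,
                           sample_volume = 5)
  expect_equal(withdrawal_corrected_cumulative(p), c(10, 10.1, 10.2))
  p0 <- dissolution_profile(1:3, c(3, 7, 2), sample_volume = 0)
  expect_equal(withdrawal_corrected_cumulative(p0), c(3, 7, 2))  # identity
  # the correction is a nondecreasing add-on
  set.seed(1)
  cc <- runif(8, 0, 50)
  pr <- dissolution_profile(1:8, cc)
  add_on <- withdrawal_corrected_cumulative(pr) - cc
  expect_true(all(diff(add_on) >= 0))
  expect_error(dissolution_profile(1:3, c(1, 2, 3), medium_volume = 5,
                                   sample_volume = 10), "smaller")
})

test_that("intrinsic dissolution rate is the corrected-mass OLS slope", {
  # exactly linear mass profile: slope s mg/min/cm2
  s <- 0.8
  t <- seq(0, 15, by = 3)
  disc <- 0.5
  vol <- 500
  conc <- s * t * disc * 1000 / vol  # ug/mL, no withdrawal
  p <- dissolution_profile(t[-1], conc[-1], vol, sample_volume = 0,
                           disc_area = disc)
  expect_equal(intrinsic_dissolution_rate(p), s, tolerance = 1e-10)
  # early-window fit on a one-exponential profile approximates initial rate
  cinf <- 40
  k <- 0.01
  tt <- seq(1, 5)
  prof <- dissolution_profile(tt, cinf * (1 - exp(-k * tt)), vol, 0, disc)
  idr <- intrinsic_dissolution_rate(prof, window = c(1, 5))
  init_rate <- cinf * k * vol / 1000 / disc
  expect_equal(idr, init_rate, tolerance = 0.04)
  # flat profile has zero slope
  flat <- dissolution_profile(1:5, rep(12, 5), vol, 0, disc)
  expect_equal(intrinsic_dissolution_rate(flat), 0, tolerance = 1e-12)
  expect_error(intrinsic_dissolution_rate(flat, window = c(4, 5)),
               "insufficient")
})

test_that("fold changes reproduce the printed comparisons", {
  expect_equal(fold_change(8.6, 1.8, 1), 4.8)
  expect_equal(fold_change(6.43, 0.0667, 0), 96)
  expect_equal(fold_change(14.45, 5.61, 1), 2.6)
  expect_equal(fold_change(3.7, 3.7, 1), 1)
  expect_error(fold_change(1, 0), "must be > 0")
})

test_that("NCA matches hand-checkable profiles", {
  # constant concentration 1 over [0, 24]: rectangle AUC
  p <- pk_profile(c(0, 24), c(1, 1))
  expect_equal(auc_linear(p$times, p$concentrations), 24)
  # Cmax/tmax lookup
  p2 <- pk_profile(c(0, 0.5, 1.6, 3, 6), c(0, 2, 5, 3, 1))
  r2 <- nca(p2)
  expect_equal(r2$cmax, 5)
  expect_equal(r2$tmax, 1.6)
  # pure mono-exponential decay: everything closed-form
  ke <- 0.2
  t <- seq(0, 40, by = 0.5)
  p3 <- pk_profile(t, 10 * exp(-ke * t))
  r3 <- nca(p3, terminal_points = 5)
  expect_equal(r3$ke, ke, tolerance = 1e-8)
  expect_equal(r3$t_half, log(2) / ke, tolerance = 1e-8)
  expect_equal(r3$auc_0_inf, 10 / ke, tolerance = 0.01)
  expect_equal(r3$mrt, 1 / ke, tolerance = 0.02)
})

test_that("NCA AUC is additive over subintervals and scale-equivariant", {
  set.seed(8)
  t <- sort(c(0, runif(10, 0, 24)))
  cc <- abs(rnorm(11, 5, 2))
  i <- 6
  expect_equal(auc_linear(t[1:i], cc[1:i]) +
                 auc_linear(t[i:11], cc[i:11]),
               auc_linear(t, cc), tolerance = 1e-12)
  p <- simulate_pk_profile(pk_sim_config(10, 1.5, 0.12, 4))
  r <- nca(p)
  ps <- pk_profile(p$times, p$concentrations * 3, dose = p$dose)
  rs <- nca(ps)
  expect_equal(rs$cmax, 3 * r$cmax)
  expect_equal(rs$auc_0_t, 3 * r$auc_0_t)
  expect_equal(rs$auc_0_inf, 3 * r$auc_0_inf)
  expect_equal(rs$tmax, r$tmax)
  expect_equal(rs$ke, r$ke)
  expect_equal(rs$t_half, r$t_half)
  expect_equal(rs$mrt, r$mrt)
})

test_that("NCA recovers half-life across a (ka, ke) grid", {
  for (ka in c(0.8, 1.5, 3)) {
    for (ke in c(0.05, 0.1, 0.2)) {
      horizon <- 5 * log(2) / ke
      cfg <- pk_sim_config(10, ka, ke, 5,
                           sample_times = c(0, exp(seq(log(0.25),
                                                       log(horizon),
                                                       length.out = 18))))
      r <- nca(simulate_pk_profile(cfg))
      expect_equal(r$t_half, log(2) / ke, tolerance = 0.02)
      expect_equal(r$auc_0_inf, 10 / (5 * ke),
                   tolerance = 0.02)
    }
  }
})

test_that("a rising terminal phase flags ke as undefined", {
  p <- pk_profile(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))
  expect_warning(r <- nca(p), "nonpositive terminal slope")
  expect_true(is.na(r$ke) && is.na(r$t_half) && is.na(r$auc_0_inf) &&
                is.na(r$mrt))
  expect_false(is.na(r$auc_0_t))
})

test_that("relative bioavailability reproduces the printed PK ratios", {
  t9 <- load_fixture("table9_pk")
  m <- function(par, dose, prod)
    t9$mean[t9$parameter == par & t9$dose_mg_kg == dose & t9$product == prod]
  expect_equal(round(relative_bioavailability(
    m("auc_0_24", 40, "nanoformulation"), m("auc_0_24", 40, "celebrex")), 1),
    145.2)
  expect_equal(round(relative_bioavailability(
    m("auc_0_24", 10, "nanoformulation"), m("auc_0_24", 10, "celebrex")), 1),
    99.5)
  expect_equal(relative_bioavailability(10, 10), 100)
  # dose normalization
  expect_equal(relative_bioavailability(20, 10, dose_test = 2, dose_ref = 1),
               100)
  expect_error(relative_bioavailability(1, 0), "> 0")
})
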