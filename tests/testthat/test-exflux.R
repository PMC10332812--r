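test_that("growth fitting recovers exact exponential series", {
  t <- seq(0, 72, by = 24)
  x <- 2e4 * exp(0.02 * t)
  g <- fit_growth_rate(t, x)
  expect_equal(g$mu, 0.02, tolerance = 1e-10)
  expect_equal(g$X0, 2e4, tolerance = 1e-6)
  expect_error(fit_growth_rate(t, c(-1, x[-1])), "non-positive")
  expect_error(fit_growth_rate(t[1:2], x[1:2]), "3 distinct")
})

test_that("robust growth fit resists a 10x outlier better than OLS", {
  t <- seq(0, 72, by = 12)
  x <- 2e4 * exp(0.02 * t)
  x[7] <- x[7] * 10
  g <- fit_growth_rate(t, x)
  ols <- coef(lm(log(x) ~ t))[2]
  expect_lt(abs(g$mu - 0.02) / 0.02, 0.05)
  expect_gt(abs(ols - 0.02), abs(g$mu - 0.02))
})

test_that("fitted growth rates preserve the hypoxia ordering", {
  times <- seq(0, 72, by = 24)
  gn <- ground_truth(mu = 0.0238, seed = 5)
  gh <- ground_truth(mu = 0.0168, seed = 6)
  dn <- simulate_growth_timecourse(gn, times, replicates = 4)
  dh <- simulate_growth_timecourse(gh, times, replicates = 4)
  fn <- fit_growth_rate(dn$time_h, dn$cells)
  fh <- fit_growth_rate(dh$time_h, dh$cells)
  expect_gt(fn$mu, fh$mu)
  expect_lt(abs(fn$mu - 0.0238), 3 * fn$se_mu)
})

test_that("evaporation gives linear monotone volumes at density 1 g/mL", {
  vol <- estimate_evaporation(c(0, 72), c(2.0, 1.8))
  expect_equal(vol(36), 1.9)
  expect_equal(vol(0), 2.0)
  flat <- estimate_evaporation(c(0, 24, 48), c(2, 2, 2))
  expect_equal(flat(30), 2)
  expect_warning(estimate_evaporation(c(0, 24, 48), c(2, 2.2, 1.9)),
                 "increase")
  expect_error(estimate_evaporation(c(0, 24), c(2, -0.1)), "depleted")
})

test_that("degradation screening includes only significant rates", {
  t <- seq(0, 72, by = 12)
  flat <- estimate_degradation(t, rep(1000, length(t)))
  expect_false(flat$used)
  expect_equal(flat$k_effective, 0)

  set.seed(3)
  m <- 1000 * exp(-0.005 * t) * (1 + rnorm(length(t), 0, 0.005))
  dr <- estimate_degradation(t, m)
  expect_true(dr$used)
  expect_gt(dr$k, 0)                 # decay = positive degradation rate
  expect_lt(abs(dr$k - 0.005), 3 * dr$se)

  set.seed(4)
  weak <- 1000 * exp(-0.0001 * t) * (1 + rnorm(length(t), 0, 0.05))
  dw <- estimate_degradation(t, weak)
  expect_false(dw$used)
  expect_equal(dw$k_effective, 0)
})

test_that("flux regression matches the closed form exactly", {
  t <- seq(0, 72, by = 24)
  g <- list(mu = 0.0238, X0 = 25000)
  # constant mass, no degradation: zero flux
  fz <- estimate_flux(t, rep(5000, 4), g, k = 0)
  expect_equal(fz$v, 0, tolerance = 1e-8)
  # closed-form consumption series recovers v = -500 fmol/cell/h
  k <- -0.004
  mass <- exp(-k * t) * (-500e-6 * g$X0 / (g$mu + k) *
                           (exp((g$mu + k) * t) - 1) + 16000)
  fe <- estimate_flux(t, mass, g, k = k)
  expect_equal(fe$v, -500, tolerance = 1e-6 * 500)
  # accumulating product gives positive flux (efflux)
  lac <- -(-1000e-6) * g$X0 / g$mu * (exp(g$mu * t) - 1) + 0
  fl <- estimate_flux(t, lac, g, k = 0)
  expect_gt(fl$v, 0)
  expect_equal(fl$v, 1000, tolerance = 1e-4)
})

test_that("mu + k = 0 uses the analytic limit, not an epsilon", {
  t <- seq(0, 72, by = 12)
  g <- list(mu = 0.01, X0 = 25000)
  mass <- exp(0.01 * t) * (-200e-6 * g$X0 * t + 10000)
  fe <- estimate_flux(t, mass, g, k = -0.01)
  expect_equal(fe$v, -200, tolerance = 1e-6 * 200)
})

test_that("flux estimates are invariant to shifting the time origin", {
  t <- seq(0, 72, by = 24)
  gt <- ground_truth(seed = 9)
  sim <- simulate_medium_timecourse(gt, t, replicates = 1, noise = FALSE)
  d <- sim$medium[sim$medium$analyte == "GLC", ]
  g1 <- list(mu = gt$mu, X0 = gt$X0)
  f1 <- estimate_flux(d$time_h, d$mass_nmol, g1, k = 0)
  # re-anchor t = 0 at 24 h: X0 rescales, v must not
  g2 <- list(mu = gt$mu, X0 = gt$X0 * exp(gt$mu * 24))
  f2 <- estimate_flux(d$time_h - 24, d$mass_nmol, g2, k = 0)
  expect_equal(f1$v, f2$v, tolerance = 1e-6)
  expect_equal(f1$v, gt$v_map[["GLC"]], tolerance = 1e-4)
})

test_that("noiseless synthetic pipeline recovers all parameters", {
  gt <- ground_truth(mu = 0.021, X0 = 25000, evap_rate = 0.002,
                     k_map = c(GLN = -0.003), seed = 2)
  t <- seq(0, 72, by = 24)
  cells <- simulate_growth_timecourse(gt, t, replicates = 1, noise = FALSE)
  med <- simulate_medium_timecourse(gt, t, replicates = 1, noise = FALSE)
  g <- fit_growth_rate(cells$time_h, cells$cells)
  expect_equal(g$mu, gt$mu, tolerance = 1e-8)
  expect_equal(g$X0, gt$X0, tolerance = 1e-3)
  for (a in c("GLC", "LAC", "GLN")) {
    k <- if (a %in% names(gt$k_map)) gt$k_map[[a]] else 0
    d <- med$medium[med$medium$analyte == a, ]
    fe <- estimate_flux(d$time_h, d$mass_nmol, g, k = k)
    expect_equal(fe$v, gt$v_map[[a]],
                 tolerance = 1e-6 * max(abs(gt$v_map[[a]]), 1),
                 label = paste("flux", a))
  }
})

test_that("noisy replicated estimates land near truth", {
  t <- seq(0, 72, by = 24)
  errs <- vapply(1:20, function(s) {
    gt <- ground_truth(seed = s)
    cells <- simulate_growth_timecourse(gt, t, replicates = 8)
    med <- simulate_medium_timecourse(gt, t, replicates = 8)
    g <- fit_growth_rate(cells$time_h, cells$cells)
    d <- med$medium[med$medium$analyte == "GLC", ]
    fe <- estimate_flux(d$time_h, d$mass_nmol, g, k = 0)
    abs(fe$v - gt$v_map[["GLC"]]) / abs(gt$v_map[["GLC"]])
  }, 1)
  expect_lt(median(errs), 0.10)
})

test_that("the long-format wrapper ties the stage together", {
  gt <- ground_truth(seed = 13)
  t <- seq(0, 72, by = 24)
  cells <- simulate_growth_timecourse(gt, t, replicates = 3)
  med <- simulate_medium_timecourse(gt, t, replicates = 3)
  tc <- rbind(
    data.frame(time_h = cells$time_h, replicate = cells$replicate,
               analyte = "cells", value = cells$cells),
    data.frame(time_h = med$medium$time_h,
               replicate = med$medium$replicate,
               analyte = med$medium$analyte, value = med$medium$conc_mM))
  out <- extracellular_fluxes(tc, med$dish_weights)
  expect_s3_class(out$growth, "growth_fit")
  expect_true(all(c("GLC", "LAC", "GLN") %in% out$fluxes$analyte))
  glc <- out$fluxes[out$fluxes$analyte == "GLC", ]
  expect_lt(abs(glc$v - gt$v_map[["GLC"]]) / 500, 0.2)
  expect_lt(out$fluxes$v[out$fluxes$analyte == "GLC"], 0)
  expect_gt(out$fluxes$v[out$fluxes$analyte == "LAC"], 0)
})

test_that("DNA standard curves interpolate cell counts linearly", {
  expect_equal(dna_to_cells(c(7.4, 14.8), pg_per_cell = 7.4e-3) * 1e-3,
               c(1, 2))
  expect_equal(dna_to_cells(10, 2, intercept_pg = 4), 3)
  expect_warning(dna_to_cells(1, 2, intercept_pg = 4), "non-positive")
})
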