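toy_fit_setup <- function(seed = 42, noise_sd = 0, flux_cv = 0.05) {
  toy <- toy_condensation_network()
  param <- free_flux_parameterization(toy)
  set.seed(seed)
  truth <- sample_flux_map(toy, param, net_range = c(5, 50))
  trs <- list(main = list(tracer("A.x", 1, fraction = 0.5)))
  mids <- simulate_steady_state_mids(toy, truth, trs$main)
  rows <- lapply(names(mids), function(m) {
    v <- as.numeric(mids[[m]])
    if (noise_sd > 0) {
      v <- pmax(v + rnorm(length(v), 0, noise_sd), 0)
      v <- v / sum(v)
    }
    data.frame(experiment = "main", metabolite = m,
               mass_shift = seq_along(v) - 1, value = v, sd = 0.003)
  })
  fl <- truth$net[c("AIN", "R4")]
  sdv <- pmax(abs(fl) * flux_cv, 0.5)
  if (noise_sd > 0) fl <- fl + rnorm(2, 0, sdv)
  ms <- measurement_set(mids = do.call(rbind, rows),
                        fluxes = data.frame(id = names(fl), value = fl,
                                            sd = sdv))
  list(network = toy, truth = truth, tracers = trs, ms = ms,
       param = param)
}

test_that("SSR is the weighted residual sum and pairs by name", {
  expect_equal(compute_ssr(c(a = 1, b = 2), c(a = 1, b = 2)), 0)
  expect_equal(compute_ssr(5, 3, sd = 1), 4)   # one 2-SD residual
  set.seed(1)
  sim <- rnorm(20); meas <- rnorm(20); sd <- runif(20, 0.5, 2)
  expect_equal(compute_ssr(sim, meas, sd), sum(((sim - meas) / sd)^2))
  expect_error(compute_ssr(c(a = 1), c(b = 1)), "paired")
})

test_that("chi-square intervals reproduce the published footnotes", {
  expect_equal(round(chi2_acceptance_interval(362), 1), c(311.2, 416.6))
  expect_equal(round(chi2_acceptance_interval(359), 1), c(308.4, 413.4))
  expect_equal(round(chi2_acceptance_interval(563), 1), c(499.1, 630.6))
  expect_equal(round(chi2_acceptance_interval(545), 1), c(482.2, 611.6))
  expect_equal(chi2_acceptance_interval(1),
               qchisq(c(0.025, 0.975), 1), tolerance = 1e-12)
  expect_error(chi2_acceptance_interval(0), "dof")
})

test_that("noiseless toy fits recover the generating fluxes", {
  cs <- toy_fit_setup(seed = 42, noise_sd = 0)
  fit <- fit_fluxes(cs$network, cs$ms, cs$tracers, restarts = 5, seed = 7,
                    net_scale = 50)
  expect_lt(fit$ssr, 1e-6)
  for (id in names(cs$truth$net))
    expect_equal(fit$flux$net[[id]], cs$truth$net[[id]],
                 tolerance = 1e-4 * max(abs(cs$truth$net[[id]]), 1),
                 label = paste("flux", id))
  expect_s3_class(fit, "flux_fit")
  expect_equal(fit$dof, cs$ms$n - cs$param$n_par)
})

test_that("fits are deterministic given the seed", {
  cs <- toy_fit_setup(seed = 1, noise_sd = 0.003)
  f1 <- fit_fluxes(cs$network, cs$ms, cs$tracers, restarts = 3, seed = 5,
                   net_scale = 50)
  f2 <- fit_fluxes(cs$network, cs$ms, cs$tracers, restarts = 3, seed = 5,
                   net_scale = 50)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$restart_table$ssr, f2$restart_table$ssr)
})

test_that("best-of-restarts SSR is non-increasing in restart count", {
  cs <- toy_fit_setup(seed = 3, noise_sd = 0.005)
  ssrs <- vapply(c(1, 3, 6), function(r)
    fit_fluxes(cs$network, cs$ms, cs$tracers, restarts = r, seed = 11,
               net_scale = 50)$ssr, 1)
  expect_true(all(diff(ssrs) <= 1e-8))
})

test_that("SSR at the truth is chi-square distributed over noise draws", {
  cs0 <- toy_fit_setup(seed = 8, noise_sd = 0)
  ctx <- make_fit_context(cs0$network, cs0$ms, cs0$tracers, cs0$param)
  th <- cs0$param$flux_to_theta(cs0$truth)
  clean <- fit_residuals(th, ctx)
  n <- cs0$ms$n
  set.seed(99)
  ssrs <- vapply(1:200, function(i) {
    noisy <- clean[seq_len(n)] + rnorm(n)
    sum(noisy^2)
  }, 1)
  ks <- suppressWarnings(stats::ks.test(ssrs, "pchisq", df = n))
  expect_gt(ks$p.value, 0.01)
})

test_that("wald intervals match the analytic form on a linear model", {
  # fluxes only (no labeling): the SSR surface is exactly quadratic
  toy <- parse_network("@unbalanced A C
R1: A (a) -> B (a)
R2: B (a) -> C (a)")
  ms <- measurement_set(fluxes = data.frame(id = c("R1", "R2"),
                                            value = c(10, 11),
                                            sd = c(1, 2)))
  fit <- fit_fluxes(toy, ms, list(), restarts = 2, seed = 1,
                    net_scale = 20)
  # weighted LS solution: v = (10/1 + 11/4)/(1 + 1/4)
  vhat <- (10 + 11 / 4) / (1 + 1 / 4)
  expect_equal(unname(fit$flux$net["R1"]), vhat, tolerance = 1e-6)
  se <- 1 / sqrt(1 + 1 / 4)
  ci <- confidence_intervals(fit, "R1")
  expect_equal(unname(ci[1, ]), c(vhat - 1.96 * se, vhat + 1.96 * se),
               tolerance = 1e-3)
  cip <- confidence_intervals(fit, "R1", method = "profile")
  expect_equal(unname(cip[1, ]), unname(ci[1, ]), tolerance = 0.02)
})

test_that("profile intervals flag unidentifiable parameters as unbounded", {
  cs <- toy_fit_setup(seed = 21, noise_sd = 0.003)
  # remove the flux measurements: absolute scale is then set only by the
  # two measured fluxes; drop them so one direction is unconstrained
  ms2 <- measurement_set(mids = cs$ms$mids)
  fit <- fit_fluxes(cs$network, ms2, cs$tracers, restarts = 3, seed = 2,
                    net_scale = 50)
  ci <- confidence_intervals(fit, "AIN", method = "profile", maxiter = 20)
  expect_true(!is.finite(ci[1, 2]) || ci[1, 2] > 1e3)
})

test_that("flux ratio tables match hand arithmetic and flag separation", {
  a <- data.frame(id = c("HK", "MCT", "Z"), flux = c(100, 200, 1e-9),
                  lb = c(95, 190, 0), ub = c(105, 210, 1))
  b <- data.frame(id = c("HK", "MCT", "Z"), flux = c(144, 178, 5),
                  lb = c(140, 168, 4), ub = c(148, 195, 6))
  rt <- flux_ratio_table(a, b)
  expect_equal(rt$ratio[rt$id == "HK"], 1.44)
  expect_equal(rt$ratio[rt$id == "MCT"], 0.89)
  expect_true(is.na(rt$ratio[rt$id == "Z"]))
  expect_match(rt$note[rt$id == "Z"], "omitted")
  expect_true(rt$distinct[rt$id == "HK"])
  expect_false(rt$distinct[rt$id == "MCT"])
  ident <- flux_ratio_table(a, a)
  expect_true(all(ident$ratio[1:2] == 1))
  expect_false(any(ident$distinct[1:2]))
})

test_that("growth normalization rescales fluxes as 1/mu", {
  v <- c(HK = 100, LDH = 50)
  expect_equal(growth_normalized_fluxes(v, 1)$normalized, c(100, 50))
  half <- growth_normalized_fluxes(v, 0.5)$normalized
  expect_equal(half, c(200, 100))
  expect_error(growth_normalized_fluxes(v, 0), "positive")
  # a raw decrease can become a normalized increase when growth slows more
  raw_a <- c(HK = 500); mu_a <- 0.024
  raw_b <- c(HK = 440); mu_b <- 0.017
  na_ <- growth_normalized_fluxes(raw_a, mu_a)$normalized
  nb_ <- growth_normalized_fluxes(raw_b, mu_b)$normalized
  expect_lt(raw_b[["HK"]], raw_a[["HK"]])
  expect_gt(nb_, na_)
})

test_that("measurement sets validate and floor their SDs", {
  m <- data.frame(experiment = "e", metabolite = "B", mass_shift = 0:1,
                  value = c(0.6, 0.4), sd = c(1e-5, 0.01))
  ms <- measurement_set(mids = m)
  expect_equal(ms$mids$sd, c(0.003, 0.01))
  expect_equal(ms$n, 2)
  expect_error(measurement_set(mids = m[, -5]), "misses columns")
  expect_error(measurement_set(fluxes = data.frame(id = "R", value = 1,
                                                   sd = 0)),
               "positive")
})
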