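# Synthetic-data generation with the exact statistical structure the
# downstream stages assume: exponential growth, first-order medium
# degradation/accumulation with evaporative volume loss, labeling
# dynamics from a known flux map, and QC-bracketed metabolomics batches
# with smooth instrument drift.

# deterministic per-operation substream of a global seed
substream_seed <- function(seed, op) {
  offs <- c(growth = 101L, medium = 211L, labeling = 307L,
            metabolomics = 401L)
  if (!op %in% names(offs)) stop("unknown substream: ", op)
  (as.integer(seed) * 1009L + offs[[op]]) %% 2147483647L
}

#' Define ground-truth parameters for synthetic culture data
#'
#' Defaults mirror the study conditions: 25,000 cells seeded per 35 mm
#' dish, sampling every 24 h for 72 h, ~2 mL medium, growth rates around
#' 0.02-0.024 1/h. Measurement-error magnitudes are configurable
#' defaults, not literature claims: MID SD 0.003 mol fraction,
#' concentration CV 5%, count CV 5% (lognormal).
#'
#' @param mu Growth rate (1/h).
#' @param X0 Initial cell count.
#' @param fluxes Optional [flux_map()] (balanced) for labeling dynamics.
#' @param pool_sizes Named pool sizes (fmol/cell) for nonstationary runs.
#' @param k_map Named first-order degradation/accumulation rates (1/h)
#'   per medium metabolite.
#' @param evap_rate Medium mass loss (g/h).
#' @param V0 Initial medium volume (mL; density 1 g/mL).
#' @param M0_map Named initial medium metabolite masses (nmol).
#' @param v_map Named extracellular fluxes (fmol/cell/h; negative =
#'   consumption).
#' @param noise List of per-channel noise SDs: `count_cv` (lognormal
#'   sdlog), `conc_cv` (Gaussian CV, floored at 0), `mid_sd`.
#' @param seed Global integer seed fanned out to per-operation
#'   substreams.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(mu = 0.0238, X0 = 25000, fluxes = NULL,
                         pool_sizes = NULL, k_map = numeric(),
                         evap_rate = 0.003, V0 = 2,
                         M0_map = c(GLC = 16000, LAC = 0, GLN = 2000),
                         v_map = c(GLC = -500, LAC = 1000, GLN = -40),
                         noise = list(count_cv = 0.05, conc_cv = 0.05,
                                      mid_sd = 0.003),
                         seed = 1) {
  stopifnot(mu >= 0, X0 > 0, evap_rate >= 0, V0 > 0,
            all(unlist(noise) >= 0))
  if (!is.null(pool_sizes)) stopifnot(all(pool_sizes > 0))
  structure(list(mu = mu, X0 = X0, fluxes = fluxes,
                 pool_sizes = pool_sizes, k_map = k_map,
                 evap_rate = evap_rate, V0 = V0, M0_map = M0_map,
                 v_map = v_map, noise = noise, seed = seed),
            class = "ground_truth")
}

#' Write / read a ground truth as YAML
#' @param truth A `ground_truth`.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$fluxes <- if (!is.null(truth$fluxes))
    list(net = as.list(truth$fluxes$net),
         exchange = as.list(truth$fluxes$exchange))
  if (!is.null(x$pool_sizes)) x$pool_sizes <- as.list(x$pool_sizes)
  if (length(x$k_map)) x$k_map <- as.list(x$k_map)
  x$M0_map <- as.list(x$M0_map)
  x$v_map <- as.list(x$v_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  fl <- NULL
  if (!is.null(x$fluxes))
    fl <- flux_map(unlist(x$fluxes$net), unlist(x$fluxes$exchange))
  ground_truth(mu = x$mu, X0 = x$X0, fluxes = fl,
               pool_sizes = if (length(x$pool_sizes)) unlist(x$pool_sizes),
               k_map = if (length(x$k_map)) unlist(x$k_map) else numeric(),
               evap_rate = x$evap_rate, V0 = x$V0,
               M0_map = unlist(x$M0_map), v_map = unlist(x$v_map),
               noise = x$noise, seed = x$seed)
}

#' Simulate cell-growth time courses
#'
#' Noiseless expectation `X0 exp(mu t)`; multiplicative lognormal noise
#' (counts stay positive). Reproducible given the truth's seed.
#'
#' @param truth A [ground_truth()].
#' @param times Sorted nonnegative times (h).
#' @param replicates Number of replicate wells.
#' @param noise Apply noise (`FALSE` returns the expectation).
#' @return Data frame: replicate, time_h, cells.
#' @export
simulate_growth_timecourse <- function(truth, times, replicates = 3,
                                       noise = TRUE) {
  if (any(times < 0)) stop("negative times")
  if (is.unsorted(times)) stop("times must be sorted")
  set.seed(substream_seed(truth$seed, "growth"))
  ex <- truth$X0 * exp(truth$mu * times)
  out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    x <- if (noise && truth$noise$count_cv > 0)
      ex * stats::rlnorm(length(times), 0, truth$noise$count_cv)
    else ex
    data.frame(replicate = r, time_h = times, cells = x)
  }))
  out
}

# closed-form medium metabolite mass (nmol) at time t
medium_mass_closed_form <- function(t, mu, X0, v_nmol, k, M0) {
  if (abs(mu + k) < 1e-12) {
    # analytic limit of the closed form as mu + k -> 0
    exp(-k * t) * (v_nmol * X0 * t + M0)
  } else {
    exp(-k * t) * (v_nmol * X0 / (mu + k) * (exp((mu + k) * t) - 1) + M0)
  }
}

#' Simulate medium metabolite time courses with evaporation
#'
#' Noiseless metabolite mass follows the exponential-growth mass balance
#' exactly; dish weight falls linearly at the evaporation rate and
#' concentration = mass / volume. Gaussian concentration noise is floored
#' at zero.
#'
#' @inheritParams simulate_growth_timecourse
#' @return List: `medium` data frame (replicate, time_h, analyte,
#'   conc_mM, mass_nmol), `dish_weights` (time_h, weight_g), and the
#'   volume function.
#' @export
simulate_medium_timecourse <- function(truth, times, replicates = 3,
                                       noise = TRUE) {
  if (any(times < 0)) stop("negative times")
  horizon <- max(times)
  depletion <- truth$V0 / truth$evap_rate
  if (truth$evap_rate > 0 && depletion <= horizon)
    stop("evaporation depletes the medium at t = ", signif(depletion, 4),
         " h, inside the sampling horizon")
  set.seed(substream_seed(truth$seed, "medium"))
  vol <- function(t) truth$V0 - truth$evap_rate * t
  analytes <- names(truth$M0_map)
  rows <- list()
  for (r in seq_len(replicates)) {
    for (a in analytes) {
      k <- if (a %in% names(truth$k_map)) truth$k_map[[a]] else 0
      v <- if (a %in% names(truth$v_map)) truth$v_map[[a]] else 0
      mass <- medium_mass_closed_form(times, truth$mu, truth$X0, v * 1e-6,
                                      k, truth$M0_map[[a]])
      conc <- mass / vol(times) / 1000     # nmol / mL -> mM
      if (noise && truth$noise$conc_cv > 0)
        conc <- pmax(conc * (1 + stats::rnorm(length(conc), 0,
                                              truth$noise$conc_cv)), 0)
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, time_h = times, analyte = a, conc_mM = conc,
        mass_nmol = conc * vol(times) * 1000)
    }
  }
  weigh_t <- seq(0, horizon, by = 24)
  list(medium = do.call(rbind, rows),
       dish_weights = data.frame(time_h = weigh_t,
                                 weight_g = truth$V0 -
                                   truth$evap_rate * weigh_t),
       volume = vol)
}

#' Simulate labeling measurements from a known flux map
#'
#' Noiseless MIDs equal the forward-model output (steady-state EMU solve,
#' or nonstationary integration when pool sizes and positive times are
#' supplied). Optional forward convolution with natural abundance
#' exercises the correction stage; additive Gaussian noise is truncated
#' at zero and renormalized to the simplex.
#'
#' @param truth A [ground_truth()] with a balanced `fluxes` map.
#' @param network A `flux_network`.
#' @param tracer_sets Named list of tracer experiments.
#' @param observed Metabolite ids to measure.
#' @param times `NULL` for isotopic steady state, else sampling times
#'   (h) for nonstationary labeling (requires `pool_sizes`).
#' @param replicates Replicate measurements per condition.
#' @param noise_sd MID measurement SD (mol fraction); `NULL` uses the
#'   truth's default.
#' @param natural_abundance Convolve with natural abundance using the
#'   supplied compositions (named list metabolite -> formula), or `NULL`
#'   for corrected-space output.
#' @param emu Optional precomputed decomposition.
#' @return Tidy data frame: experiment, metabolite, time (NA at steady
#'   state), replicate, mass_shift, fraction.
#' @export
simulate_labeling_measurements <- function(truth, network, tracer_sets,
                                           observed, times = NULL,
                                           replicates = 3, noise_sd = NULL,
                                           natural_abundance = NULL,
                                           emu = NULL) {
  if (is.null(truth$fluxes)) stop("ground truth carries no flux map")
  chk <- check_flux_balance(network, truth$fluxes, tol_rel = 1e-6)
  if (!attr(chk, "pass")) stop("ground-truth flux map is not balanced")
  if (is.null(noise_sd)) noise_sd <- truth$noise$mid_sd
  if (is.null(emu)) emu <- emu_decomposition(network, observed)
  set.seed(substream_seed(truth$seed, "labeling"))
  rows <- list()
  for (ex in names(tracer_sets)) {
    trs <- tracer_sets[[ex]]
    if (is.null(times)) {
      mids <- simulate_steady_state_mids(network, truth$fluxes, trs,
                                         emu = emu)
      frames <- list(list(time = NA_real_, mids = mids))
    } else {
      if (is.null(truth$pool_sizes))
        stop("nonstationary labeling needs pool_sizes")
      inst <- simulate_inst_mids(network, truth$fluxes, truth$pool_sizes,
                                 trs, times, emu = emu)
      frames <- lapply(seq_along(times), function(i)
        list(time = times[i],
             mids = lapply(inst[names(emu$observed)], function(m) m[i, ])))
    }
    for (fr in frames) {
      for (met in names(fr$mids)) {
        clean <- as.numeric(fr$mids[[met]])
        if (!is.null(natural_abundance)) {
          comp <- natural_abundance[[met]]
          if (is.null(comp)) stop("no composition for ", met)
          clean <- convolve_natural_abundance(clean, comp)
        }
        for (r in seq_len(replicates)) {
          x <- clean
          if (noise_sd > 0) {
            x <- pmax(clean + stats::rnorm(length(clean), 0, noise_sd), 0)
            x <- x / sum(x)
          }
          rows[[length(rows) + 1]] <- data.frame(
            experiment = ex, metabolite = met, time = fr$time,
            replicate = r, mass_shift = seq_along(x) - 1, fraction = x)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate an LC-MS metabolomics batch with drift and pooled QCs
#'
#' Pooled QC injections (sharing one composition, the column means of the
#' truth) bracket the run and recur every `qc_every` samples; a smooth
#' positive drift multiplies intensities as a function of injection
#' order; missingness is completely at random.
#'
#' @param truth_matrix Samples x features matrix of true abundances.
#' @param drift Function of injection order returning a positive
#'   multiplier, or a numeric vector; `NULL` (default) applies no drift.
#' @param qc_every QC spacing: one pooled QC between every `qc_every`
#'   samples (study protocol: 4), plus QCs at the beginning and end.
#' @param missing_rate MCAR missingness probability applied to samples.
#' @param noise_cv Multiplicative lognormal noise CV (0 = none).
#' @param seed Integer seed.
#' @return List: `areas` (matrix, rows in injection order), `manifest`
#'   data frame (injection, class, sample), `truth` row mapping.
#' @export
simulate_metabolomics_batch <- function(truth_matrix, drift = NULL,
                                        qc_every = 4, missing_rate = 0,
                                        noise_cv = 0, seed = 1) {
  stopifnot(qc_every >= 1, missing_rate >= 0, missing_rate < 1)
  set.seed(substream_seed(seed, "metabolomics"))
  ns <- nrow(truth_matrix)
  qc <- colMeans(truth_matrix)
  classes <- c("QC")
  srcs <- c(0L)
  for (i in seq_len(ns)) {
    classes <- c(classes, "sample")
    srcs <- c(srcs, i)
    if (i %% qc_every == 0 && i < ns) { classes <- c(classes, "QC"); srcs <- c(srcs, 0L) }
  }
  classes <- c(classes, "QC"); srcs <- c(srcs, 0L)
  n_inj <- length(classes)
  dr <- if (is.null(drift)) rep(1, n_inj)
        else if (is.function(drift)) vapply(seq_len(n_inj), drift, 1)
        else rep_len(drift, n_inj)
  if (any(dr <= 0)) stop("drift profile must be positive")
  areas <- matrix(NA_real_, n_inj, ncol(truth_matrix),
                  dimnames = list(NULL, colnames(truth_matrix)))
  for (i in seq_len(n_inj)) {
    base <- if (classes[i] == "QC") qc else truth_matrix[srcs[i], ]
    x <- base * dr[i]
    if (noise_cv > 0) x <- x * stats::rlnorm(length(x), 0, noise_cv)
    areas[i, ] <- x
  }
  if (missing_rate > 0) {
    sel <- which(classes == "sample")
    mask <- matrix(stats::runif(length(sel) * ncol(areas)) < missing_rate,
                   length(sel), ncol(areas))
    areas[sel, ][mask] <- NA
  }
  list(areas = areas,
       manifest = data.frame(injection = seq_len(n_inj), class = classes,
                             sample = ifelse(srcs == 0, NA, srcs)),
       drift = dr)
}
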