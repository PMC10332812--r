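# Parameter-recovery study on synthetic labeling data: the package's
# main self-validation surface for the fitting stage.

#' Reference synthetic flux map for the packaged network
#'
#' The published LF 21% oxygen net solution projected onto exact mass
#' balance, with exchange fluxes clipped to an identifiable magnitude
#' (1e3 fmol/cell/h): exchanges far above the largest net flux are
#' experimentally indistinguishable from infinite and make recovery
#' ill-posed by construction.
#'
#' @param network The network the map must live on (default: packaged LF
#'   network).
#' @param exch_cap Clip applied to the published exchange fluxes.
#' @return A balanced `flux_map`.
#' @export
reference_flux_map <- function(network = NULL, exch_cap = 1e3) {
  if (is.null(network)) network <- read_network(isoflux_network_file("lf"))
  d <- isoflux_flux_table("lf_oxygen")
  balance_flux_map(network,
                   flux_map(flux_table_vector(d, "21pct"),
                            pmin(flux_table_vector(d, "21pct", "EXCH"),
                                 exch_cap)))
}

#' The twelve measured metabolites of the packaged network
#'
#' 2-oxoglutarate, 3-phosphoglycerate, alanine, aspartate, citrate,
#' fructose bisphosphate, glutamate, glutamine, lactate, malate, pyruvate
#' (the mixed measured pool) and serine, as model ids.
#'
#' @return Character vector of metabolite ids.
#' @export
measured_metabolite_ids <- function() {
  c("AKG", "PG3", "ALA", "ASP", "CIT", "FBP", "GLU", "GLN", "LAC", "MAL",
    "PYR.ms", "SER")
}

# transport reactions observed by the extracellular-flux stage
extracellular_reaction_ids <- function() {
  c("GLUT", "PYRR", "MCT", "ALAR", "GLNR", "GLUR", "ASPR", "SERR",
    "CYSR", "GLYR")
}

#' Build one synthetic measurement set from a ground-truth flux map
#'
#' Generates MID measurements for the given tracer experiments (SD 0.003
#' mol fraction), noisy extracellular fluxes for the transport reactions
#' (CV 5%) and a growth-rate observation from the biomass flux (CV 5%).
#'
#' @param network A `flux_network`.
#' @param truth Balanced `flux_map` ground truth.
#' @param tracer_sets Named list of tracer experiments.
#' @param seed Integer seed for all noise draws.
#' @param mid_sd MID noise SD.
#' @param flux_cv Extracellular flux / growth relative error.
#' @param observed Measured metabolite ids.
#' @param emu Optional precomputed decomposition.
#' @return A [measurement_set()].
#' @export
synthetic_measurements <- function(network, truth, tracer_sets, seed,
                                   mid_sd = 0.003, flux_cv = 0.05,
                                   observed = measured_metabolite_ids(),
                                   emu = NULL) {
  gt <- ground_truth(fluxes = truth, seed = seed)
  lab <- simulate_labeling_measurements(gt, network, tracer_sets, observed,
                                        replicates = 1, noise_sd = mid_sd,
                                        emu = emu)
  mids <- data.frame(experiment = lab$experiment,
                     metabolite = lab$metabolite,
                     mass_shift = lab$mass_shift, value = lab$fraction,
                     sd = mid_sd)
  exf <- intersect(extracellular_reaction_ids(), names(truth$net))
  set.seed(substream_seed(seed, "medium"))
  sdv <- pmax(abs(truth$net[exf]) * flux_cv, 0.05)
  fv <- truth$net[exf] + stats::rnorm(length(exf), 0, sdv)
  growth <- NULL
  if ("BIOMASS" %in% names(truth$net)) {
    mu <- truth$net[["BIOMASS"]]
    growth <- c(mu + stats::rnorm(1, 0, mu * flux_cv), mu * flux_cv)
  }
  measurement_set(mids = mids,
                  fluxes = data.frame(id = exf, value = unname(fv),
                                      sd = unname(sdv)),
                  growth = growth, noise_model = "truncated")
}

#' Parameter-recovery study over noise replicates
#'
#' For each seed, generates a synthetic measurement set from the same
#' ground-truth flux map, fits it, and records confidence-interval
#' coverage of the true net fluxes. The first seed is fitted from
#' `restarts_first` random starts; later seeds reuse the first seed's
#' solution as a warm start alongside `restarts_rest` random starts —
#' the data differ only in noise, so the warm start is a computational
#' shortcut, not information about the current replicate's noise.
#'
#' A net flux counts as well determined when its magnitude exceeds
#' 1 fmol/cell/h and its interval is finite with width at most half the
#' estimate — fluxes with wider intervals are, by definition, not
#' resolved by the measurements, and fluxes at the polytope boundary
#' (near-zero or saturated mixing weights) have one-sided uncertainty a
#' symmetric interval cannot represent. Coverage is assessed over the
#' well-determined set.
#'
#' @param network A `flux_network`.
#' @param truth Balanced ground-truth `flux_map`.
#' @param tracer_sets Named list of tracer experiments.
#' @param seeds Integer seeds, one noise replicate each.
#' @param restarts_first,restarts_rest Random-start counts.
#' @param rounds Optimization rounds per start (see [fit_fluxes()]).
#' @param level Confidence level for the intervals.
#' @param ... Passed to [fit_fluxes()].
#' @return A `recovery_study`: per-seed table (seed, ssr, dof, accepted,
#'   n_well, n_covered) and the pooled coverage fraction.
#' @export
recovery_study <- function(network, truth, tracer_sets, seeds = 1:20,
                           restarts_first = 6, restarts_rest = 0,
                           rounds = 10, level = 0.95, ...) {
  emu <- emu_decomposition(network, measured_metabolite_ids())
  param <- free_flux_parameterization(network)
  ref <- NULL
  rows <- list()
  covered_all <- 0
  well_all <- 0
  for (i in seq_along(seeds)) {
    s <- seeds[i]
    ms <- synthetic_measurements(network, truth, tracer_sets, seed = s,
                                 emu = emu)
    fit <- if (i == 1) {
      fit_fluxes(network, ms, tracer_sets, restarts = restarts_first,
                 seed = s, rounds = rounds, round_tol = 0.002, beam = 1,
                 param = param, emu = emu, ...)
    } else {
      fit_fluxes(network, ms, tracer_sets, restarts = restarts_rest,
                 seed = s, start = ref, rounds = 4, round_tol = 0.002,
                 maxiter = 60, bfgs_maxit = 60, param = param, emu = emu,
                 ...)
    }
    if (i == 1) ref <- fit$flux
    ci <- confidence_intervals(fit, level = level)
    ids <- sub("^net\\.", "", rownames(ci))
    width <- ci[, 2] - ci[, 1]
    est <- abs(fit$flux$net[ids])
    well <- is.finite(width) & est > 1 & width <= 0.5 * est
    cov <- truth$net[ids] >= ci[, 1] & truth$net[ids] <= ci[, 2]
    rows[[i]] <- data.frame(seed = s, ssr = fit$ssr, dof = fit$dof,
                            accepted = fit$accepted,
                            n_well = sum(well),
                            n_covered = sum(cov & well))
    covered_all <- covered_all + sum(cov & well)
    well_all <- well_all + sum(well)
  }
  structure(list(per_seed = do.call(rbind, rows),
                 coverage = covered_all / well_all,
                 n_well = well_all, level = level),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf(
    "Recovery study: %d seeds, %.1f%% CI coverage over %d well-determined fluxes\n",
    nrow(x$per_seed), 100 * x$coverage, x$n_well))
  cat(sprintf("  accepted fits: %d/%d\n", sum(x$per_seed$accepted),
              nrow(x$per_seed)))
  invisible(x)
}
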