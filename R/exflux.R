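# Growth-rate and extracellular-flux estimation from culture time courses.
#
# Under exponential growth X = X0 exp(mu t) and first-order medium
# degradation/accumulation dM/dt = -kM + vX, metabolite mass obeys the
# closed form M exp(kt) = v X0 / (mu + k) (exp((mu + k) t) - 1) + M0, so
# the per-cell flux v follows from the slope of M exp(kt) regressed on
# exp((mu + k) t) - 1. Negative fluxes denote consumption.

huber_rlm <- function(x, y) {
  if (length(unique(x)) < 2) stop("degenerate design: need >=2 distinct x")
  ols <- stats::lm(y ~ x)
  # an (almost) exact fit starves the robust scale estimate; ordinary
  # least squares is then already the M-estimate
  if (stats::sigma(ols) < 1e-8 * max(stats::mad(y), abs(stats::median(y)),
                                     1e-12)) {
    # summary.lm warns about "essentially perfect" fits; near-zero SEs
    # are the correct answer for noiseless data
    cf <- suppressWarnings(summary(ols)$coefficients)
    return(list(fit = ols, intercept = cf[1, 1], slope = cf[2, 1],
                se_intercept = cf[1, 2], se_slope = cf[2, 2]))
  }
  fit <- MASS::rlm(y ~ x, k = 1.345, maxit = 200)
  cf <- summary(fit)$coefficients
  list(fit = fit,
       intercept = cf[1, 1], slope = cf[2, 1],
       se_intercept = cf[1, 2], se_slope = cf[2, 2])
}

#' Interpolate cell counts from total DNA
#'
#' Cultures assayed by DNA quantification are converted to cell counts
#' through a linear standard curve calibrated per cell type (DNA mass per
#' cell from known seedings).
#'
#' @param dna_pg Total DNA (pg).
#' @param pg_per_cell Standard-curve slope (pg DNA per cell).
#' @param intercept_pg Standard-curve intercept (pg).
#' @return Estimated cell counts.
#' @export
dna_to_cells <- function(dna_pg, pg_per_cell, intercept_pg = 0) {
  stopifnot(pg_per_cell > 0)
  counts <- (dna_pg - intercept_pg) / pg_per_cell
  if (any(counts <= 0))
    warning("non-positive interpolated cell counts")
  counts
}

#' Flag outliers by the median-absolute-deviation rule
#'
#' Marks values farther than `cutoff` times the median absolute deviation
#' from the median.
#'
#' @param x Numeric vector.
#' @param cutoff Multiplier on the MAD (default 2).
#' @return Logical vector, `TRUE` for outliers.
#' @export
mad_outliers <- function(x, cutoff = 2) {
  md <- stats::median(x, na.rm = TRUE)
  m <- stats::mad(x, na.rm = TRUE)
  if (m == 0) return(rep(FALSE, length(x)))
  abs(x - md) > cutoff * m
}

#' Fit a growth rate from a cell-count time course
#'
#' Robust (Huber M-estimation, tuning constant 1.345) linear fit of
#' log cell count against time: the slope is the growth rate mu (1/h) and
#' the exponentiated intercept the count at time 0.
#'
#' @param times Times (h).
#' @param counts Cell counts (or DNA-interpolated counts), all positive.
#' @param flag_outliers Pre-screen log-counts with [mad_outliers()] on the
#'   residuals of an initial least-squares line before the robust fit.
#' @return A `growth_fit` object: `mu`, `X0`, standard errors, fitted
#'   values and outlier flags.
#' @export
fit_growth_rate <- function(times, counts, flag_outliers = FALSE) {
  stopifnot(length(times) == length(counts))
  if (length(unique(times)) < 3) stop("need at least 3 distinct time points")
  if (any(counts <= 0)) stop("non-positive cell counts")
  keep <- rep(TRUE, length(times))
  if (flag_outliers) {
    res <- stats::residuals(stats::lm(log(counts) ~ times))
    keep <- !mad_outliers(res)
  }
  h <- huber_rlm(times[keep], log(counts[keep]))
  structure(list(mu = unname(h$slope), X0 = exp(unname(h$intercept)),
                 se_mu = unname(h$se_slope),
                 se_lnX0 = unname(h$se_intercept),
                 times = times, counts = counts, used = keep,
                 fit = h$fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit: mu = %.5f 1/h (SE %.5f), X0 = %.0f cells\n",
              x$mu, x$se_mu, x$X0))
  cat(sprintf("  doubling time %.1f h; %d/%d points used\n",
              log(2) / x$mu, sum(x$used), length(x$used)))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu = object$mu, X0 = object$X0)
}

#' Piecewise-linear well volume from dish weights
#'
#' Converts cell-free dish weighings to a volume function assuming medium
#' density 1.00 g/mL and linear interpolation between weighings.
#' Weight gains beyond `tol` trigger a warning and are clamped so the
#' volume is monotone non-increasing.
#'
#' @param times Weighing times (h).
#' @param weights Medium weights (g).
#' @param tol Allowed non-monotone wiggle (g) before warning.
#' @return Function `volume(t)` returning mL (constant extrapolation
#'   outside the weighing range).
#' @export
estimate_evaporation <- function(times, weights, tol = 1e-6) {
  stopifnot(length(times) == length(weights), length(times) >= 2)
  o <- order(times)
  times <- times[o]; weights <- weights[o]
  if (any(diff(weights) > tol))
    warning("dish weights increase over time; clamping to monotone")
  weights <- cummin(weights)
  if (any(weights <= 0))
    stop("medium depleted by evaporation at t = ",
         times[which(weights <= 0)[1]], " h")
  stats::approxfun(times, weights, rule = 2)   # 1 g/mL
}

#' First-order degradation rates from unconditioned medium
#'
#' Robust fit of log metabolite mass against time in cell-free medium.
#' Under the governing balance `dM/dt = -kM + vX` a positive `k` is
#' degradation, so the reported rate is the negated slope of `ln M`
#' against `t`. A t-test on the slope at level `alpha` decides whether
#' the rate enters downstream flux calculations (`k_effective` is 0 when
#' not significant).
#'
#' @param times Times (h).
#' @param masses Metabolite masses (nmol), positive.
#' @param alpha Significance level for inclusion.
#' @return A `degradation_rate`: `k` (1/h, positive = degradation), `se`,
#'   `p`, `used`, `k_effective`.
#' @export
estimate_degradation <- function(times, masses, alpha = 0.05) {
  stopifnot(length(times) == length(masses))
  if (length(times) < 3) stop("need at least 3 points")
  if (any(masses <= 0)) stop("non-positive masses")
  h <- huber_rlm(times, log(masses))
  k <- -unname(h$slope)
  se <- unname(h$se_slope)
  df <- length(times) - 2
  p <- 2 * stats::pt(abs(k / se), df, lower.tail = FALSE)
  used <- is.finite(p) && p < alpha
  structure(list(k = k, se = se, p = p, df = df, used = used,
                 k_effective = if (used) k else 0),
            class = "degradation_rate")
}

#' @export
print.degradation_rate <- function(x, ...) {
  cat(sprintf("k = %.3g 1/h (SE %.2g, p = %.3g) -> %s\n", x$k, x$se, x$p,
              if (x$used) "included" else "treated as 0"))
  invisible(x)
}

#' Estimate an extracellular flux from metabolite masses
#'
#' Robust regression of `M exp(kt)` on `exp((mu + k) t) - 1`; the slope s
#' gives `v = s (mu + k) / X0`. When `mu + k = 0` the analytic limit is
#' used: `M exp(kt)` is linear in `t` with slope `v X0`. Masses in nmol
#' with counts in cells yield v in fmol/cell/h after the unit conversion
#' applied internally (1 nmol = 1e6 fmol). Negative values indicate
#' consumption.
#'
#' @param times Times (h).
#' @param masses Metabolite masses (nmol), typically concentration times
#'   well volume.
#' @param growth A `growth_fit` (or list with `mu`, `X0`).
#' @param k First-order degradation/accumulation rate (1/h), usually
#'   `k_effective` from [estimate_degradation()].
#' @return A `flux_estimate`: `v` (fmol/cell/h), `se`, `M0` (nmol).
#' @export
estimate_flux <- function(times, masses, growth, k = 0) {
  stopifnot(length(times) == length(masses))
  if (length(unique(times)) < 3) stop("need at least 3 distinct time points")
  mu <- growth$mu; X0 <- growth$X0
  y <- masses * exp(k * times)
  if (abs(mu + k) < 1e-10) {
    h <- huber_rlm(times, y)
    v_nmol <- unname(h$slope) / X0
    se_nmol <- unname(h$se_slope) / X0
  } else {
    x <- exp((mu + k) * times) - 1
    h <- huber_rlm(x, y)
    v_nmol <- unname(h$slope) * (mu + k) / X0
    se_nmol <- unname(h$se_slope) * abs(mu + k) / X0
  }
  structure(list(v = v_nmol * 1e6, se = se_nmol * 1e6,
                 M0 = unname(h$intercept), mu = mu, k = k, X0 = X0),
            class = "flux_estimate")
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("v = %.4g fmol/cell/h (SE %.2g) [%s]\n", x$v, x$se,
              if (x$v < 0) "consumption" else "production"))
  invisible(x)
}

#' Full extracellular-flux stage on a long-format time course
#'
#' Convenience wrapper running growth fitting, evaporation correction,
#' degradation screening and flux regression for every metabolite of a
#' tidy long table.
#'
#' @param tc Data frame with columns `time_h`, `replicate`, `analyte`,
#'   `value`; cell counts carry `analyte == "cells"`, other analytes are
#'   medium concentrations (mM).
#' @param dish_weights Data frame with `time_h`, `weight_g` from cell-free
#'   dishes.
#' @param unconditioned Optional data frame (`time_h`, `analyte`, `value`
#'   mM) from cell-free medium for degradation screening.
#' @param alpha Significance level passed to [estimate_degradation()].
#' @return List with `growth` (a `growth_fit`) and `fluxes` (data frame:
#'   analyte, v, se, k, k_used).
#' @export
extracellular_fluxes <- function(tc, dish_weights, unconditioned = NULL,
                                 alpha = 0.05) {
  vol <- estimate_evaporation(dish_weights$time_h, dish_weights$weight_g)
  cells <- tc[tc$analyte == "cells", ]
  growth <- fit_growth_rate(cells$time_h, cells$value)
  analytes <- setdiff(unique(tc$analyte), "cells")
  rows <- lapply(analytes, function(a) {
    d <- tc[tc$analyte == a, ]
    mass <- d$value * vol(d$time_h)   # mM * mL = umol -> nmol
    mass <- mass * 1e3
    k <- 0; k_used <- FALSE
    if (!is.null(unconditioned)) {
      u <- unconditioned[unconditioned$analyte == a, ]
      if (nrow(u) >= 3) {
        dr <- estimate_degradation(u$time_h, u$value * vol(u$time_h) * 1e3,
                                   alpha = alpha)
        k <- dr$k_effective; k_used <- dr$used
      }
    }
    fe <- estimate_flux(d$time_h, mass, growth, k = k)
    data.frame(analyte = a, v = fe$v, se = fe$se, k = k, k_used = k_used)
  })
  list(growth = growth, fluxes = do.call(rbind, rows))
}
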