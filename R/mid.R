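# Natural-abundance correction of mass isotopomer distributions.

#' Representative natural isotope abundances
#'
#' Heavy-isotope abundances used to build correction matrices: 13C 0.0107,
#' 2H 0.000115, 15N 0.00364, 17O 0.00038, 18O 0.00205, 29Si 0.0468,
#' 30Si 0.0309, 33S 0.0076, 34S 0.0429 (IUPAC representative values);
#' phosphorus is monoisotopic.
#' Each element maps to a vector of (abundance, mass shift) pairs encoded
#' as a numeric vector indexed by mass shift starting at 0.
#'
#' @return Named list of per-element isotope distributions.
#' @export
natural_abundances <- function() {
  list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    P = 1,
    S = c(0.9495, 0.0076, 0.0429),
    Si = c(0.9223, 0.0468, 0.0309))
}

#' Parse an elemental composition
#'
#' @param formula Either a named integer vector (`c(C = 3, H = 4, O = 3)`)
#'   or a molecular formula string (`"C3H4O3"`).
#' @return Named integer vector of element counts.
#' @export
element_composition <- function(formula) {
  if (is.numeric(formula)) {
    stopifnot(!is.null(names(formula)), all(formula >= 0))
    return(formula)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  counts <- integer()
  for (tk in toks) {
    el <- gsub("[0-9]", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    counts[el] <- (if (el %in% names(counts)) counts[el] else 0L) +
      (if (nzchar(n)) as.integer(n) else 1L)
  }
  counts
}

#' Build a natural-abundance correction matrix
#'
#' Column j (0-based) is the expected measured MID of a species carrying
#' exactly j tracer-element labels: the multinomial isotope expansion of
#' all non-tracer atoms convolved with the natural-isotope distribution of
#' the remaining (n - j) unlabeled tracer-element atoms, truncated to mass
#' shifts 0..n. Columns are sub-distributions (entries >= 0, sums <= 1).
#'
#' @param comp Elemental composition ([element_composition()] input).
#' @param abundances Per-element isotope distributions; default
#'   [natural_abundances()].
#' @param tracer_element Element carrying the label (carbon).
#' @return (n+1) x (n+1) matrix, n = tracer-element atom count.
#' @export
build_correction_matrix <- function(comp, abundances = natural_abundances(),
                                    tracer_element = "C") {
  comp <- element_composition(comp)
  unknown <- setdiff(names(comp)[comp > 0], names(abundances))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  n <- comp[[tracer_element]]
  if (is.null(n) || n < 1)
    stop("composition must contain at least one ", tracer_element)
  # isotope envelope of all non-tracer atoms
  base <- 1
  for (el in names(comp)) {
    if (el == tracer_element || comp[[el]] == 0) next
    d <- abundances[[el]]
    for (i in seq_len(comp[[el]])) base <- convolve_mid(base, d)
  }
  dC <- abundances[[tracer_element]]
  M <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    env <- base
    if (n - j > 0)
      for (i in seq_len(n - j)) env <- convolve_mid(env, dC)
    col <- numeric(n + 1)
    idx <- j + seq_along(env)        # labeled atoms shift the envelope by j
    keep <- idx <= n + 1
    col[idx[keep]] <- env[keep]
    M[, j + 1] <- col
  }
  M
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves `M x = raw` by nonnegative least squares (so noisy data cannot
#' produce negative fractions) and renormalizes `x` to the simplex.
#'
#' @param raw Numeric vector of measured fractions M0..Mn (normalized or
#'   normalizable).
#' @param comp Elemental composition of the measured ion.
#' @param abundances Isotope table, default [natural_abundances()].
#' @param max_condition Condition-number guard for the correction matrix.
#' @return Corrected MID vector; attributes `"residual"` (NNLS residual
#'   norm) and `"raw_fit"`.
#' @export
correct_natural_abundance <- function(raw, comp,
                                      abundances = natural_abundances(),
                                      max_condition = 1e8) {
  M <- build_correction_matrix(comp, abundances)
  if (length(raw) != nrow(M))
    stop("raw MID length ", length(raw), " does not match matrix size ",
         nrow(M))
  kap <- kappa(M, exact = TRUE)
  if (kap > max_condition)
    stop("ill-conditioned correction matrix (condition number ",
         signif(kap, 3), ")")
  raw <- raw / sum(raw)
  fit <- pracma::lsqnonneg(M, raw)
  x <- fit$x
  if (sum(x) <= 0) stop("natural-abundance correction collapsed to zero")
  out <- x / sum(x)
  attr(out, "residual") <- sqrt(fit$resid.norm)
  attr(out, "raw_fit") <- as.vector(M %*% x)
  out
}

#' Forward-convolve a clean MID with natural abundance
#'
#' The generative counterpart of [correct_natural_abundance()]: computes
#' the MID an instrument would measure for a species with the given
#' tracer-labeling distribution. Round-tripping through the correction
#' recovers the input.
#'
#' @param mid Clean MID vector M0..Mn.
#' @param comp Elemental composition.
#' @param abundances Isotope table.
#' @return Measured-space MID (renormalized over shifts 0..n).
#' @export
convolve_natural_abundance <- function(mid, comp,
                                       abundances = natural_abundances()) {
  M <- build_correction_matrix(comp, abundances)
  v <- as.vector(M %*% mid)
  v / sum(v)
}

#' Normalize isotopologue peak areas to a MID
#'
#' Negative areas (baseline artifacts) are clamped to zero with a warning.
#'
#' @param areas Numeric vector of peak areas M0..Mn.
#' @return MID vector summing to 1.
#' @export
normalize_peak_areas <- function(areas) {
  if (any(areas < 0)) {
    warning("negative peak area(s) clamped to 0")
    areas <- pmax(areas, 0)
  }
  s <- sum(areas)
  if (s <= 0) stop("all peak areas are zero")
  areas / s
}

#' Quadrupole bias hook
#'
#' Applies optional per-mass multiplicative transmission factors to raw
#' areas. The default is a pass-through (all factors 1); instrument-
#' specific factors must be supplied by the user.
#'
#' @param areas Numeric vector of peak areas.
#' @param factors Multiplicative factor per mass shift (recycled if
#'   length 1).
#' @return Adjusted areas.
#' @export
apply_mass_bias <- function(areas, factors = 1) {
  if (length(factors) == 1) factors <- rep(factors, length(areas))
  stopifnot(length(factors) == length(areas), all(factors > 0))
  areas * factors
}
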