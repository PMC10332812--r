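#' Define a labeled tracer component
#'
#' A tracer component is one isotopic species of a substrate: the labeled
#' carbon positions, its mole fraction in the substrate mixture, and the
#' isotopic purity of the labeled positions. Unspecified substrates, and
#' the remaining mole fraction of a partially labeled substrate, are
#' unlabeled (simulation runs in natural-abundance-corrected space, so
#' unlabeled means M0 = 1).
#'
#' @param substrate Metabolite id of the (unbalanced) substrate,
#'   e.g. `"GLC.x"`.
#' @param positions Integer vector of labeled carbon positions (empty for
#'   an unlabeled component).
#' @param fraction Mole fraction of this component in the substrate.
#' @param purity Probability that a nominally labeled position carries
#'   the heavy isotope.
#' @param enrichment Per-position enrichment multiplier (default 1).
#' @return A `tracer` object (a named list).
#' @export
tracer <- function(substrate, positions = integer(), fraction = 1,
                   purity = 1, enrichment = 1) {
  stopifnot(fraction >= 0, fraction <= 1, purity > 0, purity <= 1,
            enrichment >= 0, enrichment <= 1)
  structure(list(substrate = substrate, positions = as.integer(positions),
                 fraction = fraction, purity = purity,
                 enrichment = enrichment), class = "tracer")
}

#' The three-tracer design used for the packaged network
#'
#' [1,2-13C2] glucose, [U-13C6] glucose and [U-13C5] glutamine, as three
#' parallel labeling experiments.
#'
#' @param purity Isotopic purity applied to every labeled position.
#' @return Named list of three tracer sets (each a list of [tracer()]s).
#' @export
standard_tracer_sets <- function(purity = 0.99) {
  list(
    glc12 = list(tracer("GLC.x", c(1, 2), 1, purity)),
    glcU  = list(tracer("GLC.x", 1:6, 1, purity)),
    glnU  = list(tracer("GLN.x", 1:5, 1, purity)))
}

# positional label probabilities for each mixture component of a substrate;
# returns list of list(prob = numeric(carbons), fraction)
tracer_components <- function(tracers, met, carbons) {
  comps <- list()
  tot <- 0
  for (tr in tracers) {
    if (!inherits(tr, "tracer")) stop("tracers must be tracer() objects")
    if (tr$substrate != met) next
    p <- rep(0, carbons)
    if (length(tr$positions)) {
      if (max(tr$positions) > carbons)
        stop("tracer position beyond carbon count of ", met)
      p[tr$positions] <- tr$purity * tr$enrichment
    }
    comps[[length(comps) + 1]] <- list(prob = p, fraction = tr$fraction)
    tot <- tot + tr$fraction
  }
  if (tot > 1 + 1e-9) stop("tracer fractions for ", met, " exceed 1")
  if (tot < 1 - 1e-9)
    comps[[length(comps) + 1]] <- list(prob = rep(0, carbons),
                                       fraction = 1 - tot)
  if (!length(comps)) comps <- list(list(prob = rep(0, carbons), fraction = 1))
  comps
}

#' Effective input MID of a (possibly impure) tracer substrate
#'
#' Each nominally labeled position carries the heavy isotope independently
#' with probability `purity`, so e.g. a uniformly labeled C6 substrate at
#' purity 0.99 has an M6 fraction of 0.99^6.
#'
#' @param tracers List of [tracer()] components describing one substrate.
#' @param met Substrate metabolite id.
#' @param carbons Number of carbon atoms.
#' @param positions Carbon positions of the fragment (default: all).
#' @return Numeric MID vector of length `length(positions) + 1`.
#' @export
apply_tracer_impurity <- function(tracers, met, carbons,
                                  positions = seq_len(carbons)) {
  comps <- tracer_components(tracers, met, carbons)
  mid <- rep(0, length(positions) + 1)
  for (cm in comps) {
    v <- 1
    for (p in cm$prob[positions]) v <- convolve_mid(v, c(1 - p, p))
    mid <- mid + cm$fraction * v
  }
  mid
}

# discrete convolution of two MID vectors
convolve_mid <- function(a, b) {
  n <- length(a) + length(b) - 1
  out <- numeric(n)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# full positional isotopomer distribution (length 2^carbons) of a substrate;
# bit i of the state index (little-endian) is carbon position i
tracer_isotopomers <- function(tracers, met, carbons) {
  comps <- tracer_components(tracers, met, carbons)
  dist <- numeric(2^carbons)
  for (cm in comps) dist <- dist + cm$fraction * iso_from_prob(cm$prob)
  dist
}

# independent-position isotopomer distribution; bit (i-1) of the state
# index marks a label at carbon i
iso_from_prob <- function(prob) {
  d <- 1
  for (p in prob) d <- as.vector(outer(d, c(1 - p, p)))
  d
}
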