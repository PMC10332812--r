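# Untargeted-metabolomics processing: pooled-QC drift correction,
# feature filtering, imputation, probabilistic quotient normalization.
# The pipeline order is fixed: drift -> filter -> impute -> normalize.

#' Correct instrument drift against pooled QC injections
#'
#' Per feature, fits a cubic smoothing spline (stiffness by generalized
#' cross-validation) of QC peak area against injection order, divides
#' every injection by the spline prediction at its order, and rescales to
#' the median QC level. With fewer than four QC points a linear model is
#' used instead, with a warning.
#'
#' @param areas Matrix of peak areas, rows in injection order.
#' @param classes Character vector per row: `"QC"` or `"sample"`.
#' @param injection Injection order (default row order).
#' @return Corrected matrix (same dimensions; NA preserved).
#' @export
drift_correct <- function(areas, classes, injection = seq_len(nrow(areas))) {
  stopifnot(nrow(areas) == length(classes),
            length(injection) == nrow(areas))
  qi <- which(classes == "QC")
  if (length(qi) < 3) stop("need at least 3 QC injections")
  out <- areas
  linear_warned <- FALSE
  for (j in seq_len(ncol(areas))) {
    y <- areas[qi, j]
    ok <- is.finite(y) & y > 0
    if (sum(ok) < 3) next
    x <- injection[qi][ok]
    if (sum(ok) >= 4) {
      sp <- stats::smooth.spline(x, y[ok], cv = FALSE)
      pred <- stats::predict(sp, injection)$y
    } else {
      if (!linear_warned) {
        warning("fewer than 4 usable QCs; falling back to a linear drift model")
        linear_warned <- TRUE
      }
      lf <- stats::lm(y[ok] ~ x)
      pred <- stats::predict(lf, data.frame(x = injection))
    }
    pred[pred <= 0] <- NA
    out[, j] <- areas[, j] / pred * stats::median(y[ok])
  }
  out
}

#' Filter unreliable features by QC statistics
#'
#' Removes features with a relative standard deviation above `rsd_max`
#' in the pooled QC injections or a dispersion ratio (QC variability over
#' biological-sample variability) above `dratio_max`. Retained features'
#' values are never altered.
#'
#' @param areas Drift-corrected matrix.
#' @param classes `"QC"`/`"sample"` per row.
#' @param rsd_max QC relative-standard-deviation threshold (default 0.2).
#' @param dratio_max Dispersion-ratio threshold (default 0.4).
#' @param robust Use MAD-based spreads instead of standard deviations.
#' @return List: `report` data frame (feature, rsd, dratio, retained,
#'   reason) and `filtered` matrix of retained features.
#' @export
filter_features <- function(areas, classes, rsd_max = 0.2,
                            dratio_max = 0.4, robust = FALSE) {
  qi <- classes == "QC"
  si <- classes == "sample"
  spread <- if (robust) function(x) stats::mad(x, na.rm = TRUE)
            else function(x) stats::sd(x, na.rm = TRUE)
  rep <- data.frame(feature = colnames(areas) %||% seq_len(ncol(areas)),
                    rsd = NA_real_, dratio = NA_real_,
                    retained = FALSE, reason = "")
  for (j in seq_len(ncol(areas))) {
    q <- areas[qi, j]; s <- areas[si, j]
    mq <- mean(q, na.rm = TRUE)
    if (!is.finite(mq) || mq == 0) {
      rep$reason[j] <- "undefined RSD (zero/NA QC mean)"
      next
    }
    rsd <- spread(q) / mq
    ssd <- spread(s)
    dr <- if (is.finite(ssd) && ssd > 0) spread(q) / ssd else 0
    rep$rsd[j] <- rsd; rep$dratio[j] <- dr
    if (rsd > rsd_max) rep$reason[j] <- "QC RSD above threshold"
    else if (dr > dratio_max) rep$reason[j] <- "dispersion ratio above threshold"
    else rep$retained[j] <- TRUE
  }
  list(report = rep, filtered = areas[, rep$retained, drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute missing peak areas
#'
#' Pluggable strategies: `"rf"` (iterative random-forest imputation,
#' default), `"knn"` (k-nearest samples on shared features), and
#' `"halfmin"` (half the feature minimum). Deterministic given `seed`.
#'
#' @param areas Matrix with missing values.
#' @param strategy Imputation strategy.
#' @param seed Integer seed (random forest).
#' @param k Neighbors for `"knn"`.
#' @param iterations Random-forest refinement passes.
#' @return Complete matrix.
#' @export
impute_missing <- function(areas, strategy = c("rf", "knn", "halfmin"),
                           seed = 1, k = 5, iterations = 2) {
  strategy <- match.arg(strategy)
  miss <- is.na(areas)
  if (!any(miss)) return(areas)
  allmiss <- colSums(!miss) == 0
  if (any(allmiss))
    stop("feature(s) entirely missing: ",
         paste(utils::head(which(allmiss), 5), collapse = ", "))
  frac <- colMeans(miss)
  if (any(frac >= 0.5))
    stop("feature(s) with >=50% missing values; filter first")
  halfmin <- function(m) {
    for (j in seq_len(ncol(m))) {
      mj <- is.na(m[, j])
      if (any(mj)) m[mj, j] <- min(m[, j], na.rm = TRUE) / 2
    }
    m
  }
  if (strategy == "halfmin") return(halfmin(areas))
  if (strategy == "knn") {
    out <- areas
    for (i in which(rowSums(miss) > 0)) {
      for (j in which(miss[i, ])) {
        shared <- !miss[i, ] & !miss[, j]
        cand <- which(shared & seq_len(nrow(areas)) != i)
        if (!length(cand)) next
        d <- vapply(cand, function(r) {
          cols <- !miss[i, ] & !miss[r, ]
          sqrt(mean((areas[i, cols] - areas[r, cols])^2))
        }, 1)
        nn <- cand[order(d)[seq_len(min(k, length(cand)))]]
        out[i, j] <- mean(areas[nn, j])
      }
    }
    return(halfmin(out))
  }
  # iterative random forest: initialize with half-minimum, then refit
  # each incomplete feature on the others
  set.seed(seed)
  out <- halfmin(areas)
  for (it in seq_len(iterations)) {
    for (j in which(colSums(miss) > 0)) {
      train <- !miss[, j]
      rf <- randomForest::randomForest(
        x = out[train, -j, drop = FALSE], y = areas[train, j],
        ntree = 100)
      out[!train, j] <- stats::predict(rf, out[!train, -j, drop = FALSE])
    }
  }
  out
}

#' Probabilistic quotient normalization
#'
#' Each sample's dilution quotient is the median over features of its
#' ratio to a reference spectrum (median QC spectrum by default, median
#' over all samples otherwise); dividing by the quotient removes
#' sample-level dilution exactly and is robust to a minority of truly
#' changing features. Applying it twice equals applying it once.
#'
#' @param areas Complete matrix.
#' @param classes Optional `"QC"`/`"sample"` classes (for the QC
#'   reference).
#' @param reference `"median QC"` or `"median"` or a numeric reference
#'   spectrum.
#' @return List: `normalized` matrix, `quotients` per sample.
#' @export
pqn_normalize <- function(areas, classes = NULL,
                          reference = "median QC") {
  if (is.character(reference)) {
    ref <- if (identical(reference, "median QC") && !is.null(classes) &&
               any(classes == "QC"))
      apply(areas[classes == "QC", , drop = FALSE], 2, stats::median)
    else apply(areas, 2, stats::median)
  } else ref <- reference
  usable <- is.finite(ref) & ref > 0
  if (!all(usable))
    warning(sum(!usable), " non-positive reference entries excluded ",
            "from quotients")
  q <- apply(areas, 1, function(x)
    stats::median(x[usable] / ref[usable], na.rm = TRUE))
  list(normalized = sweep(areas, 1, q, `/`), quotients = q)
}

#' Internal-standard ratio normalization (pre-step hook)
#'
#' Divides every feature by a spiked internal-standard feature (e.g. a
#' deuterated amino acid added at extraction) and rescales to the
#' standard's median level. Off by default in [metabolomics_qc()]: spiked
#' standards track extraction recovery, which not every protocol uses
#' for scaling.
#'
#' @param areas Peak-area matrix.
#' @param is_column Column index or name of the internal standard.
#' @return Matrix with the internal-standard column removed.
#' @export
normalize_internal_standard <- function(areas, is_column) {
  is_vals <- areas[, is_column]
  if (any(!is.finite(is_vals) | is_vals <= 0))
    stop("internal standard missing or non-positive in some injections")
  keep <- setdiff(seq_len(ncol(areas)),
                  if (is.character(is_column))
                    match(is_column, colnames(areas)) else is_column)
  sweep(areas[, keep, drop = FALSE], 1, is_vals / stats::median(is_vals),
        `/`)
}

#' Run the full metabolomics QC chain
#'
#' Fixed order: drift correction, feature filtering, imputation,
#' probabilistic quotient normalization.
#'
#' @param areas Raw peak-area matrix in injection order.
#' @param classes `"QC"`/`"sample"` per row.
#' @param rsd_max,dratio_max Filter thresholds.
#' @param strategy Imputation strategy.
#' @param seed Seed for imputation.
#' @return List with each stage's output and the final `normalized`
#'   matrix.
#' @export
metabolomics_qc <- function(areas, classes, rsd_max = 0.2,
                            dratio_max = 0.4, strategy = "rf", seed = 1) {
  dc <- drift_correct(areas, classes)
  fl <- filter_features(dc, classes, rsd_max, dratio_max)
  im <- impute_missing(fl$filtered, strategy = strategy, seed = seed)
  pq <- pqn_normalize(im, classes)
  list(drift_corrected = dc, filter = fl, imputed = im,
       normalized = pq$normalized, quotients = pq$quotients)
}
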