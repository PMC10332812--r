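qc_batch <- function(ns = 16, nf = 20, seed = 21, drift = NULL,
                     missing_rate = 0, noise_cv = 0) {
  set.seed(seed)
  truth <- matrix(stats::rlnorm(ns * nf, log(1e6), 0.5), ns, nf,
                  dimnames = list(NULL, paste0("f", seq_len(nf))))
  b <- simulate_metabolomics_batch(truth, drift = drift,
                                   missing_rate = missing_rate,
                                   noise_cv = noise_cv, seed = seed)
  list(truth = truth, batch = b)
}

test_that("QC injections bracket the run every four samples", {
  x <- qc_batch(ns = 12)
  cl <- x$batch$manifest$class
  expect_equal(cl[1], "QC")
  expect_equal(cl[length(cl)], "QC")
  gaps <- diff(which(cl == "QC")) - 1
  expect_true(all(gaps == 4))
})

test_that("identity drift and no missingness reproduce the truth", {
  x <- qc_batch()
  sm <- x$batch$manifest$class == "sample"
  expect_equal(unname(x$batch$areas[sm, ]), unname(x$truth))
  qc_rows <- x$batch$areas[!sm, ]
  expect_true(all(apply(qc_rows, 2, function(v) diff(range(v)) == 0)))
})

test_that("constant QC areas leave the matrix unchanged after correction", {
  x <- qc_batch()
  out <- drift_correct(x$batch$areas, x$batch$manifest$class)
  expect_equal(out, x$batch$areas, tolerance = 1e-10)
})

test_that("spline drift correction inverts a known monotone drift", {
  drift <- function(i) 1 + 0.2 * (i - 1) / 20     # 20% over the run
  x <- qc_batch(ns = 16, drift = drift)
  cl <- x$batch$manifest$class
  out <- drift_correct(x$batch$areas, cl)
  qcr <- out[cl == "QC", ]
  rsd <- apply(qcr, 2, function(v) sd(v) / mean(v))
  expect_lt(max(rsd), 0.02)
  # biological contrasts are preserved within 1%
  sm <- which(cl == "sample")
  ratio_raw <- x$truth[2, ] / x$truth[7, ]
  ratio_cor <- out[sm[2], ] / out[sm[7], ]
  expect_lt(max(abs(ratio_cor / ratio_raw - 1)), 0.01)
  # and the sample/QC ratio is restored to within 1% of truth
  qc_truth <- colMeans(x$truth)
  rel <- out[sm[5], ] / apply(qcr, 2, median) /
    (x$truth[5, ] / qc_truth)
  expect_lt(max(abs(rel - 1)), 0.01)
})

test_that("feature filtering applies the RSD and D-ratio rules", {
  set.seed(5)
  n <- 30
  cl <- rep(c("QC", "sample"), c(10, 20))
  good <- c(rnorm(10, 100, 1), rnorm(20, 100, 20))
  highrsd <- c(100 * (1 + rnorm(10, 0, 0.25)), rnorm(20, 100, 30))
  highd <- c(rnorm(10, 100, 8), rnorm(20, 100, 2))   # varies mostly in QCs
  clean <- rep(100, 30)
  m <- cbind(good = good, highrsd = highrsd, highd = highd, clean = clean)
  out <- filter_features(m, cl)
  expect_true(out$report$retained[out$report$feature == "good"])
  expect_true(out$report$retained[out$report$feature == "clean"])
  expect_equal(out$report$rsd[out$report$feature == "clean"], 0)
  expect_false(out$report$retained[out$report$feature == "highrsd"])
  expect_false(out$report$retained[out$report$feature == "highd"])
  expect_match(out$report$reason[out$report$feature == "highd"],
               "dispersion")
  # retained values are untouched
  expect_equal(out$filtered[, "good"], good)
})

test_that("imputation strategies are deterministic and accurate enough", {
  # correlated features (shared sample-level factor), as in real batches:
  # an imputer can only recover what other features predict
  set.seed(33)
  lv <- rlnorm(24, log(1e6), 0.6)
  load <- rlnorm(12, 0, 0.5)
  truth <- outer(lv, load) * rlnorm(24 * 12, 0, 0.05)
  colnames(truth) <- paste0("f", 1:12)
  b <- simulate_metabolomics_batch(truth, missing_rate = 0.1,
                                   noise_cv = 0.02, seed = 33)
  x <- list(truth = truth, batch = b)
  m <- x$batch$areas
  complete <- x$truth
  expect_identical(impute_missing(complete, strategy = "rf"), complete)
  hm <- impute_missing(m, strategy = "halfmin")
  expect_false(anyNA(hm))
  miss <- is.na(m)
  # half-minimum fills with min/2 by definition
  j <- which(colSums(miss) > 0)[1]
  expect_equal(unique(hm[miss[, j], j]), min(m[, j], na.rm = TRUE) / 2)

  rf1 <- impute_missing(m, strategy = "rf", seed = 4)
  rf2 <- impute_missing(m, strategy = "rf", seed = 4)
  expect_identical(rf1, rf2)
  # mask-and-recover: median relative error under 15% on smooth data
  sm <- x$batch$manifest$class == "sample"
  truth_full <- x$truth
  errs <- abs(rf1[sm, ][miss[sm, ]] - truth_full[miss[sm, ]]) /
    truth_full[miss[sm, ]]
  expect_lt(median(errs), 0.15)
})

test_that("PQN recovers constructed dilutions exactly and is idempotent", {
  # samples sharing one composition: a 2x dilution gives quotient 1/2
  # exactly and normalization restores the undiluted spectrum
  set.seed(21)
  base <- rlnorm(20, log(1e6), 0.5)
  shared <- matrix(base, 10, 20, byrow = TRUE,
                   dimnames = list(NULL, paste0("f", 1:20)))
  b <- simulate_metabolomics_batch(shared, seed = 21)
  cl <- b$manifest$class
  m <- b$areas
  target <- which(cl == "sample")[3]
  m[target, ] <- m[target, ] / 2        # 2x diluted sample
  out <- pqn_normalize(m, cl)
  expect_equal(unname(out$quotients[target]), 0.5, tolerance = 1e-12)
  expect_equal(out$normalized[target, ], b$areas[target, ],
               tolerance = 1e-12)
  # idempotence
  again <- pqn_normalize(out$normalized, cl)
  expect_lt(max(abs(again$quotients - 1)), 1e-12)
  # heterogeneous compositions: the dilution still divides the sample's
  # quotient exactly, and the normalized spectrum is unchanged
  x <- qc_batch(ns = 10)
  cl2 <- x$batch$manifest$class
  t2 <- which(cl2 == "sample")[4]
  m2 <- x$batch$areas
  q_undiluted <- pqn_normalize(m2, cl2)$quotients[t2]
  m2[t2, ] <- m2[t2, ] / 3
  out2 <- pqn_normalize(m2, cl2)
  expect_equal(unname(out2$quotients[t2] / q_undiluted), 1 / 3,
               tolerance = 1e-12)
  # robustness: spiking 5% of features x10 moves the quotient < 1%
  spiked <- b$areas
  jj <- seq_len(ncol(spiked) %/% 20)
  spiked[target, jj] <- spiked[target, jj] * 10
  q <- pqn_normalize(spiked, cl)$quotients[target]
  expect_lt(abs(q - 1), 0.01)
})

test_that("the full QC chain runs in the documented order", {
  drift <- function(i) 1 + 0.15 * sin(i / 8)
  x <- qc_batch(ns = 16, nf = 10, drift = drift, missing_rate = 0.05,
                noise_cv = 0.02, seed = 8)
  out <- metabolomics_qc(x$batch$areas, x$batch$manifest$class,
                         strategy = "halfmin")
  expect_false(anyNA(out$normalized))
  expect_true(all(out$filter$report$retained[
    colnames(x$batch$areas) %in% colnames(out$normalized)]))
})

test_that("internal-standard normalization removes injection-level recovery", {
  set.seed(44)
  truth <- matrix(rlnorm(8 * 5, log(1e6), 0.3), 8, 5,
                  dimnames = list(NULL, c(paste0("f", 1:4), "IS")))
  truth[, "IS"] <- 1e6                  # identical spike per injection
  recovery <- runif(8, 0.5, 1.5)
  obs <- truth * recovery
  out <- normalize_internal_standard(obs, "IS")
  expect_equal(colnames(out), paste0("f", 1:4))
  ratio <- out / truth[, 1:4]
  expect_lt(diff(range(ratio)), 1e-9)   # recovery factor removed
  bad <- obs; bad[3, "IS"] <- 0
  expect_error(normalize_internal_standard(bad, "IS"), "non-positive")
})
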