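test_that("fully labeled substrate propagates to full product labeling", {
  toy <- parse_network("
@unbalanced GLC.x OUT.x
GLUT: GLC.x (abcdef) -> GLC (abcdef)
SPLIT: GLC (abcdef) -> PYR (cba) + PYR (def)
OUT: PYR (abc) -> OUT.x (abc)
")
  fm <- flux_map(c(GLUT = 100, SPLIT = 100, OUT = 200))
  full <- simulate_steady_state_mids(toy, fm, list(tracer("GLC.x", 1:6)))
  expect_equal(as.numeric(full$PYR), c(0, 0, 0, 1))
  half <- simulate_steady_state_mids(
    toy, fm, list(tracer("GLC.x", 1:6, fraction = 0.5)))
  expect_equal(as.numeric(half$PYR), c(0.5, 0, 0, 0.5))
  none <- simulate_steady_state_mids(toy, fm, list())
  expect_equal(as.numeric(none$GLC), c(1, rep(0, 6)))
})

test_that("EMU decomposition finds the expected units", {
  chain <- parse_network("@unbalanced IN.x OUT.x
U: IN.x (ab) -> A (ab)
V: A (ab) -> B (ab)
W: B (ab) -> OUT.x (ab)")
  emu <- emu_decomposition(chain, "B")
  expect_setequal(emu$emus$key, c("B|1,2", "A|1,2", "IN.x|1,2"))
  cond <- parse_network("@unbalanced X.x Y.x OUT.x
XI: X.x (ab) -> X (ab)
YI: Y.x (cd) -> Y (cd)
C: X (ab) + Y (cd) -> Z (abcd)
O: Z (abcd) -> OUT.x (abcd)")
  emu2 <- emu_decomposition(cond, "Z")
  z <- emu2$terms[["Z|1,2,3,4"]]
  expect_equal(length(z[[1]]$sources), 2)   # convolution of X12 and Y12
  expect_error(emu_decomposition(chain, list(list(met = "A",
                                                  positions = 1:3))),
               "larger than")
})

test_that("EMU simulation matches the brute-force oracle on random networks", {
  worst <- 0
  for (s in 1:50) {
    cs <- random_small_network(s)
    e <- simulate_steady_state_mids(cs$network, cs$flux, cs$tracers)
    o <- brute_force_isotopomer_oracle(cs$network, cs$flux, cs$tracers)
    for (m in names(o))
      worst <- max(worst, max(abs(e[[m]] - o[[m]])))
  }
  expect_lt(worst, 1e-8)
})

test_that("condensation products are convolutions of their substrates", {
  cond <- parse_network("@unbalanced X.x Y.x OUT.x
XI: X.x (ab) -> X (ab)
YI: Y.x (cd) -> Y (cd)
C: X (ab) + Y (cd) -> Z (abcd)
O: Z (abcd) -> OUT.x (abcd)")
  fm <- flux_map(c(XI = 5, YI = 5, C = 5, O = 5))
  trs <- list(tracer("X.x", 1, fraction = 0.6),
              tracer("Y.x", 1:2, fraction = 0.3))
  r <- simulate_steady_state_mids(cond, fm, trs)
  conv <- convolve_mid(as.numeric(r$X), as.numeric(r$Y))
  expect_equal(as.numeric(r$Z), conv, tolerance = 1e-12)
  o <- brute_force_isotopomer_oracle(cond, fm, trs)
  expect_equal(as.numeric(o$Z), conv, tolerance = 1e-10)
})

test_that("symmetric-molecule scrambling is orientation invariant", {
  base <- "
@unbalanced A.x OUT.x
@symmetric FUM
AIN: A.x (abcd) -> FUM (%s)
OUT: FUM (abcd) -> M (abcd)
MO: M (abcd) -> OUT.x (abcd)
"
  fm <- flux_map(c(AIN = 10, OUT = 10, MO = 10))
  trs <- list(tracer("A.x", 1, fraction = 0.8))
  r1 <- simulate_steady_state_mids(parse_network(sprintf(base, "abcd")),
                                   fm, trs)
  r2 <- simulate_steady_state_mids(parse_network(sprintf(base, "dcba")),
                                   fm, trs)
  expect_equal(r1$M, r2$M, tolerance = 1e-12)
  o <- brute_force_isotopomer_oracle(parse_network(sprintf(base, "abcd")),
                                     fm, trs, max_carbons = 12)
  expect_equal(as.numeric(r1$M), as.numeric(o$M), tolerance = 1e-10)
})

test_that("tracer impurity follows the binomial expectation", {
  mid_u <- apply_tracer_impurity(list(tracer("GLC.x", 1:6, purity = 0.99)),
                                 "GLC.x", 6)
  expect_equal(mid_u[7], 0.99^6, tolerance = 1e-12)
  mid_12 <- apply_tracer_impurity(list(tracer("GLC.x", 1:2, purity = 0.99)),
                                  "GLC.x", 6)
  expect_equal(mid_12[3], 0.99^2, tolerance = 1e-12)
  expect_equal(mid_12[2], 2 * 0.99 * 0.01, tolerance = 1e-12)
  expect_equal(mid_12[1], 0.01^2, tolerance = 1e-12)
  pure <- apply_tracer_impurity(list(tracer("GLC.x", 1:6)), "GLC.x", 6)
  expect_equal(pure[7], 1)
})

test_that("carbon enrichment is conserved from inputs to products", {
  cs <- random_small_network(99)
  e <- simulate_steady_state_mids(cs$network, cs$flux, cs$tracers)
  # in a single linear chain with no loss, mean enrichment of terminal
  # products equals the flux-weighted input enrichment
  enr <- function(mid) sum((seq_along(mid) - 1) * mid) / (length(mid) - 1)
  in_s <- apply_tracer_impurity(cs$tracers, "S.x", 2)
  in_t <- apply_tracer_impurity(cs$tracers, "T.x", 2)
  v <- cs$flux$net
  input_c <- 2 * v[["SIN"]] * enr(in_s) + 2 * v[["TIN"]] * enr(in_t)
  output_c <- 4 * v[["R3"]] * enr(e$D) + 2 * v[["R4"]] * enr(e$C)
  expect_equal(output_c, input_c, tolerance = 1e-8 * input_c)
})

test_that("nonstationary labeling approaches steady state and time-dilates", {
  cs <- random_small_network(7)
  ss <- simulate_steady_state_mids(cs$network, cs$flux, cs$tracers)
  out <- metabolite_outflow(cs$network,
                            oneway_fluxes(cs$network, cs$flux))
  tmax <- 25 * max(1 / out)
  inst <- simulate_inst_mids(cs$network, cs$flux, pools = 1, cs$tracers,
                             times = c(0, tmax / 2, tmax))
  for (m in names(ss))
    expect_lt(max(abs(inst[[m]][3, ] - ss[[m]])), 1e-6)
  # all trajectories stay on the simplex
  expect_true(all(abs(rowSums(inst$D) - 1) < 1e-9))
  # single-pool exponential approach: fraction follows 1 - exp(-v t / P)
  single <- parse_network("@unbalanced IN.x OUT.x
I: IN.x (a) -> A (a)
O: A (a) -> OUT.x (a)")
  fms <- flux_map(c(I = 4, O = 4))
  tt <- c(0, 0.1, 0.5, 1, 2)
  si <- simulate_inst_mids(single, fms, pools = c(A = 8),
                           list(tracer("IN.x", 1)), times = tt)
  expect_equal(si$A[, 2], 1 - exp(-4 * tt / 8), tolerance = 1e-7)
  # scaling pools by 10 dilates the curves by 10 exactly
  s10 <- simulate_inst_mids(single, fms, pools = c(A = 80),
                            list(tracer("IN.x", 1)), times = tt * 10)
  expect_equal(s10$A[, 2], si$A[, 2], tolerance = 1e-8)
})

test_that("unbalanced flux maps and zero-throughput systems are refused", {
  toy <- toy_condensation_network()
  bad <- flux_map(c(AIN = 10, R1 = 5, R2 = 5, R3 = 5, R4 = 5, R5 = 10))
  expect_error(simulate_steady_state_mids(toy, bad,
                                          list(tracer("A.x", 1:2))),
               "not balanced")
  iso <- parse_network("@unbalanced IN.x OUT.x
I: IN.x (a) -> A (a)
L: B (a) <-> C (a)
O: A (a) -> OUT.x (a)")
  fmz <- flux_map(c(I = 1, L = 0, O = 1))
  expect_error(simulate_steady_state_mids(iso, fmz,
                                          list(tracer("IN.x", 1))),
               "singular")
})

test_that("oracle refuses oversized networks and handles unlabeled input", {
  net <- lf_network()
  fm <- lf_reference_flux()
  expect_error(brute_force_isotopomer_oracle(net, fm, list()),
               "limit")
  cs <- random_small_network(3)
  o <- brute_force_isotopomer_oracle(cs$network, cs$flux, list())
  for (m in names(o)) expect_equal(o[[m]][1], 1, tolerance = 1e-10)
})
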