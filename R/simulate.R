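# Labeling simulation: cascaded linear EMU solves at isotopic steady
# state, stiff ODE integration for the nonstationary approach, and a
# brute-force positional-isotopomer oracle used to validate both.

# input MIDs for all input EMUs of an emu_network
input_emu_mids <- function(emu, tracers) {
  carb <- stats::setNames(emu$network$metabolites$carbons,
                          emu$network$metabolites$id)
  mids <- list()
  for (i in which(emu$emus$input)) {
    k <- emu$emus$key[i]
    met <- emu$emus$met[i]
    pos <- emu$positions[[k]]
    mids[[k]] <- apply_tracer_impurity(tracers, met, carb[met], pos)
  }
  mids
}

#' Simulate mass isotopomer distributions at isotopic steady state
#'
#' Solves, for each EMU size in ascending order, the linear balance
#' `A(v) X = -B(v) Y` in which `Y` stacks tracer-input MIDs and
#' convolutions of smaller-size solutions. Requires a balanced flux map;
#' outputs lie on the probability simplex.
#'
#' @param network A `flux_network`.
#' @param flux A [flux_map()] satisfying steady-state balance.
#' @param tracers List of [tracer()] components.
#' @param observed Metabolite ids (or fragment list) to report; defaults
#'   to all balanced metabolites with carbons.
#' @param emu Optional precomputed [emu_decomposition()] (reused across
#'   calls during fitting).
#' @param balance_tol Relative steady-state tolerance checked before
#'   simulating.
#' @return Named list of MID vectors for the observed fragments, with the
#'   full EMU solution in attribute `"emu_mids"`.
#' @export
simulate_steady_state_mids <- function(network, flux, tracers,
                                       observed = NULL, emu = NULL,
                                       balance_tol = 1e-6) {
  if (is.null(emu)) {
    if (is.null(observed)) {
      m <- network$metabolites
      observed <- m$id[m$balanced & m$carbons > 0]
    }
    emu <- emu_decomposition(network, observed)
  }
  chk <- check_flux_balance(network, flux, tol_rel = balance_tol)
  if (!attr(chk, "pass"))
    stop("flux map is not balanced (max relative residual ",
         signif(max(chk$rel), 3), ")")
  ow <- oneway_fluxes(network, flux)
  outflow <- metabolite_outflow(network, ow)
  mids <- input_emu_mids(emu, tracers)
  solve_emu_cascade(emu, ow, outflow, mids)
}

# Precompiled solve plan: per EMU size, integer-indexed term structure so
# repeated solves during fitting avoid name lookups. fb is the stacked
# one-way flux vector c(fwd, bwd); fidx indexes into it.
compile_emu_plan <- function(emu) {
  if (!is.null(emu$plan_env$plan)) return(emu$plan_env$plan)
  rids <- vapply(emu$network$reactions, `[[`, "", "id")
  R <- length(rids)
  rix <- stats::setNames(seq_len(R), rids)
  layers <- list()
  for (sz in sort(unique(emu$emus$size[!emu$emus$input]))) {
    keys <- emu$emus$key[emu$emus$size == sz & !emu$emus$input]
    n <- length(keys)
    idx <- stats::setNames(seq_len(n), keys)
    mets <- sub("\\|.*", "", keys)
    ai <- integer(); aj <- integer(); afx <- integer(); aw <- numeric()
    forcing <- vector("list", n)
    for (i in seq_len(n)) {
      for (tm in emu$terms[[keys[i]]]) {
        fidx <- rix[[tm$rid]] + if (tm$dir == 1L) 0L else R
        src <- tm$sources
        if (length(src) == 1 && !is.na(idx[src])) {
          ai <- c(ai, i); aj <- c(aj, idx[[src]])
          afx <- c(afx, fidx); aw <- c(aw, tm$weight)
        } else {
          forcing[[i]] <- c(forcing[[i]],
                            list(list(fidx = fidx, w = tm$weight,
                                      src = src)))
        }
      }
    }
    cells <- (aj - 1L) * n + ai
    layers[[as.character(sz)]] <- list(
      sz = sz, keys = keys, n = n, mets = mets,
      acell = cells, afx = afx, aw = aw, forcing = forcing)
  }
  # constant map from stacked one-way fluxes to per-metabolite outflow
  bal <- emu$network$metabolites$id[emu$network$metabolites$balanced]
  C <- matrix(0, length(bal), 2 * R, dimnames = list(bal, NULL))
  for (r in emu$network$reactions) {
    j <- rix[[r$id]]
    for (inst in r$reactants)
      if (inst$met %in% bal) C[inst$met, j] <- C[inst$met, j] + inst$coef
    for (inst in r$products)
      if (inst$met %in% bal)
        C[inst$met, j + R] <- C[inst$met, j + R] + inst$coef
  }
  plan <- list(layers = layers, R = R, outflow_map = C)
  emu$plan_env$plan <- plan
  plan
}

solve_emu_cascade <- function(emu, ow, outflow, mids) {
  plan <- compile_emu_plan(emu)
  fb <- c(ow$fwd, ow$bwd)
  env <- list2env(mids, hash = TRUE)
  for (ly in plan$layers) {
    n <- ly$n
    A <- matrix(0, n, n)
    diag(A) <- -outflow[ly$mets]
    if (length(ly$acell)) {
      av <- fb[ly$afx] * ly$aw
      agg <- rowsum(av, ly$acell)
      A[as.integer(rownames(agg))] <- A[as.integer(rownames(agg))] + agg
    }
    B <- matrix(0, n, ly$sz + 1)
    for (i in seq_len(n)) {
      for (tm in ly$forcing[[i]]) {
        f <- fb[tm$fidx]
        if (f == 0) next
        v <- env[[tm$src[1]]]
        if (length(tm$src) > 1)
          for (s in tm$src[-1]) v <- convolve_mid(v, env[[s]])
        B[i, ] <- B[i, ] - f * tm$w * v
      }
    }
    X <- tryCatch(solve(A, B), error = function(e)
      stop("singular EMU system at size ", ly$sz,
           " (zero-throughput EMU among: ",
           paste(utils::head(ly$keys, 5), collapse = ", "), ")",
           call. = FALSE))
    for (i in seq_len(n)) env[[ly$keys[i]]] <- pmax(X[i, ], 0)
  }
  out <- lapply(emu$observed, function(k) {
    v <- env[[k]]
    v / sum(v)
  })
  attr(out, "emu_mids") <- env
  out
}

#' Simulate time-resolved MIDs before isotopic steady state
#'
#' Integrates the EMU labeling ODEs `P dX/dt = A(v) X + B(v) Y` from an
#' unlabeled initial condition with a stiff-capable adaptive integrator.
#' Pool sizes time-scale the dynamics: scaling all pools by c dilates the
#' labeling curves by c at fixed fluxes.
#'
#' @inheritParams simulate_steady_state_mids
#' @param pools Named numeric vector of pool sizes (fmol/cell) for
#'   balanced metabolites; a single unnamed value is recycled.
#' @param times Sorted nonnegative times (h) starting at 0.
#' @param rtol,atol Integrator tolerances.
#' @return List with `times` and, per observed fragment, a matrix
#'   (time x mass shift) of MID fractions.
#' @export
simulate_inst_mids <- function(network, flux, pools, tracers, times,
                               observed = NULL, emu = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(!is.unsorted(times), times[1] >= 0)
  if (is.null(emu)) {
    if (is.null(observed)) {
      m <- network$metabolites
      observed <- m$id[m$balanced & m$carbons > 0]
    }
    emu <- emu_decomposition(network, observed)
  }
  ow <- oneway_fluxes(network, flux)
  outflow <- metabolite_outflow(network, ow)
  inputs <- input_emu_mids(emu, tracers)
  if (any(pools <= 0)) stop("pool sizes must be positive")
  pool_of <- function(met) {
    if (is.null(names(pools))) pools[1]
    else if (met %in% names(pools)) pools[[met]]
    else stop("no pool size for ", met)
  }

  # The EMU cascade is exploited layer by layer: the size-k fractions obey
  # a constant-coefficient linear ODE P dx/dt = A x + b(t) whose forcing
  # b(t) involves only inputs and smaller-size solutions, interpolated on
  # a dense grid.
  tmax <- max(times)
  grid <- unique(sort(c(times, tmax * seq(0, 1, length.out = 201)^2)))
  traj <- list()   # dense trajectories, key -> matrix (grid x (size+1))
  for (k in names(inputs))
    traj[[k]] <- matrix(inputs[[k]], length(grid), length(inputs[[k]]),
                        byrow = TRUE)

  for (sz in sort(unique(emu$emus$size[!emu$emus$input]))) {
    keys <- emu$emus$key[emu$emus$size == sz & !emu$emus$input]
    n <- length(keys)
    ln <- sz + 1
    idx <- stats::setNames(seq_len(n), keys)
    mets <- sub("\\|.*", "", keys)
    pv <- vapply(mets, pool_of, 1)
    A <- matrix(0, n, n)
    forcing_terms <- vector("list", n)
    for (i in seq_len(n)) {
      A[i, i] <- -outflow[mets[i]]
      for (tm in emu$terms[[keys[i]]]) {
        f <- if (tm$dir == 1L) ow$fwd[tm$rid] else ow$bwd[tm$rid]
        if (f == 0) next
        w <- f * tm$weight
        src <- tm$sources
        if (length(src) == 1 && !is.na(idx[src])) {
          A[i, idx[src]] <- A[i, idx[src]] + w
        } else {
          forcing_terms[[i]] <- c(forcing_terms[[i]],
                                  list(list(w = w, src = src)))
        }
      }
    }
    # forcing matrix on the dense grid: rows grid points, cols n*(sz+1)
    Bg <- matrix(0, length(grid), n * ln)
    for (i in seq_len(n)) {
      for (tm in forcing_terms[[i]]) {
        v <- traj[[tm$src[1]]]
        if (length(tm$src) > 1)
          for (s in tm$src[-1]) {
            u <- traj[[s]]
            nv <- matrix(0, length(grid), ncol(v) + ncol(u) - 1)
            for (a in seq_len(ncol(v)))
              for (b2 in seq_len(ncol(u)))
                nv[, a + b2 - 1] <- nv[, a + b2 - 1] + v[, a] * u[, b2]
            v <- nv
          }
        cols <- (i - 1) * ln + seq_len(ln)
        Bg[, cols] <- Bg[, cols] + tm$w * v
      }
    }
    splines <- lapply(seq_len(ncol(Bg)), function(j)
      stats::splinefun(grid, Bg[, j], method = "natural"))
    bfun <- function(t) vapply(splines, function(s) s(t), 1)
    y0 <- rep(c(1, numeric(sz)), n)
    Pinv <- rep(1 / pv, each = ln)
    deriv <- function(t, y, parms) {
      Y <- matrix(y, n, ln, byrow = TRUE)
      acc <- A %*% Y
      list(Pinv * (as.vector(t(acc)) + bfun(t)))
    }
    jac <- local({
      J <- matrix(0, n * ln, n * ln)
      for (a in seq_len(n)) for (b2 in seq_len(n)) {
        if (A[a, b2] == 0) next
        for (m2 in seq_len(ln))
          J[(a - 1) * ln + m2, (b2 - 1) * ln + m2] <- A[a, b2] / pv[a]
      }
      function(t, y, parms) J
    })
    sol <- deSolve::ode(y0, grid, deriv, parms = NULL, method = "lsoda",
                        jacfunc = jac, jactype = "fullusr",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("labeling ODE integration failed at EMU size ", sz)
    for (i in seq_len(n))
      traj[[keys[i]]] <- sol[, 1 + (i - 1) * ln + seq_len(ln), drop = FALSE]
  }

  sel <- match(times, grid)
  out <- list(times = times)
  for (nm in names(emu$observed)) {
    m <- traj[[emu$observed[[nm]]]][sel, , drop = FALSE]
    m <- m / rowSums(m)
    colnames(m) <- paste0("M", 0:(ncol(m) - 1))
    out[[nm]] <- m
  }
  out
}

#' Random small validation network
#'
#' Generates a seeded random atom-mapped network (10 balanced carbons:
#' a 2-carbon chain with a randomized carbon permutation, an optional
#' reversible step, and a condensation to a 4-carbon product) together
#' with a feasible flux map and a random two-substrate tracer mix. Small
#' enough for [brute_force_isotopomer_oracle()]; used to cross-validate
#' the EMU simulator.
#'
#' @param seed Integer seed.
#' @return List with `network`, `flux` (a `flux_map`) and `tracers`.
#' @export
random_validation_network <- function(seed) {
  set.seed(seed)
  perm2 <- paste(sample(c("a", "b")), collapse = "")
  permC <- paste(sample(c("a", "b")), collapse = "")
  permD <- paste(sample(c("a", "b", "c", "d")), collapse = "")
  rev1 <- sample(c("->", "<->"), 1)
  txt <- sprintf("
@unbalanced S.x T.x OUTD.x OUTC.x
SIN: S.x (ab) -> A (%s)
TIN: T.x (cd) -> B (cd)
R1: A (ab) %s C (%s)
R2: C (ab) + B (cd) -> D (%s)
R3: D (abcd) -> OUTD.x (abcd)
R4: C (ab) -> OUTC.x (ab)
", perm2, rev1, permC, permD)
  net <- parse_network(txt)
  v_tin <- stats::runif(1, 5, 30)
  v_sin <- v_tin + stats::runif(1, 1, 30)
  nets <- c(SIN = v_sin, TIN = v_tin, R1 = v_sin, R2 = v_tin,
            R3 = v_tin, R4 = v_sin - v_tin)
  ex <- if (rev1 == "<->") c(R1 = stats::runif(1, 0, 20)) else numeric()
  trs <- list(
    tracer("S.x", sample(1:2, sample(1:2, 1)),
           fraction = stats::runif(1, 0.3, 1),
           purity = stats::runif(1, 0.95, 1)),
    tracer("T.x", 1:2, fraction = stats::runif(1, 0.2, 0.9)))
  list(network = net, flux = flux_map(nets, ex), tracers = trs)
}

#' Brute-force isotopomer oracle
#'
#' Solves the full positional-isotopomer balance of a small network by
#' damped fixed-point iteration and marginalizes to MIDs. Completely
#' independent of the EMU machinery; used as the validation oracle.
#'
#' @inheritParams simulate_steady_state_mids
#' @param max_carbons Refuses networks whose balanced metabolites carry
#'   more than this many carbons in total.
#' @param tol Fixed-point convergence tolerance (max absolute change).
#' @param max_iter Iteration budget.
#' @return Named list of MID vectors for all balanced metabolites with
#'   carbons; isotopomer distributions in attribute `"isotopomers"`.
#' @export
brute_force_isotopomer_oracle <- function(network, flux, tracers,
                                          max_carbons = 12, tol = 1e-13,
                                          max_iter = 50000) {
  m <- network$metabolites
  bal <- m[m$balanced & m$carbons > 0, , drop = FALSE]
  if (sum(bal$carbons) > max_carbons)
    stop("network exceeds the ", max_carbons,
         "-carbon limit for full isotopomer enumeration")
  carb <- stats::setNames(m$carbons, m$id)
  symm <- stats::setNames(m$symmetric, m$id)
  ow <- oneway_fluxes(network, flux)
  outflow <- metabolite_outflow(network, ow)

  dists <- list()
  for (i in seq_len(nrow(bal)))
    dists[[bal$id[i]]] <- c(1, numeric(2^bal$carbons[i] - 1))
  src_dist <- function(met) {
    if (!is.null(dists[[met]])) dists[[met]]
    else tracer_isotopomers(tracers, met, carb[met])
  }

  # enumerate producing terms once: for each balanced metabolite, a list of
  # (flux id, dir, weight, reactant instances with their atom letters and
  # the product atom letters)
  prods <- lapply(bal$id, function(x) list())
  names(prods) <- bal$id
  for (r in network$reactions) {
    if (!r$atom_mapped) next
    dirs <- if (r$reversible) c(1L, -1L) else 1L
    for (d in dirs) {
      side_prod <- if (d == 1L) r$products else r$reactants
      side_reac <- if (d == 1L) r$reactants else r$products
      for (inst in side_prod) {
        met <- inst$met
        if (is.null(prods[[met]]) || is.null(inst$atoms) || inst$coef == 0)
          next
        variants <- list(inst$atoms)
        wt <- inst$coef
        if (isTRUE(symm[met])) {
          variants <- list(inst$atoms, rev(inst$atoms))
          wt <- wt / 2
        }
        for (atoms in variants) {
          srcs <- Filter(function(ri) !is.null(ri$atoms) &&
                           any(ri$atoms %in% atoms), side_reac)
          prods[[met]][[length(prods[[met]]) + 1]] <-
            list(rid = r$id, dir = d, weight = wt, atoms = atoms,
                 srcs = srcs)
        }
      }
    }
  }

  # product isotopomer distribution induced by one term given current dists
  induce <- function(tm) {
    n <- length(tm$atoms)
    out <- numeric(2^n)
    src_d <- lapply(tm$srcs, function(ri) src_dist(ri$met))
    grids <- lapply(tm$srcs, function(ri) 0:(2^length(ri$atoms) - 1))
    # map: product bit b (position j) comes from reactant i, bit k
    maps <- lapply(tm$srcs, function(ri) match(ri$atoms, tm$atoms))
    combo <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
    pr <- rep(1, nrow(combo))
    state <- rep(0L, nrow(combo))
    for (i in seq_along(tm$srcs)) {
      s <- combo[[i]]
      pr <- pr * src_d[[i]][s + 1]
      mp <- maps[[i]]
      for (k in seq_along(mp)) {
        if (is.na(mp[k])) next
        bit <- bitwAnd(s, bitwShiftL(1L, k - 1L)) > 0
        state <- state + ifelse(bit, bitwShiftL(1L, mp[k] - 1L), 0L)
      }
    }
    for (j in seq_len(nrow(combo))) out[state[j] + 1] <- out[state[j] + 1] + pr[j]
    out
  }

  for (it in seq_len(max_iter)) {
    delta <- 0
    for (met in bal$id) {
      acc <- numeric(2^carb[met])
      for (tm in prods[[met]]) {
        f <- if (tm$dir == 1L) ow$fwd[tm$rid] else ow$bwd[tm$rid]
        if (f == 0) next
        acc <- acc + f * tm$weight * induce(tm)
      }
      new <- acc / outflow[met]
      delta <- max(delta, max(abs(new - dists[[met]])))
      dists[[met]] <- new
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("isotopomer fixed point not fully converged (delta = ",
            signif(delta, 3), ")")
  mids <- lapply(stats::setNames(bal$id, bal$id), function(met) {
    d <- dists[[met]]
    shifts <- vapply(0:(length(d) - 1), function(s)
      sum(bitwAnd(s, bitwShiftL(1L, 0:30)) > 0), 1)
    mid <- vapply(0:carb[met], function(k) sum(d[shifts == k]), 1)
    mid / sum(mid)
  })
  attr(mids, "isotopomers") <- dists
  mids
}
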