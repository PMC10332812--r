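# Analytic sensitivities of simulated MIDs with respect to the free-flux
# parameters, by implicit differentiation of the cascaded EMU systems:
# for each size, A dX/dtheta = -(dA/dtheta X + dB/dtheta Y + B dY/dtheta),
# solved with the already-factorized A. This replaces finite differencing
# of the whole simulation during fitting.

# derivative of net fluxes wrt theta (constant: the net part of the
# parameterization is affine; exchange parameters do not move net fluxes)
net_jacobian <- function(param) {
  th0 <- stats::setNames(rep(0, param$n_par), param$theta_names)
  v0 <- param$theta_to_flux(th0)$net
  nf <- length(param$free_net)
  D <- matrix(0, length(v0), param$n_par,
              dimnames = list(names(v0), param$theta_names))
  for (j in seq_len(nf)) {
    th <- th0; th[j] <- 1
    D[, j] <- param$theta_to_flux(th)$net - v0
  }
  D
}

# smooth one-way flux split used during fitting: softplus with width s
# satisfies sp(x) - sp(-x) = x, so the net flux (hence mass balance) is
# preserved exactly while the split is differentiable everywhere
softplus <- function(x, s) {
  z <- x / s
  s * ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
}

sigmoid <- function(x, s) 1 / (1 + exp(-pmin(pmax(x / s, -30), 30)))

# smooth one-way fluxes for the residual side (same split as the
# gradient side below). Only reversible reactions are smoothed — their
# softplus split preserves the net flux exactly and merely adds a
# vanishing pseudo-exchange near the sign change. Irreversible reactions
# keep the exact clamp: smoothing them distorts small fluxes (a biomass
# drain of 0.02 would gain several-fold spurious flux, amplified by its
# large stoichiometric coefficients).
smooth_oneway <- function(ctx, fm, s = 0.2) {
  net <- fm$net
  rids <- names(net)
  rev <- rids %in% ctx$param$exch_ids
  exch <- stats::setNames(rep(0, length(rids)), rids)
  exch[ctx$param$exch_ids] <- fm$exchange[ctx$param$exch_ids]
  list(fwd = stats::setNames(
         ifelse(rev, softplus(net, s) + exch, pmax(net, 0)), rids),
       bwd = stats::setNames(
         ifelse(rev, softplus(-net, s) + exch, 0), rids))
}

# one-way fluxes and their theta-derivatives at theta
oneway_with_grad <- function(ctx, theta, s = 0.2) {
  param <- ctx$param
  fm <- param$theta_to_flux(theta)
  net <- fm$net
  rids <- names(net)
  rev <- rids %in% param$exch_ids
  exch <- stats::setNames(rep(0, length(rids)), rids)
  exch[param$exch_ids] <- fm$exchange[param$exch_ids]
  fwd <- stats::setNames(
    ifelse(rev, softplus(net, s) + exch, pmax(net, 0)), rids)
  bwd <- stats::setNames(ifelse(rev, softplus(-net, s) + exch, 0), rids)
  Dnet <- ctx$Dnet[rids, , drop = FALSE]
  # right-derivative for the irreversible clamp so fluxes at exactly
  # zero still expose a descent direction
  pos <- ifelse(rev, sigmoid(net, s), as.numeric(net >= 0))
  neg <- ifelse(rev, sigmoid(-net, s), 0)
  Dfwd <- Dnet * pos
  Dbwd <- -Dnet * neg
  Dbwd[!rev, ] <- 0
  # exchange columns: d exch / d theta_x = ln(10) * exch. The derivative
  # is kept nonzero at the cap so a parameter pushed onto the bound still
  # sees the descent direction that leads away from it.
  nf <- length(param$free_net)
  for (j in seq_along(param$exch_ids)) {
    r <- param$exch_ids[j]
    g <- log(10) * exch[r]
    Dfwd[r, nf + j] <- Dfwd[r, nf + j] + g
    Dbwd[r, nf + j] <- Dbwd[r, nf + j] + g
  }
  list(fm = fm, fwd = stats::setNames(fwd, rids),
       bwd = stats::setNames(bwd, rids), Dfwd = Dfwd, Dbwd = Dbwd,
       Dnet = Dnet)
}

# EMU cascade with sensitivities, on the precompiled plan. Returns
# hashed environments `mids` (key -> vector) and `sens`
# (key -> (size+1) x n_par matrix).
solve_emu_cascade_sens <- function(emu, owg, ctx, input_mids) {
  plan <- compile_emu_plan(emu)
  np <- ncol(owg$Dfwd)
  fb <- c(owg$fwd, owg$bwd)
  Dfb <- rbind(owg$Dfwd, owg$Dbwd)
  outflow <- as.vector(plan$outflow_map %*% fb)
  names(outflow) <- rownames(plan$outflow_map)
  Dout <- plan$outflow_map %*% Dfb
  mids <- list2env(input_mids, hash = TRUE)
  sens <- new.env(hash = TRUE)
  for (ly in plan$layers) {
    n <- ly$n
    ln <- ly$sz + 1
    A <- matrix(0, n, n)
    diag(A) <- -outflow[ly$mets]
    av <- fb[ly$afx] * ly$aw
    if (length(ly$acell)) {
      agg <- rowsum(av, ly$acell)
      cells <- as.integer(rownames(agg))
      A[cells] <- A[cells] + agg
    }
    B <- matrix(0, n, ln)
    G <- matrix(0, n, ln * np)       # d(forcing)/dtheta, row-wise vec
    for (i in seq_len(n)) {
      for (tm in ly$forcing[[i]]) {
        f <- fb[tm$fidx]
        df <- Dfb[tm$fidx, ]
        v <- mids[[tm$src[1]]]
        dv <- sens[[tm$src[1]]]
        if (is.null(dv)) dv <- matrix(0, length(v), np)
        if (length(tm$src) > 1) {
          for (s in tm$src[-1]) {
            u <- mids[[s]]
            du <- sens[[s]]
            if (is.null(du)) du <- matrix(0, length(u), np)
            nlen <- length(v) + length(u) - 1
            ndv <- matrix(0, nlen, np)
            nv <- numeric(nlen)
            for (a in seq_along(v)) {
              ii <- a + seq_along(u) - 1
              nv[ii] <- nv[ii] + v[a] * u
              ndv[ii, ] <- ndv[ii, ] + v[a] * du + outer(u, dv[a, ])
            }
            v <- nv; dv <- ndv
          }
        }
        if (f != 0) B[i, ] <- B[i, ] + f * tm$w * v
        G[i, ] <- G[i, ] + as.vector(tm$w * (outer(v, df) + f * dv))
      }
    }
    lu <- tryCatch(
      {
        d <- qr(A, LAPACK = TRUE)
        if (min(abs(diag(qr.R(d)))) < 1e-300) NULL else d
      },
      error = function(e) NULL)
    if (is.null(lu)) stop("singular EMU system at size ", ly$sz)
    X <- qr.solve(lu, -B)
    if (!is.matrix(X)) X <- matrix(X, n, ln)
    # sensitivity RHS: -(dA X + dforcing), columns stacked per parameter
    RHS <- G
    # diagonal part: -Dout[met,] X[i,]
    for (i in seq_len(n))
      RHS[i, ] <- RHS[i, ] - as.vector(outer(X[i, ], Dout[ly$mets[i], ]))
    if (length(ly$acell)) {
      # off-diagonal dA entries: aw * Dfb[afx, ] applied to X rows aj
      aj <- ((ly$acell - 1L) %/% n) + 1L
      ai <- ((ly$acell - 1L) %% n) + 1L
      for (t in seq_along(ai))
        RHS[ai[t], ] <- RHS[ai[t], ] +
          as.vector(outer(X[aj[t], ], ly$aw[t] * Dfb[ly$afx[t], ]))
    }
    DX <- qr.solve(lu, -RHS)
    if (!is.matrix(DX)) DX <- matrix(DX, n, ln * np)
    for (i in seq_len(n)) {
      mids[[ly$keys[i]]] <- pmax(X[i, ], 0)
      sens[[ly$keys[i]]] <- matrix(DX[i, ], ln, np)
    }
  }
  list(mids = mids, sens = sens)
}

# residuals and analytic Jacobian at theta, matching fit_residuals order
fit_residuals_jac <- function(theta, ctx) {
  owg <- oneway_with_grad(ctx, theta)
  J <- NULL
  if (!is.null(ctx$meas$mids)) {
    rows <- list()
    for (ex in names(ctx$tracer_sets)) {
      sel <- ctx$meas$mids$experiment == ex
      if (!any(sel)) next
      sol <- solve_emu_cascade_sens(ctx$emu, owg, ctx, ctx$input_mids[[ex]])
      d <- ctx$meas$mids[sel, ]
      Dc <- list()
      for (met in unique(d$metabolite)) {
        k <- ctx$emu$observed[[met]]
        # observed fragments are renormalized; quotient rule
        v <- sol$mids[[k]]
        S <- sum(v)
        dvm <- sol$sens[[k]]
        v1 <- v / S
        D <- (dvm * S - outer(v, colSums(dvm))) / S^2
        if (identical(ctx$meas$noise_model, "truncated")) {
          dg <- d[d$metabolite == met, ]
          sv <- rep(ctx$meas$sd_floor, length(v1))
          sv[dg$mass_shift + 1] <- dg$sd
          tr <- trunc_expectation(v1, sv)
          Dt <- tr$dt * D
          Tt <- sum(tr$t)
          D <- (Dt * Tt - outer(tr$t, colSums(Dt))) / Tt^2
        }
        Dc[[met]] <- D
      }
      for (i in seq_len(nrow(d)))
        rows[[length(rows) + 1]] <-
          Dc[[d$metabolite[i]]][d$mass_shift[i] + 1, ] / d$sd[i]
    }
    J <- do.call(rbind, rows)
  }
  if (!is.null(ctx$meas$fluxes)) {
    d <- ctx$meas$fluxes
    J <- rbind(J, owg$Dnet[d$id, , drop = FALSE] / d$sd)
  }
  if (!is.null(ctx$meas$growth)) {
    J <- rbind(J, owg$Dnet[ctx$meas$biomass_reaction, , drop = FALSE] /
                 ctx$meas$growth[2])
  }
  v <- owg$fm$net[ctx$param$irrev_ids]
  Jpen <- owg$Dnet[ctx$param$irrev_ids, , drop = FALSE] *
    penalty_gradient_factor(v, ctx$penalty)
  rbind(J, Jpen)
}
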