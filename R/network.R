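#' Parse a carbon-transition network
#'
#' Reads the plain-text atom-map dialect used to describe compartmented
#' metabolic networks. Each reaction line has the form
#' `ID: coef*MET (atoms) + ... -> products` with lowercase letters mapping
#' carbons one-to-one across the arrow; `<->` marks a reversible reaction
#' carrying both a net and an exchange flux. Directives: `@pathway NAME`
#' tags subsequent reactions, `@unbalanced`, `@symmetric` and `@pseudo`
#' list unbalanced species, rotationally symmetric species, and
#' pseudo-reactions (mixing rows, lumped unlabeled sources). Metabolites
#' with an `.x` suffix are extracellular and always unbalanced. A reactant
#' coefficient of `0` contributes label but no mass (pool mixing).
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @return A `flux_network` object: lists `metabolites` (id, carbons,
#'   balanced, symmetric) and `reactions` (id, pathway, reversible, pseudo,
#'   reactants, products), where each side is a list of instances with
#'   `met`, `coef` and `atoms` (integer carbon letters, or `NULL` for
#'   atom-free rows such as a biomass drain).
#' @seealso [read_network()] to read from a file.
#' @export
parse_network <- function(text) {
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  unbalanced <- character()
  symmetric <- character()
  pseudo <- character()
  pathway <- ""
  reactions <- list()
  for (ln in seq_along(text)) {
    line <- sub("#.*", "", text[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, "@")) {
      parts <- strsplit(line, "\\s+")[[1]]
      key <- sub("^@", "", parts[1])
      val <- parts[-1]
      switch(key,
        unbalanced = unbalanced <- c(unbalanced, val),
        symmetric = symmetric <- c(symmetric, val),
        pseudo = pseudo <- c(pseudo, val),
        pathway = pathway <- val[1],
        stop("line ", ln, ": unknown directive @", key)
      )
      next
    }
    m <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3) stop("line ", ln, ": cannot parse reaction: ", line)
    rid <- trimws(m[2])
    body <- m[3]
    reversible <- grepl("<->", body, fixed = TRUE)
    sides <- strsplit(body, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("line ", ln, ": missing arrow in ", rid)
    parse_side <- function(s) {
      terms <- strsplit(s, "+", fixed = TRUE)[[1]]
      lapply(terms, function(tm) {
        tm <- trimws(tm)
        coef <- 1
        if (grepl("*", tm, fixed = TRUE)) {
          cs <- strsplit(tm, "*", fixed = TRUE)[[1]]
          coef <- as.numeric(cs[1])
          tm <- trimws(cs[2])
        }
        atoms <- NULL
        am <- regmatches(tm, regexec("^(\\S+)\\s*\\(([a-z]+)\\)$", tm))[[1]]
        if (length(am) == 3) {
          tm <- am[2]
          atoms <- strsplit(am[3], "")[[1]]
        }
        list(met = tm, coef = coef, atoms = atoms)
      })
    }
    reac <- parse_side(sides[1])
    prod <- parse_side(sides[2])
    mapped <- any(vapply(c(reac, prod), function(i) !is.null(i$atoms), TRUE))
    if (mapped) {
      rl <- unlist(lapply(reac, `[[`, "atoms"))
      pl <- unlist(lapply(prod, `[[`, "atoms"))
      if (anyDuplicated(rl) || anyDuplicated(pl))
        stop("line ", ln, ": duplicated atom letters in ", rid)
      if (!setequal(rl, pl) || length(rl) != length(pl))
        stop("line ", ln, ": unbalanced atom letters in ", rid)
    }
    if (rid %in% vapply(reactions, `[[`, "", "id"))
      stop("line ", ln, ": duplicate reaction id ", rid)
    reactions[[length(reactions) + 1]] <- list(
      id = rid, pathway = pathway, reversible = reversible,
      pseudo = FALSE, atom_mapped = mapped,
      reactants = reac, products = prod, line = ln)
  }
  for (i in seq_along(reactions))
    reactions[[i]]$pseudo <- reactions[[i]]$id %in% pseudo

  # metabolite table with carbon counts inferred from the atom maps
  mets <- new.env()
  for (r in reactions) {
    for (inst in c(r$reactants, r$products)) {
      n <- if (is.null(inst$atoms)) NA_integer_ else length(inst$atoms)
      old <- mets[[inst$met]]
      if (is.null(old)) {
        mets[[inst$met]] <- n
      } else if (!is.na(n) && !is.na(old) && n != old) {
        stop("metabolite ", inst$met, " has inconsistent carbon counts (",
             old, " vs ", n, ")")
      } else if (is.na(old) && !is.na(n)) mets[[inst$met]] <- n
    }
  }
  ids <- sort(ls(mets))
  metabolites <- data.frame(
    id = ids,
    carbons = vapply(ids, function(i) as.integer(mets[[i]]), 1L),
    stringsAsFactors = FALSE)
  metabolites$balanced <- !(grepl("\\.x$", metabolites$id) |
                            metabolites$id %in% unbalanced)
  metabolites$symmetric <- metabolites$id %in% symmetric
  rownames(metabolites) <- NULL

  net <- structure(list(metabolites = metabolites, reactions = reactions),
                   class = "flux_network")
  net
}

#' Read a carbon-transition network file
#'
#' @param path Path to a network file in the dialect of [parse_network()].
#' @return A `flux_network` object.
#' @export
read_network <- function(path) parse_network(readLines(path, warn = FALSE))

#' Path to a packaged network fixture
#'
#' @param cell `"lf"` (lung fibroblast) or `"pasmc"` (pulmonary artery
#'   smooth muscle cell); the two differ only in biomass coefficients.
#' @return File path under the installed package.
#' @export
isoflux_network_file <- function(cell = c("lf", "pasmc")) {
  cell <- match.arg(cell)
  system.file("extdata", paste0("network_", cell, ".net"),
              package = "isoflux", mustWork = TRUE)
}

#' Read a packaged published flux solution table
#'
#' The tables ship the published net and exchange flux solutions (value,
#' lower and upper 95% bound, fmol/cell/h) for paired culture conditions.
#'
#' @param which `"lf_oxygen"`, `"lf_bay"` or `"pasmc_oxygen"`.
#' @return Data frame with columns type, id, condition, flux, lb, ub.
#' @export
isoflux_flux_table <- function(which = c("lf_oxygen", "lf_bay",
                                         "pasmc_oxygen")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("fluxes_", which, ".tsv"),
                      package = "isoflux", mustWork = TRUE)
  read_flux_table(path)
}

#' @export
print.flux_network <- function(x, ...) {
  nr <- sum(!vapply(x$reactions, `[[`, TRUE, "pseudo"))
  np <- length(x$reactions) - nr
  cat("Carbon-transition network:", nr, "reactions")
  if (np > 0) cat(" (+", np, "pseudo-reactions)")
  cat("\n  ", sum(x$metabolites$balanced), "balanced /",
      sum(!x$metabolites$balanced), "unbalanced metabolites\n")
  rev <- sum(vapply(x$reactions, `[[`, TRUE, "reversible"))
  cat("  ", rev, "reversible (net + exchange) reactions\n")
  invisible(x)
}

#' Number of chemical reactions in a network
#'
#' Pseudo-reactions (pool mixing rows, lumped unlabeled sources) are not
#' counted.
#' @param network A `flux_network`.
#' @return Integer count.
#' @export
n_reactions <- function(network) {
  sum(!vapply(network$reactions, `[[`, TRUE, "pseudo"))
}

#' Stoichiometric matrix over balanced metabolites
#'
#' Builds the matrix `S` such that metabolic steady state requires
#' `S %*% v_net = 0`. Rows are balanced metabolites only; unbalanced
#' (extracellular, sink and source) species impose no constraint.
#' Zero-coefficient mixing reactants contribute no entry.
#'
#' @param network A `flux_network`.
#' @return Numeric matrix, balanced metabolites x reactions.
#' @export
stoichiometric_matrix <- function(network) {
  bal <- network$metabolites$id[network$metabolites$balanced]
  rids <- vapply(network$reactions, `[[`, "", "id")
  S <- matrix(0, length(bal), length(rids), dimnames = list(bal, rids))
  for (r in network$reactions) {
    for (inst in r$reactants)
      if (inst$met %in% bal) S[inst$met, r$id] <- S[inst$met, r$id] - inst$coef
    for (inst in r$products)
      if (inst$met %in% bal) S[inst$met, r$id] <- S[inst$met, r$id] + inst$coef
  }
  S
}

#' Check a flux map against steady-state mass balance
#'
#' Computes the net production residual of every balanced metabolite and
#' compares it, relative to the total inflow at that metabolite, with a
#' tolerance. Printed flux solutions rounded to three significant figures
#' pass at `tol_rel = 0.02`.
#'
#' @param network A `flux_network`.
#' @param flux Named numeric vector of net fluxes covering every reaction,
#'   or a `flux_map`.
#' @param tol_rel Relative tolerance on |residual| / max(inflow, outflow).
#' @return Data frame (metabolite, residual, inflow, rel) with attribute
#'   `pass`; also classed `flux_balance_report`.
#' @export
check_flux_balance <- function(network, flux, tol_rel = 0.02) {
  if (inherits(flux, "flux_map")) flux <- flux$net
  S <- stoichiometric_matrix(network)
  missing <- setdiff(colnames(S), names(flux))
  if (length(missing))
    stop("flux map misses reactions: ", paste(missing, collapse = ", "))
  v <- flux[colnames(S)]
  contrib <- sweep(S, 2, v, `*`)
  residual <- rowSums(contrib)
  inflow <- rowSums(pmax(contrib, 0))
  outflow <- rowSums(pmax(-contrib, 0))
  scale <- pmax(inflow, outflow)
  rel <- ifelse(scale > 0, abs(residual) / scale, abs(residual))
  rep <- data.frame(metabolite = rownames(S), residual = residual,
                    inflow = inflow, rel = rel, row.names = NULL)
  attr(rep, "pass") <- all(rel <= tol_rel)
  attr(rep, "tol_rel") <- tol_rel
  class(rep) <- c("flux_balance_report", "data.frame")
  rep
}

#' @export
print.flux_balance_report <- function(x, ...) {
  cat(if (attr(x, "pass")) "PASS" else "FAIL",
      sprintf("(max relative residual %.3g, tolerance %.3g)\n",
              max(x$rel), attr(x, "tol_rel")))
  worst <- utils::head(x[order(-x$rel), ], 5)
  print.data.frame(worst, digits = 3)
  invisible(x)
}

#' Construct a flux map
#'
#' @param net Named numeric vector of net fluxes (fmol/cell/h).
#' @param exchange Named numeric vector of exchange fluxes for reversible
#'   reactions (missing entries default to 0).
#' @param cap Upper cap applied to exchange fluxes.
#' @return A `flux_map` object.
#' @export
flux_map <- function(net, exchange = numeric(), cap = 1e7) {
  stopifnot(!is.null(names(net)))
  exchange <- pmin(pmax(exchange, 0), cap)
  structure(list(net = net, exchange = exchange, cap = cap),
            class = "flux_map")
}

#' @export
print.flux_map <- function(x, ...) {
  cat("Flux map:", length(x$net), "net fluxes,",
      length(x$exchange), "exchange fluxes\n")
  invisible(x)
}

# Effective one-way fluxes for every reaction.
# Returns list(fwd, bwd) of named vectors. For reversibles,
# fwd = max(net, 0) + exch and bwd = max(-net, 0) + exch.
oneway_fluxes <- function(network, fmap, clamp = FALSE) {
  rids <- vapply(network$reactions, `[[`, "", "id")
  net <- fmap$net[rids]
  if (anyNA(net)) stop("flux map misses reactions: ",
                       paste(rids[is.na(net)], collapse = ", "))
  exch <- rep(0, length(rids))
  names(exch) <- rids
  if (length(fmap$exchange)) {
    common <- intersect(names(fmap$exchange), rids)
    exch[common] <- fmap$exchange[common]
  }
  rev <- vapply(network$reactions, `[[`, TRUE, "reversible")
  exch[!rev] <- 0
  fwd <- stats::setNames(ifelse(rev, pmax(net, 0) + exch, net), rids)
  bwd <- stats::setNames(ifelse(rev, pmax(-net, 0) + exch, 0), rids)
  if (!clamp && any(fwd < -1e-9))
    stop("negative net flux on irreversible reaction: ",
         paste(rids[fwd < -1e-9], collapse = ", "))
  list(fwd = pmax(fwd, 0), bwd = bwd)
}

# Total one-way consumption of each balanced metabolite (its EMU outflow).
metabolite_outflow <- function(network, ow) {
  bal <- network$metabolites$id[network$metabolites$balanced]
  out <- stats::setNames(numeric(length(bal)), bal)
  for (r in network$reactions) {
    for (inst in r$reactants)
      if (inst$met %in% bal)
        out[inst$met] <- out[inst$met] + inst$coef * ow$fwd[r$id]
    for (inst in r$products)
      if (inst$met %in% bal)
        out[inst$met] <- out[inst$met] + inst$coef * ow$bwd[r$id]
  }
  out
}

#' Parameterize the flux space of a network
#'
#' Expresses every steady-state net flux vector as a particular solution
#' plus a combination of free fluxes, by column-pivoted QR of the
#' stoichiometric constraints (plus optional fixed-flux equalities).
#' Exchange fluxes of reversible chemical reactions are parameterized on a
#' log10 scale, clipped to `[0, cap]`. The returned maps are exact
#' round-trip inverses on the feasible set.
#'
#' @param network A `flux_network`.
#' @param fixed Named vector of equality-constrained net fluxes (default
#'   pins any `sPYR`-style unit mixing outflow present to 1).
#' @param cap Exchange flux cap.
#' @return A `flux_parameterization`: members `free_net` (reaction ids of
#'   free net fluxes), `exch_ids`, `theta_to_flux(theta)`,
#'   `flux_to_theta(fmap)`, `n_par`, and bookkeeping matrices.
#' @export
free_flux_parameterization <- function(network, fixed = NULL, cap = 1e7) {
  S <- stoichiometric_matrix(network)
  rids <- colnames(S)
  if (is.null(fixed) && "sPYR" %in% rids) fixed <- c(sPYR = 1)
  E <- matrix(0, length(fixed), length(rids), dimnames = list(NULL, rids))
  for (i in seq_along(fixed)) E[i, names(fixed)[i]] <- 1
  K <- rbind(S, E)
  b <- c(rep(0, nrow(S)), unname(fixed))
  qrK <- qr(K)
  rank <- qrK$rank
  piv <- qrK$pivot
  dep <- rids[piv[seq_len(rank)]]
  fre <- rids[piv[-seq_len(rank)]]
  Kd <- K[, dep, drop = FALSE]
  Kf <- K[, fre, drop = FALSE]
  # v_dep = solve(Kd) (b - Kf v_free), least-squares via QR (Kd col rank = rank)
  qrd <- qr(Kd)
  rev <- vapply(network$reactions, `[[`, TRUE, "reversible")
  pseudo <- vapply(network$reactions, `[[`, TRUE, "pseudo")
  exch_ids <- rids[rev & !pseudo]
  irrev_ids <- rids[!rev]
  theta_names <- c(if (length(fre)) paste0("net.", fre),
                   if (length(exch_ids)) paste0("xch.", exch_ids))

  theta_to_flux <- function(theta) {
    vf <- theta[seq_along(fre)]
    vd <- qr.coef(qrd, b - as.vector(Kf %*% vf))
    v <- stats::setNames(numeric(length(rids)), rids)
    v[dep] <- vd
    v[fre] <- vf
    ex <- pmin(10^theta[length(fre) + seq_along(exch_ids)], cap)
    names(ex) <- exch_ids
    flux_map(v, ex, cap = cap)
  }
  flux_to_theta <- function(fmap) {
    ex <- stats::setNames(rep(0, length(exch_ids)), exch_ids)
    common <- intersect(names(fmap$exchange), exch_ids)
    ex[common] <- fmap$exchange[common]
    stats::setNames(c(fmap$net[fre], log10(pmax(ex, 1e-9))), theta_names)
  }
  structure(list(S = S, K = K, b = b, dep = dep, free_net = fre,
                 exch_ids = exch_ids, irrev_ids = irrev_ids,
                 theta_names = theta_names,
                 n_par = length(theta_names), cap = cap,
                 theta_to_flux = theta_to_flux,
                 flux_to_theta = flux_to_theta),
            class = "flux_parameterization")
}

#' @export
print.flux_parameterization <- function(x, ...) {
  cat("Flux parameterization:", length(x$free_net), "free net fluxes +",
      length(x$exch_ids), "exchange fluxes =", x$n_par, "parameters\n")
  invisible(x)
}

#' Project a flux map onto exact steady-state balance
#'
#' Finds the smallest least-squares adjustment of the net fluxes that
#' satisfies `S v = 0` (plus any fixed-flux equalities). Useful for
#' rounding-level imbalances, e.g. published solutions printed to three
#' significant figures.
#'
#' @param network A `flux_network`.
#' @param flux Named net-flux vector or `flux_map`.
#' @param fixed Equality constraints as in [free_flux_parameterization()].
#' @return A `flux_map` with balanced net fluxes (exchange fluxes, if any
#'   were supplied, are carried over).
#' @export
balance_flux_map <- function(network, flux, fixed = NULL) {
  ex <- numeric()
  if (inherits(flux, "flux_map")) {
    ex <- flux$exchange
    flux <- flux$net
  }
  param <- free_flux_parameterization(network, fixed = fixed)
  v <- flux[colnames(param$K)]
  project <- function(v, K, b) {
    # magnitude-weighted minimum-norm correction into {v : K v = b}, so
    # near-zero fluxes are perturbed least
    w <- pmax(abs(v), 1e-3)
    r <- as.vector(K %*% v) - b
    KW <- sweep(K, 2, w, `*`)
    sv <- svd(KW)
    pos <- sv$d > max(sv$d) * 1e-12
    u <- sv$v[, pos] %*% ((t(sv$u[, pos]) %*% r) / sv$d[pos])
    stats::setNames(v - w * as.vector(u), names(v))
  }
  K <- param$K; b <- param$b
  v2 <- project(v, K, b)
  for (i in 1:5) {
    bad <- param$irrev_ids[v2[param$irrev_ids] < 0]
    if (!length(bad)) break
    # pin violated irreversible fluxes to zero and re-project
    add <- matrix(0, length(bad), ncol(K), dimnames = list(NULL, colnames(K)))
    for (j in seq_along(bad)) add[j, bad[j]] <- 1
    K <- rbind(K, add); b <- c(b, rep(0, length(bad)))
    v2[bad] <- 0
    v2 <- project(v2, K, b)
  }
  flux_map(v2, ex)
}

#' Sample a balanced flux map from the null space of the network
#'
#' Draws free net fluxes uniformly and exchange fluxes log-uniformly;
#' draws violating irreversibility are projected onto the feasible
#' polytope by least squares on the violations (in high dimension pure
#' rejection essentially never hits the polytope). Returns a balanced
#' `flux_map`.
#'
#' @param network A `flux_network`.
#' @param param Optional pre-built parameterization.
#' @param net_range Range for free net fluxes.
#' @param exch_range Range (log10) for exchange fluxes.
#' @param max_tries Sampling budget.
#' @return A `flux_map`.
#' @export
sample_flux_map <- function(network, param = NULL, net_range = c(0, 100),
                            exch_range = c(-1, 2), max_tries = 50) {
  if (is.null(param)) param <- free_flux_parameterization(network)
  nf <- length(param$free_net)
  viol <- function(tn, tx) {
    v <- param$theta_to_flux(c(tn, tx))$net[param$irrev_ids]
    pmin(v, 0)
  }
  for (i in seq_len(max_tries)) {
    tn <- stats::runif(nf, net_range[1], net_range[2])
    tx <- stats::runif(length(param$exch_ids), exch_range[1], exch_range[2])
    if (any(viol(tn, tx) < 0)) {
      f <- tryCatch(minpack.lm::nls.lm(
        tn, fn = function(p) viol(p, tx),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(f)) next
      tn <- coef(f)
    }
    if (all(viol(tn, tx) >= -1e-10)) return(param$theta_to_flux(c(tn, tx)))
  }
  stop("could not sample a feasible flux map in ", max_tries, " tries")
}
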