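#' Decompose a network into elementary metabolite units
#'
#' Starting from the observed metabolite fragments, traces each EMU (a
#' metabolite together with a subset of its carbon positions) back through
#' every reaction able to produce it, yielding the minimal set of EMU
#' balances that determines the observed mass isotopomer distributions.
#' The result is layered by EMU size so that the size-k linear systems
#' depend only on smaller sizes and on labeled inputs. Production into
#' rotationally symmetric metabolites (succinate, fumarate) is split 50/50
#' over the two orientations, which makes simulated MIDs invariant to the
#' orientation convention.
#'
#' @param network A `flux_network`.
#' @param observed Character vector of metabolite ids (full carbon
#'   fragments) or a list of `list(met, positions)` fragments.
#' @return An `emu_network`: `emus` table (key, met, size, input), `terms`
#'   (per non-input EMU, the producing reaction terms), and the observed
#'   keys. Ordering is deterministic.
#' @export
emu_decomposition <- function(network, observed) {
  mets <- network$metabolites
  carb <- stats::setNames(mets$carbons, mets$id)
  bal <- stats::setNames(mets$balanced, mets$id)
  symm <- stats::setNames(mets$symmetric, mets$id)

  canon <- function(met, pos) {
    pos <- sort(pos)
    if (isTRUE(symm[met])) {
      mir <- sort(carb[met] + 1 - pos)
      if (paste(mir, collapse = ",") < paste(pos, collapse = ","))
        pos <- mir
    }
    pos
  }
  key_of <- function(met, pos) paste0(met, "|", paste(pos, collapse = ","))

  if (is.character(observed))
    observed <- lapply(observed, function(m) {
      if (is.na(carb[m])) stop("unknown or carbon-free metabolite: ", m)
      list(met = m, positions = seq_len(carb[m]))
    })
  obs_keys <- vapply(observed, function(o) {
    if (max(o$positions) > carb[o$met])
      stop("fragment larger than metabolite ", o$met)
    key_of(o$met, canon(o$met, o$positions))
  }, "")

  emu_met <- list(); emu_pos <- list(); emu_input <- list()
  terms <- list()
  queue <- unique(obs_keys)
  seen <- new.env()
  for (k in queue) assign(k, TRUE, envir = seen)

  # pre-index: for each metabolite, the (reaction, direction, instance)
  # triples that produce it
  producers <- new.env()
  add_prod <- function(met, entry) {
    producers[[met]] <- c(producers[[met]], list(entry))
  }
  for (r in network$reactions) {
    if (!r$atom_mapped) next
    for (pi in seq_along(r$products)) {
      inst <- r$products[[pi]]
      if (!is.null(inst$atoms))
        add_prod(inst$met, list(r = r, dir = 1L, inst = pi))
    }
    if (r$reversible) {
      for (pi in seq_along(r$reactants)) {
        inst <- r$reactants[[pi]]
        if (!is.null(inst$atoms) && inst$coef > 0)
          add_prod(inst$met, list(r = r, dir = -1L, inst = pi))
      }
    }
  }

  while (length(queue)) {
    k <- queue[[1]]; queue <- queue[-1]
    met <- sub("\\|.*", "", k)
    pos <- as.integer(strsplit(sub(".*\\|", "", k), ",")[[1]])
    emu_met[[k]] <- met; emu_pos[[k]] <- pos
    if (!isTRUE(bal[met])) { emu_input[[k]] <- TRUE; next }
    emu_input[[k]] <- FALSE
    tlist <- list()
    for (entry in if (is.null(producers[[met]])) list() else producers[[met]]) {
      r <- entry$r
      side_prod <- if (entry$dir == 1L) r$products else r$reactants
      side_reac <- if (entry$dir == 1L) r$reactants else r$products
      inst <- side_prod[[entry$inst]]
      variants <- list(pos)
      wt <- inst$coef
      if (isTRUE(symm[met])) {
        mir <- sort(carb[met] + 1 - pos)
        variants <- list(pos, mir)
        wt <- wt / 2
      }
      for (vpos in variants) {
        letters <- inst$atoms[vpos]
        srcs <- list()
        for (ri in side_reac) {
          if (is.null(ri$atoms)) next
          hit <- which(ri$atoms %in% letters)
          if (length(hit)) {
            cp <- canon(ri$met, hit)
            srcs[[length(srcs) + 1]] <- key_of(ri$met, cp)
            kk <- key_of(ri$met, cp)
            if (!exists(kk, envir = seen)) {
              assign(kk, TRUE, envir = seen)
              queue <- c(queue, kk)
            }
          }
        }
        if (!length(srcs))
          stop("no atom source for EMU ", k, " in reaction ", r$id)
        tlist[[length(tlist) + 1]] <-
          list(rid = r$id, dir = entry$dir, weight = wt,
               sources = unlist(srcs))
      }
    }
    if (!length(tlist))
      stop("EMU ", k, " of balanced metabolite has no producing reaction")
    terms[[k]] <- tlist
  }

  keys <- names(emu_met)
  sizes <- vapply(keys, function(k) length(emu_pos[[k]]), 1L)
  ord <- order(sizes, keys)
  emus <- data.frame(key = keys[ord], met = unlist(emu_met)[ord],
                     size = sizes[ord],
                     input = unlist(emu_input)[ord],
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(emus = emus, positions = emu_pos, terms = terms,
                 observed = stats::setNames(obs_keys,
                   vapply(observed, `[[`, "", "met")),
                 network = network, plan_env = new.env(parent = emptyenv())),
            class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat("EMU network:", nrow(x$emus), "EMUs (",
      sum(x$emus$input), "inputs ) in sizes",
      paste(sort(unique(x$emus$size)), collapse = ", "), "\n")
  invisible(x)
}
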