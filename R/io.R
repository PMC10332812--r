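#' Read a delimited flux table
#'
#' Reads tab- (or comma-) separated flux tables in the published layout:
#' columns `type` (NET/EXCH), `id`, `condition`, `flux`, `lb`, `ub`.
#' Scientific notation (`5.14E+02`) and `Inf`/`-Inf` bounds parse exactly.
#' Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_flux_table <- function(path) {
  first <- readLines(path, n = 20)
  sep <- if (any(grepl("\t", first))) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("type", "id", "condition", "flux")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("flux table ", path, " misses columns: ", paste(miss, collapse = ", "))
  for (cl in intersect(c("flux", "lb", "ub"), names(d)))
    d[[cl]] <- as.numeric(d[[cl]])
  d
}

#' Write a flux table
#'
#' @param d Data frame as returned by [read_flux_table()] or built from a
#'   [flux_map()] via [flux_map_to_table()].
#' @param path Output path; tab-separated.
#' @export
write_flux_table <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert between a flux map and the tabular layout
#'
#' @param fmap A `flux_map`.
#' @param condition Condition label for the table rows.
#' @return Data frame with columns type, id, condition, flux.
#' @export
flux_map_to_table <- function(fmap, condition = "fit") {
  rbind(
    data.frame(type = "NET", id = names(fmap$net), condition = condition,
               flux = unname(fmap$net)),
    if (length(fmap$exchange))
      data.frame(type = "EXCH", id = names(fmap$exchange),
                 condition = condition, flux = unname(fmap$exchange)))
}

#' Extract a named net-flux vector from a flux table
#'
#' @param d Flux table data frame.
#' @param condition Condition label to select.
#' @param type Row type, default `"NET"`.
#' @return Named numeric vector.
#' @export
flux_table_vector <- function(d, condition, type = "NET") {
  sel <- d$condition == condition & d$type == type
  if (!any(sel)) stop("no rows for condition ", condition)
  stats::setNames(d$flux[sel], d$id[sel])
}

#' Read and validate a tidy MID table
#'
#' Expected columns: metabolite, mass_shift (0..n), fraction, and
#' optionally sample/tracer/time/sd. Fractions for each group must lie on
#' the probability simplex within `tol`.
#'
#' @param path File path (TSV or CSV).
#' @param tol Allowed deviation of each group's fraction sum from 1.
#' @return Data frame.
#' @export
read_mid_table <- function(path, tol = 1e-3) {
  first <- readLines(path, n = 5)
  sep <- if (any(grepl("\t", first))) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("metabolite", "mass_shift", "fraction")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("MID table misses columns: ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(d[setdiff(names(d),
                                    c("mass_shift", "fraction", "sd"))],
                          sep = "\r"))
  sums <- tapply(d$fraction, key, sum)
  bad <- abs(sums - 1) > tol
  if (any(bad))
    stop("MID fractions off the simplex (sum != 1) for: ",
         paste(utils::head(sub("\r.*", "", names(sums)[bad]), 3),
               collapse = ", "))
  d
}

#' Write a tidy MID table
#' @param d Data frame of MIDs.
#' @param path Output path; tab-separated.
#' @export
write_mid_table <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth or tracer configuration from YAML
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a configuration to YAML
#' @param x Named list.
#' @param path Output path.
#' @export
write_config <- function(x, path) {
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records input checksums, seed and package version so a run can be
#' reproduced byte-for-byte for its deterministic stages.
#'
#' @param inputs Character vector of input file paths.
#' @param seed Integer seed used.
#' @param extra Optional named list of additional entries.
#' @param path Output path.
#' @export
write_manifest <- function(inputs, seed, extra = list(), path) {
  sums <- vapply(inputs, function(p) {
    as.character(sum(as.integer(charToRaw(paste(readLines(p, warn = FALSE),
                                                collapse = "\n")))))
  }, "")
  manifest <- c(list(
    package = "isoflux",
    version = as.character(utils::packageVersion("isoflux")),
    seed = seed,
    inputs = as.list(sums)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
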