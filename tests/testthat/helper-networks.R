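# Shared fixtures built in code.

lf_network <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- read_network(isoflux_network_file("lf"))
    net
  }
})

pasmc_network <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- read_network(isoflux_network_file("pasmc"))
    net
  }
})

measured_metabolites <- function() {
  c("AKG", "PG3", "ALA", "ASP", "CIT", "FBP", "GLU", "GLN", "LAC", "MAL",
    "PYR.ms", "SER")
}

# published LF 21% solution projected onto exact balance, with its
# printed exchange fluxes: the reference "plausible flux map"
lf_reference_flux <- local({
  fm <- NULL
  function() {
    if (is.null(fm)) {
      d <- isoflux_flux_table("lf_oxygen")
      fm <<- balance_flux_map(lf_network(),
                              flux_map(flux_table_vector(d, "21pct"),
                                       flux_table_vector(d, "21pct",
                                                         "EXCH")))
    }
    fm
  }
})

# small linear+condensation test network used across simulation tests
toy_condensation_network <- function() {
  parse_network("
@unbalanced A.x E.x F.x
AIN: A.x (ab) -> A (ab)
R1: A (ab) <-> B (ab)
R2: B (ab) -> C (ba)
R3: A (ab) + C (cd) -> D (abdc)
R4: D (abcd) -> E.x (abcd)
R5: B (ab) -> F.x (ab)
")
}

# random small atom-mapped validation case (shared with the package)
random_small_network <- function(seed) random_validation_network(seed)
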