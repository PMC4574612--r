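#' Metabolite names of the monolignol pathway model
#'
#' The sixteen state variables of the normalized pathway model, in model
#' order (Z1..Z16).
#'
#' @return Named character vector of length 16; names are `Z1`..`Z16`.
#' @export
pathway_metabolites <- function() {
  c(Z1  = "phenylalanine",
    Z2  = "cinnamic acid",
    Z3  = "p-coumaric acid",
    Z4  = "p-coumaroyl-CoA",
    Z5  = "p-coumaryl aldehyde",
    Z6  = "p-coumaryl alcohol",
    Z7  = "caffeic acid",
    Z8  = "caffeoyl-CoA",
    Z9  = "ferulic acid",
    Z10 = "feruloyl-CoA",
    Z11 = "coniferaldehyde",
    Z12 = "coniferyl alcohol",
    Z13 = "5-OH-coniferaldehyde",
    Z14 = "5-OH-coniferyl alcohol",
    Z15 = "sinapaldehyde",
    Z16 = "sinapyl alcohol")
}

#' Enzyme labels of the monolignol pathway model
#'
#' Enzymes and formal efflux activities are independent variables Z17..Z34.
#' Named catalytic enzymes follow the standard pathway nomenclature; the
#' remaining entries are dedicated activities for effluxes that leave the
#' pathway (held at 1 unless a scenario perturbs them). `Z34` is the
#' putative CCR1/CAD channel complex.
#'
#' @return Named character vector of length 18; names are `Z17`..`Z34`.
#' @export
pathway_enzymes <- function() {
  c(Z17 = "PAL",
    Z18 = "efflux:cinnamic acid",
    Z19 = "C4H",
    Z20 = "4CL",
    Z21 = "CCR1",
    Z22 = "CAD",
    Z23 = "efflux:H",
    Z24 = "efflux:p-coumaric acid",
    Z25 = "HCT/C3pH/CSE",
    Z26 = "efflux:p-coumaroyl-CoA",
    Z27 = "COMT",
    Z28 = "CCoAOMT",
    Z29 = "efflux:G",
    Z30 = "efflux:ferulic acid",
    Z31 = "F5H",
    Z32 = "efflux:5-OH-coniferyl alcohol",
    Z33 = "efflux:S",
    Z34 = "CCR1:CAD channel")
}

# Flux table for the full (channel-containing) network: one substrate per
# flux, at most one product-inhibition partner, optional competition
# regulators (substrates competing for the shared enzyme), and the single
# catalysing enzyme (indices on the Z17..Z34 scale).
flux_table_full <- function() {
  data.frame(
    flux       = paste0("V", 1:26),
    substrate  = c(1, 2, 2, 3, 4, 5, 6, 3, 4, 4, 7, 7, 8, 9, 10, 11,
                   12, 9, 11, 12, 14, 13, 14, 15, 16, 10),
    product    = c(2, NA, 3, 4, 5, 6, NA, NA, 7, NA, 8, 9, 10, 10, 11, 12,
                   NA, NA, 13, 14, NA, 15, 16, 16, NA, 12),
    competitor = c(NA, NA, NA, NA, 10, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                   4, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, 4),
    enzyme     = c(17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 20, 27, 28, 20,
                   21, 22, 29, 30, 31, 31, 32, 27, 27, 22, 33, 34),
    stringsAsFactors = FALSE
  )
}

# Signed incidence of the full network: rows Z1..Z16, columns V1..V26.
stoichiometry_full <- function() {
  S <- matrix(0L, nrow = 16, ncol = 26,
              dimnames = list(names(pathway_metabolites()),
                              paste0("V", 1:26)))
  put <- function(i, plus = integer(), minus = integer()) {
    S[i, plus] <<- 1L
    S[i, minus] <<- -1L
  }
  put(1,  minus = 1)                 # phenylalanine: I1 - V1
  put(2,  plus = 1,        minus = c(2, 3))
  put(3,  plus = 3,        minus = c(4, 8))    # + I2
  put(4,  plus = 4,        minus = c(5, 9, 10))
  put(5,  plus = 5,        minus = 6)
  put(6,  plus = 6,        minus = 7)
  put(7,  plus = 9,        minus = c(11, 12))
  put(8,  plus = 11,       minus = 13)
  put(9,  plus = 12,       minus = c(14, 18))
  put(10, plus = c(13, 14), minus = c(15, 26))
  put(11, plus = 15,       minus = c(16, 19))
  put(12, plus = c(16, 26), minus = c(17, 20))
  put(13, plus = 19,       minus = 22)
  put(14, plus = 20,       minus = c(21, 23))
  put(15, plus = 22,       minus = 24)
  put(16, plus = c(23, 24), minus = 25)
  S
}

#' Build a pathway topology for one channel configuration
#'
#' Constructs the monolignol pathway network under one of three candidate
#' configurations of the CCR1/CAD channel that converts feruloyl-CoA to
#' coniferyl alcohol:
#'
#' * Configuration 1: the channel flux `V26` operates in parallel with the
#'   free two-step route `V15` (CCR1) + `V16` (CAD).
#' * Configuration 2: no channel; the free route only (25 fluxes).
#' * Configuration 3: the channel replaces the free route (`V15` and `V16`
#'   removed). The coniferaldehyde sub-branch (`V19`, `V22`, `V24`) then
#'   has no supply and is allowed to carry zero flux.
#'
#' @param config_id Integer 1, 2 or 3.
#' @param channel_coupling How the channel activity `Z34` is derived from
#'   the relative activities of its constituents CCR1 (`Z21`) and CAD
#'   (`Z22`): `"ccr1"` (default; the complex tracks its committed
#'   reductase step, so CAD knockdowns leave the channel intact --
#'   the only coupling consistent with the observed S/G directions in
#'   CCR1 versus CAD transgenics), `"product"`, or `"min"`.
#' @return An object of class `pathway_topology`: a list with the
#'   metabolite and enzyme tables, the flux table (substrate, product
#'   inhibitor, competition regulators, enzyme per flux), the signed
#'   stoichiometric incidence matrix (16 x n_flux), influx placement
#'   (`I1` feeds Z1, `I2` feeds Z3), and bookkeeping fields.
#' @examples
#' top <- build_topology(1)
#' dim(top$stoich)
#' @export
build_topology <- function(config_id,
                           channel_coupling = c("ccr1", "product", "min")) {
  if (length(config_id) != 1L || !config_id %in% c(1, 2, 3))
    stop("unknown configuration id: ", paste(config_id, collapse = ","),
         " (must be 1, 2 or 3)")
  channel_coupling <- match.arg(channel_coupling)

  ft <- flux_table_full()
  S <- stoichiometry_full()
  drop <- switch(as.character(config_id),
                 "1" = character(0),
                 "2" = "V26",
                 "3" = c("V15", "V16"))
  keep <- !ft$flux %in% drop
  ft <- ft[keep, , drop = FALSE]
  rownames(ft) <- ft$flux
  S <- S[, keep, drop = FALSE]

  # fluxes whose steady-state value is structurally forced to zero
  zero_ok <- if (config_id == 3) c("V19", "V22", "V24") else character(0)

  structure(list(
    config_id        = as.integer(config_id),
    metabolites      = pathway_metabolites(),
    enzymes          = pathway_enzymes(),
    fluxes           = ft,
    stoich           = S,
    influx_targets   = c(I1 = 1L, I2 = 3L),
    channel_coupling = channel_coupling,
    zero_ok          = zero_ok
  ), class = "pathway_topology")
}

#' @export
print.pathway_topology <- function(x, ...) {
  cat("Monolignol pathway topology (configuration ", x$config_id, ")\n",
      sep = "")
  cat("  ", length(x$metabolites), " metabolites, ", nrow(x$fluxes),
      " fluxes, 2 influxes\n", sep = "")
  cat("  channel flux V26: ",
      if ("V26" %in% x$fluxes$flux) "present" else "absent",
      "; free route V15/V16: ",
      if ("V15" %in% x$fluxes$flux) "present" else "absent", "\n", sep = "")
  cat("  channel activity coupling: ", x$channel_coupling, "\n", sep = "")
  invisible(x)
}

#' Product-inhibition and competition pairs of a topology
#'
#' Lists the (metabolite, flux) kinetic-order slots of a topology, split by
#' role. Each flux has exactly one substrate slot; product-inhibition and
#' competition slots exist only for fluxes that have the corresponding
#' regulator.
#'
#' @param topology A `pathway_topology`.
#' @return A list with data.frames `substrate`, `inhibition`, `competition`,
#'   each with columns `met` (metabolite index) and `flux` (flux id).
#' @export
kinetic_order_slots <- function(topology) {
  ft <- topology$fluxes
  list(
    substrate = data.frame(met = ft$substrate, flux = ft$flux,
                           stringsAsFactors = FALSE),
    inhibition = {
      has <- !is.na(ft$product)
      data.frame(met = ft$product[has], flux = ft$flux[has],
                 stringsAsFactors = FALSE)
    },
    competition = {
      has <- !is.na(ft$competitor)
      data.frame(met = ft$competitor[has], flux = ft$flux[has],
                 stringsAsFactors = FALSE)
    }
  )
}

#' Write a pathway topology to a structured text file
#'
#' Serializes the topology as human-editable YAML (metabolites, influxes,
#' and one block per flux listing substrate, product inhibitor, competition
#' regulators and enzyme). [read_topology()] restores it.
#'
#' @param topology A `pathway_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  ft <- topology$fluxes
  fx <- lapply(seq_len(nrow(ft)), function(i) {
    out <- list(substrate = ft$substrate[i],
                enzyme = ft$enzyme[i],
                stoich = as.integer(topology$stoich[, i]))
    if (!is.na(ft$product[i])) out$product_inhibitor <- ft$product[i]
    if (!is.na(ft$competitor[i])) out$competitor <- ft$competitor[i]
    out
  })
  names(fx) <- ft$flux
  doc <- list(config_id = topology$config_id,
              channel_coupling = topology$channel_coupling,
              metabolites = as.list(topology$metabolites),
              enzymes = as.list(topology$enzymes),
              influx_targets = as.list(topology$influx_targets),
              zero_ok = as.list(topology$zero_ok),
              fluxes = fx)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Read a pathway topology from a structured text file
#'
#' @param path File written by [write_topology()].
#' @return A `pathway_topology`.
#' @export
read_topology <- function(path) {
  doc <- yaml::read_yaml(path)
  ft <- data.frame(
    flux = names(doc$fluxes),
    substrate = vapply(doc$fluxes, function(f) as.numeric(f$substrate), 0),
    product = vapply(doc$fluxes, function(f)
      if (is.null(f$product_inhibitor)) NA_real_ else as.numeric(f$product_inhibitor), 0),
    competitor = vapply(doc$fluxes, function(f)
      if (is.null(f$competitor)) NA_real_ else as.numeric(f$competitor), 0),
    enzyme = vapply(doc$fluxes, function(f) as.numeric(f$enzyme), 0),
    stringsAsFactors = FALSE
  )
  rownames(ft) <- ft$flux
  S <- vapply(doc$fluxes, function(f) as.integer(f$stoich),
              integer(length(doc$metabolites)))
  dimnames(S) <- list(names(doc$metabolites), names(doc$fluxes))
  structure(list(
    config_id = as.integer(doc$config_id),
    metabolites = unlist(doc$metabolites),
    enzymes = unlist(doc$enzymes),
    fluxes = ft,
    stoich = S,
    influx_targets = unlist(doc$influx_targets),
    channel_coupling = doc$channel_coupling,
    zero_ok = as.character(unlist(doc$zero_ok))
  ), class = "pathway_topology")
}
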