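#' Construct a GMA parameter set
#'
#' Bundles a kinetic-order matrix, a rate-constant vector and regulation
#' flags into a parameter set for one model instance. Kinetic orders are
#' stored densely as a 16 x n_flux matrix `g` aligned with the topology's
#' flux table; entries are zero where a metabolite does not enter a flux.
#' Enzyme exponents are fixed at 1 (a flux is linear in its enzyme).
#'
#' @param topology A `pathway_topology`.
#' @param g Kinetic-order matrix (16 x n_flux), rows Z1..Z16, columns in
#'   topology flux order. Substrate/activator entries must lie in (0,1],
#'   inhibitor entries in \[-1,0).
#' @param alpha Positive rate-constant vector, one entry per flux
#'   (zero allowed only for fluxes listed in `topology$zero_ok`).
#' @param flags Named logical vector with elements `product_inhibition`,
#'   `ccr_competition`, `fourcl_inhibition`.
#' @param phi Optional 4CL-inhibition factor in (0,1), used only by
#'   scenarios with `fourcl_inhibition = TRUE`; it scales the activity of
#'   4CL (equivalently the rate constants of V4, V11, V14).
#' @param influx Exogenous influxes `c(I1, I2)` the rate constants are
#'   anchored to; the all-100 state is a fixed point only under these.
#' @return An object of class `gma_parameters`.
#' @export
gma_parameters <- function(topology, g, alpha,
                           flags = c(product_inhibition = TRUE,
                                     ccr_competition = TRUE,
                                     fourcl_inhibition = TRUE),
                           phi = NA_real_,
                           influx = c(I1 = 1, I2 = 0)) {
  nf <- nrow(topology$fluxes)
  if (!is.matrix(g) || nrow(g) != 16L || ncol(g) != nf)
    stop("kinetic-order matrix must be 16 x ", nf,
         " for this topology, got ", nrow(g), " x ", ncol(g))
  if (length(alpha) != nf)
    stop("alpha must have one entry per flux (", nf, ")")
  if (any(alpha < 0) ||
      any(alpha == 0 & !topology$fluxes$flux %in% topology$zero_ok))
    stop("rate constants must be positive for structurally required fluxes")
  dimnames(g) <- list(names(topology$metabolites), topology$fluxes$flux)
  names(alpha) <- topology$fluxes$flux
  structure(list(g = g, alpha = alpha, h = 1,
                 flags = flags, phi = phi, influx = influx),
            class = "gma_parameters")
}

#' @export
print.gma_parameters <- function(x, ...) {
  cat("GMA parameter set: ", length(x$alpha), " fluxes, ",
      sum(x$g != 0), " nonzero kinetic orders\n", sep = "")
  cat("  regulation:",
      paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  if (!is.na(x$phi)) cat("  4CL inhibition factor phi =", x$phi, "\n")
  invisible(x)
}

#' Wild-type enzyme profile
#'
#' All activities relative to wild type; the wild type is the all-ones
#' vector over `Z17`..`Z34`.
#'
#' @return Named numeric vector of 18 ones.
#' @export
wildtype_enzymes <- function() {
  stats::setNames(rep(1, 18), names(pathway_enzymes()))
}

#' Build an enzyme activity profile from named multipliers
#'
#' Accepts multipliers keyed either by enzyme symbol (`"4CL"`, `"CCR1"`,
#' ...) or by model id (`"Z20"`). Unless `Z34` is set explicitly, the
#' channel activity is derived from the CCR1 and CAD activities by the
#' topology's coupling rule (`product` or `min`).
#'
#' @param topology A `pathway_topology`.
#' @param multipliers Named numeric vector/list of relative activities.
#' @return Named numeric vector over `Z17`..`Z34`.
#' @export
enzyme_profile <- function(topology, multipliers = NULL) {
  act <- wildtype_enzymes()
  labels <- pathway_enzymes()
  z34_set <- FALSE
  for (nm in names(multipliers)) {
    val <- as.numeric(multipliers[[nm]])
    if (val < 0) stop("enzyme activity must be >= 0: ", nm)
    zid <- if (nm %in% names(labels)) nm else names(labels)[match(nm, labels)]
    if (is.na(zid)) stop("unknown enzyme: ", nm)
    act[[zid]] <- val
    if (zid == "Z34") z34_set <- TRUE
  }
  if (!z34_set) {
    act[["Z34"]] <- switch(topology$channel_coupling,
                           ccr1 = act[["Z21"]],
                           product = act[["Z21"]] * act[["Z22"]],
                           min = min(act[["Z21"]], act[["Z22"]]))
  }
  act
}

#' Evaluate all GMA flux laws at a state
#'
#' Computes `V_j = alpha_j * prod_r Z_r^{g_{r,j}} * E_j` for every flux,
#' where `E_j` is the activity of the flux's enzyme (exponent 1).
#'
#' @param topology A `pathway_topology`.
#' @param params A `gma_parameters`.
#' @param state Strictly positive numeric vector of 16 normalized
#'   concentrations.
#' @param enzymes Named activity vector over `Z17`..`Z34` (default wild
#'   type).
#' @return Named flux vector.
#' @export
evaluate_fluxes <- function(topology, params, state,
                            enzymes = wildtype_enzymes()) {
  if (length(state) != 16L)
    stop("state must have 16 entries, got ", length(state))
  if (any(!is.finite(state)) || any(state <= 0))
    stop("power-law fluxes are undefined at non-positive concentrations")
  eact <- enzymes[paste0("Z", topology$fluxes$enzyme)]
  v <- params$alpha * exp(drop(crossprod(params$g, log(state)))) * eact
  names(v) <- topology$fluxes$flux
  v
}

#' Time derivative of the normalized pathway state
#'
#' `dZ/dt = S V(Z) + I`, with influx `I1` feeding phenylalanine (Z1) and
#' `I2` feeding p-coumaric acid (Z3). Influxes are exogenous constants.
#'
#' @inheritParams evaluate_fluxes
#' @param influx Numeric vector `c(I1 = ..., I2 = ...)`; defaults to the
#'   influxes the parameter set was anchored to.
#' @return Named derivative vector of length 16.
#' @export
gma_rhs <- function(topology, params, state, enzymes = wildtype_enzymes(),
                    influx = params$influx) {
  v <- evaluate_fluxes(topology, params, state, enzymes)
  dz <- drop(topology$stoich %*% v)
  dz[topology$influx_targets[["I1"]]] <- dz[topology$influx_targets[["I1"]]] +
    influx[["I1"]]
  dz[topology$influx_targets[["I2"]]] <- dz[topology$influx_targets[["I2"]]] +
    influx[["I2"]]
  names(dz) <- names(topology$metabolites)
  dz
}

#' Shipped example model instance
#'
#' One member of the accepted Configuration-1 ensemble (full regulation:
#' universal product inhibition, CCR1 substrate competition, 4CL
#' inhibition), used for validation runs and as a numerical fixture. Rate
#' constants and kinetic orders are given to four decimals; the flux
#' distribution implied through the steady-state relation
#' `V_j = alpha_j * 100^{sum_r g_{r,j}}` is attached.
#'
#' As printed, the set leaves one node (cinnamic acid) slightly
#' unbalanced: the implied `V1` (about 1.00) does not equal `V2 + V3`
#' (about 1.16), so the all-100 state is not an exact fixed point. With
#' `balanced = TRUE` the phenylalanine influx and `alpha_1` are raised to
#' close that balance (the only self-consistent one-parameter repair),
#' and the anchored influxes are attached, making the all-100 state an
#' exact wild-type fixed point suitable for simulation.
#'
#' @param balanced Repair the cinnamic-acid imbalance (see above) and
#'   attach anchored influxes. `FALSE` returns the verbatim values.
#' @return A list with `topology`, `params` (`gma_parameters`) and
#'   `fluxes` (implied steady-state flux vector).
#' @export
example_model <- function(balanced = FALSE) {
  topology <- build_topology(1)
  alpha <- c(0.5233, 0.1053, 0.15, 0.2711, 0.1832, 0.003, 0.0042, 0.0058,
             0.2265, 0.0024, 0.1054, 0.1095, 0.1452, 0.2681, 0.0771,
             0.0881, 0.0168, 0.002, 0.2212, 0.0402, 0.0002, 0.0392,
             0.1573, 0.0712, 0.1154, 0.0814)
  ko <- list(                                  # (metabolite, flux, order)
    c(1, 1, 0.2813),  c(2, 1, -0.1406),
    c(2, 2, 0.0846),
    c(2, 3, 0.8240),  c(3, 3, -0.4120),
    c(3, 4, 0.5669),  c(4, 4, -0.2835),
    c(4, 5, 0.0710),  c(5, 5, -0.0355),  c(10, 5, -0.4505),
    c(5, 6, 0.9630),  c(6, 6, -0.4815),
    c(6, 7, 0.4040),
    c(3, 8, 0.5759),
    c(4, 9, 0.6118),  c(7, 9, -0.3059),
    c(4, 10, 0.6398),
    c(7, 11, 0.6277), c(8, 11, -0.3138),
    c(7, 12, 0.6414), c(9, 12, -0.3207),
    c(8, 13, 0.4885), c(10, 13, -0.2442),
    c(9, 14, 0.2046), c(10, 14, -0.1023),
    c(10, 15, 0.9009), c(11, 15, -0.4505), c(4, 15, -0.0355),
    c(11, 16, 0.5198), c(12, 16, -0.2599),
    c(12, 17, 0.7121),
    c(9, 18, 0.6982),
    c(11, 19, 0.0160), c(13, 19, -0.0080),
    c(12, 20, 0.6973), c(14, 20, -0.3487),
    c(14, 21, 0.8535),
    c(13, 22, 0.7673), c(15, 22, -0.3836),
    c(14, 23, 0.1043), c(16, 23, -0.0521),
    c(15, 24, 0.5080), c(16, 24, -0.2540),
    c(16, 25, 0.2855),
    c(10, 26, 0.7116), c(12, 26, -0.3558), c(4, 26, -0.0355))
  g <- matrix(0, 16, 26)
  for (e in ko) g[e[1], e[2]] <- e[3]
  params <- gma_parameters(topology, g, alpha)
  fluxes <- params$alpha * 100^colSums(params$g)
  names(fluxes) <- topology$fluxes$flux
  if (balanced) {
    fluxes[["V1"]] <- fluxes[["V2"]] + fluxes[["V3"]]
    influx <- c(I1 = fluxes[["V1"]],
                I2 = fluxes[["V4"]] + fluxes[["V8"]] - fluxes[["V3"]])
    fd <- list(V = fluxes, I1 = influx[["I1"]], I2 = influx[["I2"]])
    alpha <- compute_rate_constants(topology, fd, g)
    params <- gma_parameters(topology, g, alpha, phi = 0.5,
                             influx = influx)
  }
  list(topology = topology, params = params, fluxes = fluxes)
}
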