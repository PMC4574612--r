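#' Sampler configuration
#'
#' Settings for the Monte Carlo generation of kinetic-order sets. The
#' sampling space is the unit hypercube over the free coordinates: one
#' substrate order per flux, one inhibition ratio per product-inhibition
#' or competition pair (when sampled), and the 4CL-inhibition factor.
#' A fraction of the sets is drawn by Latin hypercube sampling for
#' homogeneous coverage; the rest are plain uniform draws.
#'
#' @param n_sets Number of parameter sets.
#' @param lhs_fraction Fraction drawn by Latin hypercube sampling
#'   (default 0.1, i.e. 10,000 out of every 100,000).
#' @param seed Integer seed; two runs with the same configuration are
#'   identical.
#' @param inhibition_ratio_mode `"sampled_per_flux"` (default): each
#'   product-inhibition/competition pair gets its own ratio drawn
#'   uniformly from `ratio_range`; `"fixed"`: every pair uses
#'   `fixed_ratio`.
#' @param fixed_ratio Ratio g_I/g_S used in `"fixed"` mode; must lie in
#'   (-1, 0). The shipped example model uses -0.5 throughout.
#' @param ratio_range Sampling range for ratios in `"sampled_per_flux"`
#'   mode (kept strictly inside (-1, 0)).
#' @param phi_range Range of the per-set 4CL-inhibition factor applied in
#'   scenarios that inhibit 4CL.
#' @param flags Regulation structure: `product_inhibition`,
#'   `ccr_competition`, `fourcl_inhibition`.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_sets = 1000,
                           lhs_fraction = 0.1,
                           seed = 1L,
                           inhibition_ratio_mode = c("sampled_per_flux",
                                                     "fixed"),
                           fixed_ratio = -0.5,
                           ratio_range = c(-0.99, -0.01),
                           phi_range = c(0.1, 0.9),
                           flags = c(product_inhibition = TRUE,
                                     ccr_competition = TRUE,
                                     fourcl_inhibition = TRUE)) {
  inhibition_ratio_mode <- match.arg(inhibition_ratio_mode)
  stopifnot(n_sets >= 1, lhs_fraction >= 0, lhs_fraction <= 1,
            fixed_ratio > -1, fixed_ratio < 0,
            ratio_range[1] > -1, ratio_range[2] < 0,
            ratio_range[1] < ratio_range[2])
  structure(list(n_sets = as.integer(n_sets), lhs_fraction = lhs_fraction,
                 seed = as.integer(seed),
                 inhibition_ratio_mode = inhibition_ratio_mode,
                 fixed_ratio = fixed_ratio, ratio_range = ratio_range,
                 phi_range = phi_range, flags = flags),
            class = "sampler_config")
}

# Active kinetic-order slots for a topology under a regulation structure.
active_slots <- function(topology, flags) {
  slots <- kinetic_order_slots(topology)
  if (!flags[["product_inhibition"]])
    slots$inhibition <- slots$inhibition[0, , drop = FALSE]
  if (!flags[["ccr_competition"]])
    slots$competition <- slots$competition[0, , drop = FALSE]
  slots
}

# For a competition slot (metabolite m competing in flux j), the reference
# substrate order is m's own substrate order: the flux in which m is the
# substrate, catalysed by the same enzyme.
competition_reference <- function(topology, slots) {
  if (nrow(slots$competition) == 0) return(character(0))
  vapply(seq_len(nrow(slots$competition)), function(i) {
    m <- slots$competition$met[i]
    j <- slots$competition$flux[i]
    enz <- topology$fluxes[j, "enzyme"]
    cand <- topology$fluxes$flux[topology$fluxes$substrate == m &
                                   topology$fluxes$enzyme == enz]
    if (length(cand) == 0)                       # fall back to any flux of m
      cand <- topology$fluxes$flux[topology$fluxes$substrate == m]
    cand[1]
  }, "")
}

#' Sample kinetic-order sets for a topology
#'
#' Draws `config$n_sets` kinetic-order maps. Substrate orders are uniform
#' on (0, 1]. Each product-inhibition order is its paired substrate order
#' times a ratio in (-1, 0); each competition order is the competing
#' substrate's own order times a ratio under the same rule. Regulation
#' slots are present only when the corresponding flag is on. The first
#' `round(n_sets * lhs_fraction)` sets come from a Latin hypercube.
#'
#' @param topology A `pathway_topology`.
#' @param config A `sampler_config`.
#' @return A list of class `kinetic_order_sample`: `g` is a list of 16 x
#'   n_flux kinetic-order matrices; `phi` is the vector of 4CL-inhibition
#'   factors (NA when the flag is off); `flags`, `seed` are recorded.
#' @export
sample_kinetic_orders <- function(topology, config = sampler_config()) {
  flags <- config$flags
  slots <- active_slots(topology, flags)
  nf <- nrow(topology$fluxes)
  n_inh <- nrow(slots$inhibition)
  n_cmp <- nrow(slots$competition)
  sampled_ratios <- config$inhibition_ratio_mode == "sampled_per_flux"
  need_phi <- isTRUE(unname(flags[["fourcl_inhibition"]]))
  d <- nf + (if (sampled_ratios) n_inh + n_cmp else 0L) +
    (if (need_phi) 1L else 0L)

  set.seed(config$seed)
  n_lhs <- round(config$n_sets * config$lhs_fraction)
  U <- rbind(
    if (n_lhs > 0) lhs::randomLHS(n_lhs, d),
    if (config$n_sets - n_lhs > 0)
      matrix(stats::runif((config$n_sets - n_lhs) * d),
             ncol = d)
  )

  cmp_ref <- competition_reference(topology, slots)
  met_names <- names(topology$metabolites)
  flux_ids <- topology$fluxes$flux

  g_list <- vector("list", config$n_sets)
  phi <- rep(NA_real_, config$n_sets)
  for (i in seq_len(config$n_sets)) {
    u <- U[i, ]
    gs <- u[seq_len(nf)]                    # substrate orders, U(0,1]
    gs[gs == 0] <- .Machine$double.eps
    col <- nf
    if (sampled_ratios) {
      r_inh <- config$ratio_range[1] +
        u[col + seq_len(n_inh)] * diff(config$ratio_range)
      col <- col + n_inh
      r_cmp <- config$ratio_range[1] +
        u[col + seq_len(n_cmp)] * diff(config$ratio_range)
      col <- col + n_cmp
    } else {
      r_inh <- rep(config$fixed_ratio, n_inh)
      r_cmp <- rep(config$fixed_ratio, n_cmp)
    }
    if (need_phi)
      phi[i] <- config$phi_range[1] + u[col + 1L] * diff(config$phi_range)

    g <- matrix(0, 16, nf, dimnames = list(met_names, flux_ids))
    g[cbind(slots$substrate$met, match(slots$substrate$flux, flux_ids))] <- gs
    if (n_inh > 0) {
      sub_of_flux <- gs[match(slots$inhibition$flux, flux_ids)]
      g[cbind(slots$inhibition$met,
              match(slots$inhibition$flux, flux_ids))] <- r_inh * sub_of_flux
    }
    if (n_cmp > 0) {
      ref_order <- gs[match(cmp_ref, flux_ids)]
      g[cbind(slots$competition$met,
              match(slots$competition$flux, flux_ids))] <- r_cmp * ref_order
    }
    g_list[[i]] <- g
  }
  structure(list(g = g_list, phi = phi, flags = flags,
                 seed = config$seed, topology_config = topology$config_id),
            class = "kinetic_order_sample")
}

#' Compute rate constants from a flux distribution
#'
#' At the normalized wild-type steady state every concentration equals
#' 100, so each steady-state flux is `V_j = alpha_j * 100^{sum_r g_{r,j}}`
#' and the rate constant anchoring the model to a flux distribution is
#' `alpha_j = V_j / 100^{sum_r g_{r,j}}`. By construction the all-100
#' state is then an exact fixed point of the ODE system.
#'
#' @param topology A `pathway_topology`.
#' @param fluxdist A `flux_distribution` with strictly positive fluxes
#'   (zero allowed only for fluxes the topology marks as structurally
#'   zero, e.g. the unsupplied coniferaldehyde branch of Configuration 3).
#' @param g A 16 x n_flux kinetic-order matrix.
#' @return Named rate-constant vector `alpha`.
#' @export
compute_rate_constants <- function(topology, fluxdist, g) {
  V <- fluxdist$V[topology$fluxes$flux]
  bad <- which(V <= 0 & !topology$fluxes$flux %in% topology$zero_ok)
  if (length(bad) > 0)
    stop("non-positive flux for structurally required flux(es): ",
         paste(topology$fluxes$flux[bad], collapse = ", "))
  alpha <- V / 100^colSums(g)
  alpha[V == 0] <- 0
  stats::setNames(alpha, topology$fluxes$flux)
}

#' Build a GMA parameter ensemble
#'
#' Combines sampled kinetic orders with rate constants computed from the
#' flux anchor into a list of complete parameter sets, each having the
#' all-100 state as its wild-type fixed point.
#'
#' @param topology A `pathway_topology`.
#' @param fluxdist A `flux_distribution` (see [solve_wildtype_fluxes()]).
#' @param config A `sampler_config`.
#' @return A list of class `gma_ensemble`: `sets` is a list of
#'   `gma_parameters`; `seed`, `flags` and `config_id` record provenance.
#' @export
build_parameter_ensemble <- function(topology, fluxdist,
                                     config = sampler_config()) {
  ks <- sample_kinetic_orders(topology, config)
  influx <- c(I1 = fluxdist$I1, I2 = fluxdist$I2)
  sets <- lapply(seq_along(ks$g), function(i) {
    alpha <- compute_rate_constants(topology, fluxdist, ks$g[[i]])
    gma_parameters(topology, ks$g[[i]], alpha, flags = config$flags,
                   phi = ks$phi[i], influx = influx)
  })
  structure(list(sets = sets, seed = config$seed, flags = config$flags,
                 config_id = topology$config_id),
            class = "gma_ensemble")
}

#' @export
print.gma_ensemble <- function(x, ...) {
  cat("GMA ensemble: ", length(x$sets), " parameter sets (configuration ",
      x$config_id, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Flatten the nonzero kinetic orders of a parameter set to a vector
#'
#' Used for ensemble persistence and PCA: returns the kinetic orders in a
#' fixed slot order (substrates, then product-inhibition, then
#' competition entries), named `g<met>,<flux>`.
#'
#' @param topology A `pathway_topology`.
#' @param params A `gma_parameters` (or bare kinetic-order matrix).
#' @param flags Regulation flags naming which slots are active.
#' @return Named numeric vector.
#' @export
kinetic_order_vector <- function(topology, params,
                                 flags = c(product_inhibition = TRUE,
                                           ccr_competition = TRUE,
                                           fourcl_inhibition = TRUE)) {
  g <- if (inherits(params, "gma_parameters")) params$g else params
  slots <- active_slots(topology, flags)
  all <- rbind(slots$substrate, slots$inhibition, slots$competition)
  idx <- cbind(all$met, match(all$flux, topology$fluxes$flux))
  stats::setNames(g[idx], paste0("g", all$met, ",", sub("^V", "", all$flux)))
}

#' Persist / restore an ensemble as tabular text
#'
#' One row per parameter set (kinetic-order vector, phi), preceded by a
#' JSON metadata header line (`# {...}`) recording seed, flags and
#' configuration. Values are written in full precision so the round trip
#' is bit-exact.
#'
#' @param ensemble A `gma_ensemble`.
#' @param topology The matching `pathway_topology`.
#' @param path Output path.
#' @return `path` invisibly / a data.frame with attribute `meta`.
#' @export
write_ensemble <- function(ensemble, topology, path) {
  rows <- t(vapply(ensemble$sets, function(p)
    c(kinetic_order_vector(topology, p, ensemble$flags), phi = p$phi),
    numeric(length(kinetic_order_vector(topology, ensemble$sets[[1]],
                                        ensemble$flags)) + 1L)))
  meta <- jsonlite::toJSON(list(seed = ensemble$seed,
                                config_id = ensemble$config_id,
                                flags = as.list(ensemble$flags)),
                           auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  writeLines(paste(c("set", colnames(rows)), collapse = "\t"), con)
  for (i in seq_len(nrow(rows)))
    writeLines(paste(c(i, sprintf("%.17g", rows[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  df <- utils::read.delim(text = lines[-1], check.names = FALSE)
  attr(df, "meta") <- meta
  df
}
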