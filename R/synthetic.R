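#' Generate a ground-truth model instance
#'
#' Builds a fully admissible model instance for recovery experiments: a
#' topology, one sampled kinetic-order set under the full regulation
#' structure, and rate constants anchored to the default flux
#' distribution, so the all-100 state is its wild-type fixed point.
#'
#' Admissibility requires more than the wild-type fixed point: every
#' default knockdown scenario must converge to an in-bounds steady
#' state, or the instance could not be observed. Candidate draws are
#' taken from a deterministic sub-seed sequence until one is admissible
#' (the attempt count is recorded).
#'
#' @param config_id Topology configuration (1, 2 or 3).
#' @param seed Integer seed.
#' @param bounds A `bounds_config` for the flux anchor.
#' @param flags Regulation flags of the truth instance.
#' @param max_attempts Candidate draws before giving up.
#' @param require_signature If `TRUE`, additionally require the
#'   instance's observations to carry the channel's structural
#'   fingerprint — S/G clearly decreased under the CAD knockdown and
#'   clearly increased under the CCR1 knockdown. Structure-recovery
#'   experiments need signature-bearing data: a truth whose fold
#'   changes sit near 1 is compatible with every configuration and
#'   cannot discriminate anything (just as featureless experimental
#'   data could not).
#' @return A list of class `truth_instance` with `topology`, `params`,
#'   `fluxdist`, `seed`, `attempts`.
#' @export
generate_truth_instance <- function(config_id = 1, seed = 1L,
                                    bounds = default_bounds(),
                                    flags = c(product_inhibition = TRUE,
                                              ccr_competition = TRUE,
                                              fourcl_inhibition = TRUE),
                                    max_attempts = 80L,
                                    require_signature = FALSE) {
  topology <- build_topology(config_id)
  fd <- solve_wildtype_fluxes(topology, bounds)
  scenarios <- default_scenarios()
  for (attempt in seq_len(max_attempts)) {
    sub_seed <- (as.integer(seed) + 1000003L * (attempt - 1L)) %%
      2147483647L
    cfg <- sampler_config(n_sets = 1, lhs_fraction = 0, seed = sub_seed,
                          flags = flags)
    ens <- build_parameter_ensemble(topology, fd, cfg)
    recs <- lapply(scenarios, function(sc)
      simulate_scenario(topology, ens$sets[[1]], sc))
    ok <- all(vapply(recs, function(r) r$status == "converged", TRUE))
    if (ok && require_signature) {
      ok <- recs[["CAD"]]$folds[["SG"]] < 0.98 &&
        recs[["CCR1"]]$folds[["SG"]] > 1.02
    }
    if (ok) {
      return(structure(list(topology = topology, params = ens$sets[[1]],
                            fluxdist = fd, seed = as.integer(seed),
                            attempts = attempt),
                       class = "truth_instance"))
    }
  }
  stop("no admissible truth instance found in ", max_attempts,
       " attempts; try another seed")
}

#' Simulate noisy fold-change observations from a truth instance
#'
#' Simulates the truth instance under each scenario and emits an
#' observation table in the same layout as the transgenic fold-change
#' data: per scenario, fold changes for H, G, S, total, the S/G
#' direction, and the two COMT marker metabolites (ferulic acid Z9 and
#' coniferaldehyde Z11). Multiplicative lognormal noise with standard
#' deviation `noise_sigma` (on the log scale) is applied to every fold
#' change; fold-change data are strictly positive, so this is the
#' natural error model. Directions are taken from the noisy folds so the
#' table stays internally consistent.
#'
#' @param instance A `truth_instance`.
#' @param scenarios Scenarios to observe (default [default_scenarios()]
#'   without the wild type).
#' @param noise_sigma Lognormal sigma (0 gives exact fold changes).
#' @param seed Integer seed for the noise.
#' @param control Solver control.
#' @return A data.frame of class `synthetic_observations` with columns
#'   `scenario`, `H`, `G`, `S`, `total`, `SG_fold`, `sg_direction`,
#'   `Z9`, `Z11` (metabolite columns only for scenarios with 4CL
#'   inhibition).
#' @export
generate_observations <- function(instance, scenarios = NULL,
                                  noise_sigma = 0.05, seed = 1L,
                                  control = ss_control()) {
  stopifnot(noise_sigma >= 0)
  if (is.null(scenarios)) {
    scenarios <- default_scenarios()
    scenarios <- scenarios[names(scenarios) != "wildtype"]
  }
  set.seed(as.integer(seed))
  rows <- lapply(scenarios, function(sc) {
    rec <- simulate_scenario(instance$topology, instance$params, sc,
                             control)
    if (rec$status != "converged")
      stop("truth instance failed to converge under scenario ", sc$name)
    noise <- function(x) x * exp(stats::rnorm(length(x), 0, noise_sigma))
    f <- noise(rec$folds[c("H", "G", "S", "total")])
    sgf <- noise(rec$folds[["SG"]])
    met <- if (isTRUE(sc$fourcl_inhibition))
      noise(rec$met_fold[c("Z9", "Z11")]) else c(Z9 = NA_real_,
                                                 Z11 = NA_real_)
    data.frame(scenario = sc$name, H = f[["H"]], G = f[["G"]],
               S = f[["S"]], total = f[["total"]], SG_fold = sgf,
               sg_direction = if (sgf > 1) "increase" else "decrease",
               Z9 = met[["Z9"]], Z11 = met[["Z11"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("synthetic_observations", class(out))
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Convert an observation table into screening criteria
#'
#' Synthetic observation tables and the published fold-change table are
#' interchangeable: both become interval criteria via a relative
#' tolerance on point values, with S/G matched by direction.
#'
#' @param observations A `synthetic_observations` data.frame.
#' @param rel_tol Relative tolerance applied to each fold change.
#' @return A `screening_criteria`.
#' @export
criteria_from_observations <- function(observations, rel_tol = 0.2) {
  stopifnot(rel_tol > 0)
  pt <- function(v) c(v * (1 - rel_tol), v * (1 + rel_tol))
  crit <- lapply(seq_len(nrow(observations)), function(i) {
    row <- observations[i, ]
    cr <- list(H = pt(row$H), G = pt(row$G), S = pt(row$S),
               total = pt(row$total), sg_direction = row$sg_direction)
    if (!is.na(row$Z9))
      cr$metabolites <- list(Z9 = pt(row$Z9), Z11 = pt(row$Z11))
    cr
  })
  names(crit) <- observations$scenario
  structure(crit, class = "screening_criteria", rel_tol = rel_tol)
}

#' Write / read a synthetic observation table
#'
#' @param observations A `synthetic_observations` data.frame.
#' @param path Tab-separated output path.
#' @return `path` invisibly / the restored data.frame.
#' @export
write_observations <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("synthetic_observations", class(out))
  out
}
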