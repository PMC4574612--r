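#' Reconstruct a kinetic-order matrix from a flat kinetic-order vector
#'
#' Inverse of [kinetic_order_vector()]: places the entries of a flat
#' vector (substrates, inhibition, competition, in slot order) back into
#' a 16 x n_flux matrix.
#'
#' @param topology A `pathway_topology`.
#' @param gvec Flat kinetic-order vector.
#' @param flags Regulation flags the vector was built under.
#' @return A 16 x n_flux kinetic-order matrix.
#' @export
kinetic_order_matrix <- function(topology, gvec,
                                 flags = c(product_inhibition = TRUE,
                                           ccr_competition = TRUE,
                                           fourcl_inhibition = TRUE)) {
  slots <- active_slots(topology, flags)
  all <- rbind(slots$substrate, slots$inhibition, slots$competition)
  if (length(gvec) != nrow(all))
    stop("kinetic-order vector has length ", length(gvec),
         ", expected ", nrow(all))
  g <- matrix(0, 16, nrow(topology$fluxes),
              dimnames = list(names(topology$metabolites),
                              topology$fluxes$flux))
  g[cbind(all$met, match(all$flux, topology$fluxes$flux))] <- gvec
  g
}

#' Build a multi-enzyme activity vector
#'
#' Default profile for a transcription-factor-like global reduction of
#' the pathway: every named catalytic enzyme (PAL, C4H, 4CL, CCR1, CAD,
#' HCT/C3'H/CSE, COMT, CCoAOMT, F5H) is reduced to `level`; formal efflux
#' activities stay at 1; the channel activity follows the coupling rule.
#' Any user-supplied activities override the defaults.
#'
#' @param level Relative activity of the catalytic enzymes.
#' @param overrides Optional named activities (by enzyme symbol or Z id).
#' @return Named multiplier vector suitable for [run_perturbation()].
#' @export
global_reduction <- function(level = 0.4, overrides = NULL) {
  catalytic <- c("PAL", "C4H", "4CL", "CCR1", "CAD", "HCT/C3pH/CSE",
                 "COMT", "CCoAOMT", "F5H")
  act <- stats::setNames(rep(level, length(catalytic)), catalytic)
  for (nm in names(overrides)) act[nm] <- overrides[[nm]]
  act
}

#' Run a multi-enzyme perturbation
#'
#' Simulates the pathway under an arbitrary enzyme-activity vector (e.g.
#' a PvMYB4-like global reduction) and reports lignin fold changes and
#' the normalized steady-state metabolite profile (wild type = 100).
#'
#' @param topology A `pathway_topology`.
#' @param params A `gma_parameters` from the accepted ensemble.
#' @param activities Named multipliers (enzyme symbol or Z id); missing
#'   enzymes default to 1. The channel activity is derived by the
#'   coupling rule unless set explicitly.
#' @param control Solver control.
#' @return A list of class `perturbation_report`: `status`, `folds`
#'   (H, G, S, total, SG fold changes), `profile` (16 steady-state
#'   values, wild type = 100), `activities`.
#' @export
run_perturbation <- function(topology, params, activities = NULL,
                             control = ss_control()) {
  scenario <- structure(list(name = "perturbation",
                             multipliers = activities,
                             fourcl_inhibition = FALSE),
                        class = "knockdown_scenario")
  rec <- simulate_scenario(topology, params, scenario, control)
  profile <- if (rec$status == "converged") rec$met_fold * 100 else NULL
  structure(list(status = rec$status, folds = rec$folds,
                 profile = profile,
                 activities = enzyme_profile(topology, activities)),
            class = "perturbation_report")
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat("Perturbation report (", x$status, ")\n", sep = "")
  if (!is.null(x$folds)) {
    cat("  fold changes: ",
        paste(sprintf("%s=%.3f", names(x$folds), x$folds),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Simulate combinatorial knockdowns
#'
#' Applies several single-knockdown scenarios simultaneously (activity
#' multipliers are combined multiplicatively per enzyme) and reports the
#' same schema as [run_perturbation()]. An empty scenario list gives the
#' wild-type report.
#'
#' @param topology A `pathway_topology`.
#' @param params A `gma_parameters`.
#' @param scenarios List of `knockdown_scenario`s to combine.
#' @param control Solver control.
#' @return A `perturbation_report`.
#' @export
combinatorial_knockdown <- function(topology, params, scenarios = list(),
                                    control = ss_control()) {
  mult <- list()
  fourcl <- FALSE
  for (s in scenarios) {
    for (nm in names(s$multipliers)) {
      mult[[nm]] <- (if (is.null(mult[[nm]])) 1 else mult[[nm]]) *
        s$multipliers[[nm]]
    }
    fourcl <- fourcl || isTRUE(s$fourcl_inhibition)
  }
  scenario <- structure(list(name = "combinatorial",
                             multipliers = unlist(mult),
                             fourcl_inhibition = fourcl),
                        class = "knockdown_scenario")
  rec <- simulate_scenario(topology, params, scenario, control)
  profile <- if (rec$status == "converged") rec$met_fold * 100 else NULL
  act <- enzyme_profile(topology, unlist(mult))
  if (fourcl && isTRUE(unname(params$flags[["fourcl_inhibition"]])) &&
      !is.na(params$phi))
    act[["Z20"]] <- act[["Z20"]] * params$phi
  structure(list(status = rec$status, folds = rec$folds,
                 profile = profile, activities = act),
            class = "perturbation_report")
}

#' Write a perturbation report as labeled tabular text
#'
#' Two blocks: lignin fold changes, then the metabolite steady-state
#' profile (wild type = 100).
#'
#' @param report A `perturbation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_perturbation_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# lignin fold changes (wild type = 1)", con)
  writeLines(paste(names(report$folds), sprintf("%.6g", report$folds),
                   sep = "\t"), con)
  if (!is.null(report$profile)) {
    writeLines("# steady-state metabolite profile (wild type = 100)", con)
    writeLines(paste(names(report$profile),
                     sprintf("%.6g", report$profile), sep = "\t"), con)
  }
  invisible(path)
}
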