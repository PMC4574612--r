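#' Default knockdown scenarios
#'
#' The transgenic lines used for screening, as enzyme-activity
#' multipliers relative to wild type: 4CL down-regulated by 40 %
#' (activity 0.6), CCR1 by 50 % (0.5), COMT by 30 % (0.7, with the
#' inferred 4CL inhibition enabled), CAD by 30 % (0.7). When CCR1 or CAD
#' is reduced, the channel complex activity `Z34` is co-reduced by the
#' topology's coupling rule.
#'
#' @return Named list of `knockdown_scenario` objects (including the
#'   wild type).
#' @export
default_scenarios <- function() {
  sc <- list(
    wildtype = list(name = "wildtype", multipliers = NULL,
                    fourcl_inhibition = FALSE),
    `4CL`  = list(name = "4CL",  multipliers = c(`4CL` = 0.6),
                  fourcl_inhibition = FALSE),
    CCR1   = list(name = "CCR1", multipliers = c(CCR1 = 0.5),
                  fourcl_inhibition = FALSE),
    COMT   = list(name = "COMT", multipliers = c(COMT = 0.7),
                  fourcl_inhibition = TRUE),
    CAD    = list(name = "CAD",  multipliers = c(CAD = 0.7),
                  fourcl_inhibition = FALSE)
  )
  lapply(sc, function(s) structure(s, class = "knockdown_scenario"))
}

#' Default screening criteria: the experimental match conditions
#'
#' Encodes the four match conditions the screening is built on,
#' quantitatively where the data are quantitative and directionally
#' elsewhere:
#'
#' * 4CL knockdown: the H-lignin fold change must reach the reported
#'   accumulation (1.82, within `rel_tol`); G and total lignin must
#'   decrease; S/G must increase.
#' * CCR1 knockdown: total lignin must decrease; S/G must increase.
#' * COMT knockdown: the metabolite signature must match (ferulic acid
#'   +30 %, coniferaldehyde -20 %, each within `rel_tol`); total lignin
#'   and S/G must decrease.
#' * CAD knockdown: total lignin must decrease; S/G must decrease.
#'
#' Directions are strict inequalities against 1. The published
#' fold-change table can be enforced entry-by-entry instead with
#' [table_criteria()]; see the package vignette for why full interval
#' containment is not satisfiable at a true steady state (with constant
#' influxes, total efflux is conserved, so the printed 15-25 % total
#' lignin reductions under downstream knockdowns are out of reach of
#' any parameter set of this model class).
#'
#' @param rel_tol Relative tolerance applied to the quantitative
#'   targets.
#' @return A list of class `screening_criteria`; one element per
#'   scenario. Each quantity is either an `[lo, hi]` interval or a
#'   direction string (`"increase"`/`"decrease"`), plus an
#'   `sg_direction` and optional `metabolites` intervals.
#' @export
default_criteria <- function(rel_tol = 0.2) {
  stopifnot(rel_tol > 0)
  pt <- function(v) c(v * (1 - rel_tol), v * (1 + rel_tol))
  structure(list(
    `4CL` = list(H = pt(1.82), G = "decrease", total = "decrease",
                 sg_direction = "increase"),
    CCR1 = list(total = "decrease", sg_direction = "increase"),
    COMT = list(total = "decrease", sg_direction = "decrease",
                metabolites = list(Z9 = pt(1.30), Z11 = pt(0.80))),
    CAD  = list(total = "decrease", sg_direction = "decrease")
  ), class = "screening_criteria", rel_tol = rel_tol)
}

#' Entry-by-entry criteria from the published fold-change table
#'
#' The strict reading of the transgenic fold-change table: every
#' printed point value (H 1.82, G 0.53, S 1.00, total 0.78 for 4CL;
#' ~0.75 for CCR1) matched within `rel_tol`, printed ranges (COMT and
#' CAD columns) by containment, S/G by direction, and the COMT
#' metabolite signature within `rel_tol`. Provided for completeness and
#' sensitivity analyses; see [default_criteria()] for why this reading
#' admits (almost) no steady-state parameter sets.
#'
#' @inheritParams default_criteria
#' @return A `screening_criteria`.
#' @export
table_criteria <- function(rel_tol = 0.2) {
  stopifnot(rel_tol > 0)
  pt <- function(v) c(v * (1 - rel_tol), v * (1 + rel_tol))
  structure(list(
    `4CL` = list(H = pt(1.82), G = pt(0.53), S = pt(1.00),
                 total = pt(0.78), sg_direction = "increase"),
    CCR1 = list(G = pt(0.75), S = pt(0.75), total = pt(0.75),
                sg_direction = "increase"),
    COMT = list(G = c(0.76, 0.98), S = c(0.42, 0.96),
                total = c(0.84, 0.96), sg_direction = "decrease",
                metabolites = list(Z9 = pt(1.30), Z11 = pt(0.80))),
    CAD  = list(G = c(0.67, 0.83), S = c(0.58, 0.87),
                total = c(0.78, 0.86), sg_direction = "decrease")
  ), class = "screening_criteria", rel_tol = rel_tol)
}

#' Simulate one knockdown scenario for one parameter set
#'
#' Applies the scenario's enzyme multipliers (deriving the channel
#' activity by the coupling rule, and scaling 4CL by the parameter set's
#' inhibition factor `phi` when the scenario calls for 4CL inhibition),
#' integrates to steady state from the wild-type state, and reports fold
#' changes of the lignin readouts and of all 16 metabolites relative to
#' wild type.
#'
#' @param topology A `pathway_topology`.
#' @param params A `gma_parameters` from an anchored ensemble.
#' @param scenario A `knockdown_scenario` (see [default_scenarios()]).
#' @param control Solver control, see [ss_control()].
#' @return A list of class `scenario_record`: `scenario`, `status`
#'   (`"converged"` or a failure flag), `folds` (H, G, S, total, SG),
#'   `met_fold` (16 metabolite fold changes, wild type = 1).
#' @export
simulate_scenario <- function(topology, params, scenario,
                              control = ss_control()) {
  act <- enzyme_profile(topology, scenario$multipliers)
  if (isTRUE(scenario$fourcl_inhibition) &&
      isTRUE(unname(params$flags[["fourcl_inhibition"]])) &&
      !is.na(params$phi)) {
    act[["Z20"]] <- act[["Z20"]] * params$phi
  }

  wt_v <- params$alpha * 100^colSums(params$g)   # wild-type fluxes, exact
  names(wt_v) <- topology$fluxes$flux
  wt <- c(H = wt_v[["V7"]], G = wt_v[["V17"]], S = wt_v[["V25"]])
  wt["total"] <- sum(wt)

  if (all(act == 1)) {                           # identity scenario
    return(structure(list(
      scenario = scenario$name, status = "converged",
      folds = c(H = 1, G = 1, S = 1, total = 1, SG = 1),
      met_fold = stats::setNames(rep(1, 16), names(topology$metabolites))
    ), class = "scenario_record"))
  }

  ss <- simulate_steady_state(topology, params, enzymes = act,
                              control = control)
  if (ss$status != "converged") {
    return(structure(list(scenario = scenario$name, status = ss$status,
                          folds = NULL, met_fold = NULL),
                     class = "scenario_record"))
  }
  v <- evaluate_fluxes(topology, params, ss$state, act)
  kd <- c(H = v[["V7"]], G = v[["V17"]], S = v[["V25"]])
  kd["total"] <- sum(kd)
  folds <- kd / wt
  folds["SG"] <- (kd[["S"]] / kd[["G"]]) / (wt[["S"]] / wt[["G"]])
  structure(list(scenario = scenario$name, status = "converged",
                 folds = folds, met_fold = ss$state / 100),
            class = "scenario_record")
}

# Check one scenario record against its criteria block; NULL if it
# passes, otherwise a reason code naming the first failed criterion.
check_scenario_record <- function(record, crit, scname) {
  if (is.null(record) || record$status != "converged")
    return(paste0(scname, ":inadmissible(",
                  if (is.null(record)) "missing" else record$status, ")"))
  for (q in c("H", "G", "S", "total")) {
    if (!is.null(crit[[q]])) {
      v <- record$folds[[q]]
      cq <- crit[[q]]
      ok <- if (is.character(cq)) {
        switch(cq, increase = v > 1, decrease = v < 1, TRUE)
      } else {
        v >= cq[1] && v <= cq[2]
      }
      if (!ok) return(paste0(scname, ":", q, "_fold"))
    }
  }
  if (!is.null(crit$sg_direction)) {
    sg <- record$folds[["SG"]]
    ok <- switch(crit$sg_direction,
                 increase = sg > 1, decrease = sg < 1, TRUE)
    if (!ok) return(paste0(scname, ":SG_direction"))
  }
  for (m in names(crit$metabolites)) {
    v <- record$met_fold[[m]]
    if (v < crit$metabolites[[m]][1] || v > crit$metabolites[[m]][2])
      return(paste0(scname, ":", m))
  }
  NULL
}

#' Evaluate a complete scenario record set against screening criteria
#'
#' @param records Named list of `scenario_record`s covering every
#'   scenario named in `criteria`.
#' @param criteria A `screening_criteria`.
#' @return A list with `pass` (logical) and `reasons` (character vector
#'   of reason codes, one per failed scenario; empty when passing).
#' @export
evaluate_criteria <- function(records, criteria) {
  reasons <- character(0)
  for (scname in names(criteria)) {
    r <- check_scenario_record(records[[scname]], criteria[[scname]],
                               scname)
    if (!is.null(r)) reasons <- c(reasons, r)
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Screen a parameter ensemble against the knockdown data
#'
#' Runs the full pipeline stage for one or more topology configurations
#' and regulation variants: solve the flux anchor, sample kinetic orders,
#' anchor rate constants, simulate every knockdown scenario, and accept
#' the parameter sets whose simulated fold changes satisfy all criteria.
#' Individual simulation failures are recorded as reason codes and never
#' abort the sweep. Deterministic under the master seed (each
#' configuration/variant cell receives a deterministically derived
#' sub-seed).
#'
#' @param configs Configuration ids to screen (subset of 1:3).
#' @param variants Named list of regulation-flag vectors; default is the
#'   full regulation structure.
#' @param config A `sampler_config`; its `flags` are overridden per
#'   variant and its `seed` acts as the master seed.
#' @param criteria A `screening_criteria`.
#' @param bounds A `bounds_config` for the flux anchor.
#' @param control Solver control.
#' @param lazy If `TRUE` (default), scenarios are simulated in criteria
#'   order and a set is abandoned at its first failed criterion;
#'   unevaluated fold changes are `NA`. Acceptance is a pure per-set
#'   predicate, so this does not change which sets are accepted.
#' @param phi_grid For scenarios with 4CL inhibition, the inhibition
#'   strength is a nuisance parameter of the scenario (no measured value
#'   exists), so a set matches if *some* admissible strength reproduces
#'   the data: the set's own sampled `phi` is tried first, then this
#'   deterministic grid. Set to `NULL` to require the sampled `phi`
#'   itself to match.
#' @return A list of class `screening_result`: `counts` (per cell:
#'   sampled, admissible, accepted), `details` (per-set pass/fail,
#'   reason, fold changes), `accepted` (list of accepted sets with their
#'   kinetic-order vectors, `phi`, records and provenance), and
#'   `fluxdist` per configuration.
#' @export
screen_ensemble <- function(configs = 1:3,
                            variants = list(full = c(
                              product_inhibition = TRUE,
                              ccr_competition = TRUE,
                              fourcl_inhibition = TRUE)),
                            config = sampler_config(),
                            criteria = default_criteria(),
                            bounds = default_bounds(),
                            control = ss_control(),
                            lazy = TRUE,
                            phi_grid = seq(0.15, 0.9, by = 0.15)) {
  scen <- default_scenarios()
  scen_order <- intersect(c("4CL", "CCR1", "COMT", "CAD"), names(criteria))
  counts <- NULL
  details <- list()
  accepted <- list()
  fluxdists <- list()

  for (cfg in configs) {
    topology <- build_topology(cfg)
    fd <- solve_wildtype_fluxes(topology, bounds)
    fluxdists[[as.character(cfg)]] <- fd
    for (vi in seq_along(variants)) {
      vname <- names(variants)[vi]
      vflags <- variants[[vi]]
      sub_seed <- (config$seed + 7919L * cfg + 104729L * vi) %% 2147483647L
      scfg <- config
      scfg$flags <- vflags
      scfg$seed <- as.integer(sub_seed)
      ens <- build_parameter_ensemble(topology, fd, scfg)

      n <- length(ens$sets)
      pass <- logical(n)
      adm <- logical(n)
      reason <- character(n)
      foldcols <- c(outer(c("H", "G", "S", "total", "SG"), scen_order,
                          function(q, s) paste0(s, "_", q)))
      fm <- matrix(NA_real_, n, length(foldcols),
                   dimnames = list(NULL, foldcols))
      z9 <- rep(NA_real_, n); z11 <- rep(NA_real_, n)

      for (i in seq_len(n)) {
        p <- ens$sets[[i]]
        records <- list()
        fail <- NULL
        ok_adm <- TRUE
        for (scname in scen_order) {
          needs_phi <- isTRUE(scen[[scname]]$fourcl_inhibition) &&
            isTRUE(unname(vflags[["fourcl_inhibition"]])) &&
            !is.null(phi_grid)
          phis <- if (needs_phi) unique(c(p$phi, phi_grid)) else NA
          rec <- NULL
          for (phv in phis) {
            pp <- p
            if (needs_phi) pp$phi <- phv
            cand <- simulate_scenario(topology, pp, scen[[scname]],
                                      control)
            if (is.null(rec)) rec <- cand     # sampled phi is reported
            if (is.null(check_scenario_record(cand, criteria[[scname]],
                                              scname))) {
              rec <- cand
              if (needs_phi) p$phi_used <- phv
              break
            }
          }
          records[[scname]] <- rec
          if (rec$status == "converged") {
            fm[i, paste0(scname, "_", names(rec$folds))] <- rec$folds
            if (scname == "COMT") {
              z9[i] <- rec$met_fold[["Z9"]]
              z11[i] <- rec$met_fold[["Z11"]]
            }
          } else {
            ok_adm <- FALSE
          }
          r <- check_scenario_record(rec, criteria[[scname]], scname)
          if (!is.null(r)) {
            fail <- c(fail, r)
            if (lazy) break
          }
        }
        adm[i] <- ok_adm
        pass[i] <- is.null(fail)
        reason[i] <- if (is.null(fail)) "" else fail[1]
        if (pass[i]) {
          accepted[[length(accepted) + 1L]] <- list(
            config = cfg, variant = vname, index = i, params = p,
            g_vector = kinetic_order_vector(topology, p, vflags),
            phi = p$phi,
            phi_used = if (is.null(p$phi_used)) p$phi else p$phi_used,
            records = records)
        }
      }
      counts <- rbind(counts, data.frame(
        config = cfg, variant = vname, sampled = n,
        admissible = sum(adm), accepted = sum(pass),
        stringsAsFactors = FALSE))
      details[[paste(cfg, vname, sep = "/")]] <- data.frame(
        config = cfg, variant = vname, set = seq_len(n),
        pass = pass, reason = reason, fm,
        COMT_Z9 = z9, COMT_Z11 = z11,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  structure(list(counts = counts,
                 details = do.call(rbind, c(details, make.row.names = FALSE)),
                 accepted = accepted,
                 fluxdist = fluxdists,
                 seed = config$seed),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Ensemble screening (master seed ", x$seed, "):\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Median fold changes over the accepted sets of a screening result
#'
#' @param result A `screening_result`.
#' @param config Restrict to one configuration (default: all).
#' @param variant Restrict to one variant name (default: all).
#' @return Named list with median fold changes per scenario/quantity and
#'   COMT metabolite fold changes, over accepted sets.
#' @export
accepted_fold_summary <- function(result, config = NULL, variant = NULL) {
  d <- result$details[result$details$pass, , drop = FALSE]
  if (!is.null(config)) d <- d[d$config %in% config, , drop = FALSE]
  if (!is.null(variant)) d <- d[d$variant %in% variant, , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  num <- vapply(d, is.numeric, TRUE) & !names(d) %in% c("config", "set")
  as.list(vapply(d[num], stats::median, 0, na.rm = TRUE))
}
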