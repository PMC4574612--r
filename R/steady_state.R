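#' Solver control settings for steady-state integration
#'
#' @param rtol,atol Relative/absolute integration tolerances. Power laws
#'   with fractional exponents are mildly stiff near zero, so an implicit
#'   stiff-capable method (`lsoda`) is used throughout.
#' @param ss_tol Steady state declared when `max |dZ/dt|` falls below this
#'   value on the normalized (wild type = 100) scale.
#' @param tmax Integration horizon; failure to reach `ss_tol` by `tmax`
#'   is reported as non-convergence.
#' @param floor Concentration floor applied inside the right-hand side so
#'   negative exponents stay defined.
#' @param diverge_at States exceeding this value trigger a divergence flag.
#' @param state_bounds Admissible range for converged steady states on the
#'   normalized scale; convergence to a state outside it is reported
#'   distinctly (out of bounds, not non-convergence).
#' @return A list of control settings.
#' @export
ss_control <- function(rtol = 1e-8, atol = 1e-8, ss_tol = 1e-6,
                       tmax = 1e5, floor = 1e-9, diverge_at = 1e7,
                       state_bounds = c(1, 1e4)) {
  list(rtol = rtol, atol = atol, ss_tol = ss_tol, tmax = tmax,
       floor = floor, diverge_at = diverge_at, state_bounds = state_bounds)
}

#' Integrate the pathway model to steady state
#'
#' Integrates `dZ/dt = S V(Z) + I` with a stiff-capable solver, stopping
#' as soon as `max |dZ/dt|` drops below `control$ss_tol` (root finding) or
#' any state exceeds the divergence guard. Convergence to a state outside
#' the admissible bounds is distinguished from both proper convergence and
#' non-convergence.
#'
#' @inheritParams gma_rhs
#' @param init Strictly positive initial state (default all-100, the
#'   normalized wild-type steady state).
#' @param control See [ss_control()].
#' @return A list with `state` (final state), `status` (one of
#'   `"converged"`, `"out_of_bounds"`, `"nonconverged"`, `"diverged"`,
#'   `"error"`), `residual` (final `max |dZ/dt|`), and `time`.
#' @export
simulate_steady_state <- function(topology, params,
                                  enzymes = wildtype_enzymes(),
                                  influx = params$influx,
                                  init = rep(100, 16),
                                  control = ss_control()) {
  if (any(init <= 0)) stop("initial state must be strictly positive")
  eact <- enzymes[paste0("Z", topology$fluxes$enzyme)]
  aeff <- params$alpha * eact          # enzyme factor folded into rates
  S <- topology$stoich
  gT <- t(params$g)
  itar <- topology$influx_targets
  ivec <- numeric(16)
  ivec[itar[["I1"]]] <- influx[["I1"]]
  ivec[itar[["I2"]]] <- ivec[itar[["I2"]]] + influx[["I2"]]
  floor <- control$floor

  deriv <- function(t, z, p) {
    z <- pmax(z, floor)
    v <- aeff * exp(drop(gT %*% log(z)))
    list(drop(S %*% v) + ivec)
  }
  rootfn <- function(t, z, p) {
    dz <- deriv(t, z, p)[[1]]
    c(max(abs(dz)) - control$ss_tol, control$diverge_at - max(z))
  }

  d0 <- deriv(0, init, NULL)[[1]]
  if (max(abs(d0)) < control$ss_tol) {
    return(finish_ss(init, 0, max(abs(d0)), control))
  }

  # Newton polish in log space with the analytic Jacobian
  # dV_j/dZ_r = V_j g_{r,j} / Z_r; accepted only if it stays near the
  # integrated trajectory (the attractor being approached), so slow final
  # relaxation is short-circuited without jumping to a foreign root.
  newton <- function(z0) {
    z <- pmax(z0, floor)
    for (it in 1:40) {
      v <- aeff * exp(drop(gT %*% log(z)))
      f <- drop(S %*% v) + ivec
      if (max(abs(f)) < control$ss_tol * 0.1) break
      J <- S %*% (v * gT)                   # d(dZ/dt)/d(log Z)
      step <- try(solve(J, -f), silent = TRUE)
      if (inherits(step, "try-error")) return(NULL)
      step <- pmin(pmax(step, -1), 1)       # damp to one log unit
      z <- z * exp(step)
      if (any(!is.finite(z)) || any(z <= 0)) return(NULL)
    }
    v <- aeff * exp(drop(gT %*% log(z)))
    f <- drop(S %*% v) + ivec
    if (max(abs(f)) >= control$ss_tol) return(NULL)
    if (any(z / z0 > 3) || any(z0 / z > 3)) return(NULL)  # foreign root
    list(z = z, resid = max(abs(f)))
  }

  z <- init
  tnow <- 0
  for (tend in unique(pmin(c(2e3, 2e4, control$tmax), control$tmax))) {
    out <- try(suppressWarnings(
      deSolve::lsodar(y = z, times = c(tnow, tend),
                      func = deriv, parms = NULL,
                      rootfunc = rootfn,
                      rtol = control$rtol, atol = control$atol,
                      maxsteps = 20000)), silent = TRUE)
    if (inherits(out, "try-error")) {
      return(list(state = rep(NA_real_, 16), status = "error",
                  residual = NA_real_, time = NA_real_))
    }
    zf <- as.numeric(out[nrow(out), -1])
    tf <- out[nrow(out), 1]
    if (any(!is.finite(zf)) || max(zf) >= control$diverge_at) {
      return(list(state = zf, status = "diverged",
                  residual = NA_real_, time = tf))
    }
    resid <- max(abs(deriv(tf, zf, NULL)[[1]]))
    if (resid <= control$ss_tol * 1.01) {  # root fires at resid == tol
      return(finish_ss(zf, tf, resid, control))
    }
    pol <- newton(zf)
    if (!is.null(pol)) {
      return(finish_ss(pol$z, tf, pol$resid, control))
    }
    z <- pmax(zf, floor)
    tnow <- tf
    if (tf < tend - 1e-9) {                # integrator gave up early
      return(list(state = zf, status = "nonconverged",
                  residual = resid, time = tf))
    }

  }
  list(state = z, status = "nonconverged",
       residual = max(abs(deriv(tnow, z, NULL)[[1]])), time = tnow)
}

finish_ss <- function(z, t, resid, control) {
  status <- if (any(z < control$state_bounds[1]) ||
                any(z > control$state_bounds[2])) "out_of_bounds"
            else "converged"
  names(z) <- names(pathway_metabolites())
  list(state = z, status = status, residual = resid, time = t)
}

#' Lignin production readout at a steady state
#'
#' Lignin production is read out as the steady-state value of the three
#' terminal monolignol fluxes: `V7` (H, from p-coumaryl alcohol), `V17`
#' (G, from coniferyl alcohol) and `V25` (S, from sinapyl alcohol). The
#' minor 5-OH-coniferyl alcohol efflux (`V21`) is not counted in totals.
#'
#' @inheritParams evaluate_fluxes
#' @param ss_state A converged steady state.
#' @return A list of class `lignin_readout` with `H`, `G`, `S`, `total`
#'   and `SG_ratio` (`NA` with a warning when `G` is zero).
#' @export
lignin_readout <- function(topology, params, ss_state,
                           enzymes = wildtype_enzymes()) {
  v <- evaluate_fluxes(topology, params, ss_state, enzymes)
  H <- v[["V7"]]
  G <- v[["V17"]]
  S <- v[["V25"]]
  sg <- if (G > 0) S / G else {
    warning("G-lignin flux is zero; S/G undefined")
    NA_real_
  }
  structure(list(H = H, G = G, S = S, total = H + G + S, SG_ratio = sg),
            class = "lignin_readout")
}

#' @export
print.lignin_readout <- function(x, ...) {
  cat(sprintf("Lignin readout: H=%.4g G=%.4g S=%.4g total=%.4g S/G=%.4g\n",
              x$H, x$G, x$S, x$total, x$SG_ratio))
  invisible(x)
}
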