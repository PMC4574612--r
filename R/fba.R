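#' Default bounds and composition constraints for the flux balance stage
#'
#' The linear program maximizes total lignin production (`V7 + V17 + V25`)
#' subject to steady-state mass balance. The bounds normalize the main
#' influx to 1 and keep every pathway route active:
#'
#' * `I1` (phenylalanine supply) is fixed at `i1`.
#' * `I2` (direct p-coumaric acid supply, e.g. from tyrosine) is free in
#'   `i2_range`.
#' * The non-lignin effluxes (`V2`, `V8`, `V10`, `V18`, `V21`) carry at
#'   least their configured lower bound (small positive values on the
#'   scale of the shipped example model's implied flux distribution, so no
#'   rate constant degenerates to zero) and at most `efflux_cap` of the
#'   total influx.
#' * H-lignin is pinned to `h_share` of total lignin (H monomers are a
#'   small fraction of switchgrass lignin, about 3 %).
#' * The wild-type S/G flux ratio is constrained to `sg_range`.
#'
#' @param i1 Fixed phenylalanine influx (scale of the system).
#' @param i2_range Bounds for the secondary influx.
#' @param efflux_lb Named lower bounds for the non-lignin effluxes.
#' @param efflux_cap Cap on each non-lignin efflux, as a fraction of
#'   `I1 + I2`.
#' @param h_share Fraction of total lignin flux through the H branch.
#' @param sg_range Admissible wild-type S/G flux ratio window.
#' @return A list of class `bounds_config`.
#' @export
default_bounds <- function(i1 = 1,
                           i2_range = c(0, 0.1),
                           efflux_lb = c(V2 = 0.155, V8 = 0.082,
                                         V10 = 0.046, V18 = 0.050,
                                         V21 = 0.010),
                           efflux_cap = 0.3,
                           h_share = 0.03,
                           sg_range = c(0.5, 1.0)) {
  structure(list(i1 = i1, i2_range = i2_range, efflux_lb = efflux_lb,
                 efflux_cap = efflux_cap, h_share = h_share,
                 sg_range = sg_range),
            class = "bounds_config")
}

#' Solve the wild-type flux distribution by linear programming
#'
#' Finds a steady-state flux distribution maximizing total lignin
#' production under the mass-balance equalities of the topology and the
#' bounds in `bounds`. Degenerate alternate optima (e.g. the split between
#' the free route and the channel, or the S/G split inside its window) are
#' tie-broken by minimizing the Euclidean norm of the flux vector among
#' optima, giving a deterministic, reproducible anchor.
#'
#' @param topology A `pathway_topology`.
#' @param bounds A `bounds_config` (see [default_bounds()]).
#' @return A list of class `flux_distribution` with `V` (named flux
#'   vector), `I1`, `I2`, `objective` (total lignin flux) and `residual`
#'   (largest mass-balance violation).
#' @export
solve_wildtype_fluxes <- function(topology, bounds = default_bounds()) {
  S <- topology$stoich
  # structurally dead fluxes (unsupplied branches) make the simplex
  # degenerate; solve without them and reassemble zeros afterwards
  live <- !colnames(S) %in% topology$zero_ok
  S <- S[, live, drop = FALSE]
  dead_rows <- rowSums(S != 0) == 0 &
    !seq_len(16) %in% topology$influx_targets
  S <- S[!dead_rows, , drop = FALSE]
  nf <- ncol(S)
  fx <- colnames(S)
  nv <- nf + 2L                        # variables: fluxes, I1, I2
  i1col <- nf + 1L
  i2col <- nf + 2L

  # steady state: S V + I = 0  ->  -(S V) = I placement rows
  Aeq <- cbind(S, 0, 0)
  Aeq[match("Z1", rownames(S)), i1col] <- 1
  Aeq[match("Z3", rownames(S)), i2col] <- 1
  beq <- rep(0, nrow(S))

  # fix I1, pin H share: V7 - h*(V7+V17+V25) = 0
  fixI1 <- numeric(nv); fixI1[i1col] <- 1
  hrow <- numeric(nv)
  hrow[match(c("V7", "V17", "V25"), fx)] <- -bounds$h_share
  hrow[match("V7", fx)] <- 1 - bounds$h_share
  A3 <- rbind(Aeq, fixI1, hrow)
  b3 <- c(beq, bounds$i1, 0)

  # inequalities: efflux caps/floors, I2 range, S/G window
  effl <- intersect(names(bounds$efflux_lb), fx)
  Ub <- t(vapply(effl, function(f) {
    r <- numeric(nv)
    r[match(f, fx)] <- 1
    r[c(i1col, i2col)] <- -bounds$efflux_cap
    r
  }, numeric(nv)))                     # V_e - cap*(I1+I2) <= 0
  i2ub <- numeric(nv); i2ub[i2col] <- 1
  sgu <- numeric(nv)
  sgu[match("V25", fx)] <- 1
  sgu[match("V17", fx)] <- -bounds$sg_range[2]   # V25 - r_hi*V17 <= 0
  A1 <- rbind(Ub, i2ub, sgu)
  b1 <- c(rep(0, length(effl)), bounds$i2_range[2], 0)

  Lb <- t(vapply(effl, function(f) {
    r <- numeric(nv); r[match(f, fx)] <- 1; r
  }, numeric(nv)))
  i2lb <- numeric(nv); i2lb[i2col] <- 1
  sgl <- numeric(nv)
  sgl[match("V25", fx)] <- 1
  sgl[match("V17", fx)] <- -bounds$sg_range[1]   # V25 - r_lo*V17 >= 0
  A2 <- rbind(Lb, i2lb, sgl)
  b2 <- c(bounds$efflux_lb[effl], bounds$i2_range[1], 0)

  obj <- numeric(nv)
  obj[match(c("V7", "V17", "V25"), fx)] <- 1

  lp <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                      A3 = A3, b3 = b3, maxi = TRUE)
  if (lp$solved == -1) {
    chk <- paste(rownames(S)[rowSums(abs(S)) > 0], collapse = ", ")
    stop("flux balance LP infeasible under the supplied bounds; ",
         "check mass balances for: ", chk)
  }
  if (lp$solved != 1)
    stop("flux balance LP did not converge (possibly unbounded); ",
         "check that influx and efflux bounds are finite")
  x <- lp$soln
  opt <- lp$value

  # L2 tie-break among alternate optima (objective pinned at the optimum)
  objrow <- obj
  Aq <- rbind(A3, objrow)              # equalities incl. objective value
  bq <- c(b3, opt)
  # inequalities in >= form: A2 x >= b2, -A1 x >= -b1, x >= 0
  Amat <- rbind(Aq, A2, -A1, diag(nv))
  bvec <- c(bq, b2, -b1, rep(0, nv))
  qp <- try(quadprog::solve.QP(Dmat = diag(nv), dvec = rep(0, nv),
                               Amat = t(Amat), bvec = bvec,
                               meq = nrow(Aq)), silent = TRUE)
  if (!inherits(qp, "try-error")) x <- qp$solution
  x[abs(x) < 1e-12] <- 0

  V <- stats::setNames(rep(0, nrow(topology$fluxes)),
                       topology$fluxes$flux)
  V[fx] <- x[seq_len(nf)]
  fd <- structure(list(V = V, I1 = x[i1col], I2 = x[i2col],
                       objective = sum(V[c("V7", "V17", "V25")])),
                  class = "flux_distribution")
  fd$residual <- max(abs(balance_residuals(topology, fd)))
  fd
}

balance_residuals <- function(topology, fluxdist) {
  net <- drop(topology$stoich %*% fluxdist$V)
  net[topology$influx_targets[["I1"]]] <-
    net[topology$influx_targets[["I1"]]] + fluxdist$I1
  net[topology$influx_targets[["I2"]]] <-
    net[topology$influx_targets[["I2"]]] + fluxdist$I2
  stats::setNames(net, names(pathway_metabolites()))
}

#' Per-metabolite mass-balance report for a flux distribution
#'
#' Computes the net production rate of every metabolite under a flux
#' vector (LP output or externally supplied fluxes, e.g. back-computed
#' from a printed parameter set via the steady-state flux relation) and
#' flags nodes whose imbalance exceeds `tol`.
#'
#' @param topology A `pathway_topology`.
#' @param fluxdist A `flux_distribution` (or list with `V`, `I1`, `I2`).
#' @param tol Imbalance tolerance.
#' @return A data.frame with columns `metabolite`, `net`, `balanced`.
#' @export
check_balance <- function(topology, fluxdist, tol = 1e-9) {
  net <- balance_residuals(topology, fluxdist)
  data.frame(metabolite = names(net), net = as.numeric(net),
             balanced = abs(net) <= tol, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("Flux distribution: ", length(x$V), " fluxes, I1=", signif(x$I1, 4),
      " I2=", signif(x$I2, 4), "\n", sep = "")
  cat("  total lignin flux (V7+V17+V25): ", signif(x$objective, 5),
      ", max |balance residual|: ", format(x$residual, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Write / read a flux distribution as labeled tabular text
#'
#' @param fluxdist A `flux_distribution`.
#' @param path File path (tab-separated, columns `flux`, `value`).
#' @return `path` invisibly / a `flux_distribution`.
#' @export
write_flux_distribution <- function(fluxdist, path) {
  df <- data.frame(flux = c(names(fluxdist$V), "I1", "I2"),
                   value = c(unname(fluxdist$V), fluxdist$I1, fluxdist$I2))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_distribution
#' @param path File written by `write_flux_distribution`.
#' @export
read_flux_distribution <- function(path) {
  df <- utils::read.delim(path)
  v <- df$value[!df$flux %in% c("I1", "I2")]
  names(v) <- df$flux[!df$flux %in% c("I1", "I2")]
  structure(list(V = v,
                 I1 = df$value[df$flux == "I1"],
                 I2 = df$value[df$flux == "I2"],
                 objective = sum(v[c("V7", "V17", "V25")], na.rm = TRUE)),
            class = "flux_distribution")
}
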