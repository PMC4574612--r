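# Shared fixtures, built once per test run.

TOP1 <- build_topology(1)
TOP2 <- build_topology(2)
TOP3 <- build_topology(3)
FD1 <- solve_wildtype_fluxes(TOP1)

# Independent hand-coded mass balances: per metabolite, influx ids and
# efflux ids, written directly from the model equations (not from the
# package's incidence constructor).
BALANCE_ORACLE <- list(
  Z1  = list(plus = character(0),     minus = "V1"),
  Z2  = list(plus = "V1",             minus = c("V2", "V3")),
  Z3  = list(plus = "V3",             minus = c("V4", "V8")),
  Z4  = list(plus = "V4",             minus = c("V5", "V9", "V10")),
  Z5  = list(plus = "V5",             minus = "V6"),
  Z6  = list(plus = "V6",             minus = "V7"),
  Z7  = list(plus = "V9",             minus = c("V11", "V12")),
  Z8  = list(plus = "V11",            minus = "V13"),
  Z9  = list(plus = "V12",            minus = c("V14", "V18")),
  Z10 = list(plus = c("V13", "V14"),  minus = c("V15", "V26")),
  Z11 = list(plus = "V15",            minus = c("V16", "V19")),
  Z12 = list(plus = c("V16", "V26"),  minus = c("V17", "V20")),
  Z13 = list(plus = "V19",            minus = "V22"),
  Z14 = list(plus = "V20",            minus = c("V21", "V23")),
  Z15 = list(plus = "V22",            minus = "V24"),
  Z16 = list(plus = c("V23", "V24"),  minus = "V25")
)

# Brute-force flux/rhs oracle: evaluates every flux by explicit loops
# over the flux table, independent of the matrix-based implementation.
oracle_fluxes <- function(topology, params, state, enzymes) {
  ft <- topology$fluxes
  v <- numeric(nrow(ft))
  for (j in seq_len(nrow(ft))) {
    prod <- params$alpha[[ft$flux[j]]]
    for (r in 1:16) {
      if (params$g[r, j] != 0) prod <- prod * state[r]^params$g[r, j]
    }
    v[j] <- prod * enzymes[[paste0("Z", ft$enzyme[j])]]
  }
  names(v) <- ft$flux
  v
}

oracle_rhs <- function(topology, params, state, enzymes, influx) {
  v <- oracle_fluxes(topology, params, state, enzymes)
  dz <- numeric(16)
  for (i in 1:16) {
    bo <- BALANCE_ORACLE[[i]]
    for (f in bo$plus)  if (f %in% names(v)) dz[i] <- dz[i] + v[[f]]
    for (f in bo$minus) if (f %in% names(v)) dz[i] <- dz[i] - v[[f]]
  }
  dz[1] <- dz[1] + influx[["I1"]]
  dz[3] <- dz[3] + influx[["I2"]]
  dz
}

# Small sampled ensemble reused across tests.
small_ensemble <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- build_parameter_ensemble(TOP1, FD1,
                                        sampler_config(n_sets = 20,
                                                       seed = 99))
    memo
  }
})
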