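#' Principal component analysis of an accepted kinetic-order ensemble
#'
#' Centered (unscaled) PCA on the kinetic-order vectors of the accepted
#' parameter sets. Rate constants are excluded: they are derived from the
#' flux anchor and carry no independent information. Axis signs are fixed
#' by making each axis's largest-magnitude loading positive, so results
#' are deterministic.
#'
#' @param accepted Either a `screening_result` (its accepted sets are
#'   used) or a numeric matrix with one kinetic-order vector per row.
#' @param template Optional constraint template for resampling: a list
#'   with `topology` and `flags`. Filled automatically when `accepted` is
#'   a `screening_result` with a single configuration/variant.
#' @return A list of class `ensemble_pca`: `mean`, `rotation` (axes in
#'   columns), `sdev`, `var_explained` (fractions, non-increasing, sum
#'   1), `scores`, `score_range` (per-axis min/max of the accepted
#'   scores), `n`, `template`.
#' @export
pca_fit <- function(accepted, template = NULL) {
  if (inherits(accepted, "screening_result")) {
    if (length(accepted$accepted) < 2)
      stop("need at least 2 accepted sets for PCA, got ",
           length(accepted$accepted))
    X <- t(vapply(accepted$accepted, function(a) a$g_vector,
                  accepted$accepted[[1]]$g_vector))
    if (is.null(template)) {
      cfgs <- unique(vapply(accepted$accepted, function(a) a$config, 0))
      flg <- accepted$accepted[[1]]$params$flags
      if (length(cfgs) == 1)
        template <- list(topology = build_topology(cfgs), flags = flg)
    }
  } else {
    X <- as.matrix(accepted)
  }
  if (nrow(X) < 2) stop("need at least 2 sets for PCA, got ", nrow(X))

  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # sign convention: dominant loading of each axis is positive
  for (k in seq_len(ncol(pc$rotation))) {
    dom <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[dom, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(mean = pc$center, rotation = pc$rotation, sdev = pc$sdev,
                 var_explained = ve, scores = pc$x,
                 score_range = apply(pc$x, 2, range),
                 n = nrow(X), template = template),
            class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  k <- min(4, length(x$var_explained))
  cat("PCA of accepted ensemble: ", x$n, " sets, ",
      length(x$mean), " kinetic orders\n", sep = "")
  cat("  cumulative variance, components 1-", k, ": ",
      round(100 * sum(x$var_explained[seq_len(k)]), 1), " %\n", sep = "")
  invisible(x)
}

# Validate a kinetic-order vector against the sign and ratio constraints
# of its topology/regulation template.
valid_g_vector <- function(gvec, topology, flags) {
  slots <- active_slots(topology, flags)
  ns <- nrow(slots$substrate)
  ni <- nrow(slots$inhibition)
  nc <- nrow(slots$competition)
  gs <- gvec[seq_len(ns)]
  if (any(gs <= 0) || any(gs > 1)) return(FALSE)
  if (ni > 0) {
    gi <- gvec[ns + seq_len(ni)]
    gsub <- gs[match(slots$inhibition$flux, slots$substrate$flux)]
    ratio <- gi / gsub
    if (any(gi >= 0) || any(gi < -1) || any(ratio <= -1) || any(ratio >= 0))
      return(FALSE)
  }
  if (nc > 0) {
    gc_ <- gvec[ns + ni + seq_len(nc)]
    ref <- competition_reference(topology, slots)
    gref <- gs[match(ref, slots$substrate$flux)]
    ratio <- gc_ / gref
    if (any(gc_ >= 0) || any(gc_ < -1) || any(ratio <= -1) ||
        any(ratio >= 0))
      return(FALSE)
  }
  TRUE
}

#' Resample kinetic-order sets within the reduced principal subspace
#'
#' Draws new kinetic-order vectors uniformly within the accepted
#' ensemble's per-axis score ranges along the first `k` principal axes
#' (remaining axes held at the ensemble mean), back-transforms them to
#' the original coordinates, and rejects draws that violate the sign or
#' inhibition-ratio constraints (redrawing up to `max_tries` rounds
#' rather than clipping, which would distort the constraint geometry).
#'
#' @param summary An `ensemble_pca` with a constraint `template`.
#' @param k Number of leading axes to vary (1..dimension).
#' @param n Number of sets to draw.
#' @param seed Integer seed.
#' @param max_tries Redraw rounds before giving up on the remainder.
#' @return A matrix with `n` (or fewer, with a warning) valid
#'   kinetic-order vectors in rows.
#' @export
resample_in_pc_space <- function(summary, k, n, seed = 1L,
                                 max_tries = 50L) {
  d <- ncol(summary$rotation)
  stopifnot(k >= 1, k <= d)
  set.seed(as.integer(seed))
  lo <- summary$score_range[1, seq_len(k)]
  hi <- summary$score_range[2, seq_len(k)]
  out <- matrix(NA_real_, 0, length(summary$mean),
                dimnames = list(NULL, names(summary$mean)))
  tries <- 0L
  while (nrow(out) < n && tries < max_tries) {
    m <- n - nrow(out)
    scores <- matrix(stats::runif(m * k, rep(lo, each = m),
                                  rep(hi, each = m)), nrow = m)
    X <- matrix(rep(summary$mean, each = m), nrow = m) +
      scores %*% t(summary$rotation[, seq_len(k), drop = FALSE])
    if (!is.null(summary$template)) {
      ok <- apply(X, 1, valid_g_vector,
                  topology = summary$template$topology,
                  flags = summary$template$flags)
      X <- X[ok, , drop = FALSE]
    }
    out <- rbind(out, X)
    tries <- tries + 1L
  }
  if (nrow(out) < n)
    warning("only ", nrow(out), " of ", n,
            " requested resampled sets satisfied the constraints")
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}

#' Export principal axes and variances as tabular text
#'
#' @param summary An `ensemble_pca`.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_pca_summary <- function(summary, path) {
  df <- data.frame(component = seq_along(summary$var_explained),
                   sdev = summary$sdev,
                   var_explained = summary$var_explained,
                   cumulative = cumsum(summary$var_explained))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
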