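#' Default pipeline configuration
#'
#' All knobs of the pipeline with their defaults: master seed, flux
#' anchor bounds, sampler settings, screening tolerance and
#' configurations, PCA dimension, and the validation stage toggle. A
#' configuration file supplies any subset of these; everything else
#' falls back to the defaults shown here.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = "lignin-run",
    fba = list(i1 = 1, i2_range = c(0, 0.1),
               efflux_lb = c(V2 = 0.155, V8 = 0.082, V10 = 0.046,
                             V18 = 0.050, V21 = 0.010),
               efflux_cap = 0.3, h_share = 0.03, sg_range = c(0.5, 1.0)),
    sampler = list(n_sets = 1000L, lhs_fraction = 0.1,
                   inhibition_ratio_mode = "sampled_per_flux",
                   fixed_ratio = -0.5, ratio_range = c(-0.99, -0.01),
                   phi_range = c(0.1, 0.9)),
    screening = list(configs = c(1L, 2L, 3L), rel_tol = 0.2,
                     variants = list(full = c(product_inhibition = TRUE,
                                              ccr_competition = TRUE,
                                              fourcl_inhibition = TRUE))),
    pca = list(k = 4L),
    validate = list(run = FALSE, level = 0.4)
  ), class = "pipeline_config")
}

merge_config <- function(base, override, path = character(0)) {
  for (nm in names(override)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ",
           paste(c(path, nm), collapse = "."))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], c(path, nm))
    } else {
      v <- override[[nm]]
      if (is.list(v) && all(vapply(v, is.numeric, TRUE)) &&
          is.numeric(base[[nm]]))
        v <- unlist(v)
      base[[nm]] <- v
    }
  }
  base
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML configuration, overlays it on [default_config()], and
#' validates it. Unknown keys are rejected with a message naming the
#' key; invalid values (e.g. a negative tolerance) are rejected.
#'
#' @param path YAML file; an empty file yields all defaults.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (length(user) > 0) cfg <- merge_config(cfg, user)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$screening$rel_tol <= 0)
    stop("screening.rel_tol must be positive, got ",
         cfg$screening$rel_tol)
  if (cfg$sampler$n_sets < 1) stop("sampler.n_sets must be >= 1")
  if (cfg$sampler$lhs_fraction < 0 || cfg$sampler$lhs_fraction > 1)
    stop("sampler.lhs_fraction must be in [0, 1]")
  if (!all(cfg$screening$configs %in% 1:3))
    stop("screening.configs must be a subset of 1:3")
  if (cfg$fba$h_share <= 0 || cfg$fba$h_share >= 1)
    stop("fba.h_share must be in (0, 1)")
  if (cfg$pca$k < 1) stop("pca.k must be >= 1")
  cfg$seed <- as.integer(cfg$seed)
  cfg$sampler$n_sets <- as.integer(cfg$sampler$n_sets)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$output_dir <- NULL                 # hash the semantics, not paths
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full ensemble-modeling pipeline
#'
#' Executes the stages in order -- flux balance, sampling, screening,
#' PCA on the accepted ensemble, and (optionally) the global-reduction
#' validation scenario -- and writes all artifacts to
#' `config$output_dir`: per-configuration flux distributions, screening
#' counts and per-set details, the accepted ensemble, PCA variances, and
#' a JSON run manifest with the config hash, per-stage seeds and counts.
#' Identical configuration and seed give byte-identical result tables.
#'
#' @param config A `pipeline_config` (see [default_config()],
#'   [load_config()]).
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  logf <- file.path(cfg$output_dir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  log <- function(...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...),
               logcon)
  }

  bounds <- do.call(default_bounds, cfg$fba)
  scfg <- do.call(sampler_config,
                  c(cfg$sampler, list(seed = cfg$seed)))
  criteria <- default_criteria(cfg$screening$rel_tol)

  say("screening ", length(cfg$screening$configs),
      " configuration(s) x ", length(cfg$screening$variants),
      " variant(s), ", scfg$n_sets, " sets each")
  log("stage screen: start")
  res <- screen_ensemble(configs = cfg$screening$configs,
                         variants = cfg$screening$variants,
                         config = scfg, criteria = criteria,
                         bounds = bounds)
  for (cid in names(res$fluxdist))
    write_flux_distribution(res$fluxdist[[cid]],
                            file.path(cfg$output_dir,
                                      paste0("fluxes_config", cid,
                                             ".tsv")))
  utils::write.table(res$counts,
                     file.path(cfg$output_dir, "screening_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$details,
                     file.path(cfg$output_dir, "screening_details.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(res$counts)))
    log("stage screen: config ", res$counts$config[i], " variant ",
        res$counts$variant[i], " sampled ", res$counts$sampled[i],
        " admissible ", res$counts$admissible[i], " accepted ",
        res$counts$accepted[i])

  if (length(res$accepted) > 0) {
    acc_cfg <- res$accepted[[1]]$config
    acc_ens <- structure(list(
      sets = lapply(res$accepted, `[[`, "params"),
      seed = cfg$seed, flags = res$accepted[[1]]$params$flags,
      config_id = acc_cfg), class = "gma_ensemble")
    write_ensemble(acc_ens, build_topology(acc_cfg),
                   file.path(cfg$output_dir, "accepted_ensemble.tsv"))
  }

  pca <- NULL
  if (length(res$accepted) >= 2) {
    acc_cfgs <- vapply(res$accepted, function(a) a$config, 0)
    main_cfg <- as.numeric(names(which.max(table(acc_cfgs))))
    keep <- acc_cfgs == main_cfg
    X <- t(vapply(res$accepted[keep], function(a) a$g_vector,
                  res$accepted[[which(keep)[1]]]$g_vector))
    pca <- pca_fit(X, template = list(
      topology = build_topology(main_cfg),
      flags = res$accepted[[which(keep)[1]]]$params$flags))
    write_pca_summary(pca, file.path(cfg$output_dir, "pca_variance.tsv"))
    k <- min(cfg$pca$k, length(pca$var_explained))
    log("stage analyze: PCA on ", pca$n, " accepted sets, cumulative ",
        "variance 1-", k, " = ",
        round(100 * sum(pca$var_explained[seq_len(k)]), 2), "%")
  } else {
    log("stage analyze: skipped (fewer than 2 accepted sets)")
  }

  validation <- NULL
  if (isTRUE(cfg$validate$run) && length(res$accepted) > 0) {
    a <- res$accepted[[1]]
    validation <- run_perturbation(build_topology(a$config), a$params,
                                   global_reduction(cfg$validate$level))
    write_perturbation_report(validation,
                              file.path(cfg$output_dir,
                                        "validation.tsv"))
    log("stage validate: total lignin fold ",
        round(validation$folds[["total"]], 4))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ligninGMA")),
    config_hash = config_hash(cfg),
    master_seed = cfg$seed,
    counts = res$counts,
    accepted_total = length(res$accepted),
    pca_cumvar4 = if (!is.null(pca))
      sum(pca$var_explained[seq_len(min(4, length(pca$var_explained)))])
      else NA,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE),
             file.path(cfg$output_dir, "manifest.json"))
  log("pipeline complete")
  invisible(list(manifest = manifest, screening = res, pca = pca,
                 validation = validation))
}
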