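#' Build a pipeline run configuration
#'
#' Defaults follow the study design: 1000 voxels selected per fold,
#' 1000 label permutations, searchlight radius 4 voxels, FDR level 0.05,
#' saccade threshold multiplier 6.
#'
#' @param seed Master seed fanned out to the per-stage substreams.
#' @param out_dir Output directory.
#' @param paradigm List of [paradigm_spec()] arguments to override.
#' @param roi_shape 3D grid dimensions of the simulated ROI volume.
#' @param n_informative Number of implanted direction-coding voxels.
#' @param amplitude Response amplitude of the preferred direction
#'   (signal units); 0 simulates pure noise.
#' @param noise_sd,drift_amplitude Forward-model noise and drift.
#' @param k,n_perm,cost Decoding parameters (`k = NULL` disables
#'   selection).
#' @param searchlight_radius,q Searchlight and FDR parameters.
#' @param lambda Saccade velocity threshold multiplier.
#' @param stages Character vector of stages to run: subset of
#'   `"decode"`, `"searchlight"`, `"univariate"`, `"eyetrack"`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("mvpa_run_"),
                       paradigm = list(), roi_shape = c(6, 6, 6),
                       n_informative = 8, amplitude = 3, noise_sd = 1,
                       drift_amplitude = 1, k = NULL, n_perm = 100,
                       cost = 1, searchlight_radius = 2, q = 0.05,
                       lambda = 6,
                       stages = c("decode", "searchlight", "univariate",
                                  "eyetrack")) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 paradigm = paradigm, roi_shape = as.integer(roi_shape),
                 n_informative = n_informative, amplitude = amplitude,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 k = k, n_perm = n_perm, cost = cost,
                 searchlight_radius = searchlight_radius, q = q,
                 lambda = lambda, stages = stages),
            class = "run_config")
}

#' Read / write a pipeline configuration as JSON
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg[setdiff(names(cfg), character())])
}

validate_config <- function(config) {
  p <- do.call(paradigm_spec,
               c(config$paradigm[setdiff(names(config$paradigm), "seed")],
                 list(seed = config$seed)))
  if (p$n_runs < 2L)
    stop("configuration error: n_runs must be >= 2 for leave-one-run-out ",
         "decoding")
  if (!is.null(config$k) && config$k > prod(config$roi_shape))
    stop("configuration error: k exceeds the ROI voxel count")
  if (config$n_perm < 0) stop("configuration error: n_perm must be >= 0")
  p
}

#' Run the simulation-to-inference pipeline end to end
#'
#' Simulates the paradigm and BOLD data from the configuration, then runs
#' the requested stages: decoding (with permutation inference),
#' searchlight mapping, univariate GLM contrasts with a preference map,
#' and eye-movement confound checks. Writes JSON/CSV/NIfTI outputs plus a
#' provenance log (config file, its MD5 hash, seed, package and R
#' versions) to `config$out_dir`. Fully deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.json")
  write_config(config, cfg_path)
  results <- list()

  events <- generate_events(spec)
  write_events(events, file.path(config$out_dir, "events.tsv"))

  shape <- config$roi_shape
  n_inf <- min(config$n_informative, prod(shape))
  truth <- if (n_inf > 0 && config$amplitude != 0) {
    iv <- linear_to_grid(seq_len(n_inf), shape)
    amp <- with_seed(derive_seed(config$seed, "amplitudes"),
                     matrix(stats::runif(length(spec$conditions) * n_inf,
                                         0, config$amplitude),
                            length(spec$conditions), n_inf))
    ground_truth(iv, amplitudes = amp, noise_sd = config$noise_sd,
                 drift_amplitude = config$drift_amplitude,
                 seed = config$seed)
  } else ground_truth(noise_sd = config$noise_sd,
                      drift_amplitude = config$drift_amplitude,
                      seed = config$seed)
  bold <- generate_bold(events, truth, shape)
  pre <- preprocess_runs(bold)
  feats <- extract_trial_features(pre, events)
  write_features(feats, file.path(config$out_dir, "features.tsv"))

  if ("decode" %in% config$stages) {
    fit <- mvpa_decode(feats, k = config$k, n_perm = config$n_perm,
                       cost = config$cost, seed = config$seed)
    results$decoding <- fit
    jsonlite::write_json(list(
      fold_accuracies = fit$fold_accuracies,
      mean_accuracy = fit$mean_accuracy,
      confusion = as.data.frame.matrix(fit$confusion),
      null_accuracies = fit$null_accuracies,
      null_95th = fit$null_95th, p_value = fit$p_value,
      n_perm = fit$n_perm),
      file.path(config$out_dir, "decoding.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  }

  if ("searchlight" %in% config$stages) {
    ribbon <- array(TRUE, shape)
    sl <- run_searchlight(pre, events, ribbon,
                          radius = config$searchlight_radius,
                          cost = config$cost)
    results$searchlight <- sl
    write_volume(sl$accuracy, file.path(config$out_dir, "searchlight_accuracy.nii.gz"))
    write_volume(sl$chi2, file.path(config$out_dir, "searchlight_chi2.nii.gz"))
    write_volume(sl$p, file.path(config$out_dir, "searchlight_p.nii.gz"))
    write_volume(fdr_mask(sl, config$q),
                 file.path(config$out_dir, "searchlight_fdr_mask.nii.gz"))
  }

  if ("univariate" %in% config$stages) {
    X <- build_design(events, drift = TRUE)
    Y <- do.call(rbind, preprocess_runs(bold, n_cycles = 0, zscore = FALSE)$runs)
    glm <- fit_glm(Y, X)
    tmaps <- vapply(spec$conditions, function(cc) contrast_t(glm, cc),
                    numeric(prod(shape)))
    results$univariate <- list(fit = glm, tmaps = tmaps)
    for (ci in seq_along(spec$conditions))
      write_volume(array(tmaps[, ci], shape),
                   file.path(config$out_dir,
                             sprintf("tmap_cond%d.nii.gz", spec$conditions[ci])))
    sig <- if (!is.null(results$searchlight))
      as.vector(fdr_mask(results$searchlight, config$q))
    else apply(vapply(seq_along(spec$conditions), function(ci)
      fdr_threshold_t(tmaps[, ci], glm$dof, config$q), logical(prod(shape))),
      1L, any)
    pref <- preference_map(tmaps, sig)
    results$preference <- array(pref, shape)
    write_volume(results$preference,
                 file.path(config$out_dir, "preference_map.nii.gz"))
  }

  if ("eyetrack" %in% config$stages) {
    gaze <- generate_gaze(events, seed = config$seed)
    write_gaze(gaze, file.path(config$out_dir, "gaze.csv"))
    clean <- remove_blinks(gaze)
    sacc <- detect_saccades(clean, lambda = config$lambda)
    utils::write.csv(sacc, file.path(config$out_dir, "saccades.csv"),
                     row.names = FALSE)
    results$eyetrack <- list(saccades = sacc,
                             retention = attr(clean, "retention"))
  }

  prov <- list(config_file = "config.json",
               config_md5 = unname(tools::md5sum(cfg_path)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("motionmvpa")),
               r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
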