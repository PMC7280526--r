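## Workflow orchestration: configuration-driven generation of synthetic
## datasets, regularization sweeps over the estimator, and DTI comparison
## tables. Configs are plain lists, YAML or JSON files; outputs are CSV/JSON.

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config)) config <- yaml::read_yaml(config)
    else if (grepl("\\.json$", config))
      config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
    else stop("config file must be .yaml/.yml or .json")
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  config
}

.simulate_defaults <- function() {
  list(
    mode = "two_domain",
    dim = 2,
    radii = c(45, 35, 10),
    resolution = 1.5,
    D_true = list(GM = 1.3e-4 * 3600, WM = 1.1e-4 * 3600),
    profile = list(sas = list(A = 1.3, tau = 8),
                   ventricle = list(A = 0.65, tau = 8)),
    dt = 2.4, T_final = 24,
    schedule = seq(0, 24, by = 2.4),
    refine = 4, theta = 0.5,
    n_amp = 0,
    seed = 1
  )
}

#' Generate a complete synthetic dataset directory
#'
#' Builds the geometry, simulates ground truth, samples the observation
#' schedule, optionally adds uniform vertex noise (one sub-series per
#' amplitude in `n_amp`), and writes everything as plain text: the mesh
#' (MSH), per-observation CSV files, and a JSON manifest recording the full
#' configuration and the true diffusivities.
#'
#' @param config list, or path to a YAML/JSON file; unknown fields are
#'   rejected. See the package vignette for the schema; defaults reproduce
#'   the two-domain verification conditions.
#' @param outdir output directory.
#' @return the manifest list, invisibly.
#' @export
run_simulate <- function(config = list(), outdir) {
  cfg <- utils::modifyList(.simulate_defaults(), .read_config(config))
  extra <- setdiff(names(cfg), names(.simulate_defaults()))
  if (length(extra)) stop("unknown config fields: ", paste(extra, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  mesh <- build_synthetic_geometry(cfg$dim, cfg$radii, cfg$resolution,
                                   mode = cfg$mode)
  ctx <- fem_context(mesh)
  grid <- time_grid(cfg$dt, cfg$T_final)
  D_true <- do.call(region_adc, cfg$D_true[sort(unique(mesh$cell_labels))])
  profile <- boundary_profile_spec(sas = cfg$profile$sas,
                                   ventricle = cfg$profile$ventricle)
  truth <- generate_ground_truth(mesh, D_true, profile, cfg$schedule, grid,
                                 refine = cfg$refine, theta = cfg$theta,
                                 ctx = ctx)
  write_msh(mesh, file.path(outdir, "mesh.msh"))

  amps <- cfg$n_amp
  series_dirs <- character(0)
  for (amp in amps) {
    tag <- if (amp == 0) "noise_free" else sprintf("namp_%s", amp)
    obs <- if (amp > 0)
      add_noise(truth$obs, noise_spec(amp, cfg$seed)) else truth$obs
    export_state_series(obs, file.path(outdir, tag), prefix = "obs")
    series_dirs <- c(series_dirs, tag)
  }
  manifest <- list(
    config = cfg,
    D_true = as.list(unclass(D_true)),
    n_vertices = nrow(mesh$vertices),
    n_cells = nrow(mesh$cells),
    observation_times = truth$obs$times,
    series = series_dirs
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.estimate_defaults <- function() {
  list(
    dataset = NULL, series = "noise_free",
    alphas = c(1e-6, 1e-4), betas = c(1, 10),
    gamma_tildes = c(0, 0.01, 1),
    k = 10, T_final = 24,
    opt = list(), seed = 1
  )
}

#' Run the estimator over a regularization sweep
#'
#' Loads a dataset written by [run_simulate()] and runs [estimate_adc()] for
#' every combination of the regularization lists and time-step counts `k`
#' (cartesian product). A failing combination is recorded as a failed row
#' rather than aborting the sweep. When the dataset manifest records true
#' diffusivities, signed percent error columns are included.
#'
#' @param config list or YAML/JSON path: `dataset` (directory), `series`
#'   (sub-series name), `alphas`, `betas`, `gamma_tildes`, `k` (one or more
#'   step counts), `T_final`, `opt` (passed to [estimate_adc()]), `seed`.
#' @param outfile optional CSV path for the sweep table.
#' @return data.frame, one row per combination.
#' @export
run_estimate <- function(config, outfile = NULL) {
  cfg <- utils::modifyList(.estimate_defaults(), .read_config(config))
  if (is.null(cfg$dataset)) stop("config$dataset is required")
  manifest <- jsonlite::fromJSON(file.path(cfg$dataset, "manifest.json"),
                                 simplifyVector = TRUE)
  mesh <- read_msh(file.path(cfg$dataset, "mesh.msh"))
  if (manifest$config$mode == "three_domain")
    mesh$dirichlet_tags <- "RED_SAS"
  ctx <- fem_context(mesh)
  sdir <- file.path(cfg$dataset, cfg$series)
  man <- utils::read.csv(file.path(sdir, "obs_manifest.csv"))
  vals <- vapply(man$file, function(f)
    utils::read.csv(file.path(sdir, f))$value, numeric(ctx$nv))
  obs <- observation_series(man$time, vals)
  D_true <- manifest$D_true
  labels <- sort(unique(mesh$cell_labels))
  rows <- list()
  for (k in cfg$k) {
    grid <- time_grid(cfg$T_final / k, cfg$T_final)
    for (a in cfg$alphas) for (b in cfg$betas) for (gt in cfg$gamma_tildes) {
      row <- data.frame(k = k, alpha = a, beta = b, gamma_tilde = gt,
                        status = "ok", stringsAsFactors = FALSE)
      fit <- tryCatch(
        estimate_adc(obs, mesh, regularization_params(a, b, gt), grid,
                     opt_config = cfg$opt, ctx = ctx,
                     u0 = numeric(ctx$nv)),
        error = function(e) e
      )
      if (inherits(fit, "error")) {
        row$status <- conditionMessage(fit)
        for (lb in labels) row[[paste0("adc_", lb)]] <- NA_real_
      } else {
        for (lb in labels) {
          row[[paste0("adc_", lb)]] <- unname(fit$adc[lb])
          if (!is.null(D_true[[lb]]))
            row[[paste0("err_", lb)]] <-
              100 * (fit$adc[[lb]] - D_true[[lb]]) / D_true[[lb]]
        }
        row$misfit <- unname(fit$components["misfit"])
        row$alpha_term <- unname(fit$components["alpha_term"])
        row$beta_term <- unname(fit$components["beta_term"])
        row$gamma_term <- unname(fit$components["gamma_term"])
        row$iterations <- fit$iterations
        row$convergence <- fit$convergence$code
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (mcol in miss) r[[mcol]] <- NA
    r
  }))
  if (!is.null(outfile)) utils::write.csv(out, outfile, row.names = FALSE)
  out
}

#' Build a DTI-comparison table from an estimation result
#'
#' Combines estimated tracer ADCs with a table of median water ADCs from DTI
#' into the standard comparison layout: per region the DTI-predicted tracer
#' ADC, the simulated ADC, their percent difference, plus tortuosities.
#'
#' @param adc named vector/list of estimated ADCs in mm^2/h (as produced by
#'   [estimate_adc()]), or a JSON file holding one.
#' @param dti data.frame with columns `region` and `water_ADC` (mm^2/s), or a
#'   CSV path.
#' @param D_free_water free water diffusion coefficient (mm^2/s).
#' @param D_free_tracer free tracer coefficient (mm^2/s), default
#'   [D_FREE_GADOBUTROL].
#' @param outfile optional CSV path.
#' @return data.frame: region, water_ADC, lambda, dti_tracer_ADC, sim_ADC
#'   (mm^2/s), diff_percent.
#' @export
run_compare <- function(adc, dti, D_free_water,
                        D_free_tracer = D_FREE_GADOBUTROL, outfile = NULL) {
  if (is.character(adc) && length(adc) == 1L)
    adc <- unlist(jsonlite::fromJSON(adc))
  adc <- unlist(adc)
  if (is.character(dti) && length(dti) == 1L) dti <- utils::read.csv(dti)
  stopifnot(all(c("region", "water_ADC") %in% names(dti)))
  lam <- tortuosity(D_free_water, dti$water_ADC)
  pred <- adc_from_tortuosity(D_free_tracer, lam)
  sim <- convert_adc_units(unname(adc[dti$region]), "mm2_h", "mm2_s")
  out <- data.frame(
    region = dti$region,
    water_ADC = dti$water_ADC,
    lambda = lam,
    dti_tracer_ADC = pred,
    sim_ADC = sim,
    diff_percent = percent_difference(sim, pred)
  )
  if (!is.null(outfile)) utils::write.csv(out, outfile, row.names = FALSE)
  out
}
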