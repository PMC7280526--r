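## Synthetic verification data: ground-truth observation series from known
## diffusivities and a documented boundary concentration profile, uniform
## vertex noise, and the histogram-based SNR statistic.

#' Boundary concentration profile specification
#'
#' The default ground-truth boundary history is a rise-and-decay pulse
#' `g(t) = A * (t / tau) * exp(1 - t / tau)` per Dirichlet tag, mimicking the
#' arrival and washout of an intrathecally injected tracer at the SAS and
#' ventricular surfaces. `A` is the peak concentration (mM, reached at
#' `t = tau` hours). The ventricular default is half the SAS amplitude, since
#' tracer reaches the ventricles diluted.
#'
#' @param sas list with `A` and `tau` for the `RED_SAS` boundary.
#' @param ventricle list with `A` and `tau` for the `BLUE_VENTRICLE` boundary.
#' @return list of class `boundary_profile_spec`.
#' @export
boundary_profile_spec <- function(sas = list(A = 1.3, tau = 8),
                                  ventricle = list(A = 0.65, tau = 8)) {
  structure(list(RED_SAS = sas, BLUE_VENTRICLE = ventricle),
            class = "boundary_profile_spec")
}

.profile_value <- function(par, t) {
  par$A * (t / par$tau) * exp(1 - t / par$tau)
}

## Control matrix for the Dirichlet vertices of a mesh under a profile spec:
## each Dirichlet vertex takes the profile of the tag whose facets contain it.
.control_from_profile <- function(mesh, spec, grid) {
  bv <- dirichlet_vertices(mesh)
  g <- matrix(0, length(bv), grid$k + 1L)
  for (tg in intersect(mesh$dirichlet_tags, names(spec))) {
    vtx <- unique(as.vector(
      mesh$facets[mesh$facet_tags == tg, , drop = FALSE]))
    rows <- which(bv %in% vtx)
    vals <- .profile_value(spec[[tg]], grid$times)
    g[rows, ] <- matrix(vals, length(rows), grid$k + 1L, byrow = TRUE)
  }
  boundary_control(g, grid, vertices = bv)
}

#' Generate a ground-truth observation series
#'
#' Forward-simulates the diffusion model at known diffusivities and a known
#' boundary concentration history on a time grid `refine` times finer than the
#' inversion grid (so that inversion never sees data produced by its own
#' discretization), then samples the state at the requested schedule.
#'
#' @param mesh a tagged [labeled_mesh()].
#' @param D_true a [region_adc()] (mm^2/h).
#' @param g_true_spec a [boundary_profile_spec()].
#' @param schedule observation times in hours (may include 0).
#' @param grid the inversion [time_grid()]; the generator runs at
#'   `dt / refine`.
#' @param refine time-grid refinement factor for generation (default 4).
#' @param theta generator time-stepping parameter (default 0.5,
#'   Crank-Nicolson, second order: the truth should be grid-converged).
#' @param lump use lumped mass in the generator (with `theta = 1` this
#'   preserves nonnegativity of the generated fields).
#' @param ctx optional [fem_context()].
#' @return list with `obs` (an [observation_series()]) and `truth` (record of
#'   `D_true`, the profile spec and the grids used).
#' @export
generate_ground_truth <- function(mesh, D_true, g_true_spec = boundary_profile_spec(),
                                  schedule, grid, refine = 4L, theta = 0.5,
                                  lump = FALSE, ctx = NULL) {
  if (is.null(ctx)) ctx <- fem_context(mesh)
  if (any(schedule < 0 | schedule > grid$T_final + 1e-9))
    stop("schedule outside the time grid")
  fine <- time_grid(grid$dt / refine, grid$T_final)
  g_fine <- .control_from_profile(mesh, g_true_spec, fine)
  states <- solve_diffusion(mesh, D_true, g_fine, fine, theta = theta,
                            lump = lump, ctx = ctx)
  sel <- restrict_to_observation_times(states, schedule)
  obs <- observation_series(sel$times, sel$values, provenance = "synthetic",
                            noise_amp = 0)
  list(
    obs = obs,
    truth = list(
      D_true = D_true, g_spec = g_true_spec,
      schedule = schedule, inversion_grid = grid, generator_grid = fine,
      snap_log = attr(sel, "snap_log")
    )
  )
}

#' Uniform vertex noise specification
#'
#' @param n_amp noise amplitude in mM (>= 0); draws are uniform on
#'   `(-n_amp, n_amp)`.
#' @param seed integer RNG seed for reproducibility.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(n_amp, seed = 1L) {
  if (n_amp < 0) stop("n_amp must be non-negative")
  structure(list(n_amp = n_amp, seed = as.integer(seed)), class = "noise_spec")
}

#' Add independent uniform noise to every vertex of every observation
#'
#' All observations are perturbed, t = 0 included. The caller's RNG state is
#' left untouched.
#'
#' @param obs an [observation_series()].
#' @param spec a [noise_spec()].
#' @return a new [observation_series()] with `noise_amp` set.
#' @export
add_noise <- function(obs, spec) {
  if (spec$n_amp == 0) return(obs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(spec$seed)
  noise <- matrix(stats::runif(length(obs$values), -spec$n_amp, spec$n_amp),
                  nrow(obs$values), ncol(obs$values))
  observation_series(obs$times, obs$values + noise,
                     provenance = obs$provenance, noise_amp = spec$n_amp)
}

#' Histogram-based signal-to-noise ratio
#'
#' Builds a histogram of the values (Freedman-Diaconis bin rule), finds the
#' modal bin ("largest peak of the concentration distribution") and the
#' contiguous run of bins around it whose counts exceed half the modal count.
#' The noise is the standard deviation of the values inside that interval and
#' the SNR is their mean divided by that standard deviation.
#'
#' @param values numeric vector (vertex field or flattened voxel image);
#'   at least 100 values.
#' @return list of class `snr_report`: `snr` (NA when undefined), `interval`
#'   (value range used), `mean`, `sd`, `n_inside`, `defined`.
#' @export
estimate_snr <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 100L) stop("need at least 100 values")
  if (stats::sd(values) == 0) {
    return(structure(list(snr = NA_real_, interval = range(values),
                          mean = mean(values), sd = 0, n_inside = length(values),
                          defined = FALSE), class = "snr_report"))
  }
  nb <- max(2L, grDevices::nclass.FD(values))
  brk <- seq(min(values), max(values), length.out = nb + 1L)
  cnt <- graphics::hist(values, breaks = brk, plot = FALSE)$counts
  mode_bin <- which.max(cnt)
  half <- cnt[mode_bin] / 2
  lo <- mode_bin
  while (lo > 1L && cnt[lo - 1L] > half) lo <- lo - 1L
  hi <- mode_bin
  while (hi < length(cnt) && cnt[hi + 1L] > half) hi <- hi + 1L
  inside <- values >= brk[lo] & values <= brk[hi + 1L]
  mu <- mean(values[inside])
  sdev <- stats::sd(values[inside])
  if (!is.finite(sdev) || sdev == 0) {
    return(structure(list(snr = NA_real_, interval = c(brk[lo], brk[hi + 1L]),
                          mean = mu, sd = sdev, n_inside = sum(inside),
                          defined = FALSE), class = "snr_report"))
  }
  structure(list(snr = mu / sdev, interval = c(brk[lo], brk[hi + 1L]),
                 mean = mu, sd = sdev, n_inside = sum(inside),
                 defined = TRUE), class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  if (x$defined)
    cat(sprintf("SNR = %.3g (mean %.3g / sd %.3g over [%.3g, %.3g], n = %d)\n",
                x$snr, x$mean, x$sd, x$interval[1L], x$interval[2L], x$n_inside))
  else cat("SNR undefined (constant data in the peak interval)\n")
  invisible(x)
}
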