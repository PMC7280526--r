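## Forward diffusion model: implicit-Euler / P1 solution of
##   du/dt = D lap(u)  in Omega,  u = g on the Dirichlet boundary,
##   du/dn = 0 on the Neumann remainder,
## with region-wise constant apparent diffusion coefficient D (mm^2/h).

#' Uniform time grid
#'
#' @param dt step in hours (> 0).
#' @param T_final final time in hours; must be an integer multiple of `dt`.
#' @return list of class `time_grid` with `dt`, `T_final`, `k` (step count)
#'   and `times` (length `k + 1`, starting at 0).
#' @export
time_grid <- function(dt, T_final) {
  if (dt <= 0) stop("dt must be positive")
  k <- T_final / dt
  if (abs(k - round(k)) > 1e-9) stop("T_final must be a multiple of dt")
  k <- as.integer(round(k))
  if (k < 1L) stop("grid needs at least one step")
  structure(list(dt = dt, T_final = T_final, k = k,
                 times = dt * (0:k)), class = "time_grid")
}

#' Region-wise apparent diffusion coefficients
#'
#' @param ... named values in mm^2/h, e.g. `region_adc(GM = 0.47, WM = 0.40)`.
#'   Use [convert_adc_units()] for mm^2/s values.
#' @return named numeric vector of class `region_adc`.
#' @export
region_adc <- function(...) {
  v <- c(...)
  if (is.null(names(v)) || any(names(v) == ""))
    stop("all diffusivities must be named by subdomain label")
  if (any(!is.finite(v)) || any(v <= 0))
    stop("diffusivities must be finite and strictly positive")
  structure(v, class = "region_adc")
}

#' Dirichlet boundary control
#'
#' Concentration values (mM) at every Dirichlet boundary vertex for every
#' time-grid node, including t = 0.
#'
#' @param values numeric matrix, rows = Dirichlet vertices (in the order of
#'   [dirichlet_vertices()]), columns = time nodes `0..k`.
#' @param grid the [time_grid()] the columns refer to.
#' @param vertices the Dirichlet vertex indices (defaults to row count check
#'   only).
#' @return matrix of class `boundary_control` with attributes `times` and
#'   `vertices`.
#' @export
boundary_control <- function(values, grid, vertices = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != grid$k + 1L)
    stop("boundary control needs one column per time node (k + 1)")
  structure(values, times = grid$times, vertices = vertices,
            class = "boundary_control")
}

#' Time series of vertex fields
#'
#' `state_series` holds simulated fields, `observation_series` observed ones
#' (with provenance and noise amplitude metadata). Both store an `nv x nt`
#' value matrix and a strictly increasing time vector (hours).
#'
#' @param times numeric vector of times in hours.
#' @param values numeric matrix, one column per time.
#' @return object of class `state_series`.
#' @export
state_series <- function(times, values) {
  values <- as.matrix(values)
  if (length(times) != ncol(values))
    stop("one column per time required")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = values),
            class = "state_series")
}

#' @rdname state_series
#' @param provenance `"synthetic"` or `"image-derived"`.
#' @param noise_amp uniform noise amplitude in mM (0 when noise-free).
#' @export
observation_series <- function(times, values, provenance = "synthetic",
                               noise_amp = 0) {
  obj <- state_series(times, values)
  obj$provenance <- provenance
  obj$noise_amp <- noise_amp
  class(obj) <- c("observation_series", "state_series")
  obj
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("%s: %d vertices x %d times (t = %.3g .. %.3g h)\n",
              class(x)[1L], nrow(x$values), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Solve the diffusion initial-boundary-value problem
#'
#' Continuous P1 elements in space, a one-parameter theta scheme in time:
#' `theta = 1` is backward (implicit) Euler (the default), `theta = 0.5`
#' Crank-Nicolson; both are unconditionally stable.
#' Dirichlet values are imposed strongly at each step (fully implicit: the
#' value at step n is `g` at step n); zero-flux Neumann conditions hold on all
#' untagged-as-Dirichlet boundary facets. With an empty Dirichlet set the
#' problem is all-Neumann and total mass is conserved.
#'
#' @param mesh a tagged [labeled_mesh()].
#' @param D a [region_adc()] covering every label present, mm^2/h.
#' @param g a [boundary_control()] matrix (rows follow
#'   [dirichlet_vertices()]), or `NULL` for an all-Neumann run.
#' @param grid a [time_grid()].
#' @param u0 initial vertex field (mM); defaults to zero.
#' @param lump use a lumped mass matrix (preserves the discrete maximum
#'   principle on meshes with non-obtuse simplices); default off.
#' @param theta time-stepping parameter in (0, 1]; 1 = implicit Euler,
#'   0.5 = Crank-Nicolson.
#' @param ctx optional precomputed [fem_context()].
#' @return a [state_series()] with `k + 1` columns (t = 0 included).
#' @export
solve_diffusion <- function(mesh, D, g, grid, u0 = NULL, lump = FALSE,
                            theta = 1, ctx = NULL) {
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  if (is.null(ctx)) ctx <- fem_context(mesh)
  if (any(D <= 0)) stop("diffusivities must be strictly positive")
  nv <- ctx$nv
  if (is.null(u0)) u0 <- numeric(nv)
  if (length(u0) != nv) stop("u0 must have one value per vertex")
  bv <- ctx$bvert
  if (length(bv) > 0L) {
    if (is.null(g)) stop("mesh has Dirichlet facets but g is NULL")
    if (nrow(g) != length(bv))
      stop("g must have one row per Dirichlet vertex")
    if (ncol(g) != grid$k + 1L)
      stop("g must have one column per time node")
  }
  M <- if (lump) ctx$M_lumped else ctx$M
  K <- .stiffness_of(ctx, D)
  A <- M + theta * grid$dt * K             # new-step operator
  B <- M - (1 - theta) * grid$dt * K       # old-step operator
  free <- ctx$free
  U <- matrix(0, nv, grid$k + 1L)
  U[, 1L] <- u0
  if (length(bv) > 0L) U[bv, 1L] <- g[, 1L]
  A_ff <- A[free, free, drop = FALSE]
  fac <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(A_ff)),
                  error = function(e) NULL)
  if (is.null(fac))
    stop("system matrix not SPD / ill-conditioned at assembly")
  A_fd <- if (length(bv)) A[free, bv, drop = FALSE] else NULL
  B_f <- B[free, , drop = FALSE]
  for (n in seq_len(grid$k)) {
    rhs <- B_f %*% U[, n]
    if (length(bv)) {
      gb <- g[, n + 1L]
      rhs <- rhs - A_fd %*% gb
      U[bv, n + 1L] <- gb
    }
    sol <- Matrix::solve(fac, rhs, system = "A")
    U[free, n + 1L] <- as.numeric(sol)
  }
  state_series(grid$times, U)
}

#' Restrict a state series to observation times
#'
#' Each requested time is snapped to the nearest time-grid node; the snap
#' distances are recorded in the `snap_log` attribute. Two observation times
#' snapping to the same node, or times outside the grid, are errors.
#'
#' @param states a [state_series()] on the full grid.
#' @param obs_times numeric vector of observation times (hours).
#' @return a [state_series()] at the snapped times, with attribute
#'   `snap_log` (data.frame: requested, snapped, distance, column index).
#' @export
restrict_to_observation_times <- function(states, obs_times) {
  tg <- states$times
  if (any(obs_times < min(tg) - 1e-9 | obs_times > max(tg) + 1e-9))
    stop("observation time outside the simulated interval")
  idx <- vapply(obs_times, function(t0) which.min(abs(tg - t0)), integer(1))
  if (anyDuplicated(idx))
    stop("two observation times snap to the same grid node: ",
         paste(obs_times[duplicated(idx) | duplicated(idx, fromLast = TRUE)],
               collapse = ", "))
  out <- state_series(tg[idx], states$values[, idx, drop = FALSE])
  attr(out, "snap_log") <- data.frame(
    requested = obs_times, snapped = tg[idx],
    distance = abs(tg[idx] - obs_times), column = idx
  )
  out
}
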