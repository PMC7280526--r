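## Voxel-image preprocessing for the (optional) real-data path, fully
## testable on synthetic images: spoiled-gradient-echo signal to tracer
## concentration, the three boundary-data treatments (RAW sampling, CSF-value
## projection, Gaussian smoothing), and image-to-mesh interpolation.
##
## Conventions: 0-based voxel indices; the affine maps voxel *center* indices
## to physical mm coordinates (NIfTI convention); all mesh/image alignment is
## done in physical space.

#' Voxel image container
#'
#' @param data 3D numeric array.
#' @param affine 4x4 matrix mapping homogeneous 0-based voxel indices to
#'   physical mm coordinates; must be invertible.
#' @param units value units: `"mM"` or `"signal"` (arbitrary units).
#' @param labels optional integer segmentation array of identical shape.
#' @return list of class `voxel_image`.
#' @export
voxel_image <- function(data, affine = diag(4), units = "signal",
                        labels = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop("affine must be invertible")
  if (!is.null(labels)) {
    labels <- as.array(labels)
    if (!identical(dim(labels), dim(data)))
      stop("labels must have the same shape as data")
  }
  structure(list(data = data, affine = affine, units = units,
                 labels = labels), class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("voxel_image: %s voxels [%s], range %.4g..%.4g%s\n",
              paste(dim(x$data), collapse = " x "), x$units,
              min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE),
              if (!is.null(x$labels)) ", with labels" else ""))
  invisible(x)
}

#' Read / write voxel images as NIfTI
#'
#' Thin wrappers around the RNifti package; the affine is taken from / stored
#' in the NIfTI sform.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param units value units to record on the returned object.
#' @return a [voxel_image()] (`read_nifti_image`) or `path` invisibly.
#' @export
read_nifti_image <- function(path, units = "signal") {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  voxel_image(as.array(img), affine = aff, units = units)
}

#' @rdname read_nifti_image
#' @param image a [voxel_image()].
#' @export
write_nifti_image <- function(image, path) {
  nim <- RNifti::asNifti(image$data)
  RNifti::sform(nim) <- structure(image$affine[1:3, ],
                                  code = 2L)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

## Spoiled-gradient-echo steady-state signal, up to a constant M0 factor.
.spgr_signal <- function(T1, TR, flip_deg) {
  E1 <- exp(-TR / T1)
  sin(flip_deg * pi / 180) * (1 - E1) / (1 - cos(flip_deg * pi / 180) * E1)
}

#' Convert T1-weighted signal to tracer concentration
#'
#' Inverts the steady-state spoiled-gradient-echo signal model voxel-wise
#' under the linear relaxivity relation `1/T1(c) = 1/T1_0 + r1 * c`. The
#' pre-contrast T1 comes from a T1 map; voxels carrying the CSF segmentation
#' label use a fixed literature T1 instead (T1-map sequences underestimate
#' CSF T1 badly). The result is clamped at zero from below; voxels whose
#' signal ratio falls outside the invertible range of the model are masked
#' `NA` and counted.
#'
#' @param signal post-contrast [voxel_image()] (signal units).
#' @param baseline pre-contrast [voxel_image()] of identical shape/affine.
#' @param t1_map pre-contrast T1 map in ms, same shape.
#' @param r1 relaxivity in L/(mmol s) (= 1/(mM s)); default 5 (gadobutrol at
#'   3 T, order of magnitude).
#' @param TR repetition time in ms (default 5.1).
#' @param flip_deg flip angle in degrees (default 8).
#' @param csf_label integer label marking CSF voxels in `signal$labels`
#'   (optional).
#' @param csf_t1 T1 (ms) assumed for CSF voxels (default 3000).
#' @return a [voxel_image()] in mM with attribute `n_masked` (count of
#'   non-invertible voxels).
#' @export
signal_to_concentration <- function(signal, baseline, t1_map, r1 = 5,
                                    TR = 5.1, flip_deg = 8,
                                    csf_label = NULL, csf_t1 = 3000) {
  if (!identical(dim(signal$data), dim(baseline$data)) ||
      !identical(dim(signal$data), dim(t1_map$data)))
    stop("signal, baseline and t1_map shapes must match")
  if (max(abs(signal$affine - baseline$affine)) > 1e-6)
    stop("signal and baseline affines must match")
  if (r1 <= 0) stop("r1 must be positive")
  T10 <- t1_map$data
  if (any(T10 <= 0)) stop("T1 values must be positive")
  if (!is.null(csf_label) && !is.null(signal$labels))
    T10[signal$labels == csf_label] <- csf_t1

  cosf <- cos(flip_deg * pi / 180)
  E10 <- exp(-TR / T10)
  ratio <- signal$data / baseline$data
  ## S/S0 = [(1-E1)/(1-c E1)] / [(1-E10)/(1-c E10)]; solve for E1 (linear)
  q <- ratio * (1 - E10) / (1 - cosf * E10)
  E1 <- (q - 1) / (q * cosf - 1)
  ok <- is.finite(E1) & E1 > 0 & E1 < 1
  conc <- array(NA_real_, dim(signal$data))
  T1 <- -TR / log(E1[ok])
  conc[ok] <- (1000 / T1 - 1000 / T10[ok]) / r1   # ms -> s for r1 units
  conc[ok] <- pmax(conc[ok], 0)
  out <- voxel_image(conc, affine = signal$affine, units = "mM",
                     labels = signal$labels)
  attr(out, "n_masked") <- sum(!ok)
  out
}

## physical mm -> 0-based voxel index coordinates
.to_voxel_coords <- function(points, affine) {
  pts <- cbind(points, 1)
  vox <- pts %*% t(solve(affine))
  vox[, 1:3, drop = FALSE]
}

#' Sample a voxel image onto mesh vertices (the RAW treatment)
#'
#' Maps each vertex to voxel coordinates through the inverse affine and
#' interpolates. 2D meshes are treated as living in the z = 0 plane.
#'
#' @param image a [voxel_image()].
#' @param mesh a [labeled_mesh()].
#' @param mode `"trilinear"` (default) or `"nearest"` (reproduces the
#'   voxel-discontinuity artefacts of raw sampling).
#' @return numeric vertex field.
#' @export
sample_to_mesh <- function(image, mesh, mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  verts <- mesh$vertices
  if (ncol(verts) == 2L) verts <- cbind(verts, 0)
  vox <- .to_voxel_coords(verts, image$affine)
  dims <- dim(image$data)
  if (mode == "nearest") {
    idx <- round(vox)
    bad <- which(apply(idx, 1L, function(v)
      any(v < 0 | v > dims - 1L)))
    if (length(bad))
      stop("vertices outside the image volume: ",
           paste(head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) " ..." else "")
    return(image$data[cbind(idx[, 1L], idx[, 2L], idx[, 3L]) + 1L])
  }
  lo <- floor(vox)
  bad <- which(apply(vox, 1L, function(v) any(v < 0 | v > dims - 1L)))
  if (length(bad))
    stop("vertices outside the image volume: ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  lo <- pmin(pmax(lo, 0), matrix(rep(dims - 2L, each = nrow(lo)), ncol = 3L))
  w <- vox - lo
  out <- numeric(nrow(vox))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wt <- (dx * w[, 1L] + (1 - dx) * (1 - w[, 1L])) *
      (dy * w[, 2L] + (1 - dy) * (1 - w[, 2L])) *
      (dz * w[, 3L] + (1 - dz) * (1 - w[, 3L]))
    out <- out + wt * image$data[cbind(lo[, 1L] + dx, lo[, 2L] + dy,
                                       lo[, 3L] + dz) + 1L]
  }
  out
}

#' Project CSF voxel values onto Dirichlet boundary vertices (the CP method)
#'
#' For each Dirichlet boundary vertex: find its containing voxel, average the
#' values of all CSF-labeled voxels in the centered 7x7x7 neighborhood
#' (clipped at the image edges) and assign that average. When the
#' neighborhood contains no CSF voxel the vertex's own sampled value is used
#' and a warning lists the vertex.
#'
#' @param conc a [voxel_image()] in mM carrying a `labels` array.
#' @param mesh a tagged [labeled_mesh()].
#' @param csf_label integer CSF label value (default 1).
#' @param half_width neighborhood half width (default 3, i.e. 7x7x7).
#' @return numeric vector of boundary values, one per Dirichlet vertex (in
#'   [dirichlet_vertices()] order), with attribute `fallback_vertices`.
#' @export
csf_projection <- function(conc, mesh, csf_label = 1L, half_width = 3L) {
  if (is.null(conc$labels)) stop("concentration image carries no labels")
  bv <- dirichlet_vertices(mesh)
  verts <- mesh$vertices[bv, , drop = FALSE]
  if (ncol(verts) == 2L) verts <- cbind(verts, 0)
  vox <- round(.to_voxel_coords(verts, conc$affine))
  dims <- dim(conc$data)
  if (any(vox < 0) || any(vox > matrix(rep(dims - 1L, each = nrow(vox)),
                                       ncol = 3L)))
    stop("Dirichlet vertices outside the image volume")
  out <- numeric(length(bv))
  fallback <- integer(0)
  raw <- sample_to_mesh(conc, mesh, mode = "nearest")
  for (i in seq_along(bv)) {
    rng <- lapply(1:3, function(d)
      max(0L, vox[i, d] - half_width):min(dims[d] - 1L, vox[i, d] + half_width))
    block <- conc$data[rng[[1L]] + 1L, rng[[2L]] + 1L, rng[[3L]] + 1L,
                       drop = FALSE]
    lab <- conc$labels[rng[[1L]] + 1L, rng[[2L]] + 1L, rng[[3L]] + 1L,
                       drop = FALSE]
    sel <- lab == csf_label & !is.na(block)
    if (any(sel)) {
      out[i] <- mean(block[sel])
    } else {
      out[i] <- raw[bv[i]]
      fallback <- c(fallback, bv[i])
    }
  }
  if (length(fallback))
    warning("no CSF voxel in the neighborhood of vertices ",
            paste(head(fallback, 10L), collapse = ", "),
            "; vertex-sampled values used")
  attr(out, "fallback_vertices") <- fallback
  out
}

## 1D Gaussian kernel, sd in voxels, truncated at 4 sd, normalized.
.gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

## Convolve along one array dimension with reflective edge handling.
.convolve_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a)
  r <- (length(kernel) - 1L) / 2L
  n <- dim(a)[axis]
  ## reflected index vector (edge mirroring without repeating the edge voxel
  ## would be "reflect"; scipy's default mirrors including the edge)
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  idx <- pmin(pmax(idx, 1L), n)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, nrow = d[1L])
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, d[1L], ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * mp[(j - 1L) + seq_len(d[1L]), , drop = FALSE]
  }
  aperm(array(out, d), order(perm))
}

#' Gaussian smoothing of a voxel image (the GS method)
#'
#' Separable Gaussian convolution with physical standard deviation
#' `sigma_mm`, converted per axis to voxel units via the affine column
#' lengths; reflective edge handling.
#'
#' @param image a [voxel_image()].
#' @param sigma_mm standard deviation in mm (default 1.5).
#' @return smoothed [voxel_image()] (labels carried through unchanged).
#' @export
gaussian_smooth <- function(image, sigma_mm = 1.5) {
  spacing <- sqrt(colSums(image$affine[1:3, 1:3]^2))
  a <- image$data
  for (axis in 1:3) {
    a <- .convolve_axis(a, .gauss_kernel(sigma_mm / spacing[axis]), axis)
  }
  voxel_image(a, affine = image$affine, units = image$units,
              labels = image$labels)
}
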