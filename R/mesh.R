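## Labeled simplicial meshes: subdomain cell labels (CSF/GM/WM) and exterior
## facet tags marking the SAS-facing ("red") and ventricular ("blue") Dirichlet
## boundaries plus Neumann remainders.

#' Subdomain and boundary tag vocabularies
#'
#' Integer codes used when a mesh is written to or read from the MSH exchange
#' format. Cell labels: CSF = 1, GM = 2, WM = 3. Facet tags: RED_SAS = 1,
#' BLUE_VENTRICLE = 2, NEUMANN_GM_INTERFACE = 3, NEUMANN_WM_INTERFACE = 4.
#'
#' @name mesh-vocabulary
#' @keywords internal
NULL

.cell_label_codes <- c(CSF = 1L, GM = 2L, WM = 3L)
.facet_tag_codes <- c(
  RED_SAS = 1L, BLUE_VENTRICLE = 2L,
  NEUMANN_GM_INTERFACE = 3L, NEUMANN_WM_INTERFACE = 4L
)

#' Construct a labeled mesh
#'
#' @param vertices numeric matrix, one row per vertex, columns are mm
#'   coordinates (2 or 3).
#' @param cells integer matrix, one simplex per row (`dim + 1` vertex indices).
#' @param cell_labels character vector, one of `"CSF"`, `"GM"`, `"WM"` per cell.
#' @param facets integer matrix of exterior facets (`dim` vertex indices per
#'   row), or `NULL` to extract them from `cells`.
#' @param facet_tags character vector of tags per facet (see
#'   [mesh-vocabulary]); may be `NULL` when `facets` is `NULL` (use
#'   [tag_boundaries()] afterwards).
#' @param dirichlet_tags character vector naming which facet tags carry
#'   Dirichlet data; the rest are zero-flux Neumann.
#' @return An object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(vertices, cells, cell_labels, facets = NULL,
                         facet_tags = NULL, dirichlet_tags = character(0)) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  dim <- ncol(vertices)
  if (!dim %in% c(2L, 3L)) stop("vertices must have 2 or 3 columns")
  if (ncol(cells) != dim + 1L) stop("cells must have dim + 1 columns")
  if (length(cell_labels) != nrow(cells))
    stop("one label per cell required")
  if (!all(cell_labels %in% names(.cell_label_codes)))
    stop("cell labels must be CSF, GM or WM")
  if (is.null(facets)) {
    facets <- exterior_facets(cells, dim)
  } else {
    facets <- as.matrix(facets)
    storage.mode(facets) <- "integer"
  }
  if (!is.null(facet_tags) && length(facet_tags) != nrow(facets))
    stop("one tag per exterior facet required")
  if (!is.null(facet_tags) && !all(facet_tags %in% names(.facet_tag_codes)))
    stop("unknown facet tag")
  structure(
    list(
      vertices = vertices, cells = cells,
      cell_labels = as.character(cell_labels),
      facets = facets, facet_tags = facet_tags,
      dirichlet_tags = dirichlet_tags, dim = dim
    ),
    class = "labeled_mesh"
  )
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat(sprintf(
    "labeled_mesh: %dD, %d vertices, %d cells, %d exterior facets\n",
    x$dim, nrow(x$vertices), nrow(x$cells), nrow(x$facets)
  ))
  cat(" cells per label: ",
      paste(sprintf("%s=%d", names(table(x$cell_labels)),
                    as.integer(table(x$cell_labels))), collapse = ", "), "\n")
  if (!is.null(x$facet_tags))
    cat(" facets per tag:  ",
        paste(sprintf("%s=%d", names(table(x$facet_tags)),
                      as.integer(table(x$facet_tags))), collapse = ", "), "\n")
  cat(" Dirichlet tags:  ",
      if (length(x$dirichlet_tags)) paste(x$dirichlet_tags, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

## All (dim-1)-faces of the cells, one row per face occurrence, sorted indices.
.cell_faces <- function(cells, dim) {
  if (dim == 2L) {
    combs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))
  } else {
    combs <- list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  }
  faces <- do.call(rbind, lapply(combs, function(ix) cells[, ix, drop = FALSE]))
  t(apply(faces, 1L, sort.int))
}

#' Exterior facets of a simplicial mesh
#'
#' Faces belonging to exactly one cell.
#'
#' @param cells integer cell matrix.
#' @param dim spatial dimension (2 or 3).
#' @return integer matrix with `dim` columns.
#' @keywords internal
exterior_facets <- function(cells, dim) {
  faces <- .cell_faces(cells, dim)
  key <- apply(faces, 1L, paste, collapse = "_")
  tab <- table(key)
  ext <- names(tab)[tab == 1L]
  faces[match(ext, key), , drop = FALSE]
}

## TRUE when the exterior boundary is closed: in 2D every boundary vertex has
## exactly two incident boundary edges; in 3D every edge of a boundary triangle
## is shared by exactly two boundary triangles.
.boundary_closed <- function(facets, dim) {
  if (nrow(facets) == 0L) return(FALSE)
  if (dim == 2L) {
    all(table(as.vector(facets)) == 2L)
  } else {
    edges <- rbind(facets[, c(1L, 2L)], facets[, c(2L, 3L)], facets[, c(1L, 3L)])
    edges <- t(apply(edges, 1L, sort.int))
    all(table(paste(edges[, 1L], edges[, 2L])) == 2L)
  }
}

#' Measures of cells and facets
#'
#' Areas (2D) or volumes (3D) per cell; lengths (2D) or areas (3D) per facet.
#'
#' @param mesh a [labeled_mesh()].
#' @return numeric vector.
#' @keywords internal
cell_measures <- function(mesh) {
  v <- mesh$vertices
  c1 <- mesh$cells
  if (mesh$dim == 2L) {
    a <- v[c1[, 2L], ] - v[c1[, 1L], ]
    b <- v[c1[, 3L], ] - v[c1[, 1L], ]
    abs(a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]) / 2
  } else {
    a <- v[c1[, 2L], ] - v[c1[, 1L], ]
    b <- v[c1[, 3L], ] - v[c1[, 1L], ]
    d <- v[c1[, 4L], ] - v[c1[, 1L], ]
    cx <- cbind(
      a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
      a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
      a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
    )
    abs(rowSums(cx * d)) / 6
  }
}

#' @rdname cell_measures
#' @keywords internal
facet_measures <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$facets
  if (mesh$dim == 2L) {
    d <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    sqrt(rowSums(d^2))
  } else {
    a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    cx <- cbind(
      a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
      a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
      a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
    )
    sqrt(rowSums(cx^2)) / 2
  }
}

#' Total measure of a labeled subdomain or tagged boundary patch
#'
#' @param mesh a [labeled_mesh()].
#' @param label subdomain label (`"CSF"`, `"GM"`, `"WM"`).
#' @param tags facet tags; default all tagged facets.
#' @return scalar area/volume (`subdomain_measure`) or length/area
#'   (`boundary_measure`) in mm^dim / mm^(dim-1).
#' @export
subdomain_measure <- function(mesh, label) {
  sum(cell_measures(mesh)[mesh$cell_labels == label])
}

#' @rdname subdomain_measure
#' @export
boundary_measure <- function(mesh, tags = NULL) {
  m <- facet_measures(mesh)
  if (is.null(tags)) sum(m) else sum(m[mesh$facet_tags %in% tags])
}

#' Indices of vertices lying on Dirichlet-tagged facets
#'
#' @param mesh a tagged [labeled_mesh()].
#' @return sorted integer vector of vertex indices.
#' @export
dirichlet_vertices <- function(mesh) {
  if (length(mesh$dirichlet_tags) == 0L) return(integer(0))
  sel <- mesh$facet_tags %in% mesh$dirichlet_tags
  sort(unique(as.vector(mesh$facets[sel, , drop = FALSE])))
}

#' Generate a concentric brain-like labeled mesh
#'
#' Builds a synthetic stand-in for a segmented brain geometry: concentric
#' shells around an inner cavity that plays the role of the lateral ventricle.
#' In `three_domain` mode the shells are, from the outside in, CSF
#' (subarachnoid space), grey matter and white matter; in `two_domain` mode
#' the CSF compartment is omitted (the SAS has been stripped away) and the
#' shells are grey and white matter only.
#'
#' In 2D the mesh is a structured polar triangulation of an annulus (exact
#' circular interfaces); in 3D it is a Cartesian tetrahedral mesh restricted
#' to the spherical shell (staircase boundary).
#'
#' @param dim 2 or 3.
#' @param radii strictly decreasing radii in mm, outermost first:
#'   `c(CSF outer, GM outer, WM outer, ventricle)` for `three_domain`,
#'   `c(GM outer, WM outer, ventricle)` for `two_domain`.
#' @param resolution target edge length in mm (> 0).
#' @param mode `"two_domain"` or `"three_domain"`.
#' @return A tagged [labeled_mesh()]; see [tag_boundaries()] for the tagging
#'   convention.
#' @export
#' @examples
#' m <- build_synthetic_geometry(2, c(45, 35, 10), resolution = 5,
#'                               mode = "two_domain")
#' subdomain_measure(m, "GM") # close to pi * (45^2 - 35^2)
build_synthetic_geometry <- function(dim = 2L,
                                     radii,
                                     resolution = 2,
                                     mode = c("three_domain", "two_domain")) {
  mode <- match.arg(mode)
  n_expected <- if (mode == "three_domain") 4L else 3L
  if (length(radii) != n_expected)
    stop(sprintf("%s mode needs %d radii (got %d)", mode, n_expected,
                 length(radii)))
  if (any(diff(radii) >= 0)) stop("radii must be strictly decreasing")
  if (any(radii <= 0)) stop("radii must be positive")
  if (resolution <= 0) stop("resolution must be positive")

  labels_out_in <- if (mode == "three_domain") c("CSF", "GM", "WM")
                   else c("GM", "WM")

  mesh <- if (dim == 2L) {
    .annulus_mesh(radii, resolution, labels_out_in)
  } else if (dim == 3L) {
    .shell_mesh3d(radii, resolution, labels_out_in)
  } else stop("dim must be 2 or 3")

  if (nrow(mesh$cells) < 50L)
    stop("degenerate mesh: resolution yields fewer than 50 cells")
  tag_boundaries(mesh, mode)
}

## 2D structured polar annulus with rings exactly at the requested radii.
.annulus_mesh <- function(radii, res, labels_out_in) {
  r_desc <- radii                      # outermost -> innermost
  r_out <- r_desc[1L]
  ring_r <- numeric(0)
  asc <- rev(r_desc)                   # innermost -> outermost
  for (i in seq_len(length(asc) - 1L)) {
    nseg <- max(1L, ceiling((asc[i + 1L] - asc[i]) / res))
    seg <- seq(asc[i], asc[i + 1L], length.out = nseg + 1L)
    ring_r <- c(ring_r, if (i == 1L) seg else seg[-1L])
  }
  n_ring <- length(ring_r)
  n_th <- max(16L, ceiling(2 * pi * r_out / res))
  th <- 2 * pi * (seq_len(n_th) - 1L) / n_th
  verts <- cbind(
    as.vector(outer(cos(th), ring_r)),   # vertex (i_theta, j_ring)
    as.vector(outer(sin(th), ring_r))
  )
  vid <- function(j, i) (j - 1L) * n_th + ((i - 1L) %% n_th) + 1L
  tri <- vector("list", n_ring - 1L)
  for (j in seq_len(n_ring - 1L)) {
    i <- seq_len(n_th)
    a <- vid(j, i); b <- vid(j, i + 1L)
    c2 <- vid(j + 1L, i + 1L); d <- vid(j + 1L, i)
    tri[[j]] <- rbind(cbind(a, b, c2), cbind(a, c2, d))
  }
  cells <- do.call(rbind, tri)
  cent <- (verts[cells[, 1L], ] + verts[cells[, 2L], ] + verts[cells[, 3L], ]) / 3
  labels <- .label_by_radius(sqrt(rowSums(cent^2)), r_desc, labels_out_in)
  labeled_mesh(verts, cells, labels)
}

## 3D Cartesian tet mesh of a spherical shell (Kuhn subdivision of cubes whose
## centroid falls inside the shell).
.shell_mesh3d <- function(radii, res, labels_out_in) {
  r_out <- radii[1L]
  r_in <- radii[length(radii)]
  n <- ceiling(2 * r_out / res)
  xs <- seq(-r_out, r_out, length.out = n + 1L)
  h <- xs[2L] - xs[1L]
  np <- n + 1L
  vid <- function(i, j, k) (k - 1L) * np * np + (j - 1L) * np + i
  # Kuhn triangulation of the unit cube into 6 tets along the main diagonal
  kuhn <- rbind(
    c(1L, 2L, 4L, 8L), c(1L, 2L, 6L, 8L), c(1L, 3L, 4L, 8L),
    c(1L, 3L, 7L, 8L), c(1L, 5L, 6L, 8L), c(1L, 5L, 7L, 8L)
  )
  ij <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  cx <- xs[ij$i] + h / 2; cy <- xs[ij$j] + h / 2; cz <- xs[ij$k] + h / 2
  rad <- sqrt(cx^2 + cy^2 + cz^2)
  keep <- rad <= r_out & rad >= r_in
  ij <- ij[keep, , drop = FALSE]
  corn <- function(di, dj, dk) vid(ij$i + di, ij$j + dj, ij$k + dk)
  corners <- cbind(
    corn(0L, 0L, 0L), corn(1L, 0L, 0L), corn(0L, 1L, 0L), corn(1L, 1L, 0L),
    corn(0L, 0L, 1L), corn(1L, 0L, 1L), corn(0L, 1L, 1L), corn(1L, 1L, 1L)
  )
  cells <- do.call(rbind, lapply(seq_len(6L), function(t2)
    corners[, kuhn[t2, ], drop = FALSE]))
  g <- expand.grid(x = xs, y = xs, z = xs)
  used <- sort(unique(as.vector(cells)))
  remap <- integer(np^3); remap[used] <- seq_along(used)
  cells <- matrix(remap[cells], ncol = 4L)
  verts <- as.matrix(g[used, ])
  cent <- (verts[cells[, 1L], ] + verts[cells[, 2L], ] +
             verts[cells[, 3L], ] + verts[cells[, 4L], ]) / 4
  labels <- .label_by_radius(sqrt(rowSums(cent^2)), radii, labels_out_in)
  labeled_mesh(verts, cells, labels)
}

.label_by_radius <- function(r, radii_desc, labels_out_in) {
  # radii_desc: outermost ... innermost; band i is (radii[i+1], radii[i]]
  lab <- character(length(r))
  for (i in seq_along(labels_out_in)) {
    lab[r <= radii_desc[i] + 1e-9 & r > radii_desc[i + 1L] - 1e-9] <-
      labels_out_in[i]
  }
  lab[lab == ""] <- labels_out_in[length(labels_out_in)]
  lab
}

#' Tag exterior boundary facets of a concentric mesh
#'
#' Classifies every exterior facet by the radius of its centroid: facets on
#' the outermost surface are tagged `RED_SAS` and facets on the inner cavity
#' (the ventricular surface) `BLUE_VENTRICLE`. Which tags carry Dirichlet data
#' depends on the mode:
#'
#' * `two_domain`: the SAS has been stripped from the geometry, so both the
#'   outer (SAS-facing) and inner (ventricular) surfaces are Dirichlet.
#' * `three_domain`: the CSF compartment is part of the domain and only its
#'   outward-facing surface is Dirichlet; the ventricular surface keeps its
#'   `BLUE_VENTRICLE` identity but is treated as zero-flux Neumann.
#'
#' @param mesh a [labeled_mesh()] whose exterior boundary is closed.
#' @param mode `"two_domain"` or `"three_domain"`.
#' @return The mesh with `facet_tags` and `dirichlet_tags` set.
#' @export
tag_boundaries <- function(mesh, mode = c("three_domain", "two_domain")) {
  mode <- match.arg(mode)
  if (!.boundary_closed(mesh$facets, mesh$dim))
    stop("exterior boundary is not closed")
  f <- mesh$facets
  cent_r <- sqrt(rowSums((
    Reduce(`+`, lapply(seq_len(ncol(f)), function(i)
      mesh$vertices[f[, i], , drop = FALSE])) / ncol(f))^2))
  thr <- (max(cent_r) + min(cent_r)) / 2
  tags <- ifelse(cent_r >= thr, "RED_SAS", "BLUE_VENTRICLE")
  mesh$facet_tags <- tags
  mesh$dirichlet_tags <- if (mode == "two_domain")
    c("RED_SAS", "BLUE_VENTRICLE") else "RED_SAS"
  mesh
}

#' Structured rectangle mesh (verification helper)
#'
#' Triangulated `[0, Lx] x [0, Ly]` rectangle used for slab benchmarks. The
#' left edge (x = 0) is tagged `RED_SAS`, the right edge `BLUE_VENTRICLE`, top
#' and bottom `NEUMANN_GM_INTERFACE`; all cells are labeled `GM`.
#'
#' @param Lx,Ly side lengths in mm.
#' @param nx,ny number of element columns/rows.
#' @param dirichlet_tags which tags are Dirichlet (default left edge only).
#' @return a [labeled_mesh()].
#' @export
build_rectangle_mesh <- function(Lx, Ly, nx, ny,
                                 dirichlet_tags = "RED_SAS") {
  xs <- seq(0, Lx, length.out = nx + 1L)
  ys <- seq(0, Ly, length.out = ny + 1L)
  verts <- as.matrix(expand.grid(x = xs, y = ys))
  np <- nx + 1L
  vid <- function(i, j) (j - 1L) * np + i
  i <- rep(seq_len(nx), ny); j <- rep(seq_len(ny), each = nx)
  a <- vid(i, j); b <- vid(i + 1L, j); c2 <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
  cells <- rbind(cbind(a, b, c2), cbind(a, c2, d))
  mesh <- labeled_mesh(verts, cells, rep("GM", nrow(cells)))
  f <- mesh$facets
  cent <- (verts[f[, 1L], , drop = FALSE] + verts[f[, 2L], , drop = FALSE]) / 2
  tags <- rep("NEUMANN_GM_INTERFACE", nrow(f))
  tol <- 1e-9
  tags[cent[, 1L] < tol] <- "RED_SAS"
  tags[cent[, 1L] > Lx - tol] <- "BLUE_VENTRICLE"
  mesh$facet_tags <- tags
  mesh$dirichlet_tags <- dirichlet_tags
  mesh
}
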