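## P1 finite-element assembly on labeled simplicial meshes.
##
## Conventions: continuous piecewise-linear elements; consistent mass matrix
## by default with optional row-sum lumping; stiffness assembled per subdomain
## label with unit coefficient so that K(D) = sum_r D_r K_r.

## Element gradients of P1 basis functions. For a simplex with vertex matrix
## V ((dim+1) x dim), the barycentric gradient matrix is solve(T)[, -1] style;
## vectorized over cells below.

.assemble_mass <- function(mesh, cells = NULL) {
  if (is.null(cells)) cells <- mesh$cells
  d <- mesh$dim
  nloc <- d + 1L
  meas <- .simplex_measures(mesh$vertices, cells, d)
  # local P1 mass: meas / ((d+1)(d+2)) * (1 + I)
  base <- matrix(1, nloc, nloc) + diag(nloc)
  scal <- meas / ((nloc) * (nloc + 1L))
  ii <- jj <- xx <- vector("list", nloc * nloc)
  k <- 0L
  for (a in seq_len(nloc)) for (b in seq_len(nloc)) {
    k <- k + 1L
    ii[[k]] <- cells[, a]; jj[[k]] <- cells[, b]
    xx[[k]] <- scal * base[a, b]
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = rep(nrow(mesh$vertices), 2L)
  )
}

.simplex_measures <- function(verts, cells, d) {
  if (d == 2L) {
    a <- verts[cells[, 2L], , drop = FALSE] - verts[cells[, 1L], , drop = FALSE]
    b <- verts[cells[, 3L], , drop = FALSE] - verts[cells[, 1L], , drop = FALSE]
    abs(a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]) / 2
  } else {
    a <- verts[cells[, 2L], , drop = FALSE] - verts[cells[, 1L], , drop = FALSE]
    b <- verts[cells[, 3L], , drop = FALSE] - verts[cells[, 1L], , drop = FALSE]
    cc <- verts[cells[, 4L], , drop = FALSE] - verts[cells[, 1L], , drop = FALSE]
    cx <- cbind(
      a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
      a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
      a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
    )
    abs(rowSums(cx * cc)) / 6
  }
}

## Stiffness on a subset of cells (unit coefficient). Computes basis gradients
## cell-wise; meshes here are small enough that an R loop over cells is fine,
## but we vectorise via the cofactor formulae for speed.
.assemble_stiffness <- function(mesh, cells) {
  d <- mesh$dim
  verts <- mesh$vertices
  nc <- nrow(cells)
  nloc <- d + 1L
  meas <- .simplex_measures(verts, cells, d)
  # gradients: for each cell solve the (d x d) edge matrix; vectorized closed
  # form for d = 2, small loop fallback for d = 3
  if (d == 2L) {
    x1 <- verts[cells[, 1L], 1L]; y1 <- verts[cells[, 1L], 2L]
    x2 <- verts[cells[, 2L], 1L]; y2 <- verts[cells[, 2L], 2L]
    x3 <- verts[cells[, 3L], 1L]; y3 <- verts[cells[, 3L], 2L]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    gx <- cbind((y2 - y3) / det, (y3 - y1) / det, (y1 - y2) / det)
    gy <- cbind((x3 - x2) / det, (x1 - x3) / det, (x2 - x1) / det)
    grads <- array(0, c(nc, nloc, 2L))
    grads[, , 1L] <- gx; grads[, , 2L] <- gy
  } else {
    grads <- array(0, c(nc, nloc, 3L))
    for (e in seq_len(nc)) {
      V <- verts[cells[e, ], ]
      Tm <- rbind(1, t(V))            # 4x4: [1; x; y; z] columns per vertex
      G <- solve(Tm)[, -1L, drop = FALSE]  # rows: basis, cols: x,y,z
      grads[e, , ] <- G
    }
  }
  ii <- jj <- xx <- vector("list", nloc * nloc)
  k <- 0L
  for (a in seq_len(nloc)) for (b in seq_len(nloc)) {
    k <- k + 1L
    dot <- rowSums(grads[, a, , drop = FALSE] * grads[, b, , drop = FALSE],
                   dims = 1L)
    ii[[k]] <- cells[, a]; jj[[k]] <- cells[, b]
    xx[[k]] <- meas * dot
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = rep(nrow(verts), 2L)
  )
}

## Boundary facet mass/stiffness for a subset of facets (segments in 2D,
## triangles in 3D), assembled in the full vertex numbering.
.assemble_boundary_mass <- function(mesh, facets) {
  nv <- nrow(mesh$vertices)
  if (nrow(facets) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nv, nv)))
  d <- mesh$dim
  nloc <- d                     # facet simplex has dim vertices
  meas <- .facet_measures_of(mesh$vertices, facets, d)
  base <- matrix(1, nloc, nloc) + diag(nloc)
  scal <- meas / (nloc * (nloc + 1L))
  ii <- jj <- xx <- vector("list", nloc * nloc)
  k <- 0L
  for (a in seq_len(nloc)) for (b in seq_len(nloc)) {
    k <- k + 1L
    ii[[k]] <- facets[, a]; jj[[k]] <- facets[, b]
    xx[[k]] <- scal * base[a, b]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nv, nv))
}

.facet_measures_of <- function(verts, facets, d) {
  if (d == 2L) {
    dd <- verts[facets[, 2L], , drop = FALSE] - verts[facets[, 1L], , drop = FALSE]
    sqrt(rowSums(dd^2))
  } else {
    a <- verts[facets[, 2L], , drop = FALSE] - verts[facets[, 1L], , drop = FALSE]
    b <- verts[facets[, 3L], , drop = FALSE] - verts[facets[, 1L], , drop = FALSE]
    cx <- cbind(
      a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
      a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
      a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
    )
    sqrt(rowSums(cx^2)) / 2
  }
}

## Tangential (surface) stiffness on boundary facets: for segments the 1D
## stiffness (1/L)[[1,-1],[-1,1]]; for boundary triangles the in-plane P1
## stiffness computed in local 2D coordinates.
.assemble_boundary_stiffness <- function(mesh, facets) {
  nv <- nrow(mesh$vertices)
  if (nrow(facets) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nv, nv)))
  d <- mesh$dim
  if (d == 2L) {
    L <- .facet_measures_of(mesh$vertices, facets, 2L)
    i <- c(facets[, 1L], facets[, 2L], facets[, 1L], facets[, 2L])
    j <- c(facets[, 1L], facets[, 2L], facets[, 2L], facets[, 1L])
    x <- c(1 / L, 1 / L, -1 / L, -1 / L)
    return(Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nv, nv)))
  }
  nf <- nrow(facets)
  iL <- jL <- xL <- vector("list", nf)
  for (e in seq_len(nf)) {
    V <- mesh$vertices[facets[e, ], ]
    e1 <- V[2L, ] - V[1L, ]
    e2 <- V[3L, ] - V[1L, ]
    t1 <- e1 / sqrt(sum(e1^2))
    e2p <- e2 - sum(e2 * t1) * t1
    t2 <- e2p / sqrt(sum(e2p^2))
    P <- cbind(c(0, 0), c(sum(e1 * t1), 0), c(sum(e2 * t1), sum(e2 * t2)))
    det <- (P[1L, 2L] - P[1L, 1L]) * (P[2L, 3L] - P[2L, 1L]) -
      (P[1L, 3L] - P[1L, 1L]) * (P[2L, 2L] - P[2L, 1L])
    area <- abs(det) / 2
    gx <- c(P[2L, 2L] - P[2L, 3L], P[2L, 3L] - P[2L, 1L], P[2L, 1L] - P[2L, 2L]) / det
    gy <- c(P[1L, 3L] - P[1L, 2L], P[1L, 1L] - P[1L, 3L], P[1L, 2L] - P[1L, 1L]) / det
    Ke <- area * (outer(gx, gx) + outer(gy, gy))
    iL[[e]] <- rep(facets[e, ], each = 3L)
    jL[[e]] <- rep(facets[e, ], times = 3L)
    xL[[e]] <- as.vector(t(Ke))
  }
  Matrix::sparseMatrix(i = unlist(iL), j = unlist(jL), x = unlist(xL),
                       dims = c(nv, nv))
}

#' Precompute finite-element operators for a mesh
#'
#' Assembles the consistent and lumped mass matrices, the per-subdomain unit
#' stiffness matrices, and boundary mass/tangential-stiffness matrices per
#' Dirichlet facet tag. The returned context is accepted by the forward
#' solver, the objective and the estimator to avoid re-assembly.
#'
#' @param mesh a tagged [labeled_mesh()].
#' @return a list of class `fem_context`.
#' @export
fem_context <- function(mesh) {
  labels <- unique(mesh$cell_labels)
  K <- lapply(labels, function(l)
    .assemble_stiffness(mesh, mesh$cells[mesh$cell_labels == l, , drop = FALSE]))
  names(K) <- labels
  M <- .assemble_mass(mesh)
  bvert <- dirichlet_vertices(mesh)
  nv <- nrow(mesh$vertices)
  free <- setdiff(seq_len(nv), bvert)
  dtags <- mesh$dirichlet_tags
  Mb <- Kb <- list()
  for (tg in dtags) {
    fc <- mesh$facets[mesh$facet_tags == tg, , drop = FALSE]
    Mb[[tg]] <- .assemble_boundary_mass(mesh, fc)
    Kb[[tg]] <- .assemble_boundary_stiffness(mesh, fc)
  }
  structure(
    list(
      mesh = mesh, M = M,
      M_lumped = Matrix::Diagonal(x = Matrix::rowSums(M)),
      K = K, Mb = Mb, Kb = Kb,
      bvert = bvert, free = free, nv = nv
    ),
    class = "fem_context"
  )
}

## K(D): region-weighted stiffness; D named vector in mm^2/h.
.stiffness_of <- function(ctx, D) {
  labs <- names(ctx$K)
  miss <- setdiff(labs, names(D))
  if (length(miss))
    stop("RegionADC missing labels: ", paste(miss, collapse = ", "))
  Reduce(`+`, lapply(labs, function(l) D[[l]] * ctx$K[[l]]))
}
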