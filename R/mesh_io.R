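## Labeled-mesh exchange in Gmsh MSH 2.2 ASCII format. Cells are written as
## triangle (type 2) or tetrahedron (type 4) elements whose physical tag is
## the subdomain code; exterior facets as line (type 1) or triangle elements
## whose physical tag is the boundary code (codes in `.cell_label_codes` /
## `.facet_tag_codes`, offset so the two code spaces cannot collide:
## facet tags are stored as 100 + code).

.FACET_TAG_OFFSET <- 100L

#' Write a labeled mesh to a Gmsh MSH 2.2 file
#'
#' Subdomain labels and boundary tags travel as physical tags (facet tags
#' offset by 100). Round-tripping through [read_msh()] preserves vertices to
#' full double precision, cells, labels and tags exactly.
#'
#' @param mesh a [labeled_mesh()].
#' @param path output path (conventionally `.msh`).
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  nv <- nrow(mesh$vertices)
  verts <- mesh$vertices
  if (ncol(verts) == 2L) verts <- cbind(verts, 0)
  writeLines("$Nodes", con)
  writeLines(as.character(nv), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nv),
                     verts[, 1L], verts[, 2L], verts[, 3L]), con)
  writeLines("$EndNodes", con)

  cell_type <- if (mesh$dim == 2L) 2L else 4L
  facet_type <- if (mesh$dim == 2L) 1L else 2L
  nc <- nrow(mesh$cells)
  nf <- nrow(mesh$facets)
  lab_code <- .cell_label_codes[mesh$cell_labels]
  tag_code <- if (!is.null(mesh$facet_tags))
    .facet_tag_codes[mesh$facet_tags] + .FACET_TAG_OFFSET
  else rep(.FACET_TAG_OFFSET, nf)

  writeLines("$Elements", con)
  writeLines(as.character(nc + nf), con)
  cell_str <- sprintf("%d %d 2 %d %d %s", seq_len(nc), cell_type,
                      lab_code, lab_code,
                      apply(mesh$cells, 1L, paste, collapse = " "))
  facet_str <- sprintf("%d %d 2 %d %d %s", nc + seq_len(nf), facet_type,
                       tag_code, tag_code,
                       apply(mesh$facets, 1L, paste, collapse = " "))
  writeLines(c(cell_str, facet_str), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a labeled mesh from a Gmsh MSH 2.2 file
#'
#' @param path a file written by [write_msh()] (or any MSH 2.2 file using
#'   the same physical-tag convention).
#' @param dirichlet_tags which boundary tags are Dirichlet on the returned
#'   mesh.
#' @return a [labeled_mesh()].
#' @export
read_msh <- function(path, dirichlet_tags = c("RED_SAS", "BLUE_VENTRICLE")) {
  lines <- readLines(path)
  sect <- function(name) {
    beg <- which(lines == paste0("$", name)) + 1L
    end <- which(lines == paste0("$End", name)) - 1L
    if (!length(beg) || !length(end)) stop("missing section ", name)
    lines[beg:end]
  }
  nodes <- sect("Nodes")
  nn <- as.integer(nodes[1L])
  node_mat <- matrix(as.numeric(unlist(strsplit(nodes[-1L], " "))),
                     ncol = 4L, byrow = TRUE)
  verts <- node_mat[order(node_mat[, 1L]), 2:4, drop = FALSE]
  if (nrow(verts) != nn) stop("node count mismatch")
  if (all(abs(verts[, 3L]) < 1e-300)) verts <- verts[, 1:2, drop = FALSE]

  elems <- sect("Elements")[-1L]
  parts <- strsplit(elems, " ")
  etype <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  phys <- vapply(parts, function(p) as.integer(p[4L]), integer(1))
  nodes_of <- function(p) as.integer(p[-(1:(3L + as.integer(p[3L])))])

  dim <- if (any(etype == 4L)) 3L else 2L
  cell_type <- if (dim == 3L) 4L else 2L
  facet_type <- if (dim == 3L) 2L else 1L
  is_cell <- etype == cell_type & phys < .FACET_TAG_OFFSET
  is_facet <- etype == facet_type & phys >= .FACET_TAG_OFFSET
  cells <- do.call(rbind, lapply(parts[is_cell], nodes_of))
  facets <- do.call(rbind, lapply(parts[is_facet], nodes_of))
  lab_names <- names(.cell_label_codes)[match(phys[is_cell],
                                              .cell_label_codes)]
  tag_names <- names(.facet_tag_codes)[match(phys[is_facet] - .FACET_TAG_OFFSET,
                                             .facet_tag_codes)]
  labeled_mesh(verts, cells, lab_names, facets = facets,
               facet_tags = tag_names,
               dirichlet_tags = intersect(dirichlet_tags,
                                          unique(tag_names)))
}

#' Export a state series alongside a CSV manifest
#'
#' Writes one CSV per time step (`vertex, value`) plus a manifest CSV
#' (`step, time, file`), a plain-text companion to the mesh file.
#'
#' @param states a [state_series()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return manifest data.frame, invisibly.
#' @export
export_state_series <- function(states, dir, prefix = "state") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(states$times))
  for (j in seq_along(states$times)) {
    files[j] <- sprintf("%s_%03d.csv", prefix, j - 1L)
    utils::write.csv(
      data.frame(vertex = seq_len(nrow(states$values)),
                 value = states$values[, j]),
      file.path(dir, files[j]), row.names = FALSE
    )
  }
  manifest <- data.frame(step = seq_along(states$times) - 1L,
                         time = states$times, file = files)
  utils::write.csv(manifest, file.path(dir, paste0(prefix, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}
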