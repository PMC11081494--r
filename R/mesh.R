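# -- tracked polygonal cell meshes -------------------------------------------
#
# An `epi_mesh` is one time point of a tracked tessellation: shared vertices
# plus one counter-clockwise vertex cycle per cell. Cell names are track ids,
# stable across the frames of an `epi_movie`.

#' Construct a cell mesh
#'
#' @param vertices numeric matrix (n x 2) of vertex coordinates in micrometres.
#' @param cells named list of integer vectors; each vector indexes `vertices`
#'   counter-clockwise around one cell.
#' @return An object of class `epi_mesh`.
#' @export
epi_mesh <- function(vertices, cells) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, is.list(cells))
  if (is.null(names(cells)) || anyNA(names(cells)) || any(names(cells) == ""))
    stop("cells must be a named list (names are cell track ids)")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  structure(list(vertices = vertices, cells = cells), class = "epi_mesh")
}

#' @export
print.epi_mesh <- function(x, ...) {
  cat(sprintf("<epi_mesh> %d cells, %d vertices\n",
              length(x$cells), nrow(x$vertices)))
  invisible(x)
}

#' Polygon of one cell in a mesh
#' @param mesh an `epi_mesh`.
#' @param cell cell id (name) or index.
#' @return n x 2 coordinate matrix.
#' @export
mesh_polygon <- function(mesh, cell) {
  mesh$vertices[mesh$cells[[cell]], , drop = FALSE]
}

#' Per-cell geometry of a mesh
#'
#' @param mesh an `epi_mesh`.
#' @return Tibble with columns `cell_id`, `cx`, `cy` (centroid, um),
#'   `area_um2`, `n_vertices`.
#' @export
mesh_cells <- function(mesh) {
  ids <- names(mesh$cells)
  cent <- t(vapply(ids, function(id) poly_centroid(mesh_polygon(mesh, id)),
                   numeric(2)))
  area <- vapply(ids, function(id) poly_area(mesh_polygon(mesh, id)), numeric(1))
  tibble::tibble(cell_id = ids, cx = unname(cent[, 1]),
                 cy = unname(cent[, 2]),
                 area_um2 = unname(area),
                 n_vertices = unname(lengths(mesh$cells)))
}

# unordered edge key
edge_key <- function(v1, v2) paste(pmin(v1, v2), pmax(v1, v2))
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Interfaces (shared cell-cell junctions) of a mesh
#'
#' Interface length is the straight vertex-to-vertex distance and orientation
#' the acute angle from the AP axis, in [0, 90] degrees. Edges bordering only
#' one cell (tessellation boundary) are excluded.
#'
#' @param mesh an `epi_mesh`.
#' @return Tibble with columns `cell_a`, `cell_b` (cell_a < cell_b), vertex
#'   ids `v1`, `v2`, endpoint coordinates `x1`,`y1`,`x2`,`y2`, `length_um`,
#'   `orientation_deg`.
#' @export
mesh_interfaces <- function(mesh) {
  ids <- names(mesh$cells)
  cell_col <- rep(ids, lengths(mesh$cells))
  v1 <- unlist(mesh$cells, use.names = FALSE)
  v2 <- unlist(lapply(mesh$cells, function(v) c(v[-1], v[1])), use.names = FALSE)
  key <- edge_key(v1, v2)
  sp <- split(seq_along(key), key)
  two <- sp[lengths(sp) == 2L]
  if (!length(two)) {
    return(tibble::tibble(cell_a = character(), cell_b = character(),
                          v1 = integer(), v2 = integer(),
                          x1 = numeric(), y1 = numeric(),
                          x2 = numeric(), y2 = numeric(),
                          length_um = numeric(), orientation_deg = numeric()))
  }
  i1 <- vapply(two, `[`, integer(1), 1L)
  i2 <- vapply(two, `[`, integer(1), 2L)
  ca <- cell_col[i1]; cb <- cell_col[i2]
  swap <- ca > cb
  tmp <- ca[swap]; ca[swap] <- cb[swap]; cb[swap] <- tmp
  va <- pmin(v1[i1], v2[i1]); vb <- pmax(v1[i1], v2[i1])
  p1 <- mesh$vertices[va, , drop = FALSE]
  p2 <- mesh$vertices[vb, , drop = FALSE]
  dx <- p2[, 1] - p1[, 1]; dy <- p2[, 2] - p1[, 2]
  tibble::tibble(cell_a = ca, cell_b = cb, v1 = va, v2 = vb,
                 x1 = p1[, 1], y1 = p1[, 2], x2 = p2[, 1], y2 = p2[, 2],
                 length_um = sqrt(dx^2 + dy^2),
                 orientation_deg = acute_angle_from_ap(dx, dy))
}

#' Neighbour list of a mesh
#' @param mesh an `epi_mesh`.
#' @return Named list: for each cell id, character vector of neighbour ids.
#' @export
mesh_neighbours <- function(mesh) {
  intf <- mesh_interfaces(mesh)
  ids <- names(mesh$cells)
  nb <- split(c(intf$cell_b, intf$cell_a), c(intf$cell_a, intf$cell_b))
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (id in names(nb)) out[[id]] <- unique(nb[[id]])
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Vertex positions where three or more cells meet
#' @param mesh an `epi_mesh`.
#' @return Matrix of coordinates of vertices used by >= 3 cells.
#' @export
mesh_junction_vertices <- function(mesh) {
  use <- table(unlist(mesh$cells, use.names = FALSE))
  vid <- as.integer(names(use)[use >= 3])
  mesh$vertices[vid, , drop = FALSE]
}

#' Cells on the tessellation boundary
#'
#' A boundary cell owns at least one edge not shared with another cell.
#' @param mesh an `epi_mesh`.
#' @return Character vector of cell ids.
#' @export
mesh_boundary_cells <- function(mesh) {
  ids <- names(mesh$cells)
  cell_col <- rep(ids, lengths(mesh$cells))
  v1 <- unlist(mesh$cells, use.names = FALSE)
  v2 <- unlist(lapply(mesh$cells, function(v) c(v[-1], v[1])), use.names = FALSE)
  key <- edge_key(v1, v2)
  n_by_key <- table(key)
  unique(cell_col[n_by_key[key] == 1L])
}

# -- movies ------------------------------------------------------------------

#' Construct a tracked movie
#'
#' @param meshes list of `epi_mesh`, one per frame, cells identified by
#'   shared track ids.
#' @param times_min numeric vector of frame times in minutes.
#' @param id movie identifier.
#' @param genotype genotype label (e.g. "wildtype", "twist").
#' @param pixel_size_um micrometres per pixel for rendered/derived images.
#' @param ground_truth optional list of generator ground-truth tables.
#' @param cell_types optional named character vector of cell type labels.
#' @return An object of class `epi_movie`.
#' @export
epi_movie <- function(meshes, times_min, id = "movie", genotype = "unknown",
                      pixel_size_um = 0.5, ground_truth = NULL,
                      cell_types = NULL) {
  stopifnot(length(meshes) == length(times_min))
  structure(list(meshes = meshes, times_min = as.numeric(times_min), id = id,
                 genotype = genotype, pixel_size_um = pixel_size_um,
                 ground_truth = ground_truth, cell_types = cell_types),
            class = "epi_movie")
}

#' @export
print.epi_movie <- function(x, ...) {
  cat(sprintf("<epi_movie> %s (%s): %d frames, %.1f..%.1f min, %d tracks\n",
              x$id, x$genotype, length(x$meshes),
              min(x$times_min), max(x$times_min),
              length(unique(unlist(lapply(x$meshes, function(m) names(m$cells)))))))
  invisible(x)
}

#' Long table of per-cell-per-frame geometry for a movie
#'
#' @param movie an `epi_movie`.
#' @return Tibble with `frame`, `time_min`, `cell_id`, `cx`, `cy`,
#'   `area_um2`, `n_vertices`, plus `type` when cell types are assigned.
#' @export
cells_table <- function(movie) {
  out <- dplyr::bind_rows(lapply(seq_along(movie$meshes), function(f) {
    d <- mesh_cells(movie$meshes[[f]])
    d$frame <- f
    d$time_min <- movie$times_min[f]
    d
  }))
  out <- out[, c("frame", "time_min", "cell_id", "cx", "cy",
                 "area_um2", "n_vertices")]
  if (!is.null(movie$cell_types))
    out$type <- unname(movie$cell_types[out$cell_id])
  tibble::as_tibble(out)
}

#' Long table of per-interface-per-frame geometry for a movie
#'
#' @param movie an `epi_movie`.
#' @return Tibble with `frame`, `time_min` and the `mesh_interfaces` columns.
#' @export
interfaces_table <- function(movie) {
  dplyr::bind_rows(lapply(seq_along(movie$meshes), function(f) {
    d <- mesh_interfaces(movie$meshes[[f]])
    if (nrow(d)) { d$frame <- f; d$time_min <- movie$times_min[f] }
    d
  }))
}
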