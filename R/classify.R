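# -- embryonic axes, cell typing, quality control -----------------------------

#' Define the embryonic axes and midline
#'
#' The ventral midline fixes the coordinate frame: AP runs along it (+x
#' posterior) and DV perpendicular (+y away from the midline). The package's
#' geometry is already expressed in this frame, so the midline is a
#' horizontal line at `midline_y` micrometres.
#'
#' @param midline_y y position of the ventral midline (um).
#' @return An `axes_frame` object.
#' @export
axes_frame <- function(midline_y = 0) {
  structure(list(midline_y = midline_y,
                 ap = c(1, 0), dv = c(0, 1)), class = "axes_frame")
}

#' Signed DV position of cells relative to the midline
#'
#' @param cells tibble with a `cy` column (um).
#' @param axes an `axes_frame`.
#' @return Numeric vector (um); positive away from the midline.
#' @export
dv_position <- function(cells, axes) {
  cells$cy - axes$midline_y
}

# assign cells to DV rows: bands of one median effective cell diameter,
# counted outward from the midline (row 1 touches the midline)
dv_rows <- function(cells, axes, band_um = NULL) {
  dv <- abs(dv_position(cells, axes))
  if (is.null(band_um))
    band_um <- stats::median(2 * sqrt(cells$area_um2 / pi), na.rm = TRUE)
  pmax(floor(dv / band_um), 0) + 1L
}

#' Assign cell types from midline proximity
#'
#' Cells within `mesoderm_half_width_cells` rows of the ventral midline are
#' labelled mesoderm, the next row mesectoderm (the single row flanking the
#' mesoderm), and the remainder ectoderm. In the wild-type embryo the
#' mesoderm is about 18 cell rows wide in total (half-width 9); in twist
#' mutants about 8 to 10 rows (half-width 4-5). Rows are bands of one median
#' cell diameter of |DV distance|, evaluated at `reference_time_min`. An
#' optional override table (e.g. from division-timing evidence) is applied
#' last.
#'
#' @param movie an `epi_movie`.
#' @param axes an `axes_frame` (the midline definition is required).
#' @param mesoderm_half_width_cells mesoderm half-width in cell rows; 0
#'   labels only the first row (as mesectoderm).
#' @param reference_time_min time point at which proximity is evaluated
#'   (default: first frame).
#' @param band_um row band width; default one median effective cell diameter.
#' @param overrides optional tibble with `cell_id`, `type`.
#' @return The movie with `cell_types` set (named character vector with
#'   values "mesoderm", "mesectoderm", "ectoderm").
#' @export
classify_cells <- function(movie, axes, mesoderm_half_width_cells,
                           reference_time_min = NULL, band_um = NULL,
                           overrides = NULL) {
  if (is.null(axes$midline_y)) stop("axes must define the midline")
  f <- if (is.null(reference_time_min)) 1L else
    which.min(abs(movie$times_min - reference_time_min))
  cells <- mesh_cells(movie$meshes[[f]])
  rows <- dv_rows(cells, axes, band_um)
  type <- ifelse(rows <= mesoderm_half_width_cells, "mesoderm",
                 ifelse(rows == mesoderm_half_width_cells + 1L,
                        "mesectoderm", "ectoderm"))
  names(type) <- cells$cell_id
  # tracks absent at the reference frame inherit from any frame they are in
  all_ids <- unique(unlist(lapply(movie$meshes, function(m) names(m$cells))))
  missing <- setdiff(all_ids, names(type))
  if (length(missing)) {
    extra <- stats::setNames(rep("ectoderm", length(missing)), missing)
    type <- c(type, extra)
  }
  if (!is.null(overrides))
    type[overrides$cell_id] <- overrides$type
  movie$cell_types <- type
  movie
}

#' Remove inaccurately tracked cells
#'
#' Flags cells on four criteria: velocity relative to their neighbours, cell
#' area, cell area change, and the number of frames over which the cell is
#' tracked. Flagged cells are marked "excluded" in the movie's cell types so
#' they drop out of all downstream statistics; per-criterion removal counts
#' are attached as the attribute `removals`.
#'
#' @param movie an `epi_movie`.
#' @param max_rel_velocity_um_min maximum speed relative to the mean of the
#'   first-ring neighbours.
#' @param area_range_um2 length-2 admissible area range.
#' @param max_area_change_pp_min maximum |d ln area / dt|.
#' @param min_frames minimum number of tracked frames.
#' @return The movie with flagged cells typed "excluded"; attribute
#'   `removals` is a named count per criterion.
#' @export
quality_filter <- function(movie,
                           max_rel_velocity_um_min = 10,
                           area_range_um2 = c(20, 1000),
                           max_area_change_pp_min = 0.5,
                           min_frames = 5L) {
  d <- cells_table(movie)
  nbrs <- lapply(movie$meshes, mesh_neighbours)
  nF <- length(movie$meshes)

  # centroid velocities per frame pair
  bad_vel <- character(0)
  cent <- lapply(movie$meshes, function(m) {
    dd <- mesh_cells(m); mm <- cbind(dd$cx, dd$cy)
    rownames(mm) <- dd$cell_id; mm
  })
  if (nF >= 2) {
    for (f in seq_len(nF - 1L)) {
      m0 <- cent[[f]]; m1 <- cent[[f + 1L]]
      common <- intersect(rownames(m0), rownames(m1))
      dt <- movie$times_min[f + 1L] - movie$times_min[f]
      vel <- (m1[common, , drop = FALSE] - m0[common, , drop = FALSE]) / dt
      for (id in common) {
        nb <- intersect(nbrs[[f]][[id]], common)
        if (length(nb) < 2L) next
        rel <- vel[id, ] - colMeans(vel[nb, , drop = FALSE])
        if (sqrt(sum(rel^2)) > max_rel_velocity_um_min)
          bad_vel <- c(bad_vel, id)
      }
    }
  }
  bad_vel <- unique(bad_vel)

  by_cell <- split(d, d$cell_id)
  bad_area <- names(by_cell)[vapply(by_cell, function(g)
    any(g$area_um2 < area_range_um2[1] | g$area_um2 > area_range_um2[2]),
    logical(1))]
  bad_change <- names(by_cell)[vapply(by_cell, function(g) {
    if (nrow(g) < 2L) return(FALSE)
    g <- g[order(g$frame), ]
    rate <- diff(log(g$area_um2)) / diff(g$time_min)
    any(abs(rate) > max_area_change_pp_min)
  }, logical(1))]
  bad_frames <- names(by_cell)[vapply(by_cell, nrow, integer(1)) < min_frames]

  removed <- unique(c(bad_vel, bad_area, bad_change, bad_frames))
  types <- movie$cell_types
  if (is.null(types)) {
    ids <- unique(d$cell_id)
    types <- stats::setNames(rep("ectoderm", length(ids)), ids)
  }
  types[removed] <- "excluded"
  movie$cell_types <- types
  attr(movie, "removals") <- c(velocity = length(bad_vel),
                               area = length(bad_area),
                               area_change = length(bad_change),
                               n_frames = length(bad_frames),
                               total = length(removed))
  movie
}

#' Distance from the mesectoderm reference row
#'
#' Each ectodermal cell is assigned its DV distance (um) from the first row
#' of ectodermal cell centroids at the reference time (30 minutes of
#' germband extension in the emulated studies), and the value is propagated
#' along the cell's track. Non-ectodermal cells get NA.
#'
#' @param movie an `epi_movie` with cell types assigned.
#' @param axes an `axes_frame`.
#' @param reference_time_min reference time (minutes).
#' @param band_um row band width for identifying the first row.
#' @return Named numeric vector (per cell id), um.
#' @export
distance_from_mesectoderm <- function(movie, axes, reference_time_min = 30,
                                      band_um = NULL) {
  if (is.null(movie$cell_types)) stop("assign cell types first")
  f <- which.min(abs(movie$times_min - reference_time_min))
  cells <- mesh_cells(movie$meshes[[f]])
  cells$type <- movie$cell_types[cells$cell_id]
  ecto <- cells[cells$type == "ectoderm", ]
  if (!nrow(ecto)) stop("no ectodermal cells at the reference time")
  rows <- dv_rows(ecto, axes, band_um)
  first_row_dv <- mean(abs(dv_position(ecto, axes))[rows == min(rows)])
  dist <- abs(dv_position(ecto, axes)) - first_row_dv
  out <- stats::setNames(rep(NA_real_, length(movie$cell_types)),
                         names(movie$cell_types))
  out[ecto$cell_id] <- dist
  out
}
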