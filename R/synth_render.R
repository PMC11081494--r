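# -- rendering synthetic meshes to images -------------------------------------

# scanline-rasterise one polygon (um) into pixel indices of an nr x nc image
rasterise_polygon <- function(poly, pixel_size, nr, nc) {
  ymin <- max(1L, floor(min(poly[, 2]) / pixel_size) + 1L)
  ymax <- min(nr, ceiling(max(poly[, 2]) / pixel_size))
  if (ymax < ymin) return(integer(0))
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  out <- vector("list", ymax - ymin + 1L)
  for (r in ymin:ymax) {
    y <- (r - 0.5) * pixel_size
    hit <- (y1 > y) != (y2 > y)
    if (!any(hit)) next
    xs <- sort(x1[hit] + (y - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit]))
    cols <- integer(0)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c_lo <- max(1L, ceiling(xs[k] / pixel_size + 0.5))
      c_hi <- min(nc, floor(xs[k + 1] / pixel_size + 0.5))
      if (c_hi >= c_lo) cols <- c(cols, c_lo:c_hi)
    }
    if (length(cols)) out[[r - ymin + 1L]] <- (cols - 1L) * nr + r
  }
  unlist(out)
}

# pixel indices along a segment (um), sampled densely; width_px > 1 dilates
# the line with its 4-neighbourhood so the band covers the boundary pixels
# of both adjacent cells
rasterise_segment <- function(p1, p2, pixel_size, nr, nc, width_px = 1L) {
  len_px <- sqrt(sum((p2 - p1)^2)) / pixel_size
  n <- max(2L, ceiling(len_px * 4))
  tt <- seq(0, 1, length.out = n)
  x <- p1[1] + tt * (p2[1] - p1[1])
  y <- p1[2] + tt * (p2[2] - p1[2])
  r <- floor(y / pixel_size) + 1L
  c_ <- floor(x / pixel_size) + 1L
  if (width_px > 1L) {
    half <- (width_px - 1L) %/% 2L
    offs <- expand.grid(dr = -half:half, dc = -half:half)
    offs <- offs[abs(offs$dr) + abs(offs$dc) <= half, ]
    r <- rep(r, nrow(offs)) + rep(offs$dr, each = length(r))
    c_ <- rep(c_, nrow(offs)) + rep(offs$dc, each = length(c_))
  }
  r <- pmin(pmax(r, 1L), nr)
  c_ <- pmin(pmax(c_, 1L), nc)
  unique((c_ - 1L) * nr + r)
}

image_dims <- function(mesh, pixel_size, pad_um = 1) {
  nr <- ceiling((max(mesh$vertices[, 2]) + pad_um) / pixel_size)
  nc <- ceiling((max(mesh$vertices[, 1]) + pad_um) / pixel_size)
  c(nr, nc)
}

#' Render a mesh to a label image
#'
#' @param mesh an `epi_mesh` with non-negative coordinates.
#' @param pixel_size micrometres per pixel.
#' @param dims optional c(rows, cols); derived from the mesh extent if NULL.
#' @return Integer matrix; cell k (in `names(mesh$cells)` order) has label k,
#'   background 0.
#' @export
render_labels <- function(mesh, pixel_size = 0.5, dims = NULL) {
  if (is.null(dims)) dims <- image_dims(mesh, pixel_size)
  lab <- matrix(0L, dims[1], dims[2])
  for (k in seq_along(mesh$cells)) {
    idx <- rasterise_polygon(mesh_polygon(mesh, k), pixel_size,
                             dims[1], dims[2])
    idx <- idx[lab[idx] == 0L]
    lab[idx] <- k
  }
  lab
}

#' Analytic (pre-noise) junctional intensities painted by the renderer
#'
#' Each shared interface carries base + amplitude * cos 2(theta - phase)
#' averaged over the two adjacent cells' prescribed bipolarity parameters,
#' with theta the interface's directed orientation from AP.
#'
#' @param mesh an `epi_mesh`.
#' @param bipolarity tibble with `cell_id`, `base`, `amplitude`, `phase_deg`
#'   (the prescribed per-cell sampling parameters).
#' @return Tibble with `cell_a`, `cell_b`, `density`.
#' @export
painted_densities <- function(mesh, bipolarity) {
  intf <- mesh_interfaces(mesh)
  j <- stats::setNames(seq_len(nrow(bipolarity)), bipolarity$cell_id)
  theta <- directed_angle_from_ap(intf$x2 - intf$x1, intf$y2 - intf$y1)
  val_of <- function(cid, th) {
    k <- j[cid]
    bipolarity$base[k] + bipolarity$amplitude[k] *
      cos(2 * (th - bipolarity$phase_deg[k]) * pi / 180)
  }
  tibble::tibble(cell_a = intf$cell_a, cell_b = intf$cell_b,
                 density = (val_of(intf$cell_a, theta) +
                              val_of(intf$cell_b, theta)) / 2)
}

#' Render the junctional Myosin II channel of a mesh
#'
#' Paints every shared interface with intensity
#' base + amplitude * cos 2(theta - phase), averaged over the two adjacent
#' cells' prescribed bipolarity parameters (theta is the interface's directed
#' orientation from AP), then adds Gaussian pixel noise, clips at zero and
#' quantises.
#'
#' @param mesh an `epi_mesh`.
#' @param bipolarity tibble with `cell_id`, `base`, `amplitude`, `phase_deg`
#'   (as produced by [simulate_movie()]).
#' @param pixel_size micrometres per pixel.
#' @param dims optional c(rows, cols).
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param bit_depth quantisation depth (values clipped to 2^bit_depth - 1).
#' @param width_px width of the painted junctional band in pixels (the
#'   default 3 px, 1.5 um at 0.5 um/px, spans the boundary pixels of both
#'   adjacent cells, like junctional Myosin in a maximum projection).
#' @param seed optional seed for the noise.
#' @return Numeric matrix of quantised intensities.
#' @export
render_myosin <- function(mesh, bipolarity, pixel_size = 0.5, dims = NULL,
                          noise_sd = 10, bit_depth = 16, width_px = 3L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dims)) dims <- image_dims(mesh, pixel_size)
  img <- matrix(0, dims[1], dims[2])
  intf <- mesh_interfaces(mesh)
  vals <- painted_densities(mesh, bipolarity)$density
  for (i in seq_len(nrow(intf))) {
    val <- vals[i]
    idx <- rasterise_segment(c(intf$x1[i], intf$y1[i]),
                             c(intf$x2[i], intf$y2[i]),
                             pixel_size, dims[1], dims[2], width_px)
    img[idx] <- pmax(img[idx], val)
  }
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img <- pmax(img, 0)
  pmin(round(img), 2^bit_depth - 1)
}

#' Render the membrane (cell outline) channel of a mesh
#'
#' @inheritParams render_myosin
#' @param line_intensity intensity painted on all cell boundaries.
#' @return Numeric matrix.
#' @export
render_membrane <- function(mesh, pixel_size = 0.5, dims = NULL,
                            line_intensity = 180, noise_sd = 5,
                            bit_depth = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dims)) dims <- image_dims(mesh, pixel_size)
  img <- matrix(0, dims[1], dims[2])
  for (k in seq_along(mesh$cells)) {
    cyc <- mesh$cells[[k]]
    v <- mesh$vertices
    for (e in seq_along(cyc)) {
      p1 <- v[cyc[e], ]; p2 <- v[cyc[e %% length(cyc) + 1L], ]
      idx <- rasterise_segment(p1, p2, pixel_size, dims[1], dims[2])
      img[idx] <- line_intensity
    }
  }
  if (noise_sd > 0) img <- img + stats::rnorm(length(img), 0, noise_sd)
  img <- pmax(img, 0)
  pmin(round(img), 2^bit_depth - 1)
}

#' Render a whole movie to TIFF files
#'
#' Writes one label, one membrane and one Myosin TIFF per frame, plus the
#' ground-truth tables and a movie config, into `out_dir`. Label images are
#' written as 16-bit TIFFs (labels must stay below 65536).
#'
#' @param movie an `epi_movie` from [simulate_movie()].
#' @param out_dir output directory (created if missing).
#' @param frames which frames to render (default all).
#' @param noise_sd Myosin channel noise SD.
#' @param seed seed for the rendering noise.
#' @return Invisibly, the directory path.
#' @export
render_movie <- function(movie, out_dir, frames = seq_along(movie$meshes),
                         noise_sd = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ps <- movie$pixel_size_um
  dims <- image_dims(movie$meshes[[frames[1]]], ps)
  for (f in frames) {
    lab <- render_labels(movie$meshes[[f]], ps, dims)
    myo <- render_myosin(movie$meshes[[f]], movie$ground_truth$bipolarity,
                         ps, dims, noise_sd = noise_sd)
    mem <- render_membrane(movie$meshes[[f]], ps, dims)
    tiff::writeTIFF(lab / 65535, file.path(out_dir, sprintf("label_%04d.tif", f)),
                    bits.per.sample = 16L)
    tiff::writeTIFF(myo / 65535, file.path(out_dir, sprintf("myosin_%04d.tif", f)),
                    bits.per.sample = 16L)
    tiff::writeTIFF(mem / 65535, file.path(out_dir, sprintf("membrane_%04d.tif", f)),
                    bits.per.sample = 16L)
  }
  utils::write.csv(movie$ground_truth$strain,
                   file.path(out_dir, "truth_strain.csv"), row.names = FALSE)
  utils::write.csv(movie$ground_truth$swaps,
                   file.path(out_dir, "truth_swaps.csv"), row.names = FALSE)
  utils::write.csv(movie$ground_truth$bipolarity,
                   file.path(out_dir, "truth_bipolarity.csv"), row.names = FALSE)
  cfg <- list(id = movie$id, genotype = movie$genotype,
              pixel_size_um = ps, frame_interval_s =
                if (length(movie$times_min) > 1)
                  diff(movie$times_min[1:2]) * 60 else 30,
              times_min = movie$times_min[frames])
  jsonlite::write_json(cfg, file.path(out_dir, "movie_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a label TIFF written by [render_movie()]
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Read an intensity TIFF written by [render_movie()]
#' @param path TIFF path.
#' @return Numeric intensity matrix (original quantised scale).
#' @export
read_intensity_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  round(m * 65535)
}
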