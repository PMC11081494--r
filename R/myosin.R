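# -- Myosin II channel processing and planar polarity -------------------------

#' Normalise a fluorescence channel against a reference time point
#'
#' Two steps, applied in this order. Background: per frame, pixels with
#' intensity up to that frame's `background_percentile` are set to zero.
#' Histogram stretch: all frames are scaled by the single factor
#' `reference_grey` / P(reference frame, `reference_percentile`), computed on
#' the background-zeroed reference frame, and clipped at `ceiling_grey`.
#' Using one reference time point (rather than per-frame stretching)
#' preserves genuine intensity changes over time; the 200-to-255 headroom
#' leaves a tail for high-value pixels.
#'
#' @param stack a list of numeric matrices (frames), or a single matrix.
#' @param reference_frame index of the reference time point.
#' @param background_percentile percentile zeroed per frame (default 5).
#' @param reference_percentile percentile mapped to `reference_grey`
#'   (default 98.5).
#' @param reference_grey target greyscale value for the reference percentile
#'   (default 200).
#' @param ceiling_grey hard clip after scaling (default 255).
#' @return A list of float matrices (or a single matrix if the input was
#'   one), with attributes `scale_factor` and `reference_frame`.
#' @export
normalise_channel <- function(stack, reference_frame = 1L,
                              background_percentile = 5,
                              reference_percentile = 98.5,
                              reference_grey = 200, ceiling_grey = 255) {
  single <- is.matrix(stack)
  if (single) stack <- list(stack)
  if (reference_frame < 1 || reference_frame > length(stack))
    stop("reference_frame outside the sequence")
  zeroed <- lapply(stack, function(fr) {
    thr <- stats::quantile(fr, background_percentile / 100, names = FALSE)
    fr[fr <= thr] <- 0
    fr
  })
  ref_q <- stats::quantile(zeroed[[reference_frame]],
                           reference_percentile / 100, names = FALSE)
  if (ref_q <= 0) stop("reference frame has no signal above background")
  sc <- reference_grey / ref_q
  out <- lapply(zeroed, function(fr) pmin(fr * sc, ceiling_grey))
  attr(out, "scale_factor") <- sc
  attr(out, "reference_frame") <- reference_frame
  if (single) {
    res <- out[[1]]
    attr(res, "scale_factor") <- sc
    return(res)
  }
  out
}

#' Quantify junctional, vertex and non-junctional Myosin II pools
#'
#' Junctions are 1-pixel-thick lines surrounding each cell (cell pixels with
#' a 4-neighbour of a different label); the value of a shared interface is
#' the average over the two cells' lines. Pixels within
#' `vertex_exclusion_px` of a vertex point are removed from the junctional
#' quantification (vertices are often Myosin-enriched) and form the vertex
#' pool. Non-junctional Myosin is the mean over the remaining pixels of the
#' cell.
#'
#' @param label integer label image (background 0).
#' @param image fluorescence image, same size (typically the output of
#'   [normalise_channel()]).
#' @param vertex_exclusion_px exclusion radius around vertex points, pixels.
#' @return List with `interfaces` (tibble: `cell_a`, `cell_b`, `label_a`,
#'   `label_b`, `density`, `n_pixels`), `cells` (tibble: `cell_id`,
#'   `nonjunctional`, `vertex_pool`, `junctional`).
#' @export
quantify_interface_myosin <- function(label, image, vertex_exclusion_px = 2) {
  stopifnot(all(dim(label) == dim(image)))
  nr <- nrow(label); nc <- ncol(label)
  idx <- which(label > 0)
  r <- ((idx - 1L) %% nr) + 1L
  c_ <- ((idx - 1L) %/% nr) + 1L
  lab <- label[idx]

  shift_lab <- function(dr, dc) {
    rr <- r + dr; cc <- c_ + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out <- integer(length(idx))
    out[ok] <- label[(cc[ok] - 1L) * nr + rr[ok]]
    out
  }
  nb <- cbind(shift_lab(-1, 0), shift_lab(1, 0), shift_lab(0, -1), shift_lab(0, 1))
  differs <- nb != lab
  contour <- rowSums(differs) > 0

  # assign each contour pixel with a positive foreign neighbour to the
  # neighbouring cell seen most often across its 4-neighbourhood
  other <- matrix(ifelse(differs & nb > 0, nb, NA_integer_), ncol = 4)
  pick_other <- function(i) {
    v <- other[i, ]; v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tb <- table(v)
    as.integer(names(tb)[which.max(tb)])
  }
  assigned <- rep(NA_integer_, length(idx))
  cand <- which(contour & rowSums(!is.na(other)) > 0)
  assigned[cand] <- vapply(cand, pick_other, integer(1))

  # vertex exclusion: distance from pixel centres to junction corner points
  jc <- junction_corners(label)
  near_vertex <- rep(FALSE, length(idx))
  if (length(jc$row_px)) {
    px <- c_ - 0.5; py <- r - 0.5
    for (k in seq_along(jc$row_px)) {
      near_vertex <- near_vertex |
        ((px - jc$col_px[k])^2 + (py - jc$row_px[k])^2 <=
           vertex_exclusion_px^2)
    }
  }

  vals <- image[idx]
  usable <- !is.na(assigned) & !near_vertex
  key <- paste(lab[usable], assigned[usable])
  line_mean <- tapply(vals[usable], key, mean)
  line_n <- tapply(vals[usable], key, length)

  pairs <- unique(rbind(
    data.frame(a = pmin(lab[usable], assigned[usable]),
               b = pmax(lab[usable], assigned[usable]))))
  density <- n_pixels <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    k1 <- paste(pairs$a[i], pairs$b[i]); k2 <- paste(pairs$b[i], pairs$a[i])
    d1 <- line_mean[k1]; d2 <- line_mean[k2]
    density[i] <- mean(c(d1, d2), na.rm = TRUE)
    n_pixels[i] <- sum(line_n[k1], line_n[k2], na.rm = TRUE)
  }
  interfaces <- tibble::tibble(
    cell_a = sprintf("L%d", pairs$a), cell_b = sprintf("L%d", pairs$b),
    label_a = pairs$a, label_b = pairs$b,
    density = density, n_pixels = as.integer(n_pixels))

  labs <- sort(unique(lab))
  cells <- dplyr::bind_rows(lapply(labs, function(lb) {
    sel <- lab == lb
    tibble::tibble(
      cell_id = sprintf("L%d", lb),
      nonjunctional = mean(vals[sel & !contour]),
      vertex_pool = if (any(sel & contour & near_vertex))
        mean(vals[sel & contour & near_vertex]) else NA_real_,
      junctional = if (any(sel & usable))
        mean(vals[sel & usable]) else NA_real_)
  }))
  list(interfaces = interfaces, cells = cells)
}

# worker: period-2 Fourier fit of interface densities around one cell.
# endpoints: list of 2x2 matrices (rows = the two endpoints, um);
# densities: numeric; centroid: length-2; S: 2x2 shape tensor.
cell_bipolarity <- function(endpoints, densities, centroid, S) {
  ok <- !is.na(densities)
  if (sum(ok) < 3L)
    return(c(amplitude = NA_real_, phase_deg = NA_real_,
             ap_projected = NA_real_, mean_density = NA_real_))
  endpoints <- endpoints[ok]; densities <- densities[ok]
  Sn <- S / sqrt(max(det(S), .Machine$double.eps))
  Tm <- spd_powm2(Sn, -0.5)                # unstretching transform
  th <- wt <- numeric(length(densities))
  for (i in seq_along(endpoints)) {
    e <- endpoints[[i]]
    p1 <- Tm %*% (e[1, ] - centroid)
    p2 <- Tm %*% (e[2, ] - centroid)
    d <- p2 - p1
    th[i] <- atan2(d[2], d[1])             # direction; period pi below
    wt[i] <- sqrt(sum(d^2))
  }
  X <- cbind(1, cos(2 * th), sin(2 * th))
  fit <- tryCatch(stats::lm.wfit(X, densities, w = wt),
                  error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients))
    return(c(amplitude = NA_real_, phase_deg = NA_real_,
             ap_projected = NA_real_, mean_density = mean(densities)))
  p <- unname(fit$coefficients[2]); q <- unname(fit$coefficients[3])
  amp <- sqrt(p^2 + q^2)
  phase <- (atan2(q, p) / 2 * 180 / pi) %% 180
  c(amplitude = amp, phase_deg = phase,
    ap_projected = project_bipolarity(amp, phase),
    mean_density = mean(densities))
}

#' Bipolarity (period-2 planar polarity) of junctional Myosin II
#'
#' For each cell with at least 3 interfaces of defined density, the cell
#' outline is first unstretched by the inverse square root of its
#' (determinant-normalised) shape tensor, eliminating the bias that unequal
#' interface lengths of elongated cells would introduce. Interface densities
#' are then fitted, weighted by unstretched interface length, with the
#' period-2 Fourier model a0 + A cos 2(theta - phi) in the interface
#' direction theta. The amplitude A is the average size of the two opposite
#' Myosin peaks; the phase phi (degrees from AP, in [0, 180)) is the
#' direction of the enriched junctions (90 = DV-oriented junctions, the
#' polarised configuration that drives convergent extension).
#'
#' @param geometry either an `epi_mesh` or an `epi_frame` (from
#'   [build_frame()]).
#' @param densities per-interface density tibble with `cell_a`, `cell_b`,
#'   `density` (e.g. from [quantify_interface_myosin()], or
#'   `interfaces_table` joined to painted values).
#' @param cells optional subset of cell ids.
#' @return Tibble with `cell_id`, `amplitude`, `phase_deg`, `ap_projected`,
#'   `mean_density`, `n_interfaces`.
#' @export
bipolarity <- function(geometry, densities, cells = NULL) {
  if (inherits(geometry, "epi_mesh")) {
    intf <- mesh_interfaces(geometry)
    geom_cells <- mesh_cells(geometry)
    shape_of <- function(id) poly_second_moment(mesh_polygon(geometry, id))
  } else if (inherits(geometry, "epi_frame")) {
    intf <- geometry$interfaces
    geom_cells <- geometry$cells
    shape_of <- function(id) {
      row <- geom_cells[geom_cells$cell_id == id, ]
      matrix(c(row$sxx, row$sxy, row$sxy, row$syy), 2, 2)
    }
  } else stop("geometry must be an epi_mesh or epi_frame")
  intf$key <- pair_key(intf$cell_a, intf$cell_b)
  densities$key <- pair_key(densities$cell_a, densities$cell_b)
  intf <- dplyr::left_join(intf, densities[, c("key", "density")], by = "key")

  ids <- if (is.null(cells)) geom_cells$cell_id else cells
  rows <- lapply(ids, function(id) {
    sel <- intf$cell_a == id | intf$cell_b == id
    sub <- intf[sel & !is.na(intf$x1), ]
    cen <- unlist(geom_cells[geom_cells$cell_id == id, c("cx", "cy")])
    eps <- lapply(seq_len(nrow(sub)), function(i)
      rbind(c(sub$x1[i], sub$y1[i]), c(sub$x2[i], sub$y2[i])))
    res <- cell_bipolarity(eps, sub$density, cen, shape_of(id))
    tibble::tibble(cell_id = id, amplitude = res[["amplitude"]],
                   phase_deg = res[["phase_deg"]],
                   ap_projected = res[["ap_projected"]],
                   mean_density = res[["mean_density"]],
                   n_interfaces = sum(!is.na(sub$density)))
  })
  dplyr::bind_rows(rows)
}

#' Project a bipolarity measure on the AP axis
#'
#' amplitude * cos 2(phase - 90 degrees): positive when the Myosin peaks sit
#' on the DV-oriented junctions (phase 90), i.e. the polarisation that
#' produces AP-productive intercalation; negative when AP-oriented junctions
#' are enriched; zero at 45 degrees.
#'
#' @param amplitude bipolarity amplitude (f.i. units).
#' @param phase_deg enrichment direction in degrees from AP.
#' @return Signed projected bipolarity.
#' @export
project_bipolarity <- function(amplitude, phase_deg) {
  amplitude * cos(2 * (phase_deg - 90) * pi / 180)
}

#' Displace sampling positions to register a delayed channel
#'
#' Channels imaged sequentially are slightly out of register; positions
#' derived from the membrane channel are advanced by a fraction of their
#' predicted inter-frame flow (the channel time offset divided by the frame
#' interval), optionally composing the focal cell's shape strain in the same
#' fractional manner.
#'
#' @param points n x 2 matrix of positions (um).
#' @param flow n x 2 matrix of predicted inter-frame displacements (um).
#' @param offset_fraction channel offset / frame interval, in [0, 1].
#' @param shape_strain optional 2x2 strain tensor over the frame interval
#'   (dimensionless).
#' @param centroid centre for applying `shape_strain`.
#' @return n x 2 matrix of displaced positions.
#' @export
register_channels <- function(points, flow, offset_fraction,
                              shape_strain = NULL, centroid = NULL) {
  stopifnot(offset_fraction >= 0, offset_fraction <= 1)
  out <- points + offset_fraction * flow
  if (!is.null(shape_strain)) {
    if (is.null(centroid)) centroid <- colMeans(points)
    Fm <- diag(2) + offset_fraction * shape_strain
    out <- sweep(sweep(out, 2, centroid) %*% t(Fm), 2, centroid, `+`)
  }
  out
}

#' Bilinear sampling of an image at micrometre positions
#'
#' @param image numeric matrix (rows = DV, cols = AP).
#' @param points n x 2 matrix of (x, y) positions in micrometres.
#' @param pixel_size micrometres per pixel.
#' @return Numeric vector of sampled intensities (NA outside the image).
#' @export
sample_bilinear <- function(image, points, pixel_size = 0.5) {
  cc <- points[, 1] / pixel_size + 0.5
  rr <- points[, 2] / pixel_size + 0.5
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  nr <- nrow(image); nc <- ncol(image)
  get <- function(r, c_) {
    ok <- r >= 1 & r <= nr & c_ >= 1 & c_ <= nc
    out <- rep(NA_real_, length(r))
    out[ok] <- image[(c_[ok] - 1) * nr + r[ok]]
    out
  }
  v00 <- get(r0, c0); v01 <- get(r0, c0 + 1)
  v10 <- get(r0 + 1, c0); v11 <- get(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}
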