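# -- strain rates and shape metrics ------------------------------------------
#
# All strain rates are symmetric 2x2 rate-of-deformation tensors in the
# (AP, DV) frame, in proportion per minute (pp/min). Rates use a central
# window of +/- `window` frames (2 frames = 1 minute each side at 30-s
# sampling). Undefined values propagate as NA, never as zero.

#' Project a symmetric strain tensor on an embryonic axis
#'
#' Returns u' E u for the unit axis vector: `exx` on AP, `eyy` on DV, or any
#' angle in degrees from AP.
#'
#' @param exx,exy,eyy tensor components (vectorised).
#' @param axis "AP", "DV", or a numeric angle in degrees from the AP axis.
#' @return Projected strain rate (pp/min).
#' @export
project_strain <- function(exx, exy, eyy, axis = "AP") {
  if (is.character(axis)) {
    axis <- match.arg(toupper(axis), c("AP", "DV"))
    theta <- if (axis == "AP") 0 else 90
  } else theta <- axis
  th <- theta * pi / 180
  u <- c(cos(th), sin(th))
  u[1]^2 * exx + 2 * u[1] * u[2] * exy + u[2]^2 * eyy
}

#' Tissue strain rates from local centroid flow
#'
#' For each cell and frame, fits a linear velocity field v = c + L x by
#' unweighted least squares over the domain of the focal cell plus its
#' first-ring neighbours, using central-difference centroid velocities over
#' +/- `window` frames. The tissue strain rate is the symmetric part of L.
#' Cells with fewer than 3 usable neighbours, or frames where the window is
#' truncated, give NA.
#'
#' @param movie an `epi_movie`.
#' @param window half-window in frames (default 2, i.e. 1 minute at 30-s
#'   sampling).
#' @param cells optional character vector restricting the focal cells.
#' @return Tibble with `frame`, `time_min`, `cell_id`, `txx`, `txy`, `tyy`.
#' @export
tissue_strain_rates <- function(movie, window = 2L, cells = NULL) {
  nF <- length(movie$meshes)
  cent_mat <- lapply(movie$meshes, function(m) {
    d <- mesh_cells(m)
    mm <- cbind(d$cx, d$cy); rownames(mm) <- d$cell_id; mm
  })
  nbrs <- lapply(movie$meshes, mesh_neighbours)
  out <- vector("list", nF)
  for (f in seq_len(nF)) {
    ids <- rownames(cent_mat[[f]])
    focal <- if (is.null(cells)) ids else intersect(ids, cells)
    res <- matrix(NA_real_, length(focal), 3,
                  dimnames = list(focal, c("txx", "txy", "tyy")))
    if (f - window >= 1 && f + window <= nF) {
      m0 <- cent_mat[[f - window]]; m1 <- cent_mat[[f + window]]
      common <- intersect(rownames(m0), rownames(m1))
      elapsed <- movie$times_min[f + window] - movie$times_min[f - window]
      vel <- (m1[common, , drop = FALSE] - m0[common, , drop = FALSE]) / elapsed
      pos <- cent_mat[[f]]
      for (id in focal) {
        nb <- intersect(nbrs[[f]][[id]], common)
        if (length(nb) < 3L || !(id %in% common)) next
        dom <- c(id, nb)
        X <- cbind(1, pos[dom, , drop = FALSE])
        V <- vel[dom, , drop = FALSE]
        cf <- tryCatch(qr.solve(X, V), error = function(e) NULL)
        if (is.null(cf)) next
        L <- t(cf[2:3, , drop = FALSE])  # rows: velocity comp, cols: x,y
        res[id, ] <- c(L[1, 1], (L[1, 2] + L[2, 1]) / 2, L[2, 2])
      }
    }
    out[[f]] <- tibble::tibble(frame = f, time_min = movie$times_min[f],
                               cell_id = focal, txx = unname(res[, 1]),
                               txy = unname(res[, 2]), tyy = unname(res[, 3]))
  }
  dplyr::bind_rows(out)
}

# shape strain rate from moment tensors alone (no vertex correspondence):
# project S1 and S2 on the shared compromise frame W (eigenvectors of
# S1 + S2) and take per-axis log ratios. Exactly zero for rigid rotations
# (the projections are symmetric about the half-angle frame) and exact for
# stretches along the shape's principal axes.
shape_log_rate <- function(S1, S2, elapsed) {
  W <- eigen(S1 + S2, symmetric = TRUE)$vectors
  p1 <- pmax(diag(t(W) %*% S1 %*% W), .Machine$double.eps)
  p2 <- pmax(diag(t(W) %*% S2 %*% W), .Machine$double.eps)
  (W %*% diag(log(p2 / p1) / 2, 2) %*% t(W)) / elapsed
}

# shape strain rate from corresponding vertices: least-squares linear map of
# centred source vertices onto centred target vertices, then the matrix log
# of its right stretch (rotation discarded). Exact for affine deformations.
shape_vertex_rate <- function(P1, P2, elapsed) {
  X <- sweep(P1, 2, colMeans(P1))
  Y <- sweep(P2, 2, colMeans(P2))
  XtX <- t(X) %*% X
  if (abs(det(XtX)) < 1e-9) return(NULL)     # collinear: no unique map
  A <- t(solve(XtX, t(X) %*% Y))
  U <- spd_powm2(t(A) %*% A, 0.5)
  spd_logm2(U) / elapsed
}

#' Cell-shape strain rates
#'
#' For each cell and frame, finds the best linear map carrying the cell's
#' outline at frame t - window onto the one at t + window and returns the
#' matrix logarithm of its symmetric (right) stretch divided by the elapsed
#' time; the rotation part of the map is discarded, so rigid rotation of an
#' unchanged shape gives a zero tensor. When the cell's vertices correspond
#' across the window (tracked meshes) the map is the least-squares fit over
#' vertices, exact for affine deformations; otherwise it falls back to
#' mapping the cell's second-moment (shape) tensors.
#'
#' @inheritParams tissue_strain_rates
#' @return Tibble with `frame`, `time_min`, `cell_id`, `cxx`, `cxy`, `cyy`.
#' @export
cell_shape_strain_rates <- function(movie, window = 2L, cells = NULL) {
  nF <- length(movie$meshes)
  out <- vector("list", nF)
  for (f in seq_len(nF)) {
    ids <- names(movie$meshes[[f]]$cells)
    focal <- if (is.null(cells)) ids else intersect(ids, cells)
    res <- matrix(NA_real_, length(focal), 3,
                  dimnames = list(focal, c("cxx", "cxy", "cyy")))
    if (f - window >= 1 && f + window <= nF) {
      elapsed <- movie$times_min[f + window] - movie$times_min[f - window]
      m0 <- movie$meshes[[f - window]]; m1 <- movie$meshes[[f + window]]
      for (id in focal) {
        cyc0 <- m0$cells[[id]]; cyc1 <- m1$cells[[id]]
        if (is.null(cyc0) || is.null(cyc1)) next
        common <- intersect(cyc0, cyc1)
        E <- NULL
        if (length(common) >= 3L) {
          E <- shape_vertex_rate(m0$vertices[common, , drop = FALSE],
                                 m1$vertices[common, , drop = FALSE],
                                 elapsed)
        }
        if (is.null(E)) {
          S1 <- tryCatch(poly_second_moment(
            m0$vertices[cyc0, , drop = FALSE]), error = function(e) NULL)
          S2 <- tryCatch(poly_second_moment(
            m1$vertices[cyc1, , drop = FALSE]), error = function(e) NULL)
          if (is.null(S1) || is.null(S2)) next
          E <- shape_log_rate(S1, S2, elapsed)
        }
        res[id, ] <- c(E[1, 1], (E[1, 2] + E[2, 1]) / 2, E[2, 2])
      }
    }
    out[[f]] <- tibble::tibble(frame = f, time_min = movie$times_min[f],
                               cell_id = focal, cxx = unname(res[, 1]),
                               cxy = unname(res[, 2]), cyy = unname(res[, 3]))
  }
  dplyr::bind_rows(out)
}

#' Area strain rates
#'
#' d(ln area)/dt by central difference over +/- `window` frames.
#'
#' @inheritParams tissue_strain_rates
#' @return Tibble with `frame`, `time_min`, `cell_id`, `area_rate` (pp/min).
#' @export
area_strain_rates <- function(movie, window = 2L) {
  d <- cells_table(movie)
  d <- d[order(d$cell_id, d$frame), ]
  by_cell <- split(d, d$cell_id)
  out <- lapply(by_cell, function(g) {
    g$area_rate <- rate_of_change(g$area_um2, g$time_min, window,
                                  transform = log)
    g[, c("frame", "time_min", "cell_id", "area_rate")]
  })
  dplyr::bind_rows(out)
}

#' Rate of change of a per-frame series
#'
#' Central difference from `window` time points before to `window` after the
#' point in question: (x[t+w] - x[t-w]) / elapsed minutes. Ends of the series
#' where the window is truncated give NA.
#'
#' @param x numeric series sampled at `times_min`.
#' @param times_min sample times in minutes (regular spacing assumed).
#' @param window half-window in samples (default 2).
#' @param transform optional function applied to `x` first (e.g. `log` for
#'   proportional rates).
#' @return Numeric vector of per-minute rates, same length as `x`.
#' @export
rate_of_change <- function(x, times_min, window = 2L, transform = identity) {
  n <- length(x)
  y <- transform(x)
  out <- rep(NA_real_, n)
  if (n > 2 * window) {
    i <- seq.int(window + 1L, n - window)
    out[i] <- (y[i + window] - y[i - window]) /
      (times_min[i + window] - times_min[i - window])
  }
  out
}

#' Combine strain-rate tables into the tissue = cell shape + intercalation
#' decomposition
#'
#' Joins tissue and cell-shape strain-rate tables and computes the
#' intercalation strain rate as their component-wise difference, so the
#' decomposition identity holds exactly by construction.
#'
#' @param tissue output of [tissue_strain_rates()].
#' @param cell_shape output of [cell_shape_strain_rates()].
#' @return Tibble with tissue (`txx`..), cell shape (`cxx`..) and
#'   intercalation (`ixx`, `ixy`, `iyy`) components.
#' @export
strain_decomposition <- function(tissue, cell_shape) {
  d <- dplyr::inner_join(tissue, cell_shape,
                         by = c("frame", "time_min", "cell_id"))
  d$ixx <- d$txx - d$cxx
  d$ixy <- d$txy - d$cxy
  d$iyy <- d$tyy - d$cyy
  d
}

# -- cell shape descriptors ---------------------------------------------------

#' Moment ellipses of cells
#'
#' Fits the area-equivalent ellipse to each cell polygon via its second
#' moments. Semi-axes satisfy a >= b; orientation is the directed angle of
#' the long axis from AP in [0, 180) and is flagged undefined for isotropic
#' shapes.
#'
#' @param mesh an `epi_mesh`, a single 2x2 shape tensor, a list of such
#'   tensors, or a tibble with columns `sxx`, `sxy`, `syy` (and optionally
#'   `cell_id`).
#' @return Tibble with `cell_id`, `a_um`, `b_um`, `theta_deg`,
#'   `elongation` ((a-b)/(a+b)), `isotropic`.
#' @export
shape_ellipses <- function(mesh) {
  if (inherits(mesh, "epi_mesh")) {
    ids <- names(mesh$cells)
    S <- vapply(ids, function(id) {
      s <- poly_second_moment(mesh_polygon(mesh, id))
      c(s[1, 1], s[1, 2], s[2, 2])
    }, numeric(3))
    sxx <- S[1, ]; sxy <- S[2, ]; syy <- S[3, ]
  } else if (is.matrix(mesh) && all(dim(mesh) == c(2, 2))) {
    ids <- "cell"; sxx <- mesh[1, 1]; sxy <- mesh[1, 2]; syy <- mesh[2, 2]
  } else if (is.data.frame(mesh)) {
    ids <- if ("cell_id" %in% names(mesh)) mesh$cell_id else
      as.character(seq_len(nrow(mesh)))
    sxx <- mesh$sxx; sxy <- mesh$sxy; syy <- mesh$syy
  } else {
    ids <- if (is.null(names(mesh))) as.character(seq_along(mesh)) else
      names(mesh)
    sxx <- vapply(mesh, function(s) s[1, 1], numeric(1))
    sxy <- vapply(mesh, function(s) s[1, 2], numeric(1))
    syy <- vapply(mesh, function(s) s[2, 2], numeric(1))
  }
  # closed-form eigen-decomposition of the symmetric 2x2 tensors
  tr <- sxx + syy
  disc <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  a <- 2 * sqrt(pmax(l1, 0)); b <- 2 * sqrt(pmax(l2, 0))
  iso <- (a - b) < 1e-9 * (a + b)
  theta <- (0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi) %% 180
  theta[iso] <- NA_real_
  tibble::tibble(cell_id = ids, a_um = a, b_um = b, theta_deg = theta,
                 elongation = ifelse(a + b > 0, (a - b) / (a + b), 0),
                 isotropic = iso)
}

#' Cell orientation from the AP axis
#'
#' The acute angle between a cell's long axis and the AP axis, in [0, 90]
#' degrees; NA for isotropic cells.
#'
#' @param ellipses output of [shape_ellipses()] (or any tibble with
#'   `theta_deg` and `isotropic`).
#' @return Numeric vector of angles in degrees.
#' @export
cell_orientation <- function(ellipses) {
  ifelse(ellipses$isotropic, NA_real_,
         pmin(ellipses$theta_deg %% 180, 180 - ellipses$theta_deg %% 180))
}

#' Axial shape elongation
#'
#' A combined measure of cell elongation and orientation:
#' e * (-cos 2 theta), with e = (a - b)/(a + b) and theta the directed
#' long-axis angle from AP. It is 1 for cells strongly elongated in DV, -1
#' for cells strongly elongated in AP, and 0 for isotropic cells or cells
#' elongated at 45 degrees to the embryonic axes.
#'
#' @param ellipses output of [shape_ellipses()].
#' @return Numeric vector in [-1, 1].
#' @export
axial_shape_elongation <- function(ellipses) {
  e <- ellipses$elongation
  th <- ellipses$theta_deg
  ifelse(e <= .Machine$double.eps * 10 | ellipses$isotropic, 0,
         e * (-cos(2 * th * pi / 180)))
}
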