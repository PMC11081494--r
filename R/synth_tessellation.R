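# -- synthetic tessellations --------------------------------------------------

#' Generate a polygonal cell tessellation
#'
#' Builds a hexagonal lattice of cells (flat-top hexagons) and perturbs the
#' shared vertices with Gaussian jitter, giving an irregular but valid
#' tessellation: every interior cell keeps six neighbours, vertices are shared
#' where three cells meet, and polygons stay simple for the jitter levels
#' used here. The midline of the emulated embryo lies at y = 0 with the
#' tissue occupying y >= 0 (+y away from the midline, +x toward posterior).
#'
#' @param n_cells requested number of cells (>= 4); rounded up to a full
#'   `n_col` x `n_row` grid.
#' @param mean_diameter_um cell diameter (flat-to-flat), micrometres.
#' @param jitter vertex jitter as a fraction of the cell diameter
#'   (displacements are capped to keep polygons simple).
#' @param seed optional integer seed for reproducibility.
#' @param n_col,n_row optional explicit grid dimensions (override `n_cells`).
#' @return An `epi_mesh`.
#' @examples
#' m <- generate_tessellation(49, jitter = 0.1, seed = 1)
#' @export
generate_tessellation <- function(n_cells = 180, mean_diameter_um = 12,
                                  jitter = 0.15, seed = NULL,
                                  n_col = NULL, n_row = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_col) || is.null(n_row)) {
    if (n_cells < 4) stop("n_cells must be >= 4")
    n_col <- max(2L, ceiling(sqrt(n_cells * 1.2)))
    n_row <- max(2L, ceiling(n_cells / n_col))
  }
  if (mean_diameter_um <= 0) stop("mean_diameter_um must be positive")
  # pointy-top hexagons: vertical (DV-oriented) junctions exist, as in the
  # germband; flat-to-flat = sqrt(3) R = mean diameter
  R <- mean_diameter_um / sqrt(3)
  dx <- sqrt(3) * R
  dy <- 1.5 * R
  corner_ang <- (0:5) * pi / 3 + pi / 6

  verts <- list(); vkey <- character(0)
  cells <- vector("list", n_col * n_row)
  id <- character(n_col * n_row)
  k <- 0L
  vert_env <- new.env(hash = TRUE, parent = emptyenv())
  vmat <- matrix(NA_real_, n_col * n_row * 6, 2)
  nv <- 0L
  for (j in seq_len(n_row)) {
    for (i in seq_len(n_col)) {
      k <- k + 1L
      cx <- (i - 1) * dx + ifelse(j %% 2 == 0, dx / 2, 0) + dx / 2
      cy <- (j - 1) * dy + R
      px <- cx + R * cos(corner_ang)
      py <- cy + R * sin(corner_ang)
      idx <- integer(6)
      for (c6 in 1:6) {
        key <- sprintf("%.4f_%.4f", px[c6], py[c6])
        hit <- vert_env[[key]]
        if (is.null(hit)) {
          nv <- nv + 1L
          vmat[nv, ] <- c(px[c6], py[c6])
          vert_env[[key]] <- nv
          hit <- nv
        }
        idx[c6] <- hit
      }
      cells[[k]] <- idx
      id[k] <- sprintf("c%04d", k)
    }
  }
  vmat <- vmat[seq_len(nv), , drop = FALSE]
  if (jitter > 0) {
    disp <- matrix(stats::rnorm(2 * nv, sd = jitter * mean_diameter_um), nv, 2)
    nrm <- sqrt(rowSums(disp^2))
    cap <- 0.35 * R
    scale <- ifelse(nrm > cap, cap / nrm, 1)
    vmat <- vmat + disp * scale
  }
  names(cells) <- id
  epi_mesh(vmat, cells)
}
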