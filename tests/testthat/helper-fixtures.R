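# Geometry and mesh fixtures built in code.

# axis-aligned rectangle polygon (CCW)
make_rect <- function(cx, cy, w, h) {
  cbind(cx + c(-w, w, w, -w) / 2, cy + c(-h, -h, h, h) / 2)
}

# n-gon approximating an ellipse with semi-axes a, b, long axis at theta_deg
make_ellipse_poly <- function(a, b, theta_deg = 0, n = 64,
                              centre = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xy <- cbind(a * cos(t), b * sin(t))
  th <- theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(xy %*% t(R), 2, centre, `+`)
}

# a movie whose frames are explicit linear transforms of a base mesh
transform_movie <- function(mesh, maps, times_min) {
  meshes <- lapply(maps, function(A) {
    epi_mesh(mesh$vertices %*% t(A), mesh$cells)
  })
  epi_movie(meshes, times_min)
}

rot2 <- function(theta_rad) {
  matrix(c(cos(theta_rad), sin(theta_rad),
           -sin(theta_rad), cos(theta_rad)), 2, 2)
}

# unordered pair key for comparing interface / event tables
ukey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# brute-force count of touching label pairs from pixel 4-adjacency
brute_force_adjacency <- function(label) {
  pairs <- character(0)
  nr <- nrow(label); nc <- ncol(label)
  for (r in seq_len(nr)) for (c_ in seq_len(nc)) {
    a <- label[r, c_]
    if (a == 0) next
    if (r < nr) {
      b <- label[r + 1, c_]
      if (b > 0 && b != a) pairs <- c(pairs, ukey(a, b))
    }
    if (c_ < nc) {
      b <- label[r, c_ + 1]
      if (b > 0 && b != a) pairs <- c(pairs, ukey(a, b))
    }
  }
  unique(pairs)
}

# rectangular grid mesh of s x s square cells (n_col x n_row), origin (0,0)
make_grid_mesh <- function(n_col, n_row, s = 8) {
  vid <- function(i, j) (j - 1L) * (n_col + 1L) + i  # i: x index, j: y index
  verts <- as.matrix(expand.grid(x = (0:n_col) * s, y = (0:n_row) * s))
  cells <- list()
  for (j in seq_len(n_row)) for (i in seq_len(n_col)) {
    cells[[sprintf("g%02d_%02d", i, j)]] <-
      c(vid(i, j), vid(i + 1, j), vid(i + 1, j + 1), vid(i, j + 1))
  }
  epi_mesh(verts, cells)
}

# interior (non-boundary) cell ids of a mesh
interior_cells <- function(mesh) {
  setdiff(names(mesh$cells), mesh_boundary_cells(mesh))
}
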