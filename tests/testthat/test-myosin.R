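test_that("channel normalisation zeroes background and anchors the reference
           percentile", {
  set.seed(4)
  ref <- matrix(stats::rgamma(64 * 64, shape = 2, scale = 30), 64)
  other <- ref * 0.6
  out <- normalise_channel(list(other, ref), reference_frame = 2)
  expect_equal(stats::quantile(out[[2]], 0.985, names = FALSE), 200)
  # background step: lowest 5% of each frame at zero
  expect_gte(mean(out[[1]] == 0), 0.05)
  # monotone: order of unclipped pixels preserved
  v_in <- as.vector(ref); v_out <- as.vector(out[[2]])
  mid <- v_in > stats::quantile(v_in, 0.1) & v_out < 255
  expect_equal(order(v_in[mid]), order(v_out[mid]))
  # ceiling clip
  expect_lte(max(out[[2]]), 255)

  # idempotence on the unclipped range
  twice <- normalise_channel(out, reference_frame = 2)
  expect_equal(twice[[2]][out[[2]] < 255], out[[2]][out[[2]] < 255])
})

test_that("degenerate channels are rejected or zeroed", {
  flat <- matrix(7, 16, 16)
  expect_error(normalise_channel(flat), "signal")
  set.seed(1)
  ok <- matrix(stats::rgamma(256, 2, 1), 16)
  out <- normalise_channel(list(flat, ok), reference_frame = 2)
  expect_true(all(out[[1]] == 0))  # constant frame: everything <= its P5
})

test_that("interface quantification reads painted densities and ignores
           vertex disks", {
  m <- generate_tessellation(36, jitter = 0.1, seed = 21)
  lab <- render_labels(m, 0.5)
  bip <- tibble::tibble(cell_id = names(m$cells), base = 120,
                        amplitude = 0, phase_deg = 0)
  img <- render_myosin(m, bip, 0.5, dims = dim(lab), noise_sd = 0)
  q <- quantify_interface_myosin(lab, img, 2)
  # interior interfaces painted at a constant 120 are read back exactly
  inner <- match(interior_cells(m), names(m$cells))
  keep <- q$interfaces$label_a %in% inner & q$interfaces$label_b %in% inner
  expect_true(any(keep))
  expect_equal(q$interfaces$density[keep],
               rep(120, sum(keep)), tolerance = 1e-9)

  # bright disks of radius 2 px at the vertices change nothing
  img2 <- img
  jc <- epimorph:::junction_corners(lab)
  for (k in seq_along(jc$row_px)) {
    rr <- round(jc$row_px[k]) + (-2:2); cc <- round(jc$col_px[k]) + (-2:2)
    for (r in rr) for (c_ in cc) {
      if (r >= 1 && r <= nrow(img2) && c_ >= 1 && c_ <= ncol(img2) &&
          (r - 0.5 - jc$row_px[k])^2 + (c_ - 0.5 - jc$col_px[k])^2 <= 4)
        img2[r, c_] <- 5000
    }
  }
  q2 <- quantify_interface_myosin(lab, img2, 2)
  expect_equal(q2$interfaces$density[keep], q$interfaces$density[keep])
})

test_that("bipolarity on a regular hexagon recovers a painted cosine law", {
  # central cell of a honeycomb patch; interface orientations 30/90/150
  m <- generate_tessellation(n_col = 3, n_row = 3, mean_diameter_um = 12,
                             jitter = 0, seed = 1)
  centre <- interior_cells(m)[1]
  intf <- mesh_interfaces(m)
  th <- directed_angle_from_ap(intf$x2 - intf$x1, intf$y2 - intf$y1)
  dens <- tibble::tibble(cell_a = intf$cell_a, cell_b = intf$cell_b,
                         density = 100 + 40 * cos(2 * (th - 90) * pi / 180))
  bp <- bipolarity(m, dens, cells = centre)
  # dense-sampling Fourier oracle of I(theta) = 100 + 40 cos 2(theta - 90):
  # amplitude 40, phase 90
  expect_equal(bp$amplitude, 40, tolerance = 0.05)
  expect_equal(bp$phase_deg, 90, tolerance = 2 / 90)
  expect_equal(bp$ap_projected, bp$amplitude)

  # uniform densities: amplitude zero
  dens0 <- dens; dens0$density <- 77
  bp0 <- bipolarity(m, dens0, cells = centre)
  expect_lt(bp0$amplitude, 1e-9)

  # amplitude invariant under adding a constant
  densc <- dens; densc$density <- densc$density + 55
  bpc <- bipolarity(m, densc, cells = centre)
  expect_equal(bpc$amplitude, bp$amplitude, tolerance = 1e-9)
  expect_equal(bpc$phase_deg, bp$phase_deg, tolerance = 1e-9)
})

test_that("unstretching removes the geometric bias of elongated cells and
           phase rotates with the cell", {
  m <- generate_tessellation(n_col = 3, n_row = 3, mean_diameter_um = 12,
                             jitter = 0, seed = 1)
  centre <- interior_cells(m)[1]
  # stretch the whole patch 3x along DV: uniform densities must still give
  # (near) zero amplitude after unstretching
  ms <- epi_mesh(m$vertices %*% diag(c(1, 3)), m$cells)
  intf <- mesh_interfaces(ms)
  dens <- tibble::tibble(cell_a = intf$cell_a, cell_b = intf$cell_b,
                         density = 100)
  bp <- bipolarity(ms, dens, cells = centre)
  expect_lt(bp$amplitude, 0.05 * 100)
  # densities painted from the pre-stretch cosine law are recovered because
  # unstretching undoes the deformation of the hexagon
  orig <- mesh_interfaces(m)
  th_orig <- directed_angle_from_ap(orig$x2 - orig$x1, orig$y2 - orig$y1)
  key_orig <- ukey(orig$cell_a, orig$cell_b)
  th_of <- stats::setNames(th_orig, key_orig)
  dens2 <- tibble::tibble(
    cell_a = intf$cell_a, cell_b = intf$cell_b,
    density = 100 + 40 * cos(2 * (th_of[ukey(intf$cell_a, intf$cell_b)] - 90) *
                               pi / 180))
  bp2 <- bipolarity(ms, dens2, cells = centre)
  expect_equal(bp2$amplitude, 40, tolerance = 0.05)
  expect_equal(bp2$phase_deg, 90, tolerance = 2 / 90)

  # rotating the cell and its densities together rotates the phase
  mr <- epi_mesh(m$vertices %*% t(rot2(30 * pi / 180)), m$cells)
  intr <- mesh_interfaces(mr)
  thr <- directed_angle_from_ap(intr$x2 - intr$x1, intr$y2 - intr$y1)
  densr <- tibble::tibble(cell_a = intr$cell_a, cell_b = intr$cell_b,
                          density = 100 + 40 * cos(2 * (thr - 120) * pi / 180))
  bpr <- bipolarity(mr, densr, cells = centre)
  expect_equal(bpr$phase_deg, 120, tolerance = 2 / 120)
})

test_that("AP projection of bipolarity follows its sign convention", {
  expect_equal(project_bipolarity(40, 90), 40)
  expect_equal(project_bipolarity(40, 45), 0, tolerance = 1e-12)
  expect_equal(project_bipolarity(40, 0), -40)
  expect_equal(project_bipolarity(40, 135), 0, tolerance = 1e-12)
})

test_that("channel registration displaces sampling points fractionally", {
  pts <- cbind(stats::runif(20, 2, 8), stats::runif(20, 2, 8))
  flow <- matrix(rep(c(1.2, -0.6), each = 20), ncol = 2)
  expect_equal(register_channels(pts, flow, 0), pts)
  expect_equal(register_channels(pts, flow, 0.5),
               pts + 0.5 * flow[1, ][col(pts)])
  expect_equal(register_channels(pts, flow, 1), pts + flow)
  # with a shape strain applied in the same fractional manner
  E <- matrix(c(0.1, 0, 0, -0.1), 2, 2)
  ctr <- c(5, 5)
  got <- register_channels(pts, flow * 0, 0.5, shape_strain = E,
                           centroid = ctr)
  want <- sweep(sweep(pts, 2, ctr) %*% t(diag(2) + 0.5 * E), 2, ctr, `+`)
  expect_equal(got, want)
})

test_that("bilinear sampling interpolates a linear image exactly", {
  img <- outer(1:20, 1:30, function(r, c_) 2 * r + 3 * c_)
  pts <- cbind(stats::runif(50, 1, 13), stats::runif(50, 1, 8))  # um at 0.5
  got <- sample_bilinear(img, pts, 0.5)
  want <- 2 * (pts[, 2] / 0.5 + 0.5) + 3 * (pts[, 1] / 0.5 + 0.5)
  expect_equal(got, want)
})
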