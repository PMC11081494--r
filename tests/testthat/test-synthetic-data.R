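test_that("zero-jitter tessellation is a regular honeycomb", {
  m <- generate_tessellation(49, jitter = 0, seed = 1)
  intf <- mesh_interfaces(m)
  nb <- mesh_neighbours(m)
  for (id in interior_cells(m)) {
    expect_length(nb[[id]], 6L)
    expect_length(m$cells[[id]], 6L)
  }
  expect_equal(stats::sd(intf$length_um), 0, tolerance = 1e-9)
  # all cells have the hexagon area for a 12-um flat-to-flat hexagon
  expect_equal(mesh_cells(m)$area_um2,
               rep(3 * sqrt(3) / 2 * (12 / sqrt(3))^2, length(m$cells)),
               tolerance = 1e-9)
})

test_that("tessellation is reproducible and Euler-consistent under jitter", {
  m1 <- generate_tessellation(200, jitter = 0.2, seed = 42)
  m2 <- generate_tessellation(200, jitter = 0.2, seed = 42)
  expect_identical(m1, m2)
  nb <- mesh_neighbours(m1)
  inner <- interior_cells(m1)
  expect_equal(mean(lengths(nb[inner])), 6, tolerance = 0.1 / 6)
  expect_true(all(mesh_cells(m1)$area_um2 > 0))
  # vertices are shared: junction vertices used by exactly >= 3 cells exist
  expect_gt(nrow(mesh_junction_vertices(m1)), 0)
})

test_that("flow specs report the prescribed strain fields", {
  fl <- flow_dv_pull(rate = 0.02, decay_um = 50, t_on = -Inf, t_off = Inf,
                     ramp_min = 0)
  ts <- flow_true_strain(fl, rbind(c(0, 0), c(0, 50)), t = 0)
  expect_equal(ts$eyy[1], 0.02)
  expect_equal(ts$eyy[2], 0.02 / exp(1))   # 1/e at one decay length
  expect_equal(ts$exx, c(0, 0))

  af <- flow_affine(matrix(c(0.02, 0, 0, -0.02), 2, 2))
  ts2 <- flow_true_strain(af, matrix(stats::runif(10), 5, 2), t = 3)
  expect_true(all(ts2$exx == 0.02 & ts2$eyy == -0.02 & ts2$exy == 0))
})

test_that("movies under zero flow are static; affine truth is uniform", {
  m <- generate_tessellation(30, jitter = 0.1, seed = 5)
  mv <- simulate_movie(m, seq(0, 3, 0.5), flow = flow_none(),
                       track_noise_um = 0, seed = 1)
  expect_equal(mv$meshes[[1]]$vertices, mv$meshes[[7]]$vertices)
  af <- flow_affine(matrix(c(0.02, 0, 0, -0.02), 2, 2))
  mv2 <- simulate_movie(m, seq(0, 3, 0.5), flow = af,
                        track_noise_um = 0, seed = 1)
  expect_true(all(mv2$ground_truth$strain$exx == 0.02))
  expect_true(all(mv2$ground_truth$strain$eyy == -0.02))
})

test_that("movie generation is deterministic per seed", {
  m <- generate_tessellation(30, jitter = 0.1, seed = 5)
  mv1 <- simulate_movie(m, seq(0, 2, 0.5), seed = 9)
  mv2 <- simulate_movie(m, seq(0, 2, 0.5), seed = 9)
  expect_identical(mv1$meshes, mv2$meshes)
  expect_identical(mv1$ground_truth$bipolarity, mv2$ground_truth$bipolarity)
})

test_that("a scripted swap edits the neighbour graph by one edge out, one in", {
  m <- generate_tessellation(80, jitter = 0.1, seed = 5)
  sw <- schedule_swaps(m, 1, t_range = c(10, 10), seed = 2)
  mv <- simulate_movie(m, seq(0, 20, 0.5), swaps = sw, track_noise_um = 0,
                       seed = 3)
  # graph diff between the frames flanking the swap
  edges_at <- function(f) {
    i <- mesh_interfaces(mv$meshes[[f]]); sort(ukey(i$cell_a, i$cell_b))
  }
  f_swap <- which(mv$times_min >= sw$t_swap_min)[1]
  before <- edges_at(f_swap - 1L); after <- edges_at(f_swap)
  expect_equal(setdiff(before, after), ukey(sw$lose_a, sw$lose_b))
  expect_equal(setdiff(after, before), ukey(sw$gain_a, sw$gain_b))
  # all other frames flanking non-swap times are topology-constant
  expect_identical(edges_at(2), edges_at(1))

  # empty schedule: topology constant throughout
  mv0 <- simulate_movie(m, seq(0, 3, 0.5), track_noise_um = 0, seed = 4)
  expect_identical(
    lapply(mv0$meshes, function(x) x$cells),
    rep(list(mv0$meshes[[1]]$cells), length(mv0$meshes)))
})

test_that("a swap of a DV-oriented junction has productivity near one", {
  m <- generate_tessellation(80, jitter = 0.05, seed = 8)
  sw <- schedule_swaps(m, 3, t_range = c(8, 14), min_orientation_deg = 80,
                       seed = 3)
  mv <- simulate_movie(m, seq(0, 20, 0.5), swaps = sw, track_noise_um = 0,
                       seed = 3)
  expect_true(all(mv$ground_truth$swaps$productivity > 0.9))
})

test_that("rendering reproduces the painted intensity law to quantisation", {
  m <- generate_tessellation(36, jitter = 0.1, seed = 21)
  bip <- tibble::tibble(cell_id = names(m$cells), base = 100,
                        amplitude = 40, phase_deg = 90)
  img <- render_myosin(m, bip, pixel_size = 0.5, noise_sd = 0)
  img2 <- render_myosin(m, bip, pixel_size = 0.5, noise_sd = 0)
  expect_identical(img, img2)
  pd <- painted_densities(m, bip)
  intf <- mesh_interfaces(m)
  # read the image at the pixel containing each interface midpoint: painted
  # value up to rounding
  mid_px <- cbind(floor((intf$y1 + intf$y2) / 2 / 0.5) + 1L,
                  floor((intf$x1 + intf$x2) / 2 / 0.5) + 1L)
  got <- img[mid_px]
  expect_lt(max(abs(got - pd$density)), 1)

  # amplitude zero: all interfaces exactly at base after rounding
  bip0 <- tibble::tibble(cell_id = names(m$cells), base = 120,
                         amplitude = 0, phase_deg = 0)
  img0 <- render_myosin(m, bip0, pixel_size = 0.5, noise_sd = 0)
  expect_true(all(img0[mid_px] == 120))
})

test_that("rendered TIFFs round-trip losslessly", {
  m <- generate_tessellation(16, jitter = 0.1, seed = 31)
  mv <- simulate_movie(m, 0, seed = 5)
  out <- file.path(tempdir(), "epimorph-render-test")
  render_movie(mv, out, seed = 6)
  lab <- read_label_tiff(file.path(out, "label_0001.tif"))
  expect_identical(lab, render_labels(mv$meshes[[1]], mv$pixel_size_um))
  expect_true(file.exists(file.path(out, "movie_config.json")))
  unlink(out, recursive = TRUE)
})

test_that("label images are consistent with mesh interface orientations", {
  m <- generate_tessellation(49, jitter = 0.15, seed = 12)
  lab <- render_labels(m, 0.5)
  fr <- build_frame(lab, 0.5)
  intf_mesh <- mesh_interfaces(m)
  id_of <- function(lbl) names(m$cells)[lbl]
  fr$interfaces$ka <- ukey(id_of(fr$interfaces$label_a),
                           id_of(fr$interfaces$label_b))
  km <- ukey(intf_mesh$cell_a, intf_mesh$cell_b)
  mm <- match(km, fr$interfaces$ka)
  ok <- !is.na(mm) & !is.na(fr$interfaces$orientation_deg[mm]) &
    intf_mesh$length_um > 3
  dtheta <- abs(intf_mesh$orientation_deg[ok] -
                  fr$interfaces$orientation_deg[mm][ok])
  expect_lt(stats::median(dtheta), 2)
})
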