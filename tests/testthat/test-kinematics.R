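test_that("rate_of_change matches central-difference oracles", {
  t <- seq(0, 10, 0.5)
  expect_true(all(rate_of_change(rep(3, 21), t)[3:19] == 0))
  expect_equal(rate_of_change(0.5 * t, t)[3:19], rep(0.5, 17))
  # quadratic: central difference is exact for polynomials of degree <= 2
  x <- 2 + 0.3 * t - 0.1 * t^2
  expect_equal(rate_of_change(x, t)[3:19], (0.3 - 0.2 * t)[3:19])
  # truncated window ends are NA
  expect_true(all(is.na(rate_of_change(x, t)[c(1, 2, 20, 21)])))
})

test_that("strain projection follows u'Eu and sums to the trace", {
  expect_equal(project_strain(0.02, 0, -0.02, "AP"), 0.02)
  expect_equal(project_strain(0.02, 0, -0.02, "DV"), -0.02)
  expect_equal(project_strain(0.02, 0, -0.02, 45), 0, tolerance = 1e-15)
  e <- stats::rnorm(3)
  expect_equal(project_strain(e[1], e[2], e[3], "AP") +
                 project_strain(e[1], e[2], e[3], "DV"),
               e[1] + e[3])
})

test_that("tissue strain rate vanishes for rigid motions", {
  m <- generate_tessellation(49, jitter = 0.1, seed = 2)
  times <- seq(0, 2, 0.5)
  # rigid translation at 3 um/min
  maps <- lapply(times, function(t) diag(2))
  mv <- transform_movie(m, maps, times)
  for (f in seq_along(times))
    mv$meshes[[f]]$vertices <- sweep(mv$meshes[[f]]$vertices, 2,
                                     times[f] * c(3, 1), `+`)
  tis <- tissue_strain_rates(mv)
  expect_lt(max(abs(c(tis$txx, tis$txy, tis$tyy)), na.rm = TRUE), 1e-12)

  # rigid rotation at 0.05 rad/min about the tissue centre
  ctr <- colMeans(m$vertices)
  mv2 <- epi_movie(lapply(times, function(t) {
    v <- sweep(sweep(m$vertices, 2, ctr) %*% t(rot2(0.05 * t)), 2, ctr, `+`)
    epi_mesh(v, m$cells)
  }), times)
  tis2 <- tissue_strain_rates(mv2)
  expect_lt(max(abs(c(tis2$txx, tis2$txy, tis2$tyy)), na.rm = TRUE), 1e-4)
})

test_that("tissue strain rate recovers a prescribed pure shear within 5%", {
  m <- generate_tessellation(49, jitter = 0.15, seed = 7)  # 7x7 lattice
  L <- matrix(c(0.02, 0, 0, -0.02), 2, 2)
  mv <- simulate_movie(m, seq(0, 2, 0.5), flow = flow_affine(L),
                       track_noise_um = 0, seed = 1)
  tis <- tissue_strain_rates(mv)
  ok <- !is.na(tis$txx)
  expect_true(any(ok))
  expect_true(all(abs(tis$txx[ok] - 0.02) < 0.001))
  expect_true(all(abs(tis$tyy[ok] + 0.02) < 0.001))
  expect_true(all(abs(tis$txy[ok]) < 0.001))
})

test_that("cell-shape strain rate: zero for static and rigidly rotated cells,
           exact for axis-aligned exponential stretch", {
  m <- generate_tessellation(20, jitter = 0.15, seed = 9)
  times <- seq(0, 2, 0.5)
  # static
  mv <- transform_movie(m, lapply(times, function(t) diag(2)), times)
  cs <- cell_shape_strain_rates(mv)
  expect_lt(max(abs(c(cs$cxx, cs$cxy, cs$cyy)), na.rm = TRUE), 1e-10)
  # rigid rotation
  mv2 <- transform_movie(m, lapply(times, function(t) rot2(0.05 * t)), times)
  cs2 <- cell_shape_strain_rates(mv2)
  expect_lt(max(abs(c(cs2$cxx, cs2$cxy, cs2$cyy)), na.rm = TRUE), 1e-8)
  # AP-only exponential stretch at 0.01 pp/min: exact for cells whose
  # principal axes align with the stretch (square cells) ...
  g <- make_grid_mesh(5, 5, s = 10)
  mv3 <- transform_movie(g, lapply(times, function(t)
    diag(c(exp(0.01 * t), 1))), times)
  cs3 <- cell_shape_strain_rates(mv3)
  ok <- !is.na(cs3$cxx)
  expect_equal(cs3$cxx[ok], rep(0.01, sum(ok)), tolerance = 1e-8)
  expect_lt(max(abs(cs3$cyy[ok])), 1e-10)
  # ... and within a few percent for obliquely oriented jittered cells
  mv4 <- transform_movie(m, lapply(times, function(t)
    diag(c(exp(0.01 * t), 1))), times)
  cs4 <- cell_shape_strain_rates(mv4)
  ok4 <- !is.na(cs4$cxx)
  expect_equal(cs4$cxx[ok4], rep(0.01, sum(ok4)), tolerance = 0.05)
  expect_lt(max(abs(cs4$cyy[ok4])), 5e-4)
})

test_that("the decomposition identity tissue = cell shape + intercalation is exact", {
  m <- generate_tessellation(60, jitter = 0.15, seed = 4)
  sw <- schedule_swaps(m, 3, t_range = c(2, 6), seed = 5)
  mv <- simulate_movie(m, seq(0, 8, 0.5),
                       flow = flow_affine(matrix(c(0.01, 0.005, 0.005, -0.02),
                                                 2, 2)),
                       swaps = sw, seed = 6)  # default tracking noise on
  dec <- strain_decomposition(tissue_strain_rates(mv),
                              cell_shape_strain_rates(mv))
  ok <- !is.na(dec$ixx) & !is.na(dec$txx) & !is.na(dec$cxx)
  expect_true(any(ok))
  expect_identical(dec$ixx[ok], (dec$txx - dec$cxx)[ok])
  expect_identical(dec$iyy[ok], (dec$tyy - dec$cyy)[ok])
})

test_that("area strain rate matches d(ln area)/dt oracles", {
  # a single cell growing isotropically: area ~ exp(0.03 t)
  sq <- make_rect(5, 5, 4, 4)
  cells <- list(c1 = 1:4)
  times <- seq(0, 4, 0.5)
  meshes <- lapply(times, function(t)
    epi_mesh(sq * exp(0.015 * t), cells))
  mv <- epi_movie(meshes, times)
  ar <- area_strain_rates(mv)
  ok <- !is.na(ar$area_rate)
  expect_equal(ar$area_rate[ok], rep(0.03, sum(ok)), tolerance = 1e-9)
  # trace identity: uniform flow diag(0.01, 0.01) gives area rate 0.02
  meshes2 <- lapply(times, function(t) epi_mesh(sq * exp(0.01 * t), cells))
  ar2 <- area_strain_rates(epi_movie(meshes2, times))
  expect_equal(ar2$area_rate[!is.na(ar2$area_rate)],
               rep(0.02, sum(!is.na(ar2$area_rate))), tolerance = 1e-9)
})

test_that("shape ellipses and orientations follow the moment tensor", {
  e90 <- shape_ellipses(poly_second_moment(make_ellipse_poly(3, 1, 90, 256)))
  expect_equal(e90$theta_deg, 90, tolerance = 1e-6)
  expect_equal(cell_orientation(e90), 90, tolerance = 1e-6)
  e0 <- shape_ellipses(poly_second_moment(make_ellipse_poly(3, 1, 0, 256)))
  expect_equal(cell_orientation(e0), 0, tolerance = 1e-6)
  expect_equal(e0$a_um / e0$b_um, 3, tolerance = 1e-3)
  # isotropic: orientation undefined
  iso <- shape_ellipses(poly_second_moment(make_ellipse_poly(2, 2, 0, 256)))
  expect_true(iso$isotropic)
  expect_true(is.na(cell_orientation(iso)))
})

test_that("axial shape elongation is antisymmetric under 90-degree rotation
           and invariant under 180", {
  for (th in c(10, 37, 62)) {
    v1 <- axial_shape_elongation(
      shape_ellipses(poly_second_moment(make_ellipse_poly(3, 1.2, th, 128))))
    v2 <- axial_shape_elongation(
      shape_ellipses(poly_second_moment(make_ellipse_poly(3, 1.2, th + 90, 128))))
    v3 <- axial_shape_elongation(
      shape_ellipses(poly_second_moment(make_ellipse_poly(3, 1.2, th + 180, 128))))
    expect_equal(v1, -v2, tolerance = 1e-6)
    expect_equal(v1, v3, tolerance = 1e-6)
  }
})
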