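test_that("divergence-theorem volume is exact on a cube and invariant to translation", {
  cube <- make_cube_mesh(10)
  expect_equal(mesh_volume(cube), 1, tolerance = 1e-12)
  moved <- make_cube_mesh(10, origin = c(-123.4, 56.7, 890.1))
  expect_equal(mesh_volume(moved), mesh_volume(cube), tolerance = 1e-9)
})

test_that("icosphere volume converges to the analytic sphere volume", {
  g <- gen_mesh("sphere", c(r = 10), subdivisions = 4)
  expect_equal(mesh_volume(g$mesh), 4.18879, tolerance = 0.005)
  # refinement reduces the error monotonically
  errs <- vapply(1:3, function(s) {
    abs(mesh_volume(gen_mesh("sphere", c(r = 10), subdivisions = s)$mesh) -
          4 / 3 * pi) / (4 / 3 * pi)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("non-watertight and degenerate meshes are reported", {
  cube <- make_cube_mesh(10)
  holed <- cube
  holed$faces <- holed$faces[-1, ]
  expect_error(mesh_volume(holed), "not watertight.*open", perl = TRUE)
  v <- rbind(cube$vertices, cube$vertices[1, ])
  f <- rbind(cube$faces, c(9, 9, 2))
  expect_message(m <- muscle_mesh(v, f), "degenerate")
  expect_identical(nrow(m$faces), 12L)
})

test_that("maximal CSA matches analytic cross-sections", {
  cyl <- gen_mesh("cylinder", c(r = 10, l = 100))$mesh
  ax <- max_csa(cyl, axis = c(0, 0, 1), slice_step_mm = 2)
  expect_equal(ax$csa_max_mm2, pi * 100, tolerance = 0.01)
  sph <- gen_mesh("sphere", c(r = 10), subdivisions = 4)$mesh
  for (axis in list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1))) {
    cs <- max_csa(sph, axis = axis, slice_step_mm = 2)
    expect_equal(cs$csa_max_mm2, pi * 100, tolerance = 0.01)
    expect_equal(cs$location_mm, 0, tolerance = 0.5)
  }
  # cylinder sliced perpendicular to its axis: rectangle 2r x l
  perp <- max_csa(cyl, axis = c(1, 0, 0), slice_step_mm = 2)
  expect_equal(perp$csa_max_mm2, 2 * 10 * 100, tolerance = 0.01 * 2000)
})

test_that("CSA converges as the slice step shrinks", {
  fb <- gen_mesh("fused_bumps", c(r = 10, l = 80, amp = 4))$mesh
  a2 <- max_csa(fb, slice_step_mm = 2)$csa_max_mm2
  a1 <- max_csa(fb, slice_step_mm = 1)$csa_max_mm2
  expect_lt(abs(a1 - a2) / a2, 0.005)
})

test_that("volume and CSA are invariant under rigid motion", {
  g <- gen_mesh("fused_bumps", c(r = 10, l = 80, amp = 4))
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  shift <- c(15, -40, 7)
  rot <- g$mesh
  rot$vertices <- sweep(g$mesh$vertices %*% t(R), 2, shift, `+`)
  expect_equal(mesh_volume(rot), mesh_volume(g$mesh), tolerance = 1e-3)
  ax0 <- max_csa(g$mesh, axis = c(0, 0, 1), slice_step_mm = 2)
  ax1 <- max_csa(rot, axis = as.numeric(R %*% c(0, 0, 1)), slice_step_mm = 2)
  expect_equal(ax1$csa_max_mm2, ax0$csa_max_mm2, tolerance = 1e-3 * ax0$csa_max_mm2)
})

test_that("divergence volume agrees with an independent voxel-fill oracle", {
  sph <- gen_mesh("sphere", c(r = 10), subdivisions = 4)
  vx <- voxel_volume_cm3(function(x, y, z) x^2 + y^2 + z^2 <= 100,
                         rbind(c(-10, 10), c(-10, 10), c(-10, 10)))
  expect_equal(mesh_volume(sph$mesh), vx, tolerance = 0.01 * vx)
  ell <- gen_mesh("ellipsoid", c(a = 12, b = 8, c = 20), subdivisions = 4)
  vx_e <- voxel_volume_cm3(
    function(x, y, z) (x / 12)^2 + (y / 8)^2 + (z / 20)^2 <= 1,
    rbind(c(-12, 12), c(-8, 8), c(-20, 20)))
  expect_equal(mesh_volume(ell$mesh), vx_e, tolerance = 0.01 * vx_e)
})

test_that("BMI normalization and additivity of muscle-group volume", {
  m <- structure(list(label = "VL", side = "right", volume_cm3 = 500,
                      csa_max_mm2 = 2800, csa_axis = c(0, 0, 1),
                      csa_location_mm = 0, volume_per_bmi = NA_real_),
                 class = "muscle_morphometry")
  expect_equal(normalize_morphometry(m, 25)$volume_per_bmi, 20)
  expect_equal(normalize_morphometry(m, 1)$volume_per_bmi, m$volume_cm3)
  # a muscle group's volume is the sum of its components
  parts <- c(RF = 224, VL = 597, VI = 430.2, VM = 422.4)
  expect_equal(sum(parts), 1673.6)
})

test_that("muscle_morphometry wraps volume, CSA and normalization", {
  g <- gen_mesh("cylinder", c(r = 10, l = 100))
  m <- muscle_morphometry(g$mesh, bmi = 22.2)
  expect_equal(m$volume_cm3, g$truth$mesh_volume_cm3, tolerance = 1e-6)
  expect_equal(m$csa_max_mm2, g$truth$csa_max_mm2, tolerance = 0.01 * g$truth$csa_max_mm2)
  expect_equal(m$volume_per_bmi, m$volume_cm3 / 22.2)
  expect_true(m$csa_location_mm >= 0 && m$csa_location_mm <= 100)
})

test_that("STL round-trips in both dialects preserve geometry", {
  g <- gen_mesh("fused_bumps", c(r = 8, l = 50, amp = 3), n_seg = 48)
  v0 <- mesh_volume(g$mesh)
  fa <- tempfile(fileext = ".stl")
  write_stl(g$mesh, fa, ascii = TRUE)
  ma <- read_stl(fa, label = "fb")
  expect_equal(mesh_volume(ma), v0, tolerance = 1e-6)
  fb <- tempfile(fileext = ".stl")
  write_stl(g$mesh, fb, ascii = FALSE)
  mb <- read_stl(fb)
  expect_equal(mesh_volume(mb), v0, tolerance = 1e-5)
  expect_identical(nrow(mb$faces), nrow(g$mesh$faces))
  unlink(c(fa, fb))
})
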