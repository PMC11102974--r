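# Fixtures built in code: meshes with closed-form volume, voxel oracles,
# and small conveniences shared across test files.

# Axis-aligned cube [0, side]^3 as a watertight, outward-oriented mesh.
make_cube_mesh <- function(side = 10, origin = c(0, 0, 0)) {
  s <- side
  v <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0),
             c(0, 0, s), c(s, 0, s), c(s, s, s), c(0, s, s))
  v <- sweep(v, 2, origin, `+`)
  f <- rbind(c(1, 4, 3), c(1, 3, 2),    # bottom  (-z)
             c(5, 6, 7), c(5, 7, 8),    # top     (+z)
             c(1, 2, 6), c(1, 6, 5),    # front   (-y)
             c(3, 4, 8), c(3, 8, 7),    # back    (+y)
             c(1, 5, 8), c(1, 8, 4),    # left    (-x)
             c(2, 3, 7), c(2, 7, 6))    # right   (+x)
  muscle_mesh(v, f, label = "cube")
}

# Voxel-fill volume oracle: counts voxel centres inside an analytic solid.
# Entirely independent of the divergence-theorem route.
voxel_volume_cm3 <- function(inside_fun, bbox, step_mm = 0.5) {
  gx <- seq(bbox[1, 1] + step_mm / 2, bbox[1, 2], by = step_mm)
  gy <- seq(bbox[2, 1] + step_mm / 2, bbox[2, 2], by = step_mm)
  gz <- seq(bbox[3, 1] + step_mm / 2, bbox[3, 2], by = step_mm)
  n_in <- 0
  for (z in gz) {
    xy <- expand.grid(x = gx, y = gy)
    n_in <- n_in + sum(inside_fun(xy$x, xy$y, z))
  }
  n_in * step_mm^3 / 1000
}

# 3-D rotation matrix about an arbitrary axis (Rodrigues).
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# A stimulus_event at a known sample, for direct compute_car tests.
make_event <- function(onset_idx, rate_hz, source = "trigger_channel") {
  structure(list(onset_idx = as.integer(onset_idx),
                 onset_s = (onset_idx - 1) / rate_hz, source = source),
            class = "stimulus_event")
}

# Standard noise window for generated traces with a 2 s lead-in at 2000 Hz.
std_seg_params <- function(...) {
  segmentation_params(noise_window = c(400, 3600), ...)
}
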