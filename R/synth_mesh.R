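# Analytic-solid mesh generators. These stand in for segmented muscle
# surfaces: every mesh is watertight, consistently outward-oriented, and
# ships with its analytic volume/CSA as ground truth.

# Unit icosahedron (12 vertices, 20 faces), outward-wound.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# Loop-style 1->4 subdivision with midpoint reuse, then radial projection.
subdivide_sphere <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  midmap <- new.env(hash = TRUE)
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- midmap[[key]]
    if (!is.null(hit)) return(hit)
    m <- (v[i, ] + v[j, ]) / 2
    m <- m / sqrt(sum(m^2))
    v <<- rbind(v, m)
    idx <- nrow(v)
    midmap[[key]] <- idx
    idx
  }
  nf <- matrix(0L, nrow(f) * 4L, 3L)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
    nf[(4L * i - 3L):(4L * i), ] <- rbind(
      c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
  }
  list(vertices = v, faces = nf)
}

# Unit icosphere at the given subdivision level.
icosphere <- function(subdivisions = 4L) {
  m <- icosahedron()
  for (s in seq_len(subdivisions)) m <- subdivide_sphere(m)
  m
}

# Closed surface of revolution of radius profile r(z) about the z axis,
# capped with triangle fans at both ends.
revolve_mesh <- function(radius_fun, z, n_seg = 96L) {
  stopifnot(length(z) >= 2L, n_seg >= 3L)
  theta <- 2 * pi * (0:(n_seg - 1L)) / n_seg
  r <- vapply(z, radius_fun, numeric(1))
  stopifnot(all(r > 0))
  nv <- length(z) * n_seg
  verts <- matrix(0, nv + 2L, 3L)
  for (i in seq_along(z)) {
    rows <- ((i - 1L) * n_seg + 1L):(i * n_seg)
    verts[rows, ] <- cbind(r[i] * cos(theta), r[i] * sin(theta), z[i])
  }
  bot <- nv + 1L
  top <- nv + 2L
  verts[bot, ] <- c(0, 0, z[1])
  verts[top, ] <- c(0, 0, z[length(z)])
  faces <- list()
  ring <- function(i) ((i - 1L) * n_seg + 1L):(i * n_seg)
  nxt <- function(k) (k %% n_seg) + 1L
  for (i in seq_len(length(z) - 1L)) {
    lo <- ring(i); hi <- ring(i + 1L)
    for (k in seq_len(n_seg)) {
      k2 <- nxt(k)
      faces[[length(faces) + 1L]] <- c(lo[k], lo[k2], hi[k2])
      faces[[length(faces) + 1L]] <- c(lo[k], hi[k2], hi[k])
    }
  }
  lo <- ring(1L); hi <- ring(length(z))
  for (k in seq_len(n_seg)) {
    k2 <- nxt(k)
    faces[[length(faces) + 1L]] <- c(bot, lo[k2], lo[k])   # bottom cap
    faces[[length(faces) + 1L]] <- c(top, hi[k], hi[k2])   # top cap
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

#' Generate an analytic-solid mesh with known volume and CSA
#'
#' Watertight, outward-oriented triangulated surfaces of simple solids,
#' together with the analytic (or numerically integrated, for the revolved
#' bump shape) volume and maximal cross-sectional area along the z axis.
#' Generation is deterministic: the same arguments always return the same
#' mesh.
#'
#' @param shape `"sphere"`, `"ellipsoid"`, `"cylinder"` or `"fused_bumps"`
#'   (a surface of revolution whose radius profile carries two Gaussian
#'   bulges, mimicking adjacent muscle bellies).
#' @param dims Named numeric vector of dimensions in mm: sphere `r`;
#'   ellipsoid `a`, `b`, `c`; cylinder `r`, `l`; fused_bumps `r`, `l`,
#'   `amp` (bulge amplitude).
#' @param subdivisions Icosphere subdivision level for sphere/ellipsoid
#'   (default 4).
#' @param n_seg Circumferential segments for revolved shapes (default 128).
#' @param label,side Mesh metadata.
#' @return List: `mesh` (a [muscle_mesh()]), `truth` (list with
#'   `volume_cm3`, `csa_max_mm2`, `csa_axis`, `shape`, `dims`).
#' @export
gen_mesh <- function(shape = c("sphere", "ellipsoid", "cylinder",
                               "fused_bumps"),
                     dims = c(r = 10), subdivisions = 4L, n_seg = 128L,
                     label = shape, side = NA_character_) {
  shape <- match.arg(shape)
  d <- as.list(dims)
  axis <- c(0, 0, 1)
  if (shape == "sphere") {
    r <- d$r
    m <- icosphere(subdivisions)
    m$vertices <- m$vertices * r
    truth <- list(volume_cm3 = 4 / 3 * pi * r^3 / 1000,
                  csa_max_mm2 = pi * r^2)
  } else if (shape == "ellipsoid") {
    m <- icosphere(subdivisions)
    m$vertices <- sweep(m$vertices, 2, c(d$a, d$b, d$c), `*`)
    truth <- list(volume_cm3 = 4 / 3 * pi * d$a * d$b * d$c / 1000,
                  csa_max_mm2 = pi * d$a * d$b)
  } else if (shape == "cylinder") {
    m <- revolve_mesh(function(z) d$r, z = seq(0, d$l, length.out = 2L),
                      n_seg = n_seg)
    # polygonal cross-section of the inscribed n-gon
    poly_area <- n_seg / 2 * d$r^2 * sin(2 * pi / n_seg)
    truth <- list(volume_cm3 = pi * d$r^2 * d$l / 1000,
                  csa_max_mm2 = pi * d$r^2,
                  mesh_volume_cm3 = poly_area * d$l / 1000,
                  mesh_csa_mm2 = poly_area)
  } else {
    r0 <- d$r; len <- d$l; amp <- if (is.null(d$amp)) 0.4 * d$r else d$amp
    z1 <- 0.3 * len; z2 <- 0.7 * len; sg <- 0.08 * len
    rf <- function(z) {
      r0 + amp * exp(-(z - z1)^2 / (2 * sg^2)) +
        amp * exp(-(z - z2)^2 / (2 * sg^2))
    }
    z <- seq(0, len, length.out = 121L)
    m <- revolve_mesh(rf, z = z, n_seg = n_seg)
    # revolved volume pi * int r(z)^2 dz by fine quadrature
    zq <- seq(0, len, length.out = 20001L)
    rq <- vapply(zq, rf, numeric(1))
    vol_mm3 <- pi * sum((rq[-1]^2 + rq[-length(rq)]^2) / 2 * diff(zq))
    rmax <- max(rq)
    truth <- list(volume_cm3 = vol_mm3 / 1000, csa_max_mm2 = pi * rmax^2)
  }
  truth$csa_axis <- axis
  truth$shape <- shape
  truth$dims <- dims
  list(mesh = muscle_mesh(m$vertices, m$faces, label = label, side = side),
       truth = truth)
}
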