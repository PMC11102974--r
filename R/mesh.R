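#' Triangulated muscle surface mesh
#'
#' Vertices are in millimetres (DICOM-derived segmentations); faces are
#' 1-based vertex-index triples wound counter-clockwise seen from outside.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of vertex indices.
#' @param label Muscle name (RF, VL, VI, VM, ST, BF, ...).
#' @param side `"left"`, `"right"` or NA.
#' @param unit_scale Multiplier applied to vertices to obtain mm (default 1).
#' @return A `muscle_mesh` object. Degenerate faces (repeated vertex
#'   indices) are dropped with a message.
#' @export
muscle_mesh <- function(vertices, faces, label = "", side = NA_character_,
                        unit_scale = 1) {
  vertices <- as.matrix(vertices) * unit_scale
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("muscle_mesh: face indices out of range", call. = FALSE)
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (any(degen)) {
    message(sprintf("muscle_mesh: dropped %d degenerate face(s)", sum(degen)))
    faces <- faces[!degen, , drop = FALSE]
  }
  structure(
    list(vertices = vertices, faces = faces, label = as.character(label),
         side = side),
    class = "muscle_mesh"
  )
}

#' @export
print.muscle_mesh <- function(x, ...) {
  cat(sprintf("<muscle_mesh> %s: %d vertices, %d faces\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Count of boundary (open) directed edges; 0 for a watertight,
# consistently oriented surface, where every directed edge is matched by
# its reverse exactly once.
open_edge_count <- function(mesh) {
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fwd <- paste(he[, 1], he[, 2])
  rev <- paste(he[, 2], he[, 1])
  if (anyDuplicated(fwd)) return(NA_integer_)  # non-manifold / inconsistent
  sum(!(fwd %in% rev))
}

#' Check a mesh is watertight and consistently oriented
#'
#' @param mesh A `muscle_mesh`.
#' @return Invisibly TRUE; otherwise an error naming the open edges.
#' @export
assert_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "muscle_mesh"))
  oe <- open_edge_count(mesh)
  if (is.na(oe)) {
    stop("mesh is non-manifold or inconsistently oriented ",
         "(duplicated directed edges)", call. = FALSE)
  }
  if (oe > 0L) {
    stop(sprintf("mesh is not watertight: %d open (unmatched) edge(s)", oe),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem (signed tetrahedron) volume:
#' `|sum det(v1, v2, v3)| / 6`, converted from cubic millimetres to cubic
#' centimetres. Taking the absolute value makes the result independent of
#' global orientation.
#'
#' @param mesh A watertight `muscle_mesh` with vertices in mm.
#' @return Volume in cm^3.
#' @examples
#' # 10 mm cube = 1 cm^3
#' @export
mesh_volume <- function(mesh) {
  assert_watertight(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(det6)) / 6 / 1000
}

# Signed cross-section area (mm^2) of the mesh cut by the plane
# {p : <p, axis> = c}. Each straddling triangle contributes one oriented
# segment; because the mesh is closed and consistently oriented, the
# shoelace sum over the segments equals the enclosed polygon area without
# explicit polygon chaining (holes subtract automatically).
section_area <- function(vertices, faces, axis, e1, e2, c) {
  h <- vertices %*% axis
  h1 <- h[faces[, 1]]; h2 <- h[faces[, 2]]; h3 <- h[faces[, 3]]
  lo <- pmin(h1, h2, h3)
  hi <- pmax(h1, h2, h3)
  idx <- which(lo < c & hi > c)
  if (length(idx) == 0L) return(0)
  total <- 0
  for (i in idx) {
    tri <- faces[i, ]
    p <- vertices[tri, , drop = FALSE]
    hh <- c(h1[i], h2[i], h3[i])
    pts <- matrix(0, 2, 3)
    k <- 0L
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      ha <- hh[e[1]]; hb <- hh[e[2]]
      if ((ha < c && hb > c) || (ha > c && hb < c)) {
        t <- (c - ha) / (hb - ha)
        k <- k + 1L
        pts[k, ] <- p[e[1], ] + t * (p[e[2], ] - p[e[1], ])
      }
    }
    if (k != 2L) next
    # orient the segment along cross(axis, face normal)
    nrm <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    d <- cross3(axis, nrm)
    seg <- pts[2, ] - pts[1, ]
    if (sum(seg * d) < 0) pts <- pts[2:1, , drop = FALSE]
    u1 <- sum(pts[1, ] * e1); v1 <- sum(pts[1, ] * e2)
    u2 <- sum(pts[2, ] * e1); v2 <- sum(pts[2, ] * e2)
    total <- total + (u1 * v2 - u2 * v1)
  }
  total / 2
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Orthonormal basis completing a unit axis.
plane_basis <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(ref, axis)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(axis, e1)
  list(e1 = e1, e2 = e2)
}

#' Maximal anatomical cross-sectional area along an axis
#'
#' The mesh is sliced by planes perpendicular to `axis` every
#' `slice_step_mm`; per-plane area is the summed area of the closed
#' intersection polygons. After the coarse scan the neighbourhood of the
#' best slice is re-scanned at `slice_step_mm / 20` so the reported maximum
#' is not quantized to the slice grid. Anatomical (plane-perpendicular)
#' CSA, not physiological.
#'
#' @param mesh A watertight `muscle_mesh` (vertices in mm).
#' @param axis Slicing direction (default the scanner z-axis); need not be
#'   unit length.
#' @param slice_step_mm Plane spacing (default 2, the MRI slice thickness).
#' @param refine Refine around the coarse maximum (default TRUE).
#' @return List: `csa_max_mm2`, `location_mm` (offset of the maximal slice
#'   along the unit axis), `axis` (unit vector).
#' @export
max_csa <- function(mesh, axis = c(0, 0, 1), slice_step_mm = 2,
                    refine = TRUE) {
  assert_watertight(mesh)
  stopifnot(slice_step_mm > 0)
  nrmax <- sqrt(sum(axis^2))
  if (nrmax == 0) stop("max_csa: axis must be non-zero", call. = FALSE)
  axis <- axis / nrmax
  bb <- plane_basis(axis)
  h <- mesh$vertices %*% axis
  lo <- min(h); hi <- max(h)
  if (hi - lo <= 0) stop("max_csa: degenerate mesh extent", call. = FALSE)
  eps <- (hi - lo) * 1e-9
  scan <- function(cs) {
    vapply(cs, function(c) {
      if (any(abs(h - c) < eps)) c <- c + 2 * eps  # avoid vertices on plane
      abs(section_area(mesh$vertices, mesh$faces, axis, bb$e1, bb$e2, c))
    }, numeric(1))
  }
  cs <- seq(lo + slice_step_mm / 2, hi - slice_step_mm / 2,
            by = slice_step_mm)
  if (length(cs) == 0L) cs <- (lo + hi) / 2
  areas <- scan(cs)
  if (all(areas == 0)) {
    stop("max_csa: no plane intersects the mesh", call. = FALSE)
  }
  best <- which.max(areas)
  c_best <- cs[best]
  a_best <- areas[best]
  if (refine) {
    fine <- seq(max(lo + eps, c_best - slice_step_mm),
                min(hi - eps, c_best + slice_step_mm),
                by = slice_step_mm / 20)
    fa <- scan(fine)
    if (max(fa) > a_best) {
      a_best <- max(fa)
      c_best <- fine[which.max(fa)]
    }
  }
  list(csa_max_mm2 = a_best, location_mm = c_best, axis = axis)
}

#' Morphometry of one muscle mesh
#'
#' Volume (divergence theorem) plus maximal cross-sectional area along a
#' slicing axis, with optional BMI normalization.
#'
#' @param mesh A watertight `muscle_mesh`.
#' @param axis Slicing axis (default scanner z).
#' @param slice_step_mm Plane spacing (default 2).
#' @param bmi Optional body-mass index (kg/m^2) for size normalization.
#' @return A `muscle_morphometry`: `label`, `side`, `volume_cm3`,
#'   `csa_max_mm2`, `csa_axis`, `csa_location_mm`, `volume_per_bmi` (NA
#'   unless `bmi` given).
#' @export
muscle_morphometry <- function(mesh, axis = c(0, 0, 1), slice_step_mm = 2,
                               bmi = NULL) {
  vol <- mesh_volume(mesh)
  csa <- max_csa(mesh, axis = axis, slice_step_mm = slice_step_mm)
  m <- structure(
    list(label = mesh$label, side = mesh$side, volume_cm3 = vol,
         csa_max_mm2 = csa$csa_max_mm2, csa_axis = csa$axis,
         csa_location_mm = csa$location_mm, volume_per_bmi = NA_real_),
    class = "muscle_morphometry"
  )
  if (!is.null(bmi)) m <- normalize_morphometry(m, bmi)
  m
}

#' BMI-normalized muscle volume
#'
#' Dividing volume by body-mass index removes the confounding effect of
#' stature and mass when comparing cohorts.
#'
#' @param m A `muscle_morphometry`.
#' @param bmi Body-mass index in kg/m^2 (> 0).
#' @return The morphometry with `volume_per_bmi` filled in.
#' @export
normalize_morphometry <- function(m, bmi) {
  stopifnot(inherits(m, "muscle_morphometry"), bmi > 0)
  m$volume_per_bmi <- m$volume_cm3 / bmi
  m
}

#' @export
print.muscle_morphometry <- function(x, ...) {
  cat(sprintf("<muscle_morphometry> %s: %.1f cm^3, max CSA %.1f mm^2 @ %.1f mm\n",
              if (nzchar(x$label)) x$label else "(unnamed)", x$volume_cm3,
              x$csa_max_mm2, x$csa_location_mm))
  invisible(x)
}
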