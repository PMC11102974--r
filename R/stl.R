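#' Read a triangulated surface from an STL file
#'
#' Both STL dialects are accepted: ASCII (`solid ... facet normal ...`) and
#' the 80-byte-header binary layout. Vertices repeated across facets are
#' merged (exact coordinate match after rounding to 1e-6 mm) so that
#' watertightness checks and the divergence-theorem volume are meaningful.
#'
#' @param path Path to the STL file.
#' @param label,side Metadata for the resulting mesh.
#' @param unit_scale Multiplier to mm (default 1: file already in mm).
#' @return A [muscle_mesh()].
#' @export
read_stl <- function(path, label = "", side = NA_character_,
                     unit_scale = 1) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  close(con)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    is_ascii_stl(path)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  mesh_from_triangle_soup(tri, label = label, side = side,
                          unit_scale = unit_scale)
}

# Some binary files also start with "solid"; require the token "facet"
# within the first chunk of printable text to call it ASCII.
is_ascii_stl <- function(path) {
  txt <- suppressWarnings(readLines(path, n = 5L))
  any(grepl("facet", txt, fixed = TRUE)) ||
    (length(txt) >= 1L && grepl("^solid", txt[1]) && length(txt) == 1L)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) {
    stop("read_stl: ASCII STL vertex count not a multiple of 3",
         call. = FALSE)
  }
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }, numeric(3)))
  nums
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- readBin(con, "raw", n_tri * 50L)
  if (length(rec) < n_tri * 50L) {
    stop("read_stl: truncated binary STL", call. = FALSE)
  }
  m <- matrix(rec, nrow = 50L)
  tri <- matrix(0, n_tri * 3L, 3L)
  for (k in 1:3) {  # vertex k of each facet at byte offset 12 + 12*(k-1)
    off <- 12L + 12L * (k - 1L)
    xyz <- readBin(as.raw(m[(off + 1L):(off + 12L), , drop = FALSE]),
                   "numeric", n_tri * 3L, size = 4L, endian = "little")
    tri[seq(k, by = 3L, length.out = n_tri), ] <-
      matrix(xyz, ncol = 3L, byrow = TRUE)
  }
  tri
}

# 3n x 3 triangle soup -> deduplicated muscle_mesh
mesh_from_triangle_soup <- function(tri, label = "", side = NA_character_,
                                    unit_scale = 1) {
  key <- apply(round(tri, 6), 1, paste, collapse = ",")
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  vertices <- tri[uk, , drop = FALSE]
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  muscle_mesh(vertices, faces, label = label, side = side,
              unit_scale = unit_scale)
}

#' Write a mesh to an STL file
#'
#' @param mesh A [muscle_mesh()].
#' @param path Output path.
#' @param ascii Write the ASCII dialect (default TRUE); FALSE writes binary.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path, ascii = TRUE) {
  stopifnot(inherits(mesh, "muscle_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  nrm <- t(vapply(seq_len(nrow(f)), function(i) {
    p <- v[f[i, ], , drop = FALSE]
    n <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    l <- sqrt(sum(n^2))
    if (l > 0) n / l else c(0, 0, 0)
  }, numeric(3)))
  name <- if (nzchar(mesh$label)) mesh$label else "mesh"
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", name), con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      p <- v[f[i, ], , drop = FALSE]
      for (k in 1:3) {
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           p[k, 1], p[k, 2], p[k, 3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines(sprintf("endsolid %s", name), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(sprintf("%-79s", name)), as.raw(0)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      p <- v[f[i, ], , drop = FALSE]
      writeBin(as.numeric(c(nrm[i, ], t(p))), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}
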