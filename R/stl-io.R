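# STL (stereolithography) reading and writing.
#
# Binary layout: 80-byte header, uint32 little-endian face count, then per
# face 12 float32 (normal, 3 vertices) + uint16 attribute = 50 bytes.
# ASCII layout: "solid"/"facet normal"/"outer loop"/"vertex"... keywords.
# STL is a triangle soup with no shared-vertex concept; on read, vertices
# closer than `merge_tol` are merged so area sums and point queries behave.

#' Read an STL surface mesh (binary or ASCII)
#'
#' Dialect is auto-detected: a file is treated as ASCII only if it parses
#' fully as ASCII STL; a `solid` prefix alone is not sufficient (some binary
#' exporters write one). Coordinates are taken as millimetres unchanged, as
#' intraoral scanners export mm.
#'
#' @param path Path to an `.stl` file.
#' @param merge_tol Vertices closer than this (mm) are merged into one;
#'   `0` disables merging. Default `1e-6`.
#' @param source_label Label stored on the mesh; defaults to the file name.
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path, merge_tol = 1e-6, source_label = basename(path)) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  size <- file.info(path)$size
  if (is.na(size) || size < 15) {
    stop("STL format error in '", path, "': file too short (", size,
         " bytes)", call. = FALSE)
  }
  tri <- if (stl_is_ascii(path)) read_stl_ascii(path) else read_stl_binary(path)
  stl_soup_to_mesh(tri, merge_tol = merge_tol, source_label = source_label)
}

# TRUE iff the file parses fully as ASCII STL.
stl_is_ascii <- function(path) {
  head <- readBin(path, "raw", n = 6L)
  if (!identical(rawToChar(head[1:5]), "solid")) return(FALSE)
  ok <- TRUE
  tryCatch(read_stl_ascii(path), error = function(e) ok <<- FALSE)
  ok
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks <- trimws(lines)
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0 || !startsWith(toks[1], "solid")) {
    stop("not ASCII STL: missing 'solid' header", call. = FALSE)
  }
  vx <- toks[startsWith(toks, "vertex")]
  n_facet <- sum(startsWith(toks, "facet normal"))
  if (!any(startsWith(toks, "endsolid"))) {
    stop("not ASCII STL: missing 'endsolid'", call. = FALSE)
  }
  if (length(vx) != 3L * n_facet || n_facet == 0) {
    stop("ASCII STL parse error: ", n_facet, " facets but ", length(vx),
         " vertex lines", call. = FALSE)
  }
  coords <- vapply(strsplit(sub("^vertex\\s+", "", vx), "\\s+"), function(p) {
    v <- suppressWarnings(as.numeric(p))
    if (length(v) != 3 || anyNA(v)) stop("bad vertex line", call. = FALSE)
    v
  }, numeric(3))
  # quantize to float32 so ASCII and binary encodings of one mesh are equal
  matrix(float32_round(t(coords)), ncol = 3)  # 3 rows per facet
}

read_stl_binary <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n_faces <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * n_faces
  if (size < expected) {
    stop("STL format error: truncated binary body, expected ", expected,
         " bytes for ", n_faces, " faces but file has ", size,
         " (missing data from byte offset ", size, ")", call. = FALSE)
  }
  if (size > expected) {
    stop("STL format error: face-count mismatch, header declares ", n_faces,
         " faces (", expected, " bytes) but file has ", size,
         " bytes; extra data begins at byte offset ", expected, call. = FALSE)
  }
  body <- readBin(con, "raw", n = 50L * n_faces)
  body_m <- matrix(body, nrow = 50L)  # one column per facet
  tri <- matrix(0, nrow = 3L * n_faces, ncol = 3)
  for (i in seq_len(n_faces)) {
    vals <- readBin(body_m[1:48, i], "double", n = 12L, size = 4L,
                    endian = "little")
    tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], ncol = 3, byrow = TRUE)
  }
  tri
}

float32_round <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          "double", n = length(x), size = 4L, endian = "little")
}

# Collapse the per-facet vertex soup (3 rows per face) into shared vertices.
stl_soup_to_mesh <- function(tri, merge_tol, source_label) {
  if (merge_tol > 0) {
    key <- paste(round(tri[, 1] / merge_tol), round(tri[, 2] / merge_tol),
                 round(tri[, 3] / merge_tol))
  } else {
    key <- paste(tri[, 1], tri[, 2], tri[, 3])
  }
  idx <- match(key, key[!duplicated(key)])
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces, source_label = source_label, validate = FALSE)
}

#' Write a mesh as STL
#'
#' The binary dialect is little-endian with face normals recomputed from
#' vertex winding; the file is exactly `84 + 50 * n_faces` bytes. Vertices
#' are stored as float32, the format's precision.
#'
#' @param mesh A [surface_mesh()] with at least one face.
#' @param path Output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  issues <- validate_mesh(mesh)
  if (nrow(issues) > 0 && any(issues$issue != "zero_area_face")) {
    stop("refusing to write invalid mesh: ",
         paste(unique(issues$issue), collapse = "; "), call. = FALSE)
  }
  if (nrow(mesh$faces) == 0) stop("refusing to write empty mesh", call. = FALSE)
  # Round to float32 up front so ASCII and binary dialects encode identical
  # coordinates (binary stores float32 by definition).
  v <- matrix(float32_round(mesh$vertices), ncol = 3)
  f <- mesh$faces
  normals <- t(vapply(seq_len(nrow(f)), function(i) {
    n <- cross3(v[f[i, 2], ] - v[f[i, 1], ], v[f[i, 3], ] - v[f[i, 1], ])
    len <- vnorm(n)
    if (len > 0) n / len else c(0, 0, 0)
  }, numeric(3)))
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "ucsalign binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(c(normals[i, ], t(v[f[i, ], , drop = FALSE])), con,
               size = 4L, endian = "little")
      writeBin(as.integer(0), con, size = 2L, endian = "little")
    }
  } else {
    lines <- c(sprintf("solid %s", mesh$source_label))
    for (i in seq_len(nrow(f))) {
      lines <- c(lines,
        sprintf("  facet normal %.9g %.9g %.9g",
                normals[i, 1], normals[i, 2], normals[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g",
                v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
        "    endloop",
        "  endfacet")
    }
    lines <- c(lines, sprintf("endsolid %s", mesh$source_label))
    writeLines(lines, path)
  }
  invisible(path)
}
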