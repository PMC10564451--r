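#' Triangle surface mesh of one arch scan
#'
#' A minimal container for a triangulated arch surface at one time point:
#' an `n x 3` matrix of vertex coordinates in millimetres (the shared X/Y/Z
#' coordinate axes: X buccolingual, Y mesiodistal, Z vertical) and an
#' `m x 3` integer matrix of 1-based vertex indices per triangular face.
#'
#' @param vertices Numeric matrix (`n x 3`) of vertex coordinates in mm.
#' @param faces Integer matrix (`m x 3`) of 1-based vertex indices.
#' @param source_label Free-text provenance label, e.g. `"maxilla_T0"`.
#' @param validate If `TRUE` (default), reject meshes with non-finite
#'   coordinates, out-of-range face indices, or no faces.
#'
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `source_label`.
#' @seealso [read_stl()], [write_stl()], [validate_mesh()]
#' @export
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' m <- surface_mesh(v, rbind(c(1L, 2L, 3L)))
#' m
surface_mesh <- function(vertices, faces, source_label = "", validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  mesh <- structure(
    list(vertices = vertices, faces = faces,
         source_label = as.character(source_label)[1]),
    class = "surface_mesh"
  )
  if (validate) {
    issues <- validate_mesh(mesh)
    if (nrow(issues) > 0) {
      stop("invalid surface_mesh: ",
           paste(unique(issues$issue), collapse = "; "), call. = FALSE)
    }
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s: %d vertices, %d faces (mm)\n",
              if (nzchar(x$source_label)) x$source_label else "(unlabelled)",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Report structural problems in a mesh without modifying it
#'
#' Checks for non-finite coordinates, face indices outside `1..n_vertices`,
#' zero-area (degenerate) triangles, and an empty face list. Purely a
#' reporting operation: the input is never mutated and no error is thrown.
#'
#' @param mesh A `surface_mesh` (or a bare list with `vertices`/`faces`).
#' @return A tibble with columns `issue`, `location`, `detail`; zero rows for
#'   a clean mesh.
#' @export
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' validate_mesh(surface_mesh(v, rbind(c(1L, 2L, 3L))))
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  issues <- list()
  add <- function(issue, location, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      issue = issue, location = as.integer(location), detail = detail)
  }
  bad_coord <- which(!apply(is.finite(v), 1, all))
  for (i in bad_coord) add("non_finite_coordinate", i,
                           sprintf("vertex %d has a non-finite coordinate", i))
  if (nrow(f) == 0) {
    add("empty_mesh", NA, "mesh has no faces")
  } else {
    n <- nrow(v)
    bad_idx <- which(apply(f, 1, function(r) any(r < 1L | r > n)))
    for (i in bad_idx) add("face_index_out_of_range", i,
                           sprintf("face %d references a vertex outside 1..%d", i, n))
    ok <- setdiff(seq_len(nrow(f)), bad_idx)
    for (i in ok) {
      a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; ce <- v[f[i, 3], ]
      if (all(is.finite(c(a, b, ce))) &&
          vnorm(cross3(b - a, ce - a)) / 2 <= .Machine$double.eps * 100) {
        add("zero_area_face", i, sprintf("face %d has (near-)zero area", i))
      }
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(issue = character(), location = integer(), detail = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Total surface area of a mesh
#'
#' @param mesh A `surface_mesh`.
#' @return Total triangle area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  sum(vapply(seq_len(nrow(f)), function(i) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; ce <- v[f[i, 3], ]
    vnorm(cross3(b - a, ce - a)) / 2
  }, numeric(1)))
}
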