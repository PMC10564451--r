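# Single-point superposition: both scans carry coordinates in a shared
# Cartesian frame (scanner/software orientation), so aligning the single
# landmark reduces to a pure translation. The rotation slot exists so the
# transform type is a general rigid map, but this method always sets it to
# the identity; the translation-only assumption is a documented property of
# the method, verified (and negatively controlled) in the test suite.

#' Rigid transform (rotation + translation)
#'
#' Point-wise convention: `v' = R v + t`, applied to the T1 model to bring
#' it onto T0 (T0 is the fixed reference).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (identity by
#'   default).
#' @param translation Numeric length-3 vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
#' @examples
#' rigid_transform(translation = c(-3, -4, 0))
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- vec3(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation matrix is not orthonormal within 1e-9", call. = FALSE)
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation matrix determinant is not +1 within 1e-9 ",
         "(reflections are not rigid motions)", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  is_ident <- max(abs(x$rotation - diag(3))) < 1e-12
  cat(sprintf("<rigid_transform> translation (%.4f, %.4f, %.4f) mm; rotation %s\n",
              x$translation[1], x$translation[2], x$translation[3],
              if (is_ident) "identity" else "general"))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the map "apply `t1`, then `t2`".
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return The composed [rigid_transform()].
#' @export
compose_transforms <- function(t2, t1) {
  rigid_transform(rotation = t2$rotation %*% t1$rotation,
                  translation = as.numeric(t2$rotation %*% t1$translation) +
                    t2$translation)
}

#' Translation-only transform that superposes the T1 landmark onto T0
#'
#' The core of the single-point method: both landmarks are read in the same
#' Cartesian frame, so the T1 model is moved by `point(T0) - point(T1)` with
#' no rotation. Applying the returned transform to the T1 landmark
#' reproduces the T0 landmark exactly.
#'
#' @param landmark_t0,landmark_t1 One-row landmark tibbles from the same
#'   arch (see [intersect_guides()]).
#' @return A [rigid_transform()] with identity rotation.
#' @export
#' @examples
#' lm0 <- intersect_guides(guide_line(c(1, 0, 3), c(1, 5, 3), "vertical"),
#'                         guide_line(c(-9, 2, 3), c(9, 2, 3), "horizontal"))
#' lm1 <- lm0; lm1$x <- lm1$x + 3; lm1$timepoint <- "T1"
#' ucs_superpose_transform(lm0, lm1)
ucs_superpose_transform <- function(landmark_t0, landmark_t1) {
  if (!identical(landmark_t0$arch, landmark_t1$arch)) {
    stop("landmark arch mismatch: T0 is '", landmark_t0$arch,
         "' but T1 is '", landmark_t1$arch, "'", call. = FALSE)
  }
  rigid_transform(translation = landmark_point(landmark_t0) -
                    landmark_point(landmark_t1))
}

#' Apply a rigid transform to a mesh, points table, or bare coordinates
#'
#' Every vertex maps as `v' = R v + t`; faces and all non-coordinate columns
#' are unchanged. Pairwise distances are preserved to double precision.
#'
#' @param x A [surface_mesh()], a tooth-points tibble (columns `x`,`y`,`z`),
#'   or an `n x 3` numeric matrix.
#' @param transform A [rigid_transform()].
#' @return Object of the same type as `x`, transformed.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  UseMethod("apply_transform")
}

#' @export
apply_transform.surface_mesh <- function(x, transform) {
  x$vertices <- transform_coords(x$vertices, transform)
  x
}

#' @export
apply_transform.matrix <- function(x, transform) {
  transform_coords(x, transform)
}

#' @export
apply_transform.data.frame <- function(x, transform) {
  m <- transform_coords(cbind(x$x, x$y, x$z), transform)
  x$x <- m[, 1]; x$y <- m[, 2]; x$z <- m[, 3]
  x
}

#' @export
apply_transform.numeric <- function(x, transform) {
  as.numeric(transform_coords(matrix(x, ncol = 3), transform))
}

transform_coords <- function(m, transform) {
  out <- m %*% t(transform$rotation)
  out[, 1] <- out[, 1] + transform$translation[1]
  out[, 2] <- out[, 2] + transform$translation[2]
  out[, 3] <- out[, 3] + transform$translation[3]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Superpose a T1 model onto T0 via the single-point method
#'
#' Convenience composition of [ucs_superpose_transform()] and
#' [apply_transform()]; returns both the moved model and the transform used
#' so it can be logged and applied to the T1 tooth points.
#'
#' @param model_t1 The T1 [surface_mesh()].
#' @param landmark_t1,landmark_t0 One-row landmark tibbles.
#' @return A list with `model` (superposed T1 mesh) and `transform`.
#' @export
superpose <- function(model_t1, landmark_t1, landmark_t0) {
  tr <- ucs_superpose_transform(landmark_t0, landmark_t1)
  list(model = apply_transform(model_t1, tr), transform = tr)
}

#' Write / read a rigid transform as JSON (row-major rotation matrix)
#'
#' @param transform A [rigid_transform()].
#' @param path JSON path.
#' @return `path` invisibly / the transform.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(rotation_row_major = as.numeric(t(transform$rotation)),
         translation_mm = transform$translation),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  rigid_transform(rotation = matrix(obj$rotation_row_major, 3, 3, byrow = TRUE),
                  translation = obj$translation_mm)
}
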