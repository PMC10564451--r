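# Construction of the single superposition landmark per arch: the
# intersection of a vertical guide line (palatal suture midline / mandibular
# midline) with a horizontal guide line (second palatal ruga / mucogingival
# junction). Operator-picked guide lines never intersect exactly in 3D, so
# skew pairs resolve to the midpoint of their common-perpendicular segment.

#' Define a guide line from two picked points
#'
#' Guide lines are idealised as infinite straight 3D lines through two
#' operator-picked points.
#'
#' @param p1,p2 Numeric length-3 points (mm); must differ.
#' @param label `"vertical"` or `"horizontal"`.
#' @return An object of class `guide_line` with fields `p1`, `p2`, `label`.
#' @export
#' @examples
#' guide_line(c(0, -5, 0), c(0, 20, 0), "vertical")
guide_line <- function(p1, p2, label = c("vertical", "horizontal")) {
  label <- match.arg(label)
  p1 <- vec3(p1); p2 <- vec3(p2)
  if (!all(is.finite(c(p1, p2)))) {
    stop("guide line points must be finite", call. = FALSE)
  }
  if (vnorm(p2 - p1) == 0) {
    stop("guide line is degenerate: p1 equals p2", call. = FALSE)
  }
  structure(list(p1 = p1, p2 = p2, label = label), class = "guide_line")
}

#' @export
print.guide_line <- function(x, ...) {
  cat(sprintf("<guide_line %s> (%.3f, %.3f, %.3f) -- (%.3f, %.3f, %.3f)\n",
              x$label, x$p1[1], x$p1[2], x$p1[3], x$p2[1], x$p2[2], x$p2[3]))
  invisible(x)
}

#' Intersect the vertical and horizontal guide lines into a landmark
#'
#' For exactly intersecting lines the landmark is the intersection point
#' with `gap_mm = 0`. For skew lines it is the midpoint of the mutual
#' perpendicular segment, with `gap_mm` equal to the segment length (the
#' true minimum distance between the infinite lines); a warning is emitted
#' when the gap exceeds `tolerance`, flagging a sloppy pick.
#'
#' @param vertical,horizontal [guide_line()] objects (order does not affect
#'   the result).
#' @param tolerance Gap (mm) above which a warning is raised. Default 0.5.
#' @param name,arch,timepoint Metadata recorded on the landmark.
#' @return A one-row tibble (the landmark) with columns `name`, `arch`,
#'   `timepoint`, `x`, `y`, `z`, `gap_mm`, `snap_mm`, `gap_warning`.
#' @export
#' @examples
#' v <- guide_line(c(0, -1, 0), c(0, 1, 0), "vertical")
#' h <- guide_line(c(-1, 0, 0), c(1, 0, 0), "horizontal")
#' intersect_guides(v, h)
intersect_guides <- function(vertical, horizontal, tolerance = 0.5,
                             name = "ucs_landmark",
                             arch = c("maxilla", "mandible"),
                             timepoint = c("T0", "T1")) {
  arch <- match.arg(arch)
  timepoint <- match.arg(timepoint)
  stopifnot(inherits(vertical, "guide_line"), inherits(horizontal, "guide_line"))
  d1 <- unitize(vertical$p2 - vertical$p1)
  d2 <- unitize(horizontal$p2 - horizontal$p1)
  cr <- cross3(d1, d2)
  sin_angle <- vnorm(cr)
  if (sin_angle <= 1e-6) {
    stop("degenerate geometry: guide lines are (near-)parallel ",
         "(angle <= 1e-6 rad)", call. = FALSE)
  }
  # Closest points: solve [d1.d1 -d1.d2; d1.d2 -d2.d2] (t, s)' = (w.d1, w.d2)'
  w <- horizontal$p1 - vertical$p1
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  den <- a * cc - b * b
  t1 <- (sum(w * d1) * cc - sum(w * d2) * b) / den
  t2 <- (sum(w * d1) * b - sum(w * d2) * a) / den
  q1 <- vertical$p1 + t1 * d1
  q2 <- horizontal$p1 + t2 * d2
  gap <- vnorm(q1 - q2)
  mid <- (q1 + q2) / 2
  warn <- gap > tolerance
  if (warn) {
    warning(sprintf("guide lines miss each other by %.3f mm (> %.3f mm tolerance)",
                    gap, tolerance), call. = FALSE)
  }
  tibble::tibble(
    name = name, arch = arch, timepoint = timepoint,
    x = mid[1], y = mid[2], z = mid[3],
    gap_mm = gap, snap_mm = NA_real_, gap_warning = warn)
}

#' Closest point on a mesh surface
#'
#' Exact closest point over every triangle (face interior, edge or vertex),
#' with a deterministic tie-break by lowest face index.
#'
#' @param mesh A non-empty [surface_mesh()].
#' @param point Numeric length-3 query point (mm).
#' @return A list with `point` (closest surface point), `distance` (mm), and
#'   `face` (1-based index of the winning triangle).
#' @export
snap_to_surface <- function(mesh, point) {
  point <- vec3(point)
  f <- mesh$faces
  if (nrow(f) == 0) stop("cannot snap to an empty mesh", call. = FALSE)
  v <- mesh$vertices
  best <- list(point = NULL, distance = Inf, face = NA_integer_)
  for (i in seq_len(nrow(f))) {
    q <- unname(closest_point_on_triangle(point, v[f[i, 1], ], v[f[i, 2], ],
                                          v[f[i, 3], ]))
    d <- vnorm(point - q)
    if (d < best$distance - 1e-15) {
      best <- list(point = q, distance = d, face = i)
    }
  }
  best
}

# Ericson's closest-point-on-triangle (Real-Time Collision Detection, 5.1.5).
closest_point_on_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    return(b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b))
  }
  den <- 1 / (va + vb + vc)
  a + ab * (vb * den) + ac * (vc * den)
}

#' Construct the arch superposition landmark from guide lines
#'
#' Composes [intersect_guides()] with an optional snap of the landmark onto
#' the mesh surface (snapping is for visual QC; the superposition itself
#' only needs the coordinates).
#'
#' @inheritParams intersect_guides
#' @param mesh The arch [surface_mesh()].
#' @param snap If `TRUE` (default), replace the landmark point by its
#'   closest point on the mesh and record the snap distance.
#' @return A one-row landmark tibble as in [intersect_guides()], with
#'   `snap_mm` filled in when `snap = TRUE`.
#' @export
make_arch_landmark <- function(mesh, vertical, horizontal, tolerance = 0.5,
                               snap = TRUE, name = "ucs_landmark",
                               arch = c("maxilla", "mandible"),
                               timepoint = c("T0", "T1")) {
  lm <- intersect_guides(vertical, horizontal, tolerance = tolerance,
                         name = name, arch = match.arg(arch),
                         timepoint = match.arg(timepoint))
  if (snap) {
    s <- snap_to_surface(mesh, c(lm$x, lm$y, lm$z))
    lm$x <- s$point[1]; lm$y <- s$point[2]; lm$z <- s$point[3]
    lm$snap_mm <- s$distance
  }
  lm
}

landmark_point <- function(landmark) c(landmark$x, landmark$y, landmark$z)

#' Write / read a landmark as JSON
#'
#' @param landmark A one-row landmark tibble.
#' @param path JSON path.
#' @return `path` invisibly / the landmark tibble.
#' @export
write_landmark <- function(landmark, path) {
  jsonlite::write_json(landmark, path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_landmark
#' @export
read_landmark <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}
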