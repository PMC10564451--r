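# Synthetic dental arches with known ground truth.
#
# Teeth are analytic cones placed along a parabolic arch curve; each cone
# apex IS the cusp/incisal landmark, so applied movements can be recovered
# exactly by the measurement pipeline (ground-truth closure). Realistic
# crown/gingiva geometry is deliberately out of scope: the math under test
# needs exact landmarks, not anatomy.

#' Specification of a synthetic arch
#'
#' @param arch `"maxilla"` or `"mandible"`.
#' @param n_teeth_per_side Teeth per quadrant (default 7: incisors to second
#'   molar).
#' @param arch_width Transverse distance (mm) spanned by the arch at the
#'   distal molars (default 50).
#' @param arch_depth Anteroposterior depth (mm) from molars to incisors
#'   (default 40).
#' @param tooth_height Cone height (mm), base plane to cusp apex (default 8).
#' @param tooth_radius Cone base radius (mm, default 3).
#' @param seed Integer seed recorded on the spec; arch construction itself
#'   is deterministic, the seed feeds downstream noise simulators.
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(arch = c("maxilla", "mandible"), n_teeth_per_side = 7,
                      arch_width = 50, arch_depth = 40, tooth_height = 8,
                      tooth_radius = 3, seed = 1L) {
  arch <- match.arg(arch)
  if (n_teeth_per_side < 2) stop("need n_teeth_per_side >= 2", call. = FALSE)
  if (min(arch_width, arch_depth, tooth_height, tooth_radius) <= 0) {
    stop("arch dimensions must be positive", call. = FALSE)
  }
  structure(list(arch = arch, n_teeth_per_side = as.integer(n_teeth_per_side),
                 arch_width = arch_width, arch_depth = arch_depth,
                 tooth_height = tooth_height, tooth_radius = tooth_radius,
                 seed = as.integer(seed)),
            class = "arch_spec")
}

# Parabolic arch curve: x in [-w/2, w/2], y = depth * (1 - (2x/w)^2).
# Anterior teeth sit near the apex (x ~ 0), molars at the open ends.
arch_curve_point <- function(spec, x) {
  c(x, spec$arch_depth * (1 - (2 * x / spec$arch_width)^2), 0)
}

arch_curve_tangent <- function(spec, x) {
  unitize(c(1, spec$arch_depth * (-8 * x / spec$arch_width^2), 0))
}

# Tooth id: U/L for arch, R (x < 0) or L (x > 0), position 1 (central
# incisor, nearest midline) .. n (most distal).
tooth_positions <- function(spec) {
  n <- spec$n_teeth_per_side
  w <- spec$arch_width
  step <- w / (2 * n)
  xs <- c(-rev(seq_len(n)), seq_len(n))  # slot indices -n..-1, 1..n
  xs <- (abs(xs) - 0.5) * step * sign(xs)
  pos <- c(rev(seq_len(n)), seq_len(n))
  side <- rep(c("R", "L"), each = n)
  prefix <- if (spec$arch == "maxilla") "U" else "L"
  tibble::tibble(
    tooth_id = paste0(prefix, side, pos), position = pos, side = side,
    x = xs)
}

#' Generate a synthetic arch: mesh, tooth points, and guide lines
#'
#' Places `2 * n_teeth_per_side` conical teeth along a parabolic arch curve.
#' Each cone apex is the exact cusp/incisal landmark: incisors and canines
#' get incisal-edge points (mesial/mid/distal along the local arch tangent)
#' plus the canine cusp tip / buccal cusp; premolars and molars get the
#' mesiobuccal cusp. A midline vertical guide line and a transverse
#' horizontal guide line are emitted so the landmarking stage can be
#' exercised; they intersect exactly on the arch base plane. Fully
#' deterministic given the spec.
#'
#' @param spec An [arch_spec()].
#' @return A list of class `synthetic_arch`: `mesh` ([surface_mesh()]),
#'   `points` (tooth-points tibble, timepoint `"T0"`), `guides` (list with
#'   `vertical` and `horizontal` [guide_line()]s), `centers` (per-tooth
#'   placement table), `spec`.
#' @export
#' @examples
#' arch <- generate_arch(arch_spec("mandible"))
#' arch$mesh
generate_arch <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  teeth <- tooth_positions(spec)
  n_seg <- 8L
  verts <- list(); faces <- list(); pts <- list()
  v_off <- 0L
  edge_half <- min(1.5, spec$tooth_radius / 2)
  for (i in seq_len(nrow(teeth))) {
    ctr <- arch_curve_point(spec, teeth$x[i])
    tang <- arch_curve_tangent(spec, teeth$x[i])
    apex <- ctr + c(0, 0, spec$tooth_height)
    ang <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
    ring <- cbind(ctr[1] + spec$tooth_radius * cos(ang),
                  ctr[2] + spec$tooth_radius * sin(ang),
                  ctr[3])
    tooth_v <- rbind(ring, apex, ctr)          # n_seg + apex + base centre
    apex_i <- n_seg + 1L; base_i <- n_seg + 2L
    side <- cbind(seq_len(n_seg), c(seq_len(n_seg)[-1], 1L), apex_i)
    base <- cbind(c(seq_len(n_seg)[-1], 1L), seq_len(n_seg), base_i)
    verts[[i]] <- tooth_v
    faces[[i]] <- rbind(side, base) + v_off
    v_off <- v_off + nrow(tooth_v)

    id <- teeth$tooth_id[i]; p <- teeth$position[i]
    add_pt <- function(role, q) tibble::tibble(
      tooth_id = id, role = role, timepoint = "T0",
      x = q[1], y = q[2], z = q[3])
    tooth_pts <- list()
    if (p <= 3) {  # incisors and canines: incisal edge along local tangent
      tooth_pts <- c(tooth_pts, list(
        add_pt("incisal_edge_mesial", apex - edge_half * tang),
        add_pt("incisal_edge_distal", apex + edge_half * tang),
        add_pt("incisal_edge_mid", apex)))
    }
    if (p == 3) {
      tooth_pts <- c(tooth_pts, list(add_pt("canine_cusp_tip", apex),
                                     add_pt("buccal_cusp", apex)))
    }
    if (p >= 4) {
      tooth_pts <- c(tooth_pts, list(add_pt("mesiobuccal_cusp", apex)))
    }
    pts[[i]] <- dplyr::bind_rows(tooth_pts)
  }
  mesh <- surface_mesh(do.call(rbind, verts), do.call(rbind, faces),
                       source_label = paste0(spec$arch, "_T0"))
  y_ruga <- 0.6 * spec$arch_depth
  guides <- list(
    vertical = guide_line(c(0, -5, 0), c(0, spec$arch_depth + 5, 0),
                          "vertical"),
    horizontal = guide_line(c(-10, y_ruga, 0), c(10, y_ruga, 0),
                            "horizontal"))
  structure(list(mesh = mesh, points = as_tooth_points(dplyr::bind_rows(pts)),
                 guides = guides, centers = teeth, spec = spec),
            class = "synthetic_arch")
}

#' @export
print.synthetic_arch <- function(x, ...) {
  cat(sprintf("<synthetic_arch> %s: %d teeth, %d mesh faces, %d tooth points\n",
              x$spec$arch, nrow(x$centers), nrow(x$mesh$faces),
              nrow(x$points)))
  invisible(x)
}

#' Per-tooth movement specification
#'
#' @param per_tooth Tibble with columns `tooth_id`, `buccolingual`,
#'   `mesiodistal`, `vertical` (signed mm; vertical + = toward the gingiva),
#'   `rotation` (degrees about the tooth's own vertical axis, in
#'   `(-180, 180]`). Omitted movements default to 0.
#' @param global_offset Length-3 translation (mm) modelling the
#'   scanner-pose difference between the T0 and T1 acquisitions.
#' @param global_rotation Degrees of global rotation about the vertical
#'   axis through the origin, applied with the offset; nonzero values exist
#'   for negative-control experiments on the translation-only superposition
#'   assumption. Default 0.
#' @return An object of class `movement_spec`.
#' @export
movement_spec <- function(per_tooth = NULL, global_offset = c(0, 0, 0),
                          global_rotation = 0) {
  if (is.null(per_tooth)) {
    per_tooth <- tibble::tibble(tooth_id = character())
  }
  per_tooth <- tibble::as_tibble(per_tooth)
  for (cc in c("buccolingual", "mesiodistal", "vertical", "rotation")) {
    if (is.null(per_tooth[[cc]])) per_tooth[[cc]] <- 0
    if (any(!is.finite(per_tooth[[cc]]))) {
      stop("non-finite movement value in '", cc, "'", call. = FALSE)
    }
  }
  if (any(per_tooth$rotation <= -180 | per_tooth$rotation > 180)) {
    stop("rotation must lie in (-180, 180] degrees", call. = FALSE)
  }
  structure(list(per_tooth = per_tooth, global_offset = vec3(global_offset),
                 global_rotation = global_rotation),
            class = "movement_spec")
}

#' Apply known tooth movements plus a global pose change to build T1
#'
#' Each listed tooth is rotated about its own vertical axis (through its
#' arch-curve centre) and then translated by its signed buccolingual (X),
#' mesiodistal (Y) and vertical (Z, + toward gingiva) components — the same
#' axes the measurement stage projects onto, so noise-free recovery is
#' exact. The whole T1 model (mesh, points, guide lines) then receives the
#' global rotation (if any) and offset, emulating a different scanner pose
#' at the second acquisition.
#'
#' @param arch A `synthetic_arch` from [generate_arch()].
#' @param spec A [movement_spec()]; every `tooth_id` must exist in the arch.
#' @return A list of class `synthetic_pair`: `arch_t0` (the input), `mesh_t1`,
#'   `points_t1` (timepoint `"T1"`), `guides_t1`, `ground_truth` (tibble of
#'   applied per-tooth values), `global_transform` (the applied pose
#'   [rigid_transform()]).
#' @export
apply_movements <- function(arch, spec) {
  stopifnot(inherits(arch, "synthetic_arch"), inherits(spec, "movement_spec"))
  unknown <- setdiff(spec$per_tooth$tooth_id, arch$centers$tooth_id)
  if (length(unknown) > 0) {
    stop("unknown tooth_id(s) in movement spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mesh <- arch$mesh
  pts <- arch$points
  verts <- mesh$vertices
  pm <- cbind(pts$x, pts$y, pts$z)
  n_seg_block <- nrow(verts) / nrow(arch$centers)  # vertices per tooth block
  for (j in seq_len(nrow(spec$per_tooth))) {
    row <- spec$per_tooth[j, ]
    i <- match(row$tooth_id, arch$centers$tooth_id)
    ctr <- arch_curve_point(arch$spec, arch$centers$x[i])
    vidx <- ((i - 1) * n_seg_block + 1):(i * n_seg_block)
    pidx <- which(pts$tooth_id == row$tooth_id)
    d <- c(row$buccolingual, row$mesiodistal, row$vertical)
    if (row$rotation != 0) {
      verts[vidx, ] <- rotate_about_vertical(verts[vidx, , drop = FALSE],
                                             row$rotation, ctr[1], ctr[2])
      pm[pidx, ] <- rotate_about_vertical(pm[pidx, , drop = FALSE],
                                          row$rotation, ctr[1], ctr[2])
    }
    verts[vidx, ] <- sweep(verts[vidx, , drop = FALSE], 2, d, "+")
    pm[pidx, ] <- sweep(pm[pidx, , drop = FALSE], 2, d, "+")
  }
  rot <- if (spec$global_rotation != 0) {
    rotation_about_axis(c(0, 0, 1), spec$global_rotation)
  } else diag(3)
  pose <- rigid_transform(rotation = rot, translation = spec$global_offset)
  verts <- transform_coords(verts, pose)
  pm <- transform_coords(pm, pose)
  mesh_t1 <- surface_mesh(verts, mesh$faces,
                          source_label = sub("_T0$", "_T1",
                                             mesh$source_label))
  points_t1 <- pts
  points_t1$x <- pm[, 1]; points_t1$y <- pm[, 2]; points_t1$z <- pm[, 3]
  points_t1$timepoint <- "T1"
  guides_t1 <- list(
    vertical = guide_line(apply_transform(arch$guides$vertical$p1, pose),
                          apply_transform(arch$guides$vertical$p2, pose),
                          "vertical"),
    horizontal = guide_line(apply_transform(arch$guides$horizontal$p1, pose),
                            apply_transform(arch$guides$horizontal$p2, pose),
                            "horizontal"))
  truth <- tidyr::pivot_longer(
    spec$per_tooth, cols = c("buccolingual", "mesiodistal", "vertical",
                             "rotation"),
    names_to = "movement", values_to = "value")
  truth$units <- ifelse(truth$movement == "rotation", "degrees", "mm")
  structure(list(arch_t0 = arch, mesh_t1 = mesh_t1, points_t1 = points_t1,
                 guides_t1 = guides_t1, ground_truth = truth,
                 global_transform = pose),
            class = "synthetic_pair")
}

#' Simulate repeated digitization of tooth points
#'
#' Adds isotropic Gaussian jitter to every point, independently per repeat,
#' modelling operator point-placement error in repeated examinations.
#'
#' @param points A tooth-points tibble.
#' @param sd Per-axis standard deviation of the jitter (mm), `>= 0`.
#' @param n_repeats Number of repeated digitizations.
#' @param seed Integer seed; results are reproducible.
#' @return A tibble: the input rows replicated with a `repeat_id` column and
#'   jittered coordinates.
#' @export
simulate_digitization <- function(points, sd, n_repeats = 2, seed = 1L) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  points <- as_tooth_points(points)
  n <- nrow(points)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    purrr::map_dfr(seq_len(n_repeats), function(r) {
      out <- points
      out$repeat_id <- r
      out$x <- out$x + stats::rnorm(n, 0, sd)
      out$y <- out$y + stats::rnorm(n, 0, sd)
      out$z <- out$z + stats::rnorm(n, 0, sd)
      out
    })
  })
}

#' Simulate a subjects-by-measurements rater study
#'
#' Generates `value[i, j] = true[i] + e[i, j]` with
#' `e ~ N(0, sigma_error^2)`: the additive two-way model underlying
#' ICC(2,1), so the expected ICC is
#' `var(true) / (var(true) + sigma_error^2)`.
#'
#' @param true_values Numeric vector of per-subject true values (length
#'   `n >= 2`).
#' @param sigma_error Error SD, `>= 0`.
#' @param k_measurements Number of repeated measurements (`>= 2`).
#' @param seed Integer seed.
#' @return A long tibble with columns `subject`, `rater`, `value`, directly
#'   consumable by [icc_2_1()].
#' @export
simulate_rater_study <- function(true_values, sigma_error, k_measurements = 2,
                                 seed = 1L) {
  n <- length(true_values)
  if (n < 2 || k_measurements < 2) {
    stop("need >= 2 subjects and >= 2 measurements", call. = FALSE)
  }
  if (sigma_error < 0) stop("sigma_error must be >= 0", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  tidyr::expand_grid(subject = seq_len(n), rater = seq_len(k_measurements)) |>
    dplyr::mutate(value = true_values[.data$subject] +
                    stats::rnorm(dplyr::n(), 0, sigma_error))
}
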