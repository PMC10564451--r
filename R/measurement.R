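# Per-tooth movement measurement between superposed T0 and T1 models.
#
# Axis conventions of the shared coordinate frame: X buccolingual,
# Y mesiodistal, Z vertical. Signs: displacement toward the gingiva is
# intrusion (+), toward the occlusal plane is extrusion (-); rotation is the
# unsigned acute angle (degrees, [0, 90]) between the projections of the T0
# and T1 incisal-edge lines onto the occlusal plane.

#' Arch measurement frame
#'
#' Directions that fix the signs of the vertical measurement and the
#' projection plane of the rotation measurement. The gingival direction
#' depends on how the arch is oriented in the scanner frame and must be set
#' per dataset; the default (+Z) matches an occlusal-surface-up mandible.
#'
#' @param gingival_direction Unit 3-vector pointing from the occlusal
#'   surfaces toward the gingiva.
#' @param occlusal_plane_normal Unit 3-vector normal to the occlusal plane.
#' @return An object of class `arch_frame`.
#' @export
arch_frame <- function(gingival_direction = c(0, 0, 1),
                       occlusal_plane_normal = c(0, 0, 1)) {
  g <- vec3(gingival_direction); n <- vec3(occlusal_plane_normal)
  if (abs(vnorm(g) - 1) > 1e-9) {
    stop("gingival_direction must be unit length within 1e-9", call. = FALSE)
  }
  if (abs(vnorm(n) - 1) > 1e-9) {
    stop("occlusal_plane_normal must be unit length within 1e-9", call. = FALSE)
  }
  structure(list(gingival_direction = g, occlusal_plane_normal = n),
            class = "arch_frame")
}

movement_record <- function(tooth_id, movement, value, units, axis,
                            points_used, status = "ok") {
  tibble::tibble(
    tooth_id = tooth_id, movement = movement,
    value = value, magnitude = abs(value), units = units, axis = axis,
    points_used = points_used, status = status)
}

#' Single-axis translation measurements
#'
#' `buccolingual_translation()` projects the T0-to-T1 displacement of a cusp
#' point onto the X axis (buccal cusps of canines, mesiobuccal cusps of
#' premolars and molars); `mesiodistal_translation()` onto the Y axis.
#' Models must already be superposed.
#'
#' @param p_t0,p_t1 Numeric length-3 points (mm) for the same tooth and role
#'   at T0 and T1.
#' @param tooth_id,role Identification recorded on the output.
#' @return A one-row movement-record tibble with signed `value` (mm) and its
#'   `magnitude`.
#' @export
#' @examples
#' buccolingual_translation(c(10, 5, 2), c(10.4, 5, 2), tooth_id = "UR3")
buccolingual_translation <- function(p_t0, p_t1, tooth_id = "",
                                     role = "buccal_cusp") {
  d <- vec3(p_t1) - vec3(p_t0)
  movement_record(tooth_id, "buccolingual_translation", d[1], "mm", "X", role)
}

#' @rdname buccolingual_translation
#' @export
mesiodistal_translation <- function(p_t0, p_t1, tooth_id = "",
                                    role = "buccal_cusp") {
  d <- vec3(p_t1) - vec3(p_t0)
  movement_record(tooth_id, "mesiodistal_translation", d[2], "mm", "Y", role)
}

#' Vertical movement (intrusion / extrusion)
#'
#' Projects the displacement onto the gingival direction of the
#' [arch_frame()]: positive values are intrusion (movement toward the
#' gingiva), negative values extrusion (toward the occlusal plane). Measured
#' on canine cusp tips and the middle of the incisal edges.
#'
#' @inheritParams buccolingual_translation
#' @param frame An [arch_frame()].
#' @return A one-row movement-record tibble (mm, Z axis by default frame).
#' @export
vertical_movement <- function(p_t0, p_t1, frame = arch_frame(),
                              tooth_id = "", role = "incisal_edge_mid") {
  stopifnot(inherits(frame, "arch_frame"))
  d <- vec3(p_t1) - vec3(p_t0)
  movement_record(tooth_id, "vertical", sum(d * frame$gingival_direction),
                  "mm", "Z", role)
}

#' Rotation angle between the T0 and T1 incisal-edge lines
#'
#' Both edges (mesial and distal incisal-edge points of the same tooth) are
#' projected onto the occlusal plane; the result is the unsigned acute angle
#' between the undirected projected lines, in degrees, in \[0, 90\]. The
#' undirected convention makes the value independent of which edge point
#' was picked first.
#'
#' @param edge_t0,edge_t1 Lists/matrices of two length-3 points each: the
#'   mesial and distal incisal-edge picks at each time point.
#' @param frame An [arch_frame()] supplying the occlusal plane normal.
#' @param tooth_id Identification recorded on the output.
#' @return A one-row movement-record tibble (`units = "degrees"`,
#'   `axis = "XY-plane"` for the default frame).
#' @export
#' @examples
#' e0 <- rbind(c(0, 0, 0), c(1, 0, 0))
#' e1 <- rbind(c(0, 0, 0), c(0, 1, 0))
#' rotation_angle(e0, e1, tooth_id = "LR1")$value  # 90
rotation_angle <- function(edge_t0, edge_t1, frame = arch_frame(),
                           tooth_id = "") {
  stopifnot(inherits(frame, "arch_frame"))
  proj_dir <- function(edge) {
    edge <- if (is.matrix(edge)) edge else do.call(rbind, edge)
    d <- edge[2, ] - edge[1, ]
    d <- d - sum(d * frame$occlusal_plane_normal) * frame$occlusal_plane_normal
    if (vnorm(d) < 1e-12) {
      stop("degenerate geometry: incisal edge projects to a point in the ",
           "occlusal plane", call. = FALSE)
    }
    d / vnorm(d)
  }
  u <- proj_dir(edge_t0); v <- proj_dir(edge_t1)
  # undirected lines: fold to [0, 90]; atan2 keeps precision near 0 and 90
  ang <- atan2(vnorm(cross3(u, v)), abs(sum(u * v))) * 180 / pi
  movement_record(tooth_id, "rotation", ang, "degrees", "XY-plane",
                  "incisal_edge_mesial+incisal_edge_distal")
}

#' Arch expansion between antimeric teeth
#'
#' Change in the transverse distance between a left/right tooth pair (same
#' role on both sides): `||left_t1 - right_t1|| - ||left_t0 - right_t0||`,
#' positive for expansion.
#'
#' @param p_left_t0,p_right_t0,p_left_t1,p_right_t1 Length-3 points (mm).
#' @param tooth_pair Label for the pair, e.g. `"UR6:UL6"`.
#' @param role Shared point role.
#' @return A one-row movement-record tibble (mm).
#' @export
arch_expansion <- function(p_left_t0, p_right_t0, p_left_t1, p_right_t1,
                           tooth_pair = "", role = "mesiobuccal_cusp") {
  w0 <- vnorm(vec3(p_left_t0) - vec3(p_right_t0))
  w1 <- vnorm(vec3(p_left_t1) - vec3(p_right_t1))
  movement_record(tooth_pair, "arch_expansion", w1 - w0, "mm", "XY-plane", role)
}

#' Measurement plan for a batch of teeth
#'
#' A plan is a tibble with columns `movement`, `tooth_id`, `role`, and
#' (for `arch_expansion` rows) `tooth_id_2`; [measure_arch()] executes one
#' row per requested measurement. `default_measurement_plan()` builds the
#' protocol used for aligner-refinement scans: buccolingual translation of
#' canines (buccal cusp), premolars and molars (mesiobuccal cusp); vertical
#' movement and rotation of incisors and canines; plus arch expansion for
#' each antimeric pair carrying a translation cusp.
#'
#' @param points A tooth-points tibble (roles present decide which rows the
#'   plan gets).
#' @return A plan tibble.
#' @export
default_measurement_plan <- function(points) {
  points <- as_tooth_points(points)
  keys <- dplyr::distinct(points[points$timepoint == "T0", ],
                          .data$tooth_id, .data$role)
  rows <- list()
  bl <- keys[keys$role %in% c("buccal_cusp", "mesiobuccal_cusp"), ]
  if (nrow(bl) > 0) {
    rows$bl <- tibble::tibble(movement = "buccolingual_translation",
                              tooth_id = bl$tooth_id, role = bl$role,
                              tooth_id_2 = NA_character_)
  }
  vt <- keys[keys$role %in% c("canine_cusp_tip", "incisal_edge_mid"), ]
  if (nrow(vt) > 0) {
    rows$vt <- tibble::tibble(movement = "vertical",
                              tooth_id = vt$tooth_id, role = vt$role,
                              tooth_id_2 = NA_character_)
  }
  has_edge <- intersect(
    unique(keys$tooth_id[keys$role == "incisal_edge_mesial"]),
    unique(keys$tooth_id[keys$role == "incisal_edge_distal"]))
  if (length(has_edge) > 0) {
    rows$rot <- tibble::tibble(movement = "rotation", tooth_id = has_edge,
                               role = "incisal_edge_pair",
                               tooth_id_2 = NA_character_)
  }
  # Antimeric pairs: same arch+position, opposite side (UR3 <-> UL3 etc.)
  side <- substr(bl$tooth_id, 2, 2)
  pos <- paste0(substr(bl$tooth_id, 1, 1), substr(bl$tooth_id, 3, 10))
  lefts <- bl[side == "L", ]; rights <- bl[side == "R", ]
  pos_l <- pos[side == "L"]; pos_r <- pos[side == "R"]
  common <- intersect(pos_l, pos_r)
  if (length(common) > 0) {
    rows$exp <- tibble::tibble(
      movement = "arch_expansion",
      tooth_id = lefts$tooth_id[match(common, pos_l)],
      role = lefts$role[match(common, pos_l)],
      tooth_id_2 = rights$tooth_id[match(common, pos_r)])
  }
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble::tibble(movement = character(), tooth_id = character(),
                          role = character(), tooth_id_2 = character())
  }
  out
}

#' Measure every planned movement on a superposed scan pair
#'
#' Executes a measurement plan against the T0 and (already superposed) T1
#' tooth points. Missing counterpart points are reported with
#' `status = "missing"` rather than silently skipped.
#'
#' @param points_t0,points_t1 Tooth-points tibbles for the two time points
#'   (the `timepoint` column is ignored; each table is taken as its stated
#'   time point). `points_t1` must already be in the T0 frame, i.e. after
#'   [apply_transform()] with the superposition transform.
#' @param frame An [arch_frame()].
#' @param plan A plan tibble (see [default_measurement_plan()]); defaults to
#'   the standard protocol derived from the roles present.
#' @return A movement-record tibble, one row per plan row; rows whose points
#'   are missing have `value = NA` and `status = "missing"`.
#' @export
measure_arch <- function(points_t0, points_t1, frame = arch_frame(),
                         plan = NULL) {
  p0 <- as_tooth_points(points_t0)
  p1 <- as_tooth_points(points_t1)
  if (is.null(plan)) {
    both <- dplyr::bind_rows(
      dplyr::mutate(p0, timepoint = "T0"),
      dplyr::mutate(p1, timepoint = "T1"))
    both <- both[!duplicated(both[c("tooth_id", "role", "timepoint")]), ]
    plan <- default_measurement_plan(both)
  }
  if (nrow(plan) == 0) {
    return(movement_record(character(), character(), numeric(), character(),
                           character(), character(), character()))
  }
  get_pt <- function(tbl, tooth, role) {
    hit <- tbl[tbl$tooth_id == tooth & tbl$role == role, ]
    if (nrow(hit) != 1) NULL else c(hit$x, hit$y, hit$z)
  }
  missing_rec <- function(tooth, movement, role, units, axis) {
    movement_record(tooth, movement, NA_real_, units, axis, role,
                    status = "missing")
  }
  recs <- purrr::pmap(plan, function(movement, tooth_id, role, tooth_id_2) {
    if (movement == "rotation") {
      e0m <- get_pt(p0, tooth_id, "incisal_edge_mesial")
      e0d <- get_pt(p0, tooth_id, "incisal_edge_distal")
      e1m <- get_pt(p1, tooth_id, "incisal_edge_mesial")
      e1d <- get_pt(p1, tooth_id, "incisal_edge_distal")
      if (is.null(e0m) || is.null(e0d) || is.null(e1m) || is.null(e1d)) {
        return(missing_rec(tooth_id, movement, role, "degrees", "XY-plane"))
      }
      return(rotation_angle(rbind(e0m, e0d), rbind(e1m, e1d), frame,
                            tooth_id = tooth_id))
    }
    if (movement == "arch_expansion") {
      l0 <- get_pt(p0, tooth_id, role); r0 <- get_pt(p0, tooth_id_2, role)
      l1 <- get_pt(p1, tooth_id, role); r1 <- get_pt(p1, tooth_id_2, role)
      pair <- paste0(tooth_id, ":", tooth_id_2)
      if (is.null(l0) || is.null(r0) || is.null(l1) || is.null(r1)) {
        return(missing_rec(pair, movement, role, "mm", "XY-plane"))
      }
      return(arch_expansion(l0, r0, l1, r1, tooth_pair = pair, role = role))
    }
    a <- get_pt(p0, tooth_id, role); b <- get_pt(p1, tooth_id, role)
    units <- "mm"
    axis <- switch(movement, buccolingual_translation = "X",
                   mesiodistal_translation = "Y", vertical = "Z",
                   stop("unknown movement in plan: ", movement, call. = FALSE))
    if (is.null(a) || is.null(b)) {
      return(missing_rec(tooth_id, movement, role, units, axis))
    }
    switch(movement,
           buccolingual_translation =
             buccolingual_translation(a, b, tooth_id = tooth_id, role = role),
           mesiodistal_translation =
             mesiodistal_translation(a, b, tooth_id = tooth_id, role = role),
           vertical =
             vertical_movement(a, b, frame, tooth_id = tooth_id, role = role))
  })
  dplyr::bind_rows(recs)
}
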