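# Tooth point annotations: cusp tips and incisal-edge points digitised on
# each scan. Stored as a tibble ("tooth points" table) with one row per
# (tooth_id, role, timepoint) and mm coordinates.

#' Closed vocabulary of tooth-point roles
#'
#' Buccal cusps of canines and mesiobuccal cusps of premolars/molars carry
#' the translation measurements; canine cusp tips and incisal-edge points
#' carry the vertical and rotation measurements.
#'
#' @return Character vector of valid `role` values.
#' @export
tooth_point_roles <- function() {
  c("buccal_cusp", "mesiobuccal_cusp", "incisal_edge_mesial",
    "incisal_edge_distal", "incisal_edge_mid", "canine_cusp_tip")
}

#' Build a validated tooth-points table
#'
#' @param x A data frame with columns `tooth_id`, `role`, `timepoint`,
#'   `x`, `y`, `z` (coordinates in mm).
#' @return A tibble with those columns, validated: roles drawn from
#'   [tooth_point_roles()], timepoints in `{T0, T1}`, finite coordinates,
#'   and each `(tooth_id, role, timepoint)` key unique.
#' @export
#' @examples
#' as_tooth_points(data.frame(
#'   tooth_id = "LR3", role = "canine_cusp_tip", timepoint = "T0",
#'   x = 10.1, y = -21.0, z = 8.4))
as_tooth_points <- function(x) {
  need <- c("tooth_id", "role", "timepoint", "x", "y", "z")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("tooth-points table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pts <- tibble::as_tibble(x)[need]
  pts$tooth_id <- as.character(pts$tooth_id)
  pts$role <- as.character(pts$role)
  pts$timepoint <- as.character(pts$timepoint)
  bad_role <- setdiff(unique(pts$role), tooth_point_roles())
  if (length(bad_role) > 0) {
    stop("unknown tooth-point role(s): ", paste(bad_role, collapse = ", "),
         "; valid roles are ", paste(tooth_point_roles(), collapse = ", "),
         call. = FALSE)
  }
  bad_tp <- setdiff(unique(pts$timepoint), c("T0", "T1"))
  if (length(bad_tp) > 0) {
    stop("timepoint must be 'T0' or 'T1', got: ",
         paste(bad_tp, collapse = ", "), call. = FALSE)
  }
  for (cc in c("x", "y", "z")) {
    pts[[cc]] <- as.numeric(pts[[cc]])
    if (any(!is.finite(pts[[cc]]))) {
      stop("non-finite coordinate in column '", cc, "'", call. = FALSE)
    }
  }
  key <- paste(pts$tooth_id, pts$role, pts$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (tooth_id, role, timepoint) key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  pts
}

#' Read tooth points from JSON or CSV
#'
#' JSON is the canonical sidecar format (an array of records); CSV is
#' accepted for spreadsheet users. Decimal points are mandatory in CSV:
#' comma decimal separators make coordinates unparseable and are reported
#' with the offending row number.
#'
#' @param path A `.json` or `.csv` file with fields
#'   `tooth_id, role, timepoint, x, y, z`.
#' @return A validated tooth-points tibble (see [as_tooth_points()]).
#' @export
read_tooth_points <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    return(as_tooth_points(df))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (cc in c("x", "y", "z")) {
    num <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(num) & !is.na(df[[cc]]))
    if (length(bad) > 0) {
      stop("cannot parse '", df[[cc]][bad[1]], "' in column '", cc,
           "' at data row ", bad[1],
           " (decimal separator must be '.', not ',')", call. = FALSE)
    }
    df[[cc]] <- num
  }
  as_tooth_points(df)
}

#' Write tooth points to JSON or CSV
#'
#' Round-trips losslessly with [read_tooth_points()] (full double precision
#' is serialised).
#'
#' @param points A tooth-points table (validated on the way out).
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_tooth_points <- function(points, path) {
  points <- as_tooth_points(points)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(points, path, digits = NA, dataframe = "rows")
  } else {
    df <- as.data.frame(points)
    for (cc in c("x", "y", "z")) df[[cc]] <- sprintf("%.17g", df[[cc]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
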