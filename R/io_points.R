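# Plain-text exchange formats: CSV point lists and JSON / text transforms.

#' Write / read a 2D point list CSV
#'
#' Columns `id, u, v` (pixels, 0-based image coordinates).
#'
#' @param points Data frame with columns `id`, `u`, `v`.
#' @param path File path.
#' @export
write_points_2d <- function(points, path) {
  stopifnot(all(c("id", "u", "v") %in% names(points)))
  utils::write.csv(points[, c("id", "u", "v")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_2d
#' @export
read_points_2d <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("id", "u", "v") %in% names(df)))
  df
}

#' Write / read a labelled 3D point set CSV
#'
#' Columns `id, x, y, z` in mm; the space tag is kept in a comment-free
#' extra column `space`.
#'
#' @param ps A [point_set_3d()].
#' @param path File path.
#' @export
write_points_3d <- function(ps, path) {
  stopifnot(inherits(ps, "point_set_3d"))
  df <- data.frame(id = ps$labels, ps$coords, space = ps$space)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_3d
#' @export
read_points_3d <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("id", "x", "y", "z") %in% names(df)))
  space <- if ("space" %in% names(df)) df$space[1] else "tomographic"
  point_set_3d(as.matrix(df[, c("x", "y", "z")]), df$id, space)
}

#' Serialize a rigid transform
#'
#' As a row-major 4x4 matrix, either JSON (`{"matrix": [[...]]}`) or a
#' 4-line whitespace-separated text file.
#'
#' @param T A [rigid_transform()].
#' @param path File path; extension `.json` selects JSON.
#' @export
write_transform <- function(T, path) {
  m <- as_matrix4(T)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(matrix = m), path, digits = NA,
                         matrix = "rowmajor")
  } else {
    writeLines(apply(m, 1, function(r)
      paste(format(r, digits = 17), collapse = " ")), path)
  }
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)$matrix
  } else {
    m <- do.call(rbind, lapply(readLines(path), function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  }
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(4, 4)))
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' Export a 3D track as CSV
#'
#' One row per frame: `frame_id, u, v, score` per view plus the
#' triangulated and motion-compensated tip (`x, y, z, x_comp, y_comp,
#' z_comp`), as produced by [track_tip_3d()].
#'
#' @param track Data frame from [track_tip_3d()].
#' @param path File path.
#' @export
write_track <- function(track, path) {
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a grayscale frame as PNG
#'
#' @param frame Numeric matrix; values on the 0-255 scale are rescaled to
#'   [0, 1] for storage.
#' @param path PNG path.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(pmin(pmax(frame / 255, 0), 1), path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 255
}
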