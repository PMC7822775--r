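#' C-arm imaging geometry
#'
#' Bundles the full imaging state of one C-arm: gantry angulation, table
#' position, source-image distance (SID), detector field diagonal (FD),
#' source-to-patient distance (SPD) and the image matrix size. All distances
#' are millimetres, angles degrees (LAO/CRAN positive, RAO/CAUD negative).
#'
#' The world coordinate system has its origin at the iso-center with
#' x = patient-left, y = patient-anterior, z = cranial. At zero angulation the
#' frontal source sits at (0, -SPD, 0) and looks along +y.
#'
#' @param primary_angle Primary (LAO +/RAO -) angle, degrees.
#' @param secondary_angle Secondary (CRAN +/CAUD -) angle, degrees.
#' @param table Table position `c(t_x, t_y, t_z)` in mm.
#' @param sid Source-image distance, mm. Must exceed `spd`.
#' @param fd Detector field diagonal, mm.
#' @param spd Source-to-patient (iso-center) distance, mm; fixed per C-arm.
#' @param n_u,n_v Image width and height in pixels.
#' @param label One of `"frontal"`, `"lateral"`, `"monoplane"`.
#' @param pixel_pitch Optional exact pixel pitch (mm/px) overriding the
#'   FD-derived value, e.g. taken from DICOM `ImagerPixelSpacing` for a given
#'   FD setting.
#' @param angle_limits Vendor range guard `c(max |primary|, max |secondary|)`
#'   in degrees.
#' @return An object of class `carm_geometry`.
#' @examples
#' g <- carm_geometry(sid = 1200, fd = 150 * sqrt(2), spd = 810)
#' pixel_pitch(g)
#' @export
carm_geometry <- function(primary_angle = 0, secondary_angle = 0,
                          table = c(0, 0, 0), sid, fd, spd,
                          n_u = 1000L, n_v = n_u,
                          label = c("monoplane", "frontal", "lateral"),
                          pixel_pitch = NULL,
                          angle_limits = c(185, 90)) {
  label <- match.arg(label)
  stopifnot(is.numeric(sid), is.numeric(fd), is.numeric(spd),
            length(table) == 3, all(is.finite(table)),
            is.finite(primary_angle), is.finite(secondary_angle))
  if (!(spd > 0)) stop("spd must be positive")
  if (!(sid > spd)) stop("sid must exceed spd (detector beyond iso-center)")
  if (!(fd > 0)) stop("fd must be positive")
  if (n_u <= 0 || n_v <= 0) stop("image dimensions must be positive")
  if (abs(primary_angle) > angle_limits[1])
    stop("primary angle outside vendor range +/-", angle_limits[1])
  if (abs(secondary_angle) > angle_limits[2])
    stop("secondary angle outside vendor range +/-", angle_limits[2])
  if (!is.null(pixel_pitch) && !(pixel_pitch > 0))
    stop("pixel_pitch must be positive")
  structure(list(primary_angle = primary_angle,
                 secondary_angle = secondary_angle,
                 table = as.numeric(table),
                 sid = sid, fd = fd, spd = spd,
                 n_u = as.integer(n_u), n_v = as.integer(n_v),
                 label = label, pixel_pitch = pixel_pitch),
            class = "carm_geometry")
}

#' @export
print.carm_geometry <- function(x, ...) {
  cat(sprintf("C-arm geometry [%s]\n", x$label))
  cat(sprintf("  angles: primary %+.1f deg, secondary %+.1f deg\n",
              x$primary_angle, x$secondary_angle))
  cat(sprintf("  table:  (%.1f, %.1f, %.1f) mm\n",
              x$table[1], x$table[2], x$table[3]))
  cat(sprintf("  SID %.0f mm, FD %.1f mm, SPD %.0f mm, image %dx%d px\n",
              x$sid, x$fd, x$spd, x$n_u, x$n_v))
  invisible(x)
}

#' Pixel pitch of a C-arm geometry
#'
#' mm per pixel on the detector: the detector diagonal (FD) divided by the
#' image diagonal in pixels, i.e. `FD / (sqrt(2) * n_u)` for square images.
#' An explicit `pixel_pitch` override on the geometry takes precedence.
#'
#' @param geom A [carm_geometry()].
#' @return Pixel pitch in mm/px.
#' @export
pixel_pitch <- function(geom) {
  if (!is.null(geom$pixel_pitch)) return(geom$pixel_pitch)
  geom$fd / sqrt(geom$n_u^2 + geom$n_v^2)
}

deg2rad <- function(x) x * pi / 180

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' Gantry rotation matrix
#'
#' Composition `R_PA %*% R_SA` of the primary angulation (rotation about the
#' patient head-foot axis, z) and the secondary angulation (rotation about the
#' patient left-right axis, x), both in degrees.
#'
#' @param primary_angle,secondary_angle Angles in degrees.
#' @return Orthonormal 3x3 rotation matrix with determinant +1.
#' @export
rotation_gantry <- function(primary_angle, secondary_angle) {
  stopifnot(is.finite(primary_angle), is.finite(secondary_angle))
  rot_z(deg2rad(primary_angle)) %*% rot_x(deg2rad(secondary_angle))
}

# camera axes at zero angulation, as rows: u along patient-left,
# v caudal (image rows grow downward), depth along +y (source -> detector)
.A0 <- rbind(c(1, 0, 0),
             c(0, 0, -1),
             c(0, 1, 0))

#' Build the projection matrix for a C-arm geometry
#'
#' Constructs the 3x4 homogeneous pinhole projection mapping world mm to image
#' pixels for the given gantry angulation, table position, SID and FD. The
#' focal length in pixels is `SID / pixel_pitch` (`sqrt(2)*n_u*SID/FD` for
#' square images); the principal point is the image center `(n_u/2, n_v/2)`;
#' the table translation is applied in the rotated camera frame. Signs are
#' fixed so that the iso-center at zero table projects to the image center for
#' every angulation, image rows grow downward, and the magnification of an
#' object at the iso-center is SID/SPD.
#'
#' @param geom A valid [carm_geometry()].
#' @return An object of class `projection_matrix` with elements `m` (3x4,
#'   third row dimensionless depth in mm), `source_mm` (focal spot, world mm),
#'   `detector` (origin + in-plane unit axes + pixel pitch), and the intrinsic
#'   parameters.
#' @examples
#' g <- carm_geometry(sid = 1200, fd = 150 * sqrt(2), spd = 810)
#' project(build_projection(g), c(0, 0, 0))  # iso-center -> image center
#' @export
build_projection <- function(geom) {
  stopifnot(inherits(geom, "carm_geometry"))
  if (!(geom$sid > geom$spd)) stop("sid must exceed spd")
  pitch <- pixel_pitch(geom)
  f <- geom$sid / pitch
  Rg <- rotation_gantry(geom$primary_angle, geom$secondary_angle)
  A <- .A0 %*% t(Rg)                      # rows: e_u, e_v, view axis d
  b <- c(-geom$table[1], -geom$table[2], geom$spd + geom$table[3])
  K <- rbind(c(f, 0, geom$n_u / 2),
             c(0, f, geom$n_v / 2),
             c(0, 0, 1))
  m <- K %*% cbind(A, b)
  source_mm <- as.numeric(-t(A) %*% b)    # camera origin in world coords
  d_world <- as.numeric(t(A)[, 3])
  detector <- list(origin = source_mm + geom$sid * d_world,
                   e_u = as.numeric(t(A)[, 1]),
                   e_v = as.numeric(t(A)[, 2]),
                   pitch = pitch)
  structure(list(m = m, source_mm = source_mm, detector = detector,
                 A = A, b = b, f = f, n_u = geom$n_u, n_v = geom$n_v),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat("3x4 projection matrix (world mm -> image px)\n")
  print(signif(x$m, 6))
  cat(sprintf("focal spot at (%.1f, %.1f, %.1f) mm, pitch %.4f mm/px\n",
              x$source_mm[1], x$source_mm[2], x$source_mm[3],
              x$detector$pitch))
  invisible(x)
}

#' Project world points to image pixels
#'
#' Homogeneous apply-and-divide of the projection matrix. Image coordinates
#' are 0-based with the origin at the upper-left pixel; points may fall
#' outside the detector. Points at or behind the focal spot (depth <= 0) are
#' non-projectable and yield `NA` with a warning (or an error when
#' `on_behind = "error"`).
#'
#' @param pm A [build_projection()] result.
#' @param p A length-3 world point (mm) or an n x 3 matrix of points.
#' @param on_behind `"na"` or `"error"` for points with non-positive depth.
#' @return A length-2 `(u, v)` vector, or an n x 2 matrix for matrix input.
#' @export
project <- function(pm, p, on_behind = c("na", "error")) {
  on_behind <- match.arg(on_behind)
  stopifnot(inherits(pm, "projection_matrix"))
  one <- is.null(dim(p))
  p <- if (one) matrix(p, 1, 3) else as.matrix(p)
  stopifnot(ncol(p) == 3)
  h <- cbind(p, 1) %*% t(pm$m)
  # depth from the camera geometry, independent of any rescaling of m
  depth <- as.numeric((p - matrix(pm$source_mm, nrow(p), 3, byrow = TRUE)) %*%
                        (pm$detector$origin - pm$source_mm)) / pm$detector$pitch
  bad <- depth <= 0
  if (any(bad)) {
    if (on_behind == "error") stop("point at or behind the focal spot")
    warning("point(s) at or behind the focal spot: returning NA")
  }
  uv <- h[, 1:2, drop = FALSE] / h[, 3]
  uv[bad, ] <- NA_real_
  colnames(uv) <- c("u", "v")
  if (one) c(u = unname(uv[1, 1]), v = unname(uv[1, 2])) else uv
}

#' Back-project an image pixel to a viewing ray
#'
#' Returns the ray from the focal spot through the given pixel; for any depth
#' `s > 0`, `project(pm, origin + s * direction)` recovers the pixel.
#'
#' @param pm A [build_projection()] result.
#' @param q Image point `c(u, v)` in pixels (0-based).
#' @return A `ray` object: `origin` (mm) and unit `direction`.
#' @export
backproject_ray <- function(pm, q) {
  stopifnot(inherits(pm, "projection_matrix"), length(q) == 2,
            all(is.finite(q)))
  dir_cam <- c((q[1] - pm$n_u / 2) / pm$f, (q[2] - pm$n_v / 2) / pm$f, 1)
  d <- as.numeric(t(pm$A) %*% dir_cam)
  ray(pm$source_mm, d)
}

#' Construct a ray
#'
#' @param origin Length-3 origin, mm.
#' @param direction Length-3 direction; normalized internally.
#' @return A `ray` object with unit direction.
#' @export
ray <- function(origin, direction) {
  n <- sqrt(sum(direction^2))
  if (!(n > 0)) stop("zero-length ray direction")
  structure(list(origin = as.numeric(origin),
                 direction = as.numeric(direction) / n),
            class = "ray")
}
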