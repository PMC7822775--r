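# Synthetic sphere-phantom and frame generator: analytic forward projections,
# rendered geometry panels, and motion sequences with exact ground truth.
# Serves as the test fixture generator for every other component, emulating
# the MRI/XR phantom of glass spheres (6, 10, 20 mm) and a glass tube
# embedded in gel.

#' Sphere phantom scene
#'
#' @param centers n x 3 matrix of sphere centers, world mm.
#' @param diameters Sphere diameters, mm (default cycles through 6/10/20).
#' @param attenuation Attenuation coefficients per mm of sphere material.
#' @param tube Optional cylinder `list(point, axis, radius, attenuation)`
#'   (infinite axis; `point` on the axis, mm).
#' @param marker_sigma Default marker-localization noise sigma, mm.
#' @return A `phantom_scene`.
#' @export
phantom_scene <- function(centers = default_sphere_centers(),
                          diameters = rep(c(6, 10, 20), length.out =
                                            nrow(centers)),
                          attenuation = rep(0.05, nrow(centers)),
                          tube = NULL, marker_sigma = 0.5) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, all(diameters > 0),
            length(diameters) == nrow(centers),
            length(attenuation) == nrow(centers))
  structure(list(centers = centers, diameters = as.numeric(diameters),
                 attenuation = as.numeric(attenuation), tube = tube,
                 marker_sigma = marker_sigma),
            class = "phantom_scene")
}

#' Default sphere-center arrangement
#'
#' Six spheres (two each of 6, 10, 20 mm diameter) spread non-coplanarly
#' within an ~8 cm cube around the iso-center.
#' @export
default_sphere_centers <- function() {
  rbind(c(-30, -20, -25), c(25, -30, 15), c(-20, 25, 30),
        c(35, 15, -20), c(0, 35, -35), c(-35, -35, 25))
}

#' Write / read a phantom scene as YAML
#'
#' @param scene A [phantom_scene()].
#' @param path YAML file path.
#' @export
write_phantom_scene <- function(scene, path) {
  obj <- list(
    spheres = lapply(seq_len(nrow(scene$centers)), function(i)
      list(center = as.numeric(scene$centers[i, ]),
           diameter = scene$diameters[i],
           attenuation = scene$attenuation[i])),
    tube = scene$tube, marker_sigma = scene$marker_sigma)
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname write_phantom_scene
#' @export
read_phantom_scene <- function(path) {
  obj <- yaml::read_yaml(path)
  centers <- do.call(rbind, lapply(obj$spheres, function(s)
    unlist(s$center)))
  tube <- obj$tube
  if (!is.null(tube)) {
    tube$point <- unlist(tube$point)
    tube$axis <- unlist(tube$axis)
  }
  phantom_scene(centers,
                diameters = vapply(obj$spheres, `[[`, numeric(1),
                                   "diameter"),
                attenuation = vapply(obj$spheres, `[[`, numeric(1),
                                     "attenuation"),
                tube = tube, marker_sigma = obj$marker_sigma)
}

#' Empty scene (uniform background)
#' @export
empty_scene <- function() {
  structure(list(centers = matrix(numeric(0), 0, 3), diameters = numeric(0),
                 attenuation = numeric(0), tube = NULL, marker_sigma = 0),
            class = "phantom_scene")
}

#' Analytic forward projection of a phantom scene
#'
#' Renders an XR-like image of the scene for the given C-arm geometry: each
#' pixel's ray (focal spot through pixel center) is intersected analytically
#' with every sphere and the optional tube; intensity is exponential
#' attenuation of a unit background over the summed path lengths, plus
#' optional Gaussian noise. The exact projected sphere centers are returned
#' as ground truth.
#'
#' @param scene A [phantom_scene()].
#' @param geom A [carm_geometry()].
#' @param noise_sd Gaussian noise standard deviation (intensity units; the
#'   background is 1).
#' @param invert If `TRUE` (default) returns an attenuation image (bright
#'   structures on dark background) as displayed clinically.
#' @return List: `image` (n_v x n_u matrix in [0, 1], rows = v),
#'   `centers_px` (data frame id, u, v of the projected sphere centers),
#'   `pm` (the projection matrix used).
#' @export
render_projection <- function(scene, geom, noise_sd = 0, invert = TRUE) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(geom, "carm_geometry"))
  pm <- build_projection(geom)
  nu <- geom$n_u; nv <- geom$n_v
  pitch <- pm$detector$pitch
  s <- pm$source_mm
  # world position of every pixel center on the detector
  du <- (seq_len(nu) - 1 - nu / 2) * pitch
  dv <- (seq_len(nv) - 1 - nv / 2) * pitch
  o <- pm$detector$origin
  px <- outer(rep(1, nv), du)  # in-detector u offsets, nv x nu
  pv <- outer(dv, rep(1, nu))
  dirx <- o[1] + px * pm$detector$e_u[1] + pv * pm$detector$e_v[1] - s[1]
  diry <- o[2] + px * pm$detector$e_u[2] + pv * pm$detector$e_v[2] - s[2]
  dirz <- o[3] + px * pm$detector$e_u[3] + pv * pm$detector$e_v[3] - s[3]
  nrm <- sqrt(dirx^2 + diry^2 + dirz^2)
  dirx <- dirx / nrm; diry <- diry / nrm; dirz <- dirz / nrm
  path <- matrix(0, nv, nu)
  for (i in seq_len(nrow(scene$centers))) {
    cc <- scene$centers[i, ] - s
    r <- scene$diameters[i] / 2
    tca <- dirx * cc[1] + diry * cc[2] + dirz * cc[3]
    d2 <- sum(cc^2) - tca^2
    chord2 <- r^2 - d2
    chord2[chord2 < 0] <- 0
    path <- path + scene$attenuation[i] * 2 * sqrt(chord2)
  }
  if (!is.null(scene$tube)) {
    tb <- scene$tube
    ax <- tb$axis / sqrt(sum(tb$axis^2))
    m <- tb$point - s
    m_perp <- m - sum(m * ax) * ax
    dpx <- dirx - (dirx * ax[1] + diry * ax[2] + dirz * ax[3]) * ax[1]
    dpy <- diry - (dirx * ax[1] + diry * ax[2] + dirz * ax[3]) * ax[2]
    dpz <- dirz - (dirx * ax[1] + diry * ax[2] + dirz * ax[3]) * ax[3]
    a <- dpx^2 + dpy^2 + dpz^2
    bq <- -2 * (dpx * m_perp[1] + dpy * m_perp[2] + dpz * m_perp[3])
    cq <- sum(m_perp^2) - tb$radius^2
    disc <- bq^2 - 4 * a * cq
    disc[disc < 0 | a == 0] <- 0
    chord <- ifelse(a > 0, sqrt(disc) / a, 0)
    path <- path + tb$attenuation * chord
  }
  img <- exp(-path)
  if (invert) img <- 1 - img
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(nv * nu, sd = noise_sd), nv, nu)
    img <- pmin(pmax(img, 0), 1)
  }
  centers_px <- if (nrow(scene$centers)) {
    uv <- project(pm, scene$centers)
    data.frame(id = seq_len(nrow(scene$centers)), u = uv[, 1], v = uv[, 2])
  } else data.frame(id = integer(0), u = numeric(0), v = numeric(0))
  list(image = img, centers_px = centers_px, pm = pm)
}

# display rounding of the vendor panel: half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Displayed (rounded) panel reading of an exact geometry
#'
#' Rounds the metric geometry to the display precision of the live panel:
#' whole degrees for the angulations, whole centimetres for table, SID and
#' FD, rounding half away from zero.
#'
#' @param geom A [carm_geometry()].
#' @return A [geometry_reading()].
#' @export
display_reading <- function(geom) {
  geometry_reading(
    primary_angle = round_half_away(geom$primary_angle),
    secondary_angle = round_half_away(geom$secondary_angle),
    table_cm = round_half_away(geom$table / 10),
    sid_cm = round_half_away(geom$sid / 10),
    fd_cm = round_half_away(geom$fd / 10))
}

fmt_cells <- function(value, n, signed = FALSE) {
  s <- if (signed && value < 0) paste0("-", abs(value)) else
    as.character(abs(value))
  chars <- strsplit(s, "")[[1]]
  if (length(chars) > n) stop("value ", value, " does not fit ", n, " cells")
  c(rep("blank", n - length(chars)), chars)
}

#' Render the geometry panel into a frame
#'
#' Draws the orientation words, degree signs and value digits of a panel
#' reading at the layout's cell positions.
#'
#' @param frame 1024 x 1280 numeric frame matrix (modified copy returned).
#' @param reading A [geometry_reading()].
#' @param layout A [panel_layout()].
#' @param fg,bg Foreground/background glyph intensities (0-255 scale).
#' @return The frame with the panel drawn.
#' @export
render_panel <- function(frame, reading, layout = panel_layout(),
                         fg = 220, bg = 30) {
  f <- layout$fields; d <- layout$discriminators; w <- layout$words
  prim_word <- if (reading$primary_angle >= 0) c("L", "A", "O") else
    c("R", "A", "O")
  sec_word <- if (reading$secondary_angle >= 0) c("C", "R", "A", "N") else
    c("C", "A", "U", "D")
  cells <- c(w$primary, w$secondary, f$primary, f$secondary,
             list(d$primary_degree, d$secondary_degree),
             f$table_long, f$table_lat, f$table_vert, f$sid, f$fd)
  chars <- c(prim_word, sec_word,
             fmt_cells(abs(reading$primary_angle), 3),
             fmt_cells(abs(reading$secondary_angle), 2),
             "deg", "deg",
             fmt_cells(reading$table_cm[1], 3, signed = TRUE),
             fmt_cells(reading$table_cm[2], 3, signed = TRUE),
             fmt_cells(reading$table_cm[3], 3, signed = TRUE),
             fmt_cells(reading$sid_cm, 3),
             fmt_cells(reading$fd_cm, 2))
  # sub-assign in place; passing the frame through helpers would copy the
  # full raster once per glyph
  for (i in seq_along(cells)) {
    r <- cells[[i]]
    frame[(r$v0 + 1):(r$v0 + r$h), (r$u0 + 1):(r$u0 + r$w)] <-
      bg + (fg - bg) * layout$glyphs[[chars[i]]]
  }
  frame
}

#' Render a complete synthetic live-video frame
#'
#' Composes the 1280 x 1024 frame a frame grabber would deliver: the
#' forward-projected XR image in the fixed 1000 x 1000 image region and the
#' geometry panel (rendered from the display-rounded reading) on the left,
#' optionally followed by a per-frame affine intensity change emulating
#' capture-dependent luminance/contrast variation.
#'
#' @param scene A [phantom_scene()] (use [empty_scene()] for a flat image).
#' @param geom A [carm_geometry()] with a 1000 x 1000 image matrix.
#' @param layout A [panel_layout()].
#' @param gain,offset Per-frame affine intensity change applied to the whole
#'   frame (0-255 intensity scale).
#' @param noise_sd Image-region Gaussian noise (intensity fraction).
#' @return A `synthetic_frame`: `raster` (1024 x 1280, 0-255 scale),
#'   `geometry_truth` (exact [carm_geometry()]), `reading_truth` (displayed
#'   [geometry_reading()]), `centers_px` ground truth in frame coordinates.
#' @export
render_frame <- function(scene, geom, layout = panel_layout(),
                         gain = 1, offset = 0, noise_sd = 0) {
  stopifnot(geom$n_u == layout$image_rect$w, geom$n_v == layout$image_rect$h)
  reading <- display_reading(geom)
  frame <- matrix(20, layout$frame_size[2], layout$frame_size[1])
  proj <- render_projection(scene, geom, noise_sd = noise_sd)
  ir <- layout$image_rect
  frame[(ir$v0 + 1):(ir$v0 + ir$h), (ir$u0 + 1):(ir$u0 + ir$w)] <-
    proj$image * 255
  frame <- render_panel(frame, reading, layout)
  frame <- gain * frame + offset
  centers <- proj$centers_px
  centers$u <- centers$u + ir$u0
  centers$v <- centers$v + ir$v0
  structure(list(raster = frame, geometry_truth = geom,
                 reading_truth = reading, centers_px = centers),
            class = "synthetic_frame")
}

#' Synthetic biplane motion sequence with ground truth
#'
#' Renders a biplane image sequence of a scene containing a moving catheter
#' tip and a moving reference structure, with exact 2D and 3D ground-truth
#' tracks. Trajectories are translation-only, linear or sinusoidal.
#'
#' @param geom_a,geom_b C-arm geometries of the two views.
#' @param tip_start,ref_start Initial 3D positions, mm.
#' @param tip_motion,ref_motion Trajectory specs
#'   `list(type = "none"|"linear"|"sinusoid", amplitude = c(x,y,z),
#'   period = frames)`; `linear` reaches `amplitude` at the last frame.
#' @param n_frames Number of frames.
#' @param noise_sd Per-frame image noise.
#' @param seed RNG seed making the sequence deterministic.
#' @param tip_diameter,ref_diameter Rendered structure sizes, mm.
#' @return List: `frames_a`, `frames_b` (image matrices), `truth` data frame
#'   (per-frame exact 3D positions and per-view projections of tip and
#'   reference), `pm_a`, `pm_b`.
#' @export
make_motion_sequence <- function(geom_a, geom_b, tip_start, ref_start,
                                 tip_motion = list(type = "none"),
                                 ref_motion = list(type = "none"),
                                 n_frames = 20, noise_sd = 0, seed = 1,
                                 tip_diameter = 4, ref_diameter = 9) {
  set.seed(seed)
  disp <- function(motion, k) {
    amp <- motion$amplitude %||% c(0, 0, 0)
    switch(motion$type,
           none = c(0, 0, 0),
           linear = amp * (k - 1) / max(n_frames - 1, 1),
           sinusoid = amp * sin(2 * pi * (k - 1) /
                                  (motion$period %||% n_frames)),
           stop("unknown motion type ", motion$type))
  }
  pm_a <- build_projection(geom_a)
  pm_b <- build_projection(geom_b)
  frames_a <- frames_b <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    tip <- tip_start + disp(tip_motion, k)
    ref <- ref_start + disp(ref_motion, k)
    sc <- phantom_scene(rbind(tip, ref),
                        diameters = c(tip_diameter, ref_diameter),
                        attenuation = c(0.4, 0.25))
    ra <- render_projection(sc, geom_a, noise_sd = noise_sd)
    rb <- render_projection(sc, geom_b, noise_sd = noise_sd)
    frames_a[[k]] <- ra$image
    frames_b[[k]] <- rb$image
    truth[[k]] <- data.frame(frame_id = k - 1L,
                             tip_x = tip[1], tip_y = tip[2], tip_z = tip[3],
                             ref_x = ref[1], ref_y = ref[2], ref_z = ref[3],
                             tip_u_a = ra$centers_px$u[1],
                             tip_v_a = ra$centers_px$v[1],
                             tip_u_b = rb$centers_px$u[1],
                             tip_v_b = rb$centers_px$v[1],
                             ref_u_a = ra$centers_px$u[2],
                             ref_v_a = ra$centers_px$v[2],
                             ref_u_b = rb$centers_px$u[2],
                             ref_v_b = rb$centers_px$v[2])
  }
  list(frames_a = frames_a, frames_b = frames_b,
       truth = do.call(rbind, truth), pm_a = pm_a, pm_b = pm_b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample noisy marker sets for the registration experiment
#'
#' Emulates manual marker identification in the centers of the phantom's
#' glass spheres: tomographic (MRI-space) coordinates are the sphere centers
#' mapped through an unknown (seeded random) rigid scanner pose plus
#' isotropic Gaussian noise, and per-view 2D points are the exact biplane
#' projections plus pixel noise.
#'
#' @param scene A [phantom_scene()].
#' @param geom_a,geom_b C-arm geometries of the two views.
#' @param n_markers Number of markers (3 to the scene's sphere count).
#' @param sigma_mri Marker localization noise in MRI space: the standard
#'   deviation of the magnitude of the isotropic 3D error vector, mm
#'   (per-axis sd `sigma_mri / sqrt(3)`), matching the scalar voxel-size
#'   figure quoted for tomographic resolution.
#' @param sigma_px Marker localization noise in the projections: magnitude
#'   sd of the 2D error, px (per-axis `sigma_px / sqrt(2)`).
#' @param seed RNG seed.
#' @return List: `mri` ([point_set_3d()], tomographic), `uv_a`, `uv_b`
#'   (data frames id, u, v), `world` (exact centers, xr-world
#'   [point_set_3d()]), `pose` (the true MRI pose as a [rigid_transform()];
#'   its inverse is the expected registration result).
#' @export
sample_marker_sets <- function(scene, geom_a, geom_b, n_markers = 6,
                               sigma_mri = 0.5, sigma_px = 0, seed = 1) {
  if (n_markers < 3 || n_markers > nrow(scene$centers))
    stop("n_markers must be in [3, number of spheres]")
  set.seed(seed)
  centers <- scene$centers[seq_len(n_markers), , drop = FALSE]
  labels <- paste0("m", seq_len(n_markers))
  # unknown scanner pose: random rotation (QR of a Gaussian matrix,
  # sign-fixed to det +1) and a translation of a few cm
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  q <- q %*% diag(c(1, 1, det(q)))
  pose <- rigid_transform(q, stats::rnorm(3, sd = 30))
  mri <- apply_transform(pose, centers) +
    matrix(stats::rnorm(3 * n_markers, sd = sigma_mri / sqrt(3)),
           n_markers, 3)
  pm_a <- build_projection(geom_a)
  pm_b <- build_projection(geom_b)
  uv_a <- project(pm_a, centers) +
    matrix(stats::rnorm(2 * n_markers, sd = sigma_px / sqrt(2)),
           n_markers, 2)
  uv_b <- project(pm_b, centers) +
    matrix(stats::rnorm(2 * n_markers, sd = sigma_px / sqrt(2)),
           n_markers, 2)
  list(mri = point_set_3d(mri, labels, "tomographic"),
       uv_a = data.frame(id = labels, u = uv_a[, 1], v = uv_a[, 2]),
       uv_b = data.frame(id = labels, u = uv_b[, 1], v = uv_b[, 2]),
       world = point_set_3d(centers, labels, "xr-world"),
       pose = pose)
}

#' End-to-end biplane registration experiment
#'
#' Runs the complete phantom emulation for one geometry pair: sample noisy
#' marker sets, triangulate every marker pair from the two views,
#' rigid-register the tomographic markers onto the reconstructions, and
#' report the RMSE.
#'
#' @inheritParams sample_marker_sets
#' @return List: `transform` (fitted [rigid_transform()]), `rmse_mm`,
#'   `reconstructed` ([point_set_3d()]), `markers` (the sampled sets).
#' @export
registration_experiment <- function(scene, geom_a, geom_b, n_markers = 6,
                                    sigma_mri = 0.5, sigma_px = 0,
                                    seed = 1) {
  mk <- sample_marker_sets(scene, geom_a, geom_b, n_markers = n_markers,
                           sigma_mri = sigma_mri, sigma_px = sigma_px,
                           seed = seed)
  pm_a <- build_projection(geom_a)
  pm_b <- build_projection(geom_b)
  rec <- t(vapply(seq_len(n_markers), function(i)
    triangulate(pm_a, c(mk$uv_a$u[i], mk$uv_a$v[i]),
                pm_b, c(mk$uv_b$u[i], mk$uv_b$v[i]))$p,
    numeric(3)))
  p_xr <- point_set_3d(rec, mk$mri$labels, "xr-world")
  T <- fit_rigid(mk$mri, p_xr)
  list(transform = T, rmse_mm = attr(T, "rmse"),
       reconstructed = p_xr, markers = mk)
}
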