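# Template-matching character recognition of the geometry panel burned into
# the live XR video frame. The panel is read cell by cell: each cell is
# binarized at the midpoint of its intensity range (removing any luminance /
# contrast dependence) and classified to the glyph minimizing the Frobenius
# norm of the binary difference matrix. Orientation words (LAO/RAO,
# CRAN/CAUD) and degree signs are resolved from dedicated discriminator
# cells.

# 5x7 bitmap font; rows are strings of 0/1. Blank is all zeros.
.font5x7 <- list(
  "0" = c("01110","10001","10011","10101","11001","10001","01110"),
  "1" = c("00100","01100","00100","00100","00100","00100","01110"),
  "2" = c("01110","10001","00001","00010","00100","01000","11111"),
  "3" = c("11110","00001","00001","01110","00001","00001","11110"),
  "4" = c("00010","00110","01010","10010","11111","00010","00010"),
  "5" = c("11111","10000","11110","00001","00001","10001","01110"),
  "6" = c("00110","01000","10000","11110","10001","10001","01110"),
  "7" = c("11111","00001","00010","00100","01000","01000","01000"),
  "8" = c("01110","10001","10001","01110","10001","10001","01110"),
  "9" = c("01110","10001","10001","01111","00001","00010","01100"),
  "+" = c("00000","00100","00100","11111","00100","00100","00000"),
  "-" = c("00000","00000","00000","11111","00000","00000","00000"),
  "deg" = c("01100","10010","10010","01100","00000","00000","00000"),
  "L" = c("10000","10000","10000","10000","10000","10000","11111"),
  "R" = c("11110","10001","10001","11110","10100","10010","10001"),
  "A" = c("01110","10001","10001","11111","10001","10001","10001"),
  "O" = c("01110","10001","10001","10001","10001","10001","01110"),
  "C" = c("01110","10001","10000","10000","10000","10001","01110"),
  "N" = c("10001","11001","10101","10011","10001","10001","10001"),
  "U" = c("10001","10001","10001","10001","10001","10001","01110"),
  "D" = c("11110","10001","10001","10001","10001","10001","11110"),
  "blank" = c("00000","00000","00000","00000","00000","00000","00000")
)

font_bitmap <- function(ch, scale = 2) {
  rows <- .font5x7[[ch]]
  if (is.null(rows)) stop("no glyph for character '", ch, "'")
  m <- do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]])))
  m[rep(seq_len(nrow(m)), each = scale), rep(seq_len(ncol(m)), each = scale)]
}

#' Panel layout for geometry-panel character recognition
#'
#' Describes where, inside a 1280 x 1024 live-video frame, the geometry
#' values are displayed: the character cell rectangles of every field
#' (angulations, table coordinates, SID, FD), the discriminator cells that
#' resolve LAO/RAO, CRAN/CAUD and the degree signs, the fixed 1000 x 1000
#' image region, and the glyph bitmap set used for classification. The
#' shipped layout is synthetic (the vendor's panel coordinates and font are
#' not redistributable); real layouts are loaded from a JSON file calibrated
#' by the user.
#'
#' @param scale Integer glyph magnification of the 5x7 base font.
#' @return A `panel_layout`.
#' @export
panel_layout <- function(scale = 2) {
  cw <- 5 * scale; ch <- 7 * scale
  pitch <- cw + 2
  cell <- function(u0, v0) rect(u0, v0, cw, ch)
  row_cells <- function(u0, v0, n)
    lapply(seq_len(n) - 1, function(i) cell(u0 + i * pitch, v0))
  glyphs <- lapply(stats::setNames(nm = names(.font5x7)), font_bitmap,
                   scale = scale)
  structure(list(
    frame_size = c(1280L, 1024L),
    image_rect = rect(280, 12, 1000, 1000),
    panel_rect = rect(0, 0, 280, 1024),
    cell_size = c(cw, ch),
    fields = list(
      primary   = row_cells(64, 100, 3),
      secondary = row_cells(76, 140, 2),
      table_long = row_cells(20, 200, 3),
      table_lat  = row_cells(20, 230, 3),
      table_vert = row_cells(20, 260, 3),
      sid = row_cells(20, 320, 3),
      fd  = row_cells(20, 350, 2)
    ),
    words = list(  # decorative orientation-word cells (rendered in full)
      primary   = row_cells(20, 100, 3),
      secondary = row_cells(20, 140, 4)
    ),
    discriminators = list(
      # distinguishing letter of each word pair + degree-sign presence cells
      primary_letter = list(cell = cell(20, 100),
                            glyphs = c(pos = "L", neg = "R")),
      secondary_letter = list(cell = cell(20 + pitch, 140),
                              glyphs = c(pos = "R", neg = "A")),
      primary_degree = cell(64 + 3 * pitch, 100),
      secondary_degree = cell(76 + 2 * pitch, 140)
    ),
    glyphs = glyphs),
    class = "panel_layout")
}

#' Binarize a panel cell
#'
#' Thresholds at the midpoint between the cell's minimum and maximum
#' intensity, which removes any per-frame luminance/contrast (gain/offset)
#' dependence. A constant cell binarizes to all zeros (blank).
#'
#' @param cell Numeric matrix of cell pixels.
#' @return Integer 0/1 matrix of the same size.
#' @export
binarize_cell <- function(cell) {
  cell <- as.matrix(cell)
  if (length(cell) == 0) stop("empty cell")
  lo <- min(cell); hi <- max(cell)
  if (hi == lo) return(matrix(0L, nrow(cell), ncol(cell)))
  (cell > (lo + hi) / 2) * 1L
}

#' Classify a binarized cell against a glyph set
#'
#' Nearest-template classification: returns the glyph minimizing the
#' Frobenius norm of the element-wise difference between the binary cell and
#' the glyph bitmap. Two glyphs within 1e-9 of each other yield the
#' lowest-codepoint winner with `confident = FALSE`; a best distance above
#' `tol_frac` of the cell area also clears the confidence flag (guards
#' against e.g. inverted-polarity input).
#'
#' @param bin Binary cell matrix (from [binarize_cell()]).
#' @param glyphs Named list of 0/1 bitmaps, all the cell's size.
#' @param tol_frac Maximum fraction of differing pixels for a confident call.
#' @return List with `char`, `distance` (Frobenius), `confident`.
#' @export
classify_glyph <- function(bin, glyphs, tol_frac = 0.1) {
  sizes <- vapply(glyphs, function(g) all(dim(g) == dim(bin)), logical(1))
  if (!all(sizes)) stop("glyph/cell size mismatch")
  d <- vapply(glyphs, function(g) sqrt(sum((bin - g)^2)), numeric(1))
  ord <- order(d, names(glyphs))
  best <- ord[1]
  ambiguous <- length(d) > 1 && (d[ord[2]] - d[best]) < 1e-9
  confident <- !ambiguous && d[best] <= sqrt(tol_frac * length(bin))
  list(char = names(glyphs)[best], distance = unname(d[best]),
       confident = confident)
}

#' Geometry reading recognized from a panel
#'
#' Integer-precision live counterpart of [carm_geometry()]: angles in whole
#' degrees (sign from the recognized orientation word), table coordinates,
#' SID and FD in whole centimetres, plus per-field validity flags.
#'
#' @param primary_angle,secondary_angle Signed integer degrees.
#' @param table_cm Integer `c(long, lat, vert)` in cm.
#' @param sid_cm,fd_cm Integers, cm.
#' @param valid Named logical vector of per-field confidence flags.
#' @export
geometry_reading <- function(primary_angle, secondary_angle, table_cm,
                             sid_cm, fd_cm,
                             valid = c(primary = TRUE, secondary = TRUE,
                                       table_long = TRUE, table_lat = TRUE,
                                       table_vert = TRUE, sid = TRUE,
                                       fd = TRUE)) {
  structure(list(primary_angle = as.integer(primary_angle),
                 secondary_angle = as.integer(secondary_angle),
                 table_cm = as.integer(table_cm),
                 sid_cm = as.integer(sid_cm), fd_cm = as.integer(fd_cm),
                 valid = valid),
            class = "geometry_reading")
}

#' @export
print.geometry_reading <- function(x, ...) {
  fmt_ang <- function(v, pos, neg)
    sprintf("%s %d deg", if (is.na(v) || v >= 0) pos else neg, abs(v))
  cat("geometry reading:",
      fmt_ang(x$primary_angle, "LAO", "RAO"),
      "/", fmt_ang(x$secondary_angle, "CRAN", "CAUD"), "\n")
  cat(sprintf("  table (long, lat, vert): %d, %d, %d cm; SID %d cm; FD %d cm\n",
              x$table_cm[1], x$table_cm[2], x$table_cm[3], x$sid_cm, x$fd_cm))
  if (!all(x$valid))
    cat("  INVALID fields:", paste(names(x$valid)[!x$valid], collapse = ", "),
        "\n")
  invisible(x)
}

crop_rect <- function(frame, r) {
  frame[(r$v0 + 1):(r$v0 + r$h), (r$u0 + 1):(r$u0 + r$w), drop = FALSE]
}

# classify one cell of the frame against a restricted glyph set
read_cell <- function(frame, r, layout, set) {
  bin <- binarize_cell(crop_rect(frame, r))
  classify_glyph(bin, layout$glyphs[set])
}

# parse a run of digit/sign cells into a signed integer; NA when malformed
parse_cells <- function(chars, confident, signed = FALSE) {
  if (!all(confident)) return(NA_integer_)
  chars <- chars[chars != "blank" | cumsum(chars != "blank") > 0]  # strip lead
  if (!length(chars)) return(NA_integer_)
  sgn <- 1L
  if (signed && chars[1] %in% c("-", "+")) {
    sgn <- if (chars[1] == "-") -1L else 1L
    chars <- chars[-1]
  }
  if (!length(chars) || !all(chars %in% as.character(0:9)))
    return(NA_integer_)
  sgn * as.integer(paste(chars, collapse = ""))
}

#' Read the geometry panel of a live-video frame
#'
#' Runs the cell-wise binarize/classify pipeline over every analyzed cell of
#' the layout, resolves the degree-sign and orientation-word discriminators,
#' and assembles the signed integer geometry values. Unreadable fields are
#' returned with `valid = FALSE` rather than raising an error, so the caller
#' decides how to proceed.
#'
#' @param frame 1024 x 1280 grayscale frame matrix (rows = v).
#' @param layout A [panel_layout()].
#' @return A [geometry_reading()].
#' @export
read_geometry <- function(frame, layout = panel_layout()) {
  frame <- as.matrix(frame)
  if (nrow(frame) != layout$frame_size[2] ||
      ncol(frame) != layout$frame_size[1])
    stop("frame does not match layout dimensions")
  digit_set <- c(as.character(0:9), "+", "-", "blank")
  read_field <- function(cells, signed = FALSE) {
    cl <- lapply(cells, read_cell, frame = frame, layout = layout,
                 set = digit_set)
    parse_cells(vapply(cl, `[[`, "", "char"),
                vapply(cl, `[[`, TRUE, "confident"), signed = signed)
  }
  read_disc <- function(disc) {
    cl <- read_cell(frame, disc$cell, layout,
                    c(unname(disc$glyphs), "blank"))
    if (!cl$confident || cl$char == "blank") return(NA_integer_)
    if (cl$char == disc$glyphs[["pos"]]) 1L else -1L
  }
  degree_present <- function(r) {
    cl <- read_cell(frame, r, layout, c("deg", "blank"))
    cl$confident && cl$char == "deg"
  }
  f <- layout$fields
  dsc <- layout$discriminators
  prim_mag <- read_field(f$primary)
  prim_sign <- read_disc(dsc$primary_letter)
  prim_ok <- !is.na(prim_mag) && !is.na(prim_sign) &&
    degree_present(dsc$primary_degree)
  sec_mag <- read_field(f$secondary)
  sec_sign <- read_disc(dsc$secondary_letter)
  sec_ok <- !is.na(sec_mag) && !is.na(sec_sign) &&
    degree_present(dsc$secondary_degree)
  tl <- read_field(f$table_long, signed = TRUE)
  tt <- read_field(f$table_lat, signed = TRUE)
  tv <- read_field(f$table_vert, signed = TRUE)
  sid <- read_field(f$sid)
  fd <- read_field(f$fd)
  geometry_reading(
    primary_angle = if (prim_ok) prim_sign * prim_mag else NA_integer_,
    secondary_angle = if (sec_ok) sec_sign * sec_mag else NA_integer_,
    table_cm = c(tl, tt, tv), sid_cm = sid, fd_cm = fd,
    valid = c(primary = prim_ok, secondary = sec_ok,
              table_long = !is.na(tl), table_lat = !is.na(tt),
              table_vert = !is.na(tv), sid = !is.na(sid), fd = !is.na(fd)))
}

#' Per-C-arm configuration
#'
#' Vendor constants needed to turn an integer panel reading into a metric
#' imaging geometry: the source-to-patient distance and, optionally, exact
#' pixel pitches per FD setting (as obtained from DICOM `ImagerPixelSpacing`
#' metadata), which avoid the error introduced by the cm rounding of the
#' displayed FD.
#'
#' @param label C-arm label.
#' @param spd_mm Source-to-patient distance, mm.
#' @param n_u,n_v Image size in pixels.
#' @param sid_range_mm Allowed SID range, mm.
#' @param fd_pitch_mm_px Optional named numeric vector mapping displayed FD
#'   (cm, as character) to exact pixel pitch (mm/px).
#' @export
carm_config <- function(label = "monoplane", spd_mm,
                        n_u = 1000L, n_v = 1000L,
                        sid_range_mm = c(890, 1310),
                        fd_pitch_mm_px = NULL) {
  stopifnot(spd_mm > 0)
  structure(list(label = label, spd_mm = spd_mm,
                 n_u = as.integer(n_u), n_v = as.integer(n_v),
                 sid_range_mm = sid_range_mm,
                 fd_pitch_mm_px = fd_pitch_mm_px),
            class = "carm_config")
}

#' Default frontal/lateral C-arm configurations
#'
#' Synthetic stand-ins for the vendor constants of a biplane system: SPD
#' 810 mm (frontal) and 765 mm (lateral), with exact pixel pitches for the
#' FD settings of each C-arm (eight FDs 15-48 cm frontal, three FDs
#' 15-25 cm lateral/monoplane).
#'
#' @return Named list of [carm_config()] objects.
#' @export
default_carm_configs <- function() {
  pitch_for <- function(diag_mm) diag_mm / (sqrt(2) * 1000)
  frontal_fd <- c("15" = 151.18, "20" = 202.39, "25" = 254.56, "27" = 270.51,
                  "31" = 311.85, "37" = 369.71, "42" = 424.26, "48" = 478.42)
  lateral_fd <- frontal_fd[c("15", "20", "25")]
  list(frontal = carm_config("frontal", spd_mm = 810,
                             fd_pitch_mm_px = pitch_for(frontal_fd)),
       lateral = carm_config("lateral", spd_mm = 765,
                             fd_pitch_mm_px = pitch_for(lateral_fd)))
}

#' Write / read per-C-arm configurations as YAML
#'
#' One document per C-arm: `label`, `spd_mm`, `n_u`, `n_v`, `sid_range_mm`
#' and the `fd_pitch_mm_px` pixel-spacing override map.
#'
#' @param configs Named list of [carm_config()] objects.
#' @param path YAML file path.
#' @export
write_carm_configs <- function(configs, path) {
  obj <- lapply(configs, function(cfg) {
    out <- unclass(cfg)
    if (!is.null(out$fd_pitch_mm_px))
      out$fd_pitch_mm_px <- as.list(out$fd_pitch_mm_px)
    out
  })
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' @rdname write_carm_configs
#' @export
read_carm_configs <- function(path) {
  obj <- yaml::read_yaml(path)
  lapply(obj, function(cfg)
    carm_config(label = cfg$label, spd_mm = cfg$spd_mm,
                n_u = cfg$n_u, n_v = cfg$n_v,
                sid_range_mm = unlist(cfg$sid_range_mm),
                fd_pitch_mm_px = if (!is.null(cfg$fd_pitch_mm_px))
                  unlist(cfg$fd_pitch_mm_px)))
}

#' Convert a panel reading to a metric C-arm geometry
#'
#' cm values become mm, degrees pass through; the displayed FD is mapped to
#' its exact pixel pitch through the configuration's override table when one
#' is present (avoiding the FD rounding error), otherwise the pitch is
#' derived from the rounded FD itself.
#'
#' @param r A [geometry_reading()] with all fields valid.
#' @param config A [carm_config()].
#' @return A [carm_geometry()].
#' @export
to_carm_geometry <- function(r, config) {
  stopifnot(inherits(r, "geometry_reading"), inherits(config, "carm_config"))
  if (!all(r$valid))
    stop("reading has invalid fields: ",
         paste(names(r$valid)[!r$valid], collapse = ", "))
  pitch <- NULL
  if (!is.null(config$fd_pitch_mm_px)) {
    key <- as.character(r$fd_cm)
    if (!key %in% names(config$fd_pitch_mm_px))
      stop("unknown FD value ", r$fd_cm, " cm for C-arm '", config$label, "'")
    pitch <- unname(config$fd_pitch_mm_px[key])
  }
  carm_geometry(primary_angle = r$primary_angle,
                secondary_angle = r$secondary_angle,
                table = r$table_cm * 10,
                sid = r$sid_cm * 10, fd = r$fd_cm * 10,
                spd = config$spd_mm,
                n_u = config$n_u, n_v = config$n_v,
                label = config$label, pixel_pitch = pitch)
}

#' Write / read a panel layout as JSON
#'
#' Cell rectangles, discriminator definitions and glyph bitmaps (rows of
#' 0/1 characters) in a plain-text JSON file, so user-calibrated vendor
#' layouts can be shipped separately from the package.
#'
#' @param layout A [panel_layout()].
#' @param path File path.
#' @export
write_panel_layout <- function(layout, path) {
  enc_glyph <- function(g) apply(g, 1, paste0, collapse = "")
  obj <- layout
  obj$glyphs <- lapply(layout$glyphs, enc_glyph)
  # named vectors serialize without names; store them as objects
  obj$discriminators$primary_letter$glyphs <-
    as.list(layout$discriminators$primary_letter$glyphs)
  obj$discriminators$secondary_letter$glyphs <-
    as.list(layout$discriminators$secondary_letter$glyphs)
  class(obj) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel_layout
#' @export
read_panel_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec_glyph <- function(rows)
    do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]])))
  obj$glyphs <- lapply(obj$glyphs, dec_glyph)
  relist_rect <- function(r) rect(r$u0, r$v0, r$w, r$h)
  obj$fields <- lapply(obj$fields, function(cells)
    lapply(seq_len(nrow(cells)), function(i) as.list(cells[i, ])))
  obj$image_rect <- as.list(obj$image_rect)
  obj$panel_rect <- as.list(obj$panel_rect)
  obj$words <- lapply(obj$words, function(cells)
    lapply(seq_len(nrow(cells)), function(i) as.list(cells[i, ])))
  d <- obj$discriminators
  obj$discriminators <- list(
    primary_letter = list(cell = as.list(d$primary_letter$cell),
                          glyphs = unlist(d$primary_letter$glyphs)),
    secondary_letter = list(cell = as.list(d$secondary_letter$cell),
                            glyphs = unlist(d$secondary_letter$glyphs)),
    primary_degree = as.list(d$primary_degree),
    secondary_degree = as.list(d$secondary_degree))
  structure(obj, class = "panel_layout")
}
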