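# Minimal DICOM support for derived XR frames: explicit-VR little-endian
# secondary-capture-style files carrying the X-Ray Angiographic geometry
# tags plus RT table-top positions, with uncompressed 16-bit grayscale pixel
# data. Written in base R because no DICOM package is available in the R
# stack; scope is the package's own derived files plus any uncompressed
# explicit-VR-LE monochrome file carrying the mapped tags.

.dicom_default_tag_map <- list(
  primary_angle   = c(0x0018, 0x1510),  # Positioner Primary Angle
  secondary_angle = c(0x0018, 0x1511),  # Positioner Secondary Angle
  sid             = c(0x0018, 0x1110),  # Distance Source to Detector
  spd             = c(0x0018, 0x1111),  # Distance Source to Patient
  fd              = c(0x0018, 0x1149),  # Field of View Dimension(s)
  table_long      = c(0x300A, 0x0129),  # Table Top Longitudinal Position
  table_lat       = c(0x300A, 0x012A),  # Table Top Lateral Position
  table_vert      = c(0x300A, 0x0128),  # Table Top Vertical Position
  pixel_spacing   = c(0x0018, 0x1164)   # Imager Pixel Spacing
)

#' Default DICOM tag map for XR geometry
#'
#' Which DICOM tags carry each geometry parameter. The map is an argument of
#' [read_xr_dicom()] / [write_derived_dicom()] so vendor-specific table
#' position tags can be substituted.
#' @return Named list of `c(group, element)` integer pairs.
#' @export
dicom_tag_map <- function() .dicom_default_tag_map

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 0xFF), bitwAnd(bitwShiftR(x, 8), 0xFF)))
}
u32le <- function(x) {
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

dcm_element <- function(group, element, vr, value_raw) {
  len <- length(value_raw)
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
    c(u16le(group), u16le(element), charToRaw(vr), as.raw(c(0, 0)),
      u32le(len), value_raw)
  } else {
    c(u16le(group), u16le(element), charToRaw(vr), u16le(len), value_raw)
  }
}

pad_even <- function(r, pad = as.raw(0x20)) {
  if (length(r) %% 2 == 1) c(r, pad) else r
}

str_el <- function(group, element, vr, s) {
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  dcm_element(group, element, vr, pad_even(charToRaw(s), pad))
}

ds_el <- function(group, element, x) {
  str_el(group, element, "DS",
         paste(format(x, trim = TRUE, scientific = FALSE, digits = 10),
               collapse = "\\"))
}

us_el <- function(group, element, x) dcm_element(group, element, "US",
                                                 u16le(x))

gen_uid <- function() {
  paste0("2.25.", paste0(sample(0:9, 30, replace = TRUE), collapse = ""))
}

#' Write a derived DICOM image with XR geometry
#'
#' Writes one or more captured frames as an uncompressed explicit-VR
#' little-endian secondary-capture-style DICOM file carrying the full C-arm
#' geometry in standard tags (positioner angles, source-detector and
#' source-patient distances, field-of-view dimension, table-top positions,
#' imager pixel spacing). [read_xr_dicom()] is its inverse. Because derived
#' XR storage is not generated natively, the modality attribute defaults to
#' `"CT"` as a compatibility workaround.
#'
#' @param frames A single matrix or list of equally sized integer-valued
#'   matrices (rows = v) with values in 0..65535.
#' @param geom A [carm_geometry()].
#' @param path Output file.
#' @param modality Modality tag value.
#' @param tag_map Geometry tag map, see [dicom_tag_map()].
#' @export
write_derived_dicom <- function(frames, geom, path, modality = "CT",
                                tag_map = dicom_tag_map()) {
  stopifnot(inherits(geom, "carm_geometry"))
  if (is.matrix(frames)) frames <- list(frames)
  rows <- nrow(frames[[1]]); cols <- ncol(frames[[1]])
  for (f in frames) {
    stopifnot(nrow(f) == rows, ncol(f) == cols,
              all(f >= 0 & f < 65536))
  }
  sop_class <- "1.2.840.10008.5.1.4.1.1.7"   # secondary capture
  sop_inst <- gen_uid()
  ts <- "1.2.840.10008.1.2.1"                # explicit VR little endian
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    str_el(0x0002, 0x0002, "UI", sop_class),
    str_el(0x0002, 0x0003, "UI", sop_inst),
    str_el(0x0002, 0x0010, "UI", ts))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", u32le(length(meta))), meta)
  tg <- function(name) tag_map[[name]]
  el <- function(name, x) ds_el(tg(name)[1], tg(name)[2], x)
  pitch <- pixel_pitch(geom)
  pix <- unlist(lapply(frames, function(f) as.integer(round(t(f)))))
  pix_raw <- writeBin(pix, raw(), size = 2, endian = "little")
  body_els <- list(
    list(0x0008, str_el(0x0008, 0x0016, "UI", sop_class)),
    list(0x0008, str_el(0x0008, 0x0018, "UI", sop_inst)),
    list(0x0008, str_el(0x0008, 0x0060, "CS", modality)),
    list(tg("sid")[1] * 65536 + tg("sid")[2], el("sid", geom$sid)),
    list(NA, el("spd", geom$spd)),
    list(NA, el("fd", geom$fd)),
    list(NA, el("pixel_spacing", c(pitch, pitch))),
    list(NA, el("primary_angle", geom$primary_angle)),
    list(NA, el("secondary_angle", geom$secondary_angle)),
    list(NA, str_el(0x0028, 0x0008, "IS", as.character(length(frames)))),
    list(NA, us_el(0x0028, 0x0002, 1)),
    list(NA, str_el(0x0028, 0x0004, "CS", "MONOCHROME2")),
    list(NA, us_el(0x0028, 0x0010, rows)),
    list(NA, us_el(0x0028, 0x0011, cols)),
    list(NA, us_el(0x0028, 0x0100, 16)),
    list(NA, us_el(0x0028, 0x0101, 16)),
    list(NA, us_el(0x0028, 0x0102, 15)),
    list(NA, us_el(0x0028, 0x0103, 0)),
    list(NA, el("table_long", geom$table[1])),
    list(NA, el("table_lat", geom$table[2])),
    list(NA, el("table_vert", geom$table[3])),
    list(NA, dcm_element(0x7FE0, 0x0010, "OW", pix_raw)))
  # elements must be sorted by (group, element)
  raw_els <- lapply(body_els, `[[`, 2)
  keys <- vapply(raw_els, function(r) {
    g <- as.integer(r[1]) + 256L * as.integer(r[2])
    e <- as.integer(r[3]) + 256L * as.integer(r[4])
    g * 2^16 + e
  }, numeric(1))
  body <- unlist(raw_els[order(keys)])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# parse one explicit-VR-LE element; returns list(group, element, vr, value)
parse_elements <- function(buf) {
  n <- length(buf)
  pos <- 1
  u16 <- function(i) as.integer(buf[i]) + 256L * as.integer(buf[i + 1])
  u32 <- function(i) readBin(buf[i:(i + 3)], "integer", size = 4,
                             endian = "little")
  out <- list()
  while (pos + 7 <= n) {
    g <- u16(pos); e <- u16(pos + 2)
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (vr %in% c("OB", "OW", "SQ", "UN", "UT")) {
      len <- u32(pos + 8)
      val <- if (len > 0) buf[(pos + 12):(pos + 11 + len)] else raw(0)
      pos <- pos + 12 + len
    } else {
      len <- u16(pos + 6)
      val <- if (len > 0) buf[(pos + 8):(pos + 7 + len)] else raw(0)
      pos <- pos + 8 + len
    }
    out[[length(out) + 1]] <- list(group = g, element = e, vr = vr,
                                   value = val)
  }
  out
}

el_string <- function(el) {
  v <- el$value
  while (length(v) && v[length(v)] %in% as.raw(c(0x00, 0x20)))
    v <- v[-length(v)]
  rawToChar(v)
}
el_numeric <- function(el) {
  if (el$vr == "US") {
    as.integer(el$value[1]) + 256L * as.integer(el$value[2])
  } else {
    as.numeric(strsplit(el_string(el), "\\\\")[[1]])
  }
}

find_el <- function(els, group, element) {
  for (el in els) if (el$group == group && el$element == element) return(el)
  NULL
}

#' Read an XR DICOM file
#'
#' Parses an uncompressed explicit-VR little-endian DICOM file, extracts the
#' per-run geometry from the mapped tags and returns the frames (0-based
#' indexing). Missing mandatory geometry tags produce an error listing every
#' missing tag; a modality other than XR is accepted with a warning (derived
#' frames are written with CT metadata as a workaround).
#'
#' @param path DICOM file path.
#' @param spd_fallback Optional SPD (mm) used when the file lacks the
#'   source-to-patient tag.
#' @param tag_map Geometry tag map, see [dicom_tag_map()].
#' @return List: `frames` (list of matrices), `geometry` (a
#'   [carm_geometry()]), `record` (raw per-tag values), `modality`.
#' @export
read_xr_dicom <- function(path, spd_fallback = NULL,
                          tag_map = dicom_tag_map()) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 132 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  els <- parse_elements(buf[-(1:132)])
  ts <- find_el(els, 0x0002, 0x0010)
  if (!is.null(ts) && el_string(ts) != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax: ", el_string(ts))
  modality <- find_el(els, 0x0008, 0x0060)
  modality <- if (is.null(modality)) NA_character_ else el_string(modality)
  if (!is.na(modality) && !modality %in% c("XA", "RF"))
    warning("non-XR modality '", modality,
            "' accepted (derived-frame compatibility)")
  get_tag <- function(name) {
    t <- tag_map[[name]]
    el <- find_el(els, t[1], t[2])
    if (is.null(el)) NULL else el_numeric(el)
  }
  mandatory <- c("primary_angle", "secondary_angle", "sid", "spd",
                 "table_long", "table_lat", "table_vert")
  if (!is.null(spd_fallback)) mandatory <- setdiff(mandatory, "spd")
  vals <- lapply(stats::setNames(nm = names(tag_map)), get_tag)
  missing <- mandatory[vapply(vals[mandatory], is.null, logical(1))]
  if (length(missing)) {
    tags <- vapply(missing, function(nm)
      sprintf("(%04X,%04X) %s", tag_map[[nm]][1], tag_map[[nm]][2], nm), "")
    stop("missing mandatory geometry tags:\n  ",
         paste(tags, collapse = "\n  "))
  }
  rows <- el_numeric(find_el(els, 0x0028, 0x0010))
  cols <- el_numeric(find_el(els, 0x0028, 0x0011))
  nf_el <- find_el(els, 0x0028, 0x0008)
  nf <- if (is.null(nf_el)) 1L else as.integer(el_numeric(nf_el))
  pd <- find_el(els, 0x7FE0, 0x0010)
  frames <- list()
  if (!is.null(pd)) {
    pix <- readBin(pd$value, "integer", length(pd$value) / 2, size = 2,
                   signed = FALSE, endian = "little")
    per <- rows * cols
    frames <- lapply(seq_len(nf), function(k)
      t(matrix(pix[((k - 1) * per + 1):(k * per)], cols, rows)))
  }
  spd <- vals$spd %||% spd_fallback
  fd <- vals$fd %||% NA_real_
  pitch <- if (!is.null(vals$pixel_spacing)) vals$pixel_spacing[1] else NULL
  if (is.na(fd) && !is.null(pitch)) fd <- pitch * sqrt(rows^2 + cols^2)
  geometry <- carm_geometry(
    primary_angle = vals$primary_angle,
    secondary_angle = vals$secondary_angle,
    table = c(vals$table_long, vals$table_lat, vals$table_vert),
    sid = vals$sid, fd = fd, spd = spd,
    n_u = cols, n_v = rows, pixel_pitch = pitch)
  list(frames = frames, geometry = geometry, record = vals,
       modality = modality)
}
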