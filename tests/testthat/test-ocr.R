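render_reading_frame <- function(reading, layout = panel_layout(),
                                 gain = 1, offset = 0) {
  frame <- matrix(20, layout$frame_size[2], layout$frame_size[1])
  gain * render_panel(frame, reading, layout) + offset
}

random_reading <- function(fd_set = c(15, 20, 25, 31, 37, 42, 48)) {
  geometry_reading(sample(-185:185, 1), sample(-90:90, 1),
                   sample(-99:99, 3, replace = TRUE),
                   sample(90:130, 1), sample(fd_set, 1))
}

reading_equal <- function(a, b) {
  isTRUE(all(a$primary_angle == b$primary_angle,
             a$secondary_angle == b$secondary_angle,
             a$table_cm == b$table_cm, a$sid_cm == b$sid_cm,
             a$fd_cm == b$fd_cm))
}

test_that("cell binarization removes luminance and contrast dependence", {
  expect_equal(binarize_cell(matrix(7, 4, 5)), matrix(0L, 4, 5))
  lay <- panel_layout()
  g7 <- lay$glyphs[["7"]]
  cell_hi <- 30 + 190 * g7
  cell_lo <- 40 + 0.3 * 190 * g7   # gain 0.3, offset 40
  expect_identical(binarize_cell(cell_hi), binarize_cell(cell_lo))
  expect_identical(binarize_cell(cell_hi), g7)
})

test_that("glyph classification is exact and the confusion matrix diagonal", {
  lay <- panel_layout()
  set12 <- lay$glyphs[c(as.character(0:9), "+", "-")]
  for (ch in names(set12)) {
    cl <- classify_glyph(set12[[ch]], set12)
    expect_equal(cl$char, ch)
    expect_equal(cl$distance, 0)
    expect_true(cl$confident)
  }
  # blank cell -> 'blank'
  full <- lay$glyphs[c(names(set12), "blank")]
  blank_cell <- matrix(0L, nrow(set12[[1]]), ncol(set12[[1]]))
  expect_equal(classify_glyph(blank_cell, full)$char, "blank")
  expect_error(classify_glyph(matrix(0L, 3, 3), full), "size mismatch")
})

test_that("a rendered panel reads back field-exactly (printed example values)", {
  # frontal C-arm: RAO 26, CAUD 0, table -64/-7/6, SID 120, FD 15
  r <- geometry_reading(-26, 0, c(-64, -7, 6), 120, 15)
  rd <- read_geometry(render_reading_frame(r))
  expect_true(all(rd$valid))
  expect_equal(rd$primary_angle, -26L)
  expect_equal(rd$secondary_angle, 0L)
  expect_equal(rd$table_cm, c(-64L, -7L, 6L))
  expect_equal(rd$sid_cm, 120L)
  expect_equal(rd$fd_cm, 15L)
  # lateral at LAO 90: positive sign from the orientation word
  r90 <- geometry_reading(90, 0, c(-64, -7, 6), 130, 15)
  expect_equal(read_geometry(render_reading_frame(r90))$primary_angle, 90L)
})

test_that("recognition is exact under random per-frame gain and offset", {
  set.seed(51)
  lay <- panel_layout()
  for (i in 1:150) {
    r <- random_reading()
    frame <- render_reading_frame(r, lay, gain = runif(1, 0.2, 1),
                                  offset = runif(1, 0, 80))
    rd <- read_geometry(frame, lay)
    expect_true(all(rd$valid))
    expect_true(reading_equal(rd, r))
  }
})

test_that("inverted-polarity input is rejected by confidence, not misread", {
  r <- geometry_reading(35, -12, c(10, -5, 0), 110, 20)
  frame <- render_reading_frame(r)
  inverted <- 255 - frame
  rd <- read_geometry(inverted)
  expect_false(all(rd$valid))
})

test_that("readings convert to metric geometry with exact FD pixel pitch", {
  cfg <- default_carm_configs()$frontal
  r <- geometry_reading(-26, 0, c(-64, -7, 6), 120, 15)
  g <- to_carm_geometry(r, cfg)
  expect_equal(g$sid, 1200)
  expect_equal(g$table, c(-640, -70, 60))
  expect_equal(g$spd, 810)
  # pitch comes from the override table, not from the rounded FD
  expect_equal(pixel_pitch(g), unname(cfg$fd_pitch_mm_px["15"]))
  expect_false(isTRUE(all.equal(pixel_pitch(g), 150 / (sqrt(2) * 1000))))
  # unknown FD raises; config without a table falls back to FD-derived pitch
  r2 <- geometry_reading(-26, 0, c(-64, -7, 6), 120, 99)
  expect_error(to_carm_geometry(r2, cfg), "unknown FD")
  cfg2 <- carm_config("monoplane", spd_mm = 810)
  expect_equal(pixel_pitch(to_carm_geometry(r, cfg2)),
               150 / sqrt(2 * 1000^2))
  # invalid fields refuse conversion
  rbad <- geometry_reading(-26, 0, c(-64, -7, 6), 120, 15,
                           valid = c(primary = FALSE, secondary = TRUE,
                                     table_long = TRUE, table_lat = TRUE,
                                     table_vert = TRUE, sid = TRUE,
                                     fd = TRUE))
  expect_error(to_carm_geometry(rbad, cfg), "invalid fields")
})

test_that("geometry -> frame -> OCR -> geometry reproduces rounded values", {
  cfg <- default_carm_configs()$frontal
  set.seed(52)
  for (i in 1:10) {
    g <- carm_geometry(runif(1, -185, 185), runif(1, -90, 90),
                       table = runif(3, -990, 990),
                       sid = runif(1, 905, 1295), fd = 151.18, spd = 810,
                       label = "frontal")
    fr <- render_frame(empty_scene(), g, gain = runif(1, 0.3, 1),
                       offset = runif(1, 0, 60))
    rd <- read_geometry(fr$raster)
    g2 <- to_carm_geometry(rd, cfg)
    expect_equal(g2$primary_angle, round(g$primary_angle))
    expect_equal(g2$secondary_angle, round(g$secondary_angle))
    expect_equal(g2$table, 10 * sign(g$table) * floor(abs(g$table) / 10 + 0.5))
    expect_equal(g2$sid, 10 * round(g$sid / 10))
  }
})

test_that("panel layouts survive a JSON round trip and still drive OCR", {
  lay <- panel_layout()
  path <- withr::local_tempfile(fileext = ".json")
  write_panel_layout(lay, path)
  lay2 <- read_panel_layout(path)
  r <- geometry_reading(-142, 33, c(99, -99, 0), 95, 42)
  frame <- render_reading_frame(r, lay)
  rd <- read_geometry(frame, lay2)
  expect_true(all(rd$valid))
  expect_true(reading_equal(rd, r))
})
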