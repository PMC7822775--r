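test_that("a template cut from the frame is found with score 1", {
  set.seed(41)
  frame <- random_frame(60, 80)
  tpl <- cut_template(frame, c(40, 30), 11)
  st <- match_template(frame, tpl)
  expect_equal(st$position_px, c(40, 30))
  expect_equal(st$score, 1, tolerance = 1e-12)
  expect_true(st$valid)
})

test_that("integer frame shifts displace the match by exactly the shift", {
  set.seed(42)
  frame <- random_frame(60, 60)
  tpl <- cut_template(frame, c(30, 28), 9)
  for (shift in list(c(5, -3), c(-7, 4))) {
    shifted <- matrix(0.5, 60, 60)
    # place the original frame content displaced by (du, dv)
    src_u <- max(1, 1 - shift[1]):min(60, 60 - shift[1])
    src_v <- max(1, 1 - shift[2]):min(60, 60 - shift[2])
    shifted[src_v + shift[2], src_u + shift[1]] <- frame[src_v, src_u]
    st <- match_template(shifted, tpl)
    expect_equal(st$position_px, c(30, 28) + shift)
    expect_equal(st$score, 1, tolerance = 1e-12)
  }
})

test_that("NCC is invariant to affine intensity changes of the frame", {
  set.seed(43)
  frame <- random_frame(50, 50)
  tpl <- cut_template(frame, c(25, 20), 9)
  st0 <- match_template(frame, tpl)
  for (gain in c(0.2, 0.7)) for (offset in c(0, 40)) {
    st <- match_template(gain * frame + offset, tpl)
    expect_equal(st$position_px, st0$position_px)
    expect_equal(st$score, st0$score, tolerance = 1e-9)
  }
})

test_that("argmax equals the exhaustive double-loop NCC oracle", {
  set.seed(44)
  for (i in 1:100) {
    frame <- random_frame(40, 40)
    tpl_size <- sample(c(5, 7, 9), 1)
    cu <- sample(10:30, 1); cv <- sample(10:30, 1)
    tpl <- cut_template(frame, c(cu, cv), tpl_size)
    # corrupt the frame so the optimum is not trivially the cut position
    frame <- frame + matrix(rnorm(1600, sd = 0.15), 40, 40)
    win <- rect(4, 3, 33, 34)
    st <- match_template(frame, tpl, win)
    orc <- oracle_match_ncc(frame, tpl$pixels, win)
    expect_equal(st$position_px, orc$position)
    expect_equal(st$score, orc$score, tolerance = 1e-9)
  }
})

test_that("degenerate templates and windows are flagged, ties break (v,u)", {
  expect_error(template_patch(matrix(1, 7, 7)), "variance")
  expect_error(template_patch(matrix(rnorm(48), 6, 8)), "odd")
  # constant frame region: every placement has undefined NCC
  frame <- matrix(0.5, 30, 30)
  tpl <- template_patch(matrix(c(rep(0, 12), rep(1, 13)), 5, 5))
  st <- match_template(frame, tpl)
  expect_false(st$valid)
  expect_true(is.na(st$score))
  # two identical pattern copies: the smaller (v, u) position wins
  frame2 <- matrix(0, 40, 40)
  pat <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  frame2[10:12, 20:22] <- pat
  frame2[25:27, 5:7] <- pat
  tpl2 <- template_patch(pat)
  st2 <- match_template(frame2, tpl2)
  expect_equal(st2$position_px, c(20, 10))  # v = 10 beats v = 25
  # window geometry checks
  expect_error(match_template(frame2, tpl2, rect(38, 38, 10, 10)),
               "inside the frame")
  expect_error(match_template(frame2, tpl2, rect(0, 0, 2, 2)), "smaller")
})

test_that("2D overlay compensation shifts by the tracked displacement", {
  set.seed(45)
  frame <- random_frame(60, 60)
  tpl <- cut_template(frame, c(30, 30), 9)
  ref <- match_template(frame, tpl)
  expect_equal(compensate_overlay_2d(ref, ref, c(100, 200)), c(100, 200))
  # synthetic sinusoidal motion at integer amplitudes is tracked exactly
  for (k in 0:7) {
    shift <- c(round(5 * sin(2 * pi * k / 8)), round(3 * cos(2 * pi * k / 8)))
    moved <- matrix(0.5, 60, 60)
    src_u <- max(1, 1 - shift[1]):min(60, 60 - shift[1])
    src_v <- max(1, 1 - shift[2]):min(60, 60 - shift[2])
    moved[src_v + shift[2], src_u + shift[1]] <- frame[src_v, src_u]
    cur <- match_template(moved, tpl)
    expect_equal(compensate_overlay_2d(ref, cur, c(10, 10)),
                 c(10, 10) + shift)
  }
})

biplane_small <- function(n_px = 220) {
  list(a = carm_geometry(0, 0, sid = 1200, fd = 150 * sqrt(2), spd = 810,
                         n_u = n_px, n_v = n_px, label = "frontal"),
       b = carm_geometry(90, 0, sid = 1300, fd = 150 * sqrt(2), spd = 765,
                         n_u = n_px, n_v = n_px, label = "lateral"))
}

track_from_sequence <- function(sq) {
  t1 <- sq$truth[1, ]
  track_tip_3d(
    sq$frames_a, sq$frames_b,
    cut_template(sq$frames_a[[1]], round(c(t1$tip_u_a, t1$tip_v_a)), 11),
    cut_template(sq$frames_b[[1]], round(c(t1$tip_u_b, t1$tip_v_b)), 11),
    sq$pm_a, sq$pm_b,
    c(t1$tip_u_a, t1$tip_v_a), c(t1$tip_u_b, t1$tip_v_b),
    cut_template(sq$frames_a[[1]], round(c(t1$ref_u_a, t1$ref_v_a)), 19),
    cut_template(sq$frames_b[[1]], round(c(t1$ref_u_b, t1$ref_v_b)), 19),
    c(t1$ref_u_a, t1$ref_v_a), c(t1$ref_u_b, t1$ref_v_b))
}

# worst-case 3D uncertainty of integer-pixel matching: half a pixel in each
# view axis, mapped from detector to iso-center scale and combined
triangulation_noise_mm <- function(geoms) {
  per_view <- vapply(geoms, function(g)
    0.5 * pixel_pitch(g) * g$spd / g$sid, numeric(1))
  sqrt(sum(2 * per_view^2))
}

test_that("static biplane scene: tracked tip equals ground truth", {
  gs <- biplane_small()
  sq <- make_motion_sequence(gs$a, gs$b, tip_start = c(5, 8, -10),
                             ref_start = c(-12, -5, 10), n_frames = 4,
                             seed = 46)
  tr <- track_from_sequence(sq)
  tol <- triangulation_noise_mm(gs)
  for (k in 1:4) {
    expect_lt(sqrt(sum((unlist(tr[k, c("x", "y", "z")]) -
                          c(5, 8, -10))^2)), tol)
    expect_equal(unlist(tr[k, c("x_comp", "y_comp", "z_comp")]),
                 unlist(tr[k, c("x", "y", "z")]),
                 ignore_attr = TRUE)
  }
})

test_that("tip co-moving with the reference stays put after compensation", {
  gs <- biplane_small()
  motion <- list(type = "linear", amplitude = c(9, -7, 5))
  sq <- make_motion_sequence(gs$a, gs$b, tip_start = c(5, 8, -10),
                             ref_start = c(-12, -5, 10),
                             tip_motion = motion, ref_motion = motion,
                             n_frames = 8, seed = 47)
  tr <- track_from_sequence(sq)
  comp <- as.matrix(tr[, c("x_comp", "y_comp", "z_comp")])
  drift <- sqrt(rowSums(sweep(comp, 2, comp[1, ])^2))
  expect_lt(max(drift), 1.5 * triangulation_noise_mm(gs))
})

test_that("tip motion relative to the reference is recovered", {
  gs <- biplane_small()
  sq <- make_motion_sequence(
    gs$a, gs$b, tip_start = c(5, 8, -10), ref_start = c(-12, -5, 10),
    tip_motion = list(type = "linear", amplitude = c(10, 0, -6)),
    ref_motion = list(type = "none"), n_frames = 8, seed = 48)
  tr <- track_from_sequence(sq)
  tol <- 1.5 * triangulation_noise_mm(gs)
  for (k in 1:8) {
    rel_true <- c(5, 8, -10) + c(10, 0, -6) * (k - 1) / 7
    expect_lt(sqrt(sum((unlist(tr[k, c("x_comp", "y_comp", "z_comp")]) -
                          rel_true)^2)), tol)
  }
})
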