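#' Template patch for NCC tracking
#'
#' A grayscale patch with odd side lengths, anchored at its center pixel.
#'
#' @param pixels Numeric matrix (rows = v, columns = u).
#' @param frame_id Optional id of the frame the patch was cut from.
#' @return A `template_patch`.
#' @export
template_patch <- function(pixels, frame_id = NA) {
  pixels <- as.matrix(pixels)
  if (any(dim(pixels) %% 2 == 0))
    stop("template side lengths must be odd")
  if (stats::sd(pixels) == 0)
    stop("template has zero variance; NCC is undefined")
  structure(list(pixels = pixels, frame_id = frame_id,
                 anchor = c((ncol(pixels) - 1) / 2, (nrow(pixels) - 1) / 2)),
            class = "template_patch")
}

#' Cut a template out of a frame
#'
#' @param frame Grayscale frame matrix (rows = v, columns = u, 0-based
#'   coordinates).
#' @param center `c(u, v)` center pixel, 0-based.
#' @param size Odd side length (square template).
#' @param frame_id Optional id.
#' @export
cut_template <- function(frame, center, size, frame_id = NA) {
  h <- (size - 1) / 2
  template_patch(frame[(center[2] - h):(center[2] + h) + 1,
                       (center[1] - h):(center[1] + h) + 1],
                 frame_id = frame_id)
}

#' Rectangle in pixel coordinates
#'
#' @param u0,v0 Upper-left corner, 0-based px.
#' @param w,h Width and height, px.
#' @export
rect <- function(u0, v0, w, h) {
  stopifnot(w > 0, h > 0)
  list(u0 = u0, v0 = v0, w = w, h = h)
}

# zero-normalized cross-correlation of two equally sized vectors
zncc <- function(a, b_centered, b_norm) {
  ac <- a - mean(a)
  na <- sqrt(sum(ac^2))
  if (na == 0 || b_norm == 0) return(NA_real_)
  sum(ac * b_centered) / (na * b_norm)
}

#' Match a template inside a search window
#'
#' Slides the template over every placement fully inside the window and
#' scores each with zero-normalized cross-correlation (mean-subtracted NCC),
#' which is exactly invariant to affine intensity changes of the frame
#' (positive gain, any offset). The best-scoring center is returned; ties are
#' broken toward the smallest `(v, u)` lexicographically. Placements where
#' the frame region is constant have undefined NCC and are skipped; if every
#' placement is undefined the match is flagged invalid.
#'
#' @param frame Grayscale frame matrix (rows = v, columns = u).
#' @param tpl A [template_patch()].
#' @param window A [rect()] fully inside the frame and at least as large as
#'   the template. Defaults to the whole frame.
#' @param ref_position Optional `c(u, v)` reference position; when given,
#'   `motion_vector_px` is filled with the displacement from it.
#' @param subpixel Parabolic sub-pixel refinement of the peak (off by
#'   default).
#' @return A `track_state`: `position_px`, `score`, `search_window`,
#'   `motion_vector_px`, `valid`.
#' @export
match_template <- function(frame, tpl, window = NULL, ref_position = NULL,
                           subpixel = FALSE) {
  stopifnot(inherits(tpl, "template_patch"))
  frame <- as.matrix(frame)
  if (is.null(window)) window <- rect(0, 0, ncol(frame), nrow(frame))
  th <- nrow(tpl$pixels); tw <- ncol(tpl$pixels)
  if (window$u0 < 0 || window$v0 < 0 ||
      window$u0 + window$w > ncol(frame) ||
      window$v0 + window$h > nrow(frame))
    stop("search window must lie inside the frame")
  if (window$w < tw || window$h < th)
    stop("search window smaller than the template")
  tc <- tpl$pixels - mean(tpl$pixels)
  tn <- sqrt(sum(tc^2))
  nu <- window$w - tw + 1   # placements along u
  nv <- window$h - th + 1
  scores <- matrix(NA_real_, nv, nu)
  for (j in seq_len(nu)) {
    c0 <- window$u0 + j - 1
    sub <- frame[(window$v0 + 1):(window$v0 + window$h),
                 (c0 + 1):(c0 + tw), drop = FALSE]
    for (i in seq_len(nv)) {
      scores[i, j] <- zncc(sub[i:(i + th - 1), ], tc, tn)
    }
  }
  if (all(is.na(scores))) {
    return(structure(list(position_px = c(NA_real_, NA_real_),
                          score = NA_real_, search_window = window,
                          motion_vector_px = c(NA_real_, NA_real_),
                          valid = FALSE),
                     class = "track_state"))
  }
  best <- max(scores, na.rm = TRUE)
  idx <- which(scores >= best - 1e-12, arr.ind = TRUE)
  # ties: smallest (v, u) lexicographic
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
  pos <- c(window$u0 + idx[2] - 1 + tpl$anchor[1],
           window$v0 + idx[1] - 1 + tpl$anchor[2])
  if (subpixel) {
    pos <- pos + c(parab_offset(scores, idx, 2), parab_offset(scores, idx, 1))
  }
  mv <- if (is.null(ref_position)) c(0, 0) else pos - ref_position
  structure(list(position_px = unname(pos), score = unname(best),
                 search_window = window, motion_vector_px = unname(mv),
                 valid = TRUE),
            class = "track_state")
}

# 1D parabolic peak interpolation along dim k (1 = v, 2 = u)
parab_offset <- function(scores, idx, k) {
  i <- idx[k]
  n <- dim(scores)[k]
  if (i <= 1 || i >= n) return(0)
  pick <- function(d) if (k == 1) scores[i + d, idx[2]] else scores[idx[1], i + d]
  ym <- pick(-1); y0 <- pick(0); yp <- pick(1)
  if (anyNA(c(ym, y0, yp))) return(0)
  den <- ym - 2 * y0 + yp
  if (den >= 0) return(0)
  off <- 0.5 * (ym - yp) / den
  max(min(off, 0.5), -0.5)
}

#' @export
print.track_state <- function(x, ...) {
  if (!x$valid) cat("track state: INVALID match\n")
  else cat(sprintf("track state: (%.2f, %.2f) px, NCC %.4f, motion (%+.2f, %+.2f)\n",
                   x$position_px[1], x$position_px[2], x$score,
                   x$motion_vector_px[1], x$motion_vector_px[2]))
  invisible(x)
}

#' 2D overlay motion compensation
#'
#' Shifts the overlay origin by the tracked structure's displacement between
#' the reference state and the current state, so the 2D model overlay follows
#' the motion pattern seen in the projection images.
#'
#' @param ref,cur [match_template()] states from the same view.
#' @param overlay_origin_px `c(u, v)` overlay origin to be shifted.
#' @return Shifted overlay origin.
#' @export
compensate_overlay_2d <- function(ref, cur, overlay_origin_px) {
  stopifnot(inherits(ref, "track_state"), inherits(cur, "track_state"))
  if (!ref$valid || !cur$valid) stop("invalid track state")
  overlay_origin_px + (cur$position_px - ref$position_px)
}

#' Biplane 3D tip tracking with motion compensation
#'
#' Tracks a catheter tip template and a reference-structure template in both
#' views of a biplane sequence, triangulates both to 3D per frame, and
#' subtracts the reference structure's 3D motion vector (its displacement
#' from the first frame) from the tip position. The compensated tip is the
#' tip trajectory relative to the moving anatomy, expressed in the static 3D
#' model frame.
#'
#' Search windows are re-centered on the previous frame's position with a
#' default size of 3x the template.
#'
#' @param frames_a,frames_b Lists of frame matrices for the two views, paired
#'   nearest-in-index.
#' @param tpl_tip_a,tpl_tip_b Tip templates per view.
#' @param tpl_ref_a,tpl_ref_b Reference-structure templates per view; `NULL`
#'   disables motion compensation (compensated tip equals the tip).
#' @param pm_a,pm_b Projection matrices of the two views.
#' @param init_tip_a,init_tip_b,init_ref_a,init_ref_b Initial `c(u, v)`
#'   positions used to center the first search windows.
#' @param window_scale Search-window size as a multiple of the template size.
#' @return A data frame with one row per frame: per-view positions and
#'   scores, triangulated `x, y, z`, ray gap, and compensated
#'   `x_comp, y_comp, z_comp` (all mm).
#' @export
track_tip_3d <- function(frames_a, frames_b, tpl_tip_a, tpl_tip_b,
                         pm_a, pm_b,
                         init_tip_a, init_tip_b,
                         tpl_ref_a = NULL, tpl_ref_b = NULL,
                         init_ref_a = NULL, init_ref_b = NULL,
                         window_scale = 3) {
  n <- min(length(frames_a), length(frames_b))
  compensate <- !is.null(tpl_ref_a) && !is.null(tpl_ref_b)
  win_for <- function(frame, tpl, center) {
    th <- nrow(tpl$pixels); tw <- ncol(tpl$pixels)
    w <- min(ncol(frame), ceiling(tw * window_scale))
    h <- min(nrow(frame), ceiling(th * window_scale))
    u0 <- max(0, min(round(center[1] - w / 2), ncol(frame) - w))
    v0 <- max(0, min(round(center[2] - h / 2), nrow(frame) - h))
    rect(u0, v0, w, h)
  }
  tip_a <- init_tip_a; tip_b <- init_tip_b
  ref_a <- init_ref_a; ref_b <- init_ref_b
  ref0_3d <- NULL
  out <- vector("list", n)
  for (k in seq_len(n)) {
    sa <- match_template(frames_a[[k]], tpl_tip_a,
                         win_for(frames_a[[k]], tpl_tip_a, tip_a))
    sb <- match_template(frames_b[[k]], tpl_tip_b,
                         win_for(frames_b[[k]], tpl_tip_b, tip_b))
    if (!sa$valid || !sb$valid) stop("invalid tip match in frame ", k)
    tip_a <- sa$position_px; tip_b <- sb$position_px
    tip <- triangulate(pm_a, tip_a, pm_b, tip_b)
    motion <- c(0, 0, 0)
    if (compensate) {
      ra <- match_template(frames_a[[k]], tpl_ref_a,
                           win_for(frames_a[[k]], tpl_ref_a, ref_a))
      rb <- match_template(frames_b[[k]], tpl_ref_b,
                           win_for(frames_b[[k]], tpl_ref_b, ref_b))
      if (!ra$valid || !rb$valid) stop("invalid reference match in frame ", k)
      ref_a <- ra$position_px; ref_b <- rb$position_px
      ref3d <- triangulate(pm_a, ref_a, pm_b, ref_b)
      if (is.null(ref0_3d)) ref0_3d <- ref3d$p
      motion <- ref3d$p - ref0_3d
    }
    comp <- tip$p - motion
    out[[k]] <- data.frame(frame_id = k - 1L,
                           u_a = tip_a[1], v_a = tip_a[2], score_a = sa$score,
                           u_b = tip_b[1], v_b = tip_b[2], score_b = sb$score,
                           x = tip$p[1], y = tip$p[2], z = tip$p[3],
                           gap_mm = tip$gap_mm,
                           x_comp = comp[1], y_comp = comp[2],
                           z_comp = comp[3])
  }
  do.call(rbind, out)
}
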