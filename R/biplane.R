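#' Triangulate a 3D point from two views
#'
#' Reconstructs the world position of a point marked in two projection images
#' (biplane frontal/lateral pair, or two monoplane acquisitions at different
#' angulations). The two pixels are back-projected to rays from the respective
#' focal spots and the midpoint of their common perpendicular is returned:
#' algebraically the point minimizing the sum of squared distances to both
#' rays. The closest-approach distance between the rays (`gap_mm`) is reported
#' as an epipolar consistency diagnostic.
#'
#' @param pm_a,pm_b Projection matrices of the two views
#'   ([build_projection()]).
#' @param q_a,q_b The corresponding image point `c(u, v)` in each view, px.
#' @param min_angle_deg Minimum angular separation of the two viewing rays in
#'   degrees; closer-to-parallel geometry raises a degenerate-geometry error.
#' @param gap_warn_mm Warn (and flag) when the ray gap exceeds this value.
#' @return A `reconstructed_point`: `p` (world mm), `gap_mm`, and
#'   `gap_exceeded` flag.
#' @export
triangulate <- function(pm_a, q_a, pm_b, q_b,
                        min_angle_deg = 15, gap_warn_mm = 5) {
  ra <- backproject_ray(pm_a, q_a)
  rb <- backproject_ray(pm_b, q_b)
  # conditioning guard on the view axes (not the individual point rays)
  ax_a <- pm_a$detector$origin - pm_a$source_mm
  ax_b <- pm_b$detector$origin - pm_b$source_mm
  cosax <- abs(sum(ax_a * ax_b)) / sqrt(sum(ax_a^2) * sum(ax_b^2))
  if (cosax > cos(deg2rad(min_angle_deg)))
    stop(sprintf(
      "degenerate geometry: view axes separated by %.2f deg (< %.1f deg)",
      acos(min(cosax, 1)) * 180 / pi, min_angle_deg))
  d1 <- ra$direction; d2 <- rb$direction
  if (abs(sum(d1 * d2)) > 1 - 1e-12)
    stop("degenerate geometry: the two viewing rays are parallel")
  o1 <- ra$origin; o2 <- rb$origin
  w <- o2 - o1
  # [s; t] solving the closest-approach normal equations for the two lines
  a11 <- sum(d1 * d1); a12 <- sum(d1 * d2); a22 <- sum(d2 * d2)
  den <- a11 * a22 - a12^2
  s <- (a22 * sum(w * d1) - a12 * sum(w * d2)) / den
  t <- (a12 * sum(w * d1) - a11 * sum(w * d2)) / den
  p1 <- o1 + s * d1
  p2 <- o2 + t * d2
  gap <- sqrt(sum((p1 - p2)^2))
  flag <- gap > gap_warn_mm
  if (flag)
    warning(sprintf("epipolar residual %.2f mm exceeds %.1f mm", gap,
                    gap_warn_mm))
  structure(list(p = (p1 + p2) / 2, gap_mm = gap, gap_exceeded = flag),
            class = "reconstructed_point")
}

#' @export
print.reconstructed_point <- function(x, ...) {
  cat(sprintf("reconstructed point (%.3f, %.3f, %.3f) mm, ray gap %.4f mm%s\n",
              x$p[1], x$p[2], x$p[3], x$gap_mm,
              if (x$gap_exceeded) " [gap threshold exceeded]" else ""))
  invisible(x)
}

# Liang-Barsky clip of segment p0..p1 against [0,w]x[0,h]; NULL if outside
clip_segment <- function(p0, p1, w, h) {
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  for (i in 1:2) {
    lim <- c(w, h)[i]
    for (side in 1:2) {
      p <- if (side == 1) -d[i] else d[i]
      q <- if (side == 1) p0[i] else lim - p0[i]
      if (p == 0) {
        if (q < 0) return(NULL)
      } else {
        r <- q / p
        if (p < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
        if (t0 > t1) return(NULL)
      }
    }
  }
  rbind(p0 + t0 * d, p0 + t1 * d)
}

#' Epipolar line of a pixel in the other view
#'
#' Projects the viewing ray of pixel `q_a` in view A into view B: the true
#' correspondence of `q_a` must lie on this line. Returned as two endpoints
#' clipped to the view-B image bounds.
#'
#' @inheritParams triangulate
#' @param depth_range Depth interval along the view-A ray (mm from the view-A
#'   focal spot) mapped into view B.
#' @return A 2x2 matrix of `(u, v)` endpoints, or an error if the sampled ray
#'   segment lies behind the view-B source or outside its image.
#' @export
epipolar_line <- function(pm_a, q_a, pm_b,
                          depth_range = NULL) {
  ra <- backproject_ray(pm_a, q_a)
  if (is.null(depth_range)) {
    # bracket the plausible working volume: around the view-A detector throw
    depth_range <- c(1, 2 * sqrt(sum((pm_a$detector$origin -
                                        pm_a$source_mm)^2)))
  }
  s <- seq(depth_range[1], depth_range[2], length.out = 33)
  pts <- t(vapply(s, function(si) ra$origin + si * ra$direction,
                  numeric(3)))
  suppressWarnings(uv <- project(pm_b, pts))
  ok <- stats::complete.cases(uv)
  if (sum(ok) < 2)
    stop("ray lies behind the view-B source over the sampled depth range")
  uv <- uv[ok, , drop = FALSE]
  seg <- clip_segment(uv[1, ], uv[nrow(uv), ], pm_b$n_u - 1, pm_b$n_v - 1)
  if (is.null(seg))
    stop("epipolar line does not intersect the view-B image bounds")
  dimnames(seg) <- list(NULL, c("u", "v"))
  seg
}
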