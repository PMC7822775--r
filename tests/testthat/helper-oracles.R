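# Independent oracles: every one recomputes the quantity under test through
# a different algebraic route than the package implementation.

# Rodrigues rotation of vector v about unit axis by angle (degrees)
rodrigues <- function(v, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# camera basis of a geometry via explicit axis-angle products
oracle_camera <- function(geom) {
  rot <- function(v)
    rodrigues(rodrigues(v, c(1, 0, 0), geom$secondary_angle),
              c(0, 0, 1), geom$primary_angle)
  e_u <- rot(c(1, 0, 0))
  e_v <- rot(c(0, 0, -1))
  d <- rot(c(0, 1, 0))
  s <- geom$table[1] * e_u + geom$table[2] * e_v -
    (geom$spd + geom$table[3]) * d
  list(e_u = e_u, e_v = e_v, d = d, source = s,
       det_center = s + geom$sid * d)
}

# project by explicitly intersecting the source->point ray with the
# detector plane (solves a 3x3 linear system; no projection matrix involved)
oracle_project <- function(geom, p) {
  cam <- oracle_camera(geom)
  A <- cbind(p - cam$source, -cam$e_u, -cam$e_v)
  sol <- solve(A, cam$det_center - cam$source)
  pitch <- if (!is.null(geom$pixel_pitch)) geom$pixel_pitch else
    geom$fd / sqrt(geom$n_u^2 + geom$n_v^2)
  c(sol[2] / pitch + geom$n_u / 2, sol[3] / pitch + geom$n_v / 2)
}

# two-ray least squares point by solving the normal equations
# sum_i (I - d_i d_i^T) p = sum_i (I - d_i d_i^T) o_i
oracle_two_ray_ls <- function(o1, d1, o2, d2) {
  P1 <- diag(3) - outer(d1, d1)
  P2 <- diag(3) - outer(d2, d2)
  as.numeric(solve(P1 + P2, P1 %*% o1 + P2 %*% o2))
}

# Horn's closed-form quaternion solution of the paired-point rigid fit
oracle_fit_rigid_horn <- function(m, f) {
  cm <- colMeans(m); cf <- colMeans(f)
  S <- crossprod(sweep(m, 2, cm), sweep(f, 2, cf))
  tr <- sum(diag(S))
  N <- rbind(
    c(tr, S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1]),
    c(S[2, 3] - S[3, 2], 2 * S[1, 1] - tr, S[1, 2] + S[2, 1],
      S[3, 1] + S[1, 3]),
    c(S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], 2 * S[2, 2] - tr,
      S[2, 3] + S[3, 2]),
    c(S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2],
      2 * S[3, 3] - tr))
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
  list(R = R, t = unname(cf - as.numeric(R %*% cm)))
}

# exhaustive double-loop NCC search over every placement in the window
oracle_match_ncc <- function(frame, tplpix, window) {
  th <- nrow(tplpix); tw <- ncol(tplpix)
  tv <- as.numeric(tplpix)
  best <- -Inf; best_pos <- c(NA, NA)
  for (v0 in window$v0:(window$v0 + window$h - th)) {
    for (u0 in window$u0:(window$u0 + window$w - tw)) {
      patch <- frame[(v0 + 1):(v0 + th), (u0 + 1):(u0 + tw)]
      pv <- as.numeric(patch)
      if (stats::sd(pv) == 0) next
      s <- stats::cor(pv, tv)
      if (s > best + 1e-12) {
        best <- s
        best_pos <- c(u0 + (tw - 1) / 2, v0 + (th - 1) / 2)
      }
    }
  }
  list(position = best_pos, score = best)
}

# random non-degenerate geometry (seeded by the caller)
random_geom <- function(n_px = 1000) {
  carm_geometry(primary_angle = stats::runif(1, -120, 120),
                secondary_angle = stats::runif(1, -40, 40),
                table = stats::runif(3, -300, 300),
                sid = stats::runif(1, 1000, 1300),
                fd = stats::runif(1, 140, 400) * sqrt(2),
                spd = stats::runif(1, 700, 900),
                n_u = n_px, n_v = n_px)
}

table3_set1 <- function() {
  list(frontal = carm_geometry(0, 0, table = c(-640, -70, 60),
                               sid = 1200, fd = 150 * sqrt(2), spd = 810,
                               label = "frontal"),
       lateral = carm_geometry(90, 0, table = c(-640, -70, 60),
                               sid = 1300, fd = 150 * sqrt(2), spd = 765,
                               label = "lateral"))
}

# small random grayscale frame with smooth structure for NCC tests
random_frame <- function(nv, nu) {
  f <- matrix(stats::runif(nv * nu), nv, nu)
  # light smoothing so templates are informative but not degenerate
  (f[, c(1, seq_len(nu - 1))] + f + f[c(1, seq_len(nv - 1)), ]) / 3
}
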