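test_that("gantry rotation follows the primary-then-secondary convention", {
  expect_equal(rotation_gantry(0, 0), diag(3))
  # stated composition: R(pa, sa) = R(pa, 0) %*% R(0, sa)
  expect_equal(rotation_gantry(90, 30),
               rotation_gantry(90, 0) %*% rotation_gantry(0, 30))
  # explicit axis-angle oracle at an arbitrary angulation
  R <- rotation_gantry(37, -22)
  oracle <- cbind(rodrigues(rodrigues(c(1, 0, 0), c(1, 0, 0), -22),
                            c(0, 0, 1), 37),
                  rodrigues(rodrigues(c(0, 1, 0), c(1, 0, 0), -22),
                            c(0, 0, 1), 37),
                  rodrigues(rodrigues(c(0, 0, 1), c(1, 0, 0), -22),
                            c(0, 0, 1), 37))
  expect_equal(R, oracle, tolerance = 1e-12)
  # orthonormal proper rotations across the angulation range
  set.seed(11)
  for (i in 1:20) {
    R <- rotation_gantry(runif(1, -185, 185), runif(1, -90, 90))
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("iso-center projects to the image center for any angulation", {
  set.seed(21)
  for (i in 1:25) {
    g <- carm_geometry(runif(1, -185, 185), runif(1, -90, 90),
                       sid = runif(1, 950, 1300), fd = 220,
                       spd = runif(1, 700, 900), n_u = 1000)
    uv <- project(build_projection(g), c(0, 0, 0))
    expect_equal(unname(uv), c(500, 500), tolerance = 1e-9)
  }
})

test_that("magnification at iso-center equals SID/SPD for any angulation", {
  set.seed(22)
  for (i in 1:10) {
    g <- random_geom()
    pm <- build_projection(g)
    pitch <- pixel_pitch(g)
    # the point on the camera axis at iso-center depth (SPD from the source)
    cam_d <- (pm$detector$origin - pm$source_mm) /
      sqrt(sum((pm$detector$origin - pm$source_mm)^2))
    base <- pm$source_mm + g$spd * cam_d
    # finite-difference magnification of an infinitesimal object there
    h <- 1e-4
    for (k in 1:3) {
      delta <- c(0, 0, 0); delta[k] <- h
      uv0 <- project(pm, base)
      uv1 <- project(pm, base + delta)
      mag <- sqrt(sum((uv1 - uv0)^2)) * pitch / h
      # the along-axis component does not displace; only delta_perp magnifies
      perp <- sqrt(sum(delta^2) - sum(delta * cam_d)^2) / h
      expect_equal(mag, (g$sid / g$spd) * perp, tolerance = 1e-6)
    }
  }
})

test_that("FD change rescales pixels about the image center only", {
  g1 <- carm_geometry(30, -15, table = c(40, -20, 10), sid = 1150,
                      fd = 150 * sqrt(2), spd = 810)
  g2 <- carm_geometry(30, -15, table = c(40, -20, 10), sid = 1150,
                      fd = 250 * sqrt(2), spd = 810)
  pm1 <- build_projection(g1); pm2 <- build_projection(g2)
  ratio <- pixel_pitch(g1) / pixel_pitch(g2)
  set.seed(3)
  pts <- matrix(runif(30, -60, 60), 10, 3)
  uv1 <- project(pm1, pts); uv2 <- project(pm2, pts)
  expect_equal(sweep(uv2, 2, c(500, 500)),
               sweep(uv1, 2, c(500, 500)) * ratio, tolerance = 1e-9)
})

test_that("table translation shifts an iso-center point by |delta_perp| * SID/SPD", {
  g0 <- carm_geometry(25, 10, sid = 1200, fd = 150 * sqrt(2), spd = 810)
  pm0 <- build_projection(g0)
  set.seed(4)
  for (i in 1:5) {
    # table axes 1 and 2 are perpendicular to the view axis, axis 3 along it
    delta <- c(runif(2, -30, 30), 0)
    g1 <- carm_geometry(25, 10, table = delta, sid = 1200,
                        fd = 150 * sqrt(2), spd = 810)
    pm1 <- build_projection(g1)
    uv0 <- project(pm0, c(0, 0, 0))
    uv1 <- project(pm1, c(0, 0, 0))
    shift_mm <- sqrt(sum((uv1 - uv0)^2)) * pixel_pitch(g0)
    expect_equal(shift_mm, sqrt(sum(delta^2)) * 1200 / 810,
                 tolerance = 1e-6)
  }
  # a pure along-axis table step (delta_perp = 0) does not shift the center
  g2 <- carm_geometry(25, 10, table = c(0, 0, 17), sid = 1200,
                      fd = 150 * sqrt(2), spd = 810)
  uvc <- project(build_projection(g2), c(0, 0, 0))
  expect_equal(unname(uvc), c(500, 500), tolerance = 1e-9)
})

test_that("a 10 mm table step maps to 10 * SID/SPD mm on the detector", {
  g <- carm_geometry(sid = 1200, fd = 150 * sqrt(2), spd = 810)
  pm <- build_projection(g)
  uv0 <- project(pm, c(0, 0, 0))
  uv1 <- project(pm, c(10, 0, 0))
  expect_equal(sqrt(sum((uv1 - uv0)^2)) * pixel_pitch(g), 10 * 1200 / 810,
               tolerance = 1e-9)
})

test_that("projection equals the ray/detector-plane intersection oracle", {
  set.seed(5)
  for (i in 1:40) {
    g <- random_geom()
    pm <- build_projection(g)
    for (j in 1:5) {
      p <- -g$table + runif(3, -80, 80)
      expect_equal(unname(project(pm, p)), unname(oracle_project(g, p)),
                   tolerance = 1e-9)
    }
  }
})

test_that("non-square images use the detector-diagonal pixel pitch", {
  g <- carm_geometry(sid = 1200, fd = 250, spd = 810, n_u = 800, n_v = 600)
  expect_equal(pixel_pitch(g), 250 / 1000)  # diagonal of 800x600 is 1000
  uv <- project(build_projection(g), c(0, 0, 0))
  expect_equal(unname(uv), c(400, 300), tolerance = 1e-9)
})

test_that("back-projection round-trips and emits rays from the focal spot", {
  set.seed(6)
  g <- random_geom()
  pm <- build_projection(g)
  for (i in 1:25) {
    p <- -g$table + runif(3, -100, 100)
    r <- backproject_ray(pm, project(pm, p))
    expect_equal(r$origin, pm$source_mm)
    s <- sum((p - r$origin) * r$direction)
    expect_lt(sqrt(sum((r$origin + s * r$direction - p)^2)), 1e-9)
  }
  # two distinct pixels give non-parallel rays from the same origin
  r1 <- backproject_ray(pm, c(200, 300))
  r2 <- backproject_ray(pm, c(700, 650))
  expect_equal(r1$origin, r2$origin)
  expect_lt(abs(sum(r1$direction * r2$direction)), 1 - 1e-8)
  # neutral geometry: image center back-projects along source -> iso-center
  g0 <- carm_geometry(sid = 1200, fd = 150 * sqrt(2), spd = 810)
  r0 <- backproject_ray(build_projection(g0), c(500, 500))
  expect_equal(r0$direction, c(0, 1, 0), tolerance = 1e-12)
})

test_that("projection is homogeneous: rescaling the matrix changes nothing", {
  g <- random_geom()
  pm <- build_projection(g)
  p <- c(30, -42, 17)
  uv <- project(pm, p)
  for (lam in c(2.5, -3, 1e-4)) {
    pm2 <- pm
    pm2$m <- lam * pm$m
    expect_equal(project(pm2, p), uv, tolerance = 1e-9)
  }
})

test_that("points behind the source are flagged non-projectable", {
  g <- carm_geometry(sid = 1200, fd = 150 * sqrt(2), spd = 810)
  pm <- build_projection(g)
  behind <- c(0, -900, 0)  # beyond the focal spot at (0, -810, 0)
  expect_warning(uv <- project(pm, behind), "behind")
  expect_true(all(is.na(uv)))
  expect_error(project(pm, behind, on_behind = "error"), "behind")
})

test_that("geometry validation rejects out-of-range parameters", {
  expect_error(carm_geometry(sid = 800, fd = 220, spd = 810), "sid")
  expect_error(carm_geometry(sid = 1200, fd = 220, spd = -1), "spd")
  expect_error(carm_geometry(200, 0, sid = 1200, fd = 220, spd = 810),
               "primary")
  expect_error(carm_geometry(0, 95, sid = 1200, fd = 220, spd = 810),
               "secondary")
  # vendor range guard is configurable
  expect_s3_class(carm_geometry(200, 0, sid = 1200, fd = 220, spd = 810,
                                angle_limits = c(270, 90)),
                  "carm_geometry")
})
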