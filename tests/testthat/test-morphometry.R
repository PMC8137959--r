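# Contour, hull, rectangle, ellipse, Feret and shape-factor operations.

test_that("degenerate masks are rejected at the contour stage", {
  g <- matrix(0L, 9, 9); g[5, 5] <- 1L
  expect_error(mask_to_contour(g), "too few boundary points|component")
  expect_error(mask_to_contour(matrix(0L, 5, 5)), "empty mask")
  g2 <- matrix(0L, 9, 9); g2[2, 2] <- 1L; g2[7, 7] <- 1L
  expect_error(mask_to_contour(g2), "multi-component")
})

test_that("a filled rectangle's contour prunes to 4 corners at pixel centers", {
  g <- matrix(0L, 30, 50); g[6:25, 6:45] <- 1L
  ct <- mask_to_contour(g, prune_collinear = TRUE)
  expect_equal(nrow(ct), 4L)
  expect_equal(diff(range(ct[, 1])), 39)
  expect_equal(diff(range(ct[, 2])), 19)
  expect_gt(shoelace_area(ct), 0)  # counter-clockwise in image coords
})

test_that("disk contour shoelace area approximates the analytic area", {
  m <- gen_mask(shape_spec("disk", a = 50, grid = c(201, 201)))
  ct <- mask_to_contour(m)
  expect_lt(abs(shoelace_area(ct) - pi * 50^2) / (pi * 50^2), 0.02)
})

test_that("convex hull contains every input point and is idempotent", {
  set.seed(5)
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10),
              cbind(runif(20, 1, 9), runif(20, 1, 9)))
  ch <- convex_hull(sq)
  expect_equal(ch$hull_area, 100)
  for (seed in 1:5) {
    set.seed(seed)
    pts <- cbind(runif(200, -30, 30), rnorm(200, 0, 12))
    ch <- convex_hull(pts)
    ok <- vapply(seq_len(nrow(pts)), function(i)
      inside_convex(pts[i, 1], pts[i, 2], ch$hull), logical(1))
    expect_true(all(ok))
    ch2 <- convex_hull(ch$hull)
    expect_equal(sort(ch2$hull[, 1]), sort(ch$hull[, 1]))
    expect_equal(ch2$hull_area, ch$hull_area)
  }
  expect_error(convex_hull(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("min-area rectangle follows the clockwise angle convention", {
  g <- matrix(0L, 30, 50); g[6:25, 6:45] <- 1L
  f <- compute_features(g)
  expect_identical(f$rect$rotate_angle, -90)
  expect_setequal(round(c(f$rect$width, f$rect$height), 9), c(39, 19))
  # square rotated 45 degrees
  m45 <- gen_mask(shape_spec("rectangle", a = 20, b = 20, theta = 45,
                             grid = c(75, 75)))
  r45 <- min_area_rect(convex_hull(mask_px(m45))$hull)
  expect_equal(r45$rotate_angle, -45, tolerance = 0.02)
  expect_lt(abs(r45$width - r45$height) / r45$width, 0.02)
})

test_that("min-area rectangle matches the brute-force angle sweep", {
  for (seed in 1:10) {
    pts <- random_blob_points(seed)
    r <- min_area_rect(convex_hull(pts)$hull)
    expect_equal(r$area, oracle_minrect_area(pts), tolerance = 1e-6)
  }
})

test_that("Feret diameters match brute-force projections and exact cases", {
  m <- gen_mask(shape_spec("disk", a = 50, grid = c(201, 201)))
  fr <- feret(convex_hull(mask_px(m))$hull)
  expect_equal(fr$max_diameter, 100, tolerance = 0.02)
  expect_equal(fr$min_diameter, 100, tolerance = 0.02)
  g <- matrix(0L, 30, 50); g[6:25, 6:45] <- 1L
  fr2 <- feret(convex_hull(mask_px(nucleus_mask(g, validate = FALSE)))$hull)
  expect_equal(fr2$max_diameter, sqrt(39^2 + 19^2))
  expect_equal(fr2$min_diameter, 19)
  expect_true(all(c(fr2$max_angle, fr2$min_angle) >= -180 &
                  c(fr2$max_angle, fr2$min_angle) <= 180))
  for (seed in 1:10) {
    pts <- random_blob_points(seed + 100)
    fr <- feret(convex_hull(pts)$hull)
    o <- oracle_feret(pts)
    expect_equal(fr$max_diameter, o$max_diameter, tolerance = 1e-6)
    expect_equal(fr$min_diameter, o$min_diameter, tolerance = 1e-6)
  }
})

test_that("ellipse fit recovers analytic shapes", {
  # self-recovery on exact ellipse points
  t <- seq(0, 2 * pi, length.out = 61)[-61]
  exact <- cbind(10 + 50 * cos(t) * cos(0.4) - 30 * sin(t) * sin(0.4),
                 -5 + 50 * cos(t) * sin(0.4) + 30 * sin(t) * cos(0.4))
  ee <- fit_ellipse(exact)
  expect_equal(ee$long_axis, 100, tolerance = 1e-6)
  expect_equal(ee$short_axis, 60, tolerance = 1e-6)
  expect_equal(ee$center, c(10, -5), tolerance = 1e-6)
  # rasterized mask contour: pixel-center boundary erodes by ~half a pixel
  m <- gen_mask(shape_spec("ellipse", a = 50, b = 30, grid = c(111, 111)))
  e <- fit_ellipse(mask_to_contour(m))
  expect_equal(e$long_axis, 100, tolerance = 0.025)
  expect_equal(e$short_axis, 60, tolerance = 0.025)
  mc <- gen_mask(shape_spec("disk", a = 40, grid = c(101, 101)))
  ec <- fit_ellipse(mask_to_contour(mc))
  expect_equal(ec$long_axis, 80, tolerance = 0.02)
  expect_equal(ec$short_axis, 80, tolerance = 0.02)
  expect_lt(sqrt(sum((ec$center - c(50, 50))^2)), 0.5)
  expect_error(fit_ellipse(cbind(1:4, c(2, 3, 1, 5))), "at least 5")
})

test_that("algebraic ellipse fit agrees with direct constrained minimization", {
  m <- random_blob_mask(3)
  ct <- mask_to_contour(m)
  e <- fit_ellipse(ct)
  # independent route: minimize the same constrained algebraic residual
  # over geometric parameters, starting from the moments ellipse
  mx <- mean(ct[, 1]); my <- mean(ct[, 2])
  x <- ct[, 1] - mx; y <- ct[, 2] - my
  obj <- function(p) {
    xc <- p[1]; yc <- p[2]; a <- exp(p[3]); b <- exp(p[4]); th <- p[5]
    ca <- cos(th); sa <- sin(th)
    A <- (ca / a)^2 + (sa / b)^2
    B <- 2 * ca * sa * (1 / a^2 - 1 / b^2)
    C <- (sa / a)^2 + (ca / b)^2
    D <- -2 * A * xc - B * yc
    E <- -B * xc - 2 * C * yc
    F <- A * xc^2 + B * xc * yc + C * yc^2 - 1
    v <- c(A, B, C, D, E, F) / sqrt(4 * A * C - B^2)
    sum((v[1] * x^2 + v[2] * x * y + v[3] * y^2 +
         v[4] * x + v[5] * y + v[6])^2)
  }
  e0 <- fit_ellipse(ct, method = "moments")
  p0 <- c(e0$center[1] - mx, e0$center[2] - my,
          log(e0$long_axis / 2), log(e0$short_axis / 2),
          e0$angle * pi / 180)
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-16))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-16))
  semis <- sort(exp(opt$par[3:4]))
  expect_equal(e$short_axis, 2 * semis[1], tolerance = 1e-6)
  expect_equal(e$long_axis, 2 * semis[2], tolerance = 1e-6)
  expect_equal(e$center, c(opt$par[1] + mx, opt$par[2] + my),
               tolerance = 1e-6)
})

test_that("ellipse perimeter matches arc-length quadrature", {
  expect_equal(ellipse_perimeter(80, 80), 2 * pi * 40)
  expect_equal(ellipse_perimeter(100, 60),
               oracle_ellipse_perimeter(100, 60), tolerance = 1e-4)
  for (sa in c(90, 70, 40, 20)) {
    expect_equal(ellipse_perimeter(100, sa),
                 oracle_ellipse_perimeter(100, sa), tolerance = 1e-4)
  }
  # degenerate limit: tends to 4a, Ramanujan's error stays below 0.5%
  expect_equal(ellipse_perimeter(100, 1e-6), 200, tolerance = 0.005)
  expect_error(ellipse_perimeter(100, -1), "non-positive")
  expect_error(ellipse_perimeter(60, 100), "exceeds")
})

test_that("shape factors honor their defining identities", {
  e <- structure(list(short_axis = 100, long_axis = 100,
                      area = pi * 50^2, perimeter = 2 * pi * 50,
                      center = c(0, 0)), class = "fitted_ellipse")
  fr <- structure(list(max_diameter = 100, min_diameter = 100,
                       max_angle = 0, min_angle = 90),
                  class = "feret_result")
  sf <- shape_factors(e, fr, hull_area = pi * 50^2)
  expect_equal(unlist(sf[c("esf", "csf", "sf1", "sf2", "elongation",
                           "convexity")]),
               c(esf = 1, csf = 1, sf1 = 1, sf2 = 1, elongation = 1,
                 convexity = 1))
  e$short_axis <- 60; e$long_axis <- 100
  expect_equal(shape_factors(e, fr, pi * 50^2)$esf, 0.6)
  fr$min_diameter <- 0
  expect_error(shape_factors(e, fr, pi * 50^2), "denominator")
})

test_that("features are invariant to orientation", {
  base <- compute_features(gen_mask(
    shape_spec("ellipse", a = 50, b = 30, theta = 0, grid = c(121, 121))))
  expect_equal(base$esf, 0.6, tolerance = 0.02)
  for (th in c(15, 30, 60, 120, -45)) {
    f <- compute_features(gen_mask(
      shape_spec("ellipse", a = 50, b = 30, theta = th, grid = c(121, 121))))
    for (feat in c("esf", "csf", "sf1", "sf2", "elongation", "convexity"))
      expect_equal(f[[feat]], base[[feat]], tolerance = 0.02)
    expect_equal(f$feret$max_diameter, base$feret$max_diameter,
                 tolerance = 0.02)
  }
  # exact lattice symmetry: 90-degree rotation of the grid itself
  m <- random_blob_mask(17)
  rot <- t(m$grid)[ncol(m$grid):1, , drop = FALSE]  # rotate 90 degrees
  f0 <- compute_features(m$grid); f90 <- compute_features(rot)
  for (feat in c("esf", "csf", "sf1", "sf2", "elongation", "convexity",
                 "hull_area"))
    expect_equal(f90[[feat]], f0[[feat]], tolerance = 1e-9)
})

test_that("features scale correctly with integer magnification", {
  # base shape large enough that half-pixel contour erosion stays under
  # the tolerance (pixel-center extents are d - 1, not d)
  f1 <- compute_features(gen_mask(
    shape_spec("blob", a = 40, b = 30, theta = 20, seed = 5,
               irregularity = 0.15)))
  f3 <- compute_features(gen_mask(
    shape_spec("blob", a = 120, b = 90, theta = 20, seed = 5,
               irregularity = 0.15)))
  expect_equal(f3$feret$max_diameter / f1$feret$max_diameter, 3,
               tolerance = 0.01)
  expect_equal(f3$ellipse$long_axis / f1$ellipse$long_axis, 3,
               tolerance = 0.01)
  expect_equal(f3$hull_area / f1$hull_area, 9, tolerance = 0.02)
  for (feat in c("esf", "csf", "sf1", "sf2", "elongation", "convexity"))
    expect_equal(f3[[feat]], f1[[feat]], tolerance = 0.02)
})

test_that("feature invariants hold on random blob masks", {
  for (seed in 1:15) {
    f <- compute_features(random_blob_mask(seed + 300))
    expect_gt(f$esf, 0); expect_lte(f$esf, 1)
    expect_gt(f$sf2, 0); expect_lte(f$sf2, 1 + 1e-12)
    expect_gte(f$elongation, 1 - 1e-12)
    expect_equal(f$elongation * f$sf2, 1, tolerance = 1e-12)
    expect_gte(f$feret$max_diameter, f$feret$min_diameter)
    expect_lte(f$hull_area, f$rect$area + 1e-9)
    m <- random_blob_mask(seed + 300)
    fgpx <- which(m$grid == 1L, arr.ind = TRUE)
    bbox <- (diff(range(fgpx[, 1]))) * (diff(range(fgpx[, 2])))
    expect_lte(f$rect$area, bbox + 1e-9)
  }
})

test_that("csf decreases strictly with ellipse elongation at fixed area", {
  esfs <- c(1.0, 0.8, 0.6, 0.4, 0.2)
  area <- pi * 40^2
  csfs <- vapply(esfs, function(q) {
    a <- sqrt(area / (pi * q))   # semi-axes a, b = q a; pi a b = area
    m <- gen_mask(shape_spec("ellipse", a = a, b = q * a,
                             grid = c(2 * ceiling(a) + 9, 2 * ceiling(a) + 9)))
    compute_features(m)$csf
  }, numeric(1))
  expect_true(all(diff(csfs) < 0))
})
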