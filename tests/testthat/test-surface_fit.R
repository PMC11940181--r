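test_that("curve fitting represents lines exactly and circles closely", {
  t <- seq(0, 1, length.out = 30)
  line <- cbind(1 + 2 * t, 3 - t, 0.5 * t)
  cv <- fit_bspline_curve(line, n_control = 8)
  expect_lt(cv$max_dev, 1e-9)
  # circle, 50 points, 12 control points: max deviation < 0.1% of radius
  th <- seq(0, 2 * pi, length.out = 50)
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  cc <- fit_bspline_curve(circ, n_control = 12)
  dense <- eval_bspline_curve(cc, seq(0, 1, length.out = 500))
  dev <- abs(sqrt(dense[, 1]^2 + dense[, 2]^2) - 10)
  expect_lt(max(dev), 0.01)
  expect_error(fit_bspline_curve(circ[1:3, ], n_control = 6, degree = 3),
               "at least")
  # curve network: one fitted curve per polyline
  net <- fit_curve_network(list(line, circ))
  expect_length(net, 2)
})

test_that("curve evaluation matches an independent de Boor oracle", {
  set.seed(3)
  pts <- cbind(cumsum(stats::runif(20)), stats::rnorm(20), stats::rnorm(20))
  cv <- fit_bspline_curve(pts, n_control = 9)
  for (u in c(0, 0.17, 0.5, 0.83, 1)) {
    got <- eval_bspline_curve(cv, u)
    want <- deboor_eval(cv$knots, cv$control, cv$degree, u)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("surface fitting is exact on planes and refines monotonically", {
  set.seed(6)
  xy <- matrix(stats::runif(400, -5, 5), 200, 2)
  plane <- cbind(xy, 0.3 * xy[, 1] - 0.2 * xy[, 2] + 1)
  fit <- fit_surface(plane, n_u = 4, n_v = 4, lambda = 0)
  expect_lt(fit$report$max_dev, 1e-8)
  # sphere patch: deviation strictly decreases as the net grows
  u <- matrix(stats::runif(1600, -0.6, 0.6), 800, 2)
  patch <- cbind(u, sqrt(pmax(1 - rowSums(u^2), 0)) * 10)
  devs <- vapply(c(4, 8, 16), function(n)
    fit_surface(patch, n_u = n, n_v = n, lambda = 1e-6)$report$mean_dev, 0)
  expect_true(all(diff(devs) < 0))
  # fairing trade-off: mean deviation non-decreasing, roughness non-increasing
  roughness <- function(surface) {
    d2 <- function(m) diff(diff(m))
    sum(vapply(1:3, function(k) sum(d2(surface$control[, , k])^2) +
                 sum(d2(t(surface$control[, , k]))^2), 0))
  }
  lams <- c(1e-6, 1e-3, 1, 1e3)
  fits <- lapply(lams, function(l) fit_surface(patch, n_u = 8, n_v = 8,
                                               lambda = l))
  means <- vapply(fits, function(f) f$report$mean_dev, 0)
  rough <- vapply(fits, function(f) roughness(f$surface), 0)
  expect_true(all(diff(means) >= -1e-12))
  expect_true(all(diff(rough) <= 1e-12))
})

test_that("surface fitting is rigid-motion equivariant", {
  set.seed(8)
  u <- matrix(stats::runif(600, -0.6, 0.6), 300, 2)
  patch <- cbind(u, 2 * exp(-rowSums(u^2)))
  f1 <- fit_surface(patch, n_u = 6, n_v = 6, lambda = 1e-4)
  R <- rotation_about_axis(c(1, 2, 1) / sqrt(6), 0.9)
  tr <- c(3, -1, 5)
  f2 <- fit_surface(sweep(patch %*% t(R), 2, tr, "+"),
                    n_u = 6, n_v = 6, lambda = 1e-4)
  g <- seq(0.1, 0.9, length.out = 7)
  s1 <- eval_bspline_surface(f1$surface, rep(g, 7), rep(g, each = 7))
  s2 <- eval_bspline_surface(f2$surface, rep(g, 7), rep(g, each = 7))
  moved <- sweep(s1 %*% t(R), 2, tr, "+")
  # same surface up to the (possibly flipped) principal parameterisation:
  # compare by nearest distance between dense samplings
  expect_lt(max(nearest_dist(moved, s2)), 1e-4)
})

test_that("rank-deficient unpenalised fits are rejected with advice", {
  few <- cbind(stats::runif(10), stats::runif(10), 0)
  expect_error(fit_surface(few, n_u = 8, n_v = 8, lambda = 0),
               "lambda")
})

test_that("stitch validation reports shared and offset boundaries", {
  set.seed(12)
  mk <- function(x0, x1, dz = 0) {
    g <- as.matrix(expand.grid(x = seq(x0, x1, length.out = 15),
                               y = seq(0, 10, length.out = 15)))
    cbind(g, 0.05 * g[, 1] + dz)
  }
  fa <- fit_surface(mk(0, 5), n_u = 4, n_v = 4, lambda = 1e-8)
  fb <- fit_surface(mk(5, 10), n_u = 4, n_v = 4, lambda = 1e-8)
  rep1 <- stitch_and_validate(list(fa$surface, fb$surface), tol = 1e-4)
  expect_true(rep1$pass)
  expect_lt(rep1$max_gap, 1e-4)
  # deliberately offset second patch by +0.5 mm
  fc <- fit_surface(mk(5, 10, dz = 0.5), n_u = 4, n_v = 4, lambda = 1e-8)
  rep2 <- stitch_and_validate(list(fa$surface, fc$surface), tol = 1e-3)
  expect_false(rep2$pass)
  expect_equal(rep2$max_gap, 0.5, tolerance = 0.05)
})

test_that("surfaces survive a JSON round trip", {
  set.seed(2)
  u <- matrix(stats::runif(300, -0.5, 0.5), 150, 2)
  f <- fit_surface(cbind(u, rowSums(u^2)), n_u = 5, n_v = 5, lambda = 1e-4)
  p <- withr::local_tempfile(fileext = ".json")
  write_bsurface_json(f$surface, p)
  s2 <- read_bsurface_json(p)
  g <- seq(0, 1, length.out = 6)
  expect_equal(eval_bspline_surface(f$surface, rep(g, 6), rep(g, each = 6)),
               eval_bspline_surface(s2, rep(g, 6), rep(g, each = 6)),
               tolerance = 1e-12)
})

test_that("fitted deviation on emulated scans stays within 3x the noise", {
  b <- default_bone()
  scan <- emulate_scan(b$mesh, sigma = 0.05, n_views = 4, n_points = 3000,
                       seed = 5)
  merged <- merge_clouds(scan$views, voxel = 0.5)
  # fit the shaft flank, a height-field region
  pts <- merged$points
  keep <- pts[, 2] > 15 & pts[, 2] < 45 & pts[, 3] > 0.5
  fit <- fit_surface(pts[keep, ], n_u = 8, n_v = 8, lambda = 1e-3)
  # amplitude of the Gaussian scanner error is its ~3 sigma peak;
  # the worst point-to-surface deviation stays within 3x that amplitude
  expect_lt(fit$report$max_dev, 3 * (3 * 0.05))
  expect_lt(fit$report$mean_dev, 2 * 0.05)
})
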