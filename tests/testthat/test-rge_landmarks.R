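test_that("RGE frame of a box has the expected centroid and axes", {
  box <- mesh_box(c(30, 10, 8), n = 3)
  fr <- rge_frame(box)
  expect_lt(max(abs(fr$centroid)), 1e-9)
  expect_equal(abs(fr$axes["primary", ]), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(abs(fr$axes["secondary", ]), c(0, 1, 0), tolerance = 1e-6)
  # right-handed orthonormal within 1e-9
  A <- fr$axes
  expect_lt(max(abs(A %*% t(A) - diag(3))), 1e-9)
  expect_equal(det(A), 1, tolerance = 1e-9)
  expect_false(fr$degenerate)
})

test_that("RGE frame is equivariant under a known rigid motion", {
  box <- mesh_box(c(30, 10, 8), n = 3)
  fr <- rge_frame(box)
  R <- rotation_about_axis(c(2, 1, 3) / sqrt(14), 1.1)
  t <- c(4, -7, 2)
  fr2 <- rge_frame(transform_geometry(box, rigid_transform(R, t)))
  expect_equal(fr2$centroid, as.vector(R %*% fr$centroid + t), tolerance = 1e-9)
  for (ax in rownames(fr$axes)) {
    got <- fr2$axes[ax, ]
    want <- as.vector(R %*% fr$axes[ax, ])
    # recovered axis equals the rotated axis up to the documented sign rule
    ang <- acos(min(1, abs(sum(got * want))))
    expect_lt(ang, 1e-4)
  }
})

test_that("a sphere triggers the degenerate-frame flag", {
  fr <- rge_frame(mesh_icosphere(10, 3))
  expect_true(fr$degenerate)
  expect_lt(max(abs(fr$axes %*% t(fr$axes) - diag(3))), 1e-9)
})

test_that("landmark alignment recovers known transforms exactly", {
  canonical <- rbind(c(0, 0, 0), c(10, 0, 0), c(3, 5, 0))
  expect_lt(max(abs(landmark_align(canonical) - diag(4))), 1e-9)
  set.seed(9)
  for (rep in 1:5) {
    R <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, pi))
    t <- stats::rnorm(3, sd = 20)
    Tm <- rigid_transform(R, t)
    moved <- sweep(canonical %*% t(R), 2, t, "+")
    rec <- landmark_align(moved)
    expect_lt(max(abs(rec %*% Tm - diag(4))), 1e-9)
    # applying the recovered transform reproduces the canonical configuration
    back <- sweep(moved %*% t(rec[1:3, 1:3]), 2, rec[1:3, 4], "+")
    expect_lt(max(abs(back - canonical)), 1e-9)
  }
  expect_error(landmark_align(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
})

test_that("cross-sections of analytic solids have the right areas", {
  cyl <- mesh_cylinder(5, 40, 64, 30)
  fr <- rge_frame(cyl)
  cs <- cross_sections(cyl, fr, n_stations = 12)
  areas <- vapply(cs$sections, function(s) if (is.null(s)) NA_real_ else s$area, 0)
  expect_true(all(abs(areas[!is.na(areas)] - 25 * pi) / (25 * pi) < 0.01))
  # cone: areas strictly monotone along the axis
  cone <- mesh_lathe(function(t) pmax(8 * (1 - t / 30), 1e-6), c(0, 30),
                     n_axial = 40, n_seg = 40)
  frc <- rge_frame(cone)
  csc <- cross_sections(cone, frc, n_stations = 10)
  a <- vapply(csc$sections, function(s) if (is.null(s)) NA_real_ else s$area, 0)
  st <- csc$stations[!is.na(a)]; a <- a[!is.na(a)]
  ord <- order(st * sign(frc$axes["primary", 2]))
  # interior stations only: the terminal stations graze the pole caps
  keep <- 2:(length(ord) - 1)
  expect_true(all(diff(a[ord][keep]) < 0))
  # polyline area equals the brute-force shoelace on the same points
  sec <- cs$sections[[5]]
  axis <- fr$axes["primary", ]
  b1 <- c(1, 0, 0); b1 <- b1 - sum(b1 * axis) * axis; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(axis[2] * b1[3] - axis[3] * b1[2], axis[3] * b1[1] - axis[1] * b1[3],
          axis[1] * b1[2] - axis[2] * b1[1])
  xy <- cbind(sec$polyline %*% b1, sec$polyline %*% b2)
  n <- nrow(xy)
  shoelace <- abs(sum(xy[, 1] * xy[c(2:n, 1), 2] -
                        xy[c(2:n, 1), 1] * xy[, 2])) / 2
  expect_equal(sec$area, shoelace, tolerance = 1e-12)
})

test_that("sphere COR fit is exact on exact data and robust to noise", {
  set.seed(1)
  u <- normalize_rows(matrix(stats::rnorm(600), 200, 3))
  sph <- sweep(u * 4, 2, c(1, 2, 3), "+")
  f <- fit_cor(sph, "sphere")
  expect_lt(sqrt(sum((f$center - c(1, 2, 3))^2)), 1e-9)
  expect_equal(f$radius, 4, tolerance = 1e-12)
  expect_lt(f$residual, 1e-9)
  # hemisphere, sigma = 0.05 mm, 500 points: mean centre error < 0.05 mm
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    d <- normalize_rows(matrix(stats::rnorm(1500), 500, 3))
    d[, 3] <- abs(d[, 3])
    p <- d * (10 + stats::rnorm(500, sd = 0.05))
    sqrt(sum(fit_cor(p, "sphere")$center^2))
  }, 0)
  expect_lt(mean(errs), 0.05)
})

test_that("COR residual grows with noise and condyle recovery hits 2%", {
  res <- vapply(c(0, 0.02, 0.05, 0.1, 0.2), function(sg) {
    set.seed(42)
    d <- normalize_rows(matrix(stats::rnorm(900), 300, 3))
    p <- d * (10 + stats::rnorm(300, sd = sg))
    fit_cor(p, "sphere")$residual
  }, 0)
  expect_true(all(diff(res) > 0))
  # synthetic phalanx head: generator-known condylar centre within 2%
  b <- default_bone()
  fr <- rge_frame(b$mesh)
  pt <- partition_bone_features(b$mesh, fr)
  cp <- head_condyle_points(b$mesh, fr, pt)
  f <- fit_cor(cp, "sphere", trim = 0.1)
  expect_lt(sqrt(sum((f$center - b$truth$cor_center)^2)),
            0.02 * b$truth$cor_radius)
})

test_that("circle-in-plane COR mode fits condylar profiles", {
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  plane_pts <- cbind(3 + 2 * cos(th), 5 + 2 * sin(th), 7)
  R <- rotation_about_axis(c(1, 0, 1) / sqrt(2), 0.6)
  pts <- plane_pts %*% t(R)
  f <- fit_cor(pts, "circle")
  expect_equal(f$radius, 2, tolerance = 1e-9)
  expect_lt(sqrt(sum((f$center - as.vector(R %*% c(3, 5, 7)))^2)), 1e-9)
  # sphere mode on coplanar points advises circle mode
  expect_error(fit_cor(plane_pts, "sphere"), "circle")
})
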