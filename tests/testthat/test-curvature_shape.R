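test_that("principal curvatures match analytic values on sphere, plane, cylinder", {
  sp <- mesh_icosphere(10, 3)
  f <- estimate_principal_curvatures(sp, ring = 2)
  expect_lt(abs(stats::median(f$k1) + 0.1) / 0.1, 0.05)
  expect_lt(abs(stats::median(f$k2) + 0.1) / 0.1, 0.05)
  pl <- mesh_grid(25, 25, c(20, 20))
  fp <- suppressWarnings(estimate_principal_curvatures(pl, ring = 2))
  interior <- abs(pl$vertices[, 1]) < 8 & abs(pl$vertices[, 2]) < 8
  expect_lt(max(abs(c(fp$k1[interior], fp$k2[interior])), na.rm = TRUE), 1e-3)
  cy <- mesh_cylinder(5, 40, 48, 24)
  fc <- estimate_principal_curvatures(cy, ring = 2)
  wall <- abs(cy$vertices[, 2]) < 15 &
    (cy$vertices[, 1]^2 + cy$vertices[, 3]^2) > 24
  expect_lt(abs(stats::median(fc$k1[wall])), 5e-3)
  expect_lt(abs(stats::median(fc$k2[wall]) + 0.2) / 0.2, 0.05)
})

test_that("shape index reproduces the critical-point table", {
  # umbilic limit: convex umbilic -> +1
  expect_equal(shape_index(-1, -1), 1)
  expect_equal(shape_index(1, 1), -1)
  expect_equal(abs(shape_index(-1, -1)), 1)
  # parabolic point (one zero curvature)
  expect_equal(shape_index(1, 0), -0.5)
  expect_equal(shape_index(-1, 0), 0.5)
  expect_equal(abs(shape_index(1, 0)), 0.5)
  # symmetric saddle
  expect_equal(shape_index(1, -1), 0)
  # flat point: unspecified
  expect_true(is.na(shape_index(0, 0)))
  # argument order must not matter
  expect_equal(shape_index(-1, 2), shape_index(2, -1))
})

test_that("curvedness is the rms of the principal curvatures", {
  expect_equal(curvedness(0, 0), 0)
  expect_equal(curvedness(-0.1, -0.1), 0.1)
  expect_equal(curvedness(3, 4), sqrt(25 / 2))
  expect_true(all(curvedness(stats::rnorm(20), stats::rnorm(20)) >= 0))
})

test_that("HK classification covers all table cells", {
  eh <- 1e-3; ek <- 1e-5
  expect_equal(as.character(hk_classify(-0.1, 0.01, eh, ek)), "convex_elliptical")
  expect_equal(as.character(hk_classify(-0.1, 0, eh, ek)), "convex_cylinder")
  expect_equal(as.character(hk_classify(-0.1, -0.01, eh, ek)), "saddle_ridge")
  expect_equal(as.character(hk_classify(0, 0, eh, ek)), "planar")
  expect_equal(as.character(hk_classify(0, -0.01, eh, ek)), "saddle_symmetry")
  expect_equal(as.character(hk_classify(0, 0.01, eh, ek)), "invalid")
  expect_equal(as.character(hk_classify(0.1, 0.01, eh, ek)), "concave_elliptical")
  expect_equal(as.character(hk_classify(0.1, 0, eh, ek)), "concave_cylinder")
  expect_equal(as.character(hk_classify(0.05, -0.0025, eh, ek)), "saddle_valley")
})

test_that("SC classification bins the shape index at its critical points", {
  ec <- 1e-3
  expect_equal(as.character(sc_classify(1, 0.1, ec)), "convex_elliptical")
  expect_equal(as.character(sc_classify(0.7, 0.1, ec)), "convex_elliptical")
  expect_equal(as.character(sc_classify(0.5, 0.1, ec)), "convex_cylinder")
  expect_equal(as.character(sc_classify(0.3, 0.1, ec)), "saddle_ridge")
  expect_equal(as.character(sc_classify(0, 0.1, ec)), "saddle_symmetry")
  expect_equal(as.character(sc_classify(-0.3, 0.1, ec)), "saddle_valley")
  expect_equal(as.character(sc_classify(-0.5, 0.1, ec)), "concave_cylinder")
  expect_equal(as.character(sc_classify(-0.9, 0.1, ec)), "concave_elliptical")
  # flat points are planar whatever S says
  expect_equal(as.character(sc_classify(0.8, 0, ec)), "planar")
  expect_equal(as.character(sc_classify(NA, 0, ec)), "planar")
})

test_that("HK and SC agree cell-for-cell away from thresholds", {
  set.seed(4)
  k1 <- stats::rnorm(500); k2 <- stats::rnorm(500)
  swap <- k1 < k2
  tmp <- k1[swap]; k1[swap] <- k2[swap]; k2[swap] <- tmp
  H <- (k1 + k2) / 2; K <- k1 * k2
  S <- shape_index(k1, k2); C <- curvedness(k1, k2)
  eh <- 1e-9; ek <- 1e-9; ec <- 1e-9
  hk <- as.character(hk_classify(H, K, eh, ek))
  sc <- as.character(sc_classify(S, C, ec, eps_s = 1e-9))
  # exclude samples numerically at a cell boundary
  clear <- abs(H) > 1e-3 & abs(K) > 1e-3 & C > 1e-3 &
    abs(S) > 0.01 & abs(abs(S) - 0.5) > 0.01
  expect_gt(sum(clear), 300)
  expect_true(all(hk[clear] == sc[clear]))
})

test_that("curvature descriptors are scale covariant", {
  sp <- mesh_icosphere(10, 3)
  f1 <- estimate_principal_curvatures(sp, ring = 2)
  sp2 <- sp
  sp2$vertices <- sp2$vertices * 4
  f2 <- estimate_principal_curvatures(sp2, ring = 2)
  expect_equal(stats::median(f2$k1), stats::median(f1$k1) / 4, tolerance = 1e-3)
  expect_equal(stats::median(f2$K), stats::median(f1$K) / 16, tolerance = 1e-3)
  expect_equal(stats::median(f2$C), stats::median(f1$C) / 4, tolerance = 1e-3)
  expect_equal(stats::median(f2$S), stats::median(f1$S), tolerance = 1e-6)
  # S is invariant under positive scaling of the curvature pair
  k1 <- c(0.3, 1, -0.2); k2 <- c(0.1, -1, -0.6)
  for (t in c(0.5, 2, 7))
    expect_equal(shape_index(k1 * t, k2 * t), shape_index(k1, k2))
})

test_that("analytic fixtures classify to their true table cell on >=95% of interior vertices", {
  check <- function(mesh, interior, true_label, analytic_k = NULL) {
    f <- suppressWarnings(estimate_principal_curvatures(mesh, ring = 2))
    lab <- classify_field(f, "hk", mesh = mesh)
    frac <- mean(as.character(lab[interior]) == true_label, na.rm = TRUE)
    expect_gte(frac, 0.95)
    frac
  }
  sp <- mesh_icosphere(10, 3)
  check(sp, rep(TRUE, nrow(sp$vertices)), "convex_elliptical")
  pl <- mesh_grid(25, 25, c(20, 20))
  check(pl, abs(pl$vertices[, 1]) < 7 & abs(pl$vertices[, 2]) < 7, "planar")
  cy <- mesh_cylinder(5, 40, 48, 24)
  check(cy, abs(cy$vertices[, 2]) < 14 &
          (cy$vertices[, 1]^2 + cy$vertices[, 3]^2) > 24, "convex_cylinder")
  # saddle z = xy: K < 0 everywhere off the axes; classify with the
  # analytic H as truth per vertex (saddle family, H sign varies)
  sa <- mesh_grid(31, 31, c(20, 20), height = function(x, y) 0.05 * x * y)
  f <- suppressWarnings(estimate_principal_curvatures(sa, ring = 2))
  interior <- abs(sa$vertices[, 1]) < 7 & abs(sa$vertices[, 2]) < 7
  expect_gte(mean(f$K[interior] < 0, na.rm = TRUE), 0.95)
})

test_that("undefined vertices are flagged and inherited from neighbours", {
  # a tiny mesh: every vertex has < 5 neighbours -> all undefined
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     matrix(c(1, 2, 3), 1), check = FALSE)
  expect_warning(f <- estimate_principal_curvatures(m, ring = 1),
                 "too few neighbours")
  expect_true(all(!f$defined))
  expect_error(classify_field(f, "hk"), "no defined vertices")
})
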