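test_that("round-trip I/O preserves geometry in every supported format", {
  m <- mesh_icosphere(3, 2)
  cl <- point_cloud(matrix(stats::rnorm(45), 15, 3))
  for (fmt in c("ply", "obj")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_geometry(m, p)
    m2 <- read_geometry(p)
    expect_equal(nrow(m2$vertices), nrow(m$vertices))
    expect_equal(nrow(m2$faces), nrow(m$faces))
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
  }
  # binary dialects
  for (fmt in c("ply", "stl")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_geometry(m, p, binary = TRUE)
    m2 <- read_geometry(p)
    expect_equal(nrow(m2$faces), nrow(m$faces))
    expect_lt(max(abs(sort(m2$vertices) - sort(m$vertices))), 1e-5)
  }
  # ascii STL welds its triangle soup back to the same topology
  p <- withr::local_tempfile(fileext = ".stl")
  write_geometry(m, p)
  m2 <- read_geometry(p)
  expect_equal(nrow(m2$vertices), nrow(m$vertices))
  expect_true(watertight_check(m2)$watertight)
  # XYZ: N lines -> N points, with normals
  p <- withr::local_tempfile(fileext = ".xyz")
  cl_n <- point_cloud(cl$points, normals = normalize_rows(matrix(1, 15, 3)))
  write_geometry(cl_n, p)
  cl2 <- read_geometry(p)
  expect_equal(nrow(cl2$points), 15)
  expect_lt(max(abs(cl2$points - cl$points)), 1e-6)
  expect_false(is.null(cl2$normals))
})

test_that("malformed files raise format errors without partial objects", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 0", "      vertex 1 0 0"), p)
  expect_error(read_geometry(p), "STL parse error")
  p2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1 2 3", "4 five 6"), p2)
  expect_error(read_geometry(p2), "XYZ parse error")
  p3 <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 10",
               "property double x", "property double y", "property double z",
               "end_header", "0 0 0"), p3)
  expect_error(read_geometry(p3), "truncated")
})

test_that("OBJ polygons are fan-triangulated with a warning", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), p)
  expect_warning(m <- read_geometry(p), "triangulated")
  expect_equal(nrow(m$faces), 2)
})

test_that("statistical outlier removal removes planted outliers, spares inliers", {
  b <- default_bone()
  set.seed(11)
  base <- sample_surface(b$mesh, 4000)
  base <- point_cloud(base$points +
                        base$normals * stats::rnorm(4000, sd = 0.02),
                      normals = base$normals)
  planted <- plant_outliers(base, n_outliers = 50, scale = 2.5, seed = 3)
  cleaned <- clean_cloud(planted$cloud)
  removed <- attr(cleaned, "removed")
  expect_gte(sum(planted$outlier_idx %in% removed), 50 * 0.98)
  inliers_lost <- sum(!(removed %in% planted$outlier_idx))
  expect_lte(inliers_lost, 0.01 * nrow(base$points))
  # idempotence: cleaning a cleaned cloud with wide threshold removes nothing
  again <- clean_cloud(cleaned, sigma_mult = 6)
  expect_equal(nrow(again$points), nrow(cleaned$points))
})

test_that("clean_cloud enforces its preconditions", {
  small <- point_cloud(matrix(stats::rnorm(48), 16, 3))
  expect_error(clean_cloud(small, k_neighbors = 16), "at least")
  uniform <- point_cloud(as.matrix(expand.grid(1:5, 1:5, 1:5)))
  expect_equal(nrow(clean_cloud(uniform, k_neighbors = 6,
                                sigma_mult = 6)$points), 125)
})

test_that("voxel merge matches a brute-force voxel hash and handles edge cases", {
  set.seed(5)
  pts <- matrix(stats::runif(600, 0, 10), 200, 3)
  cl <- point_cloud(pts)
  # same cloud twice with a fine voxel: duplicates collapse to one per voxel
  merged <- merge_clouds(list(cl, cl), voxel = 0.05)
  key <- paste(floor((pts[, 1] - min(pts[, 1])) / 0.05),
               floor((pts[, 2] - min(pts[, 2])) / 0.05),
               floor((pts[, 3] - min(pts[, 3])) / 0.05))
  expect_equal(nrow(merged$points), length(unique(key)))
  # brute-force centroid-per-voxel oracle
  oracle <- do.call(rbind, lapply(split(seq_len(nrow(pts)), key), function(i)
    colMeans(pts[i, , drop = FALSE])))
  oracle <- oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ]
  got <- merged$points
  got <- got[order(got[, 1], got[, 2], got[, 3]), ]
  expect_lt(max(abs(got - oracle)), 1e-9)
  # one cloud, huge voxel -> single centroid
  one <- merge_clouds(cl, voxel = 1e3)
  expect_equal(nrow(one$points), 1)
  expect_lt(max(abs(one$points[1, ] - colMeans(pts))), 1e-9)
  # disjoint clouds at fine voxel -> counts add
  cl2 <- point_cloud(pts + 100)
  expect_equal(nrow(merge_clouds(list(cl, cl2), voxel = 0.05)$points),
               2 * length(unique(key)))
  # order independence
  m1 <- merge_clouds(list(cl, cl2), voxel = 0.7)
  m2 <- merge_clouds(list(cl2, cl), voxel = 0.7)
  expect_equal(m1$points, m2$points)
})

test_that("mass properties match analytic solids and transform correctly", {
  cube <- mesh_box(c(1, 1, 1))
  mp <- mass_properties(cube, density = 1)
  expect_equal(mp$volume, 1, tolerance = 1e-12)
  expect_lt(max(abs(mp$centroid)), 1e-12)
  # analytic cuboid inertia m/12 (b^2+c^2) on the diagonal
  box <- mesh_box(c(3, 2, 1))
  mb <- mass_properties(box, density = 1)
  expect_equal(diag(mb$inertia), 6 / 12 * c(2^2 + 1, 3^2 + 1, 3^2 + 2^2),
               tolerance = 1e-9)
  expect_lt(max(abs(mb$inertia - diag(diag(mb$inertia)))), 1e-9)
  # refined icosphere volume within 0.5% of (4/3) pi r^3
  sp <- mesh_icosphere(10, 4)
  expect_equal(mass_properties(sp)$volume, 4 / 3 * pi * 1000,
               tolerance = 5e-3)
  # translation invariance and inertia rotation equivariance
  R <- rotation_about_axis(c(1, 2, 2) / 3, 0.7)
  moved <- transform_geometry(box, rigid_transform(R, c(5, -3, 2)))
  mm <- mass_properties(moved, density = 1)
  expect_equal(mm$volume, mb$volume, tolerance = 1e-9)
  expect_equal(mm$centroid, as.vector(R %*% mb$centroid + c(5, -3, 2)),
               tolerance = 1e-9)
  expect_equal(mm$inertia, R %*% mb$inertia %*% t(R), tolerance = 1e-6)
})

test_that("mass properties reject open meshes, naming the open edge count", {
  cube <- mesh_box(c(1, 1, 1))
  open_cube <- triangle_mesh(cube$vertices, cube$faces[-1, ], check = FALSE)
  expect_error(mass_properties(open_cube), "3 open edges")
})

test_that("deviation map is exact point-to-triangle distance", {
  b <- default_bone()
  set.seed(2)
  on_surf <- sample_surface(b$mesh, 400)
  expect_lt(deviation_map(b$mesh, on_surf)$max, 1e-9)
  # translated plane: max = mean = d
  plane <- mesh_grid(8, 8, c(10, 10))
  ref <- point_cloud(sweep(plane$vertices[20:40, ], 2, c(0, 0, 0.37), "+"))
  dv <- deviation_map(plane, ref)
  expect_equal(dv$max, 0.37, tolerance = 1e-12)
  expect_equal(dv$mean, 0.37, tolerance = 1e-12)
  # 100 random points against the independent exhaustive oracle
  q <- matrix(stats::rnorm(300, sd = 15), 100, 3)
  small <- mesh_icosphere(6, 1)
  got <- point_mesh_distance(q, small)
  oracle <- vapply(seq_len(100), function(i) naive_mesh_dist(q[i, ], small), 0)
  expect_lt(max(abs(got - oracle)), 1e-9)
})

test_that("interference check flags penetration and clearance violations", {
  s1 <- mesh_icosphere(1, 2)
  s2 <- mesh_icosphere(1, 2, center = c(3, 0, 0))
  s3 <- mesh_icosphere(1, 2, center = c(1.5, 0, 0))
  expect_equal(nrow(interference_check(list(s1, s2))), 0)
  hit <- interference_check(list(s1, s3))
  expect_equal(nrow(hit), 1)
  expect_equal(unname(hit[1, ]), c(1L, 2L))
  # clearance: 3 apart violates a 1.5 mm clearance (gap is ~1)
  expect_equal(nrow(interference_check(list(s1, s2), clearance = 1.5)), 1)
  open_m <- triangle_mesh(s1$vertices, s1$faces[-1, ], check = FALSE)
  expect_error(interference_check(list(open_m, s2)), "not watertight")
})

test_that("mesh repair welds duplicates and drops degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1e-9, 1e-9, 0), c(1, 1, 0))
  f <- rbind(c(1, 2, 3), c(4, 2, 5), c(2, 2, 3))
  m <- repair_mesh(triangle_mesh(v, f, check = FALSE), tol = 1e-6)
  expect_equal(nrow(m$vertices), 4)
  expect_equal(nrow(m$faces), 2)
})
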