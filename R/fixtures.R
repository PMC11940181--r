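#' Synthetic long-bone generator
#'
#' Builds a watertight lathed long bone emulating metacarpal/phalanx anatomy:
#' a rounded base cap, a shaft with two anatomical necks, and a spherical
#' condylar head of known centre and radius (the ground-truth joint centre of
#' rotation).  The lathe axis is +y (distal).  All ground truth is analytic
#' (solid of revolution), independent of the mesh.
#'
#' @param length bone length (mm)
#' @param base_radius,shaft_radius,head_radius profile radii (mm)
#' @param neck_stations two fractions of length in (0, 1) marking the necks
#' @param neck_factor neck radius as a fraction of the local profile
#' @param exponent superellipse cross-section exponent (2 = circular; the
#'   head is a true sphere only at 2)
#' @param n_axial,n_seg mesh resolution
#' @param seed RNG seed (kept for interface symmetry; the bone is
#'   deterministic)
#' @return list: `mesh` (`rebiom_mesh`), `truth` (list: `length`, `cog`,
#'   `volume`, `axis`, `neck_stations` (mm), `cor_center`, `cor_radius`,
#'   `profile` function)
#' @export
gen_bone <- function(length = 60, base_radius = 3.8, shaft_radius = 3.2,
                     head_radius = 4.5, neck_stations = c(0.18, 0.82),
                     neck_factor = 0.8, exponent = 2,
                     n_axial = 80L, n_seg = 40L, seed = 1L) {
  if (length <= 0 || base_radius <= 0 || shaft_radius <= 0 || head_radius <= 0)
    stop("inconsistent bone spec: lengths and radii must be positive")
  if (any(neck_stations <= 0) || any(neck_stations >= 1) ||
      neck_stations[1] >= neck_stations[2])
    stop("inconsistent bone spec: neck stations must satisfy 0 < s1 < s2 < 1")
  if (head_radius >= length / 3 || base_radius >= length / 3)
    stop("inconsistent bone spec: end radii too large for the length")
  L <- length
  s1 <- neck_stations[1] * L; s2 <- neck_stations[2] * L
  head_c <- L - head_radius
  tb <- base_radius                       # base cap extent (quarter circle)
  th <- head_c - 0.55 * head_radius       # axial start of the spherical head
  if (s1 <= tb || s2 >= th)
    stop("inconsistent bone spec: neck stations collide with the end caps")
  rn1 <- neck_factor * shaft_radius
  rn2 <- neck_factor * min(shaft_radius, head_radius)
  r_join <- head_radius * sqrt(1 - 0.55^2)
  mid <- (s1 + s2) / 2
  # half-cosine blend: r(a)=r0 at a=0, r1 at a=1, zero slope at both ends,
  # monotone -- so the profile minima sit exactly at the neck stations
  blend <- function(t, t0, t1, r0, r1) {
    a <- (t - t0) / (t1 - t0)
    r0 + (r1 - r0) * (1 - cos(pi * a)) / 2
  }
  profile <- function(t) {
    r <- numeric(length(t))
    seg <- findInterval(t, c(tb, s1, mid, s2, th))
    i <- seg == 0
    r[i] <- base_radius * sqrt(pmax(1 - ((t[i] - tb) / tb)^2, 0))
    i <- seg == 1; r[i] <- blend(t[i], tb, s1, base_radius, rn1)
    i <- seg == 2; r[i] <- blend(t[i], s1, mid, rn1, shaft_radius)
    i <- seg == 3; r[i] <- blend(t[i], mid, s2, shaft_radius, rn2)
    i <- seg == 4; r[i] <- blend(t[i], s2, th, rn2, r_join)
    i <- seg == 5
    r[i] <- sqrt(pmax(head_radius^2 - (t[i] - head_c)^2, 0))
    pmax(r, 1e-9)
  }
  mesh <- mesh_lathe(profile, c(0, L), n_axial = n_axial, n_seg = n_seg,
                     exponent = exponent)
  # analytic solid-of-revolution ground truth; the cross-section area of a
  # superellipse with semi-axes r is c_e * r^2, and c_e cancels in the CoG
  c_e <- 4 * gamma(1 + 1 / exponent)^2 / gamma(1 + 2 / exponent)
  ts <- seq(0, L, length.out = 4001)
  r2 <- profile(ts)^2
  vol <- c_e * trapz(ts, r2)
  cog_y <- c_e * trapz(ts, ts * r2) / vol
  list(mesh = mesh,
       truth = list(length = L, cog = c(0, cog_y, 0), volume = vol,
                    axis = c(0, 1, 0),
                    neck_stations = c(s1, s2),
                    cor_center = c(0, head_c, 0), cor_radius = head_radius,
                    profile = profile))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Synthetic occlusal (tooth crown) surface generator
#'
#' A height-field crown over a circular base: a nearly flat base plus
#' `n_cusps` radially placed smooth bumps with known apex positions.  The
#' molar preset has 8 cusps, the premolar 6 (third-molar and premolar
#' anatomy); incisor cusp counts are ambiguous anatomically, so they are
#' parameterised rather than preset.
#'
#' @param preset `"molar"`, `"premolar"`, or `NULL` to use `n_cusps`
#' @param n_cusps cusp count when no preset is given
#' @param crown_diameter crown diameter (mm)
#' @param cusp_height,cusp_width bump amplitude and Gaussian width (mm)
#' @param sigma Gaussian scanner-noise amplitude added to the heights (mm)
#' @param n grid resolution per side
#' @param seed RNG seed (noise realisation)
#' @return list: `mesh` (open `rebiom_mesh`, +z occlusal), `truth` (list:
#'   `n_cusps`, `apexes` matrix, `crown_diameter`)
#' @export
gen_occlusal <- function(preset = NULL, n_cusps = 8L, crown_diameter = 10,
                         cusp_height = 1.4, cusp_width = 0.85,
                         sigma = 0, n = 75L, seed = 1L) {
  if (!is.null(preset)) {
    n_cusps <- switch(match.arg(preset, c("molar", "premolar")),
                      molar = 8L, premolar = 6L)
  }
  stopifnot(n_cusps >= 1)
  R <- crown_diameter / 2
  ring_r <- 0.62 * R
  ang <- 2 * pi * (seq_len(n_cusps) - 1) / n_cusps + pi / (2 * n_cusps)
  apex_xy <- cbind(ring_r * cos(ang), ring_r * sin(ang))
  height <- function(x, y) {
    z <- 0.15 * cusp_height * (1 - ((x^2 + y^2) / R^2))  # gentle crown swell
    for (k in seq_len(n_cusps)) {
      d2 <- (x - apex_xy[k, 1])^2 + (y - apex_xy[k, 2])^2
      z <- z + cusp_height * exp(-d2 / (2 * cusp_width^2))
    }
    z
  }
  xs <- seq(-R, R, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  keep_idx <- which(g$x^2 + g$y^2 <= R^2)
  zz <- height(g$x[keep_idx], g$y[keep_idx])
  if (sigma > 0) {
    set.seed(seed)
    zz <- zz + stats::rnorm(length(zz), sd = sigma)
  }
  verts <- cbind(g$x[keep_idx], g$y[keep_idx], zz)
  # faces over the masked grid
  inside <- logical(nrow(g)); inside[keep_idx] <- TRUE
  newid <- integer(nrow(g)); newid[keep_idx] <- seq_along(keep_idx)
  faces <- NULL
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    a <- (j - 1) * n + i; b <- a + 1; c3 <- a + n; d <- c3 + 1
    if (inside[a] && inside[b] && inside[d])
      faces <- rbind(faces, newid[c(a, b, d)])
    if (inside[a] && inside[d] && inside[c3])
      faces <- rbind(faces, newid[c(a, d, c3)])
  }
  mesh <- triangle_mesh(verts, faces, check = FALSE)
  apexes <- cbind(apex_xy, height(apex_xy[, 1], apex_xy[, 2]))
  list(mesh = mesh,
       truth = list(n_cusps = n_cusps, apexes = apexes,
                    crown_diameter = crown_diameter))
}

#' Scanner emulator
#'
#' Emulates a multi-view structured-light digitisation of a mesh: per view,
#' surface points are sampled uniformly by area, kept when their outward
#' normal faces the view direction, perturbed by Gaussian noise of amplitude
#' `sigma` along the normal, thinned by the dropout probability, and moved by
#' a small per-view rigid jitter (mis-registration).  The ground-truth jitter
#' transforms are returned so registration can be validated.
#'
#' @param mesh a `rebiom_mesh`
#' @param sigma noise amplitude along the normal (mm); 0.05 mm default, the
#'   class of desktop structured-light scanners
#' @param dropout per-point dropout probability in `[0, 1)`
#' @param n_views number of scan views (directions on a circle + poles)
#' @param jitter_rot,jitter_trans per-view rigid jitter scales (rad, mm)
#' @param n_points samples drawn per view before visibility culling
#' @param seed RNG seed
#' @return list: `views` (list of [point_cloud()], `view_id` set),
#'   `jitter` (list of 4x4 true transforms applied per view), `merged_true`
#'   (single cloud with noise but no jitter)
#' @export
emulate_scan <- function(mesh, sigma = 0.05, dropout = 0, n_views = 6L,
                         jitter_rot = 0, jitter_trans = 0,
                         n_points = 4000L, seed = 1L) {
  stopifnot(sigma >= 0, dropout >= 0, dropout < 1)
  set.seed(seed)
  dirs <- view_directions(n_views)
  views <- vector("list", n_views)
  jitter <- vector("list", n_views)
  true_pts <- NULL
  for (v in seq_len(n_views)) {
    cl <- sample_surface(mesh, n_points)
    vis <- as.vector(cl$normals %*% dirs[v, ]) > 0.05
    pts <- cl$points[vis, , drop = FALSE]
    nrm <- cl$normals[vis, , drop = FALSE]
    if (sigma > 0)
      pts <- pts + nrm * stats::rnorm(nrow(pts), sd = sigma)
    if (dropout > 0) {
      keep <- stats::runif(nrow(pts)) >= dropout
      pts <- pts[keep, , drop = FALSE]
      nrm <- nrm[keep, , drop = FALSE]
    }
    true_pts <- rbind(true_pts, pts)
    Tj <- diag(4)
    if (jitter_rot > 0 || jitter_trans > 0) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      Tj <- rigid_transform(rotation_about_axis(ax, stats::rnorm(1, sd = jitter_rot)),
                            stats::rnorm(3, sd = jitter_trans))
      pts <- sweep(pts %*% t(Tj[1:3, 1:3]), 2, Tj[1:3, 4], "+")
      nrm <- nrm %*% t(Tj[1:3, 1:3])
    }
    jitter[[v]] <- Tj
    views[[v]] <- point_cloud(pts, normals = normalize_rows(nrm),
                              view_id = rep(v, nrow(pts)))
  }
  list(views = views, jitter = jitter,
       merged_true = point_cloud(true_pts))
}

view_directions <- function(n) {
  if (n <= 2) return(rbind(c(0, 0, 1), c(0, 0, -1))[seq_len(n), , drop = FALSE])
  k <- n - 2L
  th <- 2 * pi * (seq_len(k) - 1) / k
  rbind(cbind(cos(th), sin(th), 0), c(0, 0, 1), c(0, 0, -1))
}

#' Plant artificial outliers in a cloud (test fixture helper)
#'
#' Outliers are displaced along the per-point outward surface normal when
#' normals are available, guaranteeing genuine off-surface points; otherwise
#' a random direction is used.
#'
#' @param cloud a [point_cloud()]
#' @param n_outliers count
#' @param scale displacement scale (mm); displacements are drawn from
#'   `[scale, 2 scale]`
#' @param seed RNG seed
#' @return list: `cloud` with outliers appended, `outlier_idx`
#' @export
plant_outliers <- function(cloud, n_outliers = 50L, scale = 1, seed = 1L) {
  set.seed(seed)
  idx <- sample.int(nrow(cloud$points), n_outliers)
  dirs <- if (!is.null(cloud$normals)) {
    cloud$normals[idx, , drop = FALSE]
  } else {
    normalize_rows(matrix(stats::rnorm(3 * n_outliers), ncol = 3))
  }
  out_pts <- cloud$points[idx, , drop = FALSE] +
    dirs * stats::runif(n_outliers, scale, 2 * scale)
  pts <- rbind(cloud$points, out_pts)
  list(cloud = point_cloud(pts),
       outlier_idx = nrow(cloud$points) + seq_len(n_outliers))
}
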