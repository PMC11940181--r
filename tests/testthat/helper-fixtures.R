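# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

default_bone <- function() fixture("bone", function() gen_bone())

default_hand <- function() fixture("hand", function() {
  gs <- gen_skeleton()
  build_skeleton(gs$bones, gs$joints)
})

default_bundle <- function() fixture("bundle", function()
  gen_trajectories(default_hand()))

default_molar <- function() fixture("molar", function()
  gen_occlusal(preset = "molar", seed = 42))

molar_regions <- function() fixture("molar_regions", function() {
  occ <- default_molar()
  field <- suppressWarnings(estimate_principal_curvatures(occ$mesh, ring = 2))
  list(occ = occ, field = field,
       regions = segment_regions(occ$mesh, field, scheme = "hk"))
})

# independent naive point-to-triangle distance (projection + edge clamping),
# used as the exhaustive oracle against the vectorised implementation
naive_point_tri_dist <- function(q, a, b, c3) {
  ab <- b - a; ac <- c3 - a; n <- c(ab[2] * ac[3] - ab[3] * ac[2],
                                    ab[3] * ac[1] - ab[1] * ac[3],
                                    ab[1] * ac[2] - ab[2] * ac[1])
  n2 <- sum(n^2)
  best <- Inf
  if (n2 > 0) {
    # barycentric coordinates of the in-plane projection
    w <- q - a
    d00 <- sum(ab * ab); d01 <- sum(ab * ac); d11 <- sum(ac * ac)
    d20 <- sum(w * ab); d21 <- sum(w * ac)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    u <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && u >= 0 && v + u <= 1) {
      p <- a + v * ab + u * ac
      best <- sqrt(sum((q - p)^2))
    }
  }
  for (e in list(list(a, b), list(b, c3), list(c3, a))) {
    d <- e[[2]] - e[[1]]
    t0 <- sum((q - e[[1]]) * d) / sum(d * d)
    t0 <- min(max(t0, 0), 1)
    p <- e[[1]] + t0 * d
    best <- min(best, sqrt(sum((q - p)^2)))
  }
  best
}

naive_mesh_dist <- function(q, mesh) {
  f <- mesh$faces; v <- mesh$vertices
  min(vapply(seq_len(nrow(f)), function(i)
    naive_point_tri_dist(q, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]), 0))
}

# independent de Boor evaluation of a clamped B-spline curve
deboor_eval <- function(knots, control, degree, u) {
  n <- nrow(control)
  # find knot span
  if (u >= knots[n + 1]) return(control[n, ])
  k <- findInterval(u, knots, rightmost.closed = FALSE)
  k <- min(max(k, degree + 1), n)
  d <- control[(k - degree):k, , drop = FALSE]
  for (r in seq_len(degree)) {
    for (j in seq(degree, r, by = -1)) {
      i <- k - degree + j
      den <- knots[i + degree - r + 1] - knots[i]
      alpha <- if (den == 0) 0 else (u - knots[i]) / den
      d[j + 1, ] <- (1 - alpha) * d[j, ] + alpha * d[j + 1, ]
    }
  }
  d[degree + 1, ]
}

cross3_test <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# closed-form response of I th'' + c th' + k th = tau (theta0 = 0 start, at rest)
damped_step_response <- function(t, I, c, k, tau) {
  wn <- sqrt(k / I); z <- c / (2 * sqrt(k * I)); ss <- tau / k
  if (z < 1) {
    wd <- wn * sqrt(1 - z^2)
    ss * (1 - exp(-z * wn * t) * (cos(wd * t) + z * wn / wd * sin(wd * t)))
  } else if (z == 1) {
    ss * (1 - exp(-wn * t) * (1 + wn * t))
  } else {
    r1 <- -wn * (z - sqrt(z^2 - 1)); r2 <- -wn * (z + sqrt(z^2 - 1))
    ss * (1 - (r2 * exp(r1 * t) - r1 * exp(r2 * t)) / (r2 - r1))
  }
}
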