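#' Primitive meshes
#'
#' Analytic test surfaces used throughout the toolkit's validation suite:
#' axis-aligned box, icosphere, capped cylinder, planar grid, saddle patch,
#' and a lathed surface of revolution.
#'
#' @param dims box edge lengths (mm)
#' @param center centre of the solid
#' @param n per-edge vertex count where applicable
#' @return a `rebiom_mesh`
#' @name primitives
NULL

#' @rdname primitives
#' @export
mesh_box <- function(dims = c(1, 1, 1), center = c(0, 0, 0), n = 2L) {
  g <- seq(-0.5, 0.5, length.out = n)
  verts <- NULL; faces <- NULL
  add_face_grid <- function(pts, nu, nv, flip = FALSE) {
    base <- nrow(verts %||% matrix(0, 0, 3))
    verts <<- rbind(verts, pts)
    for (i in seq_len(nu - 1)) for (j in seq_len(nv - 1)) {
      a <- base + (j - 1) * nu + i
      b <- a + 1; c3 <- a + nu; d <- c3 + 1
      tri <- if (!flip) rbind(c(a, b, d), c(a, d, c3))
             else rbind(c(a, d, b), c(a, c3, d))
      faces <<- rbind(faces, tri)
    }
  }
  gg <- expand.grid(u = g, v = g)
  add_face_grid(cbind(0.5, gg$u, gg$v), n, n, flip = FALSE)
  add_face_grid(cbind(-0.5, gg$u, gg$v), n, n, flip = TRUE)
  add_face_grid(cbind(gg$u, 0.5, gg$v), n, n, flip = TRUE)
  add_face_grid(cbind(gg$u, -0.5, gg$v), n, n, flip = FALSE)
  add_face_grid(cbind(gg$u, gg$v, 0.5), n, n, flip = FALSE)
  add_face_grid(cbind(gg$u, gg$v, -0.5), n, n, flip = TRUE)
  verts <- sweep(verts %*% diag(dims), 2, center, "+")
  repair_mesh(triangle_mesh(verts, faces, check = FALSE), tol = 1e-9 * max(dims))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param radius sphere radius (mm)
#' @param subdiv icosahedron subdivision depth
#' @rdname primitives
#' @export
mesh_icosphere <- function(radius = 1, subdiv = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    nv <- nrow(v)
    newf <- matrix(0L, 0, 3)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, normalize_rows(matrix((v[a, ] + v[b, ]) / 2, 1)))
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  triangle_mesh(sweep(v * radius, 2, center, "+"), f, check = FALSE)
}

#' @param length cylinder length along +y (mm)
#' @param n_seg circumferential segments
#' @param n_axial axial segments
#' @rdname primitives
#' @export
mesh_cylinder <- function(radius = 1, length = 2, n_seg = 32L, n_axial = 16L,
                          center = c(0, 0, 0)) {
  th <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  ys <- seq(-length / 2, length / 2, length.out = n_axial + 1)
  verts <- do.call(rbind, lapply(ys, function(y)
    cbind(radius * cos(th), y, radius * sin(th))))
  faces <- NULL
  for (r in seq_len(n_axial)) {
    base <- (r - 1) * n_seg
    for (i in seq_len(n_seg)) {
      j <- if (i == n_seg) 1L else i + 1L
      a <- base + i; b <- base + j; c3 <- base + n_seg + i; d <- base + n_seg + j
      faces <- rbind(faces, c(a, c3, b), c(b, c3, d))
    }
  }
  # cap centres
  v_bot <- nrow(verts) + 1L; v_top <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, -length / 2, 0), c(0, length / 2, 0))
  top_base <- n_axial * n_seg
  for (i in seq_len(n_seg)) {
    j <- if (i == n_seg) 1L else i + 1L
    faces <- rbind(faces, c(v_bot, i, j), c(v_top, top_base + j, top_base + i))
  }
  m <- triangle_mesh(sweep(verts, 2, center, "+"), faces, check = FALSE)
  if (mesh_signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m$normals <- vertex_normals(m)
  m
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  sum(rowSums(v[f[, 1], , drop = FALSE] *
                cross3(v[f[, 2], , drop = FALSE], v[f[, 3], , drop = FALSE]))) / 6
}

#' @param nx,ny grid vertex counts
#' @param size grid side lengths (mm), length-2
#' @param height optional function `f(x, y)` returning z (height field)
#' @rdname primitives
#' @export
mesh_grid <- function(nx = 30L, ny = 30L, size = c(10, 10), height = NULL) {
  xs <- seq(-size[1] / 2, size[1] / 2, length.out = nx)
  ys <- seq(-size[2] / 2, size[2] / 2, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  z <- if (is.null(height)) rep(0, nrow(g)) else height(g$x, g$y)
  verts <- cbind(g$x, g$y, z)
  faces <- NULL
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    a <- (j - 1) * nx + i; b <- a + 1; c3 <- a + nx; d <- c3 + 1
    faces <- rbind(faces, c(a, b, d), c(a, d, c3))
  }
  triangle_mesh(verts, faces, check = FALSE)
}

#' @param profile function `r(t)` giving the lathe radius at axial station t
#' @param t_range axial range (mm), lathe axis is +y
#' @param n_axial,n_seg resolution
#' @param exponent superellipse exponent of the cross-section (2 = circular)
#' @rdname primitives
#' @export
mesh_lathe <- function(profile, t_range = c(0, 1), n_axial = 60L, n_seg = 32L,
                       exponent = 2) {
  ts <- seq(t_range[1], t_range[2], length.out = n_axial + 2)
  ts_in <- ts[2:(n_axial + 1)]
  th <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  e <- 2 / exponent
  cx <- sign(cos(th)) * abs(cos(th))^e
  cz <- sign(sin(th)) * abs(sin(th))^e
  verts <- do.call(rbind, lapply(ts_in, function(t) {
    r <- profile(t)
    cbind(r * cx, t, r * cz)
  }))
  faces <- NULL
  for (r in seq_len(n_axial - 1)) {
    base <- (r - 1) * n_seg
    for (i in seq_len(n_seg)) {
      j <- if (i == n_seg) 1L else i + 1L
      a <- base + i; b <- base + j; c3 <- base + n_seg + i; d <- base + n_seg + j
      faces <- rbind(faces, c(a, b, c3), c(b, d, c3))
    }
  }
  v_bot <- nrow(verts) + 1L; v_top <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, t_range[1], 0), c(0, t_range[2], 0))
  top_base <- (n_axial - 1) * n_seg
  for (i in seq_len(n_seg)) {
    j <- if (i == n_seg) 1L else i + 1L
    faces <- rbind(faces, c(v_bot, j, i), c(v_top, top_base + i, top_base + j))
  }
  m <- triangle_mesh(verts, faces, check = FALSE)
  if (mesh_signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m$normals <- vertex_normals(m)
  m
}

#' Uniform area-weighted surface sampling
#' @param mesh a `rebiom_mesh`
#' @param n number of samples
#' @return [point_cloud()] with normals (face normals at the samples)
#' @export
sample_surface <- function(mesh, n) {
  fa <- face_areas(mesh$vertices, mesh$faces)
  pick <- sample.int(length(fa), n, replace = TRUE, prob = fa)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w0 <- 1 - r1; w1 <- r1 * (1 - r2); w2 <- r1 * r2
  f <- mesh$faces[pick, , drop = FALSE]
  v <- mesh$vertices
  pts <- v[f[, 1], , drop = FALSE] * w0 + v[f[, 2], , drop = FALSE] * w1 +
    v[f[, 3], , drop = FALSE] * w2
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  point_cloud(pts, normals = normalize_rows(cross3(e1, e2)))
}
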