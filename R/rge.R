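#' Referential geometric frame of a bone
#'
#' The centroid is the solid centre of gravity from [mass_properties()] and
#' the axes are the eigenvectors of the solid inertia tensor, ordered by
#' descending spatial extent of the shape along each axis (so flat, wide
#' bones still receive a stable primary axis).  For open meshes the vertex
#' mean and vertex covariance are used instead, with a warning.
#'
#' Sign rule: each axis is flipped so the vertex with the largest absolute
#' projection has positive projection; the tertiary axis is then recomputed
#' as primary x secondary to keep the triple right-handed.
#'
#' @param mesh a `rebiom_mesh`
#' @return object of class `rebiom_frame`: `centroid`, `axes` (3x3, rows =
#'   primary/secondary/tertiary), `extents` (mm along each axis), `planes`
#'   (list of point+normal pairs), `degenerate` (logical), `solid` (logical)
#' @export
rge_frame <- function(mesh) {
  stopifnot(is_mesh(mesh))
  wt <- watertight_check(mesh)
  if (wt$watertight) {
    mp <- mass_properties(mesh)
    centroid <- mp$centroid
    M <- mp$inertia
    ax <- eigen(M, symmetric = TRUE)$vectors
    solid <- TRUE
  } else {
    warning("mesh not watertight; falling back to vertex mean/covariance frame")
    centroid <- colMeans(mesh$vertices)
    M <- stats::cov(mesh$vertices)
    ax <- eigen(M, symmetric = TRUE)$vectors
    solid <- FALSE
  }
  rel <- sweep(mesh$vertices, 2, centroid)
  proj <- rel %*% ax                     # columns = axis projections
  ext <- apply(proj, 2, function(p) max(p) - min(p))
  ord <- order(ext, decreasing = TRUE)
  ax <- ax[, ord, drop = FALSE]
  proj <- proj[, ord, drop = FALSE]
  ext <- ext[ord]
  for (k in 1:3) {
    far <- which.max(abs(proj[, k]))
    if (proj[far, k] < 0) { ax[, k] <- -ax[, k]; proj[, k] <- -proj[, k] }
  }
  ax[, 3] <- c(ax[2, 1] * ax[3, 2] - ax[3, 1] * ax[2, 2],
               ax[3, 1] * ax[1, 2] - ax[1, 1] * ax[3, 2],
               ax[1, 1] * ax[2, 2] - ax[2, 1] * ax[1, 2])
  degenerate <- (ext[1] - ext[3]) / max(ext[1], 1e-12) < 1e-3
  axes <- t(ax)                           # rows: primary, secondary, tertiary
  rownames(axes) <- c("primary", "secondary", "tertiary")
  planes <- lapply(1:3, function(k) list(point = centroid, normal = axes[k, ]))
  names(planes) <- rownames(axes)
  structure(list(centroid = centroid, axes = axes, extents = ext,
                 planes = planes, degenerate = degenerate, solid = solid),
            class = "rebiom_frame")
}

#' @export
print.rebiom_frame <- function(x, ...) {
  cat(sprintf("<RGE frame: centroid (%.2f, %.2f, %.2f) mm, extents %.1f/%.1f/%.1f mm%s>\n",
              x$centroid[1], x$centroid[2], x$centroid[3],
              x$extents[1], x$extents[2], x$extents[3],
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Landmark-based canonical alignment
#'
#' Computes the rigid transform taking the first landmark to the origin, the
#' second onto the +x axis, and the third into the xy-plane (positive y) --
#' the three-landmark generalisation of anatomical reference-plane alignment
#' (basion/nasion/sella-style conventions reduce to a naming of L1-L3).
#'
#' @param landmarks 3x3 numeric matrix (rows = landmarks) or named list of
#'   3-vectors; order defines the convention
#' @param convention optional character name recorded on the result
#' @return 4x4 homogeneous rigid transform (attribute `convention`)
#' @export
landmark_align <- function(landmarks, convention = "L1-origin/L2-x/L3-xy") {
  L <- if (is.list(landmarks)) do.call(rbind, landmarks) else as_xyz(landmarks)
  if (nrow(L) < 3) stop("need at least 3 landmarks")
  u <- L[2, ] - L[1, ]
  w <- L[3, ] - L[1, ]
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  sine <- sqrt(sum(cr^2)) / (nu * nw)
  if (!is.finite(sine) || sine < 1e-9)
    stop(sprintf("landmarks are collinear (collinearity measure %.3g)", sine))
  ex <- u / nu
  ez <- cr / sqrt(sum(cr^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2], ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  R <- rbind(ex, ey, ez)                 # world -> canonical rotation
  t <- -as.vector(R %*% L[1, ])
  T <- rigid_transform(R, t)
  dimnames(T) <- NULL
  attr(T, "convention") <- convention
  T
}

#' Transverse cross-sections along the primary axis
#'
#' Cuts the mesh with `n_stations` planes perpendicular to the frame's
#' primary axis, equally spaced across the axial extent.  Each section is the
#' largest closed polyline of the mesh-plane intersection with its area
#' (planar shoelace) and perimeter; stations that miss the mesh are skipped
#' and recorded.
#'
#' @param mesh a `rebiom_mesh`
#' @param frame a [rge_frame()]
#' @param n_stations number of stations (>= 2)
#' @return list of class `rebiom_sections`: `stations` (axial positions, mm),
#'   `sections` (list of `polyline` (3D), `area`, `perimeter`), `skipped`
#' @export
cross_sections <- function(mesh, frame, n_stations = 20L) {
  stopifnot(n_stations >= 2)
  axis <- frame$axes["primary", ]
  d <- as.vector(mesh$vertices %*% axis)
  lo <- min(d); hi <- max(d)
  span <- hi - lo
  stations <- seq(lo + 1e-6 * span, hi - 1e-6 * span, length.out = n_stations)
  secs <- vector("list", n_stations)
  skipped <- integer(0)
  for (s in seq_len(n_stations)) {
    loops <- mesh_plane_loops(mesh, axis, stations[s], d)
    if (length(loops) == 0) { skipped <- c(skipped, s); next }
    areas <- vapply(loops, function(L) L$area, 0)
    best <- loops[[which.max(areas)]]
    secs[[s]] <- best
  }
  structure(list(stations = stations, sections = secs, skipped = skipped,
                 axis = axis),
            class = "rebiom_sections")
}

# Intersect mesh with the plane axis . x = level; return closed loops with
# area and perimeter.  `d` are precomputed vertex projections.
mesh_plane_loops <- function(mesh, axis, level, d = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  if (is.null(d)) d <- as.vector(v %*% axis)
  s <- d - level
  s1 <- s[f[, 1]]; s2 <- s[f[, 2]]; s3 <- s[f[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossing)) return(list())
  ff <- f[crossing, , drop = FALSE]
  segs <- vector("list", nrow(ff))
  for (i in seq_len(nrow(ff))) {
    tri <- ff[i, ]
    sv <- s[tri]
    pts <- matrix(0, 0, 3)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- sv[e[1]]; b <- sv[e[2]]
      if ((a < 0 && b > 0) || (a > 0 && b < 0)) {
        t0 <- a / (a - b)
        pts <- rbind(pts, v[tri[e[1]], ] + t0 * (v[tri[e[2]], ] - v[tri[e[1]], ]))
      } else if (a == 0) {
        pts <- rbind(pts, v[tri[e[1]], ])
      }
    }
    if (nrow(pts) >= 2) segs[[i]] <- pts[1:2, ]
  }
  segs <- segs[!vapply(segs, is.null, TRUE)]
  if (length(segs) == 0) return(list())
  chain_loops(segs, axis)
}

# Chain unordered 3D segments into closed loops; compute planar area/perimeter.
chain_loops <- function(segs, axis) {
  ends <- do.call(rbind, lapply(segs, function(s) s))
  key <- apply(round(ends / 1e-7), 1, paste, collapse = ",")
  nseg <- length(segs)
  k1 <- key[seq(1, 2 * nseg, by = 2)]
  k2 <- key[seq(2, 2 * nseg, by = 2)]
  used <- logical(nseg)
  loops <- list()
  # basis in the section plane for shoelace
  b1 <- c(1, 0, 0)
  if (abs(axis[1]) > 0.9) b1 <- c(0, 1, 0)
  b1 <- b1 - sum(b1 * axis) * axis; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(axis[2] * b1[3] - axis[3] * b1[2], axis[3] * b1[1] - axis[1] * b1[3],
          axis[1] * b1[2] - axis[2] * b1[1])
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- segs[[start]]
    head_key <- k1[start]; tail_key <- k2[start]
    poly <- pts
    repeat {
      nxt <- which(!used & (k1 == tail_key | k2 == tail_key))
      if (length(nxt) == 0) break
      j <- nxt[1]
      used[j] <- TRUE
      if (k1[j] == tail_key) { poly <- rbind(poly, segs[[j]][2, ]); tail_key <- k2[j] }
      else { poly <- rbind(poly, segs[[j]][1, ]); tail_key <- k1[j] }
      if (tail_key == head_key) break
    }
    closed <- tail_key == head_key && nrow(poly) >= 3
    if (!closed) next
    xy <- cbind(poly %*% b1, poly %*% b2)
    n <- nrow(xy)
    area <- abs(sum(xy[, 1] * xy[c(2:n, 1), 2] - xy[c(2:n, 1), 1] * xy[, 2])) / 2
    per <- sum(sqrt(rowSums((poly[c(2:n, 1), ] - poly)^2)))
    if (area > 0)
      loops[[length(loops) + 1]] <- list(polyline = poly, area = area,
                                         perimeter = per)
  }
  loops
}

#' Joint centre-of-rotation fit
#'
#' Sphere mode: algebraic least-squares sphere fit refined by Gauss-Newton
#' geometric least squares -- the construction used for condylar heads of
#' two-axis joints.  Circle mode: the points are projected onto their
#' best-fit plane and a circle fitted there (Kasa algebraic seed + geometric
#' refinement) -- the single-plane condylar-profile construction used for
#' hinge joints.
#'
#' When the supplied region extends beyond the articular surface (e.g. a
#' head partition that includes part of the neck), `trim` discards that
#' fraction of worst-fitting points over a few refit rounds, a standard
#' robustification that isolates the condylar cap.
#'
#' @param x a [point_cloud()], point matrix, or `rebiom_mesh` (vertices used)
#' @param model `"sphere"` or `"circle"`
#' @param trim fraction of worst-fitting points to discard iteratively
#'   (default 0, plain least squares)
#' @param trim_rounds refit rounds used when `trim > 0`
#' @return object of class `rebiom_cor`: `center` (mm), `radius` (mm),
#'   `residual` (rms, mm), `model`; circle mode adds `normal`
#' @export
fit_cor <- function(x, model = c("sphere", "circle"), trim = 0,
                    trim_rounds = 3L) {
  model <- match.arg(model)
  p <- if (is_cloud(x)) x$points else if (is_mesh(x)) x$vertices else as_xyz(x)
  if (trim > 0) {
    stopifnot(trim < 1)
    keep_frac <- (1 - trim)^(1 / trim_rounds)
    for (round in seq_len(trim_rounds)) {
      fit <- fit_cor(p, model = model, trim = 0)
      r <- abs(sqrt(rowSums(sweep(p, 2, fit$center)^2)) - fit$radius)
      n_keep <- max(if (model == "sphere") 4L else 3L,
                    floor(keep_frac * nrow(p)))
      p <- p[order(r)[seq_len(n_keep)], , drop = FALSE]
    }
    return(fit_cor(p, model = model, trim = 0))
  }
  if (model == "sphere") {
    if (nrow(p) < 4) stop("sphere fit needs at least 4 points")
    ctr <- sweep(p, 2, colMeans(p))
    sv <- svd(ctr)$d
    if (sv[3] < 1e-9 * max(sv[1], 1e-12))
      stop("points are coplanar; use model = \"circle\"")
    # algebraic: |p|^2 = 2 c.p + (r^2 - |c|^2)
    A <- cbind(2 * p, 1)
    b <- rowSums(p^2)
    sol <- qr.solve(A, b)
    center <- sol[1:3]
    radius <- sqrt(sol[4] + sum(center^2))
    res <- refine_sphere(p, center, radius)
    structure(list(center = res$center, radius = res$radius,
                   residual = res$rms, model = "sphere"),
              class = "rebiom_cor")
  } else {
    if (nrow(p) < 3) stop("circle fit needs at least 3 points")
    mu <- colMeans(p)
    ctr <- sweep(p, 2, mu)
    sv <- svd(ctr)
    nrm <- sv$v[, 3]
    uv <- ctr %*% sv$v[, 1:2]
    # Kasa: u^2 + v^2 = 2a u + 2b v + c
    A <- cbind(2 * uv, 1)
    b <- rowSums(uv^2)
    sol <- qr.solve(A, b)
    cen2 <- sol[1:2]
    radius <- sqrt(sol[3] + sum(cen2^2))
    gn <- refine_circle(uv, cen2, radius)
    center <- mu + as.vector(sv$v[, 1:2] %*% gn$center)
    structure(list(center = center, radius = gn$radius, residual = gn$rms,
                   normal = as.vector(nrm), model = "circle"),
              class = "rebiom_cor")
  }
}

#' @export
print.rebiom_cor <- function(x, ...) {
  cat(sprintf("<COR (%s): center (%.3f, %.3f, %.3f) mm, radius %.3f mm, rms %.2e mm>\n",
              x$model, x$center[1], x$center[2], x$center[3], x$radius,
              x$residual))
  invisible(x)
}

refine_sphere <- function(p, center, radius, iters = 30) {
  for (it in seq_len(iters)) {
    diff <- sweep(p, 2, center)
    dist <- sqrt(rowSums(diff^2))
    r <- dist - radius
    J <- cbind(-diff / dist, -1)
    step <- tryCatch(qr.solve(J, -r), error = function(e) rep(0, 4))
    center <- center + step[1:3]
    radius <- radius + step[4]
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  diff <- sweep(p, 2, center)
  r <- sqrt(rowSums(diff^2)) - radius
  list(center = center, radius = radius, rms = sqrt(mean(r^2)))
}

refine_circle <- function(uv, center, radius, iters = 30) {
  for (it in seq_len(iters)) {
    diff <- sweep(uv, 2, center)
    dist <- sqrt(rowSums(diff^2))
    r <- dist - radius
    J <- cbind(-diff / dist, -1)
    step <- tryCatch(qr.solve(J, -r), error = function(e) rep(0, 3))
    center <- center + step[1:2]
    radius <- radius + step[3]
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  diff <- sweep(uv, 2, center)
  r <- sqrt(rowSums(diff^2)) - radius
  list(center = center, radius = radius, rms = sqrt(mean(r^2)))
}
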