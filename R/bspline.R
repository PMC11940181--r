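#' Least-squares B-spline curve fit
#'
#' Fits a clamped cubic (by default) B-spline to an ordered polyline by
#' linear least squares with chord-length parameterisation; the endpoints are
#' interpolated exactly by pinning the first and last control points.
#'
#' @param points ordered polyline (matrix, one row per point, any dimension)
#' @param n_control number of control points (>= degree + 1)
#' @param degree spline degree (default 3, cubic)
#' @return object of class `rebiom_bcurve`: `degree`, `knots`, `control`
#'   (matrix), `params` (chord-length parameters of the input), `max_dev`,
#'   `mean_dev` (deviation at the fit parameters, mm)
#' @export
fit_bspline_curve <- function(points, n_control = 12L, degree = 3L) {
  p <- as.matrix(points)
  m <- nrow(p)
  if (m < degree + 1)
    stop("need at least degree + 1 = ", degree + 1, " points")
  n_control <- max(degree + 1L, min(as.integer(n_control), m))
  u <- chord_params(p)
  kn <- clamped_knots(n_control, degree)
  B <- splines::splineDesign(kn, u, ord = degree + 1, outer.ok = FALSE)
  ctrl <- matrix(0, n_control, ncol(p))
  ctrl[1, ] <- p[1, ]
  ctrl[n_control, ] <- p[m, ]
  if (n_control > 2) {
    rhs <- p - outer(B[, 1], p[1, ]) - outer(B[, n_control], p[m, ])
    Bi <- B[, 2:(n_control - 1), drop = FALSE]
    ctrl[2:(n_control - 1), ] <- qr.solve(crossprod(Bi), crossprod(Bi, rhs))
  }
  fit <- B %*% ctrl
  dev <- sqrt(rowSums((fit - p)^2))
  structure(list(degree = degree, knots = kn, control = ctrl, params = u,
                 max_dev = max(dev), mean_dev = mean(dev)),
            class = "rebiom_bcurve")
}

chord_params <- function(p) {
  d <- c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                   p[-nrow(p), , drop = FALSE])^2))))
  if (d[length(d)] == 0) return(seq(0, 1, length.out = nrow(p)))
  d / d[length(d)]
}

clamped_knots <- function(n_control, degree) {
  n_int <- n_control - degree - 1L
  c(rep(0, degree + 1),
    if (n_int > 0) seq_len(n_int) / (n_int + 1),
    rep(1, degree + 1))
}

#' Evaluate a fitted B-spline curve
#' @param curve a `rebiom_bcurve`
#' @param u parameter values in `[0, 1]`
#' @return matrix of curve points
#' @export
eval_bspline_curve <- function(curve, u) {
  B <- splines::splineDesign(curve$knots, pmin(pmax(u, 0), 1),
                             ord = curve$degree + 1)
  B %*% curve$control
}

#' Fit a B-spline curve network
#'
#' Fits one least-squares B-spline per polyline (region boundary loops,
#' cross-section profiles), the curve scaffold used for feature extraction
#' and surface modelling.
#'
#' @param polylines list of point matrices
#' @param n_control control points per curve
#' @param degree spline degree
#' @return list of `rebiom_bcurve` objects
#' @export
fit_curve_network <- function(polylines, n_control = 12L, degree = 3L) {
  if (is.matrix(polylines)) polylines <- list(polylines)
  lapply(polylines, fit_bspline_curve, n_control = n_control, degree = degree)
}

#' Penalised least-squares B-spline surface fit
#'
#' Fits a clamped tensor-product B-spline surface to scattered region points.
#' The region is parameterised by projection onto its two principal
#' directions (a height-field assumption); the objective is the data misfit
#' plus `lambda` times a thin-plate-style second-difference penalty on the
#' control net (fairing).  `lambda` is dimensionless under uniform scaling of
#' the coordinates.
#'
#' @param points region points (matrix, mm)
#' @param n_u,n_v control-net size (default 8x8)
#' @param degree degree in both directions (default 3)
#' @param lambda smoothing weight (default 1e-3); `0` requires the data to
#'   determine every control point
#' @param report_grid dense resampling grid per side for the fit report
#' @return list: `surface` (class `rebiom_bsurface`: degrees, knots, control
#'   net as an `n_u x n_v x 3` array, parameter frame) and `report` (class
#'   `rebiom_fitreport`: `max_dev`, `mean_dev`, `n_control`, `lambda`)
#' @export
fit_surface <- function(points, n_u = 8L, n_v = 8L, degree = 3L,
                        lambda = 1e-3, report_grid = 40L) {
  p <- as_xyz(points)
  if (nrow(p) < n_u * n_v && lambda == 0)
    stop("fewer points than control points; increase lambda or shrink the net")
  mu <- colMeans(p)
  ctr <- sweep(p, 2, mu)
  sv <- svd(ctr)
  basis <- sv$v                          # principal directions of the region
  uvw <- ctr %*% basis
  rng_u <- range(uvw[, 1]); rng_v <- range(uvw[, 2])
  un <- (uvw[, 1] - rng_u[1]) / diff(rng_u)
  vn <- (uvw[, 2] - rng_v[1]) / diff(rng_v)
  ku <- clamped_knots(n_u, degree); kv <- clamped_knots(n_v, degree)
  Bu <- splines::splineDesign(ku, un, ord = degree + 1)
  Bv <- splines::splineDesign(kv, vn, ord = degree + 1)
  # row-wise khatri-rao: design over the vectorised control net (u-major)
  B <- matrix(0, nrow(p), n_u * n_v)
  for (j in seq_len(n_v))
    B[, (j - 1) * n_u + seq_len(n_u)] <- Bu * Bv[, j]
  D2 <- function(n) {
    if (n < 3) return(matrix(0, 0, n))
    D <- matrix(0, n - 2, n)
    for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
    D
  }
  Pu <- kronecker(diag(n_v), D2(n_u))
  Pv <- kronecker(D2(n_v), diag(n_u))
  A <- crossprod(B) + lambda * (crossprod(Pu) + crossprod(Pv))
  qrA <- qr(A)
  if (qrA$rank < ncol(A))
    stop("rank-deficient fitting system; increase lambda (> 0) or use fewer ",
         "control points")
  ctrl <- solve(qrA, crossprod(B, p))
  net <- array(ctrl, dim = c(n_u, n_v, 3))
  surface <- structure(list(degree = c(degree, degree),
                            knots_u = ku, knots_v = kv, control = net,
                            origin = mu, basis = basis,
                            range_u = rng_u, range_v = rng_v),
                       class = "rebiom_bsurface")
  # report: distance from each data point to a dense surface sampling
  gs <- seq(0, 1, length.out = report_grid)
  samp <- eval_bspline_surface(surface, rep(gs, times = report_grid),
                               rep(gs, each = report_grid))
  dev <- nearest_dist(p, samp)
  # exact residual at the fit parameters is an upper bound refinement
  at_par <- sqrt(rowSums((B %*% ctrl - p)^2))
  dev <- pmin(dev, at_par)
  report <- structure(list(max_dev = max(dev), mean_dev = mean(dev),
                           n_control = n_u * n_v, lambda = lambda),
                      class = "rebiom_fitreport")
  list(surface = surface, report = report)
}

nearest_dist <- function(a, b) {
  n <- nrow(a)
  out <- numeric(n)
  bsq <- rowSums(b^2)
  block <- max(1L, floor(2e6 / nrow(b)))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + block - 1L)
    d2 <- outer(rowSums(a[i:j, , drop = FALSE]^2), bsq, "+") -
      2 * a[i:j, , drop = FALSE] %*% t(b)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

#' @export
print.rebiom_fitreport <- function(x, ...) {
  cat(sprintf("<surface fit: %d controls, lambda %.3g, max dev %.4g mm, mean %.4g mm>\n",
              x$n_control, x$lambda, x$max_dev, x$mean_dev))
  invisible(x)
}

#' Evaluate a fitted B-spline surface
#' @param surface a `rebiom_bsurface`
#' @param u,v parameter vectors in `[0, 1]` (recycled to equal length)
#' @return matrix of 3D surface points
#' @export
eval_bspline_surface <- function(surface, u, v) {
  n <- max(length(u), length(v))
  u <- rep_len(pmin(pmax(u, 0), 1), n)
  v <- rep_len(pmin(pmax(v, 0), 1), n)
  d <- surface$degree
  Bu <- splines::splineDesign(surface$knots_u, u, ord = d[1] + 1)
  Bv <- splines::splineDesign(surface$knots_v, v, ord = d[2] + 1)
  nu <- dim(surface$control)[1]; nv <- dim(surface$control)[2]
  out <- matrix(0, n, 3)
  for (k in 1:3) {
    Ck <- surface$control[, , k]
    out[, k] <- rowSums((Bu %*% Ck) * Bv)
  }
  out
}

#' Boundary curves of a surface patch
#' @param surface a `rebiom_bsurface`
#' @param n samples per edge
#' @return list of four point matrices (u0, u1, v0, v1 edges)
#' @export
surface_boundaries <- function(surface, n = 50L) {
  g <- seq(0, 1, length.out = n)
  list(u0 = eval_bspline_surface(surface, rep(0, n), g),
       u1 = eval_bspline_surface(surface, rep(1, n), g),
       v0 = eval_bspline_surface(surface, g, rep(0, n)),
       v1 = eval_bspline_surface(surface, g, rep(1, n)))
}

#' Stitch validation across fitted patches
#'
#' Samples the boundary curves of every patch, pairs each boundary with the
#' closest boundary of any other patch (adjacency = best-matching edge within
#' a quarter of the assembly diagonal), and reports the largest one-sided
#' gap.  Pass iff the maximum gap does not exceed `tol`.  Report-only; no
#' error is raised for failing assemblies.
#'
#' @param surfaces list of `rebiom_bsurface` patches
#' @param tol gap tolerance in mm
#' @param n samples per boundary edge
#' @return list: `max_gap` (mm), `pass`, `pairs` (data.frame of matched
#'   boundaries and gaps)
#' @export
stitch_and_validate <- function(surfaces, tol = 1e-3, n = 50L) {
  stopifnot(length(surfaces) >= 2)
  bnd <- lapply(surfaces, surface_boundaries, n = n)
  allp <- do.call(rbind, lapply(bnd, function(b) do.call(rbind, b)))
  diag_len <- sqrt(sum((apply(allp, 2, max) - apply(allp, 2, min))^2))
  couple <- 0.25 * diag_len
  rows <- NULL
  max_gap <- 0
  for (i in seq_along(surfaces)) for (ei in names(bnd[[i]])) {
    a <- bnd[[i]][[ei]]
    best <- NULL
    for (j in seq_along(surfaces)) {
      if (j == i) next
      for (ej in names(bnd[[j]])) {
        g <- max(nearest_dist(a, bnd[[j]][[ej]]))
        if (is.null(best) || g < best$gap)
          best <- list(j = j, edge = ej, gap = g)
      }
    }
    if (!is.null(best) && best$gap < couple) {
      rows <- rbind(rows, data.frame(patch = i, edge = ei,
                                     other = best$j, other_edge = best$edge,
                                     gap = best$gap))
      max_gap <- max(max_gap, best$gap)
    }
  }
  list(max_gap = max_gap, pass = max_gap <= tol,
       pairs = if (is.null(rows)) data.frame() else rows)
}

#' Serialise / restore a B-spline surface as JSON
#' @param surface a `rebiom_bsurface`
#' @param path output file
#' @return `path` (write) or `rebiom_bsurface` (read)
#' @export
write_bsurface_json <- function(surface, path) {
  obj <- list(degree = surface$degree, knots_u = surface$knots_u,
              knots_v = surface$knots_v,
              control = as.vector(surface$control),
              dim = dim(surface$control),
              origin = surface$origin, basis = as.vector(surface$basis),
              range_u = surface$range_u, range_v = surface$range_v)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_bsurface_json
#' @export
read_bsurface_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(degree = obj$degree, knots_u = obj$knots_u,
                 knots_v = obj$knots_v,
                 control = array(obj$control, dim = obj$dim),
                 origin = obj$origin,
                 basis = matrix(obj$basis, 3, 3),
                 range_u = obj$range_u, range_v = obj$range_v),
            class = "rebiom_bsurface")
}
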