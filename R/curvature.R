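#' Per-vertex principal curvature estimation
#'
#' Fits an osculating paraboloid `z = a x^2 + b xy + c y^2 + d x + e y` over
#' the `ring`-neighbourhood of every vertex in the local tangent frame spanned
#' by the vertex normal, then eigen-decomposes the shape operator of the graph
#' to obtain the principal curvatures `k1 >= k2`.
#'
#' Sign convention: a region bulging along the outward normal (convex) has
#' `k1, k2 < 0`, so `H < 0` marks convexity, matching the HK classification
#' rows.  Vertices with fewer than five usable neighbours are flagged
#' undefined (`NA`) with a warning.
#'
#' @param mesh a `rebiom_mesh` with consistent outward normals
#' @param ring neighbourhood ring depth (>= 1, default 2)
#' @return object of class `rebiom_curvature`: per-vertex `k1`, `k2`, `H`
#'   (1/mm), `K` (1/mm^2), `S` (dimensionless), `C` (1/mm), and `defined`
#'   (logical)
#' @export
estimate_principal_curvatures <- function(mesh, ring = 2L) {
  stopifnot(is_mesh(mesh), ring >= 1)
  v <- mesh$vertices
  nrm <- mesh$normals
  if (is.null(nrm)) nrm <- vertex_normals(mesh)
  adj <- vertex_adjacency(mesh)
  nv <- nrow(v)
  k1 <- k2 <- rep(NA_real_, nv)
  n_undef <- 0L
  for (i in seq_len(nv)) {
    nb <- ring_neighbors(adj, i, ring)
    if (length(nb) < 5) { n_undef <- n_undef + 1L; next }
    nz <- nrm[i, ]
    # tangent basis
    t1 <- c(1, 0, 0)
    if (abs(nz[1]) > 0.9) t1 <- c(0, 1, 0)
    t1 <- t1 - sum(t1 * nz) * nz
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nz[2] * t1[3] - nz[3] * t1[2],
            nz[3] * t1[1] - nz[1] * t1[3],
            nz[1] * t1[2] - nz[2] * t1[1])
    rel <- sweep(v[nb, , drop = FALSE], 2, v[i, ])
    x <- rel %*% t1; y <- rel %*% t2; z <- rel %*% nz
    X <- cbind(x * x, x * y, y * y, x, y)
    XtX <- crossprod(X)
    coef <- tryCatch(solve(XtX, crossprod(X, z)),
                     error = function(e) NULL)
    if (is.null(coef)) { n_undef <- n_undef + 1L; next }
    a <- coef[1]; b <- coef[2]; cc <- coef[3]; d <- coef[4]; e <- coef[5]
    # curvature of the graph z(x,y) at the origin with gradient (d, e)
    g <- 1 + d^2 + e^2
    II <- matrix(c(2 * a, b, b, 2 * cc), 2, 2) / sqrt(g)
    I1 <- matrix(c(1 + d^2, d * e, d * e, 1 + e^2), 2, 2)
    W <- solve(I1, II)
    ev <- eigen((W + t(W)) / 2, symmetric = TRUE)$values
    k1[i] <- max(ev); k2[i] <- min(ev)
  }
  if (n_undef > 0)
    warning(n_undef, " vertices had too few neighbours; curvature undefined there")
  curvature_field(k1, k2)
}

#' Assemble a curvature field from principal curvatures
#'
#' Derived descriptors: mean curvature `H = (k1 + k2)/2`, Gaussian curvature
#' `K = k1 * k2`, shape index `S` and curvedness `C`.
#'
#' @param k1,k2 per-vertex principal curvatures (1/mm), `k1 >= k2`
#' @return `rebiom_curvature` object
#' @export
curvature_field <- function(k1, k2) {
  swap <- !is.na(k1) & !is.na(k2) & k1 < k2
  if (any(swap)) { tmp <- k1[swap]; k1[swap] <- k2[swap]; k2[swap] <- tmp }
  structure(list(k1 = k1, k2 = k2,
                 H = (k1 + k2) / 2, K = k1 * k2,
                 S = shape_index(k1, k2), C = curvedness(k1, k2),
                 defined = !is.na(k1) & !is.na(k2)),
            class = "rebiom_curvature")
}

#' @export
print.rebiom_curvature <- function(x, ...) {
  cat(sprintf("<curvature field: %d vertices (%d defined)>\n",
              length(x$k1), sum(x$defined)))
  invisible(x)
}

#' Shape index
#'
#' `S = -(2/pi) * atan((k1 + k2) / (k1 - k2))` with `k1 >= k2` (inputs are
#' reordered internally).  `S` lies in `[-1, 1]`; its critical points
#' `S = 0, +/-0.5, +/-1` are where the shape class changes.  At umbilic points
#' (`k1 == k2 != 0`) the 0/0 form is resolved by continuity to `+/-1`
#' (`+1` for convex, curvature negative under this toolkit's convention);
#' at `k1 == k2 == 0` the index is undefined and `NA` is returned.
#'
#' @param k1,k2 principal curvatures (vectors, 1/mm)
#' @return shape index in `[-1, 1]`, `NA` where flat
#' @export
shape_index <- function(k1, k2) {
  lo <- pmin(k1, k2); hi <- pmax(k1, k2)
  num <- hi + lo; den <- hi - lo
  s <- rep(NA_real_, length(hi))
  reg <- !is.na(den) & den > 0
  s[reg] <- -(2 / pi) * atan(num[reg] / den[reg])
  umb <- !is.na(den) & den == 0 & num != 0
  s[umb] <- ifelse(num[umb] < 0, 1, -1)   # limit of the arctan as k2 -> k1
  s
}

#' Curvedness
#'
#' `C = sqrt((k1^2 + k2^2) / 2)`, a non-negative intensity of curvature;
#' `C = 0` only on perfectly flat points (where the shape index is undefined).
#'
#' @param k1,k2 principal curvatures (vectors, 1/mm)
#' @return curvedness (1/mm)
#' @export
curvedness <- function(k1, k2) sqrt((k1^2 + k2^2) / 2)

shape_class_levels <- c("convex_elliptical", "convex_cylinder", "saddle_ridge",
                        "planar", "saddle_symmetry", "concave_elliptical",
                        "concave_cylinder", "saddle_valley", "invalid")

#' HK (mean-Gaussian) shape classification
#'
#' Classifies by the sign pattern of the mean curvature `H` and Gaussian
#' curvature `K`, with `|H| <= eps_h` treated as zero and `|K| <= eps_k`
#' treated as zero (developable).  The cell `H = 0, K > 0` is geometrically
#' impossible and returns `"invalid"`.
#'
#' @param H mean curvature (1/mm), vectorised
#' @param K Gaussian curvature (1/mm^2), vectorised
#' @param eps_h,eps_k zero-thresholds (> 0)
#' @return factor with levels the closed shape-class vocabulary
#' @export
hk_classify <- function(H, K, eps_h, eps_k) {
  stopifnot(eps_h > 0, eps_k > 0)
  hs <- ifelse(abs(H) <= eps_h, 0, sign(H))
  ks <- ifelse(abs(K) <= eps_k, 0, sign(K))
  lab <- rep(NA_character_, length(H))
  lab[hs < 0 & ks > 0]  <- "convex_elliptical"
  lab[hs < 0 & ks == 0] <- "convex_cylinder"
  lab[hs < 0 & ks < 0]  <- "saddle_ridge"
  lab[hs == 0 & ks > 0] <- "invalid"
  lab[hs == 0 & ks == 0] <- "planar"
  lab[hs == 0 & ks < 0] <- "saddle_symmetry"
  lab[hs > 0 & ks > 0]  <- "concave_elliptical"
  lab[hs > 0 & ks == 0] <- "concave_cylinder"
  lab[hs > 0 & ks < 0]  <- "saddle_valley"
  factor(lab, levels = shape_class_levels)
}

#' SC (shape index / curvedness) classification
#'
#' Points with `C <= eps_c` are flat (`"planar"`, shape index unspecified).
#' Elsewhere the shape index is binned at its critical points
#' `S = 0, +/-0.5, +/-1`: the critical values themselves are classes (cap/cup,
#' ridge/rut, saddle), recognised within a band `eps_s`, and the open
#' intervals between them supply the remaining classes.  With the toolkit's
#' sign convention positive `S` is convex (`H < 0`), so the SC labels agree
#' cell-for-cell with [hk_classify()].
#'
#' @param S shape index, vectorised
#' @param C curvedness (1/mm), vectorised
#' @param eps_c flatness threshold (> 0)
#' @param eps_s half-width of the band around the critical points
#'   `S = 0, +/-0.5` (default 0.05)
#' @return factor with levels the closed shape-class vocabulary
#' @export
sc_classify <- function(S, C, eps_c, eps_s = 0.05) {
  stopifnot(eps_c > 0, eps_s > 0)
  lab <- rep(NA_character_, length(S))
  flat <- !is.na(C) & C <= eps_c
  lab[flat] <- "planar"
  r <- !flat & !is.na(S)
  lab[r & abs(S) <= eps_s] <- "saddle_symmetry"
  lab[r & abs(S - 0.5) <= eps_s] <- "convex_cylinder"
  lab[r & abs(S + 0.5) <= eps_s] <- "concave_cylinder"
  open <- r & is.na(lab)
  lab[open & S > 0.5] <- "convex_elliptical"
  lab[open & S > eps_s & S < 0.5] <- "saddle_ridge"
  lab[open & S < -eps_s & S > -0.5] <- "saddle_valley"
  lab[open & S < -0.5] <- "concave_elliptical"
  factor(lab, levels = shape_class_levels)
}

#' Classify every vertex of a curvature field
#'
#' Applies [hk_classify()] or [sc_classify()] with zero-thresholds derived
#' from the field's robust curvature scale `s` (median absolute deviation of
#' the curvedness over defined vertices): `eps_h = eps_c = 0.05 s` and
#' `eps_k = 0.05 s^2` (Gaussian curvature scales as curvature squared).
#' Basing every threshold on the magnitude scale keeps developable surfaces
#' (whose own `K` field is pure estimation noise) classified as `K = 0`.
#' Undefined vertices inherit the class of the nearest defined vertex when a
#' mesh is supplied.
#'
#' @param field a `rebiom_curvature`
#' @param scheme `"hk"` or `"sc"`
#' @param eps_h,eps_k,eps_c optional explicit thresholds
#' @param mesh optional mesh for nearest-neighbour fill of undefined vertices
#' @return factor of shape classes, one per vertex
#' @export
classify_field <- function(field, scheme = c("hk", "sc"),
                           eps_h = NULL, eps_k = NULL, eps_c = NULL,
                           mesh = NULL) {
  scheme <- match.arg(scheme)
  def <- field$defined
  if (!any(def)) stop("curvature field has no defined vertices")
  s <- stats::mad(field$C[def], center = 0)
  if (s == 0) s <- stats::median(field$C[def])
  if (s == 0 || !is.finite(s)) s <- 1e-8
  if (scheme == "hk") {
    if (is.null(eps_h)) eps_h <- 0.05 * s
    if (is.null(eps_k)) eps_k <- 0.05 * s^2
    lab <- hk_classify(field$H, field$K, eps_h, eps_k)
  } else {
    if (is.null(eps_c)) eps_c <- 0.05 * s
    lab <- sc_classify(field$S, field$C, eps_c)
    lab[def & is.na(lab) & field$C > eps_c] <- "planar"  # unreachable guard
  }
  if (!is.null(mesh) && any(!def)) {
    vd <- mesh$vertices[def, , drop = FALSE]
    for (i in which(!def)) {
      d2 <- colSums((t(vd) - mesh$vertices[i, ])^2)
      lab[i] <- lab[def][which.min(d2)]
    }
  }
  lab
}
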