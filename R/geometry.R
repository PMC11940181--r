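#' Geometry containers
#'
#' `point_cloud()` and `triangle_mesh()` are the two containers the toolkit is
#' built on.  All coordinates are millimetres in a right-handed frame; vertex
#' and face indices are 1-based (R convention).  For hand fixtures the frame is
#' +x radial, +y distal, +z dorsal.
#'
#' @param points numeric matrix, one row per point (x, y, z) in mm.
#' @param normals optional numeric matrix of unit normals, same rows as
#'   `points`.
#' @param view_id optional integer vector tagging the source scan view of each
#'   point.
#' @return An object of class `rebiom_cloud` with elements `points`,
#'   `normals`, `view_id`.
#' @export
point_cloud <- function(points, normals = NULL, view_id = NULL) {
  points <- as_xyz(points)
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop("point coordinates must be finite")
  if (!is.null(normals)) {
    normals <- as_xyz(normals)
    if (nrow(normals) != nrow(points))
      stop("normals must have the same length as points")
    len <- sqrt(rowSums(normals^2))
    if (any(abs(len - 1) > 1e-6))
      stop("normals must be unit length within 1e-6")
  }
  if (!is.null(view_id)) {
    view_id <- as.integer(view_id)
    if (length(view_id) != nrow(points))
      stop("view_id must have the same length as points")
  }
  structure(list(points = points, normals = normals, view_id = view_id),
            class = "rebiom_cloud")
}

#' @param vertices numeric matrix of vertex coordinates (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param check if `TRUE`, validate index ranges and drop degenerate faces.
#' @rdname point_cloud
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL, check = TRUE) {
  vertices <- as_xyz(vertices)
  faces <- matrix(as.integer(faces), ncol = 3,
                  dimnames = NULL,
                  byrow = FALSE)
  if (check) {
    if (nrow(faces) > 0 &&
        (min(faces) < 1 || max(faces) > nrow(vertices)))
      stop("face indices out of range")
    a <- face_areas(vertices, faces)
    if (any(a <= 0)) {
      faces <- faces[a > 0, , drop = FALSE]
    }
  }
  m <- structure(list(vertices = vertices, faces = faces, normals = normals),
                 class = "rebiom_mesh")
  if (is.null(normals)) m$normals <- vertex_normals(m)
  m
}

#' @export
print.rebiom_cloud <- function(x, ...) {
  cat(sprintf("<point cloud: %d points%s%s>\n", nrow(x$points),
              if (!is.null(x$normals)) ", with normals" else "",
              if (!is.null(x$view_id))
                sprintf(", %d views", length(unique(x$view_id))) else ""))
  invisible(x)
}

#' @export
print.rebiom_mesh <- function(x, ...) {
  cat(sprintf("<triangle mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

as_xyz <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3, byrow = TRUE)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 3) stop("expected 3 columns (x, y, z)")
  dimnames(m) <- NULL
  m
}

is_cloud <- function(x) inherits(x, "rebiom_cloud")
is_mesh <- function(x) inherits(x, "rebiom_mesh")

face_areas <- function(vertices, faces) {
  if (nrow(faces) == 0) return(numeric(0))
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  0.5 * sqrt(rowSums(cross3(e1, e2)^2))
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Unit-normalise the rows of a matrix
#' @param m numeric matrix (zero rows are left unchanged)
#' @return matrix of the same shape
#' @export
normalize_rows <- function(m) {
  len <- sqrt(rowSums(m^2))
  len[len == 0] <- 1
  m / len
}

#' Per-vertex normals by area-weighted face-normal averaging
#' @param mesh a `rebiom_mesh`
#' @return matrix of unit normals, one row per vertex
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  n <- matrix(0, nrow(v), 3)
  if (nrow(f) > 0) {
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    fn <- cross3(e1, e2)  # magnitude = 2*area, gives area weighting
    for (k in 1:3) {
      idx <- f[, k]
      n[, 1] <- n[, 1] + tabulate_sum(idx, fn[, 1], nrow(v))
      n[, 2] <- n[, 2] + tabulate_sum(idx, fn[, 2], nrow(v))
      n[, 3] <- n[, 3] + tabulate_sum(idx, fn[, 3], nrow(v))
    }
  }
  normalize_rows(n)
}

# sum of w by integer group idx, length n output
tabulate_sum <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# Edge list (each undirected edge once) and boundary-edge count.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  list(edges = e, key = key, counts = tab)
}

#' Watertightness check
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces.  Returns the number of open (boundary) edges.
#'
#' @param mesh a `rebiom_mesh`
#' @return list with `watertight` (logical) and `open_edges` (integer count)
#' @export
watertight_check <- function(mesh) {
  if (nrow(mesh$faces) == 0)
    return(list(watertight = FALSE, open_edges = 0L))
  tab <- mesh_edges(mesh)$counts
  open <- sum(tab != 2)
  list(watertight = open == 0, open_edges = as.integer(open))
}

#' Vertex adjacency list from the face set
#' @param mesh a `rebiom_mesh`
#' @return list, one integer vector of neighbour indices per vertex
#' @export
vertex_adjacency <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  from <- c(f[, 1], f[, 2], f[, 2], f[, 3], f[, 3], f[, 1])
  to   <- c(f[, 2], f[, 1], f[, 3], f[, 2], f[, 1], f[, 3])
  adj <- split(to, factor(from, levels = seq_len(nv)))
  lapply(adj, function(x) unique(x))
}

# k-ring neighbourhood (excluding the centre vertex) by BFS over adjacency.
ring_neighbors <- function(adj, i, ring) {
  seen <- i
  frontier <- i
  for (r in seq_len(ring)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    if (length(frontier) == 0) break
    seen <- c(seen, frontier)
  }
  setdiff(seen, i)
}

#' Weld duplicate vertices and drop degenerate faces
#'
#' Vertices closer than `tol` are merged (grid quantisation) and faces that
#' collapse to fewer than three distinct vertices or to zero area are removed.
#' This is the mesh-repair step of the reverse-engineering pipeline; full
#' surface reconstruction from raw clouds is intentionally out of scope.
#'
#' @param mesh a `rebiom_mesh`
#' @param tol welding tolerance in mm
#' @return repaired `rebiom_mesh`
#' @export
repair_mesh <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- apply(round(v / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_v <- v[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[ok, , drop = FALSE]
  a <- face_areas(new_v, f)
  f <- f[a > 0, , drop = FALSE]
  triangle_mesh(new_v, f, check = FALSE)
}

#' Taubin lambda/mu mesh fairing
#'
#' Feature-preserving smoothing alternating a positive (`lambda`) and a
#' negative (`mu`) Laplacian step, which removes scanner noise with minimal
#' shrinkage; the standard mesh-optimisation step before curvature analysis
#' of digitised surfaces.
#'
#' @param mesh a `rebiom_mesh`
#' @param iterations smoothing passes (default 10)
#' @param lambda,mu Taubin step sizes (defaults 0.5 / -0.53)
#' @return smoothed `rebiom_mesh`
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  adj <- vertex_adjacency(mesh)
  v <- mesh$vertices
  nv <- nrow(v)
  deg <- vapply(adj, length, 0L)
  idx <- unlist(adj, use.names = FALSE)
  grp <- rep.int(seq_len(nv), deg)
  step <- function(v, w) {
    nb_mean <- rowsum(v[idx, , drop = FALSE], grp) / pmax(deg, 1)
    v + w * (nb_mean - v)
  }
  for (it in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  triangle_mesh(v, mesh$faces, check = FALSE)
}

#' Apply a rigid (or general affine) transform to a mesh or cloud
#' @param x a `rebiom_mesh` or `rebiom_cloud`
#' @param transform 4x4 homogeneous transform matrix
#' @return transformed object of the same class
#' @export
transform_geometry <- function(x, transform) {
  R <- transform[1:3, 1:3]; t <- transform[1:3, 4]
  tf <- function(p) sweep(p %*% t(R), 2, t, "+")
  if (is_mesh(x)) {
    m <- x
    m$vertices <- tf(x$vertices)
    if (!is.null(x$normals)) m$normals <- normalize_rows(x$normals %*% t(R))
    m
  } else if (is_cloud(x)) {
    cl <- x
    cl$points <- tf(x$points)
    if (!is.null(x$normals)) cl$normals <- normalize_rows(x$normals %*% t(R))
    cl
  } else stop("unsupported geometry type")
}

#' Build a 4x4 homogeneous rigid transform
#' @param R 3x3 rotation matrix
#' @param t translation 3-vector (mm)
#' @return 4x4 matrix
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

#' Rotation matrix about an axis (Rodrigues formula)
#' @param axis rotation axis (normalised internally)
#' @param angle rotation angle in radians
#' @return 3x3 rotation matrix
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Ray-parity point-in-mesh test
#'
#' Casts a ray in a fixed oblique direction from each query point and counts
#' triangle crossings; odd parity means inside.  The oblique direction
#' avoids the edge/vertex grazing degeneracies that axis-aligned rays hit on
#' lathed and gridded meshes.  Requires a watertight mesh.
#'
#' @param mesh a watertight `rebiom_mesh`
#' @param points query points (matrix or vector)
#' @return logical vector
#' @export
points_in_mesh <- function(mesh, points) {
  p <- as_xyz(points)
  v <- mesh$vertices; f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  v1 <- v[f[, 2], , drop = FALSE]
  v2 <- v[f[, 3], , drop = FALSE]
  dirv <- c(0.5773503, 0.5219841, 0.6278721)   # fixed, irrational-ish
  dirv <- dirv / sqrt(sum(dirv^2))
  e1 <- v1 - v0; e2 <- v2 - v0
  pv <- cbind(dirv[2] * e2[, 3] - dirv[3] * e2[, 2],
              dirv[3] * e2[, 1] - dirv[1] * e2[, 3],
              dirv[1] * e2[, 2] - dirv[2] * e2[, 1])   # dir x e2
  det <- rowSums(e1 * pv)
  ok0 <- abs(det) > 1e-12
  inside <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    tv <- sweep(v0, 2, p[i, ], "-") * -1       # p - v0
    u <- rowSums(tv * pv) / det
    qv <- cross3(tv, e1)
    vv <- (qv[, 1] * dirv[1] + qv[, 2] * dirv[2] + qv[, 3] * dirv[3]) / det
    tt <- rowSums(qv * e2) / det
    hit <- ok0 & u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1 & tt > 1e-9
    inside[i] <- (sum(hit) %% 2) == 1
  }
  inside
}

#' Surface area of a mesh
#' @param mesh a `rebiom_mesh`
#' @return total area in mm^2
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' Bounding box of a mesh or cloud
#' @param x geometry object
#' @return 2x3 matrix (min row, max row)
#' @export
bounding_box <- function(x) {
  p <- if (is_mesh(x)) x$vertices else x$points
  rbind(apply(p, 2, min), apply(p, 2, max))
}
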