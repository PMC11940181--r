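#' Deviation map between a mesh and a reference point set
#'
#' For each reference point the exact nearest distance to the mesh surface is
#' computed (point-to-triangle, covering face interiors, edges and vertices),
#' the field the reverse-engineering literature renders as a colour difference
#' map or needle plot.
#'
#' @param model a `rebiom_mesh`
#' @param reference a [point_cloud()] (or point matrix) of measured points
#' @param signed if `TRUE`, distances are signed negative for points inside
#'   the (watertight) model
#' @return list of class `rebiom_deviation`: `distances` (per point, mm),
#'   `max`, `mean`, `signed`
#' @export
deviation_map <- function(model, reference, signed = FALSE) {
  stopifnot(is_mesh(model))
  pts <- if (is_cloud(reference)) reference$points else as_xyz(reference)
  if (nrow(pts) == 0 || nrow(model$faces) == 0)
    stop("model and reference must be non-empty")
  d <- point_mesh_distance(pts, model)
  if (signed) {
    inside <- points_in_mesh(model, pts)
    d[inside] <- -d[inside]
  }
  structure(list(distances = d, max = max(abs(d)), mean = mean(abs(d)),
                 signed = signed),
            class = "rebiom_deviation")
}

#' @export
print.rebiom_deviation <- function(x, ...) {
  cat(sprintf("<deviation map: %d points, max %.4g mm, mean %.4g mm%s>\n",
              length(x$distances), x$max, x$mean,
              if (x$signed) ", signed" else ""))
  invisible(x)
}

#' Exact nearest distance from points to a triangle mesh surface
#' @param points matrix of query points
#' @param mesh a `rebiom_mesh`
#' @return numeric vector of distances (mm)
#' @export
point_mesh_distance <- function(points, mesh) {
  p <- as_xyz(points)
  v <- mesh$vertices; f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  ab <- B - A; ac <- C - A
  d1c <- rowSums(ab * ab); d2c <- rowSums(ac * ac); dab <- rowSums(ab * ac)
  vapply(seq_len(nrow(p)), function(i)
    sqrt(min(point_tri_sqdist(p[i, ], A, B, C, ab, ac, d1c, d2c, dab))),
    0)
}

# Squared distance from a single point to every triangle (vectorised Ericson).
point_tri_sqdist <- function(q, A, B, C, ab, ac, aa, cc, bc) {
  ap <- sweep(A, 2, q, "-") * -1        # q - A
  d1 <- rowSums(ab * ap)
  d2 <- rowSums(ac * ap)
  bp <- sweep(B, 2, q, "-") * -1
  d3 <- rowSums(ab * bp)
  d4 <- rowSums(ac * bp)
  cp <- sweep(C, 2, q, "-") * -1
  d5 <- rowSums(ab * cp)
  d6 <- rowSums(ac * cp)

  n <- nrow(A)
  sq <- rep(NA_real_, n)
  done <- logical(n)

  set <- function(cond, pts) {
    cond <- cond & !done
    if (any(cond)) {
      dd <- sweep(pts[cond, , drop = FALSE], 2, q, "-")
      sq[cond] <<- rowSums(dd^2)
      done[cond] <<- TRUE
    }
  }
  # vertex regions
  set(d1 <= 0 & d2 <= 0, A)
  set(d3 >= 0 & d4 <= d3, B)
  set(d6 >= 0 & d5 <= d6, C)
  # edge AB
  vc <- d1 * d4 - d3 * d2
  cond <- vc <= 0 & d1 >= 0 & d3 <= 0
  t1 <- ifelse(d1 - d3 != 0, d1 / (d1 - d3), 0)
  set(cond, A + ab * t1)
  # edge AC
  vb <- d5 * d2 - d1 * d6
  cond <- vb <= 0 & d2 >= 0 & d6 <= 0
  t2 <- ifelse(d2 - d6 != 0, d2 / (d2 - d6), 0)
  set(cond, A + ac * t2)
  # edge BC
  va <- d3 * d6 - d5 * d4
  cond <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  denom <- (d4 - d3) + (d5 - d6)
  t3 <- ifelse(denom != 0, (d4 - d3) / denom, 0)
  set(cond, B + (C - B) * t3)
  # interior
  if (any(!done)) {
    denom <- va + vb + vc
    denom[denom == 0] <- 1
    vbar <- vb / denom; wbar <- vc / denom
    set(!done, A + ab * vbar + ac * wbar)
  }
  sq
}

#' Assembly interference check
#'
#' Reports every unordered pair of meshes whose surfaces interpenetrate or
#' approach each other closer than `clearance`.
#'
#' @param assembly list of watertight `rebiom_mesh` objects
#' @param clearance minimum allowed surface separation in mm (default 0)
#' @return integer matrix with columns `i`, `j` (1-based indices into
#'   `assembly`), zero rows when the assembly is clean
#' @export
interference_check <- function(assembly, clearance = 0) {
  stopifnot(is.list(assembly), length(assembly) >= 1)
  for (k in seq_along(assembly)) {
    wt <- watertight_check(assembly[[k]])
    if (!wt$watertight)
      stop("assembly member ", k, " is not watertight (",
           wt$open_edges, " open edges)")
  }
  boxes <- lapply(assembly, bounding_box)
  hits <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  n <- length(assembly)
  if (n < 2) return(hits)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    bi <- boxes[[i]]; bj <- boxes[[j]]
    if (any(bi[1, ] - clearance > bj[2, ] | bj[1, ] - clearance > bi[2, ]))
      next
    mi <- assembly[[i]]; mj <- assembly[[j]]
    d_ij <- min(point_mesh_distance(mi$vertices, mj))
    d_ji <- min(point_mesh_distance(mj$vertices, mi))
    gap <- min(d_ij, d_ji)
    penetrating <- any(points_in_mesh(mj, mi$vertices)) ||
      any(points_in_mesh(mi, mj$vertices))
    if (penetrating || gap < clearance)
      hits <- rbind(hits, c(i, j))
  }
  hits
}
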