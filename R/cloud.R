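#' Statistical outlier removal for point clouds
#'
#' For every point the mean distance to its `k_neighbors` nearest neighbours is
#' computed; points whose statistic exceeds mean + `sigma_mult` * sd of that
#' statistic over the whole cloud are removed.  Point order is preserved.
#'
#' @param cloud a [point_cloud()]
#' @param k_neighbors number of nearest neighbours (default 16)
#' @param sigma_mult rejection threshold in standard deviations (default 2.5)
#' @return cleaned `rebiom_cloud` (attribute `removed` holds dropped indices)
#' @export
clean_cloud <- function(cloud, k_neighbors = 16L, sigma_mult = 2.5) {
  stopifnot(is_cloud(cloud))
  n <- nrow(cloud$points)
  if (n == 0) {
    warning("empty cloud; nothing to clean")
    return(cloud)
  }
  if (n < k_neighbors + 1)
    stop("cloud must have at least k_neighbors + 1 = ", k_neighbors + 1, " points")
  d <- knn_mean_dist(cloud$points, k_neighbors)
  thr <- mean(d) + sigma_mult * stats::sd(d)
  keep <- d <= thr
  out <- subset_cloud(cloud, keep)
  attr(out, "removed") <- which(!keep)
  out
}

subset_cloud <- function(cloud, keep) {
  point_cloud(cloud$points[keep, , drop = FALSE],
              normals = if (!is.null(cloud$normals))
                cloud$normals[keep, , drop = FALSE],
              view_id = if (!is.null(cloud$view_id)) cloud$view_id[keep])
}

# mean distance to the k nearest neighbours, blocked brute force
knn_mean_dist <- function(p, k) {
  n <- nrow(p)
  block <- max(1L, floor(2e6 / n))
  sq <- rowSums(p^2)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + block - 1L)
    # squared distances block x n
    d2 <- outer(sq[i:j], sq, "+") - 2 * p[i:j, , drop = FALSE] %*% t(p)
    d2[d2 < 0] <- 0
    for (r in seq_len(j - i + 1L)) {
      dr <- d2[r, ]
      dr[i + r - 1L] <- Inf          # exclude self
      out[i + r - 1L] <- mean(sqrt(sort.int(dr, partial = k)[1:k]))
    }
    i <- j + 1L
  }
  out
}

#' Merge point-cloud views with voxel downsampling
#'
#' Views already expressed in a common frame are concatenated and reduced to
#' one representative point per occupied voxel; the representative is the
#' centroid of the voxel's points, which makes the result independent of input
#' order.
#'
#' @param clouds list of [point_cloud()] objects (a single cloud is accepted)
#' @param voxel voxel edge length in mm (> 0)
#' @return merged `rebiom_cloud`
#' @export
merge_clouds <- function(clouds, voxel) {
  if (is_cloud(clouds)) clouds <- list(clouds)
  stopifnot(voxel > 0, all(vapply(clouds, is_cloud, TRUE)))
  pts <- do.call(rbind, lapply(clouds, `[[`, "points"))
  if (is.null(pts) || nrow(pts) == 0) return(point_cloud(matrix(0, 0, 3)))
  idx <- floor(sweep(pts, 2, apply(pts, 2, min)) / voxel)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  ord <- order(key)            # deterministic independent of input order
  pts <- pts[ord, , drop = FALSE]
  key <- key[ord]
  g <- match(key, unique(key))
  cx <- rowsum(pts, g, reorder = TRUE)
  cnt <- tabulate(g)
  point_cloud(cx / cnt)
}
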