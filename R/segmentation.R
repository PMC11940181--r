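#' Curvature-class region segmentation
#'
#' Flood-fills connected components of equal shape class over the vertex
#' graph, then merges components smaller than `min_vertices` into their
#' largest-area neighbouring region (ties broken toward the lowest region
#' id).  Deterministic for a fixed vertex order.
#'
#' @param mesh a `rebiom_mesh`
#' @param field [estimate_principal_curvatures()] output for this mesh
#' @param scheme `"hk"` or `"sc"`
#' @param min_vertices minimum surviving region size (default 20)
#' @param classes optional precomputed factor of shape classes
#' @return object of class `rebiom_regions`: `region_id` (per vertex,
#'   `NA` = unassigned), `classes` (per vertex), `table` (data.frame: id,
#'   class, n_vertices, area, seed_vertex)
#' @export
segment_regions <- function(mesh, field, scheme = c("hk", "sc"),
                            min_vertices = 20L, classes = NULL) {
  scheme <- match.arg(scheme)
  if (!any(field$defined)) stop("curvature field is entirely undefined")
  if (is.null(classes))
    classes <- classify_field(field, scheme, mesh = mesh)
  adj <- vertex_adjacency(mesh)
  nv <- nrow(mesh$vertices)
  varea <- vertex_area(mesh)
  region <- rep(NA_integer_, nv)
  next_id <- 0L
  cls_chr <- as.character(classes)
  for (i in seq_len(nv)) {
    if (!is.na(region[i]) || is.na(cls_chr[i])) next
    next_id <- next_id + 1L
    queue <- i
    region[i] <- next_id
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[cur]]
      nb <- nb[is.na(region[nb]) & !is.na(cls_chr[nb]) &
                 cls_chr[nb] == cls_chr[cur]]
      region[nb] <- next_id
      queue <- c(queue, nb)
    }
  }
  # merge small regions into largest-area neighbour
  repeat {
    counts <- table(region)
    small <- as.integer(names(counts))[counts < min_vertices]
    if (length(small) == 0) break
    areas <- rowsum(varea[!is.na(region)], region[!is.na(region)])
    merged_any <- FALSE
    for (rid in small) {
      verts <- which(region == rid)
      nb_regions <- setdiff(unique(region[unlist(adj[verts], use.names = FALSE)]),
                            c(rid, NA))
      if (length(nb_regions) == 0) next
      nb_area <- areas[as.character(nb_regions), 1]
      best <- nb_regions[order(-nb_area, nb_regions)][1]
      region[verts] <- best
      merged_any <- TRUE
    }
    if (!merged_any) break
  }
  # compact ids in order of first appearance
  ids <- unique(region[!is.na(region)])
  region <- match(region, ids)
  tab <- do.call(rbind, lapply(seq_along(ids), function(k) {
    verts <- which(region == k)
    cl <- names(sort(table(cls_chr[verts]), decreasing = TRUE))[1]
    data.frame(id = k, class = cl, n_vertices = length(verts),
               area = sum(varea[verts]), seed_vertex = verts[1])
  }))
  structure(list(region_id = region, classes = classes, table = tab),
            class = "rebiom_regions")
}

#' @export
print.rebiom_regions <- function(x, ...) {
  cat(sprintf("<segmentation: %d regions over %d vertices>\n",
              nrow(x$table), length(x$region_id)))
  invisible(x)
}

# one third of incident face area per vertex
vertex_area <- function(mesh) {
  fa <- face_areas(mesh$vertices, mesh$faces)
  out <- numeric(nrow(mesh$vertices))
  for (k in 1:3)
    out <- out + tabulate_sum(mesh$faces[, k], fa / 3, nrow(mesh$vertices))
  out
}

#' Extract cusp records from a segmentation
#'
#' One record is produced per convex-elliptical region whose apex -- the
#' region vertex with the extreme projection along the region's mean outward
#' normal -- is a strict local maximum interior to the region.  This is the
#' natural segmentation of an occlusal surface into its cusps.
#'
#' Two cleanup rules reject noise artefacts: a record must protrude above
#' its boundary loop by at least `min_prominence` of the bounding-box
#' diagonal, and of two records whose apexes lie within `min_separation` of
#' the diagonal, only the more prominent survives (non-maximum suppression;
#' low-relief specks on a cusp flank are absorbed by the cusp).
#'
#' @param mesh a `rebiom_mesh`
#' @param labeling a [segment_regions()] result
#' @param min_prominence minimum apex prominence as a fraction of the
#'   bounding-box diagonal (default 0; negatives always drop)
#' @param min_separation minimum apex separation as a fraction of the
#'   bounding-box diagonal (default 0.1)
#' @return list of cusp records: `region_id`, `apex` (3-vector mm),
#'   `apex_vertex`, `area` (mm^2), `prominence` (mm), `boundary` (matrix of
#'   loop points, possibly partial), `partial` (logical: region touches the
#'   mesh border)
#' @export
extract_cusps <- function(mesh, labeling, min_prominence = 0,
                          min_separation = 0.1) {
  bb <- bounding_box(mesh)
  diag_len <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  adj <- vertex_adjacency(mesh)
  edge_tab <- mesh_edges(mesh)$counts
  tab <- labeling$table
  convex <- tab$id[tab$class == "convex_elliptical"]
  out <- list()
  for (rid in convex) {
    verts <- which(labeling$region_id == rid)
    nrm <- colMeans(mesh$normals[verts, , drop = FALSE])
    nn <- sqrt(sum(nrm^2)); if (nn == 0) next
    nrm <- nrm / nn
    # apexes = local maxima of the projection along the mean outward normal
    # over the region's interior vertices (whole 1-ring inside the region),
    # so a peak region is distinguished from convex rims/collars and a
    # region spanning two merged caps still yields both apexes
    interior_v <- verts[vapply(verts, function(vv)
      all(adj[[vv]] %in% verts), TRUE)]
    if (length(interior_v) == 0) next
    allproj <- as.vector(mesh$vertices %*% nrm)
    apexes <- interior_v[vapply(interior_v, function(vv)
      allproj[vv] >= max(allproj[adj[[vv]]]), TRUE)]
    if (length(apexes) == 0) next
    bnd <- region_boundary(mesh, labeling$region_id, rid, edge_tab)
    base_h <- if (nrow(bnd$loop) > 0) max(bnd$loop %*% nrm)
              else min(allproj[verts])
    for (apex_local in apexes) {
      prominence <- allproj[apex_local] - base_h
      if (prominence < min_prominence * diag_len) next
      out[[length(out) + 1]] <- list(
        region_id = rid, apex = mesh$vertices[apex_local, ],
        apex_vertex = apex_local,
        area = tab$area[tab$id == rid],
        prominence = prominence,
        boundary = bnd$loop, partial = bnd$partial)
    }
  }
  # non-maximum suppression on apex proximity
  if (length(out) > 1) {
    prom <- vapply(out, `[[`, 0, "prominence")
    ord <- order(-prom)
    keep <- logical(length(out))
    kept_apex <- NULL
    for (i in ord) {
      a <- out[[i]]$apex
      if (is.null(kept_apex) ||
          min(sqrt(rowSums(sweep(kept_apex, 2, a)^2))) >=
            min_separation * diag_len) {
        keep[i] <- TRUE
        kept_apex <- rbind(kept_apex, a)
      }
    }
    out <- out[keep]
  }
  out
}

# boundary loop of a region: edges with one incident face inside the region
region_boundary <- function(mesh, region_id, rid, edge_tab) {
  f <- mesh$faces
  inside <- matrix(region_id[f] == rid, ncol = 3)
  inside[is.na(inside)] <- FALSE
  face_in <- rowSums(inside) == 3
  if (!any(face_in)) return(list(loop = matrix(0, 0, 3), partial = TRUE))
  fin <- f[face_in, , drop = FALSE]
  e <- rbind(fin[, c(1, 2)], fin[, c(2, 3)], fin[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1]           # boundary of the region patch
  if (length(bkey) == 0) return(list(loop = matrix(0, 0, 3), partial = FALSE))
  # partial if any region-boundary edge is also a mesh border edge
  partial <- any(edge_tab[bkey] == 1, na.rm = TRUE)
  be <- do.call(rbind, lapply(strsplit(bkey, " "), as.integer))
  ordered <- chain_vertex_loop(be)
  list(loop = mesh$vertices[ordered, , drop = FALSE], partial = partial)
}

chain_vertex_loop <- function(edges) {
  if (nrow(edges) == 0) return(integer(0))
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  start <- edges[1, 1]
  loop <- start
  prev <- NA_integer_
  cur <- start
  for (i in seq_len(2 * nrow(edges))) {
    nxt <- setdiff(adj[[as.character(cur)]], prev)
    if (length(nxt) == 0) break
    nxt <- nxt[1]
    if (nxt == start) break
    loop <- c(loop, nxt)
    prev <- cur; cur <- nxt
  }
  loop
}

#' Long-bone feature partition: head / shaft / base
#'
#' Samples the cross-section area profile along the primary axis; the two
#' local minima of the profile nearest each extremity (the anatomical necks)
#' define the head/shaft and shaft/base boundaries.  The extremity with the
#' larger maximal cross-section area is labelled the head (metacarpal and
#' phalanx anatomy); set `head_end` to override.  `"end"` is accepted as a
#' synonym for the shaft label.
#'
#' @param mesh a long-bone `rebiom_mesh` (axial extent >= 1.5x the largest
#'   transverse extent)
#' @param frame its [rge_frame()]
#' @param n_stations stations for the area profile (default 60)
#' @param head_end `"auto"`, `"positive"` or `"negative"` (primary-axis end
#'   carrying the head)
#' @param degenerate `"error"` (default) or `"single"`: behaviour when no
#'   neck minima exist (e.g. a perfect cylinder)
#' @return object of class `rebiom_partition`: `labels` (factor per vertex:
#'   head/shaft/base), `boundaries` (axial stations, mm), `profile`
#'   (data.frame station/area)
#' @export
partition_bone_features <- function(mesh, frame, n_stations = 60L,
                                    head_end = c("auto", "positive", "negative"),
                                    degenerate = c("error", "single")) {
  head_end <- match.arg(head_end)
  degenerate <- match.arg(degenerate)
  if (frame$extents[1] < 1.5 * frame$extents[2])
    stop("not a long bone (axial extent < 1.5x transverse); ",
         "treat as a compact (carpal-style) bone instead")
  cs <- cross_sections(mesh, frame, n_stations)
  ok <- !vapply(cs$sections, is.null, TRUE)
  st <- cs$stations[ok]
  ar <- vapply(cs$sections[ok], function(s) s$area, 0)
  n <- length(st)
  if (n < 5) stop("too few valid cross-sections")
  # strict interior local minima of the area profile
  mins <- which(ar[2:(n - 1)] < ar[1:(n - 2)] & ar[2:(n - 1)] < ar[3:n]) + 1L
  # ignore minima inside the terminal 10% (cap artefacts)
  span <- st[n] - st[1]
  mins <- mins[st[mins] > st[1] + 0.08 * span & st[mins] < st[n] - 0.08 * span]
  if (length(mins) < 2) {
    if (degenerate == "single") {
      labels <- factor(rep("shaft", nrow(mesh$vertices)),
                       levels = c("head", "shaft", "base"))
      return(structure(list(labels = labels, boundaries = numeric(0),
                            profile = data.frame(station = st, area = ar)),
                       class = "rebiom_partition"))
    }
    stop("no neck minima found in the area profile; the bone may be ",
         "cylinder-like -- use degenerate = \"single\" for a single-feature fallback")
  }
  b_lo <- st[mins[1]]                     # nearest the negative extremity
  b_hi <- st[mins[length(mins)]]          # nearest the positive extremity
  d <- as.vector(mesh$vertices %*% frame$axes["primary", ])
  # head/base disambiguation by maximal cross-section area near each end
  lo_half_max <- max(ar[st <= (st[1] + st[n]) / 2])
  hi_half_max <- max(ar[st > (st[1] + st[n]) / 2])
  head_positive <- switch(head_end,
                          auto = hi_half_max >= lo_half_max,
                          positive = TRUE, negative = FALSE)
  labels <- character(length(d))
  if (head_positive) {
    labels[d >= b_hi] <- "head"
    labels[d <= b_lo] <- "base"
    labels[d > b_lo & d < b_hi] <- "shaft"
  } else {
    labels[d <= b_lo] <- "head"
    labels[d >= b_hi] <- "base"
    labels[d > b_lo & d < b_hi] <- "shaft"
  }
  structure(list(labels = factor(labels, levels = c("head", "shaft", "base")),
                 boundaries = c(b_lo, b_hi),
                 head_positive = head_positive,
                 profile = data.frame(station = st, area = ar)),
            class = "rebiom_partition")
}

#' Condylar cap points of the head feature
#'
#' Selects the distal fraction of the head-feature vertices along the
#' primary axis -- the articular cap used for centre-of-rotation fitting
#' (the neck-side rim of the head feature is not articular surface).
#'
#' @param mesh a `rebiom_mesh`
#' @param frame its [rge_frame()]
#' @param partition a [partition_bone_features()] result
#' @param frac distal fraction of the head's axial span to keep (default 0.5)
#' @return matrix of points
#' @export
head_condyle_points <- function(mesh, frame, partition, frac = 0.5) {
  d <- as.vector(mesh$vertices %*% frame$axes["primary", ])
  hv <- partition$labels == "head"
  dh <- d[hv]
  span <- range(dh)
  # the extremity is the end of the head region away from the shaft
  shaft_d <- mean(d[partition$labels == "shaft"])
  if (abs(span[2] - shaft_d) > abs(span[1] - shaft_d)) {
    cut <- span[2] - frac * diff(span)
    keep <- hv & d >= cut
  } else {
    cut <- span[1] + frac * diff(span)
    keep <- hv & d <= cut
  }
  mesh$vertices[keep, , drop = FALSE]
}

#' @export
print.rebiom_partition <- function(x, ...) {
  cat(sprintf("<bone partition: %s; boundaries at %s mm>\n",
              paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels)),
                    collapse = ", "),
              paste(sprintf("%.2f", x$boundaries), collapse = ", ")))
  invisible(x)
}
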