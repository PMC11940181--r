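#' Read a mesh or point cloud from disk
#'
#' Supported formats: PLY (ascii and binary little-endian 1.0), STL (ascii and
#' binary), OBJ (`v`/`vn`/`f` records; polygons are fan-triangulated with a
#' warning), and XYZ (whitespace-separated `x y z [nx ny nz]` per line).
#' A PLY or OBJ file without faces and an XYZ file yield a [point_cloud()];
#' everything else yields a [triangle_mesh()].
#'
#' @param path file path
#' @param format one of "ply", "stl", "obj", "xyz"; inferred from the file
#'   extension when missing
#' @return `rebiom_mesh` or `rebiom_cloud`
#' @export
read_geometry <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(tolower(format),
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path),
         xyz = read_xyz(path),
         stop("unsupported format: ", format))
}

#' Write a mesh or point cloud to disk
#'
#' @param x `rebiom_mesh` or `rebiom_cloud`
#' @param path output path
#' @param format as in [read_geometry()]
#' @param binary write the binary dialect where the format has one
#' @return `path`, invisibly
#' @export
write_geometry <- function(x, path, format = NULL, binary = FALSE) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(tolower(format),
         ply = write_ply(x, path, binary),
         stl = write_stl(x, path, binary),
         obj = write_obj(x, path),
         xyz = write_xyz(x, path),
         stop("unsupported format: ", format))
  invisible(path)
}

## ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("PLY parse error: header not terminated")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
    if (length(header) > 1000) stop("PLY parse error: runaway header")
  }
  if (trimws(header[1]) != "ply")
    stop("PLY parse error at line 1: missing 'ply' magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("PLY parse error: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("PLY parse error: unsupported format '", fmt, "'")

  elems <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        elems[[cur]]$props[[tok[5]]] <- list(list = TRUE, ctype = tok[3], type = tok[4])
      else
        elems[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
    }
  }
  if (is.null(elems$vertex)) stop("PLY parse error: no vertex element")

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    nv <- elems$vertex$count
    if (length(body) < nv) stop("PLY parse error: truncated vertex data")
    vprops <- names(elems$vertex$props)
    vmat <- matrix(scan(text = body[seq_len(nv)], quiet = TRUE),
                   nrow = nv, byrow = TRUE)
    verts <- vmat[, match(c("x", "y", "z"), vprops), drop = FALSE]
    normals <- if (all(c("nx", "ny", "nz") %in% vprops))
      vmat[, match(c("nx", "ny", "nz"), vprops), drop = FALSE] else NULL
    faces <- NULL
    if (!is.null(elems$face) && elems$face$count > 0) {
      flines <- body[nv + seq_len(elems$face$count)]
      if (anyNA(flines)) stop("PLY parse error: truncated face data")
      faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(tok) {
        n <- as.integer(tok[1])
        idx <- as.integer(tok[1 + seq_len(n)]) + 1L
        if (n == 3) matrix(idx, 1) else
          cbind(idx[1], idx[2:(n - 1)], idx[3:n])  # fan triangulation
      }))
    }
  } else {
    sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
               int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
               float = 4, float32 = 4, double = 8, float64 = 8)
    read_val <- function(type, n = 1) {
      sz <- sizes[[type]]
      if (type %in% c("float", "float32", "double", "float64"))
        readBin(con, "double", n = n, size = sz, endian = "little")
      else
        readBin(con, "integer", n = n, size = sz, endian = "little",
                signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    nv <- elems$vertex$count
    vprops <- elems$vertex$props
    vtypes <- vapply(vprops, function(p) p$type, "")
    if (length(unique(vtypes)) == 1 && !any(vapply(vprops, `[[`, TRUE, "list"))) {
      vmat <- matrix(read_val(vtypes[1], nv * length(vprops)),
                     nrow = nv, byrow = TRUE)
    } else {
      vmat <- t(vapply(seq_len(nv), function(i)
        vapply(vprops, function(p) read_val(p$type, 1), 0), numeric(length(vprops))))
    }
    if (nrow(vmat) < nv || anyNA(vmat)) stop("PLY parse error: truncated vertex data")
    pn <- names(vprops)
    verts <- vmat[, match(c("x", "y", "z"), pn), drop = FALSE]
    normals <- if (all(c("nx", "ny", "nz") %in% pn))
      vmat[, match(c("nx", "ny", "nz"), pn), drop = FALSE] else NULL
    faces <- NULL
    if (!is.null(elems$face) && elems$face$count > 0) {
      lp <- elems$face$props[[1]]
      faces <- do.call(rbind, lapply(seq_len(elems$face$count), function(i) {
        n <- read_val(lp$ctype, 1)
        if (length(n) == 0) stop("PLY parse error: truncated face data")
        idx <- read_val(lp$type, n) + 1L
        if (n == 3) matrix(idx, 1) else cbind(idx[1], idx[2:(n - 1)], idx[3:n])
      }))
    }
  }
  if (!is.null(normals)) normals <- normalize_rows(normals)
  if (is.null(faces)) point_cloud(verts, normals = normals)
  else triangle_mesh(verts, faces, normals = normals, check = FALSE)
}

write_ply <- function(x, path, binary = FALSE) {
  pts <- if (is_mesh(x)) x$vertices else x$points
  nrm <- x$normals
  faces <- if (is_mesh(x)) x$faces else NULL
  con <- file(path, if (binary) "wb" else "w")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(pts)),
           "property double x", "property double y", "property double z")
  if (!is.null(nrm))
    hdr <- c(hdr, "property double nx", "property double ny", "property double nz")
  if (!is.null(faces))
    hdr <- c(hdr, sprintf("element face %d", nrow(faces)),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  vmat <- if (is.null(nrm)) pts else cbind(pts, nrm)
  if (binary) {
    writeBin(as.vector(t(vmat)), con, size = 8, endian = "little")
    if (!is.null(faces))
      for (i in seq_len(nrow(faces))) {
        writeBin(as.raw(3), con)
        writeBin(as.integer(faces[i, ] - 1L), con, size = 4, endian = "little")
      }
  } else {
    writeLines(apply(vmat, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
    if (!is.null(faces))
      writeLines(paste(3, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  }
}

## ---- STL ----

read_stl <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80)
  ntri <- if (sz >= 84) readBin(con, "integer", 1, size = 4, endian = "little") else -1
  close(con)
  is_binary <- sz >= 84 && sz == 84 + 50 * ntri
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84)
    tri <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "double", n = 12, size = 4, endian = "little")
      if (length(rec) < 12) stop("STL parse error: truncated at triangle ", i)
      tri[(i - 1) * 3 + 1:3, ] <- matrix(rec[4:12], 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    if (length(txt) == 0 || !grepl("^\\s*solid", txt[1]))
      stop("STL parse error at line 1: not an ascii 'solid' and size inconsistent with binary STL")
    vl <- grep("^\\s*vertex\\s", txt)
    if (length(vl) == 0 || length(vl) %% 3 != 0)
      stop("STL parse error: vertex count ", length(vl), " is not a multiple of 3 (truncated file?)")
    if (!any(grepl("^\\s*endsolid", txt)))
      stop("STL parse error: missing 'endsolid' (truncated file?)")
    tri <- do.call(rbind, lapply(txt[vl], function(ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2:4])))
    if (anyNA(tri)) stop("STL parse error: malformed vertex line")
  }
  # STL stores soup triangles; weld identical vertices to recover topology
  key <- apply(tri, 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  verts <- tri[first, , drop = FALSE]
  faces <- matrix(map, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces, check = FALSE)
}

write_stl <- function(x, path, binary = FALSE) {
  if (!is_mesh(x)) stop("STL can only store triangle meshes")
  v <- x$vertices; f <- x$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- normalize_rows(cross3(e1, e2))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.vector(t(rbind(fn[i, ], v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]))),
               con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid rebiom", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.17g %.17g %.17g",
                           v[f[i, 1:3], 1], v[f[i, 1:3], 2], v[f[i, 1:3], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid rebiom", con)
  }
}

## ---- OBJ ----

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vt <- grep("^v\\s", txt, value = TRUE)
  vnl <- grep("^vn\\s", txt, value = TRUE)
  fl <- grep("^f\\s", txt, value = TRUE)
  if (length(vt) == 0) stop("OBJ parse error: no vertices")
  verts <- do.call(rbind, lapply(strsplit(vt, "\\s+"), function(t)
    as.numeric(t[2:4])))
  if (anyNA(verts)) stop("OBJ parse error: malformed vertex line")
  normals <- NULL
  if (length(vnl) == nrow(verts)) {
    normals <- normalize_rows(do.call(rbind, lapply(strsplit(vnl, "\\s+"),
                                                    function(t) as.numeric(t[2:4]))))
  }
  faces <- NULL
  if (length(fl) > 0) {
    warned <- FALSE
    faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(t) {
      idx <- as.integer(vapply(strsplit(t[-1], "/"), `[[`, "", 1))
      if (length(idx) > 3 && !warned) warned <<- TRUE
      if (length(idx) == 3) matrix(idx, 1)
      else cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
    }))
    sizes <- vapply(strsplit(fl, "\\s+"), length, 1L) - 1L
    if (any(sizes > 3)) warning("OBJ contains non-triangular faces; fan-triangulated")
  }
  if (is.null(faces)) point_cloud(verts, normals = normals)
  else triangle_mesh(verts, faces, normals = normals, check = FALSE)
}

write_obj <- function(x, path) {
  pts <- if (is_mesh(x)) x$vertices else x$points
  lines <- sprintf("v %.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3])
  if (!is.null(x$normals))
    lines <- c(lines, sprintf("vn %.9g %.9g %.9g",
                              x$normals[, 1], x$normals[, 2], x$normals[, 3]))
  if (is_mesh(x))
    lines <- c(lines, sprintf("f %d %d %d",
                              x$faces[, 1], x$faces[, 2], x$faces[, 3]))
  writeLines(lines, path)
}

## ---- XYZ ----

read_xyz <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (length(txt) == 0) return(point_cloud(matrix(0, 0, 3)))
  rows <- suppressWarnings(lapply(strsplit(trimws(txt), "\\s+"), as.numeric))
  ncols <- unique(vapply(rows, length, 1L))
  if (length(ncols) != 1 || !(ncols %in% c(3, 6)))
    stop("XYZ parse error: each line must have 3 or 6 numbers")
  m <- do.call(rbind, rows)
  if (anyNA(m)) stop("XYZ parse error: non-numeric field at line ",
                     which(apply(is.na(m), 1, any))[1])
  if (ncols == 3) point_cloud(m)
  else point_cloud(m[, 1:3, drop = FALSE], normals = normalize_rows(m[, 4:6, drop = FALSE]))
}

write_xyz <- function(x, path) {
  pts <- if (is_mesh(x)) x$vertices else x$points
  m <- if (!is.null(x$normals)) cbind(pts, x$normals) else pts
  writeLines(apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), path)
}
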