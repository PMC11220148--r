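# Surface point clouds: PLY I/O (ASCII and binary little-endian),
# expansion of a pressure grid into a registration-ready cloud, and local
# plane-fit normal estimation. All coordinates in mm.

#' Construct a surface cloud
#'
#' @param points n x 3 numeric matrix of (x, y, z) coordinates in mm.
#' @param normals optional n x 3 matrix of unit normals aligned to `points`.
#' @param frame name of the coordinate frame. The mattress scan frame has
#'   its origin at the mattress centroid with x = width, y = length,
#'   z = height; the pressure-mat frame has a lower-left origin.
#' @return an object of class `surface_cloud`.
#' @export
surface_cloud <- function(points, normals = NULL, frame = "mat") {
  points <- matrix(as.numeric(points), ncol = 3)
  if (any(!is.finite(points)))
    stop_vecforce("point coordinates must be finite", "validation_error")
  if (!is.null(normals)) {
    normals <- matrix(as.numeric(normals), ncol = 3)
    if (nrow(normals) != nrow(points))
      stop_vecforce("normals must align 1:1 with points", "shape_error")
    n2 <- rowSums(normals^2)
    if (nrow(normals) && any(abs(sqrt(n2) - 1) > 1e-6))
      stop_vecforce("normals must have unit length within 1e-6", "validation_error")
  }
  structure(list(points = points, normals = normals, frame = frame),
            class = "surface_cloud")
}

#' @export
print.surface_cloud <- function(x, ...) {
  cat(sprintf("<surface_cloud> %d points%s, frame '%s'\n", nrow(x$points),
              if (is.null(x$normals)) "" else " + normals", x$frame))
  invisible(x)
}

ply_header <- function(n, has_normals, format) {
  c("ply",
    sprintf("format %s 1.0", format),
    "comment written by vecforce",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    if (has_normals) c("property float nx", "property float ny",
                       "property float nz"),
    "end_header")
}

#' Write a surface cloud to PLY
#'
#' @param cloud a [surface_cloud()].
#' @param path output path.
#' @param binary write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, binary = TRUE) {
  n <- nrow(cloud$points)
  has_n <- !is.null(cloud$normals)
  dat <- if (has_n) cbind(cloud$points, cloud$normals) else cloud$points
  fmt <- if (binary) "binary_little_endian" else "ascii"
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(ply_header(n, has_n, fmt), con)
  if (n == 0) return(invisible(path))
  if (binary) {
    writeBin(as.vector(t(dat)), con, size = 4, endian = "little")
  } else {
    writeLines(apply(dat, 1L, function(r)
      paste(sprintf("%.9g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a surface cloud from PLY
#'
#' Supports ASCII and binary little-endian PLY with float or double vertex
#' properties; `x`, `y`, `z` are required, `nx`, `ny`, `nz` picked up when
#' present. Other vertex properties are skipped; non-vertex elements after
#' the vertex block are ignored.
#'
#' @param path PLY file path.
#' @return a [surface_cloud()].
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop_vecforce(paste("no such file:", path), "io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop_vecforce("unterminated PLY header", "format_error")
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  if (!length(hdr) || hdr[1] != "ply")
    stop_vecforce("not a PLY file", "format_error")
  fmt <- sub("^format\\s+(\\S+).*$", "\\1", grep("^format", hdr, value = TRUE)[1])
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop_vecforce(paste("unsupported PLY format:", fmt), "format_error")
  el <- grep("^element", hdr)
  vert_el <- el[grepl("^element\\s+vertex", hdr[el])]
  if (!length(vert_el)) stop_vecforce("PLY has no vertex element", "format_error")
  n <- as.integer(sub("^element\\s+vertex\\s+(\\d+).*$", "\\1", hdr[vert_el[1]]))
  if (vert_el[1] != el[1])
    stop_vecforce("vertex element must come first", "format_error")
  nxt <- el[el > vert_el[1]]
  prop_end <- if (length(nxt)) nxt[1] - 1L else length(hdr) - 1L
  props <- hdr[(vert_el[1] + 1L):prop_end]
  props <- grep("^property", props, value = TRUE)
  ptype <- sub("^property\\s+(\\S+)\\s+\\S+$", "\\1", props)
  pname <- sub("^property\\s+\\S+\\s+(\\S+)$", "\\1", props)
  if (any(grepl("^property\\s+list", props)))
    stop_vecforce("list properties on vertices are unsupported", "format_error")
  if (!all(c("x", "y", "z") %in% pname))
    stop_vecforce("PLY vertex element lacks x/y/z properties", "format_error")
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
             int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L)
  if (any(!ptype %in% names(sizes)))
    stop_vecforce("unsupported vertex property type", "format_error")
  if (n == 0) {
    has_n <- all(c("nx", "ny", "nz") %in% pname)
    return(surface_cloud(matrix(numeric(0), ncol = 3),
                         if (has_n) matrix(numeric(0), ncol = 3)))
  }
  if (fmt == "ascii") {
    rows <- readLines(con)
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) < n) stop_vecforce("truncated PLY body", "format_error")
    vals <- vapply(rows[seq_len(n)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])[seq_along(pname)],
      numeric(length(pname)), USE.NAMES = FALSE)
    m <- t(matrix(vals, nrow = length(pname)))
  } else {
    m <- matrix(NA_real_, nrow = n, ncol = length(pname))
    # properties can mix widths; read column-striped per row only if mixed,
    # else in one block
    if (length(unique(sizes[ptype])) == 1L && sizes[ptype[1]] %in% c(4L, 8L) &&
        all(ptype %in% c("float", "float32", "double", "float64"))) {
      raw <- readBin(con, "numeric", n = n * length(pname),
                     size = sizes[ptype[1]], endian = "little")
      if (length(raw) < n * length(pname))
        stop_vecforce("truncated PLY body", "format_error")
      m <- matrix(raw, ncol = length(pname), byrow = TRUE)
    } else {
      for (i in seq_len(n)) {
        for (j in seq_along(pname)) {
          what <- if (ptype[j] %in% c("float", "float32", "double", "float64"))
            "numeric" else "integer"
          m[i, j] <- readBin(con, what, n = 1L, size = sizes[ptype[j]],
                             endian = "little",
                             signed = !startsWith(ptype[j], "u"))
        }
      }
    }
  }
  colnames(m) <- pname
  pts <- m[, c("x", "y", "z"), drop = FALSE]
  nrm <- NULL
  if (all(c("nx", "ny", "nz") %in% pname)) {
    nrm <- m[, c("nx", "ny", "nz"), drop = FALSE]
    # float32 storage erodes unit length; renormalise
    len <- sqrt(rowSums(nrm^2))
    ok <- len > 0
    nrm[ok, ] <- nrm[ok, , drop = FALSE] / len[ok]
  }
  surface_cloud(pts, nrm)
}

#' Expand a pressure grid into a 3D point cloud
#'
#' Each cell with non-zero force contributes one point at its cell centre
#' with a depth-like z obtained by normalising the scalar force against the
#' z extent of the target scan:
#' `z = -(F / F_max) * (z_max - z_min)`,
#' so the highest-pressure cell maps to the deepest point and the expanded
#' cloud spans the same vertical range as the deformed surface. Zero-force
#' cells are omitted: they carry no load and would bias registration toward
#' the undeformed plane.
#'
#' @param grid a [pressure_grid()] in N.
#' @param z_max,z_min z extent (mm) of the target scan.
#' @return a [surface_cloud()] in the grid's frame.
#' @export
expand_pressure_cloud <- function(grid, z_max, z_min) {
  if (grid$units != "N")
    stop_vecforce("grid must be in N (convert_to_newtons first)", "unit_error")
  if (z_max <= z_min) stop_vecforce("z_max must exceed z_min", "validation_error")
  f_max <- max(grid$values)
  if (f_max <= 0)
    stop_vecforce("all-zero grid: no F_max to normalise against",
                  "degenerate_error")
  cc <- cell_centers(grid)
  f <- grid$values[cbind(cc$row, cc$col)]
  keep <- f > 0
  z <- -(f[keep] / f_max) * (z_max - z_min)
  surface_cloud(cbind(cc$x_mm[keep], cc$y_mm[keep], z), frame = grid$frame)
}

#' Estimate per-point normals by local plane fitting
#'
#' Fits a plane to the k nearest neighbours of every point (principal
#' component analysis of the neighbourhood: the normal is the direction of
#' least spread) and orients all normals to have non-negative z, i.e. out
#' of the mattress toward the body. In-plane ties are broken toward
#' positive x, then positive y.
#'
#' @param cloud a [surface_cloud()].
#' @param k neighbour count (>= 3).
#' @return the cloud with `normals` filled in.
#' @export
estimate_normals <- function(cloud, k = 12) {
  if (k < 3) stop_vecforce("k must be >= 3", "parameter_error")
  n <- nrow(cloud$points)
  if (n < k + 1)
    stop_vecforce("cloud must have at least k+1 points", "parameter_error")
  nn <- RANN::nn2(cloud$points, k = k + 1L)$nn.idx  # col 1 is the point itself
  pts <- cloud$points
  normals <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    nb <- pts[nn[i, ], , drop = FALSE]
    ctr <- colMeans(nb)
    cm <- crossprod(sweep(nb, 2, ctr))
    ev <- eigen(cm, symmetric = TRUE)
    v <- ev$vectors[, 3]
    if (v[3] < 0 || (v[3] == 0 && (v[1] < 0 || (v[1] == 0 && v[2] < 0))))
      v <- -v
    normals[i, ] <- v / vnorm(v)
  }
  surface_cloud(pts, normals, frame = cloud$frame)
}
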