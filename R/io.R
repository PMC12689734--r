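#' Construct a point cloud
#'
#' A point cloud is an ordered set of 3-D coordinates in millimetres with an
#' optional per-point weight and an optional free-text source label (for
#' example `"ct"` or `"us"`).
#'
#' @param points numeric matrix with one row per point and three columns
#'   (x, y, z in mm).  A 3-vector is accepted for a single point.
#' @param weights optional non-negative per-point weights; default 1 for every
#'   point.
#' @param label optional character scalar tagging the source of the cloud.
#' @return An object of class `point_cloud`: a list with elements `points`
#'   (N x 3 matrix), `weights` (length-N vector) and `label`.
#' @export
point_cloud <- function(points, weights = NULL, label = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must have three columns (x, y, z)")
  if (nrow(points) < 1L) stop("a point cloud needs at least one point")
  if (!all(is.finite(points))) stop("all coordinates must be finite")
  dimnames(points) <- NULL
  if (is.null(weights)) {
    weights <- rep(1, nrow(points))
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != nrow(points))
      stop("weights must have one entry per point")
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be finite and non-negative")
  }
  structure(list(points = points, weights = weights, label = label),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s\n", nrow(x$points),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  rng <- apply(x$points, 2, range)
  cat(sprintf("  extent (mm): x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

as_points_matrix <- function(x) {
  if (inherits(x, "point_cloud")) return(x$points)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "pcd", "xyz")) return(ext)
  if (ext %in% c("txt", "csv")) return("xyz")
  stop("cannot guess point-cloud format from extension of '", path, "'")
}

#' Read a point cloud from disk
#'
#' Supported formats: PLY (ASCII and binary little-endian; only the x/y/z
#' vertex properties are consumed), ASCII PCD, and whitespace-separated XYZ
#' text (lines starting with `#` are ignored).  Coordinates are interpreted
#' as millimetres and returned in file order.
#'
#' @param path path to the file.
#' @param format one of `"auto"`, `"ply"`, `"pcd"`, `"xyz"`.
#' @return A [point_cloud].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "pcd", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("point-cloud file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  pts <- switch(format,
    xyz = read_xyz(path),
    ply = read_ply(path),
    pcd = read_pcd(path))
  point_cloud(pts)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no coordinate records in XYZ file ", path)
  toks <- strsplit(trimws(lines[keep]), "[[:space:],]+")
  nf <- lengths(toks)
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed XYZ record at line ", keep[bad[1]], " of ", path)
  vals <- suppressWarnings(
    vapply(toks, function(t) as.numeric(t[1:3]), numeric(3)))
  if (any(is.na(vals))) {
    bad <- which(colSums(is.na(vals)) > 0)[1]
    stop("non-numeric XYZ record at line ", keep[bad], " of ", path)
  }
  t(vals)
}

ply_type_size <- function(type) {
  switch(type,
    char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
    float = 4L, float32 = 4L,
    double = 8L, float64 = 8L,
    stop("unsupported PLY property type '", type, "'"))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unterminated PLY header in ", path)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 1000L) stop("PLY header too large in ", path)
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop("missing PLY format line in ", path)
  fmt <- strsplit(trimws(fmt_line), "[[:space:]]+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format '", fmt, "' in ", path)

  # walk elements; collect vertex property layout
  n_vertex <- NA_integer_
  props <- character()
  cur_elem <- ""
  elems <- list()  # name -> count (to skip non-vertex data)
  for (ln in header) {
    t <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (t[1] == "element") {
      cur_elem <- t[2]
      elems[[cur_elem]] <- as.integer(t[3])
      if (cur_elem == "vertex") n_vertex <- as.integer(t[3])
    } else if (t[1] == "property" && cur_elem == "vertex") {
      if (t[2] == "list") stop("list properties on vertices are not supported")
      props <- c(props, structure(t[2], names = t[3]))
    }
  }
  if (is.na(n_vertex)) stop("PLY file has no vertex element: ", path)
  if (!all(c("x", "y", "z") %in% names(props)))
    stop("PLY vertex element lacks x/y/z properties in ", path)
  if (names(elems)[1] != "vertex")
    stop("PLY files with elements before 'vertex' are not supported")

  if (fmt == "ascii") {
    rows <- readLines(con, n = n_vertex)
    if (length(rows) < n_vertex) stop("truncated PLY vertex data in ", path)
    toks <- strsplit(trimws(rows), "[[:space:]]+")
    cols <- match(c("x", "y", "z"), names(props))
    vals <- vapply(seq_len(n_vertex), function(i) {
      v <- suppressWarnings(as.numeric(toks[[i]][cols]))
      if (any(is.na(v))) stop("malformed PLY vertex record ", i, " in ", path)
      v
    }, numeric(3))
    return(t(vals))
  }

  sizes <- vapply(unname(props), ply_type_size, integer(1))
  rec <- sum(sizes)
  raw <- readBin(con, what = "raw", n = rec * n_vertex)
  if (length(raw) < rec * n_vertex) stop("truncated PLY vertex data in ", path)
  offs <- c(0L, cumsum(sizes))
  out <- matrix(0, n_vertex, 3L)
  for (d in 1:3) {
    j <- match(c("x", "y", "z")[d], names(props))
    sz <- sizes[j]
    type <- unname(props[j])
    starts <- offs[j] + rec * (seq_len(n_vertex) - 1L)
    sel <- rep(starts, each = sz) + seq_len(sz)
    piece <- raw[sel]
    out[, d] <- if (type %in% c("float", "float32", "double", "float64")) {
      readBin(piece, "double", n = n_vertex, size = sz, endian = "little")
    } else {
      readBin(piece, "integer", n = n_vertex, size = sz, endian = "little")
    }
  }
  out
}

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hend <- grep("^DATA[[:space:]]", lines)
  if (length(hend) == 0L) stop("missing DATA line in PCD file ", path)
  hend <- hend[1]
  mode <- strsplit(trimws(lines[hend]), "[[:space:]]+")[[1]][2]
  if (mode != "ascii") stop("only ASCII PCD files are supported: ", path)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, "[[:space:]]"), lines[1:hend], value = TRUE)
    if (length(ln) == 0L) return(NULL)
    strsplit(trimws(ln[1]), "[[:space:]]+")[[1]][-1]
  }
  fields <- get_field("FIELDS")
  if (is.null(fields) || !all(c("x", "y", "z") %in% fields))
    stop("PCD file lacks x/y/z fields: ", path)
  npts <- as.integer(get_field("POINTS")[1])
  body <- lines[(hend + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < npts) stop("truncated PCD data in ", path)
  toks <- strsplit(trimws(body[seq_len(npts)]), "[[:space:]]+")
  cols <- match(c("x", "y", "z"), fields)
  vals <- vapply(seq_len(npts), function(i) {
    v <- suppressWarnings(as.numeric(toks[[i]][cols]))
    if (any(is.na(v))) stop("malformed PCD record ", i, " in ", path)
    v
  }, numeric(3))
  t(vals)
}

#' Write a point cloud to disk
#'
#' XYZ text is written with 17 significant digits so that a read/write round
#' trip is bit exact; PLY stores coordinates as doubles in both the ASCII and
#' binary little-endian dialects.
#'
#' @param pc a [point_cloud] (or bare N x 3 matrix).
#' @param path output file path.
#' @param format one of `"auto"`, `"ply"`, `"pcd"`, `"xyz"`.
#' @param binary for PLY, write the binary little-endian dialect.
#' @param create_dirs create missing parent directories.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(pc, path, format = c("auto", "ply", "pcd", "xyz"),
                              binary = FALSE, create_dirs = TRUE) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  pts <- as_points_matrix(pc)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    if (create_dirs) dir.create(dir, recursive = TRUE)
    else stop("directory does not exist: ", dir)
  }
  switch(format,
    xyz = {
      rows <- sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3])
      writeLines(rows, path)
    },
    ply = {
      header <- c("ply",
                  sprintf("format %s 1.0",
                          if (binary) "binary_little_endian" else "ascii"),
                  sprintf("element vertex %d", nrow(pts)),
                  "property double x", "property double y", "property double z",
                  "end_header")
      if (binary) {
        con <- file(path, "wb")
        on.exit(close(con))
        writeLines(header, con)
        writeBin(as.vector(t(pts)), con, size = 8L, endian = "little")
      } else {
        rows <- sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3])
        writeLines(c(header, rows), path)
      }
    },
    pcd = {
      header <- c("# .PCD v0.7 - Point Cloud Data file format",
                  "VERSION 0.7", "FIELDS x y z", "SIZE 8 8 8", "TYPE F F F",
                  "COUNT 1 1 1", sprintf("WIDTH %d", nrow(pts)), "HEIGHT 1",
                  "VIEWPOINT 0 0 0 1 0 0 0", sprintf("POINTS %d", nrow(pts)),
                  "DATA ascii")
      rows <- sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3])
      writeLines(c(header, rows), path)
    })
  invisible(path)
}

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 translation vector in mm.
#' @param tol tolerance for the rigidity check.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  R <- as.matrix(rotation)
  storage.mode(R) <- "double"
  t <- as.numeric(translation)
  if (!all(dim(R) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (length(t) != 3L) stop("translation must have length 3")
  if (!all(is.finite(R)) || !all(is.finite(t)))
    stop("transform entries must be finite")
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("rotation matrix is not rigid (orthonormal, det +1)")
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$R) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation %.3f mm\n",
              ang, sqrt(sum(x$t^2))))
  invisible(x)
}

#' Rotation from axis and angle
#'
#' @param axis direction of the rotation axis (any nonzero 3-vector).
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle) {
  a <- as.numeric(axis)
  n <- sqrt(sum(a^2))
  if (n == 0) return(diag(3))
  a <- a / n
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# exponential map of an axis-angle 3-vector (angle = norm)
rotation_exp <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  rotation_axis_angle(r, th)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Compose two rigid transforms
#'
#' Returns the transform applying `b` first, then `a`.
#' @param a,b [rigid_transform] objects.
#' @return A [rigid_transform] equal to `a %then-after% b`.
#' @export
compose_transform <- function(a, b) {
  R <- a$R %*% b$R
  # re-orthonormalize to keep long compositions within the rigidity tolerance
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  rigid_transform(R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param T a [rigid_transform].
#' @return The inverse [rigid_transform].
#' @export
invert_transform <- function(T) {
  rigid_transform(t(T$R), as.numeric(-t(T$R) %*% T$t))
}

#' Apply a rigid transform to points
#'
#' @param pc a [point_cloud] or N x 3 matrix.
#' @param T a [rigid_transform].
#' @return Same type as `pc`, with every point mapped to `R p + t`; weights,
#'   order and label are preserved.
#' @export
apply_transform <- function(pc, T) {
  if (!inherits(T, "rigid_transform"))
    T <- rigid_transform(T$R, T$t)  # re-validates
  if (inherits(pc, "point_cloud")) {
    out <- pc
    out$points <- transform_points(pc$points, T)
    return(out)
  }
  transform_points(as_points_matrix(pc), T)
}

transform_points <- function(X, T) {
  Y <- X %*% t(T$R)
  Y[, 1] <- Y[, 1] + T$t[1]
  Y[, 2] <- Y[, 2] + T$t[2]
  Y[, 3] <- Y[, 3] + T$t[3]
  Y
}

#' 4 x 4 homogeneous matrix of a rigid transform
#' @param T a [rigid_transform].
#' @return 4 x 4 matrix acting on column vectors.
#' @export
transform_matrix <- function(T) {
  M <- diag(4)
  M[1:3, 1:3] <- T$R
  M[1:3, 4] <- T$t
  M
}

#' Rigid transform from a 4 x 4 homogeneous matrix
#' @param M 4 x 4 matrix.
#' @return A [rigid_transform].
#' @export
transform_from_matrix <- function(M) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(4L, 4L))) stop("expected a 4 x 4 matrix")
  rigid_transform(M[1:3, 1:3], M[1:3, 4])
}

#' Write a rigid transform as JSON
#'
#' The serialized form is `{"matrix": [[...4 x 4 row-major...]], "units": "mm"}`.
#' @param T a [rigid_transform].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(T, path) {
  M <- transform_matrix(T)
  obj <- list(matrix = lapply(seq_len(4), function(i) M[i, ]), units = "mm")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path path written by [write_transform].
#' @return A [rigid_transform].
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  M <- obj$matrix
  if (is.list(M)) M <- do.call(rbind, M)
  transform_from_matrix(M)
}

#' Voxel-grid downsampling
#'
#' Points are binned on the origin-aligned cubic lattice of edge `voxel_edge`
#' (half-open intervals), and each occupied voxel is replaced by the centroid
#' of its members.  Because every centroid lies inside its own voxel, the
#' operation is exactly idempotent.  Output voxels are ordered by their
#' lattice index, so the result is deterministic.
#'
#' @param pc a [point_cloud] or N x 3 matrix.
#' @param voxel_edge voxel edge length in mm (default 0.8, the skeleton
#'   contraction down-sampling size).
#' @return A [point_cloud] of voxel centroids; per-voxel weights are the mean
#'   of member weights.
#' @export
voxel_downsample <- function(pc, voxel_edge = 0.8) {
  if (!is.numeric(voxel_edge) || length(voxel_edge) != 1L || voxel_edge <= 0)
    stop("voxel_edge must be a positive length in mm")
  is_pc <- inherits(pc, "point_cloud")
  pts <- as_points_matrix(pc)
  w <- if (is_pc) pc$weights else rep(1, nrow(pts))
  ix <- floor(pts[, 1] / voxel_edge)
  iy <- floor(pts[, 2] / voxel_edge)
  iz <- floor(pts[, 3] / voxel_edge)
  key <- paste(ix, iy, iz)
  ord <- order(ix, iy, iz)
  ukey <- unique(key[ord])
  g <- as.integer(factor(key, levels = ukey))
  cnt <- tabulate(g, nbins = length(ukey))
  cent <- rowsum(pts, g) / cnt          # rowsum sorts integer groups
  wmean <- as.vector(rowsum(w, g)) / cnt
  point_cloud(cent, weights = wmean, label = if (is_pc) pc$label else NULL)
}
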