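# MRC2014/CCP4 density map input/output and real-space map probing.
#
# No assumptions are made about the axis order or origin convention of input
# files: the header's axis-correspondence words (MAPC/MAPR/MAPS) are used to
# reindex the grid to (x, y, z), and the ORIGIN record takes precedence over
# the start indices when both are present and inconsistent. Only orthogonal
# (P1-style volume) cells are supported, which covers single-particle cryo-EM
# maps.

.map_stats <- function(grid) {
  m <- mean(grid)
  list(min = min(grid), max = max(grid), mean = m,
       rms = sqrt(mean((grid - m)^2)))
}

#' Construct a density map
#'
#' @param grid 3D numeric array in (x, y, z) index order; map values in
#'   arbitrary units.
#' @param voxel_size voxel edge lengths in Angstrom, length-3 (or scalar,
#'   recycled); all components must be positive.
#' @param origin position in Angstrom of grid index (1,1,1), length 3.
#' @return an object of class \code{density_map} with fields \code{grid},
#'   \code{voxel}, \code{origin}, \code{axis_order} and \code{stats}
#'   (min/max/mean/rms of the grid).
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size components must be > 0")
  structure(list(grid = grid, voxel = voxel_size,
                 origin = as.numeric(origin)[1:3],
                 axis_order = c(1L, 2L, 3L),
                 stats = .map_stats(grid)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<density_map> %d x %d x %d voxels, %.3g x %.3g x %.3g A/voxel\n",
    d[1], d[2], d[3], x$voxel[1], x$voxel[2], x$voxel[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A; mean %.4g, rms %.4g\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$stats$mean, x$stats$rms))
  invisible(x)
}

.read_mrc_header <- function(con) {
  ints1 <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  cellb <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  axes <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  dstats <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  ispg <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  extra <- readBin(con, "integer", n = 25L, size = 4L, endian = "little")
  orig <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  mapword <- readBin(con, "raw", n = 4L)
  machst <- readBin(con, "raw", n = 4L)
  rms <- readBin(con, "numeric", n = 1L, size = 4L, endian = "little")
  nlabl <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  labels <- readBin(con, "raw", n = 800L)
  if (length(nlabl) < 1L) stop("malformed MRC header: file shorter than 1024 bytes")
  list(nc = ints1[1], nr = ints1[2], ns = ints1[3], mode = ints1[4],
       nstart = ints1[5:7], m = ints1[8:10], cella = cella, cellb = cellb,
       axes = axes, dmin = dstats[1], dmax = dstats[2], dmean = dstats[3],
       ispg = ispg[1], nsymbt = ispg[2], origin = orig,
       mapword = mapword, rms = rms, nlabl = nlabl)
}

#' Read an MRC2014/CCP4 density map
#'
#' The grid is reindexed to (x, y, z) order using the header's
#' axis-correspondence words. The origin is taken from the ORIGIN record when
#' any component is non-zero, otherwise from the start indices times the
#' voxel size; if both are present and disagree a warning is issued and the
#' ORIGIN record wins.
#'
#' @param path file path.
#' @return a \code{density_map}; the file path and its MD5 checksum are
#'   attached as attribute \code{"source"} for provenance.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- .read_mrc_header(con)
  if (any(is.na(c(h$nc, h$nr, h$ns, h$mode))) ||
      h$nc <= 0 || h$nr <= 0 || h$ns <= 0 ||
      h$nc > 1e5 || h$nr > 1e5 || h$ns > 1e5)
    stop("malformed MRC header: implausible dimensions")
  if (!all(sort(h$axes) == 1:3))
    stop("malformed MRC header: MAPC/MAPR/MAPS is not a permutation of 1..3")
  if (any(h$m <= 0)) stop("malformed MRC header: non-positive sampling MX/MY/MZ")
  nvox <- as.double(h$nc) * h$nr * h$ns
  if (h$nsymbt > 0) invisible(readBin(con, "raw", n = h$nsymbt))
  data <- switch(as.character(h$mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = nvox, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = FALSE, endian = "little")),
    stop("unsupported MRC mode ", h$mode))
  if (length(data) < nvox)
    stop("truncated MRC file: expected ", nvox, " voxels, read ", length(data))
  arr <- array(data, dim = c(h$nc, h$nr, h$ns))
  perm <- match(1:3, h$axes)           # file-axis position of x, y, z
  grid <- aperm(arr, perm)
  voxel <- h$cella / h$m               # cell dimensions are along x, y, z
  nstart_xyz <- h$nstart[perm]
  origin_nstart <- nstart_xyz * voxel
  if (any(abs(h$origin) > 1e-6)) {
    if (any(nstart_xyz != 0L) &&
        any(abs(h$origin - origin_nstart) > 1e-3))
      warning("MRC ORIGIN record and start indices disagree; using ORIGIN")
    origin <- h$origin
  } else {
    origin <- origin_nstart
  }
  m <- density_map(grid, voxel, origin)
  m$axis_order <- h$axes
  attr(m, "source") <- list(path = path,
                            md5 = unname(tools::md5sum(path)))
  m
}

#' Write an MRC2014 density map
#'
#' Emits mode-2 (float32) data with recomputed statistics fields. The axis
#' order of the emitted file and the origin convention are configurable,
#' mainly to exercise interoperability with the dialects found in the wild;
#' the defaults write (x, y, z) order with an ORIGIN record.
#'
#' @param map a \code{density_map}.
#' @param path output file path.
#' @param axis_order permutation of 1:3 giving the map axes stored as file
#'   columns, rows and sections (MAPC/MAPR/MAPS).
#' @param origin_convention "origin" writes the ORIGIN record; "nstart"
#'   writes start indices instead (requires the origin to be an integer
#'   multiple of the voxel size).
#' @export
write_map <- function(map, path, axis_order = c(1L, 2L, 3L),
                      origin_convention = c("origin", "nstart")) {
  stopifnot(inherits(map, "density_map"))
  origin_convention <- match.arg(origin_convention)
  if (!all(sort(axis_order) == 1:3)) stop("axis_order must permute 1:3")
  d <- dim(map$grid)
  if (prod(d) == 0L) stop("refusing to write an empty map")
  st <- .map_stats(map$grid)
  nstart <- c(0L, 0L, 0L)
  orig_rec <- map$origin
  if (origin_convention == "nstart") {
    ns <- map$origin / map$voxel
    if (any(abs(ns - round(ns)) > 1e-4))
      stop("origin is not an integer multiple of voxel size; ",
           "cannot use the nstart convention")
    nstart <- as.integer(round(ns))
    orig_rec <- c(0, 0, 0)
  }
  arr <- aperm(map$grid, axis_order)
  con <- file(path, "wb")
  on.exit(close(con))
  w_int <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_flt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_int(dim(arr))                       # NC, NR, NS
  w_int(2L)                             # mode: float32
  w_int(nstart[axis_order])             # start indices, file axis order
  w_int(d)                              # MX, MY, MZ (along x, y, z)
  w_flt(d * map$voxel)                  # CELLA
  w_flt(c(90, 90, 90))                  # CELLB
  w_int(axis_order)                     # MAPC, MAPR, MAPS
  w_flt(c(st$min, st$max, st$mean))
  w_int(c(1L, 0L))                      # ISPG (volume), NSYMBT
  w_int(integer(25L))                   # extra
  w_flt(orig_rec)                       # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian MACHST
  w_flt(st$rms)
  w_int(1L)                             # NLABL
  lab <- charToRaw(formatC("created by ribomethscore", width = -80L))
  writeBin(c(lab, raw(800L - length(lab))), con)
  w_flt(as.vector(arr))
  invisible(NULL)
}

#' Interpolated map value at arbitrary positions
#'
#' Evaluates the map by trilinear interpolation of the eight voxels
#' surrounding each query position. Trilinear interpolation reproduces grid
#' node values exactly and is exact everywhere for affine fields. Positions
#' outside the interpolable domain (the box spanned by the outermost grid
#' nodes) are flagged and given value 0.
#'
#' @param map a \code{density_map}.
#' @param position numeric 3-vector, or an n x 3 matrix of positions, in
#'   Angstrom.
#' @return list with numeric vector \code{value} and logical vector
#'   \code{inside_grid}, one element per query position.
#' @export
map_value_at <- function(map, position) {
  p <- if (is.matrix(position)) position else matrix(position, nrow = 1L)
  stopifnot(ncol(p) == 3L)
  n <- dim(map$grid)
  f <- sweep(sweep(p, 2L, map$origin, "-"), 2L, map$voxel, "/")
  inside <- f[, 1L] >= 0 & f[, 1L] <= n[1L] - 1 &
            f[, 2L] >= 0 & f[, 2L] <= n[2L] - 1 &
            f[, 3L] >= 0 & f[, 3L] <= n[3L] - 1
  ix <- pmax(pmin(floor(f[, 1L]), n[1L] - 2), 0)
  iy <- pmax(pmin(floor(f[, 2L]), n[2L] - 2), 0)
  iz <- pmax(pmin(floor(f[, 3L]), n[3L] - 2), 0)
  tx <- f[, 1L] - ix; ty <- f[, 2L] - iy; tz <- f[, 3L] - iz
  g <- map$grid
  v <- numeric(nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) tx else 1 - tx) *
         (if (dy) ty else 1 - ty) *
         (if (dz) tz else 1 - tz)
    v <- v + w * g[cbind(ix + dx + 1, iy + dy + 1, iz + dz + 1)]
  }
  v[!inside] <- 0
  list(value = v, inside_grid = inside)
}

#' Average map value over a chain
#'
#' Unweighted mean of the interpolated map value over the chain's heavy
#' atoms that lie inside the grid, mirroring per-chain average map values as
#' a coarse fit diagnostic.
#'
#' @param map a \code{density_map}.
#' @param model an \code{atomic_model}.
#' @param chain_id chain identifier.
#' @return scalar mean map value, with attribute \code{n_excluded} giving
#'   the number of heavy atoms that fell outside the grid.
#' @export
chain_average_map_value <- function(map, model, chain_id) {
  a <- model$atoms
  sel <- a$chain == chain_id & toupper(a$element) != "H"
  if (!any(sel)) stop("chain '", chain_id, "' not found or has no heavy atoms")
  mv <- map_value_at(map, as.matrix(a[sel, c("x", "y", "z")]))
  if (!any(mv$inside_grid))
    stop("all atoms of chain '", chain_id, "' lie outside the map")
  out <- mean(mv$value[mv$inside_grid])
  attr(out, "n_excluded") <- sum(!mv$inside_grid)
  out
}
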