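#' Density grid container
#'
#' A 3D scalar density field on a regular orthogonal grid. Voxel
#' `values[i, j, k]` (1-based R indices) sits at physical position
#' `origin + (c(i, j, k) - 1) * spacing`, all in Angstrom. Values are
#' non-negative; the main-chain tracing method assumes non-negative density.
#'
#' @param values 3D numeric array of densities.
#' @param origin length-3 numeric, position of voxel (1,1,1) in Angstrom.
#' @param spacing length-3 numeric (or scalar), voxel pitch in Angstrom.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(values, origin = c(0, 0, 0), spacing = c(1, 1, 1)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(origin) == 3L, length(spacing) == 3L, all(spacing > 0),
            all(is.finite(values)))
  if (any(values < 0)) values[values < 0] <- 0
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("density_grid:", paste(d, collapse = " x "), "voxels\n")
  cat("  origin  (A):", format(x$origin, digits = 4), "\n")
  cat("  spacing (A):", format(x$spacing, digits = 4), "\n")
  cat("  density    : min", format(min(x$values), digits = 4),
      " max", format(max(x$values), digits = 4), "\n")
  invisible(x)
}

# physical position of 1-based voxel indices (n x 3 matrix or length-3 vector)
voxel_position <- function(grid, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Read an MRC2014/CCP4 density map
#'
#' Parses the 1024-byte MRC header plus mode-2 (float32) data. The axis order
#' recorded in the MAPC/MAPR/MAPS words is normalized so that the returned
#' array is indexed (x, y, z). The ORIGIN header record is honored when
#' nonzero, otherwise the origin is derived from NXSTART/NYSTART/NZSTART and
#' the voxel spacing (EMDB practice). Negative densities are clamped to zero.
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [density_grid()].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_i <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nxyz <- hdr_i[1:3]
  mode <- hdr_i[4]
  nstart <- hdr_i[5:7]
  mxyz <- hdr_i[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little")) # dmin/dmax/dmean
  invisible(readBin(con, "integer", n = 2, size = 4, endian = "little")) # ispg, nsymbt
  invisible(readBin(con, "integer", n = 25, size = 4, endian = "little")) # extra
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  map_stamp <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", n = 1, size = 4, endian = "little")) # machst
  invisible(readBin(con, "numeric", n = 1, size = 4, endian = "little")) # rms
  invisible(readBin(con, "integer", n = 1, size = 4, endian = "little")) # nlabl
  invisible(readBin(con, "raw", n = 800))
  if (any(nxyz < 1) || any(mxyz < 1) || !all(mapcrs %in% 1:3) ||
      anyDuplicated(mapcrs))
    stop("malformed MRC header in ", path)
  if (!(mode %in% c(0L, 1L, 2L)))
    stop("unsupported MRC mode ", mode, " (only 0, 1, 2)")
  if (any(abs(cellb - 90) > 1e-3))
    stop("non-orthogonal unit cell is not supported")
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(vals) != n) stop("truncated MRC data in ", path)
  arr <- array(vals, dim = nxyz)                 # file order: mapc fastest
  perm <- match(1:3, mapcrs)                     # file dim holding axis x,y,z
  arr <- aperm(arr, perm)
  cell_axes <- if (all(cella > 0)) cella else mxyz # fall back to unit spacing
  spacing <- cell_axes / mxyz                    # cell axes are x,y,z
  if (any(abs(orig) > 0)) {
    origin <- orig
  } else {
    origin <- nstart[perm] * spacing
  }
  density_grid(arr, origin = origin, spacing = spacing)
}

#' Write a density grid as an MRC2014 map
#'
#' Writes mode-2 (float32) data in x,y,z axis order with the ORIGIN record
#' set, the dialect used by EMDB depositions.
#'
#' @param grid a [density_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(d * grid$spacing, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  v <- grid$values
  writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")
  writeBin(integer(25), con, size = 4, endian = "little")
  writeBin(as.numeric(grid$origin), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  writeBin(as.numeric(sd(as.vector(v))), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(as.vector(v)), con, size = 4, endian = "little")
  invisible(path)
}

#' Select seed points above a density threshold
#'
#' Returns every grid point with density at or above `phi_thr`; these are the
#' initial seed points of the mean-shift stage.
#'
#' @param grid a [density_grid()].
#' @param phi_thr non-negative density threshold.
#' @return A data frame with 1-based voxel indices (`ix`,`iy`,`iz`), physical
#'   coordinates (`x`,`y`,`z`, Angstrom) and density `phi`.
#' @export
threshold_grid <- function(grid, phi_thr) {
  stopifnot(inherits(grid, "density_grid"), phi_thr >= 0)
  sel <- which(grid$values >= phi_thr, arr.ind = TRUE)
  if (nrow(sel) == 0L)
    stop("no voxel passes the density threshold ", phi_thr,
         call. = FALSE)
  pos <- voxel_position(grid, sel)
  data.frame(ix = sel[, 1], iy = sel[, 2], iz = sel[, 3],
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             phi = grid$values[sel])
}

#' Zero density outside a zone around a model
#'
#' Keeps only voxels within `radius` of any atom of `model`; a simple
#' distance-based stand-in for interactive single-subunit segmentation.
#'
#' @param grid a [density_grid()].
#' @param model an [atomic_model()].
#' @param radius zone radius in Angstrom.
#' @return A masked [density_grid()].
#' @export
zone_mask <- function(grid, model, radius) {
  stopifnot(inherits(grid, "density_grid"), radius > 0)
  xyz <- model_coords(model)
  d <- dim(grid$values)
  keep <- array(FALSE, dim = d)
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    lo <- pmax(1, ceiling((p - radius - grid$origin) / grid$spacing) + 1)
    hi <- pmin(d, floor((p + radius - grid$origin) / grid$spacing) + 1)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx2 <- (grid$origin[1] + (ii - 1) * grid$spacing[1] - p[1])^2
    dy2 <- (grid$origin[2] + (jj - 1) * grid$spacing[2] - p[2])^2
    dz2 <- (grid$origin[3] + (kk - 1) * grid$spacing[3] - p[3])^2
    ball <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
    keep[ii, jj, kk] <- keep[ii, jj, kk] | ball
  }
  out <- grid
  out$values[!keep] <- 0
  out
}
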