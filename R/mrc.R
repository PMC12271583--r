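#' Read an MRC2014 density map
#'
#' Reads a deposited-map style MRC file (modes 0, 1, 2) into a [voxel_grid()],
#' normalizing the two dialect axes of the format:
#'
#' * **Axis order**: the `mapc`/`mapr`/`maps` header words declare which
#'   physical axis varies fastest on disk. The value array is permuted so the
#'   in-memory layout is always `[i, j, k] = [z, y, x]` regardless of how the
#'   file was stored.
#' * **Origin**: the MRC2014 `ORIGIN` record wins when any component is
#'   nonzero; otherwise the origin is reconstructed from the start-index words
#'   (`nxstart` etc.) times the voxel size -- the common split between modern
#'   EMDB depositions and legacy CCP4-style files.
#'
#' Voxel sizes are `cella / (mx, my, mz)`. Little-endian files only (the EMDB
#' convention).
#'
#' @param path path to an MRC file.
#' @param origin_dialect `"auto"` (default rule above), `"header"` (always use
#'   the ORIGIN record) or `"nstart"` (always use start indices).
#' @return A [voxel_grid()]; the raw header fields are attached as the
#'   `"mrc_header"` attribute (a named list).
#' @seealso [write_mrc()]
#' @export
read_mrc <- function(path, origin_dialect = c("auto", "header", "nstart")) {
  origin_dialect <- match.arg(origin_dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  int_words <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  names(int_words) <- c("nx", "ny", "nz", "mode", "nxstart", "nystart",
                        "nzstart", "mx", "my", "mz")
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  cellb <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  dstats <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  ispg <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  invisible(readBin(con, "raw", n = 100L)) # extra words 26-49
  origin_rec <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  map_tag <- rawToChar(readBin(con, "raw", n = 4L))
  machst <- readBin(con, "raw", n = 4L)
  rms <- readBin(con, "numeric", n = 1L, size = 4L, endian = "little")
  nlabl <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  invisible(readBin(con, "raw", n = 800L))

  if (!identical(substr(map_tag, 1, 3), "MAP")) {
    stop("not an MRC2014 file (MAP signature missing) in: ", path,
         call. = FALSE)
  }
  nx <- int_words[["nx"]]; ny <- int_words[["ny"]]; nz <- int_words[["nz"]]
  if (any(c(nx, ny, nz) <= 0L)) {
    stop("MRC header field nx/ny/nz must be positive", call. = FALSE)
  }
  mode <- int_words[["mode"]]
  if (!mode %in% c(0L, 1L, 2L)) {
    stop("unsupported MRC header field `mode` = ", mode,
         " (modes 0, 1, 2 supported)", call. = FALSE)
  }
  if (any(cella <= 0)) {
    stop("MRC header field `cella` must be positive", call. = FALSE)
  }
  if (any(sort(mapcrs) != 1:3)) {
    stop("MRC header fields mapc/mapr/maps must be a permutation of 1..3",
         call. = FALSE)
  }
  if (nsymbt > 0L) invisible(readBin(con, "raw", n = nsymbt))

  n_vox <- as.numeric(nx) * ny * nz
  raw_vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n_vox, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n_vox, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n_vox, size = 4L, endian = "little")
  )
  if (length(raw_vals) < n_vox) {
    stop("truncated MRC data section: expected ", n_vox, " voxels, got ",
         length(raw_vals), call. = FALSE)
  }
  # on-disk layout: column axis fastest -> dims (ncol, nrow, nsec)
  arr_crs <- array(as.numeric(raw_vals), dim = c(nx, ny, nz))

  # stored axis s holds physical axis mapcrs[s]; we want (z, y, x)
  perm <- match(3:1, mapcrs)
  values <- aperm(arr_crs, perm)

  mxyz <- int_words[c("mx", "my", "mz")]
  if (any(mxyz <= 0L)) {
    stop("MRC header fields mx/my/mz must be positive", call. = FALSE)
  }
  voxel <- cella / mxyz # per physical axis x, y, z

  nstart_crs <- int_words[c("nxstart", "nystart", "nzstart")]
  nstart_xyz <- nstart_crs[match(1:3, mapcrs)] # physical-axis order
  origin_nstart <- nstart_xyz * voxel
  origin <- switch(origin_dialect,
    header = origin_rec,
    nstart = origin_nstart,
    auto = if (any(origin_rec != 0)) origin_rec else origin_nstart
  )

  grid <- voxel_grid(values, origin = origin, voxel = voxel)
  attr(grid, "mrc_header") <- list(
    nx = nx, ny = ny, nz = nz, mode = mode,
    nstart = unname(nstart_crs), m = unname(mxyz), cella = cella,
    cellb = cellb, mapcrs = mapcrs,
    dmin = dstats[1], dmax = dstats[2], dmean = dstats[3],
    ispg = ispg, nsymbt = nsymbt, origin = origin_rec, rms = rms,
    machst = machst, nlabl = nlabl
  )
  grid
}

#' Write a voxel grid as an MRC2014 file
#'
#' Writes mode-2 (32-bit float) MRC with canonical axis order (x fastest,
#' `mapc/mapr/maps = 1/2/3`), `cell = dims * voxel`, the ORIGIN record
#' populated from the grid origin, and the min/max/mean/rms statistics words
#' recomputed from the payload. Label maps holding small integers can be
#' stored as mode 0 (signed 8-bit) with `mode = 0`. Output is byte-wise
#' deterministic: no timestamps are written.
#'
#' @param grid a [voxel_grid()].
#' @param path output path.
#' @param mode 2 (float32, default) or 0 (int8; values must be integral and
#'   within -128..127).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path, mode = 2L) {
  stopifnot_grid(grid)
  mode <- as.integer(mode)
  if (!mode %in% c(0L, 2L)) stop("write modes supported: 0, 2", call. = FALSE)
  v <- grid$values
  if (mode == 0L) {
    if (any(v != round(v)) || min(v) < -128 || max(v) > 127) {
      stop("mode 0 requires integral values in [-128, 127]", call. = FALSE)
    }
  }
  d_xyz <- grid_dims_xyz(grid) # (nx, ny, nz)
  con <- file(path, "wb")
  on.exit(close(con))

  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  wi(d_xyz) # nx ny nz
  wi(mode)
  wi(c(0L, 0L, 0L)) # nstart
  wi(d_xyz) # mx my mz
  wf(d_xyz * grid$voxel) # cella
  wf(c(90, 90, 90)) # cellb
  wi(1:3) # mapc mapr maps
  wf(c(min(v), max(v), mean(v))) # dmin dmax dmean
  wi(1L) # ispg (3-D volume)
  wi(0L) # nsymbt
  writeBin(raw(100L), con) # extra
  wf(grid$origin) # ORIGIN x y z
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con) # little-endian machst
  wf(sqrt(mean((v - mean(v))^2))) # rms
  wi(1L) # nlabl
  lab <- charToRaw(sprintf("%-80s", "cryolabel voxel grid"))
  writeBin(c(lab, raw(720L)), con)

  # canonical layout: x fastest -> permute (i,j,k)=(z,y,x) to (x,y,z)
  arr_xyz <- aperm(v, c(3L, 2L, 1L))
  if (mode == 2L) {
    writeBin(as.numeric(arr_xyz), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(arr_xyz), con, size = 1L)
  }
  invisible(path)
}
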