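#' Read and write 3D volumes
#'
#' Two storage layouts are supported:
#' \describe{
#'   \item{raw + sidecar}{a flat binary block (`.raw`) of voxels in grid
#'     order (x fastest) plus a JSON sidecar `<path>.json` carrying shape,
#'     dtype, byte order, voxel size and axis labels.}
#'   \item{TIFF}{a multipage greyscale TIFF (uncompressed, little-endian;
#'     dtypes uint8, uint16, float32), one page per z-slice, or a directory
#'     of single-page TIFFs (one per slice, stacked in lexicographic
#'     order). TIFF carries no voxel size, so a JSON sidecar `<path>.json`
#'     (or `meta.json` inside a slice directory) is written alongside and
#'     required on read; a missing voxel size is an error, never a silent
#'     default.}
#' }
#' Round-tripping through either layout is lossless for the supported
#' dtypes. Masks are stored as uint8 with values 0/255.
#'
#' @param x a `volume3d` or `mask3d`.
#' @param path file path (`.raw`, `.tif`/`.tiff`) or directory.
#' @param format `"auto"` (from extension), `"raw"`, or `"tiff"`.
#' @param dtype storage dtype: `"uint8"`, `"uint16"`, `"float32"`,
#'   `"float64"` (raw only). Default `"float32"`, or `"uint8"` for masks.
#' @return `read_volume` returns a `volume3d` (or `mask3d` if the sidecar
#'   declares `kind: "mask"`); `write_volume` returns `path`, invisibly.
#' @export
write_volume <- function(x, path, format = c("auto", "raw", "tiff"),
                         dtype = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_path(path)
  is_mask <- inherits(x, "mask3d")
  if (is.null(dtype)) dtype <- if (is_mask) "uint8" else "float32"
  arr <- if (is_mask) array(ifelse(x$data, 255, 0), dim(x$data)) else x$data
  meta <- list(shape = dim(arr), dtype = dtype, byte_order = "little",
               voxel_size_um = x$voxel_size, axes = x$axes,
               kind = if (is_mask) "mask" else "volume")
  if (format == "raw") {
    con <- file(path, "wb"); on.exit(close(con))
    write_raw_block(arr, con, dtype)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  } else {
    if (dtype == "float64") stop("TIFF storage supports uint8/uint16/float32")
    write_tiff_pages(arr, path, dtype)
    jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param voxel_size optional voxel size (micrometres) overriding/replacing
#'   sidecar metadata, for files produced elsewhere.
#' @export
read_volume <- function(path, format = c("auto", "raw", "tiff"),
                        voxel_size = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "tiff" else format_from_path(path)
  meta <- read_sidecar(path)
  if (is.null(voxel_size)) voxel_size <- meta$voxel_size_um
  if (is.null(voxel_size))
    stop("no voxel size: provide a JSON sidecar with `voxel_size_um` or ",
         "pass `voxel_size` explicitly")
  axes <- if (!is.null(meta$axes)) unlist(meta$axes) else c("x", "y", "z")
  if (format == "raw") {
    if (is.null(meta)) stop("raw volume requires a JSON sidecar: ",
                            sidecar_path(path))
    shape <- as.integer(unlist(meta$shape))
    arr <- read_raw_block(path, shape, meta$dtype)
  } else if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("no TIFF slices in directory ", path)
    slices <- lapply(files, function(f) read_tiff_pages(f))
    slices <- do.call(c, slices)
    arr <- array(do.call(c, lapply(slices, as.vector)),
                 c(dim(slices[[1]]), length(slices)))
  } else {
    pages <- read_tiff_pages(path)
    arr <- array(do.call(c, lapply(pages, as.vector)),
                 c(dim(pages[[1]]), length(pages)))
  }
  if (!is.null(meta$shape) && !identical(as.integer(unlist(meta$shape)),
                                         dim(arr)))
    stop("sidecar shape does not match file contents")
  if (identical(meta$kind, "mask"))
    mask3d(arr > 0, voxel_size, axes, provenance = "read_volume")
  else
    volume3d(arr, voxel_size, axes)
}

format_from_path <- function(path) {
  if (grepl("\\.raw$", path)) "raw"
  else if (grepl("\\.tiff?$", path)) "tiff"
  else stop("cannot infer format from path ", path,
            " (use .raw or .tif/.tiff, or pass `format`)")
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- if (dir.exists(path)) file.path(path, "meta.json") else sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp) else NULL
}

dtype_info <- function(dtype) {
  switch(dtype,
         uint8   = list(size = 1L, what = "integer", signed = FALSE, fmt = 1L),
         uint16  = list(size = 2L, what = "integer", signed = FALSE, fmt = 1L),
         float32 = list(size = 4L, what = "double",  signed = TRUE,  fmt = 3L),
         float64 = list(size = 8L, what = "double",  signed = TRUE,  fmt = 3L),
         stop("unsupported dtype: ", dtype))
}

write_raw_block <- function(arr, con, dtype) {
  di <- dtype_info(dtype)
  v <- as.vector(arr)
  if (di$what == "integer") {
    rng <- switch(dtype, uint8 = 255, uint16 = 65535)
    if (any(v < 0 | v > rng)) stop("values out of range for ", dtype)
    writeBin(as.integer(round(v)), con, size = di$size, endian = "little")
  } else {
    writeBin(as.double(v), con, size = di$size, endian = "little")
  }
}

read_raw_block <- function(path, shape, dtype) {
  di <- dtype_info(dtype)
  n <- prod(shape)
  expected <- n * di$size
  if (file.size(path) != expected)
    stop(sprintf("raw block size %d does not match sidecar shape (%d bytes)",
                 file.size(path), expected))
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, di$what, n = n, size = di$size, signed = di$signed,
               endian = "little")
  array(v, shape)
}

# ---- minimal TIFF codec ----------------------------------------------------
# Baseline greyscale TIFF, little-endian, uncompressed, one strip per page.
# There is no TIFF library in the supported R toolchain, hence this narrow
# hand-rolled subset; it is not a general-purpose TIFF reader.

write_tiff_pages <- function(arr, path, dtype) {
  di <- dtype_info(dtype)
  d <- dim(arr)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  page_bytes <- nx * ny * di$size
  n_tags <- 9L
  ifd_bytes <- 2L + 12L * n_tags + 4L
  data_off <- 8L + (0:(nz - 1L)) * page_bytes
  ifd_off <- 8L + nz * page_bytes + (0:(nz - 1L)) * ifd_bytes
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off[1], con, size = 4, endian = "little")
  for (k in seq_len(nz))
    write_raw_block(arr[, , k, drop = TRUE], con, dtype)
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT in a 4-byte field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  for (k in seq_len(nz)) {
    writeBin(n_tags, con, size = 2, endian = "little")
    tag(256, 4, 1, nx)                 # ImageWidth
    tag(257, 4, 1, ny)                 # ImageLength
    tag(258, 3, 1, di$size * 8L)       # BitsPerSample
    tag(259, 3, 1, 1)                  # Compression: none
    tag(262, 3, 1, 1)                  # Photometric: BlackIsZero
    tag(273, 4, 1, data_off[k])        # StripOffsets
    tag(278, 4, 1, ny)                 # RowsPerStrip
    tag(279, 4, 1, page_bytes)         # StripByteCounts
    tag(339, 3, 1, di$fmt)             # SampleFormat
    writeBin(if (k < nz) ifd_off[k + 1] else 0L, con, size = 4,
             endian = "little")
  }
  invisible(path)
}

read_tiff_pages <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw_all[off + 1:4]) *
                             c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II")
    stop("only little-endian ('II') TIFF is supported")
  if (u16(2) != 42) stop("not a TIFF file")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n_tags <- u16(ifd)
    tags <- list()
    for (t in seq_len(n_tags)) {
      off <- ifd + 2 + (t - 1) * 12
      id <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      tsize <- c(1, 1, 2, 4)[min(type, 4)]
      val_off <- off + 8
      if (count * tsize > 4) val_off <- u32(off + 8)
      rd <- if (type == 3) u16 else u32
      vals <- vapply(seq_len(count) - 1,
                     function(i) rd(val_off + i * tsize), numeric(1))
      tags[[as.character(id)]] <- vals
    }
    need <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF tag ", id, " missing")
        default
      } else v
    }
    if (need(259, 1) != 1) stop("compressed TIFF is not supported")
    nx <- need(256); ny <- need(257)
    bits <- need(258); fmt <- need(339, 1)
    if (need(277, 1) != 1) stop("multi-sample TIFF is not supported")
    offs <- need(273); counts <- need(279)
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw_all[offs[s] + seq_len(counts[s])])
    what <- if (fmt == 3) "double" else "integer"
    v <- readBin(buf, what, n = nx * ny, size = bits / 8,
                 signed = (fmt != 1), endian = "little")
    pages[[length(pages) + 1]] <- matrix(v, nrow = nx, ncol = ny)
    ifd <- u32(ifd + 2 + n_tags * 12)
  }
  pages
}
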