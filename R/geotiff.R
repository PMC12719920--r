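# Minimal GeoTIFF I/O: uncompressed strip layout, float32 samples on write,
# uint/int/float 8-64 bit on read, with the three geo tags
# (ModelPixelScale, ModelTiepoint, GeoKeyDirectory) and the GDAL nodata tag.
# Supports single- and multi-band (chunky interleave) files, both byte orders
# on read; writes little-endian.

TIFF_TAG <- list(width = 256L, height = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, strip_offsets = 273L, samples = 277L,
                 rows_per_strip = 278L, strip_bytes = 279L, planar = 284L,
                 sample_format = 339L, pixel_scale = 33550L, tiepoint = 33922L,
                 geo_keys = 34735L, nodata = 42113L)

crs_epsg <- function(crs_id) {
  m <- regmatches(crs_id, regexpr("[0-9]+$", crs_id))
  if (!length(m)) stop("crs_id must carry an EPSG code, e.g. 'EPSG:32614'")
  as.integer(m)
}

# EPSG geographic (degree) ranges: 4000-4999 plus a few common ones
epsg_is_geographic <- function(code) code >= 4000L && code < 5000L

#' Write a grid to a GeoTIFF file
#'
#' Single-band, 32-bit float, uncompressed, with pixel scale, tiepoint,
#' geo-key and nodata tags so the file round-trips through standard GIS
#' readers. NA cells are stored as the grid's nodata sentinel.
#'
#' @param grid A `wep_grid`.
#' @param path Output path.
#' @export
write_grid <- function(grid, path) {
  write_bands(list(grid), path)
}

#' Write multiple co-registered grids as one multi-band GeoTIFF
#'
#' @param grids List of `wep_grid` sharing geometry; band order is list order.
#' @param path Output path.
#' @export
write_bands <- function(grids, path) {
  stopifnot(length(grids) >= 1)
  g <- grids[[1]]
  for (b in grids[-1]) stop_geometry(g, b, "bands")
  h <- nrow(g$values); w <- ncol(g$values); ns <- length(grids)
  epsg <- crs_epsg(g$crs_id)
  model_type <- if (epsg_is_geographic(epsg)) 2L else 1L

  # pixel data, chunky interleave, row-major
  arr <- array(0, dim = c(ns, w, h))
  for (b in seq_len(ns)) {
    v <- grids[[b]]$values
    v[is.na(v)] <- g$nodata
    arr[b, , ] <- t(v)
  }
  pix <- as.numeric(arr)

  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  data_off <- 8L
  pix_bytes <- length(pix) * 4L
  nodata_str <- sprintf("%.10g", g$nodata)
  nodata_raw <- c(charToRaw(nodata_str), as.raw(0))
  # keep the ASCII payload > 4 bytes so it always lives at an offset (the
  # IFD writer below stores offsets, not inlined values, for this tag)
  if (length(nodata_raw) <= 4)
    nodata_raw <- c(nodata_raw, rep(as.raw(0), 5 - length(nodata_raw)))

  # geo key directory: version, rev, minor, nkeys; then 4-short key entries
  geo_key_id <- if (model_type == 1L) 3072L else 2048L
  geo_keys <- c(1L, 1L, 0L, 3L,
                1024L, 0L, 1L, model_type,   # GTModelType
                1025L, 0L, 1L, 1L,           # GTRasterType = PixelIsArea
                geo_key_id, 0L, 1L, epsg)

  # out-of-line payload offsets (after pixel data)
  off <- function(prev, bytes) prev + bytes
  o_scale <- data_off + pix_bytes
  o_tie <- o_scale + 3L * 8L
  o_geo <- o_tie + 6L * 8L
  o_nodata <- o_geo + length(geo_keys) * 2L
  o_bits <- o_nodata + length(nodata_raw)
  need_bits_off <- ns > 2L
  need_fmt_off <- ns > 2L
  o_fmt <- o_bits + (if (need_bits_off) 2L * ns else 0L)
  o_ifd <- o_fmt + (if (need_fmt_off) 2L * ns else 0L)
  if (o_ifd %% 2L == 1L) o_ifd <- o_ifd + 1L

  # header
  writeBin(charToRaw("II"), con)
  wr2(42L); wr4(o_ifd)
  # pixel data (float32)
  writeBin(pix, con, size = 4, endian = "little")
  # payloads
  writeBin(c(g$cell_size, g$cell_size, 0), con, size = 8, endian = "little")
  writeBin(c(0, 0, 0, g$origin[1], g$origin[2], 0), con, size = 8,
           endian = "little")
  wr2(geo_keys)
  writeBin(nodata_raw, con)
  if (need_bits_off) wr2(rep(32L, ns))
  if (need_fmt_off) wr2(rep(3L, ns))
  pos <- o_fmt + (if (need_fmt_off) 2L * ns else 0L)
  if (pos %% 2L == 1L) writeBin(as.raw(0), con)

  # IFD
  entry <- function(tag, type, count, value) {
    wr2(tag); wr2(type); wr4(count)
    if (type == 3L && count <= 2L) {        # shorts packed into 4 bytes
      wr2(c(value, rep(0L, 2L - count)))
    } else {
      wr4(value)
    }
  }
  tags <- list(
    list(TIFF_TAG$width, 3L, 1L, w),
    list(TIFF_TAG$height, 3L, 1L, h),
    list(TIFF_TAG$bits, 3L, ns, if (need_bits_off) o_bits else rep(32L, ns)),
    list(TIFF_TAG$compression, 3L, 1L, 1L),
    list(TIFF_TAG$photometric, 3L, 1L, 1L),
    list(TIFF_TAG$strip_offsets, 4L, 1L, data_off),
    list(TIFF_TAG$samples, 3L, 1L, ns),
    list(TIFF_TAG$rows_per_strip, 3L, 1L, h),
    list(TIFF_TAG$strip_bytes, 4L, 1L, pix_bytes),
    list(TIFF_TAG$planar, 3L, 1L, 1L),
    list(TIFF_TAG$sample_format, 3L, ns,
         if (need_fmt_off) o_fmt else rep(3L, ns)),
    list(TIFF_TAG$pixel_scale, 12L, 3L, o_scale),
    list(TIFF_TAG$tiepoint, 12L, 6L, o_tie),
    list(TIFF_TAG$geo_keys, 3L, length(geo_keys), o_geo),
    list(TIFF_TAG$nodata, 2L, length(nodata_raw), o_nodata)
  )
  wr2(length(tags))
  for (tg in tags) entry(tg[[1]], tg[[2]], tg[[3]], tg[[4]])
  wr4(0L)  # next IFD
  invisible(path)
}

# parse the first IFD of a TIFF file into a tag table plus raw bytes
parse_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop(sprintf("unreadable TIFF: %s", path))
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop(sprintf("unreadable TIFF (bad byte order): %s", path)))
  rd <- function(at, n, size, what = "integer", signed = TRUE)
    readBin(raw[(at + 1):(at + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  magic <- rd(2, 1, 2, signed = FALSE)
  if (magic != 42) stop(sprintf("unreadable TIFF (bad magic): %s", path))
  ifd_off <- rd(4, 1, 4)
  n_entries <- rd(ifd_off, 1, 2, signed = FALSE)
  type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  tags <- list()
  for (i in seq_len(n_entries)) {
    at <- ifd_off + 2 + (i - 1) * 12
    tag <- rd(at, 1, 2, signed = FALSE)
    type <- rd(at + 2, 1, 2, signed = FALSE)
    count <- rd(at + 4, 1, 4)
    nbytes <- type_size[type] * count
    voff <- if (nbytes <= 4) at + 8 else rd(at + 8, 1, 4)
    val <- switch(as.character(type),
      "1" = rd(voff, count, 1, signed = FALSE),
      "2" = {
        s <- raw[(voff + 1):(voff + count)]
        rawToChar(s[s != as.raw(0)])
      },
      "3" = rd(voff, count, 2, signed = FALSE),
      "4" = rd(voff, count, 4),
      "8" = rd(voff, count, 2),
      "9" = rd(voff, count, 4),
      "11" = rd(voff, count, 4, what = "numeric"),
      "12" = rd(voff, count, 8, what = "numeric"),
      NULL)
    tags[[as.character(tag)]] <- val
  }
  list(tags = tags, raw = raw, endian = endian)
}

tiff_tag <- function(p, id, default = NULL) {
  v <- p$tags[[as.character(id)]]
  if (is.null(v)) default else v
}

# read every band of a GeoTIFF into a list of matrices + geometry metadata
read_tiff_bands <- function(path) {
  if (!file.exists(path)) stop(sprintf("unreadable file: %s", path))
  p <- parse_tiff(path)
  w <- tiff_tag(p, TIFF_TAG$width); h <- tiff_tag(p, TIFF_TAG$height)
  if (is.null(w) || is.null(h)) stop(sprintf("unreadable TIFF: %s", path))
  comp <- tiff_tag(p, TIFF_TAG$compression, 1L)
  if (comp != 1L) stop("only uncompressed TIFF strips are supported")
  ns <- tiff_tag(p, TIFF_TAG$samples, 1L)
  planar <- tiff_tag(p, TIFF_TAG$planar, 1L)
  if (planar != 1L && ns > 1L) stop("only chunky (interleaved) TIFF supported")
  bits <- tiff_tag(p, TIFF_TAG$bits, 1L)[1]
  fmt <- tiff_tag(p, TIFF_TAG$sample_format, 1L)[1]
  offs <- tiff_tag(p, TIFF_TAG$strip_offsets)
  cnts <- tiff_tag(p, TIFF_TAG$strip_bytes)
  size <- bits / 8
  what <- if (fmt == 3) "numeric" else "integer"
  signed <- fmt == 2 || bits >= 32
  vals <- numeric(0)
  for (i in seq_along(offs)) {
    seg <- p$raw[(offs[i] + 1):(offs[i] + cnts[i])]
    vals <- c(vals, readBin(seg, what, n = cnts[i] / size, size = size,
                            endian = p$endian, signed = signed))
  }
  arr <- array(vals, dim = c(ns, w, h))
  bands <- lapply(seq_len(ns), function(b) t(matrix(arr[b, , ], w, h)))

  # georeferencing
  scale <- tiff_tag(p, TIFF_TAG$pixel_scale)
  tie <- tiff_tag(p, TIFF_TAG$tiepoint)
  geo <- tiff_tag(p, TIFF_TAG$geo_keys)
  nd <- tiff_tag(p, TIFF_TAG$nodata)
  epsg <- NA_integer_; model_type <- NA_integer_
  if (!is.null(geo) && length(geo) >= 4) {
    nk <- geo[4]
    for (k in seq_len(nk)) {
      e <- geo[(4 * k + 1):(4 * k + 4)]
      if (e[1] == 1024) model_type <- e[4]
      if (e[1] %in% c(3072, 2048) && e[2] == 0) epsg <- e[4]
    }
  }
  list(bands = bands, width = w, height = h,
       cell_size = if (!is.null(scale)) scale[1] else NA_real_,
       origin = if (!is.null(tie) && length(tie) >= 5) tie[4:5] else c(NA, NA),
       model_type = model_type, epsg = epsg,
       nodata = if (!is.null(nd)) suppressWarnings(as.numeric(nd)) else NA)
}

#' Read one band of a GeoTIFF into a grid
#'
#' Refuses files in a geographic (degree-unit) reference system: every
#' computation in the pipeline assumes meter cells.
#'
#' @param path GeoTIFF path.
#' @param band 1-based band index.
#' @return A `wep_grid`; the file's nodata sentinel becomes `NA`.
#' @export
read_grid <- function(path, band = 1L) {
  t <- read_tiff_bands(path)
  if (!is.na(t$model_type) && t$model_type == 2L)
    stop(sprintf(paste0("file %s uses a geographic (degree-unit) reference ",
                        "system; reproject to a projected meter-unit CRS"),
                 path))
  if (band < 1 || band > length(t$bands))
    stop(sprintf("band %d out of range (file has %d)", band, length(t$bands)))
  v <- t$bands[[band]]
  nd <- t$nodata
  if (!is.na(nd)) v[abs(v - nd) < 1e-6 * max(1, abs(nd))] <- NA_real_
  cs <- if (is.na(t$cell_size)) 1 else t$cell_size
  org <- if (any(is.na(t$origin))) c(0, nrow(v) * cs) else t$origin
  crs <- if (is.na(t$epsg)) "EPSG:32614" else sprintf("EPSG:%d", t$epsg)
  grid_create(v, cs, org, crs, nodata = if (is.na(nd)) -9999 else nd)
}

#' Read all bands of a GeoTIFF
#'
#' @param path GeoTIFF path.
#' @return List of `wep_grid`, one per band.
#' @export
read_grid_bands <- function(path) {
  n <- length(read_tiff_bands(path)$bands)
  lapply(seq_len(n), function(b) read_grid(path, b))
}
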