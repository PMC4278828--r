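#' Read and write raster layers
#'
#' Two dialects are supported, chosen by `format` or inferred from the
#' file extension: ESRI ASCII grids (`.asc`; NCOLS/NROWS/XLLCORNER/
#' YLLCORNER/CELLSIZE/NODATA_value header) and single-band uncompressed
#' float32 GeoTIFF (`.tif`/`.tiff`; ModelPixelScale + ModelTiepoint
#' georeferencing, GDAL_NODATA tag honoured). Writing then reading a grid
#' round-trips values within float precision and masks exactly.
#'
#' Neither dialect carries enough CRS detail for reprojection; the package
#' only distinguishes projected-metric from geographic grids. GeoTIFFs
#' record that distinction in the GeoKey model-type; ASCII grids take it
#' from the `crs_kind` argument.
#'
#' @param path file path.
#' @param format `"geotiff"`, `"esri_ascii"`, or `NULL` to infer from the
#'   extension.
#' @param crs_kind CRS kind assumed for ASCII grids (which cannot store it).
#' @return `read_raster()` returns a [grid_layer()]; `write_raster()`
#'   returns `path` invisibly.
#' @export
read_raster <- function(path, format = NULL,
                        crs_kind = c("projected_metric", "geographic_degrees")) {
  crs_kind <- match.arg(crs_kind)
  format <- infer_format(path, format)
  if (!file.exists(path)) stop("raster file not found: ", path)
  switch(format,
         esri_ascii = read_esri_ascii(path, crs_kind),
         geotiff    = read_geotiff(path))
}

#' @rdname read_raster
#' @param grid a `grid_layer`.
#' @export
write_raster <- function(grid, path, format = NULL) {
  stopifnot(inherits(grid, "grid_layer"))
  format <- infer_format(path, format)
  ok <- switch(format,
               esri_ascii = write_esri_ascii(grid, path),
               geotiff    = write_geotiff(grid, path))
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) {
    return(match.arg(format, c("geotiff", "esri_ascii")))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "geotiff"
  else if (ext %in% c("asc", "txt")) "esri_ascii"
  else stop("cannot infer raster format from extension of ", path)
}

## ---- ESRI ASCII ----------------------------------------------------------

read_esri_ascii <- function(path, crs_kind) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("malformed ESRI ASCII header in ", path)
  hdr <- list()
  i <- 0
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  for (f in need) if (is.null(hdr[[f]]))
    stop("malformed ESRI ASCII header: missing field ", toupper(f), " in ", path)
  if (hdr$cellsize <= 0)
    stop("unsupported geometry: CELLSIZE must be > 0 in ", path)
  if (is.null(hdr$xllcorner)) {
    if (is.null(hdr$xllcenter))
      stop("malformed ESRI ASCII header: missing field XLLCORNER in ", path)
    hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  }
  if (is.null(hdr$yllcorner)) {
    if (is.null(hdr$yllcenter))
      stop("malformed ESRI ASCII header: missing field YLLCORNER in ", path)
    hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- paste(lines[(i + 1):length(lines)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  n <- hdr$nrows * hdr$ncols
  if (length(vals) != n)
    stop(sprintf("malformed ESRI ASCII body: expected %d values, found %d in %s",
                 n, length(vals), path))
  if (anyNA(vals))
    stop("malformed ESRI ASCII body: non-numeric token in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[abs(m - nodata) <= 1e-9 * max(1, abs(nodata))] <- NA_real_
  geom <- grid_geometry(hdr$nrows, hdr$ncols,
                        x_origin = hdr$xllcorner,
                        y_origin = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                        cell_size = hdr$cellsize, crs_kind = crs_kind)
  grid_layer(geom, m)
}

write_esri_ascii <- function(grid, path, nodata = -9999) {
  g <- grid$geometry
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("cannot write raster to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", g$n_cols),
    sprintf("NROWS %d", g$n_rows),
    sprintf("XLLCORNER %.10g", g$x_origin),
    sprintf("YLLCORNER %.10g", g$y_origin - g$n_rows * g$cell_size),
    sprintf("CELLSIZE %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)
  ), con)
  m <- grid$values
  m[is.na(m)] <- nodata
  writeLines(apply(m, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")),
             con)
  TRUE
}

## ---- GeoTIFF (single band, float32, uncompressed) ------------------------

FLT_NODATA <- -3.4028234663852886e+38

write_geotiff <- function(grid, path) {
  g <- grid$geometry
  vals <- t(grid$values)              # row-major pixel order
  vals[is.na(vals)] <- FLT_NODATA
  n <- length(vals)
  pix_bytes <- n * 4L
  pix_off <- 8L

  scale_off <- pix_off + pix_bytes          # 3 doubles
  tie_off <- scale_off + 24L                # 6 doubles
  geokey_off <- tie_off + 48L               # 8 shorts
  nodata_str <- sprintf("%.9g", FLT_NODATA)
  nodata_raw <- c(charToRaw(nodata_str), as.raw(0))
  nodata_off <- geokey_off + 16L
  ifd_off <- nodata_off + length(nodata_raw)
  if (ifd_off %% 2 == 1) { nodata_raw <- c(nodata_raw, as.raw(0)); ifd_off <- ifd_off + 1L }

  model_type <- if (g$crs_kind == "geographic_degrees") 2L else 1L

  con <- tryCatch(suppressWarnings(file(path, "wb")),
                  error = function(e) stop("cannot write raster to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wb(42L, 2); wb(as.integer(ifd_off), 4)
  wb(as.vector(vals), 4)                                    # float32 pixels
  wb(c(g$cell_size, g$cell_size, 0), 8)                     # ModelPixelScale
  wb(c(0, 0, 0, g$x_origin, g$y_origin, 0), 8)              # ModelTiepoint
  wb(as.integer(c(1, 1, 0, 1, 1024, 0, 1, model_type)), 2)  # GeoKeyDirectory
  writeBin(nodata_raw, con)

  entry <- function(tag, type, count, value) {
    wb(as.integer(tag), 2); wb(as.integer(type), 2); wb(as.integer(count), 4)
    if (type == 3 && count == 1) { wb(as.integer(value), 2); wb(0L, 2) }
    else wb(as.integer(value), 4)
  }
  wb(14L, 2)
  entry(256, 4, 1, g$n_cols)          # ImageWidth
  entry(257, 4, 1, g$n_rows)          # ImageLength
  entry(258, 3, 1, 32)                # BitsPerSample
  entry(259, 3, 1, 1)                 # Compression: none
  entry(262, 3, 1, 1)                 # Photometric: BlackIsZero
  entry(273, 4, 1, pix_off)           # StripOffsets
  entry(277, 3, 1, 1)                 # SamplesPerPixel
  entry(278, 4, 1, g$n_rows)          # RowsPerStrip
  entry(279, 4, 1, pix_bytes)         # StripByteCounts
  entry(339, 3, 1, 3)                 # SampleFormat: IEEE float
  entry(33550, 12, 3, scale_off)      # ModelPixelScaleTag
  entry(33922, 12, 6, tie_off)        # ModelTiepointTag
  entry(34735, 3, 8, geokey_off)      # GeoKeyDirectoryTag
  entry(42113, 2, length(nodata_raw), nodata_off)  # GDAL_NODATA
  wb(0L, 4)
  TRUE
}

read_geotiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("malformed GeoTIFF: file too short: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("malformed GeoTIFF header: byte-order mark in ", path)
  num <- function(off, type, count) {
    # off is 0-based file offset
    size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `11` = 4, `12` = 8)[[as.character(type)]]
    what <- switch(as.character(type),
                   `1` = "integer", `2` = "character", `3` = "integer",
                   `4` = "integer", `11` = "double", `12` = "double")
    bytes <- raw[(off + 1):(off + size * count)]
    if (type == 2) return(rawToChar(bytes[bytes != as.raw(0)]))
    out <- readBin(bytes, what, n = count, size = size, endian = endian,
                   signed = size > 2)
    if (type == 4) {
      out <- as.numeric(out)
      out[out < 0] <- out[out < 0] + 2^32
    }
    out
  }
  if (num(2, 3, 1) != 42) stop("malformed GeoTIFF header: magic number in ", path)
  ifd <- num(4, 4, 1)
  n_entries <- num(ifd, 3, 1)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- ifd + 2 + (k - 1) * 12
    tag <- num(e, 3, 1); type <- num(e + 2, 3, 1); count <- num(e + 4, 4, 1)
    size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `11` = 4, `12` = 8)[[as.character(type)]]
    val_off <- if (size * count <= 4) e + 8 else num(e + 8, 4, 1)
    tags[[as.character(tag)]] <- num(val_off, type, count)
  }
  tg <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  width <- tg(256); height <- tg(257)
  if (is.null(width) || is.null(height))
    stop("malformed GeoTIFF: missing ImageWidth/ImageLength in ", path)
  if (!identical(tg(259, 1), 1) && tg(259, 1) != 1)
    stop("unsupported GeoTIFF: compressed data in ", path)
  if (tg(277, 1) != 1)
    stop("unsupported GeoTIFF: multi-band rasters are not supported: ", path)
  bits <- tg(258, 32); fmt <- tg(339, 1)
  if (bits != 32 || fmt != 3)
    stop("unsupported GeoTIFF: only float32 samples are supported: ", path)
  scale <- tg(33550)
  tie <- tg(33922)
  if (is.null(scale) || is.null(tie))
    stop("malformed GeoTIFF: missing georeferencing (ModelPixelScale/ModelTiepoint) in ", path)
  if (abs(scale[1] - scale[2]) > 1e-9 * max(abs(scale[1]), abs(scale[2])))
    stop("unsupported geometry: non-square cells in ", path)
  crs_kind <- "projected_metric"
  gk <- tg(34735)
  if (!is.null(gk) && length(gk) >= 8) {
    nk <- gk[4]
    for (k in seq_len(nk)) {
      key <- gk[4 * k + 1:4]
      if (key[1] == 1024 && key[4] == 2) crs_kind <- "geographic_degrees"
    }
  }
  strip_off <- tg(273); strip_cnt <- tg(279)
  if (is.null(strip_off) || is.null(strip_cnt))
    stop("malformed GeoTIFF: missing strip offsets in ", path)
  pix <- numeric(0)
  for (k in seq_along(strip_off)) {
    bytes <- raw[(strip_off[k] + 1):(strip_off[k] + strip_cnt[k])]
    pix <- c(pix, readBin(bytes, "double", n = strip_cnt[k] / 4, size = 4,
                          endian = endian))
  }
  if (length(pix) != width * height)
    stop("malformed GeoTIFF: pixel count mismatch in ", path)
  m <- matrix(pix, nrow = height, ncol = width, byrow = TRUE)
  nd_str <- tg(42113)
  if (!is.null(nd_str)) {
    nd <- suppressWarnings(as.numeric(trimws(nd_str)))
    if (is.finite(nd))
      m[abs(m - nd) <= 1e-6 * max(1, abs(nd))] <- NA_real_
  }
  x_origin <- tie[4] - tie[1] * scale[1]
  y_origin <- tie[5] + tie[2] * scale[2]
  geom <- grid_geometry(height, width, x_origin, y_origin, scale[1], crs_kind)
  grid_layer(geom, m)
}
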