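#' Render a presence-probability map to a PNG image
#'
#' Writes an image of a probability raster with a continuous colour ramp
#' over `[0, 1]` and masked cells in a distinct neutral grey. With
#' `device = "auto"` and a capable graphics device a full plot with axes
#' and a legend labelled "proportion of runs predicting presence" is
#' drawn; `device = "raw"` writes the colour-mapped pixels directly (no
#' text), which works on any system and is byte-reproducible.
#'
#' A baseline map, whose values are only 0 or 1, renders as a two-colour
#' presence/absence image; intermediate probabilities fall on the ramp.
#'
#' @param x a `presence_probability_map` or a probability `grid_layer`
#'   with values in `[0, 1]`.
#' @param path output PNG path.
#' @param palette colour ramp (low to high).
#' @param mask_col colour for masked cells.
#' @param device `"raw"` or `"auto"`.
#' @param scale integer pixel replication factor for small grids.
#' @return `path`, invisibly.
#' @export
render_map <- function(x, path, palette = grDevices::hcl.colors(256, "viridis"),
                       mask_col = "grey75", device = c("raw", "auto"),
                       scale = 1) {
  device <- match.arg(device)
  grid <- if (inherits(x, "presence_probability_map")) x$grid else x
  stopifnot(inherits(grid, "grid_layer"))
  v <- grid$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("probability raster has values outside [0, 1]")
  if (device == "auto" &&
      (capabilities("cairo") || capabilities("aqua"))) {
    grDevices::png(path, width = 640, height = 560, type = "cairo")
    on.exit(grDevices::dev.off())
    map <- if (inherits(x, "presence_probability_map")) x else
      new_probability_map(grid, 1L, "map", "")
    plot(map, col = palette, mask_col = mask_col)
    return(invisible(path))
  }
  idx <- pmin(length(palette), pmax(1L, 1L + floor(v * (length(palette) - 1e-9))))
  rgb_pal <- grDevices::col2rgb(palette) / 255
  rgb_mask <- grDevices::col2rgb(mask_col) / 255
  nr <- nrow(v); nc <- ncol(v)
  img <- array(0, c(nr, nc, 3))
  for (ch in 1:3) {
    m <- matrix(rgb_mask[ch], nr, nc)
    ok <- !is.na(v)
    m[ok] <- rgb_pal[ch, idx[ok]]
    img[, , ch] <- m
  }
  if (scale > 1)
    img <- img[rep(seq_len(nr), each = scale),
               rep(seq_len(nc), each = scale), , drop = FALSE]
  png::writePNG(img, path)
  invisible(path)
}
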