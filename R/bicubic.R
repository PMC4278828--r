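#' Bicubic (Catmull-Rom) upsampling of a coarse grid
#'
#' Resamples a coarse grid onto a finer target geometry with the separable
#' Catmull-Rom cubic kernel. The kernel is interpolating, not
#' approximating: a fine sample taken exactly at a coarse node reproduces
#' the node value, a constant field stays constant, and planar ramps are
#' reproduced exactly on the interior. This is the kernel used to spread
#' coarsely simulated climate-error fields onto the fine climate grids, so
#' node preservation (the simulated error SD at the nodes) is the contract
#' that matters.
#'
#' The operator is linear in the input; an all-zero coarse field upsamples
#' to an all-zero fine field, which makes a zero-SD error simulation an
#' exact identity downstream.
#'
#' @param coarse a `grid_layer` with at least 2 x 2 cells and no masked
#'   cells (error surfaces must be complete).
#' @param target a `grid_geometry` whose extent lies within the coarse
#'   extent (coarse edge nodes are replicated outwards, so the half-cell
#'   border of the coarse grid is also covered).
#' @return A `grid_layer` on `target`.
#' @examples
#' co <- grid_layer(grid_geometry(3, 3, 0, 3000, 1000), 2.5)
#' fi <- bicubic_upsample(co, grid_geometry(12, 12, 0, 3000, 250))
#' range(grid_values(fi)) # constant 2.5 reproduced
#' @export
bicubic_upsample <- function(coarse, target) {
  stopifnot(inherits(coarse, "grid_layer"), inherits(target, "grid_geometry"))
  cg <- coarse$geometry
  if (cg$n_rows < 2 || cg$n_cols < 2)
    stop("coarse grid must have at least 2 x 2 cells")
  if (anyNA(coarse$values))
    stop("coarse grid has masked cells; interpolation requires a complete field")
  # containment up to half a coarse cell beyond the outer node ring
  slack <- cg$cell_size / 2 + 1e-9 * cg$cell_size
  if (target$x_origin < cg$x_origin - slack ||
      target$y_origin > cg$y_origin + slack ||
      target$x_origin + target$n_cols * target$cell_size >
        cg$x_origin + cg$n_cols * cg$cell_size + slack ||
      target$y_origin - target$n_rows * target$cell_size <
        cg$y_origin - cg$n_rows * cg$cell_size - slack)
    stop("target extent is not contained in the coarse extent")

  cc <- cell_centers(cg)
  tc <- cell_centers(target)
  Wc <- catmull_rom_weights((tc$x - cc$x[1]) / cg$cell_size, cg$n_cols)
  Wr <- catmull_rom_weights((cc$y[1] - tc$y) / cg$cell_size, cg$n_rows)
  grid_layer(target, Wr %*% coarse$values %*% t(Wc))
}

# Weight matrix mapping n_nodes coarse samples to length(u) fine samples.
# u is the continuous coarse-node coordinate (0 at the first node); edge
# nodes are replicated beyond the boundary.
catmull_rom_weights <- function(u, n_nodes) {
  i0 <- floor(u)
  t <- u - i0
  t2 <- t * t
  t3 <- t2 * t
  w <- cbind(0.5 * (-t + 2 * t2 - t3),
             0.5 * (2 - 5 * t2 + 3 * t3),
             0.5 * (t + 4 * t2 - 3 * t3),
             0.5 * (-t2 + t3))
  W <- matrix(0, length(u), n_nodes)
  for (k in 0:3) {
    idx <- pmin(pmax(i0 + k - 1, 0), n_nodes - 1) + 1
    W[cbind(seq_along(u), idx)] <- W[cbind(seq_along(u), idx)] + w[, k + 1]
  }
  W
}
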