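# Slide-scan planning, focus interpolation, tiling and mosaic stitching.
#
# Coordinate convention: row-major grids, origin at the top-left tile,
# y increases downward, 0-based grid indices, half-open pixel crops.
# Tile origins sit on a regular lattice (row * step_y, col * step_x); the
# steps are smaller than the tile dimensions so neighbouring frames share
# an overlap strip used for stitching (44 px on each axis for the default
# 1624 x 1224 frames with 1580 / 1180 steps).

#' Bilinear focus interpolation from four corner focus values
#'
#' Focus z-values selected at the four corners of the scanned area are
#' blended bilinearly to give an adequate focus at every tile position:
#' `z(u, v) = (1-u)(1-v) z_TL + u (1-v) z_TR + (1-u) v z_BL + u v z_BR`.
#'
#' @param corner_focus numeric length-4 vector of focus z-values (um) in
#'   the order top-left, top-right, bottom-left, bottom-right.
#' @param u fractional position across columns in `[0, 1]` (0 = left).
#' @param v fractional position across rows in `[0, 1]` (0 = top).
#'   `u` and `v` may be vectors of equal length.
#' @return interpolated focus z (um).
#' @export
#' @examples
#' interpolate_focus(c(0, 10, 10, 20), 0.5, 0.5)   # 10
interpolate_focus <- function(corner_focus, u, v) {
  if (!is.numeric(corner_focus) || length(corner_focus) != 4) {
    stop("corner_focus must be four z-values (TL, TR, BL, BR)", call. = FALSE)
  }
  if (any(u < 0 | u > 1) || any(v < 0 | v > 1)) {
    stop("u and v must lie in [0, 1]", call. = FALSE)
  }
  z <- corner_focus
  (1 - u) * (1 - v) * z[1] + u * (1 - v) * z[2] +
    (1 - u) * v * z[3] + u * v * z[4]
}

#' Plan a raster scan over a tile grid
#'
#' Produces the tile lattice (row-major order) with per-tile mosaic
#' origins and bilinearly interpolated focus values. Defaults mirror the
#' tissue scanner: 1624 x 1224 px frames stepped by 1580 / 1180 px,
#' leaving a 44 px overlap on each axis.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param tile_shape integer (height, width) of one frame in pixels.
#' @param step_x,step_y lateral steps between tile origins in pixels; each
#'   must not exceed the corresponding tile dimension (overlap >= 0).
#' @param corner_focus four corner focus z-values (um), order TL, TR, BL,
#'   BR.
#' @param pixel_pitch pixel size (um).
#' @return object of class `scan_plan`; `$tiles` is a data.frame with
#'   0-based `row`, `col`, pixel origins `y`, `x` and `focus_z`.
#' @export
#' @examples
#' plan <- plan_scan(2, 3, tile_shape = c(8, 10), step_x = 7, step_y = 6,
#'                   corner_focus = c(0, 1, 2, 3))
#' nrow(plan$tiles)   # 6
plan_scan <- function(n_rows, n_cols, tile_shape = c(1224, 1624),
                      step_x = 1580, step_y = 1180,
                      corner_focus = c(0, 0, 0, 0),
                      pixel_pitch = 255 / 1624) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be >= 1", call. = FALSE)
  if (length(tile_shape) != 2 || any(tile_shape < 1)) {
    stop("tile_shape must be (height, width) in pixels", call. = FALSE)
  }
  if (step_x > tile_shape[2] || step_y > tile_shape[1]) {
    stop("no overlap: step exceeds tile dimension", call. = FALSE)
  }
  if (step_x < 1 || step_y < 1) stop("steps must be >= 1 pixel", call. = FALSE)
  grid <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  grid <- grid[, c("row", "col")]
  u <- if (n_cols > 1) grid$col / (n_cols - 1) else rep(0, nrow(grid))
  v <- if (n_rows > 1) grid$row / (n_rows - 1) else rep(0, nrow(grid))
  tiles <- data.frame(
    row = grid$row, col = grid$col,
    y = grid$row * step_y, x = grid$col * step_x,
    focus_z = interpolate_focus(corner_focus, u, v)
  )
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 tile_shape = as.integer(tile_shape),
                 step_x = as.integer(step_x), step_y = as.integer(step_y),
                 corner_focus = corner_focus, pixel_pitch = pixel_pitch,
                 tiles = tiles),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf(
    "<scan_plan> %d x %d tiles of %d x %d px, steps (x %d, y %d), overlap (%d, %d) px\n",
    x$n_rows, x$n_cols, x$tile_shape[1], x$tile_shape[2],
    x$step_x, x$step_y, x$tile_shape[2] - x$step_x, x$tile_shape[1] - x$step_y))
  invisible(x)
}

mosaic_shape <- function(plan) {
  c(plan$step_y * (plan$n_rows - 1) + plan$tile_shape[1],
    plan$step_x * (plan$n_cols - 1) + plan$tile_shape[2])
}

#' Cut a large image into planned tiles
#'
#' Exact crops at the planned lattice origins; the inverse of [stitch()]
#' for consistent tiles.
#'
#' @param image numeric matrix at least as large as the mosaic footprint of
#'   `plan`.
#' @param plan a [scan_plan()].
#' @return list of tile records, row-major; each has `row`, `col`, `origin`
#'   (y, x), `focus_z` and the cropped `image`.
#' @export
tile_image <- function(image, plan) {
  stop_if_not_matrix(image, "image")
  stopifnot(inherits(plan, "scan_plan"))
  need <- mosaic_shape(plan)
  if (nrow(image) < need[1] || ncol(image) < need[2]) {
    stop(sprintf("image too small: need at least %d x %d px", need[1], need[2]),
         call. = FALSE)
  }
  th <- plan$tile_shape[1]; tw <- plan$tile_shape[2]
  lapply(seq_len(nrow(plan$tiles)), function(i) {
    t <- plan$tiles[i, ]
    list(row = t$row, col = t$col, origin = c(t$y, t$x), focus_z = t$focus_z,
         image = image[t$y + seq_len(th), t$x + seq_len(tw), drop = FALSE])
  })
}

#' Stitch planned tiles into a mosaic
#'
#' Places every tile at its planned origin and combines overlap regions
#' according to `blend`:
#' * `"feather"` (default): weighted average with per-tile weights ramping
#'   down towards the tile borders (product of the two axis ramps),
#' * `"average"`: unweighted mean of all contributing tiles,
#' * `"overwrite"`: later tiles (row-major order) replace earlier ones.
#'
#' Where overlapping tiles agree exactly, every mode returns that value, so
#' `stitch(tile_image(img, plan), plan)` reproduces `img` on the covered
#' region for any mode.
#'
#' @param tiles list of tile records (as from [tile_image()]), one per grid
#'   position.
#' @param plan the [scan_plan()] that produced them.
#' @param blend overlap combination mode.
#' @return numeric matrix of shape `step_y*(n_rows-1)+tile_h` by
#'   `step_x*(n_cols-1)+tile_w`.
#' @export
stitch <- function(tiles, plan, blend = c("feather", "average", "overwrite")) {
  stopifnot(inherits(plan, "scan_plan"))
  blend <- match.arg(blend)
  th <- plan$tile_shape[1]; tw <- plan$tile_shape[2]
  keys <- vapply(tiles, function(t) paste(t$row, t$col), character(1))
  want <- paste(plan$tiles$row, plan$tiles$col)
  miss <- setdiff(want, keys)
  if (length(miss)) {
    stop("missing tile at (row, col) = (",
         sub(" ", ", ", miss[1]), ")", call. = FALSE)
  }
  shape <- mosaic_shape(plan)
  if (blend == "overwrite") {
    mosaic <- matrix(0, shape[1], shape[2])
    for (k in order(match(keys, want))) {
      t <- tiles[[k]]
      mosaic[t$origin[1] + seq_len(th), t$origin[2] + seq_len(tw)] <- t$image
    }
    return(mosaic)
  }
  w_tile <- if (blend == "feather") {
    wy <- pmin(seq_len(th), th + 1 - seq_len(th))
    wx <- pmin(seq_len(tw), tw + 1 - seq_len(tw))
    outer(wy, wx)
  } else {
    matrix(1, th, tw)
  }
  num <- matrix(0, shape[1], shape[2])
  den <- matrix(0, shape[1], shape[2])
  for (t in tiles) {
    ys <- t$origin[1] + seq_len(th); xs <- t$origin[2] + seq_len(tw)
    num[ys, xs] <- num[ys, xs] + w_tile * t$image
    den[ys, xs] <- den[ys, xs] + w_tile
  }
  num / den
}
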