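#' Raster-order tile index within a pyramid layer
#'
#' Tiles of one resolution layer are addressed by a single integer `t` that
#' walks the tile grid in raster order: left to right within a row, rows top
#' to bottom. For a tile at column `x` and row `y` (both 0-based) of a layer
#' with `x_tiles` columns,
#'
#'   t = y * x_tiles + x.
#'
#' This is the index the tile URL grammar carries, and the frame number of the
#' WADO-RS dialect maps onto it (1-based, see [wado_frame_to_tile()]).
#'
#' @param x,y 0-based tile column and row. Vectorised.
#' @param layer A layer description with fields `x_tiles` and `y_tiles`
#'   (e.g. one row of [slide_metadata()]`$layers`, or [layer_tiling()] output).
#' @return Integer vector of raster indices.
#' @seealso [raster_coords()] for the inverse.
#' @export
#' @examples
#' lay <- layer_tiling(2560, 1280, 1, 256)  # 10 x 5 tiles
#' raster_index(3, 2, lay)                  # 23
raster_index <- function(x, y, layer) {
  xt <- as.integer(layer$x_tiles)
  yt <- as.integer(layer$y_tiles)
  x <- as.integer(x)
  y <- as.integer(y)
  if (any(is.na(x) | is.na(y) | x < 0L | y < 0L | x >= xt | y >= yt)) {
    abort_range(sprintf(
      "tile coordinate out of range for a %d x %d tile layer", xt, yt))
  }
  y * xt + x
}

#' Tile coordinates from a raster index
#'
#' Inverts [raster_index()]: `x = t mod x_tiles`, `y = t div x_tiles`.
#'
#' @param t 0-based raster index, `0 <= t < x_tiles * y_tiles`. Vectorised.
#' @inheritParams raster_index
#' @return A list with integer vectors `x` and `y`.
#' @export
raster_coords <- function(t, layer) {
  xt <- as.integer(layer$x_tiles)
  yt <- as.integer(layer$y_tiles)
  t <- as.integer(t)
  if (any(is.na(t) | t < 0L | t >= xt * yt)) {
    abort_range(sprintf(
      "tile index out of range: layer holds %d tiles", xt * yt))
  }
  list(x = t %% xt, y = t %/% xt)
}

#' Tile grid of one pyramid layer
#'
#' Computes how many fixed-size tiles cover a layer whose linear resolution is
#' `scale` times the full-resolution extent: `x_tiles = ceil(scale * width /
#' tile_size)` and likewise for `y_tiles`. Edge tiles cover the remainder.
#'
#' @param width,height Pixel extent of the highest-resolution layer.
#' @param scale Linear scale of this layer relative to the highest-resolution
#'   layer, in (0, 1].
#' @param tile_size Tile edge length in pixels.
#' @return A list with fields `x_tiles`, `y_tiles` (integers) and `scale`.
#' @export
layer_tiling <- function(width, height, scale, tile_size) {
  if (width < 1 || height < 1 || tile_size < 1) {
    abort_contract("width, height and tile_size must be positive")
  }
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    abort_contract("scale must lie in (0, 1]")
  }
  list(
    x_tiles = as.integer(ceiling(scale * width / tile_size)),
    y_tiles = as.integer(ceiling(scale * height / tile_size)),
    scale = as.numeric(scale)
  )
}

# Pixel extent of a layer: the client-facing size used to crop edge-tile
# padding. ceiling() keeps ceil(pixel_width / tile_size) == x_tiles for every
# fractional scaled extent (round() would undercount tiles when the fraction
# is <= 0.5); it is also the DeepZoom level-size convention.
layer_pixel_extent <- function(width, height, scale) {
  list(width = max(1L, as.integer(ceiling(scale * width))),
       height = max(1L, as.integer(ceiling(scale * height))))
}
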