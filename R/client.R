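# Client-side tile-source logic: the testable mirror of what a tiled viewer
# does with this server — configure pyramid levels from served metadata,
# build tile URL targets, and assemble pixel regions from fetched tiles.

#' Configure viewer levels from served slide metadata
#'
#' Parses the metadata JSON document served by the tile server and derives
#' one level per container layer: its pixel extent and tile grid. Documents
#' violating the layer invariants (grids inconsistent with extent and scale,
#' non-increasing scales) are rejected, mirroring the automatic viewer
#' configuration a tile-source performs.
#'
#' @param json Metadata JSON string (or an already parsed
#'   [slide_metadata()]).
#' @return A tibble with one row per level: `level`, `scale`, `pixel_width`,
#'   `pixel_height`, `x_tiles`, `y_tiles`, plus attribute `tile_size`.
#' @export
configure_from_metadata <- function(json) {
  meta <- if (inherits(json, "slide_metadata")) json else
    metadata_from_json(json)
  ext <- lapply(meta$layers$scale, function(s)
    layer_pixel_extent(meta$width, meta$height, s))
  levels <- tibble::tibble(
    level = seq_len(nrow(meta$layers)) - 1L,
    scale = meta$layers$scale,
    pixel_width = vapply(ext, `[[`, integer(1), "width"),
    pixel_height = vapply(ext, `[[`, integer(1), "height"),
    x_tiles = meta$layers$x_tiles,
    y_tiles = meta$layers$y_tiles
  )
  stopifnot(all(levels$x_tiles == ceiling(levels$pixel_width / meta$tile_size)),
            all(levels$y_tiles == ceiling(levels$pixel_height / meta$tile_size)))
  attr(levels, "tile_size") <- meta$tile_size
  attr(levels, "encoding") <- meta$encoding
  levels
}

#' Build the URL target of one tile
#'
#' Converts a tile's (x, y) location within a level into the server's
#' URL-target sequence, using the raster index of [raster_index()]:
#' `{server_url}/slides/{slide_id}/layers/{level}/tiles/{t}`.
#'
#' @param server_url Server base URL (no trailing slash needed).
#' @param slide_id Slide name, excluding the `.iris` extension.
#' @param level 0-based level index (0 = lowest resolution).
#' @param x,y 0-based tile column/row within the level.
#' @param levels Level table from [configure_from_metadata()], used for
#'   bounds checking.
#' @return The tile URL string.
#' @export
tile_url <- function(server_url, slide_id, level, x, y, levels) {
  if (!level %in% levels$level) {
    abort_range(sprintf("level %d out of range", level))
  }
  lay <- levels[levels$level == level, ]
  t <- raster_index(x, y, list(x_tiles = lay$x_tiles, y_tiles = lay$y_tiles))
  sprintf("%s/slides/%s/layers/%d/tiles/%d",
          sub("/+$", "", server_url), slide_id, level, t)
}

fetch_url <- function(url) {
  res <- curl::curl_fetch_memory(url)
  if (res$status_code != 200L) {
    iris_abort("iris_http_error",
               sprintf("HTTP %d: %s", res$status_code,
                       tryCatch(rawToChar(res$content),
                                error = function(e) "")),
               status = res$status_code)
  }
  res$content
}

#' Fetch a slide's metadata and configure levels
#'
#' @inheritParams tile_url
#' @return See [configure_from_metadata()].
#' @export
fetch_levels <- function(server_url, slide_id) {
  json <- rawToChar(fetch_url(sprintf("%s/slides/%s/metadata",
                                      sub("/+$", "", server_url), slide_id)))
  configure_from_metadata(json)
}

#' Fetch and assemble an exact pixel region of one level
#'
#' Downloads the tiles covering a pixel rectangle of a level, decodes them,
#' crops the replicate padding of edge tiles using the level's pixel extent,
#' and stitches exactly the requested pixels.
#'
#' @inheritParams tile_url
#' @param x0,y0 Top-left pixel of the rectangle (0-based) within the level.
#' @param width,height Rectangle extent in pixels.
#' @param levels Optional pre-fetched level table; fetched when `NULL`.
#' @return A `height` x `width` x 3 numeric array on `[0, 255]`.
#' @export
fetch_region <- function(server_url, slide_id, level, x0, y0, width, height,
                         levels = NULL) {
  if (is.null(levels)) levels <- fetch_levels(server_url, slide_id)
  lay <- levels[levels$level == level, ]
  if (nrow(lay) == 0L) abort_range(sprintf("level %d out of range", level))
  ts <- attr(levels, "tile_size")
  if (x0 < 0 || y0 < 0 || width < 1 || height < 1 ||
      x0 + width > lay$pixel_width || y0 + height > lay$pixel_height) {
    abort_range("requested rectangle exceeds the level's pixel extent")
  }
  out <- array(0, c(height, width, 3))
  tx0 <- x0 %/% ts; tx1 <- (x0 + width - 1L) %/% ts
  ty0 <- y0 %/% ts; ty1 <- (y0 + height - 1L) %/% ts
  for (ty in ty0:ty1) {
    for (tx in tx0:tx1) {
      bytes <- fetch_url(tile_url(server_url, slide_id, level, tx, ty, levels))
      px <- decode_tile_pixels(bytes, attr(levels, "encoding"))
      # crop replicate padding to the level extent
      keep_h <- min(ts, lay$pixel_height - ty * ts)
      keep_w <- min(ts, lay$pixel_width - tx * ts)
      px <- px[seq_len(keep_h), seq_len(keep_w), , drop = FALSE]
      # intersection of this tile with the requested rectangle
      rr <- max(y0, ty * ts):min(y0 + height - 1L, ty * ts + keep_h - 1L)
      cc <- max(x0, tx * ts):min(x0 + width - 1L, tx * ts + keep_w - 1L)
      out[rr - y0 + 1L, cc - x0 + 1L, ] <-
        px[rr - ty * ts + 1L, cc - tx * ts + 1L, , drop = FALSE]
    }
  }
  out
}
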