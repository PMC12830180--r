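#' Slide metadata
#'
#' The description of a pyramidal slide that the server hands to clients: the
#' pixel extent of the highest-resolution layer, the (square) tile edge
#' length, the per-tile codec label, and one entry per resolution layer giving
#' its tile grid and linear scale.
#'
#' Layers are stored lowest resolution first; `scale` is expressed relative to
#' the highest-resolution layer, so it is strictly increasing and the final
#' layer has `scale == 1`. Each layer's grid must satisfy
#' `x_tiles == ceil(scale * width / tile_size)` (and likewise for `y_tiles`);
#' the constructor enforces all of this.
#'
#' @param width,height Pixel extent of the highest-resolution layer.
#' @param layers A data frame with one row per layer and columns `x_tiles`,
#'   `y_tiles`, `scale`, ordered by ascending scale. May also be a list of
#'   [layer_tiling()] results.
#' @param tile_size Tile edge length in pixels (>= 16).
#' @param encoding Per-tile codec label; `"jpeg"` (default) or `"png"`, the
#'   debug codec.
#' @return An object of class `slide_metadata`.
#' @export
#' @examples
#' slide_metadata(512, 512, layers = list(
#'   layer_tiling(512, 512, 0.5, 256),
#'   layer_tiling(512, 512, 1.0, 256)
#' ))
slide_metadata <- function(width, height, layers, tile_size = 256L,
                           encoding = "jpeg") {
  if (is.data.frame(layers)) {
    layers <- lapply(seq_len(nrow(layers)), function(i) as.list(layers[i, ]))
  }
  lay <- tibble::tibble(
    x_tiles = vapply(layers, function(l) as.integer(l$x_tiles), integer(1)),
    y_tiles = vapply(layers, function(l) as.integer(l$y_tiles), integer(1)),
    scale = vapply(layers, function(l) as.numeric(l$scale), numeric(1))
  )
  meta <- structure(
    list(width = as.integer(width), height = as.integer(height),
         tile_size = as.integer(tile_size), encoding = as.character(encoding),
         layers = lay),
    class = "slide_metadata"
  )
  validate_metadata(meta)
  meta
}

# Invariant checks shared by the constructor and container validation.
# Signals an iris_validation_error of kind "metadata_invalid" on failure.
validate_metadata <- function(meta) {
  bad <- function(msg) abort_validation("metadata_invalid", msg)
  if (!is.integer(meta$width) || meta$width < 1L ||
      !is.integer(meta$height) || meta$height < 1L) {
    bad("slide extent must be at least 1 x 1 pixel")
  }
  if (meta$tile_size < 16L) bad("tile_size must be at least 16 pixels")
  if (!meta$encoding %in% c("jpeg", "png")) {
    bad(sprintf("unsupported tile encoding '%s'", meta$encoding))
  }
  lay <- meta$layers
  if (nrow(lay) < 1L) bad("a slide needs at least one resolution layer")
  if (any(!is.finite(lay$scale)) || any(lay$scale <= 0) || any(lay$scale > 1)) {
    bad("layer scales must lie in (0, 1]")
  }
  if (nrow(lay) > 1L && any(diff(lay$scale) <= 0)) {
    bad("layer scales must be strictly increasing (lowest resolution first)")
  }
  if (lay$scale[nrow(lay)] != 1) {
    bad("the final (highest-resolution) layer must have scale 1")
  }
  want_x <- as.integer(ceiling(lay$scale * meta$width / meta$tile_size))
  want_y <- as.integer(ceiling(lay$scale * meta$height / meta$tile_size))
  if (any(lay$x_tiles != want_x) || any(lay$y_tiles != want_y)) {
    bad("layer tile grids are inconsistent with the slide extent and scales")
  }
  invisible(meta)
}

#' @export
print.slide_metadata <- function(x, ...) {
  cat(sprintf("<slide_metadata> %d x %d px, %d-px %s tiles, %d layer(s)\n",
              x$width, x$height, x$tile_size, x$encoding, nrow(x$layers)))
  print(x$layers)
  invisible(x)
}

# Total number of tiles across all layers.
n_tiles_total <- function(meta) {
  sum(as.numeric(meta$layers$x_tiles) * as.numeric(meta$layers$y_tiles))
}

# First global tile index (0-based) of each layer, in storage order.
layer_tile_offsets <- function(meta) {
  n <- meta$layers$x_tiles * meta$layers$y_tiles
  c(0L, cumsum(n))[seq_len(nrow(meta$layers))]
}

#' Serialize slide metadata to its JSON wire form
#'
#' Emits the canonical JSON document served to clients:
#' `{"extent":{"width":...,"height":...},"tile_size":...,"encoding":...,`
#' `"layers":[{"x_tiles":...,"y_tiles":...,"scale":...},...]}` with layers in
#' stored (ascending-scale) order. The serialization is canonical: serialize,
#' parse, serialize is byte-stable.
#'
#' @param meta A [slide_metadata()] object.
#' @return A length-1 character string of JSON.
#' @seealso [metadata_from_json()]
#' @export
metadata_to_json <- function(meta) {
  doc <- list(
    extent = list(width = meta$width, height = meta$height),
    tile_size = meta$tile_size,
    encoding = meta$encoding,
    layers = lapply(seq_len(nrow(meta$layers)), function(i) {
      list(x_tiles = meta$layers$x_tiles[i],
           y_tiles = meta$layers$y_tiles[i],
           scale = meta$layers$scale[i])
    })
  )
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
}

#' Parse the JSON wire form back into slide metadata
#'
#' Validates every metadata invariant; a document whose layer grids are
#' inconsistent with its extent and scales is rejected.
#'
#' @param json JSON string as produced by [metadata_to_json()].
#' @return A [slide_metadata()] object.
#' @export
metadata_from_json <- function(json) {
  doc <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                  error = function(e) NULL)
  need <- function(x, msg) { if (is.null(x)) abort_validation("metadata_invalid", msg); x }
  doc <- need(doc, "metadata document is not valid JSON")
  ext <- need(doc$extent, "metadata document lacks an extent")
  layers <- need(doc$layers, "metadata document lacks layers")
  for (l in layers) {
    if (is.null(l$x_tiles) || is.null(l$y_tiles) || is.null(l$scale)) {
      abort_validation("metadata_invalid", "layer entry lacks x_tiles, y_tiles or scale")
    }
  }
  slide_metadata(
    width = need(ext$width, "extent lacks width"),
    height = need(ext$height, "extent lacks height"),
    tile_size = need(doc$tile_size, "metadata document lacks tile_size"),
    encoding = need(doc$encoding, "metadata document lacks encoding"),
    layers = layers
  )
}
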