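# DeepZoom (DZI) export for cross-format comparison.
#
# A DZI pyramid is an XML descriptor plus one directory per level holding one
# JPEG per tile ("{x}_{y}.jpg"). DeepZoom levels are numbered so that level k
# has extent ceil(full / 2^(max_level - k)) with
# max_level = ceil(log2(max(width, height))); our container layer l (2x
# pyramids only) therefore lands at dzi_level = max_level - (n_layers-1-l).
# Interior tiles are byte-identical copies of the container's stored JPEGs;
# edge tiles are cropped to the level pixel extent (the container stores them
# replicate-padded to full tile size) and re-encoded.

#' Export a slide container as a DeepZoom (DZI) tree
#'
#' Writes `{name}.dzi` and the nested `{name}_files/{level}/{x}_{y}.jpg`
#' directories for a 2x-downsampled container. Interior tiles reuse the
#' container's JPEG bytes unchanged, so served tiles and DZI files can be
#' compared byte-for-byte; edge tiles are cropped to the level extent and
#' re-encoded.
#'
#' @param container_path Path to a `.iris` container whose layers are
#'   separated by exact 2x downsampling (DZI requires it).
#' @param out_dir Output directory (created if needed).
#' @param name Basename for the descriptor and tile tree.
#' @param jpeg_quality Quality used when re-encoding cropped edge tiles.
#' @return Invisibly, a list with `descriptor` (path to the `.dzi` file),
#'   `files_dir` and `levels` (a tibble mapping container layer to DZI level).
#' @export
export_dzi <- function(container_path, out_dir, name,
                       jpeg_quality = 90L) {
  h <- open_slide(container_path)
  on.exit(close_slide(h))
  meta <- h$metadata
  if (meta$encoding != "jpeg") {
    iris_abort("iris_unsupported_format",
               "DZI export requires a JPEG-encoded container")
  }
  sc <- meta$layers$scale
  if (nrow(meta$layers) > 1L &&
      any(abs(sc[-1] / sc[-length(sc)] - 2) > 1e-9)) {
    iris_abort("iris_unsupported_format",
               "DZI export requires an exact 2x-downsampled pyramid")
  }
  ts <- meta$tile_size
  n_layers <- nrow(meta$layers)
  max_level <- as.integer(ceiling(log2(max(meta$width, meta$height))))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  doc <- xml2::xml_new_root(
    "Image", xmlns = "http://schemas.microsoft.com/deepzoom/2008",
    TileSize = as.character(ts), Overlap = "0", Format = "jpg")
  xml2::xml_add_child(doc, "Size", Width = as.character(meta$width),
                      Height = as.character(meta$height))
  descriptor <- file.path(out_dir, paste0(name, ".dzi"))
  xml2::write_xml(doc, descriptor)

  files_dir <- file.path(out_dir, paste0(name, "_files"))
  dzi_levels <- integer(n_layers)
  for (l in seq_len(n_layers) - 1L) {
    lay <- meta$layers[l + 1L, ]
    ext <- layer_pixel_extent(meta$width, meta$height, lay$scale)
    dzi_level <- max_level - (n_layers - 1L - l)
    dzi_levels[l + 1L] <- dzi_level
    level_dir <- file.path(files_dir, dzi_level)
    dir.create(level_dir, recursive = TRUE, showWarnings = FALSE)
    for (t in seq_len(lay$x_tiles * lay$y_tiles) - 1L) {
      xy <- raster_coords(t, lay)
      bytes <- read_tile(h, l, t)
      keep_h <- min(ts, ext$height - xy$y * ts)
      keep_w <- min(ts, ext$width - xy$x * ts)
      if (keep_h < ts || keep_w < ts) {
        px <- decode_tile_pixels(bytes)
        px <- px[seq_len(keep_h), seq_len(keep_w), , drop = FALSE]
        bytes <- encode_tile_pixels(px, jpeg_quality)
      }
      writeBin(bytes, file.path(level_dir, sprintf("%d_%d.jpg", xy$x, xy$y)))
    }
  }
  invisible(list(
    descriptor = descriptor, files_dir = files_dir,
    levels = tibble::tibble(layer = seq_len(n_layers) - 1L,
                            dzi_level = dzi_levels)))
}
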