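# Deterministic fixture pyramids.
#
# Two generator modes:
#  * identity — every tile is a solid colour that encodes its own (layer, t)
#    address in quantized RGB, so a decoded tile testifies to which tile the
#    server actually returned. Colours are multiples of 8 so they survive
#    JPEG quantization.
#  * pyramid — a seeded smooth procedural texture at full resolution, with
#    lower layers produced by block-mean downsampling, emulating a real
#    derived pyramid (2x or 4x downsampling between layers).
#
# Pixel arrays throughout are height x width x 3 numeric arrays on [0, 255].

#' Specification of a synthetic slide
#'
#' @param width,height Full-resolution extent in pixels.
#' @param tile_size Tile edge in pixels.
#' @param downsample Linear downsampling factor between adjacent layers,
#'   2 or 4.
#' @param n_layers Number of resolution layers; layer `l` (0-based) has scale
#'   `downsample^(l - (n_layers - 1))`, so the top layer has scale 1.
#' @param mode `"identity"` (address-encoding solid tiles) or `"pyramid"`
#'   (seeded texture with true downsampling).
#' @param jpeg_quality JPEG quality, 1-100. Identity decoding is robust to
#'   JPEG loss at quality >= 75.
#' @param seed RNG seed driving the pyramid-mode texture.
#' @return A `synthetic_slide_spec` list.
#' @export
synthetic_slide_spec <- function(width = 1024L, height = 1024L,
                                 tile_size = 256L, downsample = 2L,
                                 n_layers = 3L, mode = c("identity", "pyramid"),
                                 jpeg_quality = 90L, seed = 1L) {
  mode <- match.arg(mode)
  if (!downsample %in% c(2L, 4L)) {
    abort_contract("downsample must be 2 or 4")
  }
  if (n_layers < 1L) abort_contract("need at least one layer")
  if (jpeg_quality < 1L || jpeg_quality > 100L) {
    abort_contract("jpeg_quality must lie in 1..100")
  }
  spec <- list(width = as.integer(width), height = as.integer(height),
               tile_size = as.integer(tile_size),
               downsample = as.integer(downsample),
               n_layers = as.integer(n_layers), mode = mode,
               jpeg_quality = as.integer(jpeg_quality),
               seed = as.integer(seed))
  class(spec) <- "synthetic_slide_spec"
  lay <- spec_layers(spec)
  if (mode == "identity") {
    if (n_layers > 32L) abort_contract("identity mode supports at most 32 layers")
    if (any(lay$x_tiles * lay$y_tiles > 1024L)) {
      abort_contract("identity mode supports at most 1024 tiles per layer")
    }
  }
  spec
}

spec_layers <- function(spec) {
  scales <- spec$downsample^(seq_len(spec$n_layers) - spec$n_layers)
  meta <- slide_metadata(
    spec$width, spec$height,
    layers = lapply(scales, function(s)
      layer_tiling(spec$width, spec$height, s, spec$tile_size)),
    tile_size = spec$tile_size
  )
  meta$layers
}

identity_tile_color <- function(layer, t) {
  c(r = 8 * ((t %/% 32L) %% 32L),
    g = 8 * (t %% 32L),
    b = 8 * (layer %% 32L))
}

#' Recover a tile's address from its identity-mode pixels
#'
#' Reads the central pixel, rounds each channel to the nearest multiple of 8
#' (tolerating up to 3 gray levels of JPEG loss) and inverts the identity
#' colour encoding.
#'
#' @param pixels A height x width x 3 array on `[0, 255]` (a decoded tile).
#' @return A list with `layer` and `t`.
#' @export
decode_tile_identity <- function(pixels) {
  px <- pixels[ceiling(dim(pixels)[1] / 2), ceiling(dim(pixels)[2] / 2), 1:3]
  q <- round(px / 8)
  if (any(abs(px - 8 * q) > 3)) {
    iris_abort("iris_decode_error",
               "pixel channels are too far from the identity colour grid")
  }
  list(layer = as.integer(q[3]), t = as.integer(32 * q[1] + q[2]))
}

encode_tile_pixels <- function(pixels, quality, encoding = "jpeg") {
  img <- pixels / 255
  img[img < 0] <- 0; img[img > 1] <- 1
  if (encoding == "jpeg") {
    jpeg::writeJPEG(img, raw(), quality = quality / 100)
  } else {
    png::writePNG(img)
  }
}

decode_tile_pixels <- function(bytes, encoding = "jpeg") {
  img <- tryCatch(
    if (encoding == "jpeg") jpeg::readJPEG(bytes) else png::readPNG(bytes),
    error = function(e) iris_abort("iris_decode_error", conditionMessage(e)))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE] * 255
}

# Block-mean downsample a matrix by integer factor f; partial edge blocks
# average over the pixels they actually cover.
block_mean <- function(m, f) {
  if (f == 1L) return(m)
  ri <- (seq_len(nrow(m)) - 1L) %/% f
  ci <- (seq_len(ncol(m)) - 1L) %/% f
  s <- rowsum(m, ri)
  s <- t(rowsum(t(s), ci))
  s / outer(tabulate(ri + 1L), tabulate(ci + 1L))
}

# Replicate-pad a level image out to the full tile grid.
pad_replicate <- function(img, out_h, out_w) {
  img[pmin(seq_len(out_h), nrow(img)), pmin(seq_len(out_w), ncol(img)), ,
      drop = FALSE]
}

with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# Smooth seeded texture: a sum of low-frequency plane waves per channel,
# centred on mid-gray. Smoothness keeps JPEG reconstruction error small.
procedural_texture <- function(h, w, seed) {
  with_preserved_rng(seed, {
    xs <- seq_len(w); ys <- seq_len(h)
    chan <- function() {
      m <- matrix(0, h, w)
      for (k in 1:5) {
        fx <- stats::runif(1, -1, 1) / 96
        fy <- stats::runif(1, -1, 1) / 96
        ph <- stats::runif(1, 0, 2 * pi)
        amp <- stats::runif(1, 10, 30)
        m <- m + amp * cos(2 * pi * (outer(ys * fy, xs * fx, `+`)) + ph)
      }
      m
    }
    arr <- array(0, c(h, w, 3))
    for (c in 1:3) arr[, , c] <- pmin(240, pmax(16, 128 + chan()))
    arr
  })
}

#' Generate a deterministic synthetic slide container
#'
#' Builds the pyramid described by `spec`, writes it with [write_container()]
#' and returns, alongside the container path, the exact pre-compression pixel
#' image of every level for use as a reference in round-trip comparisons.
#'
#' @param spec A [synthetic_slide_spec()].
#' @param path Output container path; defaults to a tempfile ending `.iris`.
#' @return A list with `path`, `metadata`, `spec` and `levels` (one
#'   height x width x 3 reference array per layer, ascending scale).
#' @export
generate_slide <- function(spec, path = tempfile(fileext = CONTAINER_EXT)) {
  lay <- spec_layers(spec)
  meta <- slide_metadata(spec$width, spec$height, layers = lay,
                         tile_size = spec$tile_size)
  ts <- spec$tile_size
  full <- if (spec$mode == "pyramid") {
    procedural_texture(spec$height, spec$width, spec$seed)
  }
  levels <- vector("list", nrow(lay))
  tiles <- list()
  for (l in seq_len(nrow(lay)) - 1L) {
    xt <- lay$x_tiles[l + 1L]; yt <- lay$y_tiles[l + 1L]
    ext <- layer_pixel_extent(spec$width, spec$height, lay$scale[l + 1L])
    if (spec$mode == "identity") {
      level <- array(0, c(ext$height, ext$width, 3))
      for (t in seq_len(xt * yt) - 1L) {
        col <- identity_tile_color(l, t)
        xy <- raster_coords(t, lay[l + 1L, ])
        rows <- (xy$y * ts + 1L):min((xy$y + 1L) * ts, ext$height)
        cols <- (xy$x * ts + 1L):min((xy$x + 1L) * ts, ext$width)
        for (c in 1:3) level[rows, cols, c] <- col[c]
      }
    } else {
      f <- spec$downsample^(nrow(lay) - 1L - l)
      level <- array(0, c(ext$height, ext$width, 3))
      for (c in 1:3) level[, , c] <- block_mean(full[, , c], f)
    }
    levels[[l + 1L]] <- level
    padded <- pad_replicate(level, yt * ts, xt * ts)
    for (t in seq_len(xt * yt) - 1L) {
      xy <- raster_coords(t, lay[l + 1L, ])
      tile <- padded[(xy$y * ts + 1L):((xy$y + 1L) * ts),
                     (xy$x * ts + 1L):((xy$x + 1L) * ts), , drop = FALSE]
      tiles[[length(tiles) + 1L]] <- encode_tile_pixels(tile, spec$jpeg_quality)
    }
  }
  write_container(path, meta, tiles)
  list(path = path, metadata = meta, spec = spec, levels = levels)
}
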