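# On-disk pyramidal slide container (".iris").
#
# Layout (all integers little-endian):
#   bytes 0..3    magic "IRST"
#   u32           format version (currently 1)
#   u32           total tile count N
#   u32           metadata JSON byte length L
#   L bytes       metadata JSON (UTF-8), see metadata_to_json()
#   N x (u64,u64) tile table: absolute (offset, byte length) per tile, in
#                 storage order (layers lowest-resolution first, raster order
#                 within each layer)
#   ...           concatenated compressed tile payloads
#   u32           CRC32 of every preceding byte
#
# Offsets/lengths are written as u64 but handled as R doubles (exact below
# 2^53, far beyond any plausible container size).

CONTAINER_MAGIC <- charToRaw("IRST")
CONTAINER_VERSION <- 1L
CONTAINER_EXT <- ".iris"

u32_to_raw <- function(v) {
  v <- as.numeric(v)
  writeBin(as.integer(ifelse(v >= 2^31, v - 2^32, v)), raw(), size = 4L,
           endian = "little")
}

raw_to_u32 <- function(r, offset = 0L) {
  v <- readBin(r[(offset + 1L):(offset + 4L)], "integer", size = 4L,
               endian = "little")
  ifelse(v < 0, v + 2^32, as.numeric(v))
}

u64_to_raw <- function(v) {
  v <- as.numeric(v)
  c(u32_to_raw(v %% 2^32), u32_to_raw(v %/% 2^32))
}

raw_to_u64 <- function(r, offset = 0L) {
  raw_to_u32(r, offset) + raw_to_u32(r, offset + 4L) * 2^32
}

crc32_of <- function(bytes) {
  hex <- digest::digest(bytes, algo = "crc32", serialize = FALSE)
  # strtoi() overflows for values >= 2^31; fold the hex digits by hand
  Reduce(function(a, d) a * 16 + d,
         strtoi(strsplit(hex, "")[[1]], base = 16L), accumulate = FALSE, 0)
}

#' Write a pyramidal slide container
#'
#' Serializes metadata and an ordered sequence of already-compressed tile
#' payloads into a single validated container file. Payloads must be supplied
#' in storage order: layers lowest resolution first, raster order within each
#' layer (see [raster_index()]).
#'
#' @param path Output file path (conventionally ending in `.iris`).
#' @param metadata A [slide_metadata()] object.
#' @param tiles List of non-empty raw vectors, one per tile; its length must
#'   equal the metadata's total tile count.
#' @return `path`, invisibly.
#' @seealso [validate_container()], [open_slide()]
#' @export
write_container <- function(path, metadata, tiles) {
  validate_metadata(metadata)
  n <- n_tiles_total(metadata)
  if (length(tiles) != n) {
    abort_contract(sprintf(
      "metadata describes %d tiles but %d payloads were supplied",
      n, length(tiles)))
  }
  sizes <- lengths(tiles)
  if (any(sizes == 0L) || !all(vapply(tiles, is.raw, logical(1)))) {
    abort_contract("every tile payload must be a non-empty raw vector")
  }
  .write_container_raw(path, metadata, tiles)
}

# Low-level writer. `n_header_override` lets tests forge a container whose
# header tile count disagrees with its metadata.
.write_container_raw <- function(path, metadata, tiles,
                                 n_header_override = NULL) {
  json <- charToRaw(metadata_to_json(metadata))
  n <- length(tiles)
  n_header <- if (is.null(n_header_override)) n else as.integer(n_header_override)
  header <- c(CONTAINER_MAGIC, u32_to_raw(CONTAINER_VERSION),
              u32_to_raw(n_header), u32_to_raw(length(json)), json)
  payload_start <- length(header) + 16 * n_header
  sizes <- as.numeric(lengths(tiles))
  offsets <- payload_start + c(0, cumsum(sizes))[seq_len(n)]
  table <- do.call(c, lapply(seq_len(n), function(i) {
    c(u64_to_raw(offsets[i]), u64_to_raw(sizes[i]))
  }))
  body <- c(header, table[seq_len(16 * n_header)], do.call(c, tiles))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(body, con)
  writeBin(u32_to_raw(crc32_of(body)), con)
  invisible(path)
}

#' Validate a slide container
#'
#' Runs the full validation checklist before any tile can be served: magic
#' bytes, format version, metadata parse and invariants, header/metadata tile
#' count agreement, tile-table bounds (every offset/length inside the file,
#' positive, non-overlapping), and the trailing whole-file CRC32. Each failure
#' signals a distinct condition class (`iris_bad_magic`,
#' `iris_bad_version`, `iris_metadata_invalid`, `iris_count_mismatch`,
#' `iris_bounds_error`, `iris_checksum_error`), all inheriting
#' `iris_validation_error`, with a plain-text narrative.
#'
#' @param path Path to a container file.
#' @return The parsed [slide_metadata()] on success.
#' @export
validate_container <- function(path) {
  parse_container(path)$metadata
}

# Full parse used by validate_container() and open_slide(): returns bytes,
# metadata and the tile table so a handle needs no re-parse.
parse_container <- function(path) {
  if (!file.exists(path)) {
    iris_abort("iris_io_error", sprintf("no such container file: %s", path))
  }
  size <- file.size(path)
  bytes <- readBin(path, "raw", n = size)
  if (length(bytes) < size) {
    iris_abort("iris_io_error", sprintf("short read on container file: %s", path))
  }
  if (size < 20) {
    abort_validation("bounds_error",
      "container file is too short to hold a header and checksum")
  }
  if (!identical(bytes[1:4], CONTAINER_MAGIC)) {
    abort_validation("bad_magic",
      "not a slide container: magic bytes 'IRST' are missing")
  }
  version <- raw_to_u32(bytes, 4L)
  if (version != CONTAINER_VERSION) {
    abort_validation("bad_version", sprintf(
      "unsupported container format version %d (this reader supports %d)",
      version, CONTAINER_VERSION))
  }
  n_header <- raw_to_u32(bytes, 8L)
  json_len <- raw_to_u32(bytes, 12L)
  if (16 + json_len + 16 * n_header + 4 > size) {
    abort_validation("bounds_error",
      "container is truncated: header, tile table and checksum do not fit")
  }
  json <- rawToChar(bytes[17:(16 + json_len)])
  meta <- metadata_from_json(json)  # re-signals metadata_invalid on failure
  n_meta <- n_tiles_total(meta)
  if (n_meta != n_header) {
    abort_validation("count_mismatch", sprintf(
      "metadata describes %d tiles but the header declares %d table entries",
      n_meta, n_header))
  }
  table_at <- 16 + json_len
  offs <- vapply(seq_len(n_header), function(i) {
    raw_to_u64(bytes, table_at + 16 * (i - 1)) }, numeric(1))
  lens <- vapply(seq_len(n_header), function(i) {
    raw_to_u64(bytes, table_at + 16 * (i - 1) + 8) }, numeric(1))
  payload_start <- table_at + 16 * n_header
  if (any(lens <= 0)) {
    abort_validation("bounds_error", "tile table holds an empty tile region")
  }
  if (any(offs < payload_start) || any(offs + lens > size - 4)) {
    abort_validation("bounds_error",
      "tile table points outside the container's payload region")
  }
  ord <- order(offs)
  if (any(offs[ord][-1] < (offs + lens)[ord][-length(ord)])) {
    abort_validation("bounds_error", "tile table holds overlapping regions")
  }
  stored_crc <- raw_to_u32(bytes, size - 4)
  if (crc32_of(bytes[seq_len(size - 4)]) != stored_crc) {
    abort_validation("checksum_error",
      "container checksum does not verify: the file is corrupt")
  }
  list(bytes = bytes, metadata = meta, offsets = offs, lengths = lens,
       path = path)
}

#' Open a validated slide container
#'
#' Validates the container (see [validate_container()]) and returns an open
#' handle holding the container's byte view, parsed metadata and tile table,
#' so subsequent [read_tile()] calls never re-parse the file. Handles carry a
#' session reference count; the server's handle cache shares one handle per
#' path between sessions and releases the byte view when the count drops to
#' zero.
#'
#' @param path Path to a container file.
#' @return An environment of class `slide_handle` with fields `path`,
#'   `metadata`, `refcount` (starts at 1).
#' @export
open_slide <- function(path) {
  parsed <- parse_container(path)
  h <- new.env(parent = emptyenv())
  h$path <- normalizePath(path)
  h$metadata <- parsed$metadata
  h$bytes <- parsed$bytes
  h$offsets <- parsed$offsets
  h$lengths <- parsed$lengths
  h$layer_offsets <- layer_tile_offsets(parsed$metadata)
  h$refcount <- 1L
  class(h) <- "slide_handle"
  h
}

#' Close a slide handle
#'
#' Releases the handle's byte view. Called by the server's handle cache when
#' the last referencing session closes.
#'
#' @param handle A [open_slide()] handle.
#' @return `NULL`, invisibly.
#' @export
close_slide <- function(handle) {
  handle$bytes <- NULL
  handle$refcount <- 0L
  invisible(NULL)
}

#' Read one stored tile payload
#'
#' Returns the exact stored compressed bytes (no transcoding) of tile `t` of
#' layer `layer`, both 0-based, with `t` a raster-order index.
#'
#' @param handle A [open_slide()] handle.
#' @param layer 0-based layer index (0 = lowest resolution).
#' @param t 0-based raster-order tile index within the layer.
#' @return A raw vector of compressed tile bytes.
#' @export
read_tile <- function(handle, layer, t) {
  if (is.null(handle$bytes)) {
    iris_abort("iris_io_error", "slide handle has been closed")
  }
  meta <- handle$metadata
  nl <- nrow(meta$layers)
  layer <- as.integer(layer); t <- as.integer(t)
  if (is.na(layer) || layer < 0L || layer >= nl) {
    abort_range(sprintf("layer index %s out of range: slide has %d layers",
                        layer, nl))
  }
  n_layer <- meta$layers$x_tiles[layer + 1L] * meta$layers$y_tiles[layer + 1L]
  if (is.na(t) || t < 0L || t >= n_layer) {
    abort_range(sprintf("tile index %s out of range: layer %d holds %d tiles",
                        t, layer, n_layer))
  }
  g <- handle$layer_offsets[layer + 1L] + t
  off <- handle$offsets[g + 1L]
  len <- handle$lengths[g + 1L]
  handle$bytes[(off + 1):(off + len)]
}

#' @export
print.slide_handle <- function(x, ...) {
  cat(sprintf("<slide_handle> %s (refcount %d%s)\n", x$path, x$refcount,
              if (is.null(x$bytes)) ", closed" else ""))
  invisible(x)
}
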