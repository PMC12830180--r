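# Fixture builders shared across tests. Everything is generated in code; no
# stored binary fixtures.

# A distinct, valid JPEG payload (solid colour derived from i).
solid_jpeg <- function(i, size = 32L) {
  px <- array(((i * 37) %% 200 + 20) / 255, c(size, size, 3))
  jpeg::writeJPEG(px, raw(), quality = 0.9)
}

# Raw non-image payloads exercise storage identity without codec round trips.
blob_payload <- function(i, len = 64L) {
  as.raw((seq_len(len) * (i + 13L)) %% 256L)
}

# A minimal single-layer metadata object.
meta_1layer <- function(width = 256L, height = 256L, tile_size = 256L) {
  slide_metadata(width, height, tile_size = tile_size,
                 layers = list(layer_tiling(width, height, 1, tile_size)))
}

# 2-layer 512x512 metadata (scales 0.5, 1.0) -> 1 + 4 tiles.
meta_2layer <- function() {
  slide_metadata(512L, 512L, layers = list(
    layer_tiling(512L, 512L, 0.5, 256L),
    layer_tiling(512L, 512L, 1.0, 256L)))
}

# Write a container for metadata using generated blob payloads; returns path.
write_blob_container <- function(meta, path = tempfile(fileext = ".iris")) {
  n <- sum(meta$layers$x_tiles * meta$layers$y_tiles)
  write_container(path, meta, lapply(seq_len(n), blob_payload))
  path
}

# A slide directory holding one identity-mode synthetic slide.
make_slide_dir <- function(name = "demo", spec = synthetic_slide_spec()) {
  sd <- tempfile("slides-")
  dir.create(sd)
  gen <- generate_slide(spec, file.path(sd, paste0(name, ".iris")))
  list(dir = sd, gen = gen, name = name)
}
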