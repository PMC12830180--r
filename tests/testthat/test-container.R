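test_that("a single-tile container round-trips byte-for-byte", {
  meta <- meta_1layer()
  payload <- blob_payload(1)
  path <- tempfile(fileext = ".iris")
  write_container(path, meta, list(payload))
  got <- validate_container(path)
  expect_equal(got, meta)
  h <- open_slide(path)
  expect_identical(read_tile(h, 0, 0), payload)
  expect_equal(h$refcount, 1L)
  close_slide(h)
})

test_that("a 2-layer 512x512 slide stores 1 + 4 table entries", {
  meta <- meta_2layer()
  expect_identical(meta$layers$x_tiles, c(1L, 2L))
  path <- write_blob_container(meta)
  h <- open_slide(path)
  expect_length(h$offsets, 5L)
  # layer 1 reads are distinct payloads in raster order
  for (t in 0:3) expect_identical(read_tile(h, 1, t), blob_payload(t + 2L))
  close_slide(h)
})

test_that("tile reads are bounds-checked at both edges", {
  path <- write_blob_container(meta_2layer())
  h <- open_slide(path)
  expect_error(read_tile(h, 1, 4), class = "iris_range_error")  # t == x_t*y_t
  expect_error(read_tile(h, 2, 0), class = "iris_range_error")
  expect_error(read_tile(h, -1, 0), class = "iris_range_error")
  close_slide(h)
  expect_error(read_tile(h, 0, 0), class = "iris_io_error")
})

test_that("payload corruption is caught by the trailing checksum", {
  path <- write_blob_container(meta_1layer())
  bytes <- readBin(path, "raw", file.size(path))
  i <- length(bytes) - 20L  # inside the payload region
  bytes[i] <- xor(bytes[i], as.raw(0x55))
  writeBin(bytes, path)
  expect_error(validate_container(path), class = "iris_checksum_error")
})

test_that("each validation failure signals its own error kind", {
  path <- write_blob_container(meta_1layer())
  bytes <- readBin(path, "raw", file.size(path))

  bad <- bytes; bad[2] <- as.raw(0x00)
  writeBin(bad, p <- tempfile()); expect_error(validate_container(p),
                                               class = "iris_bad_magic")
  bad <- bytes; bad[5] <- as.raw(0x63)
  writeBin(bad, p <- tempfile()); expect_error(validate_container(p),
                                               class = "iris_bad_version")
  writeBin(bytes[seq_len(length(bytes) %/% 2L)], p <- tempfile())
  expect_error(validate_container(p), class = "iris_bounds_error")
  expect_error(validate_container(tempfile()), class = "iris_io_error")
})

test_that("a header tile count disagreeing with the metadata is rejected", {
  meta <- meta_1layer(512L, 512L)  # 4 tiles
  tiles <- lapply(1:4, blob_payload)
  path <- tempfile(fileext = ".iris")
  iristiles:::.write_container_raw(path, meta, tiles, n_header_override = 3L)
  expect_error(validate_container(path), class = "iris_count_mismatch")
})

test_that("writer contracts reject count mismatches and empty payloads", {
  meta <- meta_2layer()
  expect_error(write_container(tempfile(), meta, lapply(1:4, blob_payload)),
               class = "iris_contract_error")
  tiles <- lapply(1:5, blob_payload); tiles[[3]] <- raw()
  expect_error(write_container(tempfile(), meta, tiles),
               class = "iris_contract_error")
})

test_that("random slides round-trip every payload byte-for-byte", {
  set.seed(42)
  for (k in 1:5) {
    w <- sample(100:1200, 1); h <- sample(100:1200, 1)
    nl <- sample(1:3, 1)
    scales <- 2^(-(rev(seq_len(nl)) - 1))
    meta <- slide_metadata(w, h, layers = lapply(scales, function(s)
      layer_tiling(w, h, s, 256L)))
    n <- sum(meta$layers$x_tiles * meta$layers$y_tiles)
    payloads <- lapply(seq_len(n), function(i)
      as.raw(sample(0:255, sample(10:200, 1), replace = TRUE)))
    path <- tempfile(fileext = ".iris")
    write_container(path, meta, payloads)
    expect_equal(validate_container(path), meta)
    hd <- open_slide(path)
    i <- 1L
    lay <- meta$layers
    for (l in seq_len(nrow(lay)) - 1L) {
      for (t in seq_len(lay$x_tiles[l + 1] * lay$y_tiles[l + 1]) - 1L) {
        expect_identical(read_tile(hd, l, t), payloads[[i]])
        i <- i + 1L
      }
    }
    close_slide(hd)
    unlink(path)
  }
})

test_that("slide metadata JSON serialization is canonical and lossless", {
  meta <- meta_2layer()
  json <- metadata_to_json(meta)
  expect_match(json, '^\\{"extent":\\{"width":512,"height":512\\}')
  back <- metadata_from_json(json)
  expect_equal(back, meta)
  expect_identical(metadata_to_json(back), json)  # byte-stable re-serialization
})

test_that("metadata invariants are enforced", {
  expect_error(slide_metadata(0, 10, layers = list(layer_tiling(1, 10, 1, 256))),
               class = "iris_metadata_invalid")
  # scales must be ascending and end at 1
  expect_error(slide_metadata(512, 512, layers = list(
    layer_tiling(512, 512, 1, 256), layer_tiling(512, 512, 0.5, 256))),
    class = "iris_metadata_invalid")
  expect_error(slide_metadata(512, 512, layers = list(
    layer_tiling(512, 512, 0.5, 256))),
    class = "iris_metadata_invalid")
  bad <- list(x_tiles = 3L, y_tiles = 2L, scale = 1)  # grid inconsistent
  expect_error(slide_metadata(512, 512, layers = list(bad)),
               class = "iris_metadata_invalid")
  expect_error(slide_metadata(512, 512, tile_size = 8,
                              layers = list(layer_tiling(512, 512, 1, 8))),
               class = "iris_metadata_invalid")
  expect_error(metadata_from_json("{\"nope\":1}"),
               class = "iris_metadata_invalid")
})
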