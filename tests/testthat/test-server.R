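# In-process application pipeline -------------------------------------------

test_that("served tiles are byte-identical to direct container reads", {
  sl <- make_slide_dir("demo", synthetic_slide_spec(width = 700, height = 700,
                                                    n_layers = 2))
  state <- new_server_state(server_config(sl$dir))
  h <- open_slide(sl$gen$path)
  lay <- sl$gen$metadata$layers
  for (l in seq_len(nrow(lay)) - 1L) {
    for (t in seq_len(lay$x_tiles[l + 1] * lay$y_tiles[l + 1]) - 1L) {
      r1 <- serve_request(state, "GET",
                          sprintf("/slides/demo/layers/%d/tiles/%d", l, t))
      expect_identical(r1$status, 200L)
      expect_identical(r1$headers[["Content-Type"]], "image/jpeg")
      expect_identical(r1$body, read_tile(h, l, t))
      # WADO dialect, 1-based instance/frame, same bytes
      r2 <- serve_request(state, "GET",
                          sprintf("/studies/1.2/series/demo/instances/%d/frames/%d",
                                  l + 1L, t + 1L))
      expect_identical(r2$body, r1$body)
    }
  }
  close_slide(h)
  release_session(state, "local")
})

test_that("both dialects serve the identical metadata document", {
  sl <- make_slide_dir()
  state <- new_server_state(server_config(sl$dir))
  r1 <- serve_request(state, "GET", "/slides/demo/metadata")
  r2 <- serve_request(state, "GET", "/studies/1.2.3/series/demo/metadata")
  expect_identical(r1$status, 200L)
  expect_identical(r1$headers[["Content-Type"]], "application/json")
  expect_identical(r1$body, r2$body)
  expect_identical(rawToChar(r1$body), metadata_to_json(sl$gen$metadata))
  release_session(state, "local")
})

test_that("the error taxonomy maps failures to statuses and narratives", {
  sl <- make_slide_dir()
  state <- new_server_state(server_config(sl$dir))
  expect_identical(serve_request(state, "GET", "/slides/nope/metadata")$status,
                   404L)
  r <- serve_request(state, "GET", "/slides/demo/layers/0/tiles/99")
  expect_identical(r$status, 400L)
  expect_match(rawToChar(r$body), "range violation")
  expect_identical(serve_request(state, "POST", "/slides/demo/metadata")$status,
                   405L)
  expect_identical(serve_request(state, "GET", "/slides/../x/metadata")$status,
                   403L)

  # corrupt container: 500 with a failed-validation narrative, then the
  # server keeps answering other requests normally (crash containment)
  bad <- file.path(sl$dir, "broken.iris")
  writeBin(as.raw(1:100), bad)
  r <- serve_request(state, "GET", "/slides/broken/metadata")
  expect_identical(r$status, 500L)
  expect_match(rawToChar(r$body), "validation")
  expect_identical(serve_request(state, "GET", "/slides/demo/metadata")$status,
                   200L)
  release_session(state, "local")
})

test_that("random fuzz targets yield only 4xx and never slide bytes", {
  sl <- make_slide_dir("s", synthetic_slide_spec(width = 300, height = 300,
                                                 n_layers = 1))
  state <- new_server_state(server_config(sl$dir))
  container <- readBin(sl$gen$path, "raw", file.size(sl$gen$path))
  set.seed(7)
  for (i in 1:1000) {
    target <- rawToChar(as.raw(sample(32:126, sample(1:80, 1), TRUE)))
    method <- sample(c("GET", "POST", "OPTIONS", "XX"), 1)
    r <- serve_request(state, method, target, session_id = "fuzz")
    expect_true(r$status %in% c(204L, 400L, 403L, 404L, 405L))
    expect_true(length(r$body) < length(container))
  }
  release_session(state, "fuzz")
})

# Handle cache ----------------------------------------------------------------

test_that("two sessions share one handle; release drops it at zero", {
  sl <- make_slide_dir()
  cache <- new_handle_cache()
  h1 <- acquire_handle(cache, sl$gen$path)
  h2 <- acquire_handle(cache, sl$gen$path)
  expect_true(inherits(h1, "slide_handle"))
  expect_identical(h1, h2)                     # one shared handle per path
  expect_identical(h1$refcount, 2L)
  expect_identical(nrow(handle_stats(cache)), 1L)
  release_handle(cache, sl$gen$path)
  expect_identical(h1$refcount, 1L)
  release_handle(cache, sl$gen$path)
  expect_identical(nrow(handle_stats(cache)), 0L)
  expect_null(h1$bytes)                        # byte view released
})

test_that("an unknown slide is a 404 miss with no cache side effects", {
  cache <- new_handle_cache()
  e <- acquire_handle(cache, tempfile(fileext = ".iris"))
  expect_s3_class(e, "iris_error_body")
  expect_identical(e$status, 404L)
  expect_identical(nrow(handle_stats(cache)), 0L)
})

# Static file mode -------------------------------------------------------------

test_that("static mode serves the allow-list inside the root and nothing else", {
  root <- tempfile("webroot-"); dir.create(file.path(root, "sub"),
                                           recursive = TRUE)
  writeLines("<html>hi</html>", file.path(root, "index.html"))
  writeLines("body{}", file.path(root, "sub", "app.css"))
  writeLines("secret", file.path(root, "notes.txt"))
  writeBin(as.raw(1:10), file.path(root, "slide.iris"))
  sl <- make_slide_dir()
  state <- new_server_state(server_config(sl$dir, document_root = root))

  r <- serve_request(state, "GET", "/index.html")
  expect_identical(r$status, 200L)
  expect_identical(r$headers[["Content-Type"]], "text/html")
  expect_identical(serve_request(state, "GET", "/sub/app.css")$status, 200L)
  expect_identical(serve_request(state, "GET", "/slide.iris")$status, 403L)
  expect_identical(serve_request(state, "GET", "/notes.txt")$status, 403L)
  expect_identical(serve_request(state, "GET", "/missing.html")$status, 404L)
  expect_identical(serve_request(state, "GET", "/a/../../etc/hosts")$status,
                   403L)

  # symlink escape: resolves outside the root
  outside <- tempfile(fileext = ".html"); writeLines("x", outside)
  ok <- file.symlink(outside, file.path(root, "esc.html"))
  if (isTRUE(ok)) {
    expect_identical(serve_request(state, "GET", "/esc.html")$status, 403L)
  }

  # static service disabled entirely without a document root
  state2 <- new_server_state(server_config(sl$dir))
  expect_identical(serve_request(state2, "GET", "/index.html")$status, 404L)
})

# Live server: sessions, two-stack behaviour ----------------------------------

test_that("handle refcounts track live connections and end empty", {
  sl <- make_slide_dir()
  srv <- start_test_server(sl$dir, debug = TRUE)
  on.exit(stop_test_server(srv))

  c1 <- http_open(srv$port)
  r <- http_request(c1, "GET", "/slides/demo/layers/0/tiles/0")
  expect_identical(r$status, 200L)
  st <- wait_for_handles(srv$port, function(s) nrow(s) == 1 && s$refcount == 1)
  expect_equal(st$refcount, 1)

  c2 <- http_open(srv$port)
  http_request(c2, "GET", "/slides/demo/metadata")
  st <- wait_for_handles(srv$port, function(s) nrow(s) == 1 && s$refcount == 2)
  expect_equal(st$refcount, 2)   # shared between TCP sessions

  # repeated requests on the same connection take no extra reference
  http_request(c1, "GET", "/slides/demo/layers/1/tiles/2")
  expect_equal(handle_snapshot(srv$port)$refcount, 2)

  close(c1)
  st <- wait_for_handles(srv$port, function(s) nrow(s) == 1 && s$refcount == 1)
  expect_equal(st$refcount, 1)
  close(c2)
  st <- wait_for_handles(srv$port, function(s) nrow(s) == 0)
  expect_equal(nrow(st), 0)      # last session closed: slide unmapped
})

test_that("a randomized session schedule keeps refcount == live sessions", {
  sl <- make_slide_dir()
  srv <- start_test_server(sl$dir, debug = TRUE)
  on.exit(stop_test_server(srv))
  set.seed(12)
  conns <- list()
  for (step in 1:25) {
    if (length(conns) == 0L || (stats::runif(1) < 0.55 && length(conns) < 8)) {
      con <- http_open(srv$port)
      expect_identical(
        http_request(con, "GET", "/slides/demo/layers/0/tiles/0")$status, 200L)
      conns[[length(conns) + 1L]] <- con
    } else {
      k <- sample(length(conns), 1)
      close(conns[[k]])
      conns[[k]] <- NULL
    }
    n <- length(conns)
    st <- wait_for_handles(srv$port, function(s) {
      (n == 0 && nrow(s) == 0) || (n > 0 && nrow(s) == 1 && s$refcount == n)
    })
    if (n == 0) expect_equal(nrow(st), 0) else
      expect_equal(st$refcount, n)
  }
  for (con in conns) close(con)
  st <- wait_for_handles(srv$port, function(s) nrow(s) == 0)
  expect_equal(nrow(st), 0)
})

test_that("a stalled file-system worker never blocks the network stack", {
  sl <- make_slide_dir()
  srv <- start_test_server(sl$dir, fs_workers = 1, tile_delay = 1.5)
  on.exit(stop_test_server(srv))

  # occupy the single worker with a delayed tile job
  cA <- http_open(srv$port); on.exit(close(cA), add = TRUE)
  http_send(cA, "GET", "/slides/demo/layers/0/tiles/0")
  Sys.sleep(0.2)

  # a malformed request on another connection is rejected immediately
  cB <- http_open(srv$port)
  t0 <- Sys.time()
  rB <- http_request(cB, "GET", "/slides/../x/metadata")
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  close(cB)
  expect_identical(rB$status, 403L)
  expect_lt(elapsed, 0.1)

  # a second queued tile request completes after the first: FIFO order
  cC <- http_open(srv$port); on.exit(close(cC), add = TRUE)
  http_send(cC, "GET", "/slides/demo/layers/0/tiles/0")
  rA <- http_read_response(cA); tA <- Sys.time()
  rC <- http_read_response(cC); tC <- Sys.time()
  expect_identical(rA$status, 200L)
  expect_identical(rC$status, 200L)
  expect_gt(as.numeric(tC - tA, units = "secs"), 0.5)
})

test_that("OPTIONS preflight and CORS headers follow configuration", {
  sl <- make_slide_dir()
  srv <- start_test_server(sl$dir, origin = "anonymous")
  on.exit(stop_test_server(srv))
  r <- http_once(srv$port, "OPTIONS", "/slides/demo/layers/0/tiles/0")
  expect_identical(r$status, 204L)
  expect_identical(unname(r$headers["access-control-allow-methods"]),
                   "GET, OPTIONS")
  r <- http_once(srv$port, "GET", "/slides/demo/metadata")
  expect_identical(unname(r$headers["access-control-allow-origin"]), "*")

  srv2 <- start_test_server(sl$dir)
  on.exit(stop_test_server(srv2), add = TRUE)
  r <- http_once(srv2$port, "GET", "/slides/demo/metadata")
  expect_false("access-control-allow-origin" %in% names(r$headers))
})

test_that("garbage on the wire gets a 4xx and the server stays up", {
  sl <- make_slide_dir()
  srv <- start_test_server(sl$dir)
  on.exit(stop_test_server(srv))
  con <- http_open(srv$port)
  writeBin(charToRaw("NOT-HTTP\r\n\r\n"), con); flush(con)
  r <- http_read_response(con)
  expect_identical(r$status, 400L)
  close(con)
  expect_identical(http_once(srv$port, "GET", "/slides/demo/metadata")$status,
                   200L)
})
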