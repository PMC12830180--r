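# Live-server harness: runs iris_serve() in a background R process and talks
# to it either through curl or through a raw socket HTTP/1.1 client (the
# latter gives tests exact control over connection lifetimes, which the
# session-refcount contracts need).

start_test_server <- function(slide_dir, ...) {
  ready <- tempfile("ready-")
  args <- list(...)
  px <- callr::r_bg(
    function(slide_dir, ready, args) {
      do.call(iristiles::iris_serve,
              c(list(slide_dir = slide_dir, ready_file = ready, quiet = TRUE),
                args))
    },
    args = list(slide_dir = slide_dir, ready = ready, args = args),
    supervise = TRUE)
  deadline <- Sys.time() + 20
  while (!file.exists(ready)) {
    if (!px$is_alive() || Sys.time() > deadline) {
      err <- tryCatch(px$read_all_error(), error = function(e) "")
      stop("test server failed to start: ", err)
    }
    Sys.sleep(0.05)
  }
  port <- as.integer(readLines(ready))
  srv <- list(process = px, port = port,
              base = sprintf("http://127.0.0.1:%d", port))
  srv
}

stop_test_server <- function(srv) {
  try(srv$process$kill(), silent = TRUE)
  invisible(NULL)
}

with_test_server <- function(slide_dir, ..., body) {
  srv <- start_test_server(slide_dir, ...)
  on.exit(stop_test_server(srv))
  body(srv)
}

# ---- raw socket HTTP client -------------------------------------------------

http_open <- function(port) {
  socketConnection("127.0.0.1", port, blocking = TRUE, open = "a+b",
                   timeout = 15)
}

http_send <- function(con, method, target, headers = character()) {
  head <- paste0(sprintf("%s %s HTTP/1.1\r\nHost: localhost\r\n", method,
                         target),
                 paste0(headers, collapse = ""), "\r\n")
  writeBin(charToRaw(head), con)
  flush(con)
}

# Read one full HTTP response (requires a Content-Length header, which this
# server always sends).
http_read_response <- function(con) {
  buf <- raw()
  repeat {
    pos <- grepRaw("\r\n\r\n", buf, fixed = TRUE)
    if (length(pos)) break
    chunk <- readBin(con, "raw", 1L)
    if (length(chunk) == 0L) stop("connection closed before response head")
    buf <- c(buf, chunk)
  }
  head <- rawToChar(buf[seq_len(pos[1] - 1L)])
  lines <- strsplit(head, "\r\n", fixed = TRUE)[[1]]
  status <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]][2])
  hdr <- lines[-1]
  hv <- sub("^[^:]*:[ \t]*", "", hdr)
  names(hv) <- tolower(sub(":.*$", "", hdr))
  clen <- as.integer(hv[["content-length"]])
  body <- raw()
  while (length(body) < clen) {
    chunk <- readBin(con, "raw", clen - length(body))
    if (length(chunk) == 0L) stop("connection closed mid-body")
    body <- c(body, chunk)
  }
  list(status = status, headers = hv, body = body)
}

http_request <- function(con, method, target, headers = character()) {
  http_send(con, method, target, headers)
  http_read_response(con)
}

# One-shot request on its own connection.
http_once <- function(port, method, target) {
  con <- http_open(port)
  on.exit(close(con))
  http_request(con, method, target)
}

# Poll the debug handle endpoint until `pred` holds (connection closes are
# observed by the server's event loop asynchronously).
wait_for_handles <- function(port, pred, timeout = 5) {
  deadline <- Sys.time() + timeout
  repeat {
    st <- handle_snapshot(port)
    if (pred(st)) return(st)
    if (Sys.time() > deadline) return(st)
    Sys.sleep(0.05)
  }
}

handle_snapshot <- function(port) {
  res <- http_once(port, "GET", "/internal/handles")
  doc <- jsonlite::fromJSON(rawToChar(res$body))
  if (length(doc$handles) == 0L) {
    data.frame(path = character(), refcount = integer())
  } else {
    doc$handles
  }
}
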