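# The socket transport: a single-process event loop implementing the
# two-stack design.
#
# The network stack is the loop itself: it accepts connections, reads
# buffers, parses HTTP request heads and rejects anything malformed
# immediately — it never waits on slide work. Requests that need container or
# document-root bytes are appended to the file-system stack: a FIFO queue
# drained into `fs_workers` concurrency slots. A slot is occupied from
# dispatch until the job's completion deadline (the per-tile test delay
# models a slow file-system thread without blocking the loop), so queued work
# completes in submission order while connection acceptance and request
# rejection stay live.
#
# Sessions are HTTP connections (keep-alive): the first request a connection
# makes against a slide takes one reference on the shared handle; all
# references are dropped when the connection closes, and a handle whose count
# reaches zero is evicted and its byte view released.

HEADER_END <- charToRaw("\r\n\r\n")

#' Run the tile server
#'
#' Starts the RESTful slide server on `port` and serves until `max_seconds`
#' elapses (default: forever). See [server_config()] for the configuration
#' surface; this is the function behind the `iris-restful` command-line
#' entry point.
#'
#' @inheritParams server_config
#' @param ready_file Optional path; once listening, the chosen port number is
#'   written there (used by tests and supervisors to wait for startup).
#' @param max_seconds Serve for at most this many seconds.
#' @param quiet Suppress the one-line-per-request log on stderr.
#' @param poll Event-loop poll interval in seconds.
#' @return Invisibly, the number of requests served (on timed exit).
#' @export
iris_serve <- function(slide_dir, document_root = NULL, origin = NULL,
                       port = 0L, tls = c("off", "self-signed"), cert = NULL,
                       key = NULL, fs_workers = NULL, tile_delay = 0,
                       debug = FALSE, ready_file = NULL, max_seconds = Inf,
                       quiet = FALSE, poll = 0.02) {
  config <- server_config(slide_dir, document_root, origin, port, tls, cert,
                          key, fs_workers, tile_delay, debug)
  state <- new_server_state(config)
  logmsg <- function(...) if (!quiet) cat(sprintf(...), file = stderr())

  if (config$tls == "self-signed") {
    tls_info <- generate_self_signed_cert(config$cert, config$key)
    state$tls <- tls_info
    logmsg("tls: %s certificate %s (key %s, %d-bit RSA)\n",
           if (tls_info$generated) "generated self-signed" else "using supplied",
           tls_info$cert, tls_info$key, cert_key_bits(tls_info$key))
    logmsg(paste0("tls: no TLS socket support in this R runtime; ",
                  "terminate TLS at a fronting load balancer with this pair\n"))
  }

  srv <- NULL
  if (config$port > 0L) {
    srv <- serverSocket(config$port)
    chosen <- config$port
  } else {
    for (try_port in sample(20000:60000, 64L)) {
      srv <- tryCatch(serverSocket(try_port), error = function(e) NULL)
      if (!is.null(srv)) { chosen <- try_port; break }
    }
    if (is.null(srv)) iris_abort("iris_io_error", "no free TCP port found")
  }
  on.exit(close(srv), add = TRUE)
  logmsg("listening on port %d (slides: %s)\n", chosen, config$slide_dir)
  if (!is.null(ready_file)) {
    tmp <- paste0(ready_file, ".tmp")
    writeLines(as.character(chosen), tmp)
    file.rename(tmp, ready_file)
  }

  conns <- new.env(parent = emptyenv())
  next_id <- 0L
  fs_queue <- list()      # FIFO of jobs waiting for a worker slot
  pending <- list()       # dispatched jobs waiting out their deadline
  busy <- 0L
  served <- 0L
  t_end <- Sys.time() + max_seconds

  close_conn <- function(id) {
    cn <- conns[[id]]
    if (is.null(cn)) return(invisible())
    release_session(state, id)
    try(close(cn$sock), silent = TRUE)
    rm(list = id, envir = conns)
  }
  on.exit(for (id in ls(conns)) close_conn(id), add = TRUE)

  send_response <- function(id, resp, keep_alive, method = "-", target = "-",
                            started = NULL) {
    cn <- conns[[id]]
    if (is.null(cn)) return(invisible())
    resp <- finalize_response(state, resp)
    ok <- tryCatch({
      writeBin(response_wire(resp, keep_alive), cn$sock)
      TRUE
    }, error = function(e) FALSE)
    served <<- served + 1L
    ms <- if (is.null(started)) NA_real_ else
      as.numeric(Sys.time() - started, units = "secs") * 1000
    logmsg("%s %s %s %d %.1fms\n", format(Sys.time(), "%H:%M:%OS3"),
           method, target, resp$status, ms)
    if (!ok || !keep_alive) close_conn(id)
  }

  # Parse as many complete requests as the connection's buffer holds. Stops
  # while a file-system response is outstanding so responses keep request
  # order on the wire.
  process_buffer <- function(id) {
    repeat {
      cn <- conns[[id]]
      if (is.null(cn) || cn$waiting > 0L) return(invisible())
      pos <- grepRaw(HEADER_END, cn$buf, fixed = TRUE)
      if (length(pos) == 0L) {
        if (length(cn$buf) > 65536L) {  # oversized head: reject and drop
          send_response(id, build_error(400, "request head too large"), FALSE)
        }
        return(invisible())
      }
      head <- tryCatch(rawToChar(cn$buf[seq_len(pos[1] - 1L)]),
                       error = function(e) NULL)
      cn$buf <- cn$buf[-seq_len(pos[1] + 3L)]
      started <- Sys.time()
      if (is.null(head)) {
        send_response(id, build_error(400, "malformed request head"), FALSE)
        return(invisible())
      }
      lines <- strsplit(head, "\r\n", fixed = TRUE)[[1]]
      parts <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
      if (length(parts) != 3L || !startsWith(parts[3], "HTTP/1")) {
        send_response(id, build_error(400, "malformed request line"), FALSE,
                      started = started)
        return(invisible())
      }
      method <- parts[1]; target <- parts[2]
      hdr <- lines[-1]
      hv <- sub("^[^:]*:[ \t]*", "", hdr)
      names(hv) <- tolower(sub(":.*$", "", hdr))
      header <- function(n) {
        v <- unname(hv[n]); if (length(v) == 0L || is.na(v)) "" else v
      }
      conn_hdr <- tolower(header("connection"))
      keep_alive <- conn_hdr != "close" &&
        !(parts[3] == "HTTP/1.0" && conn_hdr != "keep-alive")
      clen <- suppressWarnings(as.integer(header("content-length")))
      has_body <- !is.na(clen) && clen > 0L
      if (has_body) keep_alive <- FALSE  # bodies are never consumed

      act <- classify_request(state, method, target, session_id = id)
      if (act$kind == "immediate") {
        send_response(id, act$resp, keep_alive, method, target, started)
      } else {
        cn$waiting <- cn$waiting + 1L
        fs_queue[[length(fs_queue) + 1L]] <<- list(
          id = id, job = act, keep_alive = keep_alive, method = method,
          target = target, started = started)
        return(invisible())
      }
    }
  }

  repeat {
    if (Sys.time() >= t_end) break
    ids <- ls(conns)
    socks <- c(list(srv), lapply(ids, function(i) conns[[i]]$sock))
    timeout <- poll
    if (length(pending)) {
      due <- min(vapply(pending, function(p) p$due, numeric(1)))
      timeout <- max(0, min(poll, due - as.numeric(Sys.time())))
    }
    ready <- tryCatch(socketSelect(socks, timeout = timeout),
                      error = function(e) rep(FALSE, length(socks)))

    if (isTRUE(ready[1])) {
      sock <- tryCatch(socketAccept(srv, blocking = FALSE, open = "a+b"),
                       error = function(e) NULL)
      if (!is.null(sock)) {
        next_id <- next_id + 1L
        id <- paste0("c", next_id)
        cn <- new.env(parent = emptyenv())
        cn$sock <- sock; cn$buf <- raw(); cn$waiting <- 0L
        conns[[id]] <- cn
      }
    }

    if (length(ids)) {
      for (k in seq_along(ids)[ready[-1] %in% TRUE]) {
        id <- ids[k]
        cn <- conns[[id]]
        if (is.null(cn)) next
        data <- tryCatch(readBin(cn$sock, "raw", 65536L),
                         error = function(e) raw())
        if (length(data) == 0L) {
          close_conn(id)
        } else {
          cn$buf <- c(cn$buf, data)
          process_buffer(id)
        }
      }
    }

    # dispatch: fill free worker slots in FIFO order
    while (busy < config$fs_workers && length(fs_queue)) {
      item <- fs_queue[[1]]; fs_queue <- fs_queue[-1]
      resp <- run_fs_job(item$job)
      delay <- if (isTRUE(item$job$is_tile)) config$tile_delay else 0
      pending[[length(pending) + 1L]] <- c(
        item[c("id", "keep_alive", "method", "target", "started")],
        list(resp = resp, due = as.numeric(Sys.time()) + delay))
      busy <- busy + 1L
    }

    # completions: deliver responses whose deadline has passed
    if (length(pending)) {
      now <- as.numeric(Sys.time())
      done <- vapply(pending, function(p) p$due <= now, logical(1))
      for (p in pending[done]) {
        cn <- conns[[p$id]]
        if (!is.null(cn)) cn$waiting <- cn$waiting - 1L
        send_response(p$id, p$resp, p$keep_alive, p$method, p$target,
                      p$started)
        busy <- busy - 1L
        if (!is.null(conns[[p$id]])) process_buffer(p$id)
      }
      pending <- pending[!done]
    }
  }
  invisible(served)
}
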