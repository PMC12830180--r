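# Application logic of the tile server, independent of the socket transport.
#
# classify_request() implements the network stack's share of the work: strict
# parsing and routing, with immediate rejection of anything malformed. Every
# request that needs container (or document-root) bytes is returned as a job
# closure for the file-system stack; the event loop runs those through a FIFO
# queue, while serve_request() runs them inline for embedding and testing.

STATIC_ALLOWED_EXT <- c("html", "htm", "js", "css", "json", "xml", "dzi",
                        "png", "jpg", "jpeg", "ico", "svg", "wasm")

STATIC_CONTENT_TYPES <- c(
  html = "text/html", htm = "text/html", js = "text/javascript",
  css = "text/css", json = "application/json", xml = "text/xml",
  dzi = "application/xml", png = "image/png", jpg = "image/jpeg",
  jpeg = "image/jpeg", ico = "image/x-icon", svg = "image/svg+xml",
  wasm = "application/wasm")

#' Server configuration
#'
#' @param slide_dir Directory holding `.iris` slide containers (required).
#' @param document_root Optional directory for restricted static-file service;
#'   `NULL` disables static mode.
#' @param origin Optional CORS origin value; `"anonymous"` (or `"*"`) allows
#'   any origin; `NULL` disables CORS headers.
#' @param port TCP port; 0 picks a free port.
#' @param tls `"off"` or `"self-signed"`; the latter generates a 2048-bit RSA
#'   key and self-signed certificate at startup (see
#'   [generate_self_signed_cert()]).
#' @param cert,key Optional paths to an existing PEM certificate and private
#'   key; when supplied, no generation occurs.
#' @param fs_workers Number of file-system stack worker slots (defaults to the
#'   CPU count).
#' @param tile_delay Per-tile test delay in seconds: each tile job occupies
#'   its worker slot this long before completing. A test hook, 0 in normal
#'   operation.
#' @param debug Enable the `GET /internal/handles` introspection route.
#' @return A `server_config` list.
#' @export
server_config <- function(slide_dir, document_root = NULL, origin = NULL,
                          port = 0L, tls = c("off", "self-signed"),
                          cert = NULL, key = NULL, fs_workers = NULL,
                          tile_delay = 0, debug = FALSE) {
  tls <- match.arg(tls)
  if (!dir.exists(slide_dir)) {
    abort_contract(sprintf("slide directory does not exist: %s", slide_dir))
  }
  if (!is.null(document_root) && !dir.exists(document_root)) {
    abort_contract(sprintf("document root does not exist: %s", document_root))
  }
  if (is.null(fs_workers)) {
    fs_workers <- max(1L, parallel::detectCores())
  }
  structure(list(
    slide_dir = normalizePath(slide_dir),
    document_root = if (!is.null(document_root)) normalizePath(document_root),
    origin = origin, port = as.integer(port), tls = tls,
    cert = cert, key = key, fs_workers = as.integer(fs_workers),
    tile_delay = as.numeric(tile_delay), debug = isTRUE(debug)
  ), class = "server_config")
}

#' In-process server state
#'
#' Builds the state that the socket event loop (or an embedding test) serves
#' from: the configuration, the shared handle cache and the session table.
#'
#' @param config A [server_config()].
#' @return An environment of class `server_state`.
#' @export
new_server_state <- function(config) {
  state <- new.env(parent = emptyenv())
  state$config <- config
  state$cache <- new_handle_cache()
  state$sessions <- new.env(parent = emptyenv())
  class(state) <- "server_state"
  state
}

slide_path_for <- function(state, slide_id) {
  file.path(state$config$slide_dir, paste0(slide_id, CONTAINER_EXT))
}

# Take (at most once per session) a reference on a slide's handle.
session_handle <- function(state, session_id, slide_id) {
  path <- slide_path_for(state, slide_id)
  held <- state$sessions[[session_id]]
  key <- normalizePath(path, mustWork = FALSE)
  if (!is.null(held) && key %in% held) {
    return(state$cache$handles[[key]])
  }
  h <- acquire_handle(state$cache, path)
  if (is_error_body(h)) return(h)
  state$sessions[[session_id]] <- c(held, key)
  h
}

#' Release a session and all slide references it holds
#'
#' Called when a client connection closes; drops one reference per slide the
#' session touched, releasing handles whose count reaches zero.
#'
#' @param state A [new_server_state()].
#' @param session_id Session identifier.
#' @return `NULL`, invisibly.
#' @export
release_session <- function(state, session_id) {
  held <- state$sessions[[session_id]]
  if (!is.null(held)) {
    for (key in held) release_handle(state$cache, key)
    rm(list = session_id, envir = state$sessions)
  }
  invisible(NULL)
}

# ---- file-system stack jobs -------------------------------------------------

fs_metadata_job <- function(state, session_id, req) {
  function() {
    h <- session_handle(state, session_id, req$slide_id)
    if (is_error_body(h)) return(error_body_response(h))
    http_response(200, charToRaw(metadata_to_json(h$metadata)),
                  content_type = "application/json")
  }
}

fs_tile_job <- function(state, session_id, req) {
  function() {
    h <- session_handle(state, session_id, req$slide_id)
    if (is_error_body(h)) return(error_body_response(h))
    bytes <- tryCatch(read_tile(h, req$layer, req$tile), error = function(e) e)
    if (inherits(bytes, "iris_range_error")) {
      return(build_error(400, paste("request range violation:",
                                    conditionMessage(bytes))))
    }
    if (inherits(bytes, "error")) {
      return(build_error(500, conditionMessage(bytes)))
    }
    ctype <- if (h$metadata$encoding == "png") "image/png" else "image/jpeg"
    http_response(200, bytes, content_type = ctype)
  }
}

#' Serve a static file from the restricted document root
#'
#' Serves only files whose extension is on the allow-list and whose resolved
#' path stays inside the document root. Slide containers (`.iris`) are never
#' downloadable, even when they sit inside the root; traversal or symlink
#' escapes and unknown extensions are forbidden.
#'
#' @param document_root Directory configured for static service.
#' @param rel_path Relative path from the request target (already
#'   syntax-checked).
#' @return An `iris_http_response`.
#' @export
static_fetch <- function(document_root, rel_path) {
  ext <- tolower(tools::file_ext(rel_path))
  if (ext == sub("^\\.", "", CONTAINER_EXT)) {
    return(build_error(403,
      "forbidden: slide container files cannot be downloaded"))
  }
  if (!ext %in% STATIC_ALLOWED_EXT) {
    return(build_error(403, sprintf(
      "forbidden: files of type '.%s' are not served", ext)))
  }
  path <- file.path(document_root, rel_path)
  if (!file.exists(path) || dir.exists(path)) {
    return(build_error(404, sprintf("no such file: %s", rel_path)))
  }
  resolved <- normalizePath(path)
  root <- normalizePath(document_root)
  if (!startsWith(resolved, paste0(root, "/"))) {
    return(build_error(403,
      "forbidden: the resolved path escapes the document root"))
  }
  http_response(200, readBin(path, "raw", file.size(path)),
                content_type = unname(STATIC_CONTENT_TYPES[ext]))
}

fs_static_job <- function(state, req) {
  function() static_fetch(state$config$document_root, req$file_path)
}

# ---- routing ----------------------------------------------------------------

# Network-stack share of request handling: parse, reject, or hand a job to
# the file-system stack. Returns list(kind = "immediate", resp = ...) or
# list(kind = "fs", run = function() resp, is_tile = flag).
classify_request <- function(state, method, target, session_id = "local") {
  req <- parse_target(method, target)
  if (is_error_body(req)) {
    return(list(kind = "immediate", resp = error_body_response(req)))
  }
  if (method == "OPTIONS") {
    return(list(kind = "immediate",
                resp = http_response(204,
                  headers = cors_headers(state$config$origin, preflight = TRUE))))
  }
  if (req$dialect == "internal") {
    if (!state$config$debug) {
      return(list(kind = "immediate",
                  resp = build_error(404, "no such resource")))
    }
    stats <- handle_stats(state$cache)
    doc <- jsonlite::toJSON(list(handles = stats), dataframe = "rows")
    return(list(kind = "immediate",
                resp = http_response(200, charToRaw(as.character(doc)),
                                     content_type = "application/json")))
  }
  if (req$dialect == "static") {
    if (is.null(state$config$document_root)) {
      return(list(kind = "immediate",
                  resp = build_error(404,
                    "no such resource (static file service is not enabled)")))
    }
    return(list(kind = "fs", run = fs_static_job(state, req), is_tile = FALSE))
  }
  if (req$resource == "metadata") {
    return(list(kind = "fs", run = fs_metadata_job(state, session_id, req),
                is_tile = FALSE))
  }
  list(kind = "fs", run = fs_tile_job(state, session_id, req), is_tile = TRUE)
}

finalize_response <- function(state, resp) {
  ch <- cors_headers(state$config$origin)
  if (length(ch)) resp$headers[names(ch)] <- ch
  resp
}

# Run a file-system job with per-request crash containment: any internal
# error becomes a 500 and the worker moves on.
run_fs_job <- function(job) {
  tryCatch(job$run(), error = function(e) {
    build_error(500, paste("internal server error:", conditionMessage(e)))
  })
}

#' Serve one request through the full application pipeline
#'
#' Runs a request through strict parsing, routing and (inline) the
#' file-system stack, exactly as the live server does, and returns the
#' response object. Intended for embedding and testing; the socket server
#' runs the same pipeline with the file-system share executed through its
#' FIFO worker queue.
#'
#' @param state A [new_server_state()].
#' @param method HTTP verb.
#' @param target Request target path.
#' @param session_id Session identity used for handle reference counting;
#'   call [release_session()] when a session ends.
#' @return An `iris_http_response` with fields `status`, `headers`, `body`.
#' @export
serve_request <- function(state, method, target, session_id = "local") {
  act <- classify_request(state, method, target, session_id)
  resp <- if (act$kind == "immediate") act$resp else run_fs_job(act)
  finalize_response(state, resp)
}
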