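# Strict parsing of the two API dialects.
#
# Accepted GET targets:
#   Iris RESTful:  /slides/{slide}/metadata
#                  /slides/{slide}/layers/{l}/tiles/{t}
#   WADO-RS:       /studies/{study}/series/{slide}/metadata
#                  /studies/{study}/series/{slide}/instances/{i}/frames/{f}
#
# Anything else is either a static-file candidate (when a document root is
# configured) or an error. Parsing never touches the file system: ids are
# validated against a conservative character set, indices must be plain
# decimal, and any traversal construct ("..", an encoded separator, a query
# string) is rejected outright.

ID_RE <- "^[A-Za-z0-9][A-Za-z0-9._-]*$"
INDEX_RE <- "^(0|[1-9][0-9]*)$"

parsed_request <- function(dialect, resource, slide_id = NULL, layer = NULL,
                           tile = NULL, file_path = NULL) {
  structure(list(dialect = dialect, resource = resource, slide_id = slide_id,
                 layer = layer, tile = tile, file_path = file_path),
            class = "iris_parsed_request")
}

is_safe_segment <- function(seg) {
  grepl(ID_RE, seg) && !grepl("\\.\\.", seg, fixed = FALSE)
}

#' Parse an HTTP request target against the API grammars
#'
#' Strictly classifies a request into one of the two slide API dialects
#' (`iris`, `wado`), a static-file candidate (`static`), or the debug handle
#' introspection route (`internal`). Requests that do not adhere exactly to a
#' grammar are rejected: wrong verbs get 405, malformed targets 400, and any
#' traversal construct (a `..` segment, percent-encoding, a backslash) 403 —
#' all without touching the file system.
#'
#' @param method HTTP verb, e.g. `"GET"`.
#' @param target Request target path, e.g. `"/slides/s1/layers/2/tiles/23"`.
#' @return An `iris_parsed_request` on success, otherwise an [error_body()].
#' @export
parse_target <- function(method, target) {
  if (!is.character(method) || length(method) != 1L ||
      !is.character(target) || length(target) != 1L || is.na(target)) {
    return(error_body(400, "malformed request"))
  }
  if (!method %in% c("GET", "OPTIONS")) {
    return(error_body(405, sprintf(
      "method %s is not allowed: this API accepts GET and OPTIONS only",
      method)))
  }
  if (grepl("\\.\\.", target) || grepl("%", target, fixed = TRUE) ||
      grepl("\\\\", target)) {
    return(error_body(403,
      "forbidden: the request target contains a path traversal construct"))
  }
  if (!startsWith(target, "/") || grepl("[?#[:space:][:cntrl:]]", target) ||
      !validUTF8(target)) {
    return(error_body(400, "malformed request target"))
  }
  seg <- strsplit(sub("^/", "", target), "/", fixed = TRUE)[[1]]
  if (length(seg) == 0L || any(!nzchar(seg))) {
    return(error_body(400, "malformed request target: empty path segment"))
  }

  n <- length(seg)
  if (identical(seg, c("internal", "handles"))) {
    return(parsed_request("internal", "handles"))
  }
  if (seg[1] == "slides") {
    if (n == 3L && seg[3] == "metadata" && is_safe_segment(seg[2])) {
      return(parsed_request("iris", "metadata", slide_id = seg[2]))
    }
    if (n == 6L && seg[3] == "layers" && seg[5] == "tiles" &&
        is_safe_segment(seg[2])) {
      if (!grepl(INDEX_RE, seg[4]) || !grepl(INDEX_RE, seg[6])) {
        return(error_body(400,
          "malformed request: layer and tile indices must be decimal integers"))
      }
      return(parsed_request("iris", "tile", slide_id = seg[2],
                            layer = as.integer(seg[4]),
                            tile = as.integer(seg[6])))
    }
    return(error_body(400, "malformed Iris RESTful request target"))
  }
  if (seg[1] == "studies") {
    if (n >= 2L && !is_safe_segment(seg[2])) {
      return(error_body(400, "malformed WADO-RS request: bad study id"))
    }
    if (n == 5L && seg[3] == "series" && seg[5] == "metadata" &&
        is_safe_segment(seg[4])) {
      return(parsed_request("wado", "metadata", slide_id = seg[4]))
    }
    if (n == 8L && seg[3] == "series" && seg[5] == "instances" &&
        seg[7] == "frames" && is_safe_segment(seg[4])) {
      lt <- wado_frame_to_tile(seg[6], seg[8])
      if (is_error_body(lt)) return(lt)
      return(parsed_request("wado", "tile", slide_id = seg[4],
                            layer = lt$layer, tile = lt$tile))
    }
    return(error_body(400, "malformed WADO-RS request target"))
  }
  # Everything else is only meaningful as a static-file candidate.
  if (!all(vapply(seg, is_safe_segment, logical(1)))) {
    return(error_body(400, "malformed request target"))
  }
  parsed_request("static", "file", file_path = paste(seg, collapse = "/"))
}

#' Map WADO-RS instance/frame numbers to layer and tile indices
#'
#' DICOM instances and frames are 1-based: instance `i` selects layer
#' `i - 1` and frame `f` selects raster tile index `t = f - 1`. Only a single
#' frame per request is supported; a comma-separated frame list is rejected.
#'
#' @param instance,frame Decimal strings from a WADO-RS request target.
#' @return A list with `layer` and `tile` (both 0-based), or an
#'   [error_body()].
#' @export
wado_frame_to_tile <- function(instance, frame) {
  if (grepl(",", frame, fixed = TRUE)) {
    return(error_body(400, paste(
      "this server supports retrieval of a single frame per request;",
      "comma-separated frame lists are not accepted")))
  }
  if (!grepl(INDEX_RE, instance) || !grepl(INDEX_RE, frame)) {
    return(error_body(400,
      "malformed WADO-RS request: instance and frame must be decimal integers"))
  }
  i <- as.integer(instance); f <- as.integer(frame)
  if (is.na(i) || is.na(f) || i == 0L || f == 0L) {
    return(error_body(400,
      "WADO-RS instance and frame numbers are 1-based and must be positive"))
  }
  list(layer = i - 1L, tile = f - 1L)
}

# ---- HTTP response objects --------------------------------------------------

http_response <- function(status, body = raw(), content_type = NULL,
                          headers = character()) {
  if (is.character(body)) body <- charToRaw(paste(body, collapse = "\n"))
  if (!is.null(content_type)) headers[["Content-Type"]] <- content_type
  structure(list(status = as.integer(status), headers = headers, body = body),
            class = "iris_http_response")
}

#' Build a plain-text HTTP error response
#'
#' @param status HTTP status code.
#' @param narrative Plain-text explanation carried as the response body.
#' @return An `iris_http_response`.
#' @export
build_error <- function(status, narrative) {
  http_response(status, narrative, content_type = "text/plain")
}

error_body_response <- function(e) build_error(e$status, e$narrative)

#' CORS headers for a configured origin
#'
#' When the server is started with an origin (`-o/--origin`), every response
#' carries `Access-Control-Allow-Origin` with that value (`*` when configured
#' as `"anonymous"`), and OPTIONS preflights are answered with status 204 and
#' the allowed methods (GET, OPTIONS). With no configured origin no CORS
#' headers are emitted.
#'
#' @param origin Configured origin value, or `NULL` when CORS is disabled.
#' @param preflight Whether the request is an OPTIONS preflight.
#' @return A named character vector of headers (possibly empty).
#' @export
cors_headers <- function(origin, preflight = FALSE) {
  if (is.null(origin)) return(character())
  value <- if (tolower(origin) %in% c("anonymous", "*")) "*" else origin
  h <- c("Access-Control-Allow-Origin" = value)
  if (preflight) {
    h <- c(h, "Access-Control-Allow-Methods" = "GET, OPTIONS",
           "Access-Control-Max-Age" = "86400")
  }
  h
}

STATUS_REASONS <- c(
  "200" = "OK", "204" = "No Content", "400" = "Bad Request",
  "403" = "Forbidden", "404" = "Not Found", "405" = "Method Not Allowed",
  "500" = "Internal Server Error")

# Serialize a response to HTTP/1.1 wire bytes.
response_wire <- function(resp, keep_alive = TRUE) {
  reason <- STATUS_REASONS[as.character(resp$status)]
  if (is.na(reason)) reason <- "Unknown"
  h <- resp$headers
  h[["Content-Length"]] <- as.character(length(resp$body))
  h[["Connection"]] <- if (keep_alive) "keep-alive" else "close"
  head <- paste0(
    sprintf("HTTP/1.1 %d %s\r\n", resp$status, reason),
    paste0(names(h), ": ", unlist(h), "\r\n", collapse = ""),
    "\r\n")
  c(charToRaw(head), resp$body)
}
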