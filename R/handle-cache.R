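# Reference-counted slide handle cache.
#
# At most one open handle exists per canonical container path; it is shared
# between all client sessions reading that slide. The count tracks sessions
# (HTTP connections), not requests: a session holds one reference per slide
# it has touched, taken on first touch and dropped when the connection
# closes. When the last reference goes the handle is evicted and its byte
# view released.

#' Create an empty slide-handle cache
#'
#' @return An environment of class `handle_cache`.
#' @export
new_handle_cache <- function() {
  cache <- new.env(parent = emptyenv())
  cache$handles <- new.env(parent = emptyenv())
  class(cache) <- "handle_cache"
  cache
}

#' Acquire a shared handle for a slide container
#'
#' On a cache hit the shared handle's reference count is incremented; on a
#' miss the container is validated and opened (lazily, at first touch) and
#' inserted with a count of 1. A missing file yields a 404 [error_body()]; a
#' container failing validation yields a 500 with a "failed validation"
#' narrative, and nothing is cached.
#'
#' @param cache A [new_handle_cache()].
#' @param path Path to the container file.
#' @return A `slide_handle`, or an [error_body()].
#' @export
acquire_handle <- function(cache, path) {
  if (!file.exists(path)) {
    return(error_body(404, sprintf(
      "unknown slide: no container found for '%s'",
      sub("\\.iris$", "", basename(path)))))
  }
  key <- normalizePath(path)
  entry <- cache$handles[[key]]
  if (!is.null(entry)) {
    entry$refcount <- entry$refcount + 1L
    return(entry)
  }
  h <- tryCatch(open_slide(key), error = function(e) e)
  if (inherits(h, "iris_validation_error")) {
    return(error_body(500, paste("failed validation:", conditionMessage(h))))
  }
  if (inherits(h, "error")) {
    return(error_body(500, paste("could not open slide:", conditionMessage(h))))
  }
  cache$handles[[key]] <- h
  h
}

#' Release one reference to a cached handle
#'
#' Decrements the handle's reference count; at zero the handle is evicted
#' from the cache and its mapped byte view released.
#'
#' @inheritParams acquire_handle
#' @return `TRUE` if a reference was released, invisibly.
#' @export
release_handle <- function(cache, path) {
  key <- normalizePath(path, mustWork = FALSE)
  entry <- cache$handles[[key]]
  if (is.null(entry)) return(invisible(FALSE))
  entry$refcount <- entry$refcount - 1L
  if (entry$refcount <= 0L) {
    close_slide(entry)
    rm(list = key, envir = cache$handles)
  }
  invisible(TRUE)
}

#' Snapshot of the handle cache
#'
#' @inheritParams acquire_handle
#' @return A tibble with one row per cached handle: `path`, `refcount`.
#' @export
handle_stats <- function(cache) {
  keys <- sort(ls(cache$handles))
  tibble::tibble(
    path = keys,
    refcount = vapply(keys, function(k) cache$handles[[k]]$refcount,
                      integer(1), USE.NAMES = FALSE))
}
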