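# Classed conditions used across the package.
#
# Validation failures of the on-disk container all inherit
# "iris_validation_error" plus a specific class naming the failed check, so
# callers can distinguish a bad magic number from a checksum failure without
# string matching. Range and contract violations get their own roots.

iris_abort <- function(class, message, ...) {
  cnd <- structure(
    class = c(class, "iris_error", "error", "condition"),
    list(message = message, call = NULL, ...)
  )
  stop(cnd)
}

abort_validation <- function(kind, message) {
  iris_abort(c(paste0("iris_", kind), "iris_validation_error"), message)
}

abort_range <- function(message) iris_abort("iris_range_error", message)

abort_contract <- function(message) iris_abort("iris_contract_error", message)

#' Plain-text HTTP error body
#'
#' The server's error taxonomy pairs an HTTP status code with a human-readable
#' narrative. Narratives are always plain text (no markup) so that clients can
#' surface them directly.
#'
#' @param status HTTP status code (400, 403, 404, 405 or 500).
#' @param narrative Non-empty plain-text explanation of the failure.
#' @return An object of class `iris_error_body` with fields `status` and
#'   `narrative`.
#' @export
error_body <- function(status, narrative) {
  stopifnot(is.numeric(status), length(status) == 1L,
            is.character(narrative), nzchar(narrative))
  structure(list(status = as.integer(status), narrative = narrative),
            class = "iris_error_body")
}

is_error_body <- function(x) inherits(x, "iris_error_body")

#' @export
print.iris_error_body <- function(x, ...) {
  cat(sprintf("<HTTP %d> %s\n", x$status, x$narrative))
  invisible(x)
}
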