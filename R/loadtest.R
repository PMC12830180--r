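# Ramped virtual-user load harness.
#
# Mirrors the common load-tool protocol: virtual users are started at a fixed
# ramp rate; each user fetches the slide metadata once to learn the tile
# bounds, then loops issuing GET-tile requests at uniformly random in-bounds
# (layer, x, y) addresses with a uniform think time between a response and
# the next request. No client-side caching. The report follows the usual
# load-tool CSV columns (per-second window, request count, failures, p50 /
# p75 / p95 latency) so results are directly comparable across servers;
# absolute numbers are hardware- and network-bound.

#' Sample uniformly random in-bounds tile addresses
#'
#' @param levels Level table from [configure_from_metadata()].
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return A tibble with columns `layer`, `x`, `y`, all 0-based and within
#'   each drawn layer's tile grid.
#' @export
sample_tiles <- function(levels, n, seed) {
  with_preserved_rng(seed, {
    layer <- sample(levels$level, n, replace = TRUE)
    xt <- levels$x_tiles[match(layer, levels$level)]
    yt <- levels$y_tiles[match(layer, levels$level)]
    tibble::tibble(
      layer = as.integer(layer),
      x = as.integer(floor(stats::runif(n) * xt)),
      y = as.integer(floor(stats::runif(n) * yt))
    )
  })
}

#' Run a ramped virtual-user load profile against a live server
#'
#' Ramps `users` virtual users at `ramp_rate` users per second; each user
#' performs one metadata fetch and then loops tile requests at seeded random
#' in-bounds addresses, pausing a uniform think time from `think_time`
#' between response and next request. Any non-200 tile response is counted as
#' a failure and reported, never fatal.
#'
#' @param server_url Base URL of a running server.
#' @param slide_id Slide to sample.
#' @param users Peak number of concurrent virtual users.
#' @param ramp_rate Users started per second.
#' @param duration Total test duration in seconds.
#' @param think_time Length-2 numeric, uniform think-time range in seconds.
#'   Default 1-2 ms, the interval at which each virtual user of the reference
#'   load protocol issues its next request after a response.
#' @param seed Seed for the per-user tile address and think-time sequences;
#'   a fixed seed reproduces the identical request sequence.
#' @param out Optional CSV path for the report.
#' @return A tibble of class `iris_load_report`: one row per elapsed-second
#'   window with `window`, `requests`, `failures` and latency percentiles
#'   `p50`, `p75`, `p95` (ms). Attributes `total_requests`, `total_failures`,
#'   `duration`, `users`.
#' @export
run_load_profile <- function(server_url, slide_id, users = 20L,
                             ramp_rate = 1, duration = 30,
                             think_time = c(0.001, 0.002), seed = 1L,
                             out = NULL) {
  levels <- fetch_levels(server_url, slide_id)
  max_draws <- ceiling(duration / max(min(think_time), 1e-3)) + 10L
  draws <- vector("list", users)
  thinks <- vector("list", users)
  for (u in seq_len(users)) {
    draws[[u]] <- sample_tiles(levels, max_draws, seed + u)
    thinks[[u]] <- with_preserved_rng(seed + 100000L + u,
      stats::runif(max_draws, think_time[1], think_time[2]))
  }

  pool <- curl::new_pool(total_con = users, host_con = users)
  t0 <- Sys.time()
  now <- function() as.numeric(Sys.time() - t0, units = "secs")
  lat <- numeric(0); lat_at <- numeric(0); fail_at <- numeric(0)
  user_idx <- rep(1L, users)
  user_next <- (seq_len(users) - 1L) / ramp_rate  # ramp: start times
  inflight <- rep(FALSE, users)
  meta_done <- rep(FALSE, users)
  meta_url <- sprintf("%s/slides/%s/metadata", sub("/+$", "", server_url),
                      slide_id)

  issue <- function(u) {
    i <- user_idx[u]
    if (i > max_draws) return(invisible())
    is_meta <- !meta_done[u]  # each user starts with one metadata fetch
    url <- if (is_meta) meta_url else {
      d <- draws[[u]][i, ]
      tile_url(server_url, slide_id, d$layer, d$x, d$y, levels)
    }
    started <- now()
    h <- curl::new_handle(url = url, forbid_reuse = FALSE)
    curl::multi_add(
      h, pool = pool,
      done = function(res) {
        took <- (now() - started) * 1000
        if (res$status_code == 200L) {
          lat <<- c(lat, took); lat_at <<- c(lat_at, now())
        } else {
          fail_at <<- c(fail_at, now())
        }
        if (is_meta) {
          meta_done[u] <<- TRUE
          user_next[u] <<- now()
        } else {
          user_idx[u] <<- i + 1L
          user_next[u] <<- now() + thinks[[u]][i]
        }
        inflight[u] <<- FALSE
      },
      fail = function(msg) {
        fail_at <<- c(fail_at, now())
        if (is_meta) meta_done[u] <<- TRUE else user_idx[u] <<- i + 1L
        user_next[u] <<- now() + thinks[[u]][min(i, max_draws)]
        inflight[u] <<- FALSE
      })
    inflight[u] <<- TRUE
  }

  while (now() < duration) {
    due <- which(!inflight & user_next <= now() & user_idx <= max_draws)
    for (u in due) issue(u)
    curl::multi_run(timeout = 0.02, pool = pool)
  }
  curl::multi_run(timeout = 5, pool = pool)  # drain in-flight requests

  win <- floor(lat_at)
  fwin <- floor(fail_at)
  windows <- sort(unique(c(win, fwin)))
  q <- function(w, p) {
    v <- lat[win == w]
    if (length(v) == 0L) NA_real_ else as.numeric(stats::quantile(v, p))
  }
  report <- tibble::tibble(
    window = windows,
    requests = vapply(windows, function(w) sum(win == w) + sum(fwin == w),
                      numeric(1)),
    failures = vapply(windows, function(w) sum(fwin == w), numeric(1)),
    p50 = vapply(windows, q, numeric(1), p = 0.50),
    p75 = vapply(windows, q, numeric(1), p = 0.75),
    p95 = vapply(windows, q, numeric(1), p = 0.95)
  )
  attr(report, "total_requests") <- length(lat) + length(fail_at)
  attr(report, "total_failures") <- length(fail_at)
  attr(report, "duration") <- duration
  attr(report, "users") <- users
  class(report) <- c("iris_load_report", class(report))
  if (!is.null(out)) utils::write.csv(report, out, row.names = FALSE)
  report
}

#' Plot a load-test report
#'
#' Requests per second as a line, with the p50-p95 latency band on a second
#' panel — the conventional view of a ramped load test.
#'
#' @param object An `iris_load_report` from [run_load_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.iris_load_report <- function(object, ...) {
  window <- value <- metric <- NULL  # data-masked column names
  df <- tidyr_free_pivot(object)
  ggplot2::ggplot(df, ggplot2::aes(x = window, y = value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "elapsed time (s)", y = NULL,
                  title = "Ramped load profile")
}

# long format without a tidyr dependency
tidyr_free_pivot <- function(report) {
  metrics <- c(requests = "requests / s", p50 = "p50 latency (ms)",
               p95 = "p95 latency (ms)")
  do.call(rbind, lapply(names(metrics), function(m) {
    data.frame(window = report$window, metric = metrics[[m]],
               value = report[[m]])
  }))
}
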