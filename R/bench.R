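# Resident-memory instrumentation: a sampler polls a process's RSS at a
# fixed interval (default 15 ms) and reports peak minus resting baseline,
# the convention used to isolate a computation's own RAM from the idle
# process footprint. Linux-only (reads /proc).

#' Resident set size of a process
#'
#' @param pid process id (default: this process).
#' @return RSS in MB (decimal), or `NA` if the process is gone.
#' @export
mem_sample <- function(pid = Sys.getpid()) {
  statm <- sprintf("/proc/%d/statm", pid)
  if (!file.exists(statm)) return(NA_real_)
  fields <- tryCatch(scan(statm, what = numeric(), n = 2, quiet = TRUE),
                     error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fields) || length(fields) < 2) return(NA_real_)
  page <- 4096
  fields[2] * page / 1e6
}

#' Sample a process's resident memory over time
#'
#' Polls RSS at `interval_ms` until the process exits or `max_seconds`
#' elapses; if the process disappears mid-trace the partial trace is
#' returned. The resting baseline is the mean of the first `resting_n`
#' samples; the headline number is `peak - resting`.
#'
#' @param pid process id to observe.
#' @param interval_ms sampling interval in milliseconds (default 15).
#' @param max_seconds stop after this long regardless (default 60).
#' @param resting_n samples averaged for the resting baseline.
#' @return a `memory_trace`: list with `trace` (tibble `time_s`, `rss_mb`),
#'   `resting_mb`, `peak_mb`, `delta_mb`, `interval_ms`.
#' @export
memory_trace <- function(pid, interval_ms = 15, max_seconds = 60,
                         resting_n = 5L) {
  t0 <- proc.time()[["elapsed"]]
  times <- numeric(0)
  rss <- numeric(0)
  repeat {
    now <- proc.time()[["elapsed"]] - t0
    if (now > max_seconds) break
    s <- mem_sample(pid)
    if (is.na(s)) break                       # process exited: partial trace
    times <- c(times, now)
    rss <- c(rss, s)
    Sys.sleep(interval_ms / 1000)
  }
  finish_trace(times, rss, interval_ms, resting_n)
}

finish_trace <- function(times, rss, interval_ms, resting_n) {
  resting <- if (length(rss)) mean(utils::head(rss, resting_n)) else NA_real_
  peak <- if (length(rss)) max(rss) else NA_real_
  structure(list(
    trace = tibble::tibble(time_s = times, rss_mb = rss),
    resting_mb = resting, peak_mb = peak, delta_mb = peak - resting,
    interval_ms = interval_ms), class = "memory_trace")
}

#' @export
print.memory_trace <- function(x, ...) {
  cat(sprintf(
    "<memory_trace> %d samples @ %g ms: resting %.1f MB, peak %.1f MB, delta %.1f MB\n",
    nrow(x$trace), x$interval_ms, x$resting_mb, x$peak_mb, x$delta_mb))
  invisible(x)
}

#' Profile the resident memory of an R expression
#'
#' Runs `expr` in a forked child process and samples the child's RSS from
#' the parent at `interval_ms`, so the sampler never perturbs the
#' computation's own allocations.
#'
#' @param expr expression to evaluate (in the child).
#' @param interval_ms sampling interval in milliseconds.
#' @param max_seconds trace cap.
#' @return a `memory_trace` (see [memory_trace()]); the expression's value
#'   is discarded.
#' @export
mem_profile <- function(expr, interval_ms = 15, max_seconds = 300) {
  expr <- substitute(expr)
  env <- parent.frame()
  job <- parallel::mcparallel(eval(expr, env))
  on.exit(suppressWarnings(parallel::mccollect(job, wait = TRUE)), add = TRUE)
  t0 <- proc.time()[["elapsed"]]
  times <- numeric(0)
  rss <- numeric(0)
  repeat {
    now <- proc.time()[["elapsed"]] - t0
    if (now > max_seconds) break
    s <- mem_sample(job$pid)
    done <- !is.null(parallel::mccollect(job, wait = FALSE, timeout = 0))
    if (is.na(s)) break
    times <- c(times, now)
    rss <- c(rss, s)
    if (done) break
    Sys.sleep(interval_ms / 1000)
  }
  finish_trace(times, rss, interval_ms, resting_n = 5L)
}

#' Benchmark fit memory across cube sizes
#'
#' Informational check of the out-of-core contract: at fixed peak count and
#' batch size, the fit's peak-minus-resting RSS should be flat in the number
#' of spectra (and grow with the batch size, not the cube). Not intended as
#' a hard assertion — absolute numbers are hardware- and allocator-
#' dependent.
#'
#' @param n_spectra_values cube sizes (rows) to test.
#' @param n_peaks peak count for every cube.
#' @param batch_size batch size for every fit (default heuristic at the
#'   smallest cube).
#' @param dir scratch directory for the generated cubes.
#' @param interval_ms RSS sampling interval.
#' @return tibble: `n_spectra`, `delta_mb`, `peak_mb`, `seconds`.
#' @export
bench_fit_memory <- function(n_spectra_values = c(10000L, 50000L, 100000L),
                             n_peaks = 50L, batch_size = NULL,
                             dir = tempdir(), interval_ms = 15) {
  if (is.null(batch_size))
    batch_size <- default_batch_size(n_peaks, min(n_spectra_values))
  rows <- lapply(n_spectra_values, function(m) {
    sp <- synthetic_spec(m, n_peaks, rank = 5L, seed = 97L)
    p <- file.path(dir, sprintf("bench_%d", m))
    gen <- generate_datacube(sp, p)
    t0 <- proc.time()[["elapsed"]]
    tr <- mem_profile(ipca_fit(gen$cube, batch_size = batch_size),
                      interval_ms = interval_ms)
    tibble::tibble(n_spectra = m, delta_mb = tr$delta_mb,
                   peak_mb = tr$peak_mb,
                   seconds = proc.time()[["elapsed"]] - t0)
  })
  dplyr::bind_rows(rows)
}
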