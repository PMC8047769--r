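#' Scan timing model for the virtual instrument
#'
#' On a real instrument the time between successive scan start times folds
#' together acquisition and controller processing. The simulator uses that
#' folded duration directly: the clock advances by `ms1` seconds per MS1
#' survey scan (acquisition plus processing) and `ms2` seconds per MS2 scan.
#' Optional Gaussian jitter on the durations emulates the run-to-run scan
#' time variation of real hardware (off by default, keeping runs exactly
#' reproducible).
#'
#' Typical folded MS1 durations differ by controller because processing
#' differs: see [default_timing()].
#'
#' @param ms1 MS1 duration in seconds (> 0).
#' @param ms2 MS2 duration in seconds (> 0).
#' @param jitter_sd standard deviation of additive Gaussian jitter on each
#'   scan duration (seconds, >= 0; default 0).
#' @return a `scan_timing_model` list.
#' @export
scan_timing_model <- function(ms1 = 0.56, ms2 = 0.20, jitter_sd = 0) {
  stopifnot(ms1 > 0, ms2 > 0, jitter_sd >= 0)
  structure(list(ms1 = ms1, ms2 = ms2, jitter_sd = jitter_sd),
            class = "scan_timing_model")
}

#' Default per-controller scan timing
#'
#' Folded MS1 scan-plus-processing durations measured on an Orbitrap
#' tribrid: 0.54 s for full-scan, 0.56 s for TopN, 0.61 s for WeightedDEW
#' and 0.68 s for SmartROI (ROI tracking is the slowest to process). The
#' MS2 duration defaults to 0.20 s, reflecting the much lower MS2 resolution.
#'
#' @param controller one of `"fullscan"`, `"topn"`, `"weighteddew"`,
#'   `"smartroi"`.
#' @param ms2 MS2 duration in seconds.
#' @return a [scan_timing_model()].
#' @export
default_timing <- function(controller = c("topn", "fullscan", "weighteddew",
                                          "smartroi"),
                           ms2 = 0.20) {
  controller <- match.arg(controller)
  ms1 <- switch(controller, fullscan = 0.54, topn = 0.56,
                weighteddew = 0.61, smartroi = 0.68)
  scan_timing_model(ms1 = ms1, ms2 = ms2)
}

#' Synthesize an MS1 survey scan from a mixture
#'
#' Returns the centroided MS1 peak list at time `t`: every chemical whose
#' chromatogram is at or above the detection floor appears at its true m/z
#' with its current intensity, sorted ascending by m/z.
#'
#' @param mixture a `dda_mixture`.
#' @param t scan start time in seconds, within `[0, run_length]`.
#' @param detection_floor minimum reported intensity (> 0).
#' @return a list with elements `start_time`, `mz`, `intensity` (parallel,
#'   ascending in m/z).
#' @export
acquire_ms1 <- function(mixture, t, detection_floor = 5e3) {
  stopifnot(detection_floor > 0)
  if (!is.finite(t) || t < 0 || t > mixture$run_length)
    stop("scan time ", t, " is outside the run [0, ", mixture$run_length, "]")
  ints <- mixture_intensities(mixture, t)
  keep <- which(ints >= detection_floor)
  ord <- keep[order(mixture$chemicals$mz[keep])]
  list(start_time = t,
       mz = mixture$chemicals$mz[ord],
       intensity = ints[ord])
}

#' Interleave MS2 scan requests with the next survey scan (shifted scheduling)
#'
#' Given the `n` MS2 requests produced from one MS1 scan, a shift of `k`
#' defers the last `k` of them until after the next MS1 scan: the plan is
#' `n - k` MS2 scans, then the next MS1 scan, then the remaining `k` MS2
#' scans (which still derive from the earlier MS1). With `shift_k = 0` the
#' duty cycle is the standard one: all MS2 scans, then the next MS1. On real
#' hardware this lets the controller process an MS1 scan while the deferred
#' MS2 scans are still being acquired, so the instrument does not idle.
#'
#' @param requests data frame of MS2 requests (any columns; one row per
#'   request), possibly with zero rows.
#' @param shift_k integer >= 0; number of MS2 scans to defer past the next
#'   MS1. Values above `nrow(requests)` are clamped (with a message).
#' @return a data frame plan with columns `level` (1 = MS1, 2 = MS2) and
#'   `request` (row index into `requests`, NA for the MS1 entry), in
#'   execution order. Contains exactly one MS1 entry.
#' @examples
#' reqs <- data.frame(precursor_mz = c(150, 320, 410))
#' apply_shift(reqs, 0)$level   # 2 2 2 1
#' apply_shift(reqs, 1)$level   # 2 2 1 2
#' @export
apply_shift <- function(requests, shift_k = 0) {
  n <- if (is.null(requests)) 0L else nrow(requests)
  stopifnot(length(shift_k) == 1, shift_k >= 0, shift_k == round(shift_k))
  if (shift_k > n) {
    message("shift_k = ", shift_k, " exceeds the ", n,
            " MS2 request(s); clamping to ", n)
    shift_k <- n
  }
  level <- c(rep(2L, n - shift_k), 1L, rep(2L, shift_k))
  request <- c(seq_len(n - shift_k), NA_integer_,
               if (shift_k > 0) seq.int(n - shift_k + 1L, n))
  data.frame(level = level, request = request)
}

#' Run an acquisition controller against a mixture
#'
#' The virtual-instrument event loop. Starting from one queued MS1 survey
#' scan at t = 0, the loop executes the scan at the front of the queue,
#' advances the clock by the configured duration, and — after each MS1 scan
#' — hands the completed scan to the controller, which returns zero or more
#' MS2 scan requests. The requests and the next MS1 scan are queued in the
#' order given by [apply_shift()] with the controller's shift parameter.
#' The run ends when the next scan would not finish by `run_length`.
#'
#' @param controller a controller object (see [topn_controller()],
#'   [weighted_dew_controller()], [smartroi_controller()],
#'   [fullscan_controller()]).
#' @param mixture a `dda_mixture`.
#' @param timing a [scan_timing_model()]; defaults to the controller's
#'   [default_timing()].
#' @param run_length run length in seconds (defaults to the mixture's).
#' @param detection_floor MS1 detection floor passed to [acquire_ms1()].
#' @param seed seed for the timing jitter stream (only used when
#'   `jitter_sd > 0`).
#' @return an object of class `dda_run`: list with `scans` (data frame:
#'   index, level, start_time, precursor_mz, precursor_intensity,
#'   source_ms1_index), `ms1_peaks` (list of MS1 peak lists, indexed by scan
#'   index), `controller`, `params`, `timing`, `run_length`, `seed`, and
#'   `controller_state` (the controller's final state environment, e.g. the
#'   ROI store of a SmartROI run).
#' @examples
#' mix <- generate_mixture(20, rt_range = c(20, 180), run_length = 200, seed = 3)
#' run <- run_acquisition(topn_controller(N = 5), mix,
#'                        timing = scan_timing_model(0.56, 0.2))
#' summary(run)
#' @export
run_acquisition <- function(controller, mixture,
                            timing = default_timing(controller_name(controller)),
                            run_length = mixture$run_length,
                            detection_floor = 5e3,
                            seed = 1L) {
  stopifnot(inherits(controller, "dda_controller"),
            inherits(mixture, "dda_mixture"),
            run_length > 0)
  state <- controller_init(controller)
  shift_k <- controller_shift(controller)
  jitter <- timing$jitter_sd > 0
  if (jitter) {
    jseed <- as.integer(seed)
    jcount <- 0L
  }
  draw_duration <- function(base) {
    if (!jitter) return(base)
    jcount <<- jcount + 1L
    max(1e-3, base + with_seed(jseed + jcount, stats::rnorm(1, 0, timing$jitter_sd)))
  }

  # queue of pending scans: each entry level, precursor_mz/intensity, source
  queue <- list(list(level = 1L))
  cap <- 1024L
  idx <- 0L
  level <- integer(cap); start_time <- numeric(cap)
  precursor_mz <- numeric(cap); precursor_intensity <- numeric(cap)
  source_ms1 <- integer(cap)
  ms1_peaks <- vector("list", cap)
  t <- 0

  grow <- function() {
    cap2 <- cap * 2L
    length(level) <<- cap2; length(start_time) <<- cap2
    length(precursor_mz) <<- cap2; length(precursor_intensity) <<- cap2
    length(source_ms1) <<- cap2; length(ms1_peaks) <<- cap2
    cap <<- cap2
  }

  while (length(queue) > 0) {
    entry <- queue[[1]]
    queue <- queue[-1]
    dur <- draw_duration(if (entry$level == 1L) timing$ms1 else timing$ms2)
    if (t + dur > run_length + 1e-9) break  # scan would not finish in the run
    idx <- idx + 1L
    if (idx > cap) grow()
    level[idx] <- entry$level
    start_time[idx] <- t
    if (entry$level == 1L) {
      scan <- acquire_ms1(mixture, t, detection_floor)
      scan$index <- idx
      ms1_peaks[[idx]] <- scan
      precursor_mz[idx] <- NA_real_
      precursor_intensity[idx] <- NA_real_
      source_ms1[idx] <- NA_integer_
      requests <- controller_handle_ms1(controller, state, scan)
      # a short cycle cannot defer more scans than it requested
      plan <- apply_shift(requests, min(shift_k, nrow(requests)))
      new_entries <- lapply(seq_len(nrow(plan)), function(i) {
        if (plan$level[i] == 1L) {
          list(level = 1L)
        } else {
          r <- plan$request[i]
          list(level = 2L,
               precursor_mz = requests$precursor_mz[r],
               precursor_intensity = requests$intensity[r],
               source = idx)
        }
      })
      queue <- c(queue, new_entries)
    } else {
      precursor_mz[idx] <- entry$precursor_mz
      precursor_intensity[idx] <- entry$precursor_intensity
      source_ms1[idx] <- entry$source
    }
    t <- t + dur
  }

  keep <- seq_len(idx)
  structure(list(
    scans = data.frame(index = keep, level = level[keep],
                       start_time = start_time[keep],
                       precursor_mz = precursor_mz[keep],
                       precursor_intensity = precursor_intensity[keep],
                       source_ms1_index = source_ms1[keep]),
    ms1_peaks = ms1_peaks[keep],
    controller = controller_name(controller),
    params = controller$params,
    timing = timing,
    run_length = run_length,
    detection_floor = detection_floor,
    seed = seed,
    controller_state = state
  ), class = "dda_run")
}

#' @export
print.dda_run <- function(x, ...) {
  n1 <- sum(x$scans$level == 1L)
  n2 <- sum(x$scans$level == 2L)
  cat(sprintf("DDA acquisition run: %s controller, %.1f s\n",
              x$controller, x$run_length))
  cat(sprintf("  %d scans (%d MS1, %d MS2)\n", nrow(x$scans), n1, n2))
  invisible(x)
}

#' @export
summary.dda_run <- function(object, ...) {
  s <- object$scans
  out <- list(controller = object$controller,
              n_scans = nrow(s),
              n_ms1 = sum(s$level == 1L),
              n_ms2 = sum(s$level == 2L),
              run_length = object$run_length,
              params = object$params)
  class(out) <- "summary.dda_run"
  out
}

#' @export
print.summary.dda_run <- function(x, ...) {
  cat(sprintf("%s controller: %d scans total = %d MS1 + %d MS2 over %.1f s\n",
              x$controller, x$n_scans, x$n_ms1, x$n_ms2, x$run_length))
  if (length(x$params))
    cat("  parameters:",
        paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Plot an acquisition run
#'
#' Scan map: MS1 scan times on the lower track, MS2 fragmentation events
#' above, placed at their precursor m/z.
#'
#' @param x a `dda_run`.
#' @param ... passed to [plot()].
#' @export
plot.dda_run <- function(x, ...) {
  s <- x$scans
  ms2 <- s[s$level == 2L, , drop = FALSE]
  plot(ms2$start_time, ms2$precursor_mz, pch = 16, cex = 0.4,
       xlab = "retention time (s)", ylab = "precursor m/z (Th)",
       main = sprintf("%s: %d MS2 events", x$controller, nrow(ms2)), ...)
  ms1 <- s$start_time[s$level == 1L]
  graphics::rug(ms1, side = 1)
  invisible(x)
}
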