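#' Build a fixed DDA scan schedule
#'
#' The theoretical-optimum computation assumes an idealized instrument that
#' repeats the duty cycle — one MS1 survey scan followed by `N` MS2 scans —
#' from t = 0 for the whole run, with scan start times given by the
#' cumulative mean durations. A scan is scheduled only if it finishes by
#' `run_length`.
#'
#' @param mean_ms1 mean MS1 scan duration in seconds (> 0).
#' @param mean_ms2 mean MS2 scan duration in seconds (> 0).
#' @param N MS2 scans per duty cycle (>= 1).
#' @param run_length run length in seconds.
#' @return data frame with columns `index`, `level` (1/2), `start_time`.
#' @examples
#' build_schedule(1, 1, N = 2, run_length = 6)
#' @export
build_schedule <- function(mean_ms1, mean_ms2, N, run_length) {
  stopifnot(mean_ms1 > 0, mean_ms2 > 0, N >= 1, N == round(N))
  n_cycles <- ceiling(run_length / (mean_ms1 + N * mean_ms2)) + 1L
  level <- rep(c(1L, rep(2L, N)), n_cycles)
  dur <- ifelse(level == 1L, mean_ms1, mean_ms2)
  start <- cumsum(c(0, dur))[seq_along(dur)]
  keep <- start + dur <= run_length + 1e-9   # tolerate accumulation error
  if (!any(keep)) {
    warning("run_length shorter than one MS1 scan: empty schedule")
    return(data.frame(index = integer(), level = integer(),
                      start_time = numeric()))
  }
  data.frame(index = seq_len(sum(keep)), level = level[keep],
             start_time = start[keep])
}

#' Construct a bipartite graph by hand
#'
#' Low-level constructor for a bipartite graph between `n_left` and
#' `n_right` nodes, mainly for testing the matching machinery on arbitrary
#' graphs. [build_graph()] produces the same structure from a scan schedule
#' and peak bounding boxes.
#'
#' @param n_left,n_right node counts.
#' @param left,right parallel integer vectors of edge endpoints (1-based).
#' @return an object of class `dda_bigraph`.
#' @export
bipartite_graph <- function(n_left, n_right, left = integer(),
                            right = integer()) {
  stopifnot(length(left) == length(right),
            all(left >= 1), all(left <= n_left),
            all(right >= 1), all(right <= n_right))
  structure(list(n_left = as.integer(n_left), n_right = as.integer(n_right),
                 edges = data.frame(left = as.integer(left),
                                    right = as.integer(right)),
                 left_ids = NULL, right_ids = NULL),
            class = "dda_bigraph")
}

#' @export
print.dda_bigraph <- function(x, ...) {
  cat(sprintf("Bipartite graph: %d MS2 slots x %d boxes, %d edges\n",
              x$n_left, x$n_right, nrow(x$edges)))
  invisible(x)
}

#' Intensity lookup for synthetic boxes
#'
#' Returns a lookup function mapping (boxes, time) to the MS1 intensity of
#' each box at that time, by evaluating the chromatogram of the chemical
#' whose id the box carries.
#'
#' @param mixture a `dda_mixture`.
#' @return `function(boxes, t)` returning a numeric vector, one intensity
#'   per box row.
#' @export
mixture_intensity_lookup <- function(mixture) {
  ch <- mixture$chemicals
  function(boxes, t) {
    i <- match(boxes$id, ch$id)
    ch$max_intensity[i] * exp(-(t - ch$rt_apex[i])^2 /
                                (2 * ch$width_sigma[i]^2))
  }
}

#' Intensity lookup from recorded MS1 scans
#'
#' Returns a lookup that, for a given time, finds the recorded MS1 scan at
#' that start time (within `tol` seconds) and reports, per box, the most
#' intense MS1 peak inside the box's m/z range — the lookup to use when
#' boxes come from picked real or simulated full-scan data rather than
#' from a known mixture.
#'
#' @param run a `dda_run` containing MS1 scans.
#' @param tol time matching tolerance in seconds.
#' @return `function(boxes, t)`; times with no matching MS1 scan yield
#'   `NA` intensities (treated as below the fragmentation floor by
#'   [build_graph()]).
#' @export
run_intensity_lookup <- function(run, tol = 1e-6) {
  ms1 <- run$scans$index[run$scans$level == 1L]
  times <- run$scans$start_time[run$scans$level == 1L]
  function(boxes, t) {
    k <- which(abs(times - t) <= tol)
    if (length(k) == 0) return(rep(NA_real_, nrow(boxes)))
    scan <- run$ms1_peaks[[ms1[k[1]]]]
    vapply(seq_len(nrow(boxes)), function(b) {
      inside <- scan$mz >= boxes$mz_min[b] & scan$mz <= boxes$mz_max[b]
      if (any(inside)) max(scan$intensity[inside]) else NA_real_
    }, numeric(1))
  }
}

#' Build the scan-slot / bounding-box bipartite graph
#'
#' One side of the graph is the MS2 slots of a scan schedule, the other the
#' picked-peak bounding boxes. An edge — a potential fragmentation event —
#' joins slot `s` and box `b` iff (i) the slot's start time lies within the
#' box's RT bounds, (ii) the MS1 scan immediately preceding the slot also
#' lies within the box's RT bounds, and (iii) the box's MS1 intensity at
#' that preceding scan is at or above the minimum fragmentation intensity.
#' All RT comparisons are inclusive at both endpoints. Missing intensities
#' (`NA` from the lookup) are treated as below the floor.
#'
#' @param schedule a schedule data frame ([build_schedule()] or
#'   [realized_schedule()]).
#' @param boxes bounding-box data frame ([ground_truth_boxes()] format).
#' @param min_intensity minimum MS1 intensity for fragmentation.
#' @param intensity_lookup `function(boxes, t)` as produced by
#'   [mixture_intensity_lookup()] or [run_intensity_lookup()].
#' @return a `dda_bigraph` whose left nodes are the schedule's MS2 slots
#'   (in schedule order) and right nodes the box rows.
#' @export
build_graph <- function(schedule, boxes, min_intensity, intensity_lookup) {
  stopifnot(is.function(intensity_lookup), min_intensity > 0)
  is_ms2 <- schedule$level == 2L
  ms2_rows <- which(is_ms2)
  # index of the MS1 scan preceding each schedule row
  ms1_count <- cumsum(schedule$level == 1L)
  ms1_times <- schedule$start_time[schedule$level == 1L]

  left <- integer(); right <- integer()
  n_missing <- 0L
  for (i in seq_along(ms2_rows)) {
    row <- ms2_rows[i]
    if (ms1_count[row] == 0L) next   # MS2 with no prior MS1: no edges
    t_ms2 <- schedule$start_time[row]
    t_ms1 <- ms1_times[ms1_count[row]]
    cand <- which(boxes$rt_min <= t_ms2 & t_ms2 <= boxes$rt_max &
                    boxes$rt_min <= t_ms1 & t_ms1 <= boxes$rt_max)
    if (length(cand) == 0) next
    ints <- intensity_lookup(boxes[cand, , drop = FALSE], t_ms1)
    n_missing <- n_missing + sum(is.na(ints))
    ok <- !is.na(ints) & ints >= min_intensity
    left <- c(left, rep(i, sum(ok)))
    right <- c(right, cand[ok])
  }
  if (n_missing > 0)
    message(n_missing,
            " (box, MS1 scan) pairs had no intensity data; treated as below the floor")
  g <- bipartite_graph(length(ms2_rows), nrow(boxes), left, right)
  g$left_ids <- schedule$index[ms2_rows]
  g$right_ids <- boxes$id
  g
}

#' Maximum bipartite matching (Hopcroft-Karp)
#'
#' Computes a maximum matching — a largest set of (MS2 slot, box) edges in
#' which no slot and no box appears twice — whose size is the theoretical
#' maximum number of boxes that could be fragmented at least once under
#' the schedule. Adjacency lists are traversed in deterministic (sorted)
#' order, so the returned matching (not just its size) is reproducible.
#'
#' @param graph a `dda_bigraph`.
#' @return list of class `dda_matching` with elements `size` and `pairs`
#'   (data frame `left`, `right`, plus `scan_index`/`box_id` when the graph
#'   carries ids).
#' @export
hopcroft_karp <- function(graph) {
  stopifnot(inherits(graph, "dda_bigraph"))
  adj <- rep(list(integer()), graph$n_left)
  if (nrow(graph$edges) > 0) {
    sp <- split(graph$edges$right, graph$edges$left)
    adj[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  }
  m <- if (graph$n_left == 0) integer() else
    .hk_match(graph$n_left, graph$n_right, adj)
  matched <- which(m > 0)
  pairs <- data.frame(left = matched, right = m[matched])
  if (!is.null(graph$left_ids)) pairs$scan_index <- graph$left_ids[pairs$left]
  if (!is.null(graph$right_ids)) pairs$box_id <- graph$right_ids[pairs$right]
  structure(list(size = nrow(pairs), pairs = pairs), class = "dda_matching")
}

#' @export
print.dda_matching <- function(x, ...) {
  cat(sprintf("Maximum matching: %d (scan, box) pairs\n", x$size))
  invisible(x)
}

#' Extract the realized scan schedule from an acquisition run
#'
#' @param run a `dda_run`.
#' @return schedule data frame (`index`, `level`, `start_time`) of the
#'   scans the run actually executed, usable with [build_graph()].
#' @export
realized_schedule <- function(run) {
  run$scans[, c("index", "level", "start_time")]
}

#' Theoretical optimum of DDA coverage
#'
#' Builds the idealized scan schedule, the slot/box bipartite graph, and
#' its maximum matching; the matching size is the largest number of boxes
#' any DDA controller could fragment at least once under that schedule and
#' fragmentation floor. It requires knowledge of the entire run ahead of
#' time, so it is an upper bound for benchmarking, not an executable
#' strategy.
#'
#' @param x intensity source: a `dda_mixture` (boxes carry chemical ids)
#'   or a `dda_run` with MS1 scans.
#' @param boxes bounding boxes ([ground_truth_boxes()] format).
#' @param mean_ms1,mean_ms2 mean scan durations in seconds.
#' @param N MS2 scans per duty cycle.
#' @param min_intensity minimum MS1 intensity for fragmentation.
#' @param run_length run length in seconds; defaults to the source's.
#' @return the maximum-matching size (integer); the full `dda_matching`
#'   and the graph are attached as attributes `matching` and `graph`.
#' @examples
#' mix <- generate_mixture(30, rt_range = c(20, 380), run_length = 400, seed = 4)
#' optimal_performance(mix, ground_truth_boxes(mix),
#'                     mean_ms1 = 0.56, mean_ms2 = 0.2, N = 10,
#'                     min_intensity = 5e3)
#' @export
optimal_performance <- function(x, boxes, mean_ms1 = 0.56, mean_ms2 = 0.20,
                                N = 10, min_intensity = 5e3,
                                run_length = NULL) {
  lookup <- if (inherits(x, "dda_mixture")) mixture_intensity_lookup(x)
            else if (inherits(x, "dda_run")) run_intensity_lookup(x)
            else stop("x must be a dda_mixture or a dda_run")
  if (is.null(run_length)) run_length <- x$run_length
  schedule <- build_schedule(mean_ms1, mean_ms2, N, run_length)
  graph <- build_graph(schedule, boxes, min_intensity, lookup)
  m <- hopcroft_karp(graph)
  structure(m$size, matching = m, graph = graph)
}
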