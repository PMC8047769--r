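#' Extract MS2 fragmentation events from a run
#'
#' @param run a `dda_run`.
#' @param event_time which time stamps an event for box membership: the MS2
#'   scan's own start time (`"ms2"`, default) or the source MS1 scan's
#'   start time (`"source_ms1"`).
#' @return data frame with columns `ms2_scan_index`, `time`,
#'   `precursor_mz`, `source_ms1_time`.
#' @export
fragmentation_events <- function(run, event_time = c("ms2", "source_ms1")) {
  event_time <- match.arg(event_time)
  s <- run$scans
  ms2 <- s[s$level == 2L, , drop = FALSE]
  src_time <- s$start_time[match(ms2$source_ms1_index, s$index)]
  data.frame(ms2_scan_index = ms2$index,
             time = if (event_time == "ms2") ms2$start_time else src_time,
             precursor_mz = ms2$precursor_mz,
             source_ms1_time = src_time)
}

#' Assign fragmentation events to bounding boxes
#'
#' An event falls into a box iff its precursor m/z lies within the box's
#' m/z bounds and its time within the box's RT bounds, both inclusive. An
#' event may fall into zero or several (overlapping) boxes.
#'
#' @param events event data frame ([fragmentation_events()] format: at
#'   least `time` and `precursor_mz`).
#' @param boxes bounding-box data frame.
#' @return a list, one element per event, of the ids of the boxes the
#'   event falls into (character(0) where none).
#' @export
assign_events <- function(events, boxes) {
  lapply(seq_len(nrow(events)), function(i) {
    hit <- boxes$mz_min <= events$precursor_mz[i] &
      events$precursor_mz[i] <= boxes$mz_max &
      boxes$rt_min <= events$time[i] & events$time[i] <= boxes$rt_max
    boxes$id[hit]
  })
}

#' Fragmentation coverage
#'
#' The number of distinct picked peaks (bounding boxes) that contain at
#' least one fragmentation event. By default an event falling into several
#' overlapping boxes credits all of them; with `unique_assignment = TRUE`
#' each event credits only the first box (in box order) it falls into, so
#' no MS2 scan is counted toward more than one peak.
#'
#' @inheritParams assign_events
#' @param unique_assignment credit each event to at most one box.
#' @return integer count, between 0 and `nrow(boxes)`.
#' @export
coverage <- function(events, boxes, unique_assignment = FALSE) {
  hits <- assign_events(events, boxes)
  if (unique_assignment)
    hits <- lapply(hits, function(h) h[seq_len(min(1, length(h)))])
  length(unique(unlist(hits)))
}

#' Fragmentation efficiency
#'
#' Coverage divided by the number of MS2 scans: how many picked peaks one
#' MS2 scan targets on average. A perfect value of 1.0 means every
#' fragmentation event hit one unique picked peak.
#'
#' @inheritParams coverage
#' @param n_ms2 total number of MS2 scans in the run (>= 1), including
#'   those that hit no box.
#' @return the raw ratio (not rounded).
#' @export
efficiency <- function(events, boxes, n_ms2, unique_assignment = FALSE) {
  if (n_ms2 < 1) stop("efficiency is undefined without MS2 scans (n_ms2 = 0)")
  coverage(events, boxes, unique_assignment) / n_ms2
}

#' Evaluate an acquisition run against picked peaks
#'
#' Scores a run by coverage and efficiency against a set of bounding
#' boxes, keeping the per-box hit counts.
#'
#' @param run a `dda_run`.
#' @param boxes bounding-box data frame.
#' @param unique_assignment see [coverage()].
#' @param event_time see [fragmentation_events()].
#' @return object of class `dda_evaluation`: list with `controller`,
#'   `n_boxes`, `n_scans`, `n_ms1`, `n_ms2`, `coverage`, `efficiency`
#'   (raw ratio) and `box_hits` (named integer vector of events per box).
#' @examples
#' mix <- generate_mixture(40, rt_range = c(20, 380), run_length = 400, seed = 5)
#' run <- run_acquisition(topn_controller(N = 5), mix)
#' evaluate_run(run, ground_truth_boxes(mix))
#' @export
evaluate_run <- function(run, boxes, unique_assignment = FALSE,
                         event_time = "ms2") {
  events <- fragmentation_events(run, event_time)
  hits <- assign_events(events, boxes)
  if (unique_assignment)
    hits <- lapply(hits, function(h) h[seq_len(min(1, length(h)))])
  flat <- unlist(hits)
  box_hits <- table(factor(flat, levels = boxes$id))
  cov <- sum(box_hits > 0)
  n_ms2 <- nrow(events)
  structure(list(
    controller = run$controller,
    n_boxes = nrow(boxes),
    n_scans = nrow(run$scans),
    n_ms1 = sum(run$scans$level == 1L),
    n_ms2 = n_ms2,
    coverage = cov,
    efficiency = if (n_ms2 >= 1) cov / n_ms2 else NA_real_,
    box_hits = stats::setNames(as.integer(box_hits), boxes$id)
  ), class = "dda_evaluation")
}

#' @export
print.dda_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation of %s run against %d picked peaks\n",
              x$controller, x$n_boxes))
  cat(sprintf("  scans: %d total = %d MS1 + %d MS2\n",
              x$n_scans, x$n_ms1, x$n_ms2))
  cat(sprintf("  coverage:   %d peaks fragmented\n", x$coverage))
  cat(sprintf("  efficiency: %.2f\n", x$efficiency))
  invisible(x)
}

#' @export
as.data.frame.dda_evaluation <- function(x, ...) {
  data.frame(controller = x$controller, n_boxes = x$n_boxes,
             n_scans = x$n_scans, n_ms1 = x$n_ms1, n_ms2 = x$n_ms2,
             coverage = x$coverage, efficiency = x$efficiency)
}

make_controller <- function(name, params) {
  ctor <- switch(name,
                 fullscan = fullscan_controller,
                 topn = topn_controller,
                 weighteddew = weighted_dew_controller,
                 smartroi = smartroi_controller,
                 stop("unknown controller: ", name))
  do.call(ctor, params)
}

#' Grid search over controller parameters
#'
#' Runs one simulation per grid point (same mixture, timing and seed
#' throughout, so runs are strictly comparable) and scores each against the
#' boxes. Returns the full score table and the best point; ties are broken
#' by earlier grid order. Simulations run sequentially for determinism.
#'
#' @param controller_name one of `"fullscan"`, `"topn"`, `"weighteddew"`,
#'   `"smartroi"`.
#' @param param_grid data frame, one column per controller parameter, one
#'   row per grid point (e.g. from [expand.grid()]); must be non-empty.
#' @param mixture a `dda_mixture`.
#' @param boxes bounding boxes to score against (default: the mixture's
#'   ground truth at the detection floor).
#' @param timing a [scan_timing_model()]; default per controller.
#' @param run_length run length in seconds.
#' @param objective `"coverage"` (the usual optimization target) or
#'   `"efficiency"`.
#' @param detection_floor MS1 detection floor.
#' @param fixed named list of controller parameters held fixed across the
#'   grid.
#' @return object of class `dda_grid`: list with `table` (the grid plus
#'   `coverage`, `efficiency`, `n_ms2` and `score` columns, heatmap-ready)
#'   and `best` (list: `params`, `score`, `row`).
#' @examples
#' mix <- generate_mixture(30, rt_range = c(20, 280), run_length = 300, seed = 6)
#' gs <- grid_search("topn", expand.grid(dew = c(5, 15, 60)), mix,
#'                   fixed = list(N = 5))
#' gs$best$params
#' @export
grid_search <- function(controller_name, param_grid, mixture,
                        boxes = ground_truth_boxes(mixture, detection_floor),
                        timing = default_timing(controller_name),
                        run_length = mixture$run_length,
                        objective = c("coverage", "efficiency"),
                        detection_floor = 5e3,
                        fixed = list()) {
  objective <- match.arg(objective)
  if (is.null(param_grid) || nrow(param_grid) == 0)
    stop("param_grid must contain at least one grid point")
  scores <- lapply(seq_len(nrow(param_grid)), function(i) {
    params <- c(as.list(param_grid[i, , drop = FALSE]), fixed)
    ctl <- make_controller(controller_name, params)
    run <- run_acquisition(ctl, mixture, timing = timing,
                           run_length = run_length,
                           detection_floor = detection_floor)
    ev <- evaluate_run(run, boxes)
    data.frame(coverage = ev$coverage, efficiency = ev$efficiency,
               n_ms2 = ev$n_ms2)
  })
  table <- cbind(param_grid, do.call(rbind, scores))
  table$score <- table[[objective]]
  best_row <- which.max(table$score)
  structure(list(
    controller = controller_name,
    objective = objective,
    table = table,
    best = list(params = as.list(param_grid[best_row, , drop = FALSE]),
                score = table$score[best_row],
                row = best_row)
  ), class = "dda_grid")
}

#' @export
print.dda_grid <- function(x, ...) {
  cat(sprintf("Grid search (%s, objective = %s): %d points\n",
              x$controller, x$objective, nrow(x$table)))
  cat("best: ", paste(names(x$best$params), unlist(x$best$params),
                      sep = "=", collapse = ", "),
      sprintf(" -> %s = %g\n", x$objective, x$best$score), sep = "")
  invisible(x)
}
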