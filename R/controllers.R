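#' Acquisition controllers
#'
#' Controllers decide, after every completed MS1 survey scan, which
#' precursors to fragment in the following MS2 scans. All controllers share
#' one contract: [controller_init()] creates the per-run state, and
#' [controller_handle_ms1()] receives each completed MS1 scan and returns
#' up to `N` MS2 scan requests. The virtual instrument
#' ([run_acquisition()]) consumes that contract.
#'
#' * `fullscan_controller()` never requests MS2 scans (survey-only run,
#'   used for picking ground-truth peaks).
#' * `topn_controller()` fragments the N most intense MS1 peaks at or above
#'   `min_intensity`, skipping any m/z fragmented within the last `dew`
#'   seconds (binary dynamic exclusion window).
#' * `weighted_dew_controller()` generalizes the binary exclusion to a
#'   linear weight (see [weighted_dew_weight()]) and ranks peaks by
#'   intensity times weight.
#' * `smartroi_controller()` tracks regions of interest across scans
#'   ([update_rois()]) and fragments the N most intense ROIs that pass the
#'   availability rules ([smartroi_available()]); `shift` defers the last
#'   `shift` MS2 scans past the next MS1 scan ([apply_shift()]).
#'
#' @param N maximum MS2 scans per duty cycle (>= 1).
#' @param min_intensity minimum MS1 intensity for fragmentation (> 0).
#' @param dew dynamic exclusion window t0 in seconds (TopN).
#' @param t0,t1 WeightedDEW exclusion and recovery times in seconds,
#'   `t1 >= t0`. The defaults t0 = 15 s, t1 = 120 s are the grid-search
#'   optimum on complex extracts.
#' @param alpha,beta SmartROI availability factors; the defaults
#'   alpha = 1000, beta = 0.1 are the grid-search optimum.
#' @param shift number of MS2 scans deferred past the next MS1 scan
#'   (0, 1 or 2 are the useful values).
#' @param mz_tol_ppm m/z tolerance (ppm) for matching a peak against
#'   exclusion records / ROI traces.
#' @param isolation_halfwidth precursor isolation half-width in Th
#'   (default 0.35, i.e. a 0.7 m/z isolation window).
#' @param roi_min_intensity minimum intensity to seed a new ROI
#'   (defaults to `min_intensity`).
#' @return a controller object (class `dda_controller`).
#' @name controllers
NULL

new_controller <- function(name, params, subclass) {
  structure(list(name = name, params = params),
            class = c(subclass, "dda_controller"))
}

#' @rdname controllers
#' @export
fullscan_controller <- function() {
  new_controller("fullscan", list(), "fullscan_controller")
}

#' @rdname controllers
#' @export
topn_controller <- function(N = 10, min_intensity = 5e3, dew = 15,
                            mz_tol_ppm = 10, isolation_halfwidth = 0.35) {
  stopifnot(N >= 1, min_intensity > 0, dew >= 0, mz_tol_ppm > 0,
            isolation_halfwidth > 0)
  new_controller("topn",
                 list(N = N, min_intensity = min_intensity, dew = dew,
                      mz_tol_ppm = mz_tol_ppm,
                      isolation_halfwidth = isolation_halfwidth),
                 "topn_controller")
}

#' @rdname controllers
#' @export
weighted_dew_controller <- function(N = 10, min_intensity = 5e3,
                                    t0 = 15, t1 = 120,
                                    mz_tol_ppm = 10,
                                    isolation_halfwidth = 0.35) {
  stopifnot(N >= 1, min_intensity > 0, t0 >= 0, t1 >= t0, mz_tol_ppm > 0,
            isolation_halfwidth > 0)
  new_controller("weighteddew",
                 list(N = N, min_intensity = min_intensity, t0 = t0, t1 = t1,
                      mz_tol_ppm = mz_tol_ppm,
                      isolation_halfwidth = isolation_halfwidth),
                 "weighted_dew_controller")
}

#' @rdname controllers
#' @export
smartroi_controller <- function(N = 10, min_intensity = 5e3,
                                alpha = 1000, beta = 0.1, shift = 0,
                                mz_tol_ppm = 10,
                                roi_min_intensity = min_intensity,
                                isolation_halfwidth = 0.35) {
  stopifnot(N >= 1, min_intensity > 0, shift >= 0, mz_tol_ppm > 0,
            roi_min_intensity > 0, isolation_halfwidth > 0)
  if (alpha <= 1)
    warning("alpha <= 1 is a degenerate regime: any intensity change re-arms an ROI")
  if (beta >= 1)
    warning("beta >= 1 is a degenerate regime: availability rule 3b is always satisfied")
  new_controller("smartroi",
                 list(N = N, min_intensity = min_intensity, alpha = alpha,
                      beta = beta, shift = shift, mz_tol_ppm = mz_tol_ppm,
                      roi_min_intensity = roi_min_intensity,
                      isolation_halfwidth = isolation_halfwidth),
                 "smartroi_controller")
}

#' @export
print.dda_controller <- function(x, ...) {
  cat(sprintf("<%s controller>\n", x$name))
  if (length(x$params))
    cat("  ", paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "), "\n", sep = "")
  invisible(x)
}

controller_name <- function(controller) controller$name

controller_shift <- function(controller) {
  s <- controller$params$shift
  if (is.null(s)) 0L else as.integer(s)
}

#' Initialize per-run controller state
#'
#' @param controller a controller object.
#' @return an environment holding the controller's mutable run state
#'   (exclusion records, ROI store, ...).
#' @export
controller_init <- function(controller) UseMethod("controller_init")

#' @export
controller_init.fullscan_controller <- function(controller) new.env(parent = emptyenv())

#' @export
controller_init.topn_controller <- function(controller) {
  e <- new.env(parent = emptyenv())
  e$dew <- empty_dew()
  e
}

#' @export
controller_init.weighted_dew_controller <- controller_init.topn_controller

#' @export
controller_init.smartroi_controller <- function(controller) {
  e <- new.env(parent = emptyenv())
  e$store <- roi_store(mz_tol_ppm = controller$params$mz_tol_ppm,
                       min_roi_intensity = controller$params$roi_min_intensity)
  e
}

#' React to a completed MS1 survey scan
#'
#' @param controller a controller object.
#' @param state the environment from [controller_init()] (updated in
#'   place).
#' @param scan a completed MS1 scan ([acquire_ms1()] format, plus `index`).
#' @return data frame of MS2 requests with columns `precursor_mz` and
#'   `intensity`, at most `N` rows, in fragmentation order.
#' @export
controller_handle_ms1 <- function(controller, state, scan)
  UseMethod("controller_handle_ms1")

#' @export
controller_handle_ms1.fullscan_controller <- function(controller, state, scan)
  empty_requests()

#' @export
controller_handle_ms1.topn_controller <- function(controller, state, scan) {
  p <- controller$params
  sel <- topn_select(scan, N = p$N, min_intensity = p$min_intensity,
                     dew = state$dew, t0 = p$dew, mz_tol_ppm = p$mz_tol_ppm)
  state$dew <- sel$dew
  sel$requests
}

#' @export
controller_handle_ms1.weighted_dew_controller <- function(controller, state, scan) {
  p <- controller$params
  sel <- weighted_dew_select(scan, N = p$N, min_intensity = p$min_intensity,
                             dew = state$dew, t0 = p$t0, t1 = p$t1,
                             mz_tol_ppm = p$mz_tol_ppm)
  state$dew <- sel$dew
  sel$requests
}

#' @export
controller_handle_ms1.smartroi_controller <- function(controller, state, scan) {
  p <- controller$params
  state$store <- update_rois(state$store, scan)
  sel <- smartroi_select(state$store, N = p$N,
                         min_intensity = p$min_intensity,
                         alpha = p$alpha, beta = p$beta,
                         scan_time = scan$start_time)
  state$store <- sel$store
  sel$requests
}

empty_requests <- function() {
  data.frame(precursor_mz = numeric(), intensity = numeric())
}

empty_dew <- function() {
  data.frame(mz = numeric(), t_f = numeric())
}

# Most recent fragmentation time matching each query m/z (within ppm
# tolerance of the record m/z), NA where no record matches.
dew_last_frag <- function(dew, mz, mz_tol_ppm) {
  if (nrow(dew) == 0 || length(mz) == 0) return(rep(NA_real_, length(mz)))
  tol <- dew$mz * mz_tol_ppm * 1e-6
  vapply(mz, function(m) {
    hit <- which(abs(dew$mz - m) <= tol)
    if (length(hit) == 0) NA_real_ else max(dew$t_f[hit])
  }, numeric(1))
}

# Record fragmentations at time t: overwrite the matching record (most
# recent first) or append a new one.
dew_record <- function(dew, mz, t, mz_tol_ppm) {
  for (m in mz) {
    if (nrow(dew) > 0) {
      tol <- dew$mz * mz_tol_ppm * 1e-6
      hit <- which(abs(dew$mz - m) <= tol)
    } else hit <- integer()
    if (length(hit) > 0) {
      hit <- hit[which.max(dew$t_f[hit])]
      dew$mz[hit] <- m
      dew$t_f[hit] <- t
    } else {
      dew <- rbind(dew, data.frame(mz = m, t_f = t))
    }
  }
  dew
}

# Shared ranking: by priority descending, ties toward higher m/z, then
# earlier peak index — fixed so that runs are exactly reproducible.
rank_candidates <- function(priority, mz) order(-priority, -mz, seq_along(mz))

#' TopN precursor selection with binary dynamic exclusion
#'
#' Selects up to `N` of the most intense MS1 peaks at or above
#' `min_intensity`, excluding any peak whose m/z matches an exclusion
#' record fragmented no more than `t0` seconds ago. Selected peaks are
#' recorded in the exclusion list with the scan time.
#'
#' @param scan an MS1 scan (fields `start_time`, `mz`, `intensity`).
#' @param N maximum number of requests.
#' @param min_intensity fragmentation intensity floor.
#' @param dew exclusion records: data frame with columns `mz`, `t_f`
#'   (see [topn_controller()]); start from a zero-row data frame.
#' @param t0 exclusion window in seconds.
#' @param mz_tol_ppm matching tolerance in ppm.
#' @return list with `requests` (data frame `precursor_mz`, `intensity`)
#'   and the updated `dew` records.
#' @export
topn_select <- function(scan, N, min_intensity, dew = empty_dew(),
                        t0 = 15, mz_tol_ppm = 10) {
  t <- scan$start_time
  last <- dew_last_frag(dew, scan$mz, mz_tol_ppm)
  excluded <- !is.na(last) & (t - last <= t0)
  cand <- which(scan$intensity >= min_intensity & !excluded)
  ord <- cand[rank_candidates(scan$intensity[cand], scan$mz[cand])]
  take <- utils::head(ord, N)
  requests <- data.frame(precursor_mz = scan$mz[take],
                         intensity = scan$intensity[take])
  list(requests = requests,
       dew = dew_record(dew, scan$mz[take], t, mz_tol_ppm))
}

#' WeightedDEW exclusion weight
#'
#' The weight of an ion observed at time `t` that was last fragmented at
#' `t_f`: zero for the first `t0` seconds after fragmentation (a standard
#' exclusion), then rising linearly to 1 at `t1` seconds:
#' \deqn{w = 0 \ (t - t_f \le t_0);\quad
#'       w = \frac{t - t_f - t_0}{t_1 - t_0} \ (t_0 < t - t_f < t_1);\quad
#'       w = 1 \ (t - t_f \ge t_1).}
#' With `t1 = t0` the weight is the binary indicator of a standard dynamic
#' exclusion window.
#'
#' @param t current time (seconds); vectorized.
#' @param t_f time of the most recent fragmentation of this m/z; must not
#'   be in the future (`t >= t_f`).
#' @param t0 full-exclusion time (seconds).
#' @param t1 recovery time (seconds), `t1 >= t0`.
#' @return weight(s) in `[0, 1]`.
#' @examples
#' weighted_dew_weight(50, 30, t0 = 20, t1 = 100)  # 0 (just at t0)
#' weighted_dew_weight(90, 30, t0 = 20, t1 = 100)  # 0.5 (midpoint)
#' @export
weighted_dew_weight <- function(t, t_f, t0, t1) {
  stopifnot(t1 >= t0, t0 >= 0)
  if (any(t < t_f))
    stop("t < t_f: fragmentation in the future")
  dt <- t - t_f
  if (t1 == t0) return(ifelse(dt <= t0, 0, 1))
  w <- (dt - t0) / (t1 - t0)
  pmin(1, pmax(0, w))
}

#' WeightedDEW precursor selection
#'
#' Every MS1 peak at or above `min_intensity` is assigned a priority equal
#' to its intensity times its exclusion weight
#' ([weighted_dew_weight()]; never-fragmented peaks have weight 1). The
#' top `N` peaks with strictly positive priority are requested, and their
#' fragmentation times recorded.
#'
#' @inheritParams topn_select
#' @param t1 recovery time in seconds (`t1 = t0` reduces exactly to
#'   [topn_select()]).
#' @return list with `requests` and updated `dew`, as [topn_select()].
#' @export
weighted_dew_select <- function(scan, N, min_intensity, dew = empty_dew(),
                                t0 = 15, t1 = 120, mz_tol_ppm = 10) {
  t <- scan$start_time
  cand <- which(scan$intensity >= min_intensity)
  last <- dew_last_frag(dew, scan$mz[cand], mz_tol_ppm)
  w <- rep(1, length(cand))
  seen <- !is.na(last)
  if (any(seen))
    w[seen] <- weighted_dew_weight(t, last[seen], t0, t1)
  priority <- scan$intensity[cand] * w
  pos <- priority > 0
  ord <- cand[pos][rank_candidates(priority[pos], scan$mz[cand][pos])]
  take <- utils::head(ord, N)
  requests <- data.frame(precursor_mz = scan$mz[take],
                         intensity = scan$intensity[take])
  list(requests = requests,
       dew = dew_record(dew, scan$mz[take], t, mz_tol_ppm))
}

#' SmartROI precursor selection
#'
#' Among the active ROIs that pass the availability rules
#' ([smartroi_available()]), the `N` with the highest current intensity are
#' requested for fragmentation, with the ROI's latest m/z as precursor.
#' Each selected ROI records the fragmentation: its
#' intensity-at-last-fragmentation is set to the current intensity, the
#' running maximum is reset, and the fragmentation time stored.
#'
#' @param store an [roi_store()] already updated with the latest MS1 scan.
#' @param N maximum number of requests.
#' @param min_intensity fragmentation intensity floor (availability rule 1).
#' @param alpha,beta availability factors (rules 3a/3b).
#' @param scan_time time of the triggering MS1 scan (seconds).
#' @return list with `requests` (data frame `precursor_mz`, `intensity`,
#'   `roi_id`) and the updated `store`.
#' @export
smartroi_select <- function(store, N, min_intensity, alpha = 1000,
                            beta = 0.1, scan_time = NA_real_) {
  n <- length(store$active)
  if (n == 0)
    return(list(requests = cbind(empty_requests(), roi_id = integer()),
                store = store))
  avail <- vapply(store$active, smartroi_available_core, logical(1),
                  min_intensity, alpha, beta)
  cand <- which(avail)
  cur_int <- vapply(store$active[cand], roi_current_intensity, numeric(1))
  cur_mz <- vapply(store$active[cand], roi_current_mz, numeric(1))
  keep <- utils::head(rank_candidates(cur_int, cur_mz), N)
  sel <- cand[keep]
  for (r in sel)
    store$active[[r]] <- roi_mark_fragmented(store$active[[r]], scan_time)
  requests <- data.frame(
    precursor_mz = cur_mz[keep],
    intensity = cur_int[keep],
    roi_id = vapply(store$active[sel], function(r) r$id, integer(1))
  )
  list(requests = requests, store = store)
}
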