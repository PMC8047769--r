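#' Create an empty region-of-interest store
#'
#' A region of interest (ROI) is a chain of m/z-consistent signals across
#' consecutive MS1 scans — the unit that real-time peak pickers build first,
#' and the unit the SmartROI controller prioritizes. The store keeps the
#' currently active ROIs (extended by the most recent scan) and the
#' discarded ones, together with the matching tolerance and the intensity
#' threshold for starting a new ROI.
#'
#' @param mz_tol_ppm m/z matching tolerance in parts per million
#'   (default 10).
#' @param min_roi_intensity minimum MS1 peak intensity to seed a new ROI;
#'   defaults to the controllers' minimum fragmentation intensity so that
#'   every fragmentable signal is tracked.
#' @return an object of class `roi_store`.
#' @export
roi_store <- function(mz_tol_ppm = 10, min_roi_intensity = 5e3) {
  stopifnot(mz_tol_ppm > 0, min_roi_intensity > 0)
  structure(list(active = list(), discarded = list(),
                 mz_tol_ppm = mz_tol_ppm,
                 min_roi_intensity = min_roi_intensity,
                 next_id = 1L),
            class = "roi_store")
}

new_roi <- function(id, mz, rt, intensity) {
  list(id = id, mz = mz, rt = rt, intensity = intensity,
       fragmented = FALSE,
       n_fragmentations = 0L,
       intensity_at_last_frag = NA_real_,
       max_since_frag = intensity,
       last_frag_time = NA_real_)
}

roi_current_intensity <- function(roi) roi$intensity[length(roi$intensity)]
roi_current_mz <- function(roi) roi$mz[length(roi$mz)]

#' Update the ROI store with a new MS1 scan
#'
#' Each MS1 peak extends the active ROI whose last m/z is nearest within
#' the tolerance; assignments are made greedily in order of increasing m/z
#' distance (ties broken toward lower peak m/z, then lower ROI m/z), so one
#' peak extends at most one ROI and one ROI gains at most one peak per
#' scan. Unmatched peaks at or above the ROI-creation threshold seed new
#' ROIs. Active ROIs not extended by the scan become inactive and are moved
#' to the discarded list; they are never extended or fragmented afterwards.
#' The running maximum intensity since the last fragmentation is updated
#' for every extended ROI.
#'
#' @param store an [roi_store()].
#' @param scan an MS1 scan as returned by [acquire_ms1()] (fields
#'   `start_time`, `mz`, `intensity`; `mz` ascending).
#' @return the updated `roi_store`.
#' @export
update_rois <- function(store, scan) {
  stopifnot(inherits(store, "roi_store"))
  if (is.unsorted(scan$mz)) stop("MS1 peaks must be sorted ascending by m/z")
  n_peaks <- length(scan$mz)
  n_rois <- length(store$active)

  peak_assigned <- rep(FALSE, n_peaks)
  roi_extended <- rep(FALSE, n_rois)

  if (n_peaks > 0 && n_rois > 0) {
    last_mz <- vapply(store$active, roi_current_mz, numeric(1))
    tol <- last_mz * store$mz_tol_ppm * 1e-6
    # candidate (peak, roi) pairs within tolerance
    d <- abs(outer(scan$mz, last_mz, "-"))
    ok <- which(d <= rep(tol, each = n_peaks))
    if (length(ok) > 0) {
      pk <- (ok - 1L) %% n_peaks + 1L
      ro <- (ok - 1L) %/% n_peaks + 1L
      ord <- order(d[ok], scan$mz[pk], last_mz[ro])
      for (i in ord) {
        p <- pk[i]; r <- ro[i]
        if (peak_assigned[p] || roi_extended[r]) next
        peak_assigned[p] <- TRUE
        roi_extended[r] <- TRUE
        roi <- store$active[[r]]
        roi$mz <- c(roi$mz, scan$mz[p])
        roi$rt <- c(roi$rt, scan$start_time)
        roi$intensity <- c(roi$intensity, scan$intensity[p])
        roi$max_since_frag <- max(roi$max_since_frag, scan$intensity[p])
        store$active[[r]] <- roi
      }
    }
  }

  survivors <- if (n_rois > 0) store$active[roi_extended] else list()
  if (any(!roi_extended)) {
    store$discarded <- c(store$discarded, store$active[!roi_extended])
  }

  # new ROIs from unmatched peaks above the creation threshold, in m/z order
  for (p in which(!peak_assigned)) {
    if (scan$intensity[p] >= store$min_roi_intensity) {
      survivors[[length(survivors) + 1L]] <-
        new_roi(store$next_id, scan$mz[p], scan$start_time, scan$intensity[p])
      store$next_id <- store$next_id + 1L
    }
  }
  store$active <- survivors
  store
}

#' Is an ROI available for fragmentation?
#'
#' The SmartROI availability rules, evaluated on the ROI's intensity in the
#' most recent survey scan:
#' 1. below the minimum fragmentation intensity, the ROI is unavailable,
#'    whatever its history;
#' 2. a never-fragmented ROI is available;
#' 3. a previously fragmented ROI is available if its current intensity has
#'    either (a) risen by a factor `alpha` above the intensity at which it
#'    was last fragmented, or (b) dropped to a fraction `beta` of its
#'    maximum intensity since the last fragmentation.
#'
#' Rule 3a targets ROIs that have substantially grown since fragmentation;
#' rule 3b catches the next chromatographic peak inside the same ROI. With
#' `alpha = Inf` and `beta = 0` an ROI is fragmented at most once per run.
#'
#' @param roi an ROI record from an [roi_store()].
#' @param min_intensity minimum fragmentation intensity.
#' @param alpha rise factor (> 1 in sensible regimes; default 1000).
#' @param beta drop fraction (< 1 in sensible regimes; default 0.1).
#' @return TRUE if the ROI may be fragmented now.
#' @examples
#' roi <- list(intensity = 2e5, fragmented = FALSE,
#'             intensity_at_last_frag = NA, max_since_frag = 2e5)
#' smartroi_available(roi, min_intensity = 5e3, alpha = 1000, beta = 0.1)
#' @export
smartroi_available <- function(roi, min_intensity = 5e3, alpha = 1000,
                               beta = 0.1) {
  if (alpha <= 1)
    warning("alpha <= 1 is a degenerate regime: any intensity change re-arms the ROI")
  if (beta >= 1)
    warning("beta >= 1 is a degenerate regime: rule 3b is always satisfied")
  smartroi_available_core(roi, min_intensity, alpha, beta)
}

smartroi_available_core <- function(roi, min_intensity, alpha, beta) {
  current <- roi_current_intensity(roi)
  if (current < min_intensity) return(FALSE)            # rule 1
  if (!isTRUE(roi$fragmented)) return(TRUE)             # rule 2
  current >= alpha * roi$intensity_at_last_frag ||      # rule 3a
    current <= beta * roi$max_since_frag                # rule 3b
}

# Mark an active ROI as fragmented now: record the intensity, reset the
# running maximum.
roi_mark_fragmented <- function(roi, time) {
  current <- roi_current_intensity(roi)
  roi$fragmented <- TRUE
  roi$n_fragmentations <- roi$n_fragmentations + 1L
  roi$intensity_at_last_frag <- current
  roi$max_since_frag <- current
  roi$last_frag_time <- time
  roi
}

#' Flatten an ROI store to a data frame
#'
#' One row per (ROI, trace point), for debugging and chromatogram-style
#' plots of live ROI tracking.
#'
#' @param store an [roi_store()].
#' @return data frame with columns roi_id, point_index, rt, mz, intensity,
#'   status, n_fragmentations.
#' @export
roi_store_df <- function(store) {
  flatten <- function(rois, status) {
    if (length(rois) == 0) return(NULL)
    do.call(rbind, lapply(rois, function(r) {
      data.frame(roi_id = r$id, point_index = seq_along(r$rt),
                 rt = r$rt, mz = r$mz, intensity = r$intensity,
                 status = status, n_fragmentations = r$n_fragmentations,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(flatten(store$active, "active"),
               flatten(store$discarded, "inactive"))
  if (is.null(out))
    out <- data.frame(roi_id = integer(), point_index = integer(),
                      rt = numeric(), mz = numeric(), intensity = numeric(),
                      status = character(), n_fragmentations = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
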