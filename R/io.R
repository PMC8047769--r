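#' Read and write framework objects as plain text
#'
#' All retention times are in seconds on disk and in memory; MZmine2-style
#' minute-based box exports can be converted on import with
#' `rt_minutes = TRUE`.
#'
#' @name ddasim-io
NULL

#' @describeIn ddasim-io write a mixture as CSV (columns id, mz, rt_apex,
#'   max_intensity, width_sigma, noise; run length and seed in `#`
#'   comment header lines).
#' @param mixture a `dda_mixture`.
#' @param path file path.
#' @export
write_mixture_csv <- function(mixture, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# run_length=%.10g", mixture$run_length),
               sprintf("# seed=%d", mixture$seed)), con)
  write.csv(mixture$chemicals, con, row.names = FALSE)
  invisible(path)
}

#' @describeIn ddasim-io read a mixture written by [write_mixture_csv()].
#' @export
read_mixture_csv <- function(path) {
  header <- grep("^#", readLines(path, n = 10), value = TRUE)
  get_meta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "="), header, value = TRUE)
    if (length(m) == 0) return(default)
    as.numeric(sub(paste0("^#\\s*", key, "="), "", m[1]))
  }
  chems <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  run_length <- get_meta("run_length", max(chems$rt_apex, 0))
  seed <- as.integer(get_meta("seed", NA))
  structure(list(chemicals = chems, run_length = run_length, seed = seed),
            class = "dda_mixture")
}

#' @describeIn ddasim-io write bounding boxes as CSV (id, mz_min, mz_max,
#'   rt_min, rt_max, apex_intensity).
#' @param boxes bounding-box data frame.
#' @export
write_boxes_csv <- function(boxes, path) {
  write.csv(boxes, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn ddasim-io read a bounding-box CSV. Canonical column names
#'   (`id`, `mz_min`, `mz_max`, `rt_min`, `rt_max`) are used if present;
#'   otherwise MZmine2-style headers (e.g. "row ID", "Peak m/z min",
#'   "Peak RT start") are matched loosely. `rt_minutes = TRUE` converts
#'   minute-based RT columns to seconds.
#' @param rt_minutes logical; input RT columns are minutes.
#' @export
read_boxes_csv <- function(path, rt_minutes = FALSE) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(raw))
  find_col <- function(canonical, patterns) {
    i <- match(canonical, nm)
    if (!is.na(i)) return(i)
    for (p in patterns) {
      i <- grep(p, nm)
      if (length(i) > 0) return(i[1])
    }
    stop("cannot identify column '", canonical, "' in ", path)
  }
  id_i <- tryCatch(find_col("id", c("row.?id", "^id$", "peak.?id")),
                   error = function(e) NA_integer_)
  out <- data.frame(
    id = if (is.na(id_i)) sprintf("box_%04d", seq_len(nrow(raw)))
         else as.character(raw[[id_i]]),
    mz_min = as.numeric(raw[[find_col("mz_min", c("m.?z.*min", "min.*m.?z"))]]),
    mz_max = as.numeric(raw[[find_col("mz_max", c("m.?z.*max", "max.*m.?z"))]]),
    rt_min = as.numeric(raw[[find_col("rt_min", c("rt.*(min$|start)", "min.*rt"))]]),
    rt_max = as.numeric(raw[[find_col("rt_max", c("rt.*(max$|end)", "max.*rt"))]]),
    stringsAsFactors = FALSE
  )
  if (rt_minutes) {
    out$rt_min <- out$rt_min * 60
    out$rt_max <- out$rt_max * 60
  }
  if (any(out$mz_min >= out$mz_max) || any(out$rt_min >= out$rt_max))
    stop("invalid boxes: need mz_min < mz_max and rt_min < rt_max")
  out
}

#' @describeIn ddasim-io write an acquisition log as CSV (index, level,
#'   start_time, precursor_mz, precursor_intensity, source_ms1_index; MS1
#'   peak lists are not serialized).
#' @param run a `dda_run`.
#' @export
write_acquisition_csv <- function(run, path) {
  write.csv(run$scans, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn ddasim-io read an acquisition-log CSV back to a scans data
#'   frame.
#' @export
read_acquisition_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @describeIn ddasim-io write an evaluation report as JSON.
#' @param evaluation a `dda_evaluation`.
#' @export
write_evaluation_json <- function(evaluation, path) {
  jsonlite::write_json(unclass(evaluation), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @describeIn ddasim-io read a YAML/JSON run configuration (timing model,
#'   run length, controller name and parameters, seed) into a list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @describeIn ddasim-io write a run configuration list as YAML.
#' @param config a named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Mean MS1 and MS2 scan durations
#'
#' Estimates mean scan-to-scan times by level: the duration attributed to
#' scan `i` is the difference between the start times of scans `i + 1` and
#' `i` (so MS1 durations include the controller's processing time, as on a
#' real instrument). Accepts a `dda_run` or a scans data frame; for an
#' mzML file use [scan_times_from_mzml()] first.
#'
#' @param x a `dda_run` or a data frame with `level` and `start_time`.
#' @return list with `mean_ms1` and `mean_ms2` (seconds; `NA` when a level
#'   is absent).
#' @export
mean_scan_times <- function(x) {
  s <- if (inherits(x, "dda_run")) x$scans else x
  s <- s[order(s$start_time), , drop = FALSE]
  n <- nrow(s)
  if (n < 2) return(list(mean_ms1 = NA_real_, mean_ms2 = NA_real_))
  dur <- diff(s$start_time)
  lev <- s$level[-n]
  list(mean_ms1 = if (any(lev == 1)) mean(dur[lev == 1]) else NA_real_,
       mean_ms2 = if (any(lev == 2)) mean(dur[lev == 2]) else NA_real_)
}

#' Scan times and levels from an mzML file
#'
#' Reads the scan header of a (possibly real, TopN-acquired) mzML file and
#' returns the per-scan level and start time in seconds, ready for
#' [mean_scan_times()] or [realized_schedule()]-style use. Requires the
#' `mzR` package.
#'
#' @param path path to an mzML file.
#' @return data frame with columns `index`, `level`, `start_time`.
#' @export
scan_times_from_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  h <- mzR::header(f)
  data.frame(index = seq_len(nrow(h)),
             level = as.integer(h$msLevel),
             start_time = as.numeric(h$retentionTime))
}
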