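#' Generate a synthetic chemical mixture
#'
#' Draws a ground-truth set of chemical ions eluting over a chromatographic
#' run. Each chemical is a Gaussian chromatographic peak described by its
#' m/z, apex retention time, apex intensity and peak-width standard
#' deviation. Maximum intensities are drawn log-uniformly to emulate the
#' wide dynamic range of complex extracts; m/z, apex time and width are
#' uniform over their ranges. Optionally a set of noise chemicals is added:
#' these elute and appear in MS1 scans like any other ion but are excluded
#' from the ground-truth peak list, emulating signals that a peak picker
#' would not report.
#'
#' @param n_chems number of ground-truth chemicals (>= 0).
#' @param mz_range numeric length-2, m/z range in Th. Default 70-1000
#'   (a typical positive-mode full-scan window).
#' @param rt_range numeric length-2, apex retention-time range in seconds.
#' @param intensity_range numeric length-2, bounds of the log-uniform apex
#'   intensity distribution (arbitrary ion-count units).
#' @param width_range numeric length-2, bounds of the uniform distribution
#'   of the chromatographic standard deviation (seconds).
#' @param n_noise number of additional noise chemicals (default 0).
#' @param run_length total run length in seconds; defaults to the upper end
#'   of `rt_range`.
#' @param seed integer seed; identical parameters and seed reproduce the
#'   mixture exactly.
#' @return an object of class `dda_mixture`: a list with elements
#'   `chemicals` (data frame: id, mz, rt_apex, max_intensity, width_sigma,
#'   noise), `run_length` and `seed`.
#' @examples
#' mix <- generate_mixture(50, rt_range = c(0, 400), seed = 1)
#' mix
#' @export
generate_mixture <- function(n_chems,
                             mz_range = c(70, 1000),
                             rt_range = c(0, 1560),
                             intensity_range = c(1e4, 1e7),
                             width_range = c(5, 15),
                             n_noise = 0,
                             run_length = rt_range[2],
                             seed = 1) {
  stopifnot(length(n_chems) == 1, n_chems >= 0, n_chems == round(n_chems),
            length(n_noise) == 1, n_noise >= 0)
  check_range <- function(r, name, positive = FALSE) {
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2])
      stop("invalid ", name, ": must be a finite interval (min < max)")
    if (positive && r[1] <= 0)
      stop("invalid ", name, ": must be strictly positive")
  }
  check_range(mz_range, "mz_range", positive = TRUE)
  check_range(rt_range, "rt_range")
  check_range(intensity_range, "intensity_range", positive = TRUE)
  check_range(width_range, "width_range", positive = TRUE)
  if (rt_range[1] < 0 || rt_range[2] > run_length)
    stop("rt_range must lie within [0, run_length]")

  n_total <- n_chems + n_noise
  chems <- with_seed(seed, {
    data.frame(
      id = c(sprintf("chem_%04d", seq_len(n_chems)),
             sprintf("noise_%04d", seq_len(n_noise)))[seq_len(n_total)],
      mz = runif(n_total, mz_range[1], mz_range[2]),
      rt_apex = runif(n_total, rt_range[1], rt_range[2]),
      max_intensity = 10 ^ runif(n_total, log10(intensity_range[1]),
                                 log10(intensity_range[2])),
      width_sigma = runif(n_total, width_range[1], width_range[2]),
      noise = rep(c(FALSE, TRUE), c(n_chems, n_noise)),
      stringsAsFactors = FALSE
    )
  })
  structure(list(chemicals = chems, run_length = run_length, seed = seed),
            class = "dda_mixture")
}

#' @export
print.dda_mixture <- function(x, ...) {
  n <- nrow(x$chemicals)
  nn <- sum(x$chemicals$noise)
  cat(sprintf("Synthetic chemical mixture: %d chemicals (%d noise), run length %.1f s, seed %d\n",
              n, nn, x$run_length, x$seed))
  if (n > 0) {
    cat(sprintf("  m/z %.2f-%.2f Th, apex RT %.1f-%.1f s, apex intensity %.3g-%.3g\n",
                min(x$chemicals$mz), max(x$chemicals$mz),
                min(x$chemicals$rt_apex), max(x$chemicals$rt_apex),
                min(x$chemicals$max_intensity), max(x$chemicals$max_intensity)))
  }
  invisible(x)
}

#' Chromatographic intensity of a chemical at a time point
#'
#' Evaluates the Gaussian elution profile
#' `max_intensity * exp(-(t - rt_apex)^2 / (2 * width_sigma^2))`.
#'
#' @param chem a single chemical: a list or one-row data frame with fields
#'   `rt_apex`, `max_intensity`, `width_sigma`.
#' @param t time(s) in seconds; vectorized.
#' @return intensity at each `t`.
#' @examples
#' ch <- list(rt_apex = 100, max_intensity = 1e6, width_sigma = 5)
#' intensity_at(ch, 100)       # apex
#' intensity_at(ch, 105)       # one sigma out: 1e6 * exp(-1/2)
#' @export
intensity_at <- function(chem, t) {
  stopifnot(all(is.finite(t)))
  chem$max_intensity * exp(-(t - chem$rt_apex)^2 / (2 * chem$width_sigma^2))
}

# Intensities of every chemical in the mixture at a single time point.
mixture_intensities <- function(mixture, t) {
  ch <- mixture$chemicals
  ch$max_intensity * exp(-(t - ch$rt_apex)^2 / (2 * ch$width_sigma^2))
}

#' Ground-truth peak bounding boxes for a mixture
#'
#' Emits one picked-peak bounding box per (non-noise) chemical whose apex
#' intensity exceeds the detection floor. The RT bounds are where the
#' Gaussian chromatogram crosses the floor,
#' `rt_apex +/- width_sigma * sqrt(2 * log(max_intensity / detection_floor))`,
#' clipped to the run; the m/z bounds are `mz +/- mz_halfwidth`.
#'
#' The default detection floor equals the controllers' default minimum
#' fragmentation intensity so that boxes, MS1 peak lists and matching-graph
#' edges are mutually consistent.
#'
#' @param mixture a `dda_mixture`.
#' @param detection_floor intensity below which a chemical is not detected
#'   (> 0).
#' @param mz_halfwidth half-width of the box in m/z (Th), default 0.01.
#' @return data frame with columns id, mz_min, mz_max, rt_min, rt_max,
#'   apex_intensity — one row per detectable chemical.
#' @examples
#' mix <- generate_mixture(20, rt_range = c(50, 350), run_length = 400, seed = 2)
#' boxes <- ground_truth_boxes(mix)
#' head(boxes)
#' @export
ground_truth_boxes <- function(mixture, detection_floor = 5e3,
                               mz_halfwidth = 0.01) {
  stopifnot(detection_floor > 0, mz_halfwidth > 0)
  ch <- mixture$chemicals
  ch <- ch[!ch$noise & ch$max_intensity > detection_floor, , drop = FALSE]
  if (nrow(ch) == 0) {
    return(data.frame(id = character(), mz_min = numeric(), mz_max = numeric(),
                      rt_min = numeric(), rt_max = numeric(),
                      apex_intensity = numeric(), stringsAsFactors = FALSE))
  }
  half <- ch$width_sigma * sqrt(2 * log(ch$max_intensity / detection_floor))
  data.frame(
    id = ch$id,
    mz_min = ch$mz - mz_halfwidth,
    mz_max = ch$mz + mz_halfwidth,
    rt_min = pmax(0, ch$rt_apex - half),
    rt_max = pmin(mixture$run_length, ch$rt_apex + half),
    apex_intensity = ch$max_intensity,
    stringsAsFactors = FALSE
  )
}
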