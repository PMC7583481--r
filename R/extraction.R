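# XIC construction and peak integration: from an MS run plus a theoretical
# m/z and RT window to an integrated area and apex RT.

#' Extract an ion chromatogram
#'
#' Per MS1 scan, sums centroid intensities within `+/- ppm` of the target
#' m/z; scans with no matching centroid contribute zero, so the trace covers
#' every MS1 scan inside the window.
#'
#' @param run An `ms_run`.
#' @param mz Theoretical m/z to extract.
#' @param ppm Tolerance in ppm (> 0).
#' @param rt_window Optional `c(start, stop)` in minutes; clamped to the run's
#'   RT span; default is the whole run.
#' @return An object of class `xic_trace`: a data frame with columns `rt`
#'   (strictly increasing) and `intensity`, with attributes `mz`, `ppm`.
#' @export
extract_xic <- function(run, mz, ppm = 10, rt_window = NULL) {
  stopifnot(inherits(run, "ms_run"), ppm > 0, mz > 0)
  times <- run$scan_times
  if (length(times) == 0L) stop("run has no MS1 scans")
  if (is.null(rt_window)) rt_window <- range(times)
  rt_window <- c(max(min(times), rt_window[1]), min(max(times), rt_window[2]))
  scans <- which(times >= rt_window[1] & times <= rt_window[2])
  tol <- mz * ppm * 1e-6
  hit <- run$ms1[abs(run$ms1$mz - mz) <= tol & run$ms1$scan %in% scans, ]
  intensity <- numeric(length(scans))
  if (nrow(hit)) {
    agg <- rowsum(hit$intensity, hit$scan)
    idx <- match(as.integer(rownames(agg)), scans)
    intensity[idx] <- agg[, 1]
  }
  structure(data.frame(rt = times[scans], intensity = intensity),
            mz = mz, ppm = ppm, class = c("xic_trace", "data.frame"))
}

#' Total trapezoidal area of a trace
#'
#' Area under the whole trace with no peak picking; additive over traces with
#' disjoint support.
#'
#' @param trace An `xic_trace` (or any data frame with `rt`, `intensity`).
#' @return Area in intensity x minutes.
#' @export
trace_area <- function(trace) {
  n <- nrow(trace)
  if (n < 2L) return(0)
  sum(diff(trace$rt) * (trace$intensity[-1] + trace$intensity[-n]) / 2)
}

#' Detect and integrate the main chromatographic peak in a trace
#'
#' Finds the most intense contiguous region above
#' `max(noise_floor, baseline_frac * max(trace))`, extends it downhill to the
#' flanking local minima, and integrates it by the trapezoidal rule. An empty
#' or flat trace yields area 0 with flag `"not_detected"`. When several
#' regions tie in apex intensity, the earliest-eluting one is taken.
#'
#' @param trace An `xic_trace`.
#' @param baseline_frac Fraction of the window maximum used as the detection
#'   threshold (default 0.01).
#' @param noise_floor Absolute intensity floor (default 0).
#' @return A list of class `peak_result`: `area`, `apex_rt`, `bounds`
#'   (`c(start, stop)` RT), `flag` (`"ok"` or `"not_detected"`).
#' @export
integrate_peak <- function(trace, baseline_frac = 0.01, noise_floor = 0) {
  pks <- find_peaks(trace, baseline_frac = baseline_frac,
                    noise_floor = noise_floor)
  if (length(pks) == 0L) {
    return(structure(list(area = 0, apex_rt = NA_real_,
                          bounds = c(NA_real_, NA_real_),
                          flag = "not_detected"), class = "peak_result"))
  }
  pks[[1]]
}

#' All candidate peaks in a trace
#'
#' Same detection rule as [integrate_peak()] but returns every contiguous
#' above-threshold region as an integrated peak, ordered by decreasing apex
#' intensity (ties by earlier RT). Used by the quantifier to skip candidate
#' peaks that fail identity checks (e.g. the monoisotopic-peak veto).
#'
#' @inheritParams integrate_peak
#' @return List of `peak_result`s (empty for a flat trace); each carries an
#'   `apex_intensity` element.
#' @export
find_peaks <- function(trace, baseline_frac = 0.01, noise_floor = 0) {
  stopifnot(nrow(trace) > 0)
  y <- trace$intensity
  if (max(y) <= max(noise_floor, 0)) return(list())
  thr <- max(noise_floor, baseline_frac * max(y))
  above <- y > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  pks <- lapply(runs, function(k) {
    lo <- starts[k]; hi <- ends[k]
    # extend downhill to flanking local minima
    while (lo > 1L && y[lo - 1L] < y[lo] && y[lo - 1L] > 0) lo <- lo - 1L
    while (hi < length(y) && y[hi + 1L] < y[hi] && y[hi + 1L] > 0)
      hi <- hi + 1L
    seg <- trace[lo:hi, , drop = FALSE]
    apex_i <- which.max(seg$intensity)
    structure(list(area = trace_area(seg), apex_rt = seg$rt[apex_i],
                   apex_intensity = seg$intensity[apex_i],
                   bounds = c(seg$rt[1], seg$rt[nrow(seg)]), flag = "ok"),
              class = "peak_result")
  })
  heights <- vapply(pks, `[[`, numeric(1), "apex_intensity")
  # decreasing height; ties resolved by earlier RT via stable order()
  pks[order(-heights)]
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("<peak: area %.4g, apex %.2f min, flag %s>\n",
              x$area, x$apex_rt, x$flag))
  invisible(x)
}
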