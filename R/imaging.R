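#' Region of interest over a movie frame
#'
#' A set of pixels (0-based row/col, row-major) attributed to one cell.
#' ROIs for distinct cells must be disjoint; this mirrors the manually drawn,
#' non-overlapping regions of the imaging assay.
#'
#' @param cell_id Identifier.
#' @param pixels Data frame with integer columns `row` and `col` (0-based).
#' @return An `roi` object.
#' @export
roi <- function(cell_id, pixels) {
  stop_if_not(is.data.frame(pixels) && all(c("row", "col") %in% names(pixels)),
              "pixels must be a data frame with columns row, col")
  stop_if_not(nrow(pixels) > 0, "ROI must contain at least one pixel")
  stop_if_not(all(pixels$row >= 0) && all(pixels$col >= 0),
              "pixel coordinates are 0-based and must be >= 0")
  structure(list(cell_id = cell_id,
                 pixels = pixels[, c("row", "col")]),
            class = "roi")
}

#' Disk-shaped ROI from center and radius
#'
#' @param cell_id Identifier.
#' @param center_px (row, col) center, 0-based pixels.
#' @param radius_px Radius in pixels.
#' @param height_px,width_px Frame bounds used to validate the footprint.
#' @return An `roi` object.
#' @export
roi_disk <- function(cell_id, center_px, radius_px, height_px, width_px) {
  roi(cell_id, disk_pixels(center_px, radius_px, height_px, width_px))
}

#' Summed ROI fluorescence intensity of one frame
#'
#' Computes \eqn{I = \sum_{n=1}^{N} i_n}, the sum of the N pixel intensities
#' inside the ROI. Linear in the frame values and additive over disjoint
#' ROIs.
#'
#' @param frame Numeric matrix (one movie frame).
#' @param roi An [roi()] object; must lie inside the frame.
#' @return Scalar intensity.
#' @examples
#' fr <- matrix(1:9, 3, 3, byrow = TRUE)
#' roi_intensity(fr, roi("c", data.frame(row = 0, col = 0:2)))  # 1+2+3 = 6
#' @export
roi_intensity <- function(frame, roi) {
  stopifnot(is.matrix(frame), inherits(roi, "roi"))
  px <- roi$pixels
  stop_if_not(all(px$row < nrow(frame)) && all(px$col < ncol(frame)),
              "ROI extends outside the frame")
  sum(frame[cbind(px$row + 1L, px$col + 1L)])
}

#' Extract a per-cell fluorescence trace from a movie
#'
#' Applies [roi_intensity()] to every frame of the stack. Times are taken
#' relative to the stimulus frame, which becomes `t = 0`; pre-stimulus
#' frames get negative times.
#'
#' @param movie A `scrambling_movie`, or a list with elements `stack`
#'   (array `h x w x f`) and `times_s` (length-f numeric).
#' @param roi An [roi()] object.
#' @param stimulus_frame 1-based index of the stimulus frame.
#' @return A `fluor_trace` data frame with columns `cell_id`, `time_s`,
#'   `intensity`.
#' @export
extract_trace <- function(movie, roi, stimulus_frame = 1L) {
  stop_if_not(!is.null(movie$stack) && !is.null(movie$times_s),
              "movie must carry a stack and frame times")
  n_frames <- dim(movie$stack)[3]
  stop_if_not(length(movie$times_s) == n_frames,
              "frame timestamps missing or wrong length")
  stop_if_not(stimulus_frame >= 1 && stimulus_frame <= n_frames,
              "stimulus_frame out of range")
  ivals <- vapply(seq_len(n_frames),
                  function(f) roi_intensity(movie$stack[, , f], roi),
                  numeric(1))
  out <- data.frame(cell_id = as.character(roi$cell_id),
                    time_s = movie$times_s - movie$times_s[stimulus_frame],
                    intensity = ivals, stringsAsFactors = FALSE)
  class(out) <- c("fluor_trace", "data.frame")
  out
}

# Mean pre-stimulus intensity. Uses frames in [-baseline_window_s, 0 s);
# when the trace starts at the stimulus (no negative times) the stimulus
# frame itself stands in for the baseline: scrambling has not begun at
# t = 0, and using later frames would bias half-max times on fast risers.
trace_baseline <- function(time_s, intensity, baseline_window_s = 15) {
  pre <- time_s < 0 & time_s >= -baseline_window_s
  if (any(pre)) mean(intensity[pre]) else intensity[which(time_s >= 0)[1]]
}

#' Half-maximal time of a fluorescence trace
#'
#' Implements the per-cell scrambling kinetics score: `i_max` is the maximum
#' baseline-subtracted intensity within the analysis window (default the
#' first 10 min post stimulus) and `t_half_s` is the earliest time the
#' baseline-subtracted trace reaches half of `i_max`, with linear
#' interpolation between the bracketing frames (first crossing wins).
#'
#' Baseline is the mean of pre-stimulus frames within 15 s of the stimulus,
#' or the stimulus-frame intensity when no pre-stimulus frames exist; raw
#' summed intensities make half-max degenerate for nonzero baselines, so
#' subtraction is always applied and recorded here.
#'
#' @param trace A `fluor_trace` or any data frame with `time_s` and
#'   `intensity` columns (times strictly increasing).
#' @param window_s Analysis window in seconds after the stimulus.
#' @param baseline_window_s Width of the pre-stimulus baseline window.
#' @param median_filter If `TRUE`, apply a 3-frame running median before
#'   analysis (off by default).
#' @return List with `i_max` (baseline-subtracted), `t_half_s` (`NA` when
#'   the trace never reaches half-max inside the window) and `baseline`.
#' @examples
#' tr <- data.frame(time_s = c(0, 5, 10), intensity = c(0, 40, 100))
#' compute_t_half(tr)$t_half_s  # 5 + 5 * (50 - 40) / (100 - 40) = 5.8333
#' @export
compute_t_half <- function(trace, window_s = 600, baseline_window_s = 15,
                           median_filter = FALSE) {
  stop_if_not(all(c("time_s", "intensity") %in% names(trace)),
              "trace needs time_s and intensity columns")
  t <- trace$time_s
  y <- trace$intensity
  stop_if_not(all(diff(t) > 0), "trace times must be strictly increasing")
  stop_if_not(is_scalar_num(window_s) && window_s > 0, "window_s must be > 0")
  if (median_filter && length(y) >= 3) {
    y <- stats::runmed(y, k = 3L, endrule = "keep")
    # denoise the endpoints too (they anchor the baseline estimate)
    y[1] <- stats::median(y[1:3])
    y[length(y)] <- stats::median(y[(length(y) - 2):length(y)])
  }
  base <- trace_baseline(t, y, baseline_window_s)
  inw <- t >= 0 & t <= window_s
  stop_if_not(any(inw), "analysis window contains no frames")
  ts <- t[inw]
  ys <- y[inw] - base
  i_max <- max(ys)
  if (i_max <= 0) {
    return(list(i_max = i_max, t_half_s = NA_real_, baseline = base))
  }
  half <- 0.5 * i_max
  at_or_above <- ys >= half
  k <- which(at_or_above)[1]
  t_half <- if (k == 1L) {
    ts[1]
  } else {
    # linear interpolation between the bracketing frames; earliest crossing
    ts[k - 1L] + (ts[k] - ts[k - 1L]) * (half - ys[k - 1L]) /
      (ys[k] - ys[k - 1L])
  }
  list(i_max = i_max, t_half_s = t_half, baseline = base)
}

#' Classify a cell as scrambling or non-scrambling
#'
#' A cell counts as a scrambler when its in-window maximum intensity reaches
#' `fold_threshold` times the mean baseline intensity. Non-scramblers get
#' the infinite-`t_half` sentinel and are excluded from group statistics
#' downstream. A trace with zero baseline and zero signal is classified
#' non-scrambling (degenerate rule).
#'
#' @inheritParams compute_t_half
#' @param fold_threshold Scrambler criterion as a fold change over baseline
#'   (default 2; the underlying assay states no numeric rule, so this is a
#'   configuration knob).
#' @return One-row data frame of class `scrambling_result` with columns
#'   `cell_id`, `i_max`, `t_half_s` (`Inf` for non-scramblers),
#'   `is_scrambler`, `included_in_stats`.
#' @export
classify_scrambler <- function(trace, window_s = 600,
                               baseline_window_s = 15, fold_threshold = 2,
                               median_filter = FALSE) {
  cell_id <- if ("cell_id" %in% names(trace)) {
    as.character(trace$cell_id[1])
  } else {
    NA_character_
  }
  th <- compute_t_half(trace, window_s, baseline_window_s, median_filter)
  t <- trace$time_s
  y <- trace$intensity
  inw <- t >= 0 & t <= window_s
  raw_max <- max(y[inw])
  is_scr <- if (th$baseline > 0) {
    raw_max >= fold_threshold * th$baseline
  } else {
    # zero / negative baseline: fall back on the baseline-subtracted signal
    th$i_max > 0 && is.finite(th$t_half_s %||% NA_real_) &&
      !is.na(th$t_half_s)
  }
  if (is_scr && is.na(th$t_half_s)) is_scr <- FALSE
  out <- data.frame(
    cell_id = cell_id,
    i_max = th$i_max,
    t_half_s = if (is_scr) th$t_half_s else Inf,
    is_scrambler = is_scr,
    included_in_stats = is_scr,
    stringsAsFactors = FALSE
  )
  class(out) <- c("scrambling_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify every cell of a movie
#'
#' Convenience wrapper: extracts one trace per ROI and classifies each cell.
#'
#' @param movie A `scrambling_movie` (or list with `stack` and `times_s`).
#' @param rois Named list of [roi()] objects; defaults to the movie's
#'   ground-truth ROIs when present.
#' @inheritParams classify_scrambler
#' @param stimulus_frame 1-based stimulus frame index.
#' @return `scrambling_result` data frame, one row per cell.
#' @export
quantify_movie <- function(movie, rois = movie$rois, stimulus_frame = 1L,
                           window_s = 600, baseline_window_s = 15,
                           fold_threshold = 2, median_filter = FALSE) {
  stop_if_not(length(rois) > 0, "no ROIs supplied")
  res <- lapply(rois, function(r) {
    tr <- extract_trace(movie, r, stimulus_frame)
    classify_scrambler(tr, window_s, baseline_window_s, fold_threshold,
                       median_filter)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("scrambling_result", "data.frame")
  out
}

#' Percentage of PS-positive expressing cells on a coverslip
#'
#' Pools manually counted fields of view of one coverslip:
#' `percent = 100 * sum(positives) / sum(expressing)`.
#'
#' @param per_field_counts Data frame (or matrix) with columns
#'   `n_expressing` and `n_ps_positive`, one row per field of view.
#' @param coverslip_id Identifier carried into the summary.
#' @return One-row data frame (`coverslip_summary`) with `coverslip_id`,
#'   `n_expressing`, `n_ps_positive`, `percent_ps_positive`.
#' @examples
#' percent_ps_positive(data.frame(n_expressing = c(20, 30),
#'                                n_ps_positive = c(8, 13)))  # 42%
#' @export
percent_ps_positive <- function(per_field_counts, coverslip_id = NA) {
  cnt <- as.data.frame(per_field_counts)
  stop_if_not(all(c("n_expressing", "n_ps_positive") %in% names(cnt)),
              "need columns n_expressing and n_ps_positive")
  stop_if_not(all(cnt$n_expressing >= 0) && all(cnt$n_ps_positive >= 0),
              "counts must be nonnegative")
  stop_if_not(all(cnt$n_ps_positive <= cnt$n_expressing),
              "positives cannot exceed expressing cells in a field")
  n_exp <- sum(cnt$n_expressing)
  n_pos <- sum(cnt$n_ps_positive)
  stop_if_not(n_exp > 0,
              "coverslip has no expressing cells; percentage undefined")
  out <- data.frame(coverslip_id = coverslip_id, n_expressing = n_exp,
                    n_ps_positive = n_pos,
                    percent_ps_positive = 100 * n_pos / n_exp,
                    stringsAsFactors = FALSE)
  class(out) <- c("coverslip_summary", "data.frame")
  out
}
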