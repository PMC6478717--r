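#' Specify a synthetic cell for movie generation
#'
#' Describes one cell footprint and its scrambling phenotype for
#' [generate_movie()]. The four phenotypes mirror the categories seen in
#' Annexin V imaging of CaPLSase-expressing cells: `scrambler` cells turn on
#' after the ionophore stimulus with a sigmoidal fluorescence rise,
#' `non_scrambler` cells stay at baseline, `constitutive` cells are already
#' PS-positive at the first frame, and `apoptotic` cells are constitutive
#' PS-positive cells additionally flagged as caspase-positive.
#'
#' @param cell_id Unique identifier (character or integer).
#' @param center_px Length-2 numeric, (row, col) center in pixels (0-based).
#' @param radius_px Disk footprint radius in pixels; must be > 0.
#' @param phenotype One of `"scrambler"`, `"non_scrambler"`, `"constitutive"`,
#'   `"apoptotic"`.
#' @param t_half_true_s True half-maximal time in seconds. Required finite for
#'   scramblers; `0` for constitutive/apoptotic cells (maximal from frame 0);
#'   `NA` for non-scramblers.
#' @param rise_width_s Logistic slope scale in seconds (time constant of the
#'   sigmoidal rise).
#' @param i_max_true Plateau of the summed footprint intensity (arbitrary
#'   fluorescence units); must exceed `baseline`.
#' @param baseline Pre-stimulus summed footprint intensity; must be >= 0.
#' @return A `cell_spec` list.
#' @seealso [generate_movie()], [movie_spec()]
#' @export
cell_spec <- function(cell_id, center_px, radius_px,
                      phenotype = c("scrambler", "non_scrambler",
                                    "constitutive", "apoptotic"),
                      t_half_true_s = NA_real_, rise_width_s = 20,
                      i_max_true = 1000, baseline = 0) {
  phenotype <- match.arg(phenotype)
  stop_if_not(length(center_px) == 2L && all(is.finite(center_px)),
              "center_px must be a finite length-2 numeric")
  stop_if_not(is_scalar_num(radius_px) && radius_px > 0,
              "radius_px must be a positive scalar")
  stop_if_not(is_scalar_num(i_max_true) && is_scalar_num(baseline) &&
                i_max_true > baseline && baseline >= 0,
              "need i_max_true > baseline >= 0")
  if (phenotype == "scrambler") {
    stop_if_not(is_scalar_num(t_half_true_s) && t_half_true_s > 0,
                "scrambler cells need finite t_half_true_s > 0")
    stop_if_not(is_scalar_num(rise_width_s) && rise_width_s > 0,
                "rise_width_s must be > 0")
  }
  if (phenotype %in% c("constitutive", "apoptotic")) t_half_true_s <- 0
  if (phenotype == "non_scrambler") t_half_true_s <- NA_real_
  structure(
    list(cell_id = cell_id, center_px = as.numeric(center_px),
         radius_px = radius_px, phenotype = phenotype,
         t_half_true_s = t_half_true_s, rise_width_s = rise_width_s,
         i_max_true = i_max_true, baseline = baseline),
    class = "cell_spec"
  )
}

#' Specify the acquisition settings of a synthetic movie
#'
#' Defaults follow the imaging assay this generator emulates: frames every
#' 5 s for 10 min after ionophore application (frame 0 is the stimulus).
#'
#' @param frame_interval_s Seconds between frames (> 0).
#' @param duration_s Total recorded time in seconds (>= `frame_interval_s`).
#' @param height_px,width_px Frame size in pixels.
#' @param read_noise_sd Gaussian read noise per pixel (fluorescence units).
#' @param photon_scale Shot-noise scale: per-pixel variance is
#'   `photon_scale * expected_value`. `0` disables shot noise.
#' @param seed Integer seed; all randomness in [generate_movie()] derives
#'   from it.
#' @return A `movie_spec` list.
#' @export
movie_spec <- function(frame_interval_s = 5, duration_s = 600,
                       height_px = 128, width_px = 128,
                       read_noise_sd = 0, photon_scale = 0, seed = 1L) {
  stop_if_not(is_scalar_num(frame_interval_s) && frame_interval_s > 0,
              "frame_interval_s must be > 0")
  stop_if_not(is_scalar_num(duration_s) && duration_s >= frame_interval_s,
              "duration_s must be >= frame_interval_s")
  stop_if_not(read_noise_sd >= 0 && photon_scale >= 0,
              "noise parameters must be >= 0")
  structure(
    list(frame_interval_s = frame_interval_s, duration_s = duration_s,
         height_px = as.integer(height_px), width_px = as.integer(width_px),
         read_noise_sd = read_noise_sd, photon_scale = photon_scale,
         seed = as.integer(seed)),
    class = "movie_spec"
  )
}

# Pixels (0-based row/col) of a disk footprint.
disk_pixels <- function(center_px, radius_px, height_px, width_px) {
  r0 <- floor(center_px[1] - radius_px)
  r1 <- ceiling(center_px[1] + radius_px)
  c0 <- floor(center_px[2] - radius_px)
  c1 <- ceiling(center_px[2] + radius_px)
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  d2 <- (grid$row - center_px[1])^2 + (grid$col - center_px[2])^2
  grid <- grid[d2 <= radius_px^2, , drop = FALSE]
  stop_if_not(nrow(grid) > 0, "cell footprint contains no pixels")
  stop_if_not(all(grid$row >= 0) && all(grid$row < height_px) &&
                all(grid$col >= 0) && all(grid$col < width_px),
              "cell footprint extends outside the frame")
  grid
}

# Noiseless summed footprint intensity of one cell at times `t_s`.
cell_signal <- function(cell, t_s) {
  switch(cell$phenotype,
    scrambler = cell$baseline + (cell$i_max_true - cell$baseline) *
      logistic(t_s, cell$t_half_true_s, cell$rise_width_s),
    non_scrambler = rep(cell$baseline, length(t_s)),
    constitutive = ,
    apoptotic = rep(cell$i_max_true, length(t_s))
  )
}

#' Generate a synthetic time-lapse scrambling movie
#'
#' Renders an image stack in which each cell is a disk whose *summed*
#' footprint intensity follows its phenotype: scramblers rise along
#' `baseline + (i_max - baseline) * logistic((t - t_half) / rise_width)`,
#' non-scramblers stay at baseline, constitutive/apoptotic cells sit at
#' `i_max` from frame 0. Pixel noise (Gaussian read noise plus optional
#' scaled shot noise) is added on top. Cell footprints must not overlap so
#' the per-cell ground truth is unambiguous.
#'
#' @param spec A [movie_spec()].
#' @param cells List of [cell_spec()] objects.
#' @return A list of class `scrambling_movie` with elements
#'   \describe{
#'     \item{stack}{numeric array `height x width x n_frames`;}
#'     \item{times_s}{frame times, `t = 0` at the stimulus frame;}
#'     \item{truth}{data frame with one row per cell (`cell_id`,
#'       `center_row`, `center_col`, `radius_px`, `phenotype`,
#'       `t_half_true_s`, `i_max_true`, `baseline`, `n_pixels`);}
#'     \item{rois}{named list of ground-truth [roi()] objects;}
#'     \item{spec}{the generating `movie_spec`.}
#'   }
#' @examples
#' mv <- generate_movie(
#'   movie_spec(duration_s = 60, height_px = 32, width_px = 32),
#'   list(cell_spec("c1", c(16, 16), 5, "scrambler", t_half_true_s = 30))
#' )
#' dim(mv$stack)
#' @export
generate_movie <- function(spec, cells) {
  stopifnot(inherits(spec, "movie_spec"))
  stop_if_not(length(cells) > 0, "need at least one cell")
  stop_if_not(all(vapply(cells, inherits, logical(1), "cell_spec")),
              "cells must be a list of cell_spec objects")
  ids <- vapply(cells, function(c) as.character(c$cell_id), character(1))
  stop_if_not(!anyDuplicated(ids), "cell ids must be unique")

  pix <- lapply(cells, function(cl)
    disk_pixels(cl$center_px, cl$radius_px, spec$height_px, spec$width_px))
  # overlap forbidden: keeps every ROI's ground truth unambiguous
  keys <- lapply(pix, function(p) p$row * spec$width_px + p$col)
  all_keys <- unlist(keys)
  stop_if_not(!anyDuplicated(all_keys), "cell footprints overlap")

  n_frames <- floor(spec$duration_s / spec$frame_interval_s) + 1L
  times_s <- (seq_len(n_frames) - 1L) * spec$frame_interval_s

  stack <- with_seed(spec$seed, {
    st <- array(0, dim = c(spec$height_px, spec$width_px, n_frames))
    for (i in seq_along(cells)) {
      npx <- nrow(pix[[i]])
      sig <- cell_signal(cells[[i]], times_s) / npx  # per-pixel expectation
      idx1 <- pix[[i]]$row + 1L + pix[[i]]$col * spec$height_px
      for (f in seq_len(n_frames)) {
        st[idx1 + (f - 1L) * spec$height_px * spec$width_px] <- sig[f]
      }
    }
    if (spec$photon_scale > 0) {
      st[] <- st + stats::rnorm(length(st),
                                sd = sqrt(pmax(st, 0) * spec$photon_scale))
    }
    if (spec$read_noise_sd > 0) {
      st[] <- st + stats::rnorm(length(st), sd = spec$read_noise_sd)
    }
    st
  })

  truth <- data.frame(
    cell_id = ids,
    center_row = vapply(cells, function(c) c$center_px[1], numeric(1)),
    center_col = vapply(cells, function(c) c$center_px[2], numeric(1)),
    radius_px = vapply(cells, function(c) c$radius_px, numeric(1)),
    phenotype = vapply(cells, function(c) c$phenotype, character(1)),
    t_half_true_s = vapply(cells, function(c) c$t_half_true_s, numeric(1)),
    i_max_true = vapply(cells, function(c) c$i_max_true, numeric(1)),
    baseline = vapply(cells, function(c) c$baseline, numeric(1)),
    n_pixels = vapply(pix, nrow, integer(1)),
    stringsAsFactors = FALSE
  )
  rois <- stats::setNames(
    lapply(seq_along(cells), function(i) roi(ids[i], pix[[i]])), ids)

  structure(list(stack = stack, times_s = times_s, truth = truth,
                 rois = rois, spec = spec),
            class = "scrambling_movie")
}

#' Simulate per-cell fluorescence traces without rendering images
#'
#' Produces the summed-footprint intensity traces that [generate_movie()]
#' would yield, with trace-level Gaussian noise, skipping image rendering.
#' Useful for large cohorts where only the kinetics matter.
#'
#' @inheritParams generate_movie
#' @param trace_noise_sd Gaussian noise added to each summed-trace sample.
#' @return Data frame with columns `cell_id`, `time_s`, `intensity`.
#' @export
simulate_traces <- function(spec, cells, trace_noise_sd = 0) {
  stopifnot(inherits(spec, "movie_spec"))
  n_frames <- floor(spec$duration_s / spec$frame_interval_s) + 1L
  times_s <- (seq_len(n_frames) - 1L) * spec$frame_interval_s
  with_seed(spec$seed, {
    out <- lapply(cells, function(cl) {
      y <- cell_signal(cl, times_s)
      if (trace_noise_sd > 0) {
        y <- y + stats::rnorm(length(y), sd = trace_noise_sd)
      }
      data.frame(cell_id = as.character(cl$cell_id), time_s = times_s,
                 intensity = y, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Write / read a synthetic movie as multi-page TIFF plus sidecar files
#'
#' The stack is written as 32-bit float TIFF pages scaled to `[0, 1]`;
#' the scale factor, frame times and generator seed go to a JSON sidecar and
#' the ground-truth table to CSV, so a written movie round-trips exactly.
#'
#' @param movie A `scrambling_movie` from [generate_movie()].
#' @param path Base path without extension; writes `<path>.tif`,
#'   `<path>.json` and `<path>_truth.csv`.
#' @return `path`, invisibly (for `write_movie`); a `scrambling_movie`
#'   without `rois` (for `read_movie`).
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "scrambling_movie"))
  offset <- min(movie$stack)
  scale <- max(movie$stack - offset, 1e-12)
  pages <- lapply(seq_len(dim(movie$stack)[3]),
                  function(f) (movie$stack[, , f] - offset) / scale)
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 32L)
  meta <- list(scale = scale, offset = offset, times_s = movie$times_s,
               seed = movie$spec$seed,
               frame_interval_s = movie$spec$frame_interval_s,
               pixel_convention = "0-based, row-major")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(movie$truth, paste0(path, "_truth.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                            length(pages)))
  for (f in seq_along(pages)) {
    stack[, , f] <- pages[[f]] * meta$scale + meta$offset
  }
  truth <- utils::read.csv(paste0(path, "_truth.csv"),
                           stringsAsFactors = FALSE)
  structure(list(stack = stack, times_s = meta$times_s, truth = truth,
                 rois = NULL, spec = NULL),
            class = "scrambling_movie")
}
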