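#' Restrict a trajectory to a time window
#'
#' Keeps frames with `t_start_ns <= time < t_end_ns`, preserving order.
#' The defaults drop the first 100 ns of a 400-ns run - the equilibration
#' discard conventionally applied before density analysis.
#'
#' @param traj A `particle_trajectory` data frame (needs `time_ns`).
#' @param t_start_ns,t_end_ns Window bounds in ns.
#' @param replicates Optional replicate ids to keep.
#' @return The filtered `particle_trajectory`.
#' @export
select_frames <- function(traj, t_start_ns = 100, t_end_ns = 400,
                          replicates = NULL) {
  stop_if_not(t_start_ns < t_end_ns, "t_start_ns must be < t_end_ns")
  keep <- traj$time_ns >= t_start_ns & traj$time_ns < t_end_ns
  if (!is.null(replicates)) keep <- keep & traj$replicate %in% replicates
  stop_if_not(any(keep), "frame selection is empty")
  out <- traj[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("particle_trajectory", "data.frame")
  out
}

# Apply an optional lateral cylinder filter (list(center = c(x, y),
# radius)) and species filter.
filter_particles <- function(traj, species = NULL, region = NULL) {
  keep <- rep(TRUE, nrow(traj))
  if (!is.null(species)) keep <- keep & traj$species %in% species
  if (!is.null(region)) {
    keep <- keep & (traj$x - region$center[1])^2 +
      (traj$y - region$center[2])^2 <= region$radius^2
  }
  traj[keep, , drop = FALSE]
}

#' 1D density profile along the membrane normal
#'
#' Histograms particle z positions, relative to a reference z (e.g. the
#' z coordinate of a residue marking the outer leaflet surface), over all
#' selected frames, species and the optional lateral region; counts are
#' divided by the number of frames and the bin width, giving particles per
#' Angstrom per frame. Per-replicate profiles are kept separate so the
#' downstream free-energy estimate can carry replicate standard errors.
#'
#' The conservation identity `sum(density * bin_width) == mean in-region
#' particle count per frame` holds exactly per replicate.
#'
#' @param traj A `particle_trajectory`.
#' @param species Species label(s) to include (default: all).
#' @param reference_z_A Reference z subtracted from all z values
#'   (scalar; the axis origin, positive toward the extracellular side).
#' @param bin_width_A Bin width in Angstrom (> 0).
#' @param z_range_A Optional length-2 profile range; defaults to the data
#'   range padded to whole bins.
#' @param region Optional lateral cylinder `list(center = c(x, y), radius)`.
#' @return A `density_profile` list: `bin_edges_A`, `bin_centers_A`,
#'   `density` (matrix bins x replicates, counts / A / frame),
#'   `counts` (same shape, raw), `n_frames` (per replicate),
#'   `replicates`, `bin_width_A`, `reference_z_A`.
#' @export
density_profile <- function(traj, species = NULL, reference_z_A = 0,
                            bin_width_A = 1, z_range_A = NULL,
                            region = NULL) {
  stop_if_not(bin_width_A > 0, "bin width must be > 0")
  d <- filter_particles(traj, species, region)
  stop_if_not(nrow(d) > 0, "no selected particles in any frame")
  z <- d$z - reference_z_A
  if (is.null(z_range_A)) {
    lo <- floor(min(z) / bin_width_A) * bin_width_A
    hi <- ceiling(max(z) / bin_width_A) * bin_width_A
    if (hi <= lo) hi <- lo + bin_width_A
  } else {
    lo <- z_range_A[1]; hi <- z_range_A[2]
  }
  edges <- seq(lo, hi, by = bin_width_A)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  reps <- sort(unique(d$replicate))
  counts <- matrix(0, nrow = length(edges) - 1L, ncol = length(reps))
  n_frames <- integer(length(reps))
  for (j in seq_along(reps)) {
    dr <- d[d$replicate == reps[j], ]
    n_frames[j] <- length(unique(dr$frame))
    zr <- dr$z - reference_z_A
    zr <- zr[zr >= lo & zr <= hi]
    if (length(zr)) {
      idx <- pmin(pmax(findInterval(zr, edges, rightmost.closed = TRUE),
                       1L), length(edges) - 1L)
      counts[, j] <- tabulate(idx, nbins = length(edges) - 1L)
    }
  }
  dens <- sweep(counts, 2, n_frames * bin_width_A, "/")
  structure(list(bin_edges_A = edges,
                 bin_centers_A = (edges[-1] + edges[-length(edges)]) / 2,
                 density = dens, counts = counts, n_frames = n_frames,
                 replicates = reps, bin_width_A = bin_width_A,
                 reference_z_A = reference_z_A),
            class = "density_profile")
}

#' Effective free-energy profile from per-replicate densities
#'
#' Converts each replicate's density to an effective free energy (PMF)
#' \eqn{W(z) = -kT \ln(\rho(z) / \max\rho)}, averages across replicates
#' bin-wise, computes the per-bin standard error as the sample SD across
#' replicates over `sqrt(n)`, and re-anchors the averaged profile so its
#' minimum over finite bins is zero. Zero-density bins carry a `+Inf`
#' sentinel and are excluded from the SE (no pseudocounts unless
#' `pseudocount > 0`).
#'
#' @param profile A `density_profile` (with one column per replicate).
#' @param kT Thermal energy unit for the output (1 = report in kT).
#' @param pseudocount Optional count added to every bin before taking logs.
#' @return A `free_energy_profile` data frame with `bin_center_A`, `w_kT`,
#'   `se_kT`, `n_finite_replicates`; attribute `n_replicates`.
#' @export
pmf_from_density <- function(profile, kT = 1, pseudocount = 0) {
  stopifnot(inherits(profile, "density_profile"))
  dens <- profile$density
  if (pseudocount > 0) {
    dens <- sweep(profile$counts + pseudocount, 2,
                  profile$n_frames * profile$bin_width_A, "/")
  }
  stop_if_not(any(dens > 0), "all-empty density profile")
  w <- apply(dens, 2, function(p) {
    wj <- -kT * log(p / max(p))
    wj[p == 0] <- Inf
    wj
  })
  w <- matrix(w, nrow = nrow(dens))
  fin <- is.finite(w)
  n_fin <- rowSums(fin)
  w_mean <- ifelse(n_fin > 0,
                   rowSums(ifelse(fin, w, 0)) / pmax(n_fin, 1L), Inf)
  se <- vapply(seq_len(nrow(w)), function(i) {
    x <- w[i, fin[i, ]]
    if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
  }, numeric(1))
  w_mean <- w_mean - min(w_mean[is.finite(w_mean)])  # anchor min = 0
  out <- data.frame(bin_center_A = profile$bin_centers_A, w_kT = w_mean,
                    se_kT = se, n_finite_replicates = n_fin)
  attr(out, "n_replicates") <- ncol(dens)
  class(out) <- c("free_energy_profile", "data.frame")
  out
}

#' Convert a free-energy profile from kT to kcal/mol
#'
#' @param profile A `free_energy_profile` in kT units.
#' @param temperature_K Temperature (default 298 K; kT = 0.5922 kcal/mol).
#' @return The profile with `w_kcal_mol` and `se_kcal_mol` columns added.
#' @export
pmf_in_kcal <- function(profile, temperature_K = 298) {
  kcal_per_kT <- 1.98720425864083e-3 * temperature_K  # R in kcal/mol/K
  profile$w_kcal_mol <- profile$w_kT * kcal_per_kT
  profile$se_kcal_mol <- profile$se_kT * kcal_per_kT
  profile
}

#' 3D occupancy grid of particle positions
#'
#' Bins selected particles on a uniform cubic grid (default 0.5 A spacing).
#' In `"occupancy"` mode (default) each voxel's value is the fraction of
#' frames in which at least one selected particle occupies it - a
#' probability in `[0, 1]`. In `"count"` mode values are
#' counts / n_frames (a per-frame mean occupancy count, not bounded by 1).
#'
#' @param traj A `particle_trajectory`.
#' @param species Species filter (default all).
#' @param spacing_A Cubic voxel edge (> 0), default 0.5.
#' @param mode `"occupancy"` or `"count"`; recorded in the result.
#' @param region Optional lateral cylinder filter.
#' @return A `density_grid` list: `values` (3D array), `origin_A`
#'   (position of the corner of voxel [1,1,1]), `spacing_A`, `mode`,
#'   `n_frames`.
#' @export
density_grid <- function(traj, species = NULL, spacing_A = 0.5,
                         mode = c("occupancy", "count"), region = NULL) {
  mode <- match.arg(mode)
  stop_if_not(spacing_A > 0, "spacing must be > 0")
  d <- filter_particles(traj, species, region)
  stop_if_not(nrow(d) > 0, "no selected particles")
  frames <- unique(d[, c("replicate", "frame")])
  n_frames <- nrow(frames)
  origin <- c(floor(min(d$x) / spacing_A), floor(min(d$y) / spacing_A),
              floor(min(d$z) / spacing_A)) * spacing_A
  ix <- floor((d$x - origin[1]) / spacing_A) + 1L
  iy <- floor((d$y - origin[2]) / spacing_A) + 1L
  iz <- floor((d$z - origin[3]) / spacing_A) + 1L
  dims <- c(max(ix), max(iy), max(iz))
  vox <- array(0, dim = dims)
  lin <- (iz - 1L) * dims[1] * dims[2] + (iy - 1L) * dims[1] + ix
  if (mode == "occupancy") {
    frame_key <- paste(d$replicate, d$frame, sep = "_")
    occ <- unique(data.frame(lin = lin, frame = frame_key))
    tab <- table(occ$lin)
    vox[as.integer(names(tab))] <- as.integer(tab) / n_frames
  } else {
    tab <- table(lin)
    vox[as.integer(names(tab))] <- as.integer(tab) / n_frames
  }
  structure(list(values = vox, origin_A = origin, spacing_A = spacing_A,
                 mode = mode, n_frames = n_frames),
            class = "density_grid")
}

#' Accessible-region mask of an occupancy grid
#'
#' Marks voxels whose occupancy probability strictly exceeds the threshold
#' (default 0.005); a voxel exactly at the threshold is excluded.
#'
#' @param grid A `density_grid`.
#' @param threshold Probability threshold.
#' @return List with `mask` (logical array), `threshold`, `n_voxels`,
#'   and `volume_A3` (`n_voxels * spacing^3`).
#' @export
accessible_region <- function(grid, threshold = 0.005) {
  stopifnot(inherits(grid, "density_grid"))
  mask <- grid$values > threshold
  n <- sum(mask)
  list(mask = mask, threshold = threshold, n_voxels = n,
       volume_A3 = n * grid$spacing_A^3)
}

#' Detect leaflet-to-leaflet permeation events
#'
#' A particle commits to the inner zone when `z < inner_z_A` and to the
#' outer zone when `z > outer_z_A`; the band between the thresholds is
#' hysteresis. An event is recorded each time a particle committed to one
#' zone reaches the opposite zone, whatever it does inside the band in
#' between; events per particle are non-overlapping and time-ordered.
#' Particles first observed inside the band produce no event until they
#' commit to a zone. When a lateral `region` is given, each event reports
#' whether the particle stayed within it for the whole transit
#' (`passed_through_region`).
#'
#' @param traj A `particle_trajectory`.
#' @param species Species filter.
#' @param inner_z_A,outer_z_A Zone thresholds, `inner_z_A < outer_z_A`
#'   (default -15 / +15 A about the membrane center).
#' @param region Optional lateral cylinder (groove region).
#' @return Data frame with `replicate`, `particle_id`, `start_frame`,
#'   `end_frame`, `direction` (`"inner_to_outer"` / `"outer_to_inner"`),
#'   `passed_through_region`. Zero rows when nothing crosses.
#' @export
detect_permeation_events <- function(traj, species = NULL,
                                     inner_z_A = -15, outer_z_A = 15,
                                     region = NULL) {
  stop_if_not(inner_z_A < outer_z_A,
              "inner_z_A must be below outer_z_A (thresholds inverted)")
  d <- if (is.null(species)) traj else traj[traj$species %in% species, ]
  res <- list()
  in_region <- if (is.null(region)) {
    rep(TRUE, nrow(d))
  } else {
    (d$x - region$center[1])^2 + (d$y - region$center[2])^2 <=
      region$radius^2
  }
  groups <- split(seq_len(nrow(d)),
                  list(d$replicate, d$particle_id), drop = TRUE)
  for (g in groups) {
    g <- g[order(d$frame[g])]
    z <- d$z[g]
    fr <- d$frame[g]
    inr <- in_region[g]
    zone <- ifelse(z < inner_z_A, -1L, ifelse(z > outer_z_A, 1L, 0L))
    state <- 0L       # last committed zone; 0 = none yet
    start_i <- NA_integer_
    for (k in seq_along(zone)) {
      if (zone[k] == 0L) next
      if (state == 0L) {
        state <- zone[k]
        start_i <- k
      } else if (zone[k] == state) {
        start_i <- k    # still in the starting zone: restart the transit
      } else {
        res[[length(res) + 1L]] <- data.frame(
          replicate = d$replicate[g[1]],
          particle_id = d$particle_id[g[1]],
          start_frame = fr[start_i], end_frame = fr[k],
          direction = if (state == -1L) "inner_to_outer"
                      else "outer_to_inner",
          passed_through_region = all(inr[start_i:k]),
          stringsAsFactors = FALSE)
        state <- zone[k]
        start_i <- k
      }
    }
  }
  if (!length(res)) {
    return(data.frame(replicate = integer(), particle_id = integer(),
                      start_frame = integer(), end_frame = integer(),
                      direction = character(),
                      passed_through_region = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$replicate, out$particle_id, out$start_frame), ]
  rownames(out) <- NULL
  out
}

#' Write an occupancy grid in OpenDX format
#'
#' Plain-text `.dx` with origin and delta records, voxel values z-fastest,
#' readable by common molecular-visualization tools.
#'
#' @param grid A `density_grid`.
#' @param path Output file path.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  dm <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d",
            dm[1], dm[2], dm[3]),
    sprintf("origin %g %g %g",
            grid$origin_A[1], grid$origin_A[2], grid$origin_A[3]),
    sprintf("delta %g 0 0", grid$spacing_A),
    sprintf("delta 0 %g 0", grid$spacing_A),
    sprintf("delta 0 0 %g", grid$spacing_A),
    sprintf("object 2 class gridconnections counts %d %d %d",
            dm[1], dm[2], dm[3]),
    sprintf(paste("object 3 class array type double rank 0 items %d",
                  "data follows"), prod(dm))
  ), con)
  flat <- numeric(prod(dm))  # z fastest, per the DX convention
  k <- 1L
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    flat[k:(k + dm[3] - 1L)] <- grid$values[i, j, ]
    k <- k + dm[3]
  }
  lines <- vapply(split(flat, ceiling(seq_along(flat) / 3)),
                  function(x) paste(format(x, trim = TRUE), collapse = " "),
                  character(1))
  writeLines(lines, con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}
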