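#' Specify an overdamped Langevin simulation along the membrane normal
#'
#' Defines a 1D Brownian-dynamics surrogate whose stationary law is the
#' Boltzmann distribution `exp(-U(z)/kT)`; used to validate the density /
#' free-energy post-processing against a known potential. Lateral x, y
#' coordinates are filled with independent uniform jitter so trajectories
#' carry full 3D columns.
#'
#' @param potential Function `z -> U(z)` in kT units, finite over
#'   `z_bounds`. Its gradient is taken by central differences.
#' @param kT Thermal energy (1 by convention).
#' @param diffusion_coeff Diffusion coefficient D (A^2 per step unit).
#' @param dt Time step (step units). The characteristic random step
#'   `sqrt(2 D dt)` must not exceed 10% of the `z_bounds` span.
#' @param n_particles Independent walkers per replicate.
#' @param n_steps Steps per walker.
#' @param n_replicates Number of independent replicates (default 3,
#'   matching the triplicate-simulation design this surrogate stands in
#'   for).
#' @param z_bounds Length-2 interval with reflecting walls (A).
#' @param frame_stride Record every `frame_stride`-th step.
#' @param frame_time_ns Nominal time between recorded frames in ns
#'   (metadata only; default 0.05 ns, i.e. one snapshot per 50 ps).
#' @param seed Integer seed.
#' @return A `langevin_spec` list.
#' @export
langevin_spec <- function(potential, kT = 1, diffusion_coeff = 1, dt = 0.01,
                          n_particles = 10L, n_steps = 1000L,
                          n_replicates = 3L, z_bounds = c(-10, 10),
                          frame_stride = 1L, frame_time_ns = 0.05,
                          seed = 1L) {
  stopifnot(is.function(potential))
  stop_if_not(n_replicates >= 1, "n_replicates must be >= 1")
  stop_if_not(dt > 0 && diffusion_coeff > 0 && kT > 0,
              "dt, diffusion_coeff, kT must be > 0")
  stop_if_not(length(z_bounds) == 2L && diff(z_bounds) > 0,
              "z_bounds must be a non-degenerate interval")
  step <- sqrt(2 * diffusion_coeff * dt)
  stop_if_not(step <= 0.1 * diff(z_bounds),
              paste("random step length %.3g exceeds 10%% of the z span;",
                    "integration too coarse"), step)
  structure(list(potential = potential, kT = kT,
                 diffusion_coeff = diffusion_coeff, dt = dt,
                 n_particles = as.integer(n_particles),
                 n_steps = as.integer(n_steps),
                 n_replicates = as.integer(n_replicates),
                 z_bounds = as.numeric(z_bounds),
                 frame_stride = as.integer(frame_stride),
                 frame_time_ns = frame_time_ns,
                 seed = as.integer(seed)),
            class = "langevin_spec")
}

# Reflect positions into [lo, hi] (single overshoot per step suffices for
# steps bounded at 10% of the span, but fold repeatedly to be safe).
reflect <- function(z, lo, hi) {
  span <- hi - lo
  z <- (z - lo) %% (2 * span)
  z <- ifelse(z > span, 2 * span - z, z)
  z + lo
}

#' Simulate overdamped Langevin trajectories
#'
#' Integrates `z <- z + (-dU/dz) * (D/kT) * dt + sqrt(2 D dt) * xi` with
#' reflecting walls at `z_bounds`, one independent replicate per
#' `n_replicates`. The stationary distribution converges to
#' `exp(-U(z)/kT)` up to normalization.
#'
#' @param spec A [langevin_spec()].
#' @param species Species label attached to every particle.
#' @return A `particle_trajectory` data frame with columns `replicate`,
#'   `frame`, `time_ns`, `particle_id`, `species`, `x`, `y`, `z`.
#' @export
simulate_langevin <- function(spec, species = "phosphate") {
  stopifnot(inherits(spec, "langevin_spec"))
  lo <- spec$z_bounds[1]; hi <- spec$z_bounds[2]
  stop_if_not(all(is.finite(vapply(seq(lo, hi, length.out = 101),
                                   spec$potential, numeric(1)))),
              "potential must be finite over z_bounds")
  h <- 1e-4 * (hi - lo)
  # use the potential vectorized when it supports it (hot path)
  vec_ok <- tryCatch(length(spec$potential(c(lo, hi))) == 2L,
                     error = function(e) FALSE)
  U <- if (vec_ok) {
    spec$potential
  } else {
    function(z) vapply(z, spec$potential, numeric(1))
  }
  grad <- function(z) (U(z + h) - U(z - h)) / (2 * h)
  mob <- spec$diffusion_coeff / spec$kT
  sd_step <- sqrt(2 * spec$diffusion_coeff * spec$dt)

  with_seed(spec$seed, {
    reps <- lapply(seq_len(spec$n_replicates), function(r) {
      np <- spec$n_particles
      z <- stats::runif(np, lo, hi)
      rec <- seq(spec$frame_stride, spec$n_steps, by = spec$frame_stride)
      zs <- matrix(NA_real_, nrow = length(rec), ncol = np)
      k <- 0L
      for (s in seq_len(spec$n_steps)) {
        z <- z - grad(z) * mob * spec$dt + stats::rnorm(np, sd = sd_step)
        z <- reflect(z, lo, hi)
        if (s %% spec$frame_stride == 0L) {
          k <- k + 1L
          zs[k, ] <- z
        }
      }
      n_frames <- length(rec)
      data.frame(
        replicate = r,
        frame = rep(seq_len(n_frames), each = np),
        time_ns = rep(seq_len(n_frames) * spec$frame_time_ns, each = np),
        particle_id = rep(seq_len(np), times = n_frames),
        species = species,
        x = stats::runif(n_frames * np, -5, 5),
        y = stats::runif(n_frames * np, -5, 5),
        z = as.vector(t(zs)),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, reps)
    class(out) <- c("particle_trajectory", "data.frame")
    out
  })
}

#' Write / read particle trajectories as columnar CSV
#'
#' Columns: `replicate, frame, time_ns, particle_id, species, x, y, z`.
#'
#' @param traj A `particle_trajectory` data frame.
#' @param path CSV file path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("replicate", "frame", "particle_id", "species", "z")
                  %in% names(out)),
              "trajectory file lacks required columns")
  class(out) <- c("particle_trajectory", "data.frame")
  out
}
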