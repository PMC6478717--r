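test_that("frame selection keeps [t_start, t_end) and rejects empty windows", {
  traj <- scripted_traj(rep(0, 8000))  # 0.05 ns per frame: 0.05 .. 400 ns
  sel <- select_frames(traj, 100, 400)
  expect_equal(nrow(sel), 6000)  # (400 - 100) / 0.05
  expect_true(all(sel$time_ns >= 100 & sel$time_ns < 400))
  all_of_it <- select_frames(traj, 0, 1000)
  expect_equal(nrow(all_of_it), nrow(traj))
  expect_error(select_frames(traj, 1000, 2000), "empty")
  expect_error(select_frames(traj, 400, 100), "t_start")
})

test_that("density profiles conserve particle counts exactly", {
  # single static particle: all mass in one bin, integral = 1 per frame
  traj <- scripted_traj(rep(2.3, 50))
  prof <- density_profile(traj, bin_width_A = 1)
  expect_equal(sum(prof$density * prof$bin_width_A), 1)
  expect_equal(sum(prof$density > 0), 1)

  # multi-particle, multi-replicate: integral = mean in-region count/frame
  spec <- langevin_spec(function(z) 0.5 * z^2, n_particles = 7,
                        n_steps = 400, n_replicates = 2,
                        z_bounds = c(-5, 5), frame_stride = 10, seed = 3)
  traj2 <- simulate_langevin(spec)
  prof2 <- density_profile(traj2, bin_width_A = 0.5)
  integral <- colSums(prof2$density) * prof2$bin_width_A
  expect_equal(unname(integral), c(7, 7))
})

test_that("profiles are invariant to frame order and respect the reference", {
  spec <- langevin_spec(function(z) 0.5 * z^2, n_particles = 5,
                        n_steps = 300, n_replicates = 1,
                        z_bounds = c(-5, 5), frame_stride = 5, seed = 4)
  traj <- simulate_langevin(spec)
  prof <- density_profile(traj, bin_width_A = 1)
  shuf <- traj[scramblekit:::with_seed(1, sample(nrow(traj))), ]
  prof_shuf <- density_profile(shuf, bin_width_A = 1)
  expect_equal(prof_shuf$density, prof$density)
  # shifting coordinates and reference together leaves the profile fixed
  moved <- traj; moved$z <- moved$z + 12.5
  prof_ref <- density_profile(moved, reference_z_A = 12.5, bin_width_A = 1,
                              z_range_A = range(prof$bin_edges_A))
  expect_equal(prof_ref$density, prof$density)
})

test_that("pmf_from_density handles flat, replicated, and empty-bin cases", {
  # uniform density -> W identically 0
  prof <- list(bin_edges_A = 0:5, bin_centers_A = 0:4 + 0.5,
               density = matrix(2, 5, 3), counts = matrix(20, 5, 3),
               n_frames = c(10, 10, 10), replicates = 1:3,
               bin_width_A = 1, reference_z_A = 0)
  class(prof) <- "density_profile"
  pmf <- pmf_from_density(prof)
  expect_true(all(pmf$w_kT == 0))
  # two identical replicates -> SE identically 0
  prof$density <- cbind(c(1, 2, 4, 2, 1), c(1, 2, 4, 2, 1))
  prof$counts <- prof$density * 10
  prof$n_frames <- c(10, 10)
  pmf2 <- pmf_from_density(prof)
  expect_true(all(pmf2$se_kT == 0))
  expect_equal(min(pmf2$w_kT), 0)  # anchored
  expect_equal(pmf2$w_kT[3], 0)
  expect_equal(pmf2$w_kT[1], log(4), tolerance = 1e-12)
  # zero-density bins carry the +Inf sentinel and drop out of the SE
  prof$density[1, 1] <- 0
  pmf3 <- pmf_from_density(prof)
  expect_equal(pmf3$n_finite_replicates[1], 1)
  expect_true(is.na(pmf3$se_kT[1]))
  prof$density[] <- 0
  expect_error(pmf_from_density(prof), "all-empty")
})

test_that("PMF recovery: harmonic well within stabilized 3x SE", {
  spec <- langevin_spec(function(z) 0.5 * z^2, n_particles = 20,
                        n_steps = 20000, n_replicates = 3,
                        z_bounds = c(-5, 5), dt = 0.02, frame_stride = 100,
                        seed = 14)
  traj <- simulate_langevin(spec)
  prof <- density_profile(traj, bin_width_A = 1, z_range_A = c(-5, 5))
  pmf <- pmf_from_density(prof)
  ref <- harmonic_binned_ref(prof$bin_edges_A)
  well <- apply(prof$counts, 1, min) >= 100
  se_star <- pmax(pmf$se_kT, pmf_counting_se(prof))
  dev <- (pmf$w_kT - min(pmf$w_kT[well])) - (ref - min(ref[well]))
  expect_true(all(abs(dev[well]) <= 3 * se_star[well]))
  # the 2 kT barrier at |z| = 2 A is recovered
  at2 <- which(abs(abs(pmf$bin_center_A) - 2) < 0.6 & well)
  expect_lt(max(abs(pmf$w_kT[at2] - ref[at2])), 0.5)
})

test_that("occupancy grids count voxels correctly", {
  # one particle fixed at a point: exactly one voxel at probability 1
  traj <- scripted_traj(rep(1.2, 10))
  g <- density_grid(traj, spacing_A = 0.5)
  expect_equal(sum(g$values == 1), 1)
  expect_equal(sum(g$values != 0), 1)
  # alternation between two voxels over 2N frames: both at 0.5
  traj2 <- scripted_traj(rep(c(0.2, 1.2), 10))
  g2 <- density_grid(traj2, spacing_A = 0.5)
  expect_equal(sort(g2$values[g2$values > 0]), c(0.5, 0.5))
  expect_true(all(g2$values >= 0 & g2$values <= 1))
  expect_error(density_grid(traj2, spacing_A = 0), "spacing")
})

test_that("grid occupancy is invariant under rigid translation", {
  spec <- langevin_spec(function(z) 0.5 * z^2, n_particles = 4,
                        n_steps = 200, n_replicates = 1,
                        z_bounds = c(-5, 5), frame_stride = 5, seed = 5)
  traj <- simulate_langevin(spec)
  g1 <- density_grid(traj, spacing_A = 1)
  moved <- traj
  moved$x <- moved$x + 7; moved$y <- moved$y - 3; moved$z <- moved$z + 11
  g2 <- density_grid(moved, spacing_A = 1)
  expect_equal(sum(g2$values), sum(g1$values))
  expect_equal(sort(g2$values[g2$values > 0]),
               sort(g1$values[g1$values > 0]))
})

test_that("accessible region uses a strict threshold", {
  g <- structure(list(values = array(c(0.004, 0.005, 0.006, 0),
                                     dim = c(4, 1, 1)),
                      origin_A = c(0, 0, 0), spacing_A = 0.5,
                      mode = "occupancy", n_frames = 1000),
                 class = "density_grid")
  m <- accessible_region(g, threshold = 0.005)
  expect_equal(m$n_voxels, 1)               # only the 0.006 voxel
  expect_true(m$mask[3, 1, 1])
  expect_false(m$mask[2, 1, 1])             # 0.005 excluded: strict >
  expect_equal(m$volume_A3, 0.5^3)
  empty <- accessible_region(structure(
    list(values = array(0, c(2, 2, 2)), origin_A = c(0, 0, 0),
         spacing_A = 0.5, mode = "occupancy", n_frames = 10),
    class = "density_grid"))
  expect_equal(empty$n_voxels, 0)
})

test_that("permeation events honour hysteresis, direction and order", {
  # oscillation strictly inside the band: no events
  band <- scripted_traj(c(-10, 5, -12, 8, -5, 10))
  expect_equal(nrow(detect_permeation_events(band)), 0)
  # monotone inner -> outer crossing: exactly one event
  up <- scripted_traj(c(-20, -16, -10, 0, 10, 16, 20))
  ev <- detect_permeation_events(up)
  expect_equal(nrow(ev), 1)
  expect_identical(ev$direction, "inner_to_outer")
  expect_equal(ev$start_frame, 2)  # last frame committed to the inner zone
  expect_equal(ev$end_frame, 6)
  # double round trip: two events with opposite directions in order
  rt <- scripted_traj(c(-20, 0, 20, 0, -20))
  ev2 <- detect_permeation_events(rt)
  expect_equal(ev2$direction, c("inner_to_outer", "outer_to_inner"))
  # dips back into the starting zone restart the transit, no double count
  dip <- scripted_traj(c(-20, -5, -17, 0, 20))
  expect_equal(nrow(detect_permeation_events(dip)), 1)
  expect_error(detect_permeation_events(up, inner_z_A = 15,
                                        outer_z_A = -15), "inverted")
})

test_that("event detection is reversal-symmetric", {
  z <- c(-20, -4, 8, 17, 3, -18, -2, 16, 20)
  fwd <- detect_permeation_events(scripted_traj(z))
  rev_ev <- detect_permeation_events(scripted_traj(rev(z)))
  expect_equal(nrow(fwd), nrow(rev_ev))
  expect_equal(table(fwd$direction)[["inner_to_outer"]],
               table(rev_ev$direction)[["outer_to_inner"]])
})

test_that("groove-region passage is tracked per event", {
  z <- c(-20, -10, 0, 10, 20)
  traj <- scripted_traj(z)
  traj$x <- c(0, 0, 3, 0, 0)  # briefly leaves a radius-2 cylinder
  inside <- detect_permeation_events(traj,
                                     region = list(center = c(0, 0),
                                                   radius = 5))
  expect_true(inside$passed_through_region)
  outside <- detect_permeation_events(traj,
                                      region = list(center = c(0, 0),
                                                    radius = 2))
  expect_false(outside$passed_through_region)
})

test_that("grids export to readable OpenDX text", {
  traj <- scripted_traj(rep(c(0.2, 1.2), 5))
  g <- density_grid(traj, spacing_A = 0.5)
  path <- file.path(tempdir(), "grid.dx")
  write_dx(g, path)
  lines <- readLines(path)
  expect_match(lines[1], "gridpositions counts")
  expect_match(lines[2], "^origin ")
  n_items <- prod(dim(g$values))
  expect_match(lines[7], sprintf("items %d", n_items))
})
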