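# Shared fixtures, built in code.

# Lattice of non-overlapping scrambler cells with uniform-random half-times.
make_cell_grid <- function(n_side, radius = 4, pitch = 11,
                           t_half_range = c(100, 400), rise_width_s = 15,
                           i_max = 1000, baseline = 100, seed = 7) {
  n <- n_side^2
  th <- scramblekit:::with_seed(seed, runif(n, t_half_range[1],
                                            t_half_range[2]))
  cells <- vector("list", n)
  k <- 0L
  for (i in seq_len(n_side)) for (j in seq_len(n_side)) {
    k <- k + 1L
    cells[[k]] <- cell_spec(sprintf("c%03d", k),
                            c(pitch / 2 + (i - 1) * pitch,
                              pitch / 2 + (j - 1) * pitch),
                            radius, "scrambler", t_half_true_s = th[k],
                            rise_width_s = rise_width_s, i_max_true = i_max,
                            baseline = baseline)
  }
  cells
}

# Hand-scripted single-particle trajectory along z (one row per frame).
scripted_traj <- function(z, species = "phosphate", replicate = 1L) {
  out <- data.frame(replicate = replicate, frame = seq_along(z),
                    time_ns = seq_along(z) * 0.05, particle_id = 1L,
                    species = species, x = 0, y = 0, z = z,
                    stringsAsFactors = FALSE)
  class(out) <- c("particle_trajectory", "data.frame")
  out
}

# Bin-averaged Boltzmann reference free energy for U(z) = 0.5 k z^2 in kT:
# W_ref(bin) = -log(P(bin) / max P), the correct oracle for binned samples.
harmonic_binned_ref <- function(edges, k = 1) {
  s <- 1 / sqrt(k)
  p <- pnorm(edges[-1], sd = s) - pnorm(edges[-length(edges)], sd = s)
  -log(p / max(p))
}

# Per-bin counting SE of the replicate-mean PMF (multinomial counts):
# sd(W_j) ~ sqrt((1 - p)/C) per replicate, plus the shared reference-bin
# term; stabilizes the 3x-SE comparison when the replicate SE (2 df) is
# unreliable.
pmf_counting_se <- function(profile) {
  cnt <- profile$counts
  tot <- colSums(cnt)
  se2 <- rowMeans(sweep(1 - sweep(cnt, 2, tot, "/"), 2, 1, "*") /
                    pmax(cnt, 1))
  ref <- apply(cnt, 2, max)
  se2_ref <- mean((1 - ref / tot) / ref)
  sqrt((se2 + se2_ref) / ncol(cnt))
}
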