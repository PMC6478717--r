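test_that("roi_intensity sums ROI pixels and is additive over disjoint ROIs", {
  fr <- matrix(1:9, 3, 3, byrow = TRUE)
  top <- roi("t", data.frame(row = 0, col = 0:2))
  expect_identical(roi_intensity(fr, top), 6L)          # 1 + 2 + 3
  expect_identical(roi_intensity(matrix(0, 3, 3), top), 0)
  uniform <- matrix(7, 5, 5)
  r5 <- roi("u", data.frame(row = c(0, 1, 2, 3, 4), col = c(0, 1, 2, 3, 4)))
  expect_identical(roi_intensity(uniform, r5), 35)       # N * v
  mid <- roi("m", data.frame(row = 1, col = 0:2))
  both <- roi("b", rbind(top$pixels, mid$pixels))
  expect_equal(roi_intensity(fr, both),
               roi_intensity(fr, top) + roi_intensity(fr, mid))
  expect_error(roi_intensity(fr, roi("x", data.frame(row = 3, col = 0))),
               "outside")
})

test_that("extract_trace applies the ROI per frame with stimulus-relative times", {
  stack <- array(2, dim = c(4, 4, 2))
  movie <- list(stack = stack, times_s = c(0, 5))
  r <- roi("c", data.frame(row = 0:1, col = 0))
  tr <- extract_trace(movie, r)
  expect_equal(tr$intensity, c(4, 4))
  expect_equal(tr$time_s, c(0, 5))
  # stimulus later in the stack shifts times negative before it
  tr2 <- extract_trace(list(stack = array(1, c(2, 2, 3)),
                            times_s = c(0, 5, 10)), r, stimulus_frame = 2L)
  expect_equal(tr2$time_s, c(-5, 0, 5))
  expect_error(
    extract_trace(list(stack = stack, times_s = 0), r),
    "timestamps")
})

test_that("compute_t_half matches hand-derived interpolation and symmetry", {
  # linear interpolation between bracketing frames, by hand:
  # half = 50 crosses between (5, 40) and (10, 100)
  tr <- data.frame(time_s = c(0, 5, 10), intensity = c(0, 40, 100))
  res <- compute_t_half(tr)
  expect_equal(res$i_max, 100)
  expect_equal(res$t_half_s, 5 + 5 * (50 - 40) / (100 - 40),
               tolerance = 1e-12)

  # symmetric logistic: half-max time equals the midpoint
  t <- seq(0, 600, by = 5)
  y <- 1000 / (1 + exp(-(t - 300) / 15))
  expect_equal(compute_t_half(data.frame(time_s = t, intensity = y))$t_half_s,
               300, tolerance = 1e-6)

  # linear ramp 0 -> Imax over [0, 600]
  ramp <- data.frame(time_s = t, intensity = t / 600 * 800)
  expect_equal(compute_t_half(ramp)$t_half_s, 300, tolerance = 1e-9)

  expect_error(compute_t_half(data.frame(time_s = -5, intensity = 1)),
               "window")
})

test_that("t_half is invariant to affine rescaling and shifts with time", {
  t <- seq(0, 600, by = 5)
  y <- 1000 / (1 + exp(-(t - 200) / 15))
  base <- compute_t_half(data.frame(time_s = t, intensity = y))$t_half_s
  resc <- compute_t_half(data.frame(time_s = t, intensity = 3.7 * y + 250))
  expect_equal(resc$t_half_s, base, tolerance = 1e-9)
  delayed <- 1000 / (1 + exp(-(t - 260) / 15))  # shifted 60 s later
  expect_equal(
    compute_t_half(data.frame(time_s = t, intensity = delayed))$t_half_s,
    base + 60, tolerance = 1e-6)
})

test_that("classifier separates scramblers from non-scramblers", {
  t <- seq(0, 600, by = 5)
  set.seed(5)
  flat <- data.frame(cell_id = "ns", time_s = t,
                     intensity = 100 + rnorm(length(t), sd = 3))
  res <- classify_scrambler(flat, fold_threshold = 2)
  expect_false(res$is_scrambler)
  expect_identical(res$t_half_s, Inf)
  expect_false(res$included_in_stats)

  rising <- data.frame(cell_id = "sc", time_s = t,
                       intensity = 100 + 900 /
                         (1 + exp(-(t - 150) / 20)))
  res2 <- classify_scrambler(rising, fold_threshold = 2)
  expect_true(res2$is_scrambler)
  expect_lt(abs(res2$t_half_s - 150), 1)

  # zero baseline with zero signal: degenerate rule -> non-scrambler
  zero <- data.frame(cell_id = "z", time_s = t, intensity = 0 * t)
  expect_false(classify_scrambler(zero)$is_scrambler)
})

test_that("classifier recovers a known non-scrambler fraction from traces", {
  # 48% scramblers / 52% non-scramblers, as in strong loss-of-function
  # mutants; recovery within the 95% binomial CI
  n <- 250
  frac_scr <- 0.48
  cells <- scramblekit:::with_seed(31, {
    lapply(seq_len(n), function(i) {
      if (runif(1) < frac_scr) {
        cell_spec(sprintf("c%d", i), c(0, 0), 1, "scrambler",
                  t_half_true_s = runif(1, 60, 500), rise_width_s = 20,
                  i_max_true = 1000, baseline = 100)
      } else {
        cell_spec(sprintf("c%d", i), c(0, 0), 1, "non_scrambler",
                  i_max_true = 1000, baseline = 100)
      }
    })
  })
  spec <- movie_spec(duration_s = 600, seed = 32L)
  traces <- simulate_traces(spec, cells, trace_noise_sd = 20)
  res <- do.call(rbind, lapply(split(traces, traces$cell_id),
                               classify_scrambler))
  frac_ns <- mean(!res$is_scrambler)
  ci_half <- 1.96 * sqrt(0.52 * 0.48 / n)
  expect_lt(abs(frac_ns - 0.52), ci_half)
})

test_that("percent_ps_positive pools fields per coverslip", {
  expect_equal(percent_ps_positive(
    data.frame(n_expressing = c(10, 10), n_ps_positive = c(0, 0))
  )$percent_ps_positive, 0)
  expect_equal(percent_ps_positive(
    data.frame(n_expressing = 10, n_ps_positive = 10)
  )$percent_ps_positive, 100)
  # pooled, not averaged per field: 100 * 21 / 50 = 42
  expect_equal(percent_ps_positive(
    data.frame(n_expressing = c(20, 30), n_ps_positive = c(8, 13))
  )$percent_ps_positive, 42)
  expect_error(percent_ps_positive(
    data.frame(n_expressing = 0, n_ps_positive = 0)), "undefined")
  expect_error(percent_ps_positive(
    data.frame(n_expressing = 5, n_ps_positive = 6)), "exceed")
})
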