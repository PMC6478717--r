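ext_std <- solution(na_mM = 140, cl_mM = 140)
int_low <- solution(na_mM = 14, cl_mM = 14)

test_that("GHK potential reproduces Nernst limits and symmetry", {
  # symmetric solutions: log of 1
  expect_equal(ghk_potential(1, 1, ext_std, solution(140, 140)), 0)
  expect_equal(ghk_potential(0.3, 2.4, ext_std, solution(140, 140)), 0)
  # P_Na = 0: pure Cl- electrode, (RT/F) ln([Cl]i/[Cl]o) = -59.16 mV
  expect_equal(ghk_potential(0, 1, ext_std, int_low), -59.156,
               tolerance = 1e-4)
  # P_Cl = 0: mirror case
  expect_equal(ghk_potential(1, 0, ext_std, int_low), +59.156,
               tolerance = 1e-4)
  # antisymmetric under swapping the solutions
  v <- ghk_potential(1, 3, ext_std, int_low)
  expect_equal(ghk_potential(1, 3, int_low, ext_std), -v)
  expect_equal(physical_constants()$RT_F_mV, 25.693, tolerance = 1e-4)
})

test_that("GHK potential and ratio inversion are mutual inverses", {
  ratios <- 10^seq(-3, 3, length.out = 1000)
  back <- vapply(ratios, function(r) {
    v <- ghk_potential(1, r, ext_std, int_low)
    ghk_permeability_ratio(v, ext_std, int_low)$p_cl_over_p_na
  }, numeric(1))
  expect_lt(max(abs(back - ratios) / ratios), 1e-9)
  # zero shift with the symmetric 10:1 dilution design means P_Cl = P_Na
  expect_equal(ghk_permeability_ratio(0, ext_std, int_low)$p_cl_over_p_na, 1)
  # shifts outside the attainable window are rejected
  expect_error(ghk_permeability_ratio(-59.16, ext_std, int_low),
               "not representable")
  expect_error(ghk_permeability_ratio(70, ext_std, int_low),
               "not representable")
})

test_that("ohmic steps yield a linear I-V with the generator conductance", {
  model <- ephys_model_spec(conductance_nS = 1, reversal_mV = 0)
  sw <- simulate_sweeps(model)
  iv <- build_iv(sw)
  # 1 nS * (V - 0) mV = V pA; slope exactly 1 pA/mV
  expect_equal(iv$current_pA, iv$voltage_mV, tolerance = 1e-9)
  expect_equal(iv$current_pA[iv$voltage_mV == 100], 100)
  zero <- build_iv(simulate_sweeps(ephys_model_spec(conductance_nS = 0)))
  expect_true(all(zero$current_pA == 0))
})

test_that("rectifying models round-trip through build_iv", {
  rect <- function(v) exp(v / 200)
  model <- ephys_model_spec(conductance_nS = 2, reversal_mV = -10,
                            rectification = rect)
  iv <- build_iv(simulate_sweeps(model))
  expect_equal(iv$current_pA, 2 * (iv$voltage_mV + 10) * rect(iv$voltage_mV),
               tolerance = 1e-9)
})

test_that("tail-current G-V recovers the generating Boltzmann", {
  boltz <- function(v) 5 / (1 + exp(-(v - 20) / 15))
  model <- ephys_model_spec(conductance_nS = boltz, reversal_mV = 0,
                            deactivation_tau_ms = 20)
  gv <- build_gv(simulate_sweeps(model))
  expect_equal(max(gv$g_norm), 1)
  ref <- boltz(gv$voltage_mV) / boltz(140)
  expect_equal(gv$g_norm, ref, tolerance = 1e-9)
  # scale invariance: conductance scaling leaves G-V unchanged
  gv2 <- build_gv(simulate_sweeps(
    ephys_model_spec(conductance_nS = function(v) 13 * boltz(v))))
  expect_equal(gv2$g_norm, gv$g_norm, tolerance = 1e-9)
  # voltage-independent conductance: flat at 1
  flat <- build_gv(simulate_sweeps(ephys_model_spec(conductance_nS = 1,
                                                    reversal_mV = 0)))
  expect_true(all(abs(flat$g_norm - 1) < 1e-9))
  expect_error(build_gv(simulate_sweeps(ephys_model_spec(0))), "zero")
})

test_that("reversal potential is read off the descending ramp phase", {
  prot <- voltage_protocol("inverted_v_ramp",
                           ramp_bounds_mV = c(-120, 120, -120))
  model <- ephys_model_spec(conductance_nS = 1, reversal_mV = -59.2,
                            protocol = prot)
  m <- measure_erev(simulate_sweeps(model))
  expect_equal(m$erev_mV, -59.2, tolerance = 1e-6)
  expect_identical(m$phase, "descending")
  # symmetric solutions: reversal at 0
  m0 <- measure_erev(simulate_sweeps(
    ephys_model_spec(conductance_nS = 1, reversal_mV = 0, protocol = prot)))
  expect_lt(abs(m0$erev_mV), 1e-9)
  # all-positive current never reverses
  shifted <- simulate_sweeps(model)
  shifted$sweeps$current_pA <- shifted$sweeps$current_pA + 1e4
  expect_error(measure_erev(shifted), "no reversal")
})

test_that("noisy ramps resolve multiple crossings toward the anchor", {
  prot <- voltage_protocol("inverted_v_ramp")
  model <- ephys_model_spec(conductance_nS = 0.05, reversal_mV = -20,
                            noise_sd_pA = 2, protocol = prot, seed = 9)
  m <- measure_erev(simulate_sweeps(model), previous_erev_mV = -20)
  expect_lt(abs(m$erev_mV + 20), 5)
})

test_that("sweep sets round-trip through CSV", {
  sw <- simulate_sweeps(ephys_model_spec(conductance_nS = 1,
                                         noise_sd_pA = 1, seed = 4))
  path <- file.path(tempdir(), "sweeps.csv")
  write_sweeps(sw, path)
  back <- read_sweeps(path)
  expect_equal(back$sweeps$current_pA, sw$sweeps$current_pA,
               tolerance = 1e-9)
  expect_equal(back$protocol$step_levels_mV, sw$protocol$step_levels_mV)
  iv1 <- build_iv(sw); iv2 <- build_iv(back)
  expect_equal(iv2$current_pA, iv1$current_pA, tolerance = 1e-9)
})

test_that("free calcium solves the chelator equilibrium", {
  # no added Ca -> no free Ca; no chelator -> free equals total
  expect_equal(free_calcium(solution(ca_total_mM = 0, egta_mM = 5))$ca_free_uM,
               0)
  expect_equal(free_calcium(solution(ca_total_mM = 0.1))$ca_free_uM, 100)
  # the 2.26 uM internal solution: 5 EGTA + 4.64 CaCl2, pH 7.3, 25 degC
  sol <- solution(na_mM = 140, egta_mM = 5, ca_total_mM = 4.64, ph = 7.3)
  fc <- free_calcium(sol)
  expect_lt(abs(fc$ca_free_uM - 2.26) / 2.26, 0.15)
  expect_identical(fc$constants$name, "apparent")
  # monotone in total Ca, antitone in EGTA
  up <- free_calcium(solution(egta_mM = 5, ca_total_mM = 4.8))$ca_free_uM
  dn <- free_calcium(solution(egta_mM = 6, ca_total_mM = 4.64))$ca_free_uM
  expect_gt(up, fc$ca_free_uM)
  expect_lt(dn, fc$ca_free_uM)
  # weak-binding limit: free converges to total
  weak <- egta_constants()
  weak$log_k_ca <- 1
  expect_equal(free_calcium(sol, weak)$ca_free_uM, 4640, tolerance = 0.01)
  # the tabulated constant set binds ~2.5x tighter
  mart <- free_calcium(sol, egta_constants("martell"))
  expect_lt(mart$ca_free_uM, fc$ca_free_uM)
})
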