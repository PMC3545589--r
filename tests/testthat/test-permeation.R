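test_that("Michaelis-Menten fit recovers noiseless parameters exactly", {
  cs <- c(50, 100, 200, 300, 500, 1000)
  pts <- data.frame(concentration_mM = cs, current_pA = 127 * cs / (277 + cs))
  est <- fit_michaelis_menten(pts)
  expect_equal(unname(est["Imax_pA"]), 127, tolerance = 1e-6)
  expect_equal(unname(est["Ks_mM"]), 277, tolerance = 1e-6)
  expect_error(fit_michaelis_menten(
    data.frame(concentration_mM = c(100, 100), current_pA = c(1, 1))),
    "degenerate")
})

test_that("the fitted saturation curve reproduces the interpolated currents", {
  mm <- function(c) 127 * c / (277 + c)
  expect_equal(mm(500), 81.7, tolerance = 1e-3)
  expect_equal(mm(200), 52, tolerance = 0.03)
  # doubling the concentration deep into saturation changes current < 15%
  expect_lt(mm(2 * 1500) / mm(1500) - 1, 0.15)
})

test_that("equilibrium occupancy matches the closed form", {
  # flat profile at 1 M in a 4.53 A x 36 A cylinder: ~1.40 ions
  n <- equilibrium_occupancy(flat_pmf, 1000, 4.53)
  n_exp <- 6.02214076e23 * 1000 * pi * (4.53e-10)^2 * 36e-10
  expect_equal(n, n_exp, tolerance = 1e-4)
  expect_equal(n, 1.40, tolerance = 0.01)
  expect_equal(equilibrium_occupancy(flat_pmf, 0), 0)
  # linear in concentration; Boltzmann-enhanced by wells
  expect_equal(equilibrium_occupancy(flat_pmf, 500), n / 2, tolerance = 1e-9)
  expect_gt(equilibrium_occupancy(k_pmf, 500), equilibrium_occupancy(flat_pmf, 500))
})

test_that("steady-state solver reproduces the ohmic closed form on a flat profile", {
  sp <- potassium_ion(pore_diffusion_factor = 1)
  # J = D A c u / L for a flat profile with uniform D
  for (v in c(50, 200)) {
    u <- v / nanoporesim:::kT_millivolts(310)
    D <- 1.96e-9 * 1e8; A <- pi * 4.53^2; cc <- 0.1 * 6.02214076e-4
    J_exp <- D * A * cc * u / 36 * 1e12              # ions/s
    I <- steady_state_current(flat_pmf, sp, v, 100)
    expect_equal(attr(I, "flux_per_s"), J_exp, tolerance = 1e-3)
  }
  # zero voltage, symmetric concentrations: exactly zero
  expect_equal(as.numeric(steady_state_current(k_pmf, sp, 0, 500)), 0,
               tolerance = 1e-12)
})

test_that("simulated current is computed exactly from the crossing counts", {
  cfg <- quick_config(duration_ns = 50, voltage_mV = 200,
                      concentration_mM = 500)
  r <- simulate_permeation(cfg)
  by_rep <- tapply(r$crossings$net_crossings * 1.602176634e-19 /
                     (r$duration_ns * 1e-9) * 1e12,
                   r$crossings$replicate, sum)
  expect_equal(mean(by_rep), r$current_pA, tolerance = 1e-9)
})

test_that("no net current flows at zero voltage with symmetric solutions", {
  cfg <- quick_config(duration_ns = 100, voltage_mV = 0,
                      concentration_mM = 500, n_replicates = 5, seed = 3)
  r <- simulate_permeation(cfg)
  expect_lt(abs(r$current_pA), 2 * r$current_se_pA + 1e-9)
})

test_that("single-ion current agrees with the steady-state solver", {
  cfg <- quick_config(duration_ns = 1500, voltage_mV = 200,
                      concentration_mM = 100, timestep_ps = 0.05,
                      ion_interactions = FALSE, seed = 17)
  r <- simulate_permeation(cfg)
  orc <- as.numeric(steady_state_current(k_pmf, potassium_ion(), 200, 100))
  expect_equal(r$current_pA, orc,
               tolerance = 0.06 + 3 * r$current_se_pA / orc)
})

test_that("the chloride barrier blocks conduction and deepening it never helps", {
  cl_cfg <- quick_config(pmf = cl_pmf, sp = chloride_ion(),
                         duration_ns = 100, voltage_mV = 200,
                         concentration_mM = 500)
  r <- simulate_permeation(cl_cfg)
  expect_equal(sum(r$crossings$crossings_lr + r$crossings$crossings_rl), 0)
  barriers <- c(5, 10, 20)
  counts <- vapply(barriers, function(b) {
    p <- build_pmf_from_features(cbind(c(-18, 0, 18), c(0, b, 0)), 0.1)
    cfg <- quick_config(pmf = p, sp = chloride_ion(), duration_ns = 100,
                        voltage_mV = 200, concentration_mM = 500, seed = 5)
    rr <- simulate_permeation(cfg)
    sum(abs(rr$crossings$net_crossings))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)  # a 5 kT barrier still passes some ions
})

test_that("currents are antisymmetric in voltage for a symmetric profile", {
  rp <- simulate_permeation(quick_config(duration_ns = 250, voltage_mV = 150,
                                         concentration_mM = 500, seed = 9))
  rm <- simulate_permeation(quick_config(duration_ns = 250, voltage_mV = -150,
                                         concentration_mM = 500, seed = 10))
  se <- sqrt(rp$current_se_pA^2 + rm$current_se_pA^2)
  expect_lt(abs(rp$current_pA + rm$current_pA),
            3 * se + 0.1 * abs(rp$current_pA))
  expect_gt(rp$current_pA, 0)
  expect_lt(rm$current_pA, 0)
})

test_that("halving the timestep leaves the mean current unchanged within error", {
  base <- quick_config(duration_ns = 800, voltage_mV = 200,
                       concentration_mM = 500, timestep_ps = 0.1,
                       ion_interactions = FALSE, seed = 23)
  r1 <- simulate_permeation(base)
  half <- base; half$timestep_ps <- 0.05
  r2 <- simulate_permeation(half)
  se <- sqrt(r1$current_se_pA^2 + r2$current_se_pA^2)
  expect_lt(abs(r1$current_pA - r2$current_pA),
            0.03 * abs(r1$current_pA) + 3 * se)
})

test_that("dwell histograms reflect the Boltzmann weight of the profile", {
  # flat profile: near-uniform density
  rf <- simulate_permeation(quick_config(pmf = flat_pmf, duration_ns = 300,
                                         voltage_mV = 0,
                                         concentration_mM = 1000, seed = 2,
                                         ion_interactions = FALSE))
  hf <- dwell_histogram(rf, bin_width = 2)
  inner <- hf$density[hf$z > -16 & hf$z < 16]
  expect_lt(stats::sd(inner) / mean(inner), 0.25)
  # single central well: unimodal at the origin
  wellp <- build_pmf_from_features(cbind(c(-18, 0, 18), c(0, -3, 0)), 0.1)
  rw <- simulate_permeation(quick_config(pmf = wellp, duration_ns = 300,
                                         voltage_mV = 0,
                                         concentration_mM = 500, seed = 4))
  hw <- dwell_histogram(rw, bin_width = 1)
  # centred, unimodal occupancy: mass concentrates around the well bottom
  expect_lt(abs(sum(hw$z * hw$density) / sum(hw$density)), 1.5)
  expect_gt(mean(hw$density[abs(hw$z) < 3]),
            3 * mean(hw$density[abs(hw$z) > 14]))
  # histogram density integrates to the mean occupancy
  expect_equal(sum(hw$density) * 1, rw$mean_occupancy[["K"]],
               tolerance = 0.02)
})

test_that("current-concentration scan handles the zero endpoint exactly", {
  cfg <- quick_config(duration_ns = 40)
  cc <- compute_current_concentration(cfg, c(0, 500), 200)
  expect_equal(cc$current_pA[1], 0)
  expect_equal(cc$se_pA[1], 0)
  expect_gt(cc$current_pA[2], 0)
  expect_error(compute_current_concentration(cfg, c(500, 100), 200), "sorted")
})

test_that("iv scan returns one row per voltage and propagates errors", {
  cfg <- quick_config(duration_ns = 40)
  iv <- compute_iv_curve(cfg, c(0, 200))
  expect_equal(iv$voltage_mV, c(0, 200))
  expect_true(all(is.finite(iv$current_pA)))
  expect_error(compute_iv_curve(cfg, 100), "at least 2")
})

test_that("configuration validation catches inconsistent inputs", {
  expect_error(sim_config(list(K = flat_pmf), list(chloride_ion())),
               "missing PMF for species: Cl")
  short <- pmf_profile(c(-5, 5), c(0, 0))
  expect_error(sim_config(list(K = short), list(potassium_ion())),
               "does not cover the pore span")
  expect_error(quick_config(timestep_ps = -1), "timestep_ps must be > 0")
  expect_error(quick_config(concentration_mM = -5), ">= 0")
  expect_error(ion_species("X", 1, 1e-9, pore_diffusion_factor = 2),
               "pore_diffusion_factor")
})

test_that("a drift-unstable timestep is rejected with advice", {
  steep <- build_pmf_from_features(cbind(c(-18, 0, 18), c(0, -60, 0)), 0.1)
  cfg <- quick_config(pmf = steep, timestep_ps = 20, duration_ns = 1,
                      equilibration_ns = 0, concentration_mM = 2000)
  expect_error(simulate_permeation(cfg), "reduce timestep")
})
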