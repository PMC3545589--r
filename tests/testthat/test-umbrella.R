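test_that("flat-profile window samples follow the analytic Gaussian", {
  flat <- build_pmf_from_features(NULL, 0.1, domain = c(-10, 10))
  w <- sample_umbrella_window(flat, center = 0, k = 10, n = 1e5, seed = 7)
  # sd = sqrt(kT / k) with kT = 0.61603 kcal/mol at 310 K
  sd_exp <- sqrt(kT_kcal_mol(310) / 10)
  expect_equal(sd(w$samples), sd_exp, tolerance = 0.03)
  expect_equal(mean(w$samples), 0, tolerance = 3 * sd_exp / sqrt(1e5) * 4)
})

test_that("a steep linear slope tilts the window mean by -slope/k", {
  slope <- 5  # kT/A
  ramp <- pmf_profile(seq(-10, 10, 0.1), slope * seq(-10, 10, 0.1),
                      zero_reference = FALSE)
  k <- 10  # kcal/mol/A^2
  w <- sample_umbrella_window(ramp, center = 0, k = k, n = 2e5, seed = 3)
  k_kT <- k / kT_kcal_mol(310)
  shift_exp <- -slope / k_kT
  expect_equal(mean(w$samples), shift_exp, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("sampler is deterministic per seed and validates inputs", {
  w1 <- sample_umbrella_window(k_pmf, 0, 10, 100, seed = 42)
  w2 <- sample_umbrella_window(k_pmf, 0, 10, 100, seed = 42)
  expect_identical(w1$samples, w2$samples)
  w3 <- sample_umbrella_window(k_pmf, 0, 10, 1, seed = 1)
  expect_length(w3$samples, 1)
  expect_true(is.finite(w3$samples) && abs(w3$samples) <= 18)
  expect_error(sample_umbrella_window(k_pmf, 0, -1, 10), "k must be > 0")
  expect_error(sample_umbrella_window(k_pmf, 99, 10, 10), "outside PMF grid")
})

test_that("biased samples pass a goodness-of-fit check against the analytic density", {
  g <- nanoporesim:::biased_density_grid(k_pmf, center = -9, k_kcal = 10)
  w <- sample_umbrella_window(k_pmf, center = -9, k = 10, n = 1e4, seed = 11)
  cdf <- stats::approxfun(g$z, g$cdf, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(w$samples, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("WHAM reconstructs a flat profile as flat", {
  flat <- build_pmf_from_features(NULL, 0.1, domain = c(-6, 6))
  centers <- seq(-5, 5, by = 0.5)  # protocol window spacing
  wins <- lapply(seq_along(centers), function(i)
    sample_umbrella_window(flat, centers[i], 10, 5000, seed = 100 + i))
  # a flat profile has no features to resolve: coarse bins, low noise
  res <- wham_reconstruct(wins, bin_width = 0.25)
  expect_true(res$converged)
  interior <- res$pmf$w[res$pmf$z >= -5 & res$pmf$z <= 5]
  expect_lt(diff(range(interior)), 0.2)
})

test_that("WHAM recovers the generating blocker PMF", {
  wins <- make_fixture("umbrella_set_c60f60", seed = 42, n_samples = 2000)
  res <- wham_reconstruct(wins, bin_width = 0.05)
  expect_true(res$converged)
  sel <- res$pmf$z >= 22 & res$pmf$z <= 35
  truth <- pmf_value(c60f60, res$pmf$z[sel])
  rmse <- sqrt(mean((res$pmf$w[sel] - truth)^2))
  expect_lt(rmse, 0.45)  # looser than the study-scale run (2,000 samples here)
})

test_that("WHAM is invariant to window order and stable under bin refinement", {
  wins <- make_fixture("umbrella_set_c60f60", seed = 7, n_samples = 1500)
  res <- wham_reconstruct(wins, bin_width = 0.05)
  resr <- wham_reconstruct(rev(wins), bin_width = 0.05)
  expect_equal(res$pmf$w, resr$pmf$w, tolerance = 1e-8)
  fine <- wham_reconstruct(wins, bin_width = 0.025)
  sel <- res$pmf$z > max(22.5, min(fine$pmf$z)) &
         res$pmf$z < min(34.5, max(fine$pmf$z))
  on_common <- pmf_value(fine$pmf, res$pmf$z[sel])
  expect_lt(stats::median(abs(on_common - res$pmf$w[sel])), 0.1)
})

test_that("disjoint window coverage is rejected with the gap named", {
  flat <- build_pmf_from_features(NULL, 0.1, domain = c(-10, 10))
  w1 <- sample_umbrella_window(flat, -8, 10, 500, seed = 1)
  w2 <- sample_umbrella_window(flat, 8, 10, 500, seed = 2)
  expect_error(wham_reconstruct(list(w1, w2), bin_width = 0.25),
               "disjoint window coverage")
  expect_error(wham_reconstruct(list(w1), bin_width = 0.25), "at least 2")
  w0 <- umbrella_window(0, 10, numeric(0))
  expect_error(wham_reconstruct(list(w1, w0), 0.25), "needs samples")
})

test_that("umbrella window files round-trip through disk", {
  dir <- withr::local_tempdir()
  wins <- make_fixture("umbrella_set_c60f60", seed = 5, outdir = dir,
                       n_samples = 50)
  files <- list.files(dir, pattern = "^window_", full.names = TRUE)
  expect_length(files, 27)
  back <- read_umbrella_window(files[1])
  expect_equal(back$center_z, wins[[1]]$center_z)
  expect_equal(back$force_constant, wins[[1]]$force_constant)
  expect_equal(back$samples, signif(wins[[1]]$samples, 9), tolerance = 1e-8)
})
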