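test_that("profile construction validates its invariants", {
  expect_error(pmf_profile(1, 0), "at least 2")
  expect_error(pmf_profile(c(0, 1), c(0, 1, 2)), "same length")
  expect_error(pmf_profile(c(0, 1, 1), c(0, 0, 0)), "strictly increasing")
  expect_error(pmf_profile(c(0, 1), c(0, NA)), "finite")
  p <- pmf_profile(c(0, 1, 2), c(5, 4, 3))
  expect_equal(p$w[length(p$w)], 0)  # zero-referenced at bulk (right) end
})

test_that("zero-referencing is idempotent and exact at the bulk end", {
  p <- pmf_profile(seq(-18, 18), sin(seq(-18, 18) / 5) + 2)
  p2 <- zero_reference_pmf(p)
  expect_identical(p2$w, p$w)
  expect_lt(abs(p2$w[length(p2$w)]), 1e-9)
  pl <- pmf_profile(0:5, c(3, 2, 1, 0.5, 0.2, 0.1), bulk = "left")
  expect_lt(abs(pl$w[1]), 1e-9)
})

test_that("anchor-built profiles pass through every anchor without overshoot", {
  cases <- list(
    k = cbind(c(-18, -9, 0, 9, 18), c(0, -3, -0.8, -3, 0)),
    c60f60 = cbind(c(22, 23, 24.5, 25.5, 35), c(-7, -25.6, -7.3, -9, 0)),
    ramp = cbind(c(0, 5, 10), c(-10, -5, 0)))
  for (nm in names(cases)) {
    a <- cases[[nm]]
    p <- build_pmf_from_features(a, grid_step = 0.05)
    expect_equal(pmf_value(p, a[, 1]), a[, 2], tolerance = 1e-6,
                 ignore_attr = TRUE)
    # shape preservation: the curve stays within each anchor pair's range
    for (i in seq_len(nrow(a) - 1)) {
      zz <- seq(a[i, 1], a[i + 1, 1], length.out = 101)
      lims <- range(a[i, 2], a[i + 1, 2])
      expect_true(all(pmf_value(p, zz) >= lims[1] - 0.1))
      expect_true(all(pmf_value(p, zz) <= lims[2] + 0.1))
    }
  }
})

test_that("the potassium fixture has 3 kT wells at +/-9 A under a 2.2 kT barrier", {
  expect_equal(pmf_value(k_pmf, -9), -3, ignore_attr = TRUE)
  expect_equal(pmf_value(k_pmf, 9), -3, ignore_attr = TRUE)
  expect_equal(pmf_value(k_pmf, 0), -0.8, ignore_attr = TRUE)
  expect_equal(min(k_pmf$w), -3)
})

test_that("empty anchor list gives the identity (flat) profile", {
  p <- build_pmf_from_features(NULL, 0.5, domain = c(-18, 18))
  expect_true(all(p$w == 0))
  expect_equal(range(p$z), c(-18, 18))
})

test_that("anchor validation rejects duplicates and out-of-domain points", {
  expect_error(build_pmf_from_features(cbind(c(0, 0, 1), c(1, 2, 3))),
               "duplicate anchor z coordinate at z = 0")
  expect_error(
    build_pmf_from_features(cbind(c(0, 5), c(0, 1)), domain = c(0, 4)),
    "z = 5.*outside the domain")
})

test_that("grid refinement leaves the interpolated curve essentially unchanged", {
  for (fx in list(k_pmf, c60f60)) {
    a <- attr(fx, "anchors")
    coarse <- build_pmf_from_features(a, grid_step = 0.1)
    fine <- build_pmf_from_features(a, grid_step = 0.05)
    zz <- seq(min(a[, 1]), max(a[, 1]), length.out = 301)
    expect_lt(max(abs(pmf_value(coarse, zz) - pmf_value(fine, zz))), 0.05)
  }
})

test_that("mean force matches closed forms and central finite differences", {
  flat <- build_pmf_from_features(NULL, 0.5, domain = c(0, 10))
  expect_equal(pmf_derivative(flat, c(1, 5, 9)), c(0, 0, 0))
  ramp <- pmf_profile(0:10, 0:10, zero_reference = FALSE)
  expect_equal(pmf_derivative(ramp, seq(0.5, 9.5, by = 1)),
               rep(-1, 10), tolerance = 1e-9)
  # derivative vanishes at an anchored minimum
  expect_lt(abs(pmf_derivative(k_pmf, -9)), 1e-6)
  # interior agreement with central finite differences on a smooth profile
  zz <- seq(-15, 15, by = 0.7)
  h <- 1e-4
  fd <- -(pmf_value(k_pmf, zz + h) - pmf_value(k_pmf, zz - h)) / (2 * h)
  expect_equal(pmf_derivative(k_pmf, zz), fd, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_error(pmf_derivative(k_pmf, 30), "outside PMF grid range")
})

test_that("PMF text files round-trip bit-identically", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_pmf(k_pmf, path)
  back <- read_pmf(path)
  expect_identical(signif(back$z, 9), signif(k_pmf$z, 9))
  expect_identical(signif(back$w, 9), signif(k_pmf$w, 9))
  expect_equal(back$temperature_K, k_pmf$temperature_K)
  expect_equal(back$label, k_pmf$label)
  # a second round trip is exactly stable
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_pmf(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("PMF parser reports offending line numbers", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# label: bad", "0 0", "2 1", "1 2"), path)
  expect_error(read_pmf(path), "line 4.*not strictly increasing")
  writeLines(c("0 0", "1 x"), path)
  expect_error(read_pmf(path), "line 2.*non-numeric")
  writeLines(c("# only a comment", "3 0.5"), path)
  expect_error(read_pmf(path), "fewer than 2 data rows")
})

test_that("the shipped example profile parses with its comments as label", {
  path <- system.file("extdata", "k_pmf_synthetic.txt",
                      package = "nanoporesim")
  p <- read_pmf(path)
  expect_match(p$label, "synthetic K\\+ axial PMF")
  expect_equal(pmf_value(p, c(-9, 9)), c(-3, -3), ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(p$temperature_K, 310)
})

test_that("comment-only preamble is preserved as the profile label", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# axial profile from a legacy run", "# second note",
               "0 0", "1 -1", "2 0"), path)
  p <- read_pmf(path)
  expect_equal(p$label, "axial profile from a legacy run")
  expect_length(attr(p, "comments"), 2)
})
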