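## Synthetic umbrella-sampling windows and WHAM reconstruction.
##
## Bias convention: the harmonic window restraint contributes
## 0.5 * k * (z - center)^2 with k in kcal/mol/A^2. The sampler and the WHAM
## reconstruction share this convention, so parameter-recovery tests are
## insensitive to the choice.

#' Create an umbrella window object
#'
#' @param center_z restraint centre in angstrom.
#' @param force_constant harmonic force constant in kcal/mol/A^2
#'   (bias energy = 0.5 k (z - center)^2).
#' @param samples reaction-coordinate draws in angstrom.
#' @param temperature_K temperature of the sampling.
#' @return an object of class `umbrella_window`.
#' @export
umbrella_window <- function(center_z, force_constant, samples,
                            temperature_K = 310) {
  if (!is.finite(force_constant) || force_constant <= 0)
    stop("force_constant must be > 0")
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples)))
    stop("samples must all be finite")
  structure(list(center_z = center_z, force_constant = force_constant,
                 samples = samples, temperature_K = temperature_K),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window> center %.2f A, k = %g kcal/mol/A^2, %d samples\n",
              x$center_z, x$force_constant, length(x$samples)))
  invisible(x)
}

## Biased density exp(-w(z) - 0.5 k (z-c)^2 / kT) evaluated on a fine grid.
## The grid extends past the PMF domain (6 bias standard deviations around
## the window centre, with the PMF held at its edge values) so that edge
## windows are not artificially truncated -- clipped windows would bias a
## subsequent WHAM reconstruction near the domain ends.
## Returns list(z, pdf, cdf); shared by the sampler and its tests.
biased_density_grid <- function(pmf, center, k_kcal, n_grid = 20001L) {
  kk <- force_constant_kT(k_kcal, pmf$temperature_K)
  span <- 6 / sqrt(kk)
  z <- seq(min(min(pmf$z), center - span), max(max(pmf$z), center + span),
           length.out = n_grid)
  zc <- pmin(pmax(z, min(pmf$z)), max(pmf$z))
  logp <- -pmf_interpolant(pmf)(zc) - 0.5 * kk * (z - center)^2
  logp <- logp - max(logp)
  p <- exp(logp)
  dz <- z[2] - z[1]
  cdf <- c(0, cumsum((p[-1] + p[-length(p)]) / 2 * dz))
  list(z = z, pdf = p / cdf[length(cdf)], cdf = cdf / cdf[length(cdf)])
}

#' Draw biased samples for one umbrella window
#'
#' Samples the reaction coordinate from the biased Boltzmann density
#' proportional to `exp(-w(z) - 0.5 k (z - center)^2 / kT)` by inverse-CDF
#' lookup on a fine grid, emulating the configurational distribution an
#' equilibrated restrained simulation would visit. Draws are i.i.d. (the
#' autocorrelation of a real trajectory is not modelled) and deterministic
#' under a fixed seed.
#'
#' @param pmf generating [pmf_profile()].
#' @param center restraint centre (angstrom); must lie within the PMF grid.
#' @param k force constant in kcal/mol/A^2 (> 0); the protocol value is 10.
#' @param n number of draws (>= 1).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return an [umbrella_window()].
#' @export
sample_umbrella_window <- function(pmf, center, k = 10, n, seed = 1L) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (!is.finite(k) || k <= 0) stop("force constant k must be > 0")
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  rng <- range(pmf$z)
  if (center < rng[1] || center > rng[2])
    stop(sprintf("window center %g A outside PMF grid [%g, %g]",
                 center, rng[1], rng[2]))
  g <- biased_density_grid(pmf, center, k)
  u <- withr::with_seed(seed, stats::runif(n))
  draws <- stats::approx(g$cdf, g$z, xout = u, ties = "ordered")$y
  umbrella_window(center, k, draws, pmf$temperature_K)
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' Standard self-consistent weighted-histogram iteration: histogram all
#' window samples on a common grid, then alternate between the unbiased bin
#' densities and the per-window free-energy shifts until the shifts change
#' by less than `tol` (in kT). The reconstructed profile is defined up to an
#' additive constant and is zero-referenced at the bulk end.
#'
#' @param windows list of [umbrella_window()] objects (>= 2, overlapping
#'   coverage).
#' @param bin_width histogram bin width in angstrom.
#' @param tol convergence tolerance on the per-window shifts, kT.
#' @param max_iter iteration cap; if reached the result is returned with
#'   `converged = FALSE`.
#' @param bulk which end of the reconstructed profile is bulk.
#' @param min_bin_count histogram bins holding fewer total samples than this
#'   (or than 0.5% of the best-sampled bin) are dropped from the profile:
#'   their free-energy estimates are dominated by counting noise.
#' @param bulk_ref_width_A the zero reference is the count-weighted mean
#'   free energy over this much of the bulk end of the retained range,
#'   rather than the single (noisiest) edge bin.
#' @return an object of class `wham_result` with fields `pmf`
#'   ([pmf_profile()] at occupied bin centres), `free_energy_shifts` (kT,
#'   first window = 0), `iterations`, `converged`, `bin_edges`.
#' @export
wham_reconstruct <- function(windows, bin_width = 0.05, tol = 1e-6,
                             max_iter = 1e5, bulk = c("right", "left"),
                             min_bin_count = 5, bulk_ref_width_A = 1) {
  bulk <- match.arg(bulk)
  if (length(windows) < 2L) stop("need at least 2 umbrella windows")
  if (!all(vapply(windows, inherits, logical(1), "umbrella_window")))
    stop("windows must be umbrella_window objects")
  if (bin_width <= 0) stop("bin_width must be > 0")
  ns <- vapply(windows, function(w) length(w$samples), integer(1))
  if (any(ns == 0L)) stop("every window needs samples for reconstruction")
  temperature <- windows[[1]]$temperature_K

  all_s <- unlist(lapply(windows, `[[`, "samples"))
  lo <- min(all_s); hi <- max(all_s)
  edges <- seq(lo - 1e-9, hi + bin_width, by = bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(centers)

  ## per-window histograms: nw x nb
  H <- t(vapply(windows, function(w) {
    as.numeric(graphics::hist(w$samples, breaks = edges, plot = FALSE)$counts)
  }, numeric(nb)))
  Htot <- colSums(H)

  ## coverage gap check on the well-sampled bins: a span wider than a
  ## quarter angstrom between them means the windows do not overlap;
  ## sparse single bins in the sampling tails are not coverage failures
  keep_mask <- Htot >= max(min_bin_count, 0.005 * max(Htot))
  occ <- which(keep_mask)
  gaps <- which(diff(occ) > 1L)
  for (g in gaps) {
    span <- edges[occ[g + 1]] - edges[occ[g] + 1]
    if (span > max(0.25, 2 * bin_width))
      stop(sprintf("disjoint window coverage: no samples in [%.3g, %.3g] A",
                   edges[occ[g] + 1], edges[occ[g + 1]]))
  }

  ## bin-averaged Boltzmann factor of each window's bias: the harmonic bias
  ## varies steeply across a bin far from the window centre, so the exact
  ## Gaussian bin integral is used instead of the bin-centre value
  C <- t(vapply(windows, function(w) {
    kk <- force_constant_kT(w$force_constant, temperature)
    s <- sqrt(1 / kk)
    lo <- edges[-length(edges)]; hi <- edges[-1]
    sqrt(2 * pi) * s *
      (stats::pnorm((hi - w$center_z) / s) - stats::pnorm((lo - w$center_z) / s)) /
      (hi - lo)
  }, numeric(nb)))              # nw x nb
  N <- as.numeric(ns)

  f <- numeric(length(windows)) # dimensionless shifts
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- colSums(N * exp(f) * C)       # nw recycled over rows? see below
    ## colSums(N * exp(f) * C): N*exp(f) is length-nw, recycles down columns
    rho <- ifelse(denom > 0, Htot / denom, 0)
    fnew <- -log(pmax(C %*% (rho * bin_width), .Machine$double.xmin))
    fnew <- as.numeric(fnew) - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) { converged <- TRUE; break }
  }
  denom <- colSums(N * exp(f) * C)
  rho <- ifelse(denom > 0, Htot / denom, 0)

  keep <- which(rho > 0 & keep_mask)
  w_kT <- -log(rho[keep])
  ## zero-reference against a count-weighted bulk window, not one edge bin
  zk <- centers[keep]
  ref_sel <- if (bulk == "right") zk >= max(zk) - bulk_ref_width_A
             else zk <= min(zk) + bulk_ref_width_A
  w_kT <- w_kT - stats::weighted.mean(w_kT[ref_sel], Htot[keep][ref_sel])
  prof <- pmf_profile(zk, w_kT, temperature,
                      label = "WHAM reconstruction", bulk = bulk,
                      zero_reference = FALSE)
  structure(list(pmf = prof, free_energy_shifts = f, iterations = iter,
                 converged = converged, bin_edges = edges),
            class = "wham_result")
}

#' @export
print.wham_result <- function(x, ...) {
  cat(sprintf("<wham_result> %d bins, %d windows, %d iterations, converged: %s\n",
              length(x$pmf$z), length(x$free_energy_shifts), x$iterations,
              x$converged))
  invisible(x)
}
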