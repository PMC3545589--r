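## Dissociation constants and blocker statistics from a 1D unbinding PMF.
##
## Kd^-1 = 1000 * N_A * pi * R^2 * integral_{z1}^{z2} exp(-W(z)/kT) dz
## with R the radius of the flat-bottom cylinder that restrained the blocker
## during sampling, z1 in the binding pocket and z2 in bulk where the PMF
## vanishes. Lengths enter the integral in metres; energies are in kT so the
## Boltzmann factor is exp(-w).

#' Define a PMF-based binding model
#'
#' @param pmf unbinding [pmf_profile()] along the channel axis, zero in bulk.
#' @param restraint_radius_A radius (angstrom) of the cylindrical restraint
#'   that confined the blocker during sampling; enters the dissociation
#'   integral as pi R^2. Default 8 A (interpreted as a radius).
#' @param z1 lower integration bound, in the binding pocket; default: global
#'   minimum position minus 2 A, clamped to the grid. Deep wells make Kd
#'   insensitive to this choice.
#' @param z2 upper bound, in bulk where the PMF vanishes; default: the bulk
#'   end of the grid.
#' @return object of class `binding_model`; field `zero_point_violation` is
#'   TRUE (with a warning) when |w(z2)| >= 0.1 kT.
#' @export
binding_model <- function(pmf, restraint_radius_A = 8, z1 = NULL, z2 = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (!is.finite(restraint_radius_A) || restraint_radius_A <= 0)
    stop("restraint_radius_A must be > 0")
  zmin_pos <- pmf$z[which.min(pmf$w)]
  if (is.null(z2)) z2 <- if (pmf$bulk == "right") max(pmf$z) else min(pmf$z)
  if (is.null(z1)) z1 <- max(min(pmf$z), zmin_pos - 2)
  if (z1 >= z2) stop("empty integration range: z1 must be < z2")
  rng <- range(pmf$z)
  if (z1 < rng[1] || z2 > rng[2])
    stop(sprintf("integration bounds outside PMF grid [%g, %g]", rng[1], rng[2]))
  wz2 <- pmf_value(pmf, z2)
  viol <- abs(wz2) >= 0.1
  if (viol)
    warning(sprintf("PMF at z2 = %g A is %.3g kT, not ~0: zero-point violation",
                    z2, wz2))
  structure(list(pmf = pmf, restraint_radius_A = restraint_radius_A,
                 z1 = z1, z2 = z2, zero_point_violation = viol),
            class = "binding_model")
}

## Adaptive trapezoid of exp(-w(z)) over [z1, z2] (z in angstrom).
## Doubles resolution until the Richardson estimate of the relative error
## drops below rel_tol. Returns the integral in angstrom units.
boltzmann_integral_A <- function(pmf, z1, z2, rel_tol = 1e-4) {
  f <- pmf_interpolant(pmf)
  trap <- function(n) {
    z <- seq(z1, z2, length.out = n)
    y <- exp(-f(z))
    sum((y[-1] + y[-n]) * diff(z) / 2)
  }
  n <- 2049L
  prev <- trap(n)
  repeat {
    n <- 2L * (n - 1L) + 1L
    cur <- trap(n)
    if (abs(cur - prev) <= rel_tol * abs(cur) || n > 2^21) break
    prev <- cur
  }
  cur
}

#' Dissociation constant from a 1D PMF
#'
#' Evaluates `Kd^-1 = 1000 N_A pi R^2 integral exp(-w) dz` (R and z in
#' metres) by adaptive trapezoid quadrature with a Richardson check, so the
#' quadrature error is below 0.1%.
#'
#' @param model a [binding_model()].
#' @return dissociation constant in molar, with attributes
#'   `kd_inverse_per_molar` and `integral_A` (the Boltzmann integral in
#'   angstrom).
#' @examples
#' flat <- build_pmf_from_features(NULL, 0.5, domain = c(0, 10))
#' kd_from_pmf(binding_model(flat, 8, z1 = 0, z2 = 10))  # ~0.826 M
#' @export
kd_from_pmf <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  I_A <- boltzmann_integral_A(model$pmf, model$z1, model$z2)
  R_m <- model$restraint_radius_A * .angstrom_m
  kd_inv <- 1000 * .N_avogadro * pi * R_m^2 * (I_A * .angstrom_m)
  kd <- 1 / kd_inv
  attr(kd, "kd_inverse_per_molar") <- kd_inv
  attr(kd, "integral_A") <- I_A
  kd
}

## Interior local maxima of the PMF between the global minimum and the bulk
## end; returns list(escape_w, escape_z, has_barrier).
escape_point <- function(pmf) {
  zmin_i <- which.min(pmf$w)
  idx <- if (pmf$bulk == "right") zmin_i:length(pmf$z) else seq_len(zmin_i)
  z <- pmf$z[idx]; w <- pmf$w[idx]
  if (pmf$bulk == "left") { z <- rev(z); w <- rev(w) }
  ## strict interior local maxima along the escape path
  n <- length(w)
  locmax <- which(diff(sign(diff(w))) < 0) + 1L
  locmax <- locmax[locmax > 1L & locmax < n]
  if (length(locmax)) {
    i <- locmax[which.max(w[locmax])]
    list(escape_w = w[i], escape_z = z[i], has_barrier = TRUE)
  } else {
    ## no interior barrier: escape over the bulk-end value
    list(escape_w = w[n], escape_z = z[n], has_barrier = w[n] > w[1])
  }
}

#' Spontaneous opening probability of a blocked pore
#'
#' Boltzmann escape factor `exp(-dW_escape)` where `dW_escape` is the height
#' of the confining barrier between the bound-state minimum and bulk: the
#' highest interior barrier along the escape path, or the bulk-end value when
#' the profile rises monotonically. This is an equilibrium interpretation of
#' how rarely a blocked channel is found open; a flat or monotonically
#' decreasing profile gives probability 1 with `has_barrier = FALSE`.
#'
#' @param model a [binding_model()].
#' @return probability in (0, 1], with attributes `escape_barrier_kT`,
#'   `escape_z_A` and `has_barrier`.
#' @export
open_probability <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  pmf <- model$pmf
  esc <- escape_point(pmf)
  dw <- esc$escape_w - min(pmf$w)
  p <- if (dw <= 0) 1 else exp(-dw)
  attr(p, "escape_barrier_kT") <- max(dw, 0)
  attr(p, "escape_z_A") <- esc$escape_z
  attr(p, "has_barrier") <- esc$has_barrier && dw > 0
  p
}

#' Maximum restoring force of the binding well
#'
#' The largest magnitude of the PMF slope `|dW/dz|` along the escape path
#' from the bound minimum to bulk, converted to newtons
#' (1 kT/A = kT[J] / 1e-10 m). A flat profile returns 0 with
#' `has_barrier = FALSE`.
#'
#' @param model a [binding_model()].
#' @return force in newtons, with attributes `max_slope_kT_per_A` and
#'   `at_z_A`.
#' @export
binding_force <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  pmf <- model$pmf
  zmin_pos <- pmf$z[which.min(pmf$w)]
  zb <- if (pmf$bulk == "right") max(pmf$z) else min(pmf$z)
  zz <- seq(min(zmin_pos, zb), max(zmin_pos, zb), length.out = 4001L)
  slope <- -pmf_derivative(pmf, zz)      # dW/dz in kT/A
  i <- which.max(abs(slope))
  f_N <- abs(slope[i]) * kT_joules(pmf$temperature_K) / .angstrom_m
  attr(f_N, "max_slope_kT_per_A") <- slope[i]
  attr(f_N, "at_z_A") <- zz[i]
  attr(f_N, "has_barrier") <- abs(slope[i]) > 0
  f_N
}

#' Full binding report for a blocker
#'
#' Aggregates the dissociation constant, well depth, escape barrier,
#' spontaneous opening probability and maximum restoring force for one
#' blocker-unbinding PMF.
#'
#' @param model a [binding_model()].
#' @return object of class `binding_report` with fields `kd_molar`,
#'   `well_depth_kT`, `escape_barrier_kT`, `open_probability`,
#'   `max_restoring_force_N`, `zero_point_violation`.
#' @export
binding_report <- function(model) {
  stopifnot(inherits(model, "binding_model"))
  kd <- kd_from_pmf(model)
  p <- open_probability(model)
  f <- binding_force(model)
  structure(list(
    label = model$pmf$label,
    kd_molar = as.numeric(kd),
    well_depth_kT = -min(model$pmf$w),
    escape_barrier_kT = attr(p, "escape_barrier_kT"),
    open_probability = as.numeric(p),
    max_restoring_force_N = as.numeric(f),
    zero_point_violation = model$zero_point_violation),
    class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  cat(sprintf("<binding_report> %s\n", if (nzchar(x$label)) x$label else ""))
  cat(sprintf("  Kd: %.3g M | well depth: %.3g kT | escape barrier: %.3g kT\n",
              x$kd_molar, x$well_depth_kT, x$escape_barrier_kT))
  cat(sprintf("  open probability: %.3g | max restoring force: %.3g N\n",
              x$open_probability, x$max_restoring_force_N))
  if (x$zero_point_violation)
    cat("  warning: PMF does not vanish at z2 (zero-point violation)\n")
  invisible(x)
}
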