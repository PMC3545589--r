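## Sensor-level feasibility arithmetic: Stokes drag on the reporter bead,
## drag vs. binding-force comparison, current/flux conversion and
## channel-density scaling against the gramicidin-based reference device.

#' Define the device model
#'
#' @param bead_radius_m radius of the polymer reporter bead (default 15 nm).
#' @param viscosity_Pa_s dynamic viscosity of the carrier fluid. Default
#'   1.0e-3 Pa s (nominal water); water at 310 K is closer to 0.69e-3 and is
#'   selectable. The choice is echoed in the report.
#' @param flow_speed_m_s flow speed past the bead. The default 4.24e-4 m/s
#'   is the speed at which a 15 nm bead in 1.0e-3 Pa s fluid experiences a
#'   1.2e-13 N Stokes drag (back-derived; the conversion from an injection
#'   rate to a speed depends on the unspecified chamber cross-section).
#' @param pore_density_per_cm2 nanotube channels per cm^2 (default 2.5e11).
#' @param reference_current_pA single-channel current of the reference
#'   device at 200 mV (default 4 pA, gramicidin-A).
#' @param reference_flux_per_s reference single-channel ion flux
#'   (default 2.5e7 ions/s).
#' @return object of class `device_model`.
#' @export
device_model <- function(bead_radius_m = 15e-9, viscosity_Pa_s = 1.0e-3,
                         flow_speed_m_s = 4.24e-4,
                         pore_density_per_cm2 = 2.5e11,
                         reference_current_pA = 4,
                         reference_flux_per_s = 2.5e7) {
  vals <- c(bead_radius_m, viscosity_Pa_s, flow_speed_m_s,
            pore_density_per_cm2, reference_current_pA, reference_flux_per_s)
  if (any(!is.finite(vals)) || any(vals[-3] <= 0) || flow_speed_m_s < 0)
    stop("all device parameters must be positive (flow speed may be 0)")
  structure(list(bead_radius_m = bead_radius_m,
                 viscosity_Pa_s = viscosity_Pa_s,
                 flow_speed_m_s = flow_speed_m_s,
                 pore_density_per_cm2 = pore_density_per_cm2,
                 reference_current_pA = reference_current_pA,
                 reference_flux_per_s = reference_flux_per_s),
            class = "device_model")
}

#' Stokes drag on the reporter bead
#'
#' Laminar-flow drag on a sphere, `F_D = 6 pi mu a U`.
#'
#' @param model a [device_model()].
#' @return drag force in newtons.
#' @export
stokes_drag <- function(model) {
  stopifnot(inherits(model, "device_model"))
  6 * pi * model$viscosity_Pa_s * model$bead_radius_m * model$flow_speed_m_s
}

#' Convert a single-channel current to an ion flux
#'
#' For a monovalent carrier, flux = I / e.
#'
#' @param current_pA current in pA (>= 0).
#' @return ions per second.
#' @examples
#' current_to_flux(82)  # ~5.1e8 ions/s
#' @export
current_to_flux <- function(current_pA) {
  if (any(current_pA < 0)) stop("current must be >= 0")
  current_pA * 1e-12 / .e_coulomb
}

#' Convert an ion flux to a single-channel current
#'
#' Inverse of [current_to_flux()]; round-trips to round-off.
#'
#' @param flux_per_s ions per second (>= 0).
#' @return current in pA.
#' @export
flux_to_current <- function(flux_per_s) {
  if (any(flux_per_s < 0)) stop("flux must be >= 0")
  flux_per_s * .e_coulomb * 1e12
}

#' Channel count on a membrane patch
#'
#' `count = density x area` with 1 cm^2 = 1e8 um^2.
#'
#' @param pore_density_per_cm2 channels per cm^2.
#' @param area_um2 membrane area in um^2.
#' @return integer (floored) count, with the exact real value as attribute
#'   `exact`.
#' @examples
#' channel_count(2.5e11, 1)    # 2500 channels in 1 um^2
#' channel_count(2.5e11, 1e8)  # 2.5e11 sites in 1 cm^2
#' @export
channel_count <- function(pore_density_per_cm2, area_um2) {
  if (pore_density_per_cm2 < 0 || area_um2 < 0) stop("inputs must be >= 0")
  exact <- pore_density_per_cm2 * area_um2 / 1e8
  out <- floor(exact)
  attr(out, "exact") <- exact
  out
}

#' Device feasibility report
#'
#' Compares the drag force available to strip the blocker against the
#' blocker's binding force, the single-channel current against the reference
#' device, and tabulates recognition-site counts at the requested membrane
#' areas. The binding force carries two estimates side by side: the maximum
#' restoring force computed from the PMF slope, and an externally supplied
#' literature value when given.
#'
#' @param model a [device_model()].
#' @param binding a [binding_report()] for the blocker.
#' @param channel_current_pA open single-channel current of the nanotube.
#' @param areas_um2 membrane areas to report channel counts for.
#' @param literature_binding_force_N optional reference value for the
#'   binding force to report alongside the slope-based estimate.
#' @return object of class `feasibility_report`; printable, and
#'   serializable with `jsonlite::toJSON(unclass(x))`.
#' @export
feasibility_report <- function(model, binding, channel_current_pA,
                               areas_um2 = c(1, 1e8),
                               literature_binding_force_N = NULL) {
  stopifnot(inherits(model, "device_model"), inherits(binding, "binding_report"))
  drag <- stokes_drag(model)
  fold <- channel_current_pA / model$reference_current_pA
  counts <- vapply(areas_um2, function(a)
    attr(channel_count(model$pore_density_per_cm2, a), "exact"), numeric(1))
  out <- list(
    drag_force_N = drag,
    binding_force_slope_N = binding$max_restoring_force_N,
    binding_force_literature_N = literature_binding_force_N,
    drag_to_binding_ratio = drag / binding$max_restoring_force_N,
    drag_exceeds_binding = drag > binding$max_restoring_force_N,
    channel_current_pA = channel_current_pA,
    reference_current_pA = model$reference_current_pA,
    current_fold_change = fold,
    current_fold_change_2sf = signif(fold, 2),
    channel_flux_per_s = current_to_flux(channel_current_pA),
    reference_flux_per_s = model$reference_flux_per_s,
    flux_fold_change = current_to_flux(channel_current_pA) / model$reference_flux_per_s,
    channel_counts = data.frame(area_um2 = areas_um2, channels = counts),
    blocker_kd_molar = binding$kd_molar,
    blocker_open_probability = binding$open_probability,
    viscosity_Pa_s = model$viscosity_Pa_s,
    flow_speed_m_s = model$flow_speed_m_s)
  structure(out, class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat("<feasibility_report>\n")
  cat(sprintf("  drag force: %.3g N (mu = %.3g Pa s, U = %.3g m/s)\n",
              x$drag_force_N, x$viscosity_Pa_s, x$flow_speed_m_s))
  cat(sprintf("  binding force (PMF slope): %.3g N%s\n",
              x$binding_force_slope_N,
              if (!is.null(x$binding_force_literature_N))
                sprintf(" | literature: %.3g N", x$binding_force_literature_N)
              else ""))
  cat(sprintf("  drag/binding ratio: %.3g -> blocker release %s\n",
              x$drag_to_binding_ratio,
              if (x$drag_exceeds_binding) "FEASIBLE" else "NOT feasible"))
  cat(sprintf("  current: %.3g pA vs reference %.3g pA (fold change %.3g, ~%g)\n",
              x$channel_current_pA, x$reference_current_pA,
              x$current_fold_change, x$current_fold_change_2sf))
  for (i in seq_len(nrow(x$channel_counts)))
    cat(sprintf("  %g um^2 -> %.4g channels\n",
                x$channel_counts$area_um2[i], x$channel_counts$channels[i]))
  invisible(x)
}
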