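## Quasi-1D stochastic permeation engine and its steady-state cross-check.
##
## Ions move on the channel axis under the PMF mean force, the applied field
## (linear potential drop across the pore span; reservoirs equipotential) and
## pairwise axial Coulomb forces screened by the local dielectric.
## Reservoirs are concentration-clamped slabs. Dynamics are overdamped
## Langevin with a position-dependent diffusion coefficient (bulk value
## outside the pore, a reduced value inside, smoothly tapered at the mouths).

#' Define an ion species
#'
#' @param name species label, e.g. "K" or "Cl".
#' @param valence integer charge in units of e.
#' @param bulk_diffusion bulk diffusion coefficient in m^2/s (K+ 1.96e-9,
#'   Cl- 2.03e-9).
#' @param pore_diffusion_factor dimensionless scaling of the diffusion
#'   coefficient inside the pore (0 < factor <= 1, default 0.5).
#' @return object of class `ion_species`.
#' @export
ion_species <- function(name, valence, bulk_diffusion,
                        pore_diffusion_factor = 0.5) {
  if (!is.finite(bulk_diffusion) || bulk_diffusion <= 0)
    stop("bulk_diffusion must be > 0")
  if (!is.finite(pore_diffusion_factor) || pore_diffusion_factor <= 0 ||
      pore_diffusion_factor > 1)
    stop("pore_diffusion_factor must be in (0, 1]")
  if (valence != round(valence)) stop("valence must be an integer")
  structure(list(name = name, valence = as.integer(valence),
                 bulk_diffusion = bulk_diffusion,
                 pore_diffusion_factor = pore_diffusion_factor),
            class = "ion_species")
}

#' Default potassium ion parameters
#' @param pore_diffusion_factor see [ion_species()].
#' @return an `ion_species`.
#' @export
potassium_ion <- function(pore_diffusion_factor = 0.5)
  ion_species("K", 1L, 1.96e-9, pore_diffusion_factor)

#' Default chloride ion parameters
#' @param pore_diffusion_factor see [ion_species()].
#' @return an `ion_species`.
#' @export
chloride_ion <- function(pore_diffusion_factor = 0.5)
  ion_species("Cl", -1L, 2.03e-9, pore_diffusion_factor)

#' Configure a permeation simulation
#'
#' @param pmfs named list of [pmf_profile()], one per species (names must
#'   match the species names); each PMF must cover the pore span.
#' @param species list of [ion_species()] (default: potassium only).
#' @param voltage_mV applied potential; positive values hold the left
#'   reservoir at the higher potential, and positive current is cation flow
#'   from the high- to the low-potential reservoir.
#' @param concentration_mM length-2 vector (left, right) or single symmetric
#'   value, in mM.
#' @param timestep_ps integration step (default 0.01 ps = 10 fs).
#' @param duration_ns simulated time per replicate after equilibration.
#' @param equilibration_ns discarded initial time per replicate.
#' @param n_replicates independent replicates (default 5).
#' @param seed integer; replicate seeds are derived from it.
#' @param pore_span length-2, pore region along z in angstrom.
#' @param pore_radius_A effective pore radius (default 4.53).
#' @param reservoir_length_A length of each clamped reservoir slab.
#' @param dielectric_pore,dielectric_reservoir relative permittivities used
#'   for ion-ion Coulomb forces inside / outside the pore (60 and 80).
#' @param dielectric_membrane relative permittivity of the membrane region
#'   (recorded metadata; induced-charge effects are not modelled).
#' @param ion_interactions logical; `FALSE` switches off ion-ion forces
#'   (independent-ion regime, current exactly linear in concentration).
#' @param min_interaction_distance_A Coulomb clamp distance (default 2).
#' @param diffusion_taper_A width of the smooth bulk-to-pore diffusion
#'   transition inside each pore mouth (default 2).
#' @param clamp_displacement_factor the clamped bath extends this multiple of
#'   `sqrt(D_bulk * dt)` past each pore face, compensating the boundary-layer
#'   displacement of the discrete-time concentration clamp (calibrated
#'   against the analytic flat-channel flux; see the vignette).
#' @param temperature_K simulation temperature.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(pmfs, species = list(potassium_ion()),
                       voltage_mV = 0, concentration_mM = 500,
                       timestep_ps = 0.01, duration_ns = 100,
                       equilibration_ns = 2, n_replicates = 5, seed = 1,
                       pore_span = c(-18, 18), pore_radius_A = 4.53,
                       reservoir_length_A = 30,
                       dielectric_pore = 60, dielectric_reservoir = 80,
                       dielectric_membrane = 2,
                       ion_interactions = TRUE,
                       min_interaction_distance_A = 2,
                       diffusion_taper_A = 2,
                       clamp_displacement_factor = 0.8258,
                       temperature_K = 310) {
  if (inherits(pmfs, "pmf_profile")) pmfs <- list(pmfs)
  if (inherits(species, "ion_species")) species <- list(species)
  nm <- vapply(species, `[[`, character(1), "name")
  if (is.null(names(pmfs)) || !all(nzchar(names(pmfs)))) {
    if (length(pmfs) == length(species)) names(pmfs) <- nm
    else stop("pmfs must be a named list matching the species names")
  }
  if (!all(nm %in% names(pmfs)))
    stop("missing PMF for species: ", paste(setdiff(nm, names(pmfs)), collapse = ", "))
  if (length(concentration_mM) == 1L)
    concentration_mM <- c(left = concentration_mM, right = concentration_mM)
  if (any(concentration_mM < 0)) stop("concentrations must be >= 0")
  if (timestep_ps <= 0) stop("timestep_ps must be > 0")
  if (duration_ns <= 0) stop("duration_ns must be > 0")
  if (dielectric_pore <= 0 || dielectric_reservoir <= 0 || dielectric_membrane <= 0)
    stop("dielectric constants must be > 0")
  for (s in nm) {
    p <- pmfs[[s]]
    if (!inherits(p, "pmf_profile")) stop("pmfs must contain pmf_profile objects")
    if (min(p$z) > pore_span[1] || max(p$z) < pore_span[2])
      stop(sprintf("PMF for %s does not cover the pore span [%g, %g] A",
                   s, pore_span[1], pore_span[2]))
  }
  structure(list(
    pmfs = pmfs, species = species, voltage_mV = voltage_mV,
    concentration_mM = concentration_mM, timestep_ps = timestep_ps,
    duration_ns = duration_ns, equilibration_ns = equilibration_ns,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed),
    pore_span = pore_span, pore_radius_A = pore_radius_A,
    reservoir_length_A = reservoir_length_A,
    dielectric_pore = dielectric_pore,
    dielectric_reservoir = dielectric_reservoir,
    dielectric_membrane = dielectric_membrane,
    ion_interactions = isTRUE(ion_interactions),
    min_interaction_distance_A = min_interaction_distance_A,
    diffusion_taper_A = diffusion_taper_A,
    clamp_displacement_factor = clamp_displacement_factor,
    temperature_K = temperature_K), class = "sim_config")
}

## Position-dependent diffusion profile in A^2/ps: bulk value outside the
## pore, bulk * pore_factor deep inside, cosine taper of width `taper` at
## each mouth. Shared by the BD engine tables and the Smoluchowski solver.
diffusion_profile <- function(z, sp, pore_span, taper = 2) {
  D_bulk <- sp$bulk_diffusion * 1e8  # m^2/s -> A^2/ps
  s <- pmin(z - pore_span[1], pore_span[2] - z)   # depth into pore (<0 outside)
  frac <- ifelse(s <= 0, 0, ifelse(s >= taper, 1, 0.5 * (1 - cos(pi * s / taper))))
  D_bulk * (1 - frac * (1 - sp$pore_diffusion_factor))
}

## Total dimensionless potential phi(z) = w(z) + q u(z) in kT for a species,
## with the applied potential dropping linearly across the pore span.
potential_profile <- function(z, pmf, sp, voltage_mV, pore_span, temperature_K) {
  vhat <- voltage_mV / kT_millivolts(temperature_K)  # in kT per unit charge
  L <- pore_span[2] - pore_span[1]
  u <- ifelse(z <= pore_span[1], vhat,
              ifelse(z >= pore_span[2], 0, vhat * (pore_span[2] - z) / L))
  w <- numeric(length(z))
  inside <- z >= min(pmf$z) & z <= max(pmf$z)
  w[inside] <- pmf_interpolant(pmf)(z[inside])
  w + sp$valence * u
}

## One species, one replicate: run the compiled BD engine.
run_species_replicate <- function(config, sp, seed) {
  ps <- config$pore_span
  taper <- config$diffusion_taper_A
  dom <- c(ps[1] - config$reservoir_length_A, ps[2] + config$reservoir_length_A)
  dz <- 0.02
  grid <- seq(dom[1], dom[2], by = dz)
  pmf <- config$pmfs[[sp$name]]
  f <- pmf_interpolant(pmf)
  inpore <- grid >= ps[1] & grid <= ps[2]
  force <- numeric(length(grid))
  gz <- pmin(pmax(grid[inpore], min(pmf$z)), max(pmf$z))
  force[inpore] <- -f(gz, deriv = 1L)
  vhat <- config$voltage_mV / kT_millivolts(config$temperature_K)
  force[inpore] <- force[inpore] + sp$valence * vhat / (ps[2] - ps[1])
  D <- diffusion_profile(grid, sp, ps, taper)
  dDdz <- (c(D[-1], D[length(D)]) - c(D[1], D[-length(D)])) /
    c(dz, rep(2 * dz, length(D) - 2), dz)
  conc_A3 <- config$concentration_mM * 1e-3 * 6.02214076e-4  # 1 M = 6.022e-4 ions/A^3
  area <- pi * config$pore_radius_A^2
  coulomb <- .e_coulomb^2 * 8.9875517923e9 /
    kT_joules(config$temperature_K) * 1e10   # e^2/(4 pi eps0 kT), in A
  steps <- config$duration_ns * 1000 / config$timestep_ps
  equil <- config$equilibration_ns * 1000 / config$timestep_ps
  thin <- max(1L, as.integer(round(1 / config$timestep_ps)))
  ## Milstein boundary displacement: the effective Dirichlet plane of the
  ## per-step clamped bath sits ~0.8258 sqrt(D dt) outside the slab edge, so
  ## extend the clamp by that amount past the pore face to place the
  ## effective concentration boundary at the face itself
  buffer <- -config$clamp_displacement_factor *
    sqrt(sp$bulk_diffusion * 1e8 * config$timestep_ps)
  out <- bd_run(grid, force, D, dDdz, config$timestep_ps, steps + equil, equil,
                ps[1], ps[2], config$reservoir_length_A, area,
                conc_A3[[1]], conc_A3[[2]], sp$valence,
                config$ion_interactions, config$dielectric_pore,
                config$dielectric_reservoir, config$min_interaction_distance_A,
                coulomb, ps[1], ps[2], 0.25, thin, as.integer(seed), buffer)
  if (isTRUE(out$unstable))
    stop("timestep instability: deterministic drift exceeded 1 A in one step; ",
         "reduce timestep_ps")
  out$hist_mids <- seq(ps[1] + 0.125, ps[2], by = 0.25)
  out
}

#' Run a stochastic permeation simulation
#'
#' Simulates every configured species over `n_replicates` independent
#' replicates and aggregates currents (from complete pore traversals),
#' dwell statistics and pore occupancy. Species are propagated
#' independently; ion-ion Coulomb forces act within each species.
#'
#' @param config a [sim_config()].
#' @return object of class `permeation_result` with fields `current_pA`,
#'   `current_se_pA`, `replicate_current_pA`, `crossings` (data.frame with
#'   per-species, per-replicate signed traversal counts), `dwell` (named
#'   list per species: `z`, `density` in ions/A), `mean_occupancy` (named,
#'   per species), `duration_ns`, `config`.
#' @export
simulate_permeation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max - 1L, config$n_replicates * length(config$species)))
  dur_s <- config$duration_ns * 1e-9
  rows <- list(); k <- 0L
  dwell <- list(); occ <- c()
  rep_current <- numeric(config$n_replicates)
  for (si in seq_along(config$species)) {
    sp <- config$species[[si]]
    hist_acc <- NULL; occ_acc <- 0; nsamp_acc <- 0
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1L
      out <- run_species_replicate(config, sp, seeds[k])
      net <- out$crossings_lr - out$crossings_rl
      i_pA <- net * sp$valence * .e_coulomb / dur_s * 1e12
      rows[[k]] <- data.frame(species = sp$name, replicate = r,
                              crossings_lr = out$crossings_lr,
                              crossings_rl = out$crossings_rl,
                              net_crossings = net, current_pA = i_pA)
      rep_current[r] <- rep_current[r] + i_pA
      if (is.null(hist_acc)) hist_acc <- out$hist_counts
      else hist_acc <- hist_acc + out$hist_counts
      occ_acc <- occ_acc + out$occupancy_sum
      nsamp_acc <- nsamp_acc + out$n_samples
      mids <- out$hist_mids
    }
    dwell[[sp$name]] <- list(z = mids,
                             density = hist_acc / (nsamp_acc * 0.25),
                             n_samples = nsamp_acc)
    occ[sp$name] <- occ_acc / nsamp_acc
  }
  crossings <- do.call(rbind, rows)
  se <- if (config$n_replicates > 1)
    stats::sd(rep_current) / sqrt(config$n_replicates)
  else {
    tot <- sum(crossings$crossings_lr + crossings$crossings_rl)
    sqrt(max(tot, 1)) * .e_coulomb / dur_s * 1e12
  }
  structure(list(current_pA = mean(rep_current), current_se_pA = se,
                 replicate_current_pA = rep_current, crossings = crossings,
                 dwell = dwell, mean_occupancy = occ,
                 duration_ns = config$duration_ns, config = config),
            class = "permeation_result")
}

#' @export
print.permeation_result <- function(x, ...) {
  cat(sprintf("<permeation_result> %g mV, %s mM: I = %.3g +/- %.3g pA (%d replicates)\n",
              x$config$voltage_mV,
              paste(x$config$concentration_mM, collapse = "/"),
              x$current_pA, x$current_se_pA, x$config$n_replicates))
  cat(sprintf("  mean pore occupancy: %s\n",
              paste(sprintf("%s %.3g", names(x$mean_occupancy), x$mean_occupancy),
                    collapse = ", ")))
  invisible(x)
}

#' Current-voltage curve
#'
#' Runs [simulate_permeation()] at each requested voltage.
#'
#' @param config a [sim_config()]; its voltage field is overridden.
#' @param voltages numeric vector of applied potentials in mV (>= 2 values).
#' @return data.frame with columns `voltage_mV`, `current_pA`, `se_pA`,
#'   `n_replicates`.
#' @export
compute_iv_curve <- function(config, voltages) {
  stopifnot(inherits(config, "sim_config"))
  if (length(voltages) < 2L) stop("need at least 2 voltages")
  res <- lapply(voltages, function(v) {
    cfg <- config; cfg$voltage_mV <- v
    cfg$seed <- config$seed + match(v, voltages)
    r <- simulate_permeation(cfg)
    data.frame(voltage_mV = v, current_pA = r$current_pA,
               se_pA = r$current_se_pA, n_replicates = cfg$n_replicates)
  })
  do.call(rbind, res)
}

#' Current-concentration curve
#'
#' Runs [simulate_permeation()] at each symmetric reservoir concentration at
#' a fixed voltage. Zero concentration gives exactly zero current (there are
#' no ions).
#'
#' @param config a [sim_config()].
#' @param concentrations sorted non-negative concentrations in mM.
#' @param voltage_mV applied potential.
#' @return data.frame with columns `concentration_mM`, `current_pA`,
#'   `se_pA`, `n_replicates`.
#' @export
compute_current_concentration <- function(config, concentrations, voltage_mV) {
  stopifnot(inherits(config, "sim_config"))
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (is.unsorted(concentrations)) stop("concentrations must be sorted")
  res <- lapply(seq_along(concentrations), function(i) {
    cc <- concentrations[i]
    if (cc == 0)
      return(data.frame(concentration_mM = 0, current_pA = 0, se_pA = 0,
                        n_replicates = config$n_replicates))
    cfg <- config
    cfg$concentration_mM <- c(left = cc, right = cc)
    cfg$voltage_mV <- voltage_mV
    cfg$seed <- config$seed + i
    r <- simulate_permeation(cfg)
    data.frame(concentration_mM = cc, current_pA = r$current_pA,
               se_pA = r$current_se_pA, n_replicates = cfg$n_replicates)
  })
  do.call(rbind, res)
}

#' Fit the Michaelis-Menten saturation curve
#'
#' Least-squares fit of `I = Imax * c / (Ks + c)` to current-concentration
#' points; recovers generating parameters exactly on noiseless data.
#'
#' @param points data.frame with columns `concentration_mM` (or `c_mM`) and
#'   `current_pA`; at least 2 distinct concentrations.
#' @return named numeric vector `c(Imax_pA, Ks_mM)` with the fit object as
#'   attribute `fit`.
#' @examples
#' cs <- c(50, 100, 200, 300, 500, 1000)
#' pts <- data.frame(concentration_mM = cs,
#'                   current_pA = 127 * cs / (277 + cs))
#' fit_michaelis_menten(pts)  # recovers Imax = 127, Ks = 277
#' @export
fit_michaelis_menten <- function(points) {
  cn <- intersect(c("concentration_mM", "c_mM"), names(points))
  if (!length(cn)) stop("points needs a concentration_mM column")
  cc <- points[[cn[1]]]; ii <- points$current_pA
  keep <- cc > 0
  cc <- cc[keep]; ii <- ii[keep]
  if (length(unique(cc)) < 2L)
    stop("degenerate data: need at least 2 distinct positive concentrations")
  fit <- minpack.lm::nlsLM(ii ~ Imax * cc / (Ks + cc),
                           start = list(Imax = max(ii) * 1.2,
                                        Ks = stats::median(cc)),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  out <- c(Imax_pA = unname(est["Imax"]), Ks_mM = unname(est["Ks"]))
  attr(out, "fit") <- fit
  out
}

#' Dwell histogram of pore-resident ions
#'
#' Re-bins the accumulated pore-position samples of a simulation to the
#' requested bin width. The returned density is in ions per angstrom and
#' integrates (over the pore span) to the mean occupancy of the species.
#'
#' @param result a `permeation_result`.
#' @param bin_width histogram bin width in angstrom (multiple of 0.25).
#' @param species species name; default the first simulated species.
#' @return data.frame with columns `z` (bin centres) and `density`.
#' @export
dwell_histogram <- function(result, bin_width = 1, species = NULL) {
  stopifnot(inherits(result, "permeation_result"))
  if (is.null(species)) species <- names(result$dwell)[1]
  d <- result$dwell[[species]]
  if (is.null(d) || d$n_samples == 0 || all(d$density == 0))
    stop("no pore-resident samples recorded for species ", species)
  if (bin_width < 0.25)
    stop("bin_width below the 0.25 A sampling resolution")
  fac <- max(1L, as.integer(round(bin_width / 0.25)))
  n <- length(d$z)
  grp <- (seq_len(n) - 1L) %/% fac
  z <- tapply(d$z, grp, mean)
  dens <- tapply(d$density, grp, mean)
  data.frame(z = as.numeric(z), density = as.numeric(dens), row.names = NULL)
}

#' Equilibrium pore occupancy from a PMF
#'
#' Closed-form mean number of ions in the pore at zero applied potential:
#' `<N> = 1000 N_A c pi r^2 integral exp(-w(z)) dz` with SI units inside the
#' integral. For a flat profile this reduces to concentration times pore
#' volume.
#'
#' @param pmf a [pmf_profile()] (zero-referenced at bulk).
#' @param concentration_mM bulk concentration in mM.
#' @param pore_radius_A effective pore radius in angstrom.
#' @param span integration range (default: the PMF grid range).
#' @return expected ion count (numeric).
#' @examples
#' flat <- build_pmf_from_features(NULL, 0.5, domain = c(-18, 18))
#' equilibrium_occupancy(flat, 1000, 4.53)  # ~1.40 ions at 1 M
#' @export
equilibrium_occupancy <- function(pmf, concentration_mM, pore_radius_A = 4.53,
                                  span = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (concentration_mM < 0) stop("concentration must be >= 0")
  if (concentration_mM == 0) return(0)
  if (is.null(span)) span <- range(pmf$z)
  I_A <- boltzmann_integral_A(pmf, span[1], span[2])
  c_m3 <- concentration_mM * .N_avogadro            # mM = mol/m^3
  c_m3 * pi * (pore_radius_A * .angstrom_m)^2 * (I_A * .angstrom_m)
}

#' Steady-state Smoluchowski (1D Nernst-Planck) current
#'
#' Independent boundary-value solution for the single-ion (non-interacting)
#' steady-state flux through the pore:
#' `J = (c_L exp(phi(a)) - c_R exp(phi(b))) / integral exp(phi(z)) / (D(z) A) dz`
#' with `phi = w + q u` the total dimensionless potential and Dirichlet
#' concentration boundary conditions at the pore faces (the clamped
#' reservoirs of the stochastic engine realise the same boundary
#' conditions). Computed by fine trapezoid quadrature; no stochastic
#' simulation is involved.
#'
#' @param pmf the species [pmf_profile()].
#' @param sp an [ion_species()].
#' @param voltage_mV applied potential (left reservoir high).
#' @param concentration_mM length-2 (left, right) or single symmetric value.
#' @param pore_span,pore_radius_A,diffusion_taper_A geometry, as in
#'   [sim_config()].
#' @param temperature_K temperature.
#' @param n_grid quadrature resolution.
#' @return current in pA (attribute `flux_per_s`: signed particle flux).
#' @export
steady_state_current <- function(pmf, sp = potassium_ion(), voltage_mV,
                                 concentration_mM, pore_span = c(-18, 18),
                                 pore_radius_A = 4.53, diffusion_taper_A = 2,
                                 temperature_K = 310, n_grid = 20001L) {
  if (length(concentration_mM) == 1L)
    concentration_mM <- c(concentration_mM, concentration_mM)
  z <- seq(pore_span[1], pore_span[2], length.out = n_grid)
  phi <- potential_profile(z, pmf, sp, voltage_mV, pore_span, temperature_K)
  D <- diffusion_profile(z, sp, pore_span, diffusion_taper_A)
  A <- pi * pore_radius_A^2
  integrand <- exp(phi) / (D * A)
  denom <- sum((integrand[-1] + integrand[-n_grid]) * diff(z) / 2)
  cA3 <- concentration_mM * 1e-3 * 6.02214076e-4   # ions per A^3
  J_ps <- (cA3[1] * exp(phi[1]) - cA3[2] * exp(phi[n_grid])) / denom
  flux_s <- J_ps * 1e12
  current_pA <- sp$valence * .e_coulomb * flux_s * 1e12
  attr(current_pA, "flux_per_s") <- flux_s
  current_pA
}
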