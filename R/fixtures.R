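## Synthetic fixture catalogue. Every input the pipeline needs is generated
## here, deterministically per (name, seed): PMFs anchored at the printed
## free-energy features, umbrella-window sample sets, and default device and
## simulation configurations. Each fixture records which of its numbers are
## anchored to reported values and which are modelling choices (the curve
## between anchors is always modelled, never data).

.fixture_names <- c("k_pmf", "cl_pmf", "c60f36_pmf", "c60f60_pmf", "flat_pmf",
                    "umbrella_set_c60f60", "default_device",
                    "default_sim_config")

#' Available fixture names
#' @return character vector of fixture names accepted by [make_fixture()].
#' @export
fixture_names <- function() .fixture_names

k_pmf_anchors <- function() {
  ## wells of 3 kT at +/-9 A (anchored); 2.2 kT central barrier read as
  ## height above the well floor, so the mid-channel value is -0.8 kT
  cbind(z = c(-18, -9, 0, 9, 18), w = c(0, -3, -0.8, -3, 0))
}

cl_pmf_anchors <- function() {
  ## ~20 kT central barrier excluding chloride (anchored at the apex)
  cbind(z = c(-18, 0, 18), w = c(0, 20, 0))
}

c60f36_pmf_anchors <- function() {
  ## binding well of -11.9 kT at 22 A, bulk zero at 35 A (anchored);
  ## the repulsive contact wall and the relaxation to bulk are modelled
  cbind(z = c(19, 21, 22, 24, 26, 35), w = c(8, -4, -11.9, -3, -1, 0))
}

c60f60_pmf_anchors <- function() {
  ## -25.6 kT at 23 A rising to -7.3 kT at 24.5 A, secondary minimum near
  ## 25.5 A, bulk zero at 35 A (anchored); the -9 kT depth of the secondary
  ## minimum and the -7 kT shoulder at 22 A are modelling choices
  cbind(z = c(20, 22, 23, 24.5, 25.5, 35), w = c(8, -7, -25.6, -7.3, -9, 0))
}

#' Generate a named fixture
#'
#' Deterministic generator for every input object used by the analysis
#' chain. Optionally writes the fixture to disk in the package's plain-text
#' formats ([write_pmf()] for profiles, one sample file per umbrella
#' window). Regeneration from the same (name, seed) is bit-identical.
#'
#' @param name one of [fixture_names()].
#' @param seed integer seed (only the umbrella set consumes randomness).
#' @param outdir optional directory to write files into.
#' @param n_samples samples per umbrella window (umbrella set only).
#' @return the fixture object: a [pmf_profile()], a list of
#'   [umbrella_window()], a [device_model()] or a [sim_config()]. PMF
#'   fixtures carry a `provenance` attribute separating anchored values from
#'   modelling choices.
#' @examples
#' k <- make_fixture("k_pmf")
#' min(k$w)  # -3 kT wells
#' @export
make_fixture <- function(name, seed = 42L, outdir = NULL, n_samples = 5000L) {
  if (!name %in% .fixture_names)
    stop("unknown fixture '", name, "'; available: ",
         paste(.fixture_names, collapse = ", "))
  fx <- switch(name,
    k_pmf = {
      p <- build_pmf_from_features(k_pmf_anchors(), grid_step = 0.1,
                                   label = "K+ axial PMF (two 3 kT wells at +/-9 A, 2.2 kT barrier)")
      attr(p, "provenance") <- paste(
        "anchored: well depth 3 kT at +/-9 A, barrier 2.2 kT above wells;",
        "modelled: curve between anchors")
      p
    },
    cl_pmf = {
      p <- build_pmf_from_features(cl_pmf_anchors(), grid_step = 0.1,
                                   label = "Cl- axial PMF (20 kT central barrier)")
      attr(p, "provenance") <- "anchored: 20 kT barrier; modelled: flanks"
      p
    },
    c60f36_pmf = {
      p <- build_pmf_from_features(c60f36_pmf_anchors(), grid_step = 0.05,
                                   label = "C60F36 unbinding PMF (-11.9 kT well at 22 A)")
      attr(p, "provenance") <- paste(
        "anchored: -11.9 kT at 22 A, 0 at 35 A; modelled: contact wall at",
        "19 A, shoulder at 21 A and relaxation anchors at 24/26 A")
      p
    },
    c60f60_pmf = {
      p <- build_pmf_from_features(c60f60_pmf_anchors(), grid_step = 0.05,
                                   label = "C60F60 unbinding PMF (-25.6 kT well at 23 A)")
      attr(p, "provenance") <- paste(
        "anchored: -25.6 kT at 23 A, -7.3 kT at 24.5 A, secondary minimum",
        "near 25.5 A, 0 at 35 A; modelled: -9 kT secondary depth, -7 kT",
        "shoulder at 22 A, contact wall at 20 A")
      p
    },
    flat_pmf = {
      p <- build_pmf_from_features(NULL, grid_step = 0.1, domain = c(-18, 18),
                                   label = "flat reference PMF")
      attr(p, "provenance") <- "identity profile, no anchored values"
      p
    },
    umbrella_set_c60f60 = {
      pmf <- make_fixture("c60f60_pmf")
      centers <- seq(22, 35, by = 0.5)  # 27 windows, protocol spacing
      wseeds <- withr::with_seed(seed,
        sample.int(.Machine$integer.max - 1L, length(centers)))
      lapply(seq_along(centers), function(i)
        sample_umbrella_window(pmf, centers[i], k = 10, n = n_samples,
                               seed = wseeds[i]))
    },
    default_device = device_model(),
    default_sim_config = {
      sim_config(
        pmfs = list(K = make_fixture("k_pmf"), Cl = make_fixture("cl_pmf")),
        species = list(potassium_ion(), chloride_ion()),
        voltage_mV = 200, concentration_mM = 500,
        duration_ns = 800, n_replicates = 5, seed = seed)
    })
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (inherits(fx, "pmf_profile")) {
      write_pmf(fx, file.path(outdir, paste0(name, ".txt")))
    } else if (name == "umbrella_set_c60f60") {
      for (i in seq_along(fx)) {
        w <- fx[[i]]
        path <- file.path(outdir, sprintf("window_%02d.txt", i))
        writeLines(c(sprintf("# center_z: %.9g", w$center_z),
                     sprintf("# force_constant: %.9g", w$force_constant),
                     sprintf("# temperature_K: %.9g", w$temperature_K),
                     sprintf("%.9g", w$samples)), path)
      }
    }
  }
  fx
}

#' Read an umbrella-window sample file
#'
#' Reads the one-file-per-window text format written by [make_fixture()]
#' (header comments `center_z`, `force_constant`, `temperature_K`; one
#' sample per line).
#'
#' @param path file path.
#' @return an [umbrella_window()].
#' @export
read_umbrella_window <- function(path) {
  lines <- readLines(path)
  hdr <- function(key, default = NA_real_) {
    m <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(trimws(sub(paste0("^#\\s*", key, ":"), "", m[1])))
  }
  center <- hdr("center_z"); k <- hdr("force_constant")
  temp <- hdr("temperature_K", 310)
  if (is.na(center) || is.na(k))
    stop("window file missing center_z or force_constant header")
  dat <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  samples <- as.numeric(dat)
  if (any(is.na(samples))) stop("non-numeric sample in ", path)
  umbrella_window(center, k, samples, temp)
}
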