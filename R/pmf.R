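## 1D potential-of-mean-force profiles: construction from anchor features,
## interpolation, differentiation and plain-text serialization.

#' Create a 1D potential-of-mean-force profile
#'
#' A `pmf_profile` holds a free-energy curve W(z) along the channel axis, in
#' thermal (kT) units at a stated temperature, on a strictly increasing axial
#' grid in angstrom. Profiles are zero-referenced at the bulk end, i.e. the
#' free energy vanishes where the particle is in bulk solution.
#'
#' @param z numeric vector of axial positions in angstrom, strictly
#'   increasing, length >= 2.
#' @param w numeric vector of free energies in kT, same length as `z`.
#' @param temperature_K temperature at which the kT unit is defined.
#' @param label free-text description.
#' @param bulk which end of the grid is bulk solution (`"right"` or
#'   `"left"`); the profile is zero-referenced there.
#' @param zero_reference if `TRUE` (default) shift the curve so the bulk end
#'   is exactly zero. Zero-referencing is idempotent.
#' @return An object of class `pmf_profile` with fields `z`, `w`,
#'   `temperature_K`, `label`, `bulk`.
#' @seealso [build_pmf_from_features()], [pmf_derivative()], [read_pmf()]
#' @export
pmf_profile <- function(z, w, temperature_K = 310, label = "",
                        bulk = c("right", "left"), zero_reference = TRUE) {
  bulk <- match.arg(bulk)
  z <- as.numeric(z)
  w <- as.numeric(w)
  if (length(z) < 2L) stop("PMF grid needs at least 2 points")
  if (length(z) != length(w)) stop("z and w must have the same length")
  if (!all(is.finite(z)) || !all(is.finite(w)))
    stop("PMF grid and values must be finite")
  if (any(diff(z) <= 0)) stop("z grid must be strictly increasing")
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be a positive number")
  obj <- structure(
    list(z = z, w = w, temperature_K = temperature_K,
         label = as.character(label)[1], bulk = bulk),
    class = "pmf_profile")
  if (zero_reference) obj <- zero_reference_pmf(obj)
  obj
}

#' Zero-reference a PMF at its bulk end
#'
#' Shifts the whole curve so the value at the bulk end is exactly 0 kT.
#' Applying the operation twice changes nothing.
#'
#' @param pmf a [pmf_profile()].
#' @return The shifted `pmf_profile`.
#' @export
zero_reference_pmf <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_profile"))
  ref <- if (pmf$bulk == "right") pmf$w[length(pmf$w)] else pmf$w[1L]
  pmf$w <- pmf$w - ref
  pmf
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  grid: [%.3g, %.3g] A, %d points; T = %g K; bulk = %s\n",
              min(x$z), max(x$z), length(x$z), x$temperature_K, x$bulk))
  cat(sprintf("  W range: [%.3g, %.3g] kT\n", min(x$w), max(x$w)))
  invisible(x)
}

## Shape-preserving piecewise-cubic Hermite interpolant (Fritsch-Butland
## slopes). Interior knots where the secant slope changes sign get zero
## slope, so local extrema in the data are honoured exactly and the curve
## never overshoots the values of a neighbouring knot pair. Returns a
## function of (z, deriv) with deriv 0 or 1; C1 across interior knots.
monotone_hermite <- function(x, y) {
  n <- length(x)
  h <- diff(x); s <- diff(y) / h
  m <- numeric(n)
  m[1] <- s[1]; m[n] <- s[n - 1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      if (s[i - 1] * s[i] <= 0) {
        m[i] <- 0
      } else {
        ## Fritsch-Butland weighted harmonic mean: 0 < m <= 3 min(|s|)
        m[i] <- 3 * (h[i - 1] + h[i]) /
          ((2 * h[i] + h[i - 1]) / s[i - 1] + (h[i] + 2 * h[i - 1]) / s[i])
      }
    }
  }
  ## clamp endpoint slopes to the monotonicity region of the first interval
  if (s[1] == 0 || m[1] / s[1] > 3) m[1] <- 3 * s[1]
  if (s[n - 1] == 0 || m[n] / s[n - 1] > 3) m[n] <- 3 * s[n - 1]
  function(z, deriv = 0L) {
    i <- findInterval(z, x, rightmost.closed = TRUE, all.inside = TRUE)
    t <- (z - x[i]) / h[i]
    if (deriv == 0L) {
      (1 + 2 * t) * (1 - t)^2 * y[i] + t * (1 - t)^2 * h[i] * m[i] +
        t^2 * (3 - 2 * t) * y[i + 1] + t^2 * (t - 1) * h[i] * m[i + 1]
    } else {
      (6 * t * (t - 1) * y[i] - 6 * t * (t - 1) * y[i + 1]) / h[i] +
        (1 - t) * (1 - 3 * t) * m[i] + t * (3 * t - 2) * m[i + 1]
    }
  }
}

pmf_interpolant <- function(pmf) {
  monotone_hermite(pmf$z, pmf$w)
}

#' Evaluate a PMF at arbitrary positions
#'
#' Uses a shape-preserving monotone cubic interpolant through the grid.
#'
#' @param pmf a [pmf_profile()].
#' @param z positions in angstrom, within the grid range.
#' @return free energies in kT.
#' @export
pmf_value <- function(pmf, z) {
  stopifnot(inherits(pmf, "pmf_profile"))
  rng <- range(pmf$z)
  if (any(z < rng[1] | z > rng[2]))
    stop(sprintf("z outside PMF grid range [%g, %g] A", rng[1], rng[2]))
  pmf_interpolant(pmf)(z)
}

#' Mean force -dW/dz of a PMF
#'
#' Returns the force exerted on the particle by the free-energy landscape,
#' `-dW/dz`, in kT per angstrom, using the analytic derivative of the
#' shape-preserving cubic interpolant. The derivative is continuous across
#' interior grid points.
#'
#' @param pmf a [pmf_profile()].
#' @param z positions in angstrom; must lie within the grid range.
#' @return forces in kT/A (positive force pushes towards increasing z when
#'   the free energy decreases with z).
#' @export
pmf_derivative <- function(pmf, z) {
  stopifnot(inherits(pmf, "pmf_profile"))
  rng <- range(pmf$z)
  if (any(z < rng[1] | z > rng[2]))
    stop(sprintf("z outside PMF grid range [%g, %g] A", rng[1], rng[2]))
  -pmf_interpolant(pmf)(z, deriv = 1L)
}

#' Build a PMF from printed anchor features
#'
#' Constructs a smooth profile through a small set of (z, w) control points
#' ("anchors") using monotone shape-preserving cubic interpolation, which
#' cannot overshoot beyond the values of neighbouring anchors and therefore
#' introduces no spurious wells between them. The result is zero-referenced
#' at the bulk end.
#'
#' @param anchors two-column matrix or data.frame of (z in A, w in kT)
#'   control points, or `NULL`/empty for a flat profile.
#' @param grid_step grid spacing in angstrom (> 0).
#' @param domain numeric length-2 vector, the z range of the profile;
#'   defaults to the anchor range. Anchors outside the declared domain are
#'   rejected.
#' @param channel_span numeric length-2, the pore region along z (metadata;
#'   default c(-18, 18), the 36 A channel centred at the origin).
#' @param temperature_K,label,bulk passed to [pmf_profile()].
#' @return a `pmf_profile` whose grid contains every anchor position, with
#'   attribute `anchors` recording the control points.
#' @examples
#' # potassium axial profile: two 3 kT wells at +/-9 A, 2.2 kT central barrier
#' k <- build_pmf_from_features(
#'   cbind(c(-18, -9, 0, 9, 18), c(0, -3, -0.8, -3, 0)), grid_step = 0.1)
#' @export
build_pmf_from_features <- function(anchors, grid_step = 0.1, domain = NULL,
                                    channel_span = c(-18, 18),
                                    temperature_K = 310, label = "",
                                    bulk = c("right", "left")) {
  bulk <- match.arg(bulk)
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0)
    stop("grid_step must be a positive number")
  if (is.null(anchors) || NROW(anchors) == 0L) {
    if (is.null(domain)) domain <- channel_span
    z <- seq(domain[1], domain[2], by = grid_step)
    if (z[length(z)] < domain[2]) z <- c(z, domain[2])
    return(pmf_profile(z, rep(0, length(z)), temperature_K, label, bulk))
  }
  anchors <- as.matrix(anchors)
  if (ncol(anchors) != 2L) stop("anchors must have two columns (z, w)")
  az <- anchors[, 1]; aw <- anchors[, 2]
  dup <- az[duplicated(az)]
  if (length(dup))
    stop(sprintf("duplicate anchor z coordinate at z = %g A", dup[1]))
  ord <- order(az); az <- az[ord]; aw <- aw[ord]
  if (is.null(domain)) domain <- range(az)
  if (any(az < domain[1] | az > domain[2])) {
    bad <- az[az < domain[1] | az > domain[2]][1]
    stop(sprintf("anchor at z = %g A lies outside the domain [%g, %g]",
                 bad, domain[1], domain[2]))
  }
  if (length(az) == 1L) {
    z <- sort(unique(c(seq(domain[1], domain[2], by = grid_step), az, domain)))
    prof <- pmf_profile(z, rep(aw, length(z)), temperature_K, label, bulk)
    attr(prof, "anchors") <- cbind(z = az, w = aw)
    return(prof)
  }
  fit <- monotone_hermite(az, aw)
  z <- sort(unique(c(seq(domain[1], domain[2], by = grid_step), az, domain)))
  ## outside the anchor range the profile is held at the terminal anchor value
  w <- fit(pmin(pmax(z, az[1]), az[length(az)]))
  prof <- pmf_profile(z, w, temperature_K, label, bulk)
  attr(prof, "anchors") <- cbind(z = az, w = aw)
  prof
}

#' Write a PMF profile to a two-column text file
#'
#' Plain-text format: `#`-prefixed header comments carrying the label,
#' temperature and bulk side, then whitespace-separated `z_A  W_kT` rows at 9
#' significant digits, so a write/read round trip reproduces the profile
#' bit-identically in decimal text.
#'
#' @param pmf a [pmf_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# label: %s", pmf$label),
    sprintf("# temperature_K: %.9g", pmf$temperature_K),
    sprintf("# bulk: %s", pmf$bulk),
    "# columns: z_A W_kT",
    sprintf("%.9g %.9g", pmf$z, pmf$w)), con)
  invisible(path)
}

#' Read a PMF profile from a two-column text file
#'
#' Accepts the format written by [write_pmf()]: `#` comment lines (a
#' `label:`, `temperature_K:` and `bulk:` header is recognised; other
#' comments are preserved and used as the label when no explicit label is
#' present), followed by two whitespace-separated numeric columns. Parse
#' errors report the offending line number.
#'
#' @param path input file path.
#' @return a [pmf_profile()].
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  label <- ""; temperature <- 310; bulk <- "right"
  comments <- character()
  z <- numeric(); w <- numeric()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+\\s*", "", ln))
      if (grepl("^label:", body)) {
        label <- trimws(sub("^label:", "", body))
      } else if (grepl("^temperature_K:", body)) {
        temperature <- as.numeric(trimws(sub("^temperature_K:", "", body)))
        if (is.na(temperature))
          stop(sprintf("line %d: invalid temperature header", i))
      } else if (grepl("^bulk:", body)) {
        bulk <- trimws(sub("^bulk:", "", body))
      } else if (!grepl("^columns:", body) && nzchar(body)) {
        comments <- c(comments, body)
      }
      next
    }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != 2L)
      stop(sprintf("line %d: expected two columns, found %d", i, length(tok)))
    vals <- suppressWarnings(as.numeric(tok))
    if (any(is.na(vals)))
      stop(sprintf("line %d: non-numeric token '%s'", i, tok[which(is.na(vals))[1]]))
    if (length(z) && vals[1] <= z[length(z)])
      stop(sprintf("line %d: z column not strictly increasing (z = %g)", i, vals[1]))
    z <- c(z, vals[1]); w <- c(w, vals[2])
  }
  if (length(z) < 2L) stop("fewer than 2 data rows in PMF file")
  if (!nzchar(label) && length(comments)) label <- comments[1]
  prof <- pmf_profile(z, w, temperature, label, bulk, zero_reference = FALSE)
  if (length(comments)) attr(prof, "comments") <- comments
  prof
}
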