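#' Acquisition configuration for periodic pulsed excitation
#'
#' Describes the TCSPC acquisition geometry: laser repetition rate, number of
#' histogram bins per repetition period, and the acquisition window. The
#' first-harmonic angular frequency used throughout phasor analysis is derived
#' as \eqn{\omega = 2\pi f} with \eqn{f} the repetition rate, converted to
#' rad/ns.
#'
#' @param rep_rate_mhz Excitation repetition rate in MHz (default 80, the
#'   standard Ti:sapphire repetition rate).
#' @param n_bins Number of time bins per period (integer, >= 16; default 4096,
#'   typical of TCSPC card binning).
#' @param window_ns Acquisition window in ns; defaults to one full repetition
#'   period, `1000 / rep_rate_mhz`.
#' @return An object of class `acq_config` with fields `rep_rate_mhz`,
#'   `n_bins`, `window_ns`, `angular_frequency` (rad/ns), `bin_width_ns` and
#'   `bin_centers_ns`.
#' @examples
#' cfg <- acq_config()
#' cfg$angular_frequency # 2*pi*80/1000 rad/ns
#' @export
acq_config <- function(rep_rate_mhz = 80, n_bins = 4096L,
                       window_ns = 1000 / rep_rate_mhz) {
  stop_if_not_scalar_number(rep_rate_mhz, "rep_rate_mhz", positive = TRUE)
  stop_if_not_scalar_number(window_ns, "window_ns", positive = TRUE)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins != round(n_bins) ||
      n_bins < 16) {
    stop("`n_bins` must be a single integer >= 16", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  bw <- window_ns / n_bins
  structure(
    list(
      rep_rate_mhz = rep_rate_mhz,
      n_bins = n_bins,
      window_ns = window_ns,
      angular_frequency = 2 * pi * rep_rate_mhz / 1000,
      bin_width_ns = bw,
      bin_centers_ns = (seq_len(n_bins) - 0.5) * bw
    ),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf(
    "<acq_config> %g MHz, %d bins over %.4g ns (omega = %.5g rad/ns)\n",
    x$rep_rate_mhz, x$n_bins, x$window_ns, x$angular_frequency
  ))
  invisible(x)
}

same_binning <- function(a, b) {
  isTRUE(all.equal(a$n_bins, b$n_bins)) &&
    isTRUE(all.equal(a$window_ns, b$window_ns)) &&
    isTRUE(all.equal(a$rep_rate_mhz, b$rep_rate_mhz))
}

#' Instrument response function profile
#'
#' An IRF is stored as a normalized discrete density on the same time bins as
#' the decays it deconvolves: nonnegative weights summing to one.
#'
#' @param weights Nonnegative numeric vector, one weight per bin; normalized
#'   to sum to 1.
#' @param config The [acq_config()] the IRF is binned on.
#' @return An object of class `irf_profile` with `bin_centers_ns`, `weights`
#'   and `config`.
#' @export
irf_profile <- function(weights, config) {
  stopifnot(inherits(config, "acq_config"))
  if (length(weights) != config$n_bins) {
    stop("IRF weight vector length must equal config$n_bins", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("IRF weights must be finite and nonnegative", call. = FALSE)
  }
  s <- sum(weights)
  if (s <= 0) stop("IRF weights must not all be zero", call. = FALSE)
  structure(
    list(
      bin_centers_ns = config$bin_centers_ns,
      weights = weights / s,
      config = config
    ),
    class = "irf_profile"
  )
}

#' Gaussian instrument response function
#'
#' Builds a discretized, normalized Gaussian IRF on the bins of an acquisition
#' configuration — a stand-in for a measured scatter IRF (e.g. the reflection
#' of the excitation beam).
#'
#' @param fwhm_ns Full width at half maximum in ns; must satisfy
#'   `0 < fwhm_ns < window_ns / 4`.
#' @param center_ns Peak position in ns; must satisfy
#'   `0 <= center_ns < window_ns / 2`.
#' @param config An [acq_config()].
#' @return An [irf_profile()].
#' @examples
#' irf <- make_gaussian_irf(0.2, 1, acq_config())
#' sum(irf$weights) # 1
#' @export
make_gaussian_irf <- function(fwhm_ns, center_ns, config) {
  stopifnot(inherits(config, "acq_config"))
  stop_if_not_scalar_number(fwhm_ns, "fwhm_ns", positive = TRUE)
  stop_if_not_scalar_number(center_ns, "center_ns", nonneg = TRUE)
  if (fwhm_ns >= config$window_ns / 4) {
    stop("`fwhm_ns` must be < window_ns / 4", call. = FALSE)
  }
  if (center_ns >= config$window_ns / 2) {
    stop("`center_ns` must be < window_ns / 2", call. = FALSE)
  }
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  w <- exp(-0.5 * ((config$bin_centers_ns - center_ns) / sigma)^2)
  irf_profile(w, config)
}

# Delta IRF with all weight in the first bin: useful for tests and for
# treating a decay as IRF-free.
delta_irf <- function(config) {
  w <- numeric(config$n_bins)
  w[1] <- 1
  irf_profile(w, config)
}
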