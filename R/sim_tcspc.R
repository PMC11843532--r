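#' TCSPC decay histogram
#'
#' Photon counts per time bin over one laser repetition period.
#'
#' @param counts Nonnegative integer photon counts, one per bin.
#' @param config The [acq_config()] the histogram was acquired with.
#' @param meta Optional named list of free-form labels (timepoint, well,
#'   repeat, ...).
#' @return An object of class `decay_histogram` with `bin_centers_ns`,
#'   `counts`, `config`, `meta`.
#' @export
decay_histogram <- function(counts, config, meta = list()) {
  stopifnot(inherits(config, "acq_config"))
  if (length(counts) != config$n_bins) {
    stop("counts length must equal config$n_bins", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("counts must be integers", call. = FALSE)
  }
  structure(
    list(
      bin_centers_ns = config$bin_centers_ns,
      counts = as.numeric(round(counts)),
      config = config,
      meta = meta
    ),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins, %s photons\n",
              x$config$n_bins, format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

# Steady-state periodic multi-exponential decay sampled at bin centers.
# Under pulsed excitation with period T, the tails of all preceding pulses
# sum geometrically: sum_m exp(-(t + mT)/tau) = exp(-t/tau) / (1 - exp(-T/tau)),
# which is exact for exponentials.
periodic_decay_samples <- function(model, config) {
  t <- config$bin_centers_ns
  period <- config$window_ns
  out <- numeric(length(t))
  for (i in seq_len(model$n)) {
    tau <- model$lifetimes_ns[i]
    out <- out + model$amplitudes[i] * exp(-t / tau) / (1 - exp(-period / tau))
  }
  out
}

# Circular convolution of a per-bin signal with IRF weights via FFT.
# `irf_fft` may be supplied precomputed (fit loops reuse it).
circular_convolve <- function(signal, irf_weights, irf_fft = NULL) {
  n <- length(signal)
  if (is.null(irf_fft)) irf_fft <- stats::fft(irf_weights)
  Re(stats::fft(stats::fft(signal) * irf_fft, inverse = TRUE)) / n
}

#' Expected TCSPC curve of a decay model under periodic excitation
#'
#' Computes the noise-free expected counts per bin: the periodic
#' (circular) convolution of \eqn{\sum_i \alpha_i e^{-t/\tau_i}} with the
#' instrument response function over one repetition period. Incomplete decay
#' between pulses is handled exactly by geometric summation of the tails of
#' all preceding pulses, so lifetimes comparable to the repetition period are
#' treated correctly.
#'
#' @param model A [decay_model()].
#' @param irf An [irf_profile()] on the same binning as `config`.
#' @param config An [acq_config()].
#' @param background Constant background counts per bin added to the curve
#'   (default 0).
#' @return Numeric vector of unnormalized expected counts, one per bin.
#' @examples
#' cfg <- acq_config(n_bins = 1024)
#' irf <- make_gaussian_irf(0.2, 1, cfg)
#' curve <- expected_curve(decay_model(1, 1.5), irf, cfg)
#' @export
expected_curve <- function(model, irf, config, background = 0) {
  stopifnot(inherits(model, "decay_model"), inherits(irf, "irf_profile"),
            inherits(config, "acq_config"))
  if (!same_binning(irf$config, config)) {
    stop("IRF and config binning differ", call. = FALSE)
  }
  stop_if_not_scalar_number(background, "background", nonneg = TRUE)
  circular_convolve(periodic_decay_samples(model, config), irf$weights) +
    background
}

#' Simulate a TCSPC decay histogram
#'
#' Draws Poisson photon counts around the expected periodic-excitation curve,
#' scaled so that the expected total equals `total_photons`.
#'
#' @inheritParams expected_curve
#' @param total_photons Expected total photon count (>= 0).
#' @param seed Integer seed; the same seed reproduces the same histogram.
#' @param meta Optional metadata list stored on the histogram.
#' @return A [decay_histogram()].
#' @export
simulate_decay <- function(model, irf, config, total_photons, seed,
                           background = 0, meta = list()) {
  stop_if_not_scalar_number(total_photons, "total_photons", nonneg = TRUE)
  mu <- expected_curve(model, irf, config, background = background)
  mu <- pmax(mu, 0) # guard tiny negative FFT round-off
  if (total_photons == 0 || sum(mu) == 0) {
    return(decay_histogram(numeric(config$n_bins), config, meta = meta))
  }
  mu <- mu * (total_photons / sum(mu))
  counts <- with_seed(seed, stats::rpois(length(mu), mu))
  meta$seed <- as.integer(seed)
  decay_histogram(counts, config, meta = meta)
}

#' Sum pixel decays into one histogram
#'
#' FLIM images are reduced to one decay per image by summing the individual
#' pixel decays bin-wise; this pools photons so that a single high-count fit
#' is possible.
#'
#' @param pixels A list of [decay_histogram()] objects sharing one
#'   acquisition configuration.
#' @return A [decay_histogram()] with bin-wise summed counts; `meta$n_pixels`
#'   records the number of pixels pooled.
#' @export
sum_pixel_decays <- function(pixels) {
  if (!is.list(pixels) || length(pixels) == 0L ||
      !all(vapply(pixels, inherits, logical(1), "decay_histogram"))) {
    stop("`pixels` must be a non-empty list of decay_histogram objects",
         call. = FALSE)
  }
  cfg <- pixels[[1]]$config
  for (p in pixels[-1]) {
    if (!same_binning(p$config, cfg)) {
      stop("all pixels must share one acquisition configuration",
           call. = FALSE)
    }
  }
  counts <- Reduce(`+`, lapply(pixels, `[[`, "counts"))
  decay_histogram(counts, cfg, meta = list(n_pixels = length(pixels)))
}
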