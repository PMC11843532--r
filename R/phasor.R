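#' Phasor point
#'
#' First-harmonic phasor coordinates of a fluorescence decay: the normalized
#' real (`g`) and imaginary (`s`) Fourier components at the laser's angular
#' repetition frequency, with optional 2-sigma uncertainties.
#'
#' @param g,s Phasor coordinates (unitless).
#' @param g_err,s_err 2-sigma half-widths on `g` and `s` (>= 0; 0 means "not
#'   estimated").
#' @param meta Optional named list of labels.
#' @return An object of class `phasor_point`.
#' @export
phasor_point <- function(g, s, g_err = 0, s_err = 0, meta = list()) {
  stop_if_not_scalar_number(g, "g")
  stop_if_not_scalar_number(s, "s")
  stop_if_not_scalar_number(g_err, "g_err", nonneg = TRUE)
  stop_if_not_scalar_number(s_err, "s_err", nonneg = TRUE)
  structure(list(g = g, s = s, g_err = g_err, s_err = s_err, meta = meta),
            class = "phasor_point")
}

#' @export
print.phasor_point <- function(x, ...) {
  cat(sprintf("<phasor_point> g = %.5f +/- %.5f, s = %.5f +/- %.5f\n",
              x$g, x$g_err, x$s, x$s_err))
  invisible(x)
}

#' Phasor coordinates of a decay histogram
#'
#' Computes the first-harmonic phasor of a measured decay:
#' \deqn{g = \sum_k I(t_k)\cos(\omega t_k) / \sum_k I(t_k), \quad
#'       s = \sum_k I(t_k)\sin(\omega t_k) / \sum_k I(t_k)}
#' with \eqn{t_k} the bin centers and \eqn{\omega} the angular repetition
#' frequency from the histogram's acquisition configuration. Sums are plain
#' rectangle-rule sums over bins, treating the histogram as counts per bin.
#' No IRF correction is applied by default; an optional calibration divides by
#' the phasor of a known monoexponential reference in the complex plane.
#'
#' @param hist A [decay_histogram()] with positive total counts.
#' @param calibrate_tau_ns Optional lifetime (ns) of a monoexponential
#'   reference; if given, the raw phasor is divided (complex division) by the
#'   ratio of the reference's measured-geometry phasor to its ideal
#'   closed-form phasor. Off (`NULL`) by default.
#' @return A [phasor_point()] with zero errors (use [phasor_uncertainty()] to
#'   estimate them).
#' @export
phasor_from_histogram <- function(hist, calibrate_tau_ns = NULL) {
  stopifnot(inherits(hist, "decay_histogram"))
  total <- sum(hist$counts)
  if (total <= 0) stop("histogram has zero total counts", call. = FALSE)
  omega <- hist$config$angular_frequency
  t <- hist$bin_centers_ns
  g <- sum(hist$counts * cos(omega * t)) / total
  s <- sum(hist$counts * sin(omega * t)) / total
  meta <- hist$meta
  if (!is.null(calibrate_tau_ns)) {
    ref <- phasor_from_lifetime(calibrate_tau_ns, omega)
    z <- complex(real = g, imaginary = s) / complex(real = ref$g,
                                                    imaginary = ref$s)
    g <- Re(z); s <- Im(z)
    meta$calibrated_tau_ref_ns <- calibrate_tau_ns
  }
  phasor_point(g, s, meta = meta)
}

#' Closed-form phasor of a monoexponential decay
#'
#' For a single-lifetime decay the phasor has the closed form
#' \eqn{g = 1/(1 + (\omega\tau)^2)}, \eqn{s = \omega\tau/(1 + (\omega\tau)^2)},
#' which places the point exactly on the universal circle of center (1/2, 0)
#' and radius 1/2. Multi-exponential mixtures fall strictly inside that
#' circle.
#'
#' @param tau_ns Lifetime in ns (>= 0).
#' @param omega Angular frequency in rad/ns (> 0).
#' @return A [phasor_point()].
#' @examples
#' phasor_from_lifetime(1 / (2 * pi * 0.08), 2 * pi * 0.08) # (0.5, 0.5)
#' @export
phasor_from_lifetime <- function(tau_ns, omega) {
  stop_if_not_scalar_number(tau_ns, "tau_ns", nonneg = TRUE)
  stop_if_not_scalar_number(omega, "omega", positive = TRUE)
  wt <- omega * tau_ns
  phasor_point(1 / (1 + wt^2), wt / (1 + wt^2))
}

#' Intensity-weighted phasor mixture
#'
#' Phasor coordinates combine linearly under mixing: the phasor of a sum of
#' decays is the intensity-weighted mean of the component phasors. For
#' components of a [decay_model()], the intensity weight of component i is
#' \eqn{\alpha_i \tau_i} (the integrated photon contribution).
#'
#' @param points List of [phasor_point()] objects.
#' @param intensity_weights Nonnegative weights, one per point, with positive
#'   sum.
#' @return A [phasor_point()]; errors are combined as intensity-weighted
#'   root-mean-squares (zero if none of the inputs carries errors).
#' @export
mixture_phasor <- function(points, intensity_weights) {
  if (!is.list(points) || length(points) == 0L ||
      !all(vapply(points, inherits, logical(1), "phasor_point"))) {
    stop("`points` must be a non-empty list of phasor_point objects",
         call. = FALSE)
  }
  w <- as.numeric(intensity_weights)
  if (length(w) != length(points) || any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be nonnegative, one per point", call. = FALSE)
  }
  if (sum(w) <= 0) stop("weights must not all be zero", call. = FALSE)
  w <- w / sum(w)
  g <- sum(w * vapply(points, `[[`, numeric(1), "g"))
  s <- sum(w * vapply(points, `[[`, numeric(1), "s"))
  g_err <- sqrt(sum((w * vapply(points, `[[`, numeric(1), "g_err"))^2))
  s_err <- sqrt(sum((w * vapply(points, `[[`, numeric(1), "s_err"))^2))
  phasor_point(g, s, g_err, s_err)
}

# Phasor of a decay_model under the ideal (delta-IRF) periodic geometry:
# the alpha_i * tau_i intensity-weighted mixture of closed-form component
# phasors. Used for noiseless trajectories and as ground truth in tests.
phasor_from_model <- function(model, omega) {
  pts <- lapply(model$lifetimes_ns, phasor_from_lifetime, omega = omega)
  mixture_phasor(pts, model$amplitudes * model$lifetimes_ns)
}

#' Bootstrap phasor uncertainty of a decay histogram
#'
#' Estimates 2-sigma error bars on (g, s) by parametric Poisson resampling:
#' replicate histograms are drawn with per-bin means equal to the observed
#' counts, the phasor of each replicate is computed, and the error bars are
#' twice the standard deviation over replicates. This emulates the scatter of
#' technical repeats of the same specimen.
#'
#' @param hist A [decay_histogram()].
#' @param n_replicates Number of Poisson replicates (>= 10; default 50).
#' @param seed Integer seed (resampling is deterministic given the seed).
#' @return A [phasor_point()] centered on the observed phasor, with `g_err`
#'   and `s_err` filled in.
#' @export
phasor_uncertainty <- function(hist, n_replicates = 50L, seed) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (!is.numeric(n_replicates) || n_replicates < 10) {
    stop("`n_replicates` must be >= 10", call. = FALSE)
  }
  center <- phasor_from_histogram(hist)
  omega <- hist$config$angular_frequency
  t <- hist$bin_centers_ns
  cs <- cos(omega * t)
  sn <- sin(omega * t)
  gs <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      counts <- stats::rpois(length(t), hist$counts)
      tot <- sum(counts)
      if (tot == 0) c(NA_real_, NA_real_) else
        c(sum(counts * cs), sum(counts * sn)) / tot
    }, numeric(2))
  })
  g_err <- 2 * stats::sd(gs[1, ], na.rm = TRUE)
  s_err <- 2 * stats::sd(gs[2, ], na.rm = TRUE)
  phasor_point(center$g, center$s, g_err, s_err, meta = hist$meta)
}

#' Distance of a phasor point from the universal-circle center
#'
#' The universal circle has center (1/2, 0) and radius 1/2; monoexponential
#' decays lie exactly on it and multi-exponential mixtures strictly inside.
#'
#' @param p A [phasor_point()].
#' @return Euclidean distance of (g, s) from (1/2, 0).
#' @export
universal_circle_distance <- function(p) {
  stopifnot(inherits(p, "phasor_point"))
  sqrt((p$g - 0.5)^2 + p$s^2)
}
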