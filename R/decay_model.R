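#' Multi-exponential decay model
#'
#' A fluorescence decay is modelled as \eqn{I(t) = \sum_i \alpha_i
#' e^{-t/\tau_i}}: `n` exponential components with nonnegative amplitudes
#' \eqn{\alpha_i} and positive lifetimes \eqn{\tau_i} (ns). Components are
#' stored sorted by ascending lifetime.
#'
#' @param amplitudes Nonnegative numeric vector of component amplitudes; at
#'   least one must be positive.
#' @param lifetimes_ns Positive numeric vector of component lifetimes (ns),
#'   same length as `amplitudes`.
#' @return An object of class `decay_model` with fields `amplitudes`,
#'   `lifetimes_ns` and `n`.
#' @examples
#' m <- decay_model(c(0.6, 0.4), c(0.3, 2.0))
#' amplitude_weighted_lifetime(m)
#' @export
decay_model <- function(amplitudes, lifetimes_ns) {
  if (length(amplitudes) != length(lifetimes_ns) || length(amplitudes) < 1L) {
    stop("amplitudes and lifetimes_ns must be equal-length, non-empty",
         call. = FALSE)
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop("amplitudes must be finite and >= 0", call. = FALSE)
  }
  if (all(amplitudes == 0)) {
    stop("at least one amplitude must be > 0", call. = FALSE)
  }
  if (any(!is.finite(lifetimes_ns)) || any(lifetimes_ns <= 0)) {
    stop("lifetimes must be finite and > 0", call. = FALSE)
  }
  ord <- order(lifetimes_ns)
  structure(
    list(
      amplitudes = as.numeric(amplitudes[ord]),
      lifetimes_ns = as.numeric(lifetimes_ns[ord]),
      n = length(amplitudes)
    ),
    class = "decay_model"
  )
}

#' @export
print.decay_model <- function(x, ...) {
  cat(sprintf("<decay_model> n = %d\n", x$n))
  for (i in seq_len(x$n)) {
    cat(sprintf("  alpha = %.4g, tau = %.4g ns\n",
                x$amplitudes[i], x$lifetimes_ns[i]))
  }
  cat(sprintf("  tau_m = %.4g ns\n", amplitude_weighted_lifetime(x)))
  invisible(x)
}

#' Amplitude-weighted mean lifetime
#'
#' Computes \eqn{\tau_m = \sum_i \alpha_i \tau_i / \sum_i \alpha_i}, the
#' amplitude-weighted mean lifetime of a multi-exponential decay model. This
#' is the summary lifetime reported for molecular-rotor dyes during
#' aggregation; it is invariant to rescaling all amplitudes and always lies
#' between the shortest and longest component lifetime.
#'
#' @param model A [decay_model()].
#' @return The amplitude-weighted mean lifetime in ns.
#' @export
amplitude_weighted_lifetime <- function(model) {
  stopifnot(inherits(model, "decay_model"))
  s <- sum(model$amplitudes)
  if (s <= 0) stop("sum of amplitudes must be > 0", call. = FALSE)
  sum(model$amplitudes * model$lifetimes_ns) / s
}

# Merge components whose lifetime ratio is below `ratio` (amplitudes summed,
# lifetime amplitude-weighted). Used post-fit so that near-degenerate
# components are reported as one.
merge_close_components <- function(model, ratio = 1.2) {
  a <- model$amplitudes
  tau <- model$lifetimes_ns
  repeat {
    if (length(tau) == 1L) break
    r <- tau[-1] / tau[-length(tau)] # sorted ascending, >= 1
    i <- which(r < ratio)
    if (length(i) == 0L) break
    i <- i[1]
    w <- a[i] + a[i + 1]
    tmerged <- if (w > 0) (a[i] * tau[i] + a[i + 1] * tau[i + 1]) / w else
      (tau[i] + tau[i + 1]) / 2
    a <- c(a[seq_len(i - 1)], w, a[-seq_len(i + 1)])
    tau <- c(tau[seq_len(i - 1)], tmerged, tau[-seq_len(i + 1)])
  }
  decay_model(a, tau)
}
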