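#' Fit result of a multi-exponential reconvolution fit
#'
#' @description Container returned by [fit_decay()] and [select_model()]:
#' the fitted [decay_model()], the amplitude-weighted mean lifetime, the
#' reduced chi-square, the fitted constant background, the free-parameter
#' count and a convergence flag.
#' @name fit_result
NULL

new_fit_result <- function(model, tau_m, chi2_reduced, n_free, converged,
                           background, fit_from_bin, n_requested) {
  structure(
    list(model = model, tau_m = tau_m, chi2_reduced = chi2_reduced,
         n_free = n_free, converged = converged, background = background,
         fit_from_bin = fit_from_bin, n_requested = n_requested),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> n = %d, tau_m = %.4g ns, chi2_red = %.4g, converged = %s\n",
    x$model$n, x$tau_m, x$chi2_reduced, x$converged))
  invisible(x)
}

# Residuals for weighted least squares with Neyman weights 1/max(counts, 1).
# `comp_curves` returns the per-component unit-amplitude periodic curves
# convolved with the IRF, so the model curve is their amplitude combination
# plus a constant background.
fit_residual_fn <- function(counts_fit, weights_sqrt_inv, config, irf_fft,
                            idx_fit, n) {
  t <- config$bin_centers_ns
  period <- config$window_ns
  function(par) {
    alphas <- par[seq_len(n)]
    taus <- par[n + seq_len(n)]
    bg <- par[2 * n + 1]
    curve <- numeric(config$n_bins)
    for (i in seq_len(n)) {
      comp <- exp(-t / taus[i]) / (1 - exp(-period / taus[i]))
      curve <- curve + alphas[i] * comp
    }
    curve <- circular_convolve(curve, NULL, irf_fft = irf_fft) + bg
    (counts_fit - curve[idx_fit]) * weights_sqrt_inv
  }
}

# Multi-start lifetime grids spanning [0.05, 5] ns.
start_taus <- function(n) {
  if (n == 1L) {
    lapply(c(0.05, 0.15, 0.45, 1.4, 5), function(x) x)
  } else if (n == 2L) {
    g <- c(0.05, 0.3, 1.2, 5)
    out <- list()
    for (i in 1:3) for (j in (i + 1):4) out <- c(out, list(c(g[i], g[j])))
    out
  } else {
    list(c(0.05, 0.3, 1.5), c(0.05, 0.5, 3), c(0.1, 0.7, 2.5),
         c(0.15, 1, 5), c(0.3, 1.2, 4), c(0.05, 1, 5))
  }
}

#' Fit a mono-, bi- or tri-exponential reconvolution model to a decay
#'
#' Performs weighted least squares of the expected periodic-excitation curve
#' (decay model convolved with the IRF) plus a constant background against a
#' measured histogram. Weights are Neyman weights \eqn{1/\max(c_k, 1)}.
#' By default all bins from the IRF peak bin onward are fitted, which avoids
#' rising-edge sensitivity. When no initial model is supplied a multi-start
#' grid of lifetimes spanning 0.05–5 ns is used and the best chi-square wins
#' (ties broken by fewer free parameters). Amplitudes are constrained >= 0,
#' lifetimes > 0, background >= 0. Fitted components whose lifetime ratio is
#' below 1.2 are merged before reporting.
#'
#' @param hist A [decay_histogram()] with total counts >= 100.
#' @param irf An [irf_profile()] on the same binning.
#' @param n Number of exponential components, 1, 2 or 3.
#' @param init Optional [decay_model()] used as the single starting point.
#' @param seed Integer seed (reserved for reproducibility of any randomized
#'   start jitter; the default grid is deterministic).
#' @param fit_from_peak If `TRUE` (default), fit from the IRF argmax bin to
#'   the end of the window; if `FALSE`, fit the whole period.
#' @param extra_starts Optional list of n-component [decay_model()]s appended
#'   to the multi-start grid (used by [select_model()] to nest model orders).
#' @return A `fit_result` (see [fit_result]); if no start converges the best
#'   attempt is returned with `converged = FALSE` rather than an error.
#' @export
fit_decay <- function(hist, irf, n, init = NULL, seed = 1L,
                      fit_from_peak = TRUE, extra_starts = list()) {
  stopifnot(inherits(hist, "decay_histogram"), inherits(irf, "irf_profile"))
  if (!n %in% 1:3) stop("`n` must be 1, 2 or 3", call. = FALSE)
  if (!same_binning(irf$config, hist$config)) {
    stop("IRF and histogram binning differ", call. = FALSE)
  }
  if (sum(hist$counts) < 100) {
    stop("insufficient counts for fitting (need >= 100)", call. = FALSE)
  }
  config <- hist$config
  idx_fit <- if (fit_from_peak) {
    seq.int(which.max(irf$weights), config$n_bins)
  } else {
    seq_len(config$n_bins)
  }
  counts_fit <- hist$counts[idx_fit]
  wsi <- 1 / sqrt(pmax(counts_fit, 1))
  irf_fft <- stats::fft(irf$weights)
  resid_fn <- fit_residual_fn(counts_fit, wsi, config, irf_fft, idx_fit, n)

  total <- sum(counts_fit)
  starts <- if (!is.null(init)) {
    stopifnot(inherits(init, "decay_model"))
    if (init$n != n) stop("`init` must have n components", call. = FALSE)
    list(list(alphas = init$amplitudes, taus = init$lifetimes_ns))
  } else {
    lapply(start_taus(n), function(taus) {
      # scale each start amplitude so the start curve roughly matches totals
      s <- vapply(taus, function(tau) {
        sum(exp(-config$bin_centers_ns[idx_fit] / tau)) /
          (1 - exp(-config$window_ns / tau))
      }, numeric(1))
      list(alphas = total / (n * pmax(s, 1e-12)), taus = taus)
    })
  }
  for (es in extra_starts) {
    if (inherits(es, "decay_model") && es$n == n) {
      starts <- c(starts, list(list(alphas = es$amplitudes,
                                    taus = es$lifetimes_ns)))
    }
  }

  lower <- c(rep(0, n), rep(1e-3, n), 0)
  upper <- c(rep(Inf, n), rep(20 * config$window_ns, n), max(counts_fit) + 1)
  best <- NULL
  for (st in starts) {
    par0 <- c(st$alphas, st$taus, 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200, ptol = 1e-10,
                                             ftol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    chi2 <- sum(fit$fvec^2)
    ok <- fit$info %in% 1:4
    if (is.null(best) || chi2 < best$chi2 - 1e-12 * best$chi2) {
      best <- list(fit = fit, chi2 = chi2, ok = ok)
    }
  }
  if (is.null(best)) {
    # every start errored out: report the first start, flagged
    st <- starts[[1]]
    model <- decay_model(pmax(st$alphas, 1e-12), st$taus)
    return(new_fit_result(model, amplitude_weighted_lifetime(model), Inf,
                          2 * n + 1, FALSE, 0, idx_fit[1], n))
  }
  par <- best$fit$par
  alphas <- pmax(par[seq_len(n)], 0)
  if (all(alphas == 0)) alphas[1] <- 1e-12
  taus <- par[n + seq_len(n)]
  model <- merge_close_components(decay_model(alphas, taus))
  n_free <- 2 * n + 1
  chi2_red <- best$chi2 / max(length(idx_fit) - n_free, 1)
  new_fit_result(model, amplitude_weighted_lifetime(model), chi2_red, n_free,
                 best$ok, par[2 * n + 1], idx_fit[1], n)
}

#' Select the number of decay components
#'
#' Fits 1-, 2- and (optionally) 3-component reconvolution models and picks
#' the most parsimonious adequate one: the smallest n whose reduced
#' chi-square is below `chi2_threshold`; failing that, the smallest n beyond
#' which adding a component improves the reduced chi-square by less than
#' `min_improvement` (relative); failing that, `max_n`.
#'
#' @inheritParams fit_decay
#' The n-component search additionally starts from the best (n-1)-component
#' fit padded with a vanishing extra component, so the reduced chi-square is
#' non-increasing in n (up to optimizer tolerance).
#'
#' @param max_n Largest component count to consider (1–3, default 3).
#' @param chi2_threshold Adequacy threshold on reduced chi-square
#'   (default 1.3).
#' @param min_improvement Minimum relative chi-square improvement that
#'   justifies one more component (default 0.05).
#' @return The selected `fit_result`; all candidate reduced chi-squares are
#'   attached as attribute `"chi2_by_n"`.
#' @export
select_model <- function(hist, irf, max_n = 3L, seed = 1L,
                         chi2_threshold = 1.3, min_improvement = 0.05,
                         fit_from_peak = TRUE) {
  if (!max_n %in% 1:3) stop("`max_n` must be 1, 2 or 3", call. = FALSE)
  fits <- vector("list", max_n)
  for (k in seq_len(max_n)) {
    extra <- list()
    if (k > 1) {
      prev <- fits[[k - 1]]$model
      # pad the previous best fit with a vanishing component so that the
      # k-component chi-square can never exceed the (k-1)-component one
      pad <- 0.05
      if (min(prev$lifetimes_ns) / pad < 1.5) pad <- 2 * max(prev$lifetimes_ns)
      a <- prev$amplitudes
      tau <- prev$lifetimes_ns
      while (length(a) < k) {
        a <- c(a, 1e-9 * sum(prev$amplitudes))
        tau <- c(tau, pad)
        pad <- pad * 1.7
      }
      extra <- list(decay_model(a, tau))
    }
    fits[[k]] <- fit_decay(hist, irf, k, seed = subseed(seed, k),
                           fit_from_peak = fit_from_peak,
                           extra_starts = extra)
  }
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2_reduced")
  pick <- NULL
  for (k in seq_len(max_n)) {
    if (chi2[k] < chi2_threshold) { pick <- k; break }
  }
  if (is.null(pick)) {
    for (k in seq_len(max_n - 1)) {
      if ((chi2[k] - chi2[k + 1]) < min_improvement * chi2[k]) {
        pick <- k
        break
      }
    }
  }
  if (is.null(pick)) pick <- max_n
  out <- fits[[pick]]
  attr(out, "chi2_by_n") <- chi2
  out
}
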