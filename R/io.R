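# Delimited-text readers/writers. Everything is plain text: decay histograms
# and IRFs as commented CSV, tables as headed CSV, configuration as JSON.

fmt_num <- function(x) {
  # lossless double formatting (17 significant digits round-trips exactly)
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write a decay histogram or IRF profile to CSV
#'
#' The format is two columns `time_ns,counts` preceded by comment header
#' lines `# kind=decay|irf`, `# rep_rate_mhz=`, `# n_bins=`, `# window_ns=`
#' and optional `# meta.<key>=` lines. Counts are written as integers for
#' decays and as full-precision reals for IRFs; the round-trip through
#' [read_decay_csv()] is bit-exact.
#'
#' @param obj A [decay_histogram()] or [irf_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(obj, path) {
  is_irf <- inherits(obj, "irf_profile")
  if (!is_irf && !inherits(obj, "decay_histogram")) {
    stop("`obj` must be a decay_histogram or irf_profile", call. = FALSE)
  }
  cfg <- obj$config
  lines <- c(
    sprintf("# kind=%s", if (is_irf) "irf" else "decay"),
    sprintf("# rep_rate_mhz=%s", fmt_num(cfg$rep_rate_mhz)),
    sprintf("# n_bins=%d", cfg$n_bins),
    sprintf("# window_ns=%s", fmt_num(cfg$window_ns))
  )
  meta <- if (is_irf) list() else obj$meta
  for (key in names(meta)) {
    val <- meta[[key]]
    if (length(val) == 1L && (is.numeric(val) || is.character(val) ||
                              is.logical(val))) {
      lines <- c(lines, sprintf("# meta.%s=%s", key,
                                if (is.numeric(val)) fmt_num(val) else
                                  as.character(val)))
    }
  }
  vals <- if (is_irf) obj$weights else obj$counts
  val_str <- if (is_irf) fmt_num(vals) else sprintf("%d", as.integer(vals))
  lines <- c(lines, "time_ns,counts",
             paste(fmt_num(obj$bin_centers_ns), val_str, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a decay histogram or IRF profile from CSV
#'
#' Counterpart of [write_decay_csv()]. The header must carry `kind`,
#' `rep_rate_mhz`, `n_bins` and `window_ns`; rows are validated (counts must
#' be nonnegative, integral for decays; the time column must match the bin
#' centers implied by the header) and errors name the offending line.
#'
#' @param path Input file path.
#' @return A [decay_histogram()] (kind `decay`) or [irf_profile()] (kind
#'   `irf`).
#' @export
read_decay_csv <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    kv <- sub("^#\\s*", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop(sprintf("%s: malformed header at line %d", path, i),
                     call. = FALSE)
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    if (startsWith(key, "meta.")) {
      v <- suppressWarnings(as.numeric(val))
      meta[[substring(key, 6)]] <- if (is.na(v)) val else v
    } else {
      hdr[[key]] <- val
    }
    i <- i + 1L
  }
  required <- c("kind", "rep_rate_mhz", "n_bins", "window_ns")
  missing <- setdiff(required, names(hdr))
  if (length(missing) > 0) {
    stop(sprintf("%s: header missing %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!hdr$kind %in% c("decay", "irf")) {
    stop(sprintf("%s: unknown kind '%s' at header", path, hdr$kind),
         call. = FALSE)
  }
  if (i > length(lines) || lines[i] != "time_ns,counts") {
    stop(sprintf("%s: expected 'time_ns,counts' at line %d", path, i),
         call. = FALSE)
  }
  cfg <- acq_config(rep_rate_mhz = as.numeric(hdr$rep_rate_mhz),
                    n_bins = as.integer(hdr$n_bins),
                    window_ns = as.numeric(hdr$window_ns))
  body <- lines[seq.int(i + 1L, length(lines))]
  if (length(body) != cfg$n_bins) {
    stop(sprintf("%s: expected %d data rows, found %d", path, cfg$n_bins,
                 length(body)), call. = FALSE)
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    stop(sprintf("%s: malformed row at line %d", path, i + bad[1]),
         call. = FALSE)
  }
  tm <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  vals <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  bad <- which(!is.finite(tm) | !is.finite(vals) | vals < 0)
  if (length(bad) > 0) {
    stop(sprintf("%s: invalid time or negative counts at line %d", path,
                 i + bad[1]), call. = FALSE)
  }
  # the time column must agree with the binning the header declares
  expect_t <- cfg$bin_centers_ns
  off <- which(abs(tm - expect_t) > 1e-6 * cfg$bin_width_ns)
  if (length(off) > 0) {
    stop(sprintf(
      "%s: time column inconsistent with header window_ns/n_bins at line %d",
      path, i + off[1]), call. = FALSE)
  }
  if (hdr$kind == "irf") {
    irf_profile(vals, cfg)
  } else {
    bad <- which(vals != round(vals))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-integer decay count at line %d", path,
                   i + bad[1]), call. = FALSE)
    }
    decay_histogram(vals, cfg, meta = meta)
  }
}

#' Write a phasor table to CSV
#'
#' Columns: `meta,g,s,g_err,s_err`, one row per point. `meta` is the point's
#' `meta$label` (or `meta$time_h`) if present, else the row number.
#'
#' @param points List of [phasor_point()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phasor_csv <- function(points, path) {
  rows <- vapply(seq_along(points), function(i) {
    p <- points[[i]]
    lab <- p$meta$label
    if (is.null(lab)) lab <- p$meta$time_h
    if (is.null(lab)) lab <- i
    paste(lab, fmt_num(p$g), fmt_num(p$s), fmt_num(p$g_err), fmt_num(p$s_err),
          sep = ",")
  }, character(1))
  writeLines(c("meta,g,s,g_err,s_err", rows), path)
  invisible(path)
}

#' Write / read a reference phasor set as CSV
#'
#' Columns: `label,concentration_uM,g,s,g_err,s_err`.
#'
#' @param ref A [reference_phasor_set()].
#' @param path File path.
#' @return `write_reference_csv`: `path` invisibly; `read_reference_csv`: a
#'   [reference_phasor_set()].
#' @export
write_reference_csv <- function(ref, path) {
  stopifnot(inherits(ref, "reference_phasor_set"))
  rows <- vapply(seq_along(ref$points), function(i) {
    p <- ref$points[[i]]
    paste(ref$label, fmt_num(ref$concentrations_uM[i]), fmt_num(p$g),
          fmt_num(p$s), fmt_num(p$g_err), fmt_num(p$s_err), sep = ",")
  }, character(1))
  writeLines(c("label,concentration_uM,g,s,g_err,s_err", rows), path)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("label", "concentration_uM", "g", "s", "g_err", "s_err")
  if (!all(needed %in% names(df))) {
    stop(sprintf("%s: reference CSV must have columns %s", path,
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  lab <- unique(df$label)
  if (length(lab) != 1L) {
    stop(sprintf("%s: reference CSV must carry a single label", path),
         call. = FALSE)
  }
  pts <- lapply(seq_len(nrow(df)), function(i) {
    phasor_point(df$g[i], df$s[i], df$g_err[i], df$s_err[i])
  })
  reference_phasor_set(lab, pts, df$concentration_uM)
}

# Fit results table: one row per timepoint with up to three components.
fit_results_table <- function(fits, meta = seq_along(fits)) {
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    a <- rep(NA_real_, 3)
    tau <- rep(NA_real_, 3)
    a[seq_len(f$model$n)] <- f$model$amplitudes
    tau[seq_len(f$model$n)] <- f$model$lifetimes_ns
    data.frame(meta = meta[i], n = f$model$n,
               alpha1 = a[1], tau1_ns = tau[1],
               alpha2 = a[2], tau2_ns = tau[2],
               alpha3 = a[3], tau3_ns = tau[3],
               tau_m_ns = f$tau_m, chi2_reduced = f$chi2_reduced,
               converged = f$converged)
  })
  do.call(rbind, rows)
}

write_table_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 12, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
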