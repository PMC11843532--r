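#' Pipeline run configuration
#'
#' Collects everything a full analysis run needs: either a phenotype preset
#' name or explicit kinetic parameters + optical profile, the acquisition
#' geometry, the timepoint grid, photon budget, seed, and the classification
#' and onset parameters. Fully serializable to/from JSON with
#' [write_run_config()] / [read_run_config()].
#'
#' @param preset_name One of `"wt_like"`, `"a30p_like"`, `"dp1_like"`, or
#'   `NULL` when `params` and `profile` are given explicitly.
#' @param params,profile Explicit [kinetic_params()] and [optical_profile()]
#'   (ignored when `preset_name` is set).
#' @param m0 Initial monomer concentration (uM).
#' @param rep_rate_mhz,n_bins,window_ns Acquisition geometry (see
#'   [acq_config()]); the pipeline default of 1024 bins keeps per-timepoint
#'   fits fast while leaving the phasor discretization error far below the
#'   bootstrap error bars.
#' @param timepoints_h Timepoint grid (hours).
#' @param photons_per_timepoint Photon budget per simulated decay.
#' @param seed Run-level seed; all stage seeds are fanned out from it with
#'   [subseed()].
#' @param irf_fwhm_ns,irf_center_ns Gaussian IRF shape.
#' @param max_n Largest component count for [select_model()].
#' @param window,threshold,deviation_threshold Classification parameters
#'   (see [assign_regions()]).
#' @param n_replicates Bootstrap replicates for phasor error bars.
#' @param reference_photons Photon budget per titration reference point.
#' @param reference_fractions Photon fractions of the titrated species in the
#'   simulated reference sets.
#' @param input_dir Optional directory of externally supplied decay CSVs with
#'   a `manifest.json`; when set, ingestion replaces simulation (see
#'   [run_pipeline()]).
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(preset_name = "wt_like", params = NULL, profile = NULL,
                       m0 = 100,
                       rep_rate_mhz = 80, n_bins = 1024L,
                       window_ns = 1000 / rep_rate_mhz,
                       timepoints_h = seq(0, 120, by = 1),
                       photons_per_timepoint = 5e5,
                       seed = 1L,
                       irf_fwhm_ns = 0.2, irf_center_ns = 1,
                       max_n = 3L,
                       window = 5L, threshold = 0.60,
                       deviation_threshold = 0.40,
                       n_replicates = 50L,
                       reference_photons = 1000,
                       reference_fractions = seq(0.35, 1, length.out = 40),
                       input_dir = NULL) {
  if (is.null(preset_name) && (is.null(params) || is.null(profile))) {
    stop("give either `preset_name` or both `params` and `profile`",
         call. = FALSE)
  }
  if (length(timepoints_h) == 0L) {
    stop("`timepoints_h` must not be empty", call. = FALSE)
  }
  cfg <- list(
    preset_name = preset_name, params = params, profile = profile, m0 = m0,
    rep_rate_mhz = rep_rate_mhz, n_bins = as.integer(n_bins),
    window_ns = window_ns, timepoints_h = as.numeric(timepoints_h),
    photons_per_timepoint = photons_per_timepoint, seed = as.integer(seed),
    irf_fwhm_ns = irf_fwhm_ns, irf_center_ns = irf_center_ns,
    max_n = as.integer(max_n), window = as.integer(window),
    threshold = threshold, deviation_threshold = deviation_threshold,
    n_replicates = as.integer(n_replicates),
    reference_photons = reference_photons,
    reference_fractions = as.numeric(reference_fractions),
    input_dir = input_dir
  )
  structure(cfg, class = "run_config")
}

config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$params)) out$params <- unclass(out$params)
  if (!is.null(out$profile)) {
    pr <- out$profile
    out$profile <- list(
      decays = lapply(pr$decays, function(d) {
        list(amplitudes = d$amplitudes, lifetimes_ns = d$lifetimes_ns)
      }),
      photon_weights = as.list(pr$photon_weights),
      intensity_brightness = as.list(pr$intensity_brightness)
    )
  }
  out
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  # digits = 17 guarantees a lossless double round-trip
  jsonlite::write_json(config_to_list(config), path, auto_unbox = TRUE,
                       digits = 17, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- if (!is.null(x$params)) {
    kinetic_params(x$params$k1, x$params$k2, x$params$k3,
                   if (is.null(x$params$ke)) 0 else x$params$ke)
  }
  profile <- if (!is.null(x$profile)) {
    optical_profile(
      decays = lapply(x$profile$decays, function(d) {
        decay_model(d$amplitudes, d$lifetimes_ns)
      }),
      photon_weights = unlist(x$profile$photon_weights),
      intensity_brightness = unlist(x$profile$intensity_brightness)
    )
  }
  run_config(
    preset_name = x$preset_name, params = params, profile = profile,
    m0 = x$m0, rep_rate_mhz = x$rep_rate_mhz, n_bins = x$n_bins,
    window_ns = x$window_ns, timepoints_h = x$timepoints_h,
    photons_per_timepoint = x$photons_per_timepoint, seed = x$seed,
    irf_fwhm_ns = x$irf_fwhm_ns, irf_center_ns = x$irf_center_ns,
    max_n = x$max_n, window = x$window, threshold = x$threshold,
    deviation_threshold = x$deviation_threshold,
    n_replicates = x$n_replicates,
    reference_photons = x$reference_photons,
    reference_fractions = x$reference_fractions,
    input_dir = x$input_dir
  )
}

resolve_model_spec <- function(config) {
  if (!is.null(config$preset_name)) {
    p <- preset(config$preset_name)
    list(params = p$params, profile = p$profile, m0 = p$m0,
         name = p$name)
  } else {
    list(params = config$params, profile = config$profile, m0 = config$m0,
         name = "custom")
  }
}

ingest_decays <- function(input_dir, acq) {
  manifest_path <- file.path(input_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("ingestion requires ", manifest_path, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  irf <- read_decay_csv(file.path(input_dir, man$irf))
  if (!same_binning(irf$config, acq)) {
    stop("ingested IRF binning differs from the run configuration",
         call. = FALSE)
  }
  tps <- man$timepoints
  time_h <- vapply(tps, function(x) as.numeric(x$time_h), numeric(1))
  intensity <- vapply(tps, function(x) as.numeric(x$intensity), numeric(1))
  decays <- lapply(tps, function(x) {
    h <- read_decay_csv(file.path(input_dir, x$decay))
    if (!same_binning(h$config, acq)) {
      stop("ingested decay binning differs from the run configuration",
           call. = FALSE)
    }
    h
  })
  list(time_h = time_h, intensity = intensity, decays = decays, irf = irf)
}

#' Run the full aggregation-analysis pipeline
#'
#' Executes, in order: data acquisition (simulate an aggregation experiment
#' from the configured preset, or ingest externally supplied decay CSVs),
#' per-timepoint model-order selection and reconvolution fitting (giving the
#' fitted amplitude-weighted mean lifetime), phasor computation with
#' bootstrap 2-sigma error bars, titration-reference simulation, region
#' classification of the phasor trajectory, and the kinetics summary. All
#' outputs are written as CSV under `out_dir` together with the JSON
#' configuration (stamped with a hash) and a stage log; every stage's seed
#' derives from the run seed, so a run is byte-reproducible.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress console stage messages (default TRUE).
#' @return Invisibly, a list with the in-memory results (`trace`, `fits`,
#'   `phasors`, `regions`, `kinetics`, `references`) and `paths` of all files
#'   written.
#' @export
run_pipeline <- function(config, out_dir, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (length(config$timepoints_h) == 0L) {
    stop("pipeline: configuration has zero timepoints", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  t_start <- proc.time()[["elapsed"]]
  # the log file must be byte-reproducible, so wall-clock timings go to the
  # console only
  stage <- function(msg) {
    log_lines <<- c(log_lines, msg)
    if (!quiet) {
      message(sprintf("[%8.2fs] %s", proc.time()[["elapsed"]] - t_start, msg))
    }
  }
  fail <- function(stage_name, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage_name,
                 conditionMessage(e)), call. = FALSE)
  }

  acq <- acq_config(config$rep_rate_mhz, config$n_bins, config$window_ns)
  spec <- resolve_model_spec(config)
  irf <- make_gaussian_irf(config$irf_fwhm_ns, config$irf_center_ns, acq)

  # --- acquire ---
  if (is.null(config$input_dir)) {
    trace <- tryCatch(
      simulate_experiment(spec$params, spec$profile, config$timepoints_h,
                          acq, config$photons_per_timepoint,
                          seed = config$seed, irf = irf, m0 = spec$m0),
      error = function(e) fail("simulate", e))
    stage(sprintf("simulate: preset=%s, %d timepoints, %g photons each",
                  spec$name, length(trace$time_h),
                  config$photons_per_timepoint))
  } else {
    ing <- tryCatch(ingest_decays(config$input_dir, acq),
                    error = function(e) fail("ingest", e))
    trace <- list(time_h = ing$time_h, decays = ing$decays,
                  intensity = ing$intensity)
    irf <- ing$irf
    stage(sprintf("ingest: %d timepoints from %s", length(ing$time_h),
                  config$input_dir))
  }
  if (is.null(trace$decays)) {
    stop("pipeline stage 'acquire' failed: no decays ",
         "(photons_per_timepoint must be > 0)", call. = FALSE)
  }
  n_t <- length(trace$time_h)

  # --- fit ---
  fits <- tryCatch(
    lapply(seq_len(n_t), function(i) {
      select_model(trace$decays[[i]], irf, max_n = config$max_n,
                   seed = subseed(config$seed, 100000 + i))
    }),
    error = function(e) fail("fit", e))
  tau_m_fit <- vapply(fits, `[[`, numeric(1), "tau_m")
  stage(sprintf("fit: %d decays, model orders %s", n_t,
                paste(range(vapply(fits, function(f) f$model$n, numeric(1))),
                      collapse = "-")))

  # --- phasor ---
  phasors <- tryCatch(
    lapply(seq_len(n_t), function(i) {
      phasor_uncertainty(trace$decays[[i]],
                         n_replicates = config$n_replicates,
                         seed = subseed(config$seed, 200000 + i))
    }),
    error = function(e) fail("phasor", e))
  stage(sprintf("phasor: %d points with %d-replicate bootstrap errors",
                n_t, config$n_replicates))

  # --- references ---
  ref_profile <- spec$profile
  if (is.null(ref_profile)) {
    stop("pipeline stage 'references' failed: ingestion runs still need a ",
         "profile (preset or explicit) to build reference sets",
         call. = FALSE)
  }
  fib_ref <- tryCatch(
    simulate_reference_set("fibril", ref_profile, acq, irf = irf,
                           fractions = config$reference_fractions,
                           photons = config$reference_photons,
                           n_replicates = config$n_replicates,
                           seed = subseed(config$seed, 300000)),
    error = function(e) fail("references", e))
  oli_ref <- tryCatch(
    simulate_reference_set("typeB", ref_profile, acq, irf = irf,
                           fractions = config$reference_fractions,
                           photons = config$reference_photons,
                           n_replicates = config$n_replicates,
                           seed = subseed(config$seed, 400000)),
    error = function(e) fail("references", e))
  stage(sprintf("references: fibril + stabilized-oligomer, %d points each",
                length(fib_ref$points)))

  # --- classify ---
  regions <- tryCatch(
    assign_regions(phasors, fib_ref, oli_ref, window = config$window,
                   threshold = config$threshold,
                   deviation_threshold = config$deviation_threshold),
    error = function(e) fail("classify", e))
  region_per_point <- character(n_t)
  for (r in seq_len(nrow(regions))) {
    region_per_point[seq.int(regions$segment_start[r],
                             regions$segment_end[r])] <- regions$label[r]
  }
  stage(sprintf("classify: %d segments (%s)", nrow(regions),
                paste(unique(regions$label), collapse = " -> ")))

  # --- kinetics ---
  kin_trace <- list(time_h = trace$time_h, tau_m = tau_m_fit,
                    intensity = trace$intensity)
  kinetics <- tryCatch(kinetics_summary(kin_trace),
                       error = function(e) fail("kinetics", e))
  stage(sprintf("kinetics: tau_m onset %.3g h, intensity t50 %.3g h",
                kinetics$tau_m_onset_h, kinetics$intensity_t50_h))

  # --- write outputs ---
  cfg_json <- jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE,
                               digits = 17, null = "null")
  cfg_hash <- fnv1a32(as.character(cfg_json))
  paths <- list(
    config = file.path(out_dir, "config.json"),
    trace = file.path(out_dir, "trace.csv"),
    fits = file.path(out_dir, "fits.csv"),
    phasors = file.path(out_dir, "phasors.csv"),
    regions = file.path(out_dir, "regions.csv"),
    kinetics = file.path(out_dir, "kinetics.csv"),
    reference_fibril = file.path(out_dir, "reference_fibril.csv"),
    reference_oligomer = file.path(out_dir, "reference_oligomer.csv"),
    log = file.path(out_dir, "log.txt")
  )
  write_run_config(config, paths$config)
  trace_df <- data.frame(
    time_h = trace$time_h,
    intensity = trace$intensity,
    tau_m_ns = tau_m_fit,
    g = vapply(phasors, `[[`, numeric(1), "g"),
    s = vapply(phasors, `[[`, numeric(1), "s"),
    g_err = vapply(phasors, `[[`, numeric(1), "g_err"),
    s_err = vapply(phasors, `[[`, numeric(1), "s_err"),
    region = region_per_point
  )
  write_table_csv(trace_df, paths$trace)
  write_table_csv(fit_results_table(fits, meta = trace$time_h), paths$fits)
  write_phasor_csv(phasors, paths$phasors)
  write_table_csv(regions, paths$regions)
  kin_out <- cbind(data.frame(variant = spec$name), kinetics,
                   config_hash = cfg_hash, seed = config$seed)
  write_table_csv(kin_out, paths$kinetics)
  write_reference_csv(fib_ref, paths$reference_fibril)
  write_reference_csv(oli_ref, paths$reference_oligomer)
  stage(sprintf("write: %d output files (config hash %s)", length(paths),
                cfg_hash))
  writeLines(c(sprintf("# synflim pipeline log, config hash %s, seed %d",
                       cfg_hash, config$seed), log_lines), paths$log)

  invisible(list(trace = trace_df, fits = fits, phasors = phasors,
                 regions = regions, kinetics = kin_out,
                 references = list(fibril = fib_ref, oligomer = oli_ref),
                 config_hash = cfg_hash, paths = paths))
}
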