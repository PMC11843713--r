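#' Process a coincidence stream into per-event records
#'
#' Runs the full readout chain on every event of a simulated stream:
#' optional optical crosstalk at the arrival level, waveform rendering for
#' both pixels, optional electronic crosstalk at the waveform level,
#' leading-edge timestamping, adaptive pickoff, early-signal charge
#' integration, single-photon-grid calibration and quantization, the
#' trigger-time-window zeroing rule, and the merged energy integral with
#' photopeak-anchored energy calibration.
#'
#' @param stream A [simulate_coincidence_stream()] result.
#' @param template SPAD pulse template (default segmented,
#'   [single_spad_template()]).
#' @param threshold Leading-edge threshold in mV (default 13, half the
#'   segmented single-SPAD amplitude).
#' @param k Adaptive pickoff margin in ps (default 0).
#' @param dt Sampling step in ps (default 80, i.e. 12.5 GS/s).
#' @param trace_start,trace_end Trace window in ps relative to the
#'   interaction time (defaults -2000 and 30000).
#' @param noise_sigma Waveform noise in mV (default 1).
#' @param crosstalk Optional [crosstalk_config()]; `NULL` disables both
#'   mechanisms.
#' @param integration_window Early-integration window in ps (default 1000).
#' @param trigger_window Trigger time window for the zeroing rule in ps
#'   (default 300).
#' @param start_mode Where the integration window starts: each pixel's own
#'   trigger (`"own_trigger"`, default) or the earlier of the two triggers
#'   (`"earlier_trigger"`).
#' @param seed Optional integer seed (noise and crosstalk draws).
#'
#' @return A data.frame of event records with one row per coincidence:
#'   timestamps (`T_A_ps`, `T_B_ps`, `T_adaptive_ps`, `delta_T_ps`),
#'   charges (`charge_A`, `charge_B`, `energy_integral`), calibrated
#'   energy (`energy_keV`), photon counts (`n_A`, `n_B`, `n_total`,
#'   `zeroed`), and the generation columns. The estimated
#'   single-photon charge and energy factor are attached as attributes
#'   `single_photon_charge` and `energy_factor`.
#' @export
process_events <- function(stream,
                           template = single_spad_template(),
                           threshold = 13, k = 0, dt = 80,
                           trace_start = -2000, trace_end = 30000,
                           noise_sigma = 1, crosstalk = NULL,
                           integration_window = 1000, trigger_window = 300,
                           start_mode = c("own_trigger", "earlier_trigger"),
                           seed = NULL) {
  stopifnot(inherits(stream, "coincidence_stream"))
  start_mode <- match.arg(start_mode)
  events <- stream$events
  arr <- stream$arrivals
  n <- nrow(events)
  n_samples <- ceiling((trace_end - trace_start) / dt)
  xt <- crosstalk
  optical_on <- !is.null(xt) && xt$optical_prob > 0
  electronic_on <- !is.null(xt) && xt$electronic_amplitude_fraction > 0
  L <- stream$config$crystal_length

  id_f <- factor(arr$event_id, levels = events$event_id)
  t_by_ev <- split(arr$time_ps, id_f)
  p_by_ev <- split(arr$pixel, id_f)
  o_by_ev <- split(arr$origin, id_f)

  T_A <- T_B <- charge_A <- charge_B <- e_int <- rep(NA_real_, n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      times <- t_by_ev[[i]]
      pix <- p_by_ev[[i]]
      a <- times[pix == "A"]
      b <- times[pix == "B"]
      if (optical_on) {
        org <- o_by_ev[[i]]
        inj <- inject_optical_crosstalk(
          data.frame(time_ps = a, origin = org[pix == "A"],
                     stringsAsFactors = FALSE),
          data.frame(time_ps = b, origin = org[pix == "B"],
                     stringsAsFactors = FALSE),
          xt, L)
        a <- inj$arrivals_A$time_ps
        b <- inj$arrivals_B$time_ps
      }
      t0 <- events$interaction_time_ps[i] + trace_start
      wa <- render_waveform(a, template, t0 = t0, n_samples = n_samples,
                            dt = dt, noise_sigma = noise_sigma)
      wb <- render_waveform(b, template, t0 = t0, n_samples = n_samples,
                            dt = dt, noise_sigma = noise_sigma)
      if (electronic_on) {
        onsets <- list(A = if (length(a)) min(a) else NA_real_,
                       B = if (length(b)) min(b) else NA_real_)
        w <- inject_electronic_crosstalk(wa, wb, onsets, xt, template)
        wa <- w$A; wb <- w$B
      }
      T_A[i] <- leading_edge_timestamp(wa, threshold)
      T_B[i] <- leading_edge_timestamp(wb, threshold)
      start_a <- T_A[i]; start_b <- T_B[i]
      if (start_mode == "earlier_trigger") {
        first <- min(c(T_A[i], T_B[i]), na.rm = TRUE)
        if (is.finite(first)) start_a <- start_b <- first
      }
      charge_A[i] <- integrate_initial(wa, start_a, integration_window)
      charge_B[i] <- integrate_initial(wb, start_b, integration_window)
      e_int[i] <- merged_energy_integral(wa, wb)
    }
  })

  spc <- tryCatch(
    calibrate_single_photon_charge(c(charge_A, charge_B)),
    error = function(e) NA_real_)
  if (is.finite(spc)) {
    n_A <- quantize_photon_count(charge_A, spc)
    n_B <- quantize_photon_count(charge_B, spc)
  } else {
    n_A <- n_B <- rep(0L, n)
  }
  zeroed <- apply_trigger_time_window(n_A, n_B, T_A, T_B, trigger_window)
  e_factor <- tryCatch(calibrate_energy(e_int), error = function(e) NA_real_)

  out <- data.frame(
    event_id = events$event_id,
    energy_true_keV = events$energy_keV,
    interaction_time_ps = events$interaction_time_ps,
    reference_timestamp_ps = events$reference_timestamp_ps,
    T_A_ps = T_A, T_B_ps = T_B,
    T_adaptive_ps = adaptive_timestamp(T_A, T_B, k),
    delta_T_ps = trigger_time_difference(T_A, T_B),
    threshold_mV = rep(threshold, n), k_ps = rep(k, n),
    charge_A = charge_A, charge_B = charge_B,
    energy_integral = e_int,
    energy_keV = if (is.finite(e_factor)) e_int * e_factor else
      rep(NA_real_, n),
    n_A = zeroed$n_A, n_B = zeroed$n_B,
    n_total = zeroed$n_A + zeroed$n_B,
    zeroed = zeroed$zeroed
  )
  attr(out, "single_photon_charge") <- spc
  attr(out, "energy_factor") <- e_factor
  out
}

# columns every persisted event-record table must carry
EVENT_RECORD_COLUMNS <- c(
  "event_id", "energy_true_keV", "interaction_time_ps",
  "reference_timestamp_ps", "T_A_ps", "T_B_ps", "T_adaptive_ps",
  "delta_T_ps", "threshold_mV", "k_ps", "charge_A", "charge_B",
  "energy_integral", "energy_keV", "n_A", "n_B", "n_total", "zeroed")

#' Read and write event-record tables
#'
#' Event records are persisted as plain CSV with one row per coincidence
#' and a fixed documented header (times in ps, energies in keV, charges in
#' mV*ps). Reading validates the schema and names any missing columns.
#'
#' @param records An event-record data.frame from [process_events()].
#' @param path CSV file path.
#' @return `read_event_records()` returns the validated data.frame;
#'   `write_event_records()` returns `path` invisibly.
#' @export
write_event_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records[intersect(EVENT_RECORD_COLUMNS, names(records))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_records
#' @export
read_event_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(EVENT_RECORD_COLUMNS, names(df))
  if (length(miss) > 0)
    stop("event table schema mismatch; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read and write photon-arrival tables
#'
#' One row per detected photon arrival: `event_id`, `pixel`, `time_ps`,
#' `origin`.
#'
#' @param arrivals Arrival data.frame (see
#'   [simulate_coincidence_stream()]).
#' @param path CSV file path.
#' @return `read_arrivals()` returns the validated data.frame.
#' @export
write_arrivals <- function(arrivals, path) {
  utils::write.csv(arrivals, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arrivals
#' @export
read_arrivals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("event_id", "pixel", "time_ps", "origin"), names(df))
  if (length(miss) > 0)
    stop("arrival table schema mismatch; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read and write waveform tables
#'
#' Waveforms are persisted in a long columnar layout, one row per sample:
#' `event_id`, `pixel`, `t0_ps`, `dt_ps`, `sample_mV`. Samples of one
#' trace are stored contiguously in time order.
#'
#' @param waveforms A data.frame in the long layout, or a named list of
#'   [waveform()] objects (names used as `pixel`, `event_id` taken from
#'   the `event_id` argument).
#' @param path CSV file path.
#' @param event_id Event id used when `waveforms` is a list.
#' @return `read_waveforms()` returns a list of [waveform()] objects named
#'   `"<event_id>.<pixel>"`.
#' @export
write_waveforms <- function(waveforms, path, event_id = 1L) {
  if (is.data.frame(waveforms)) {
    df <- waveforms
  } else {
    blocks <- Map(function(wf, nm) {
      data.frame(event_id = event_id, pixel = nm, t0_ps = wf$t0,
                 dt_ps = wf$dt, sample_mV = wf$samples,
                 stringsAsFactors = FALSE)
    }, waveforms, names(waveforms))
    df <- do.call(rbind, blocks)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms
#' @export
read_waveforms <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("event_id", "pixel", "t0_ps", "dt_ps", "sample_mV"),
                  names(df))
  if (length(miss) > 0)
    stop("waveform table schema mismatch; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  key <- paste(df$event_id, df$pixel, sep = ".")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    waveform(d$sample_mV, t0 = d$t0_ps[1], dt = d$dt_ps[1])
  })
}

#' Simulate, process and persist a run
#'
#' End-to-end simulation entry point: generates a coincidence stream,
#' processes it into event records, and writes `event_records.csv`, an
#' arrival table for the first `n_arrival_events` events, waveform traces
#' for the first `n_waveform_events` events, and a JSON run manifest that
#' snapshots the configuration and seeds so the run can be reproduced
#' bit-for-bit.
#'
#' @param config A [physics_config()].
#' @param n_events Number of coincidences.
#' @param seed Integer seed driving both generation and processing.
#' @param out_dir Output directory (created if needed).
#' @param reference_fwhm Reference detector resolution in ps (default 83).
#' @param crosstalk Optional [crosstalk_config()].
#' @param n_arrival_events,n_waveform_events How many leading events get
#'   their arrivals/waveforms persisted (defaults 100 and 5).
#' @param ... Further arguments passed to [process_events()].
#' @return Invisibly, a list with `records`, `stream` and `manifest`.
#' @export
run_simulate <- function(config, n_events, seed, out_dir,
                         reference_fwhm = 83, crosstalk = NULL,
                         n_arrival_events = 100, n_waveform_events = 5, ...) {
  validate_physics_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  stream <- simulate_coincidence_stream(config, n_events,
                                        reference_fwhm = reference_fwhm,
                                        seed = seed)
  records <- process_events(stream, crosstalk = crosstalk,
                            seed = seed + 1L, ...)
  write_event_records(records, file.path(out_dir, "event_records.csv"))
  arr_sub <- stream$arrivals[stream$arrivals$event_id <= n_arrival_events, ,
                             drop = FALSE]
  write_arrivals(arr_sub, file.path(out_dir, "arrivals.csv"))
  if (n_waveform_events > 0 && n_events > 0) {
    wf_rows <- lapply(seq_len(min(n_waveform_events, n_events)), function(i) {
      sel <- stream$arrivals[stream$arrivals$event_id == i, , drop = FALSE]
      tpl <- single_spad_template()
      t0 <- stream$events$interaction_time_ps[i] - 2000
      ns <- ceiling(32000 / 80)
      blocks <- lapply(c("A", "B"), function(px) {
        wf <- render_waveform(sel$time_ps[sel$pixel == px], tpl, t0 = t0,
                              n_samples = ns, dt = 80)
        data.frame(event_id = i, pixel = px, t0_ps = wf$t0, dt_ps = wf$dt,
                   sample_mV = wf$samples, stringsAsFactors = FALSE)
      })
      do.call(rbind, blocks)
    })
    write_waveforms(do.call(rbind, wf_rows),
                    file.path(out_dir, "waveforms.csv"))
  }
  manifest <- run_manifest(
    stage = "simulate", seed = seed, config = config, crosstalk = crosstalk,
    counts = list(n_events = n_events,
                  n_arrivals = nrow(stream$arrivals),
                  n_triggered_both = sum(!is.na(records$delta_T_ps))),
    outputs = c("event_records.csv", "arrivals.csv",
                if (n_waveform_events > 0 && n_events > 0) "waveforms.csv"))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(records = records, stream = stream, manifest = manifest))
}

#' Analyze a processed event table
#'
#' Applies the energy window, then produces the standard result tables:
#' CTR versus the adaptive margin `k` (`ctr_vs_k.csv`), CTR versus the
#' trigger-time-difference window (`ctr_vs_dtk.csv`), decile timing
#' kernels (`kernel_table.csv`), photon-number kernels
#' (`kernel_by_photon_number.csv`) and per-energy-bin summaries
#' (`tdiff_by_energy.csv`), plus a manifest recording the input/output
#' event counts of every filter stage.
#'
#' @param events An event-record data.frame or a path to an
#'   `event_records.csv`.
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param k_grid,dtk_grid Sweep grids in ps (defaults as in [ctr_vs_k()]
#'   and [ctr_vs_dtk()]).
#' @param quiet Suppress the per-stage count messages (default `FALSE`).
#' @return Invisibly, a list with the result tables and the manifest.
#' @export
run_analyze <- function(events, config = analysis_config(), out_dir = NULL,
                        k_grid = seq(-500, 500, by = 25),
                        dtk_grid = c(seq(50, 1000, by = 50),
                                     seq(1250, 3000, by = 250)),
                        quiet = FALSE) {
  if (is.character(events)) events <- read_event_records(events)
  miss <- setdiff(EVENT_RECORD_COLUMNS, names(events))
  if (length(miss) > 0)
    stop("event table schema mismatch; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  n0 <- nrow(events)
  sel <- energy_window_filter(events, config$energy_window[1],
                              config$energy_window[2])
  say("energy window %g-%g keV: %d -> %d events",
      config$energy_window[1], config$energy_window[2], n0, nrow(sel))
  vk <- ctr_vs_k(sel, k_grid, bin_width = config$bin_width,
                 method = config$fwhm_method)
  vdtk <- ctr_vs_dtk(sel, dtk_grid, bin_width = config$bin_width,
                     method = config$fwhm_method)
  say("delta_T_k selection at %g ps: %d -> %d events", config$delta_T_k,
      nrow(sel), sum(abs(sel$delta_T_ps) <= config$delta_T_k, na.rm = TRUE))
  deciles <- tryCatch(
    classify_deciles(sel, bin_width = config$bin_width,
                     method = config$fwhm_method),
    error = function(e) NULL)
  if (!is.null(deciles))
    say("decile classes: %s events",
        paste(deciles$n_events, collapse = "/"))
  kern_n <- kernels_by_photon_number(sel, bin_width = config$bin_width,
                                     method = config$fwhm_method)
  by_energy <- tdiff_by_energy(events, bin_width = config$bin_width)
  manifest <- run_manifest(
    stage = "analyze", seed = NA, config = config, crosstalk = NULL,
    counts = list(n_input = n0, n_energy_window = nrow(sel),
                  n_delta_T_k = sum(abs(sel$delta_T_ps) <= config$delta_T_k,
                                    na.rm = TRUE)),
    outputs = c("ctr_vs_k.csv", "ctr_vs_dtk.csv", "kernel_table.csv",
                "kernel_by_photon_number.csv", "tdiff_by_energy.csv"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(vk, file.path(out_dir, "ctr_vs_k.csv"),
                     row.names = FALSE)
    utils::write.csv(vdtk, file.path(out_dir, "ctr_vs_dtk.csv"),
                     row.names = FALSE)
    if (!is.null(deciles))
      utils::write.csv(deciles, file.path(out_dir, "kernel_table.csv"),
                       row.names = FALSE)
    utils::write.csv(kern_n,
                     file.path(out_dir, "kernel_by_photon_number.csv"),
                     row.names = FALSE)
    utils::write.csv(by_energy$summary,
                     file.path(out_dir, "tdiff_by_energy.csv"),
                     row.names = FALSE)
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  invisible(list(ctr_vs_k = vk, ctr_vs_dtk = vdtk, deciles = deciles,
                 kernels_by_n = kern_n, by_energy = by_energy$summary,
                 manifest = manifest))
}

run_manifest <- function(stage, seed, config, crosstalk, counts, outputs) {
  list(
    stage = stage,
    package = "segtof",
    version = as.character(utils::packageVersion("segtof")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = if (!is.null(config)) unclass(config),
    crosstalk = if (!is.null(crosstalk)) unclass(crosstalk),
    counts = counts,
    outputs = as.list(outputs)
  )
}

#' Write or read a run manifest
#'
#' Manifests are JSON snapshots of the configuration, seeds and per-stage
#' event counts of a run; rerunning with the recorded seeds reproduces the
#' outputs bit-for-bit.
#'
#' @param manifest A manifest list.
#' @param path JSON file path.
#' @return `read_manifest()` returns the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Generate the bundled test fixtures
#'
#' Writes four tiny seeded datasets (300 events each) that exercise the
#' pipeline's branches: `photopeak` (defaults), `continuum` (Compton
#' spectrum, energy-cut analyses), `crosstalk` (both crosstalk mechanisms
#' on, side peaks and the zeroing rule), and `black_reflector` (absorbing
#' wrap, reduced initial photon counts). Each fixture directory holds an
#' `event_records.csv` and a manifest with the generating seed.
#'
#' @param out_dir Output directory.
#' @param seed Base integer seed (each fixture offsets it).
#' @param n_events Events per fixture (default 300).
#' @return Invisibly, the named list of fixture directories.
#' @export
write_fixture_bundle <- function(out_dir, seed = 20240, n_events = 300) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    photopeak = list(config = physics_config(), crosstalk = NULL),
    continuum = list(config = physics_config(energy_mode = "compton_continuum"),
                     crosstalk = NULL),
    crosstalk = list(config = physics_config(),
                     crosstalk = crosstalk_config(optical_prob = 0.15)),
    black_reflector = list(config = physics_config(reflector_mode = "black"),
                           crosstalk = NULL)
  )
  dirs <- list()
  for (i in seq_along(specs)) {
    nm <- names(specs)[i]
    d <- file.path(out_dir, nm)
    run_simulate(specs[[i]]$config, n_events, seed = seed + i, out_dir = d,
                 crosstalk = specs[[i]]$crosstalk, n_arrival_events = 20,
                 n_waveform_events = 2)
    dirs[[nm]] <- d
  }
  invisible(dirs)
}
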