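#' Default pipeline configuration
#'
#' All tunable parameters of the extraction and analysis pipeline in one
#' validated list: filter design per modality, peak-detection threshold and
#' refractory period, segment-selection quality gate, ectopic screening,
#' spectral estimation, and cohort-statistics settings. Every random draw
#' in the pipeline flows from the single `seed`.
#'
#' @param filter List: `cutoff_ehg` (Hz), `cutoff_ecg` (Hz), `order`.
#' @param detection List: `min_height` (fraction of normalized max),
#'   `refractory` (ms).
#' @param segment List: `duration` (s), `quality_threshold` (max corrected
#'   fraction), `min_beats`.
#' @param ectopic List: `dev_threshold`, `bounds` (ms).
#' @param spectral List: `fs_interp` (Hz), `window_s`, `overlap`, `detrend`.
#' @param stats List: `alpha`, `n_mc` (Lilliefors null size), `adjust`
#'   (`"none"` or `"BH"`).
#' @param seed Integer master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = list(cutoff_ehg = 5, cutoff_ecg = 0.5,
                                          order = 4L),
                            detection = list(min_height = 0.4,
                                             refractory = 250),
                            segment = list(duration = 300,
                                           quality_threshold = 0.05,
                                           min_beats = 150L),
                            ectopic = list(dev_threshold = 0.2,
                                           bounds = c(250, 2000)),
                            spectral = list(fs_interp = 4, window_s = 150,
                                            overlap = 0.5, detrend = TRUE),
                            stats = list(alpha = 0.05, n_mc = 10000L,
                                         adjust = "none"),
                            seed = 1L) {
  cfg <- list(filter = filter, detection = detection, segment = segment,
              ectopic = ectopic, spectral = spectral, stats = stats,
              seed = as.integer(seed))
  stopifnot(filter$cutoff_ehg > 0, filter$cutoff_ecg > 0, filter$order >= 1,
            detection$min_height > 0, detection$min_height < 1,
            detection$refractory > 0,
            segment$duration > 0, segment$quality_threshold >= 0,
            segment$quality_threshold <= 1,
            ectopic$dev_threshold > 0, length(ectopic$bounds) == 2L,
            ectopic$bounds[1] < ectopic$bounds[2],
            spectral$fs_interp > 0.8, spectral$window_s > 0,
            spectral$overlap >= 0, spectral$overlap < 1,
            stats$alpha > 0, stats$alpha < 1,
            stats$adjust %in% c("none", "BH"))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' YAML round trip; `read_config(write_config(cfg, path))` reproduces the
#' configuration exactly.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$ectopic$bounds <- as.numeric(raw$ectopic$bounds)
  do.call(pipeline_config, raw)
}

#' Read a single-channel signal file
#'
#' Two formats are supported. `"csv"`: a 2-column file `time_s,value`
#' (sampling rate inferred from the time column) or a 1-column `value` file
#' with metadata comment lines such as `# fs: 200`; comment lines may also
#' carry `modality` and subject fields (`id`, `age`, `bmi`, `ga_recording`,
#' `ga_delivery`, `delivery_mode`, `dataset`). `"physionet"`: a minimal
#' adapter for PhysioNet-style waveform records (text `.hea` header plus
#' 16-bit little-endian `.dat`); pass the `.hea` path and, for multichannel
#' records, a `channel` selector.
#'
#' @param path File path (`.csv` or `.hea`).
#' @param format `"csv"` or `"physionet"`; default guessed from extension.
#' @param channel Channel index (1-based) for multichannel records.
#' @param modality Signal modality if the file does not declare one.
#' @return A [raw_recording()].
#' @export
read_signal <- function(path, format = NULL, channel = NULL,
                        modality = "EHG") {
  format <- format %||% if (grepl("\\.hea$", path)) "physionet" else "csv"
  if (format == "physionet") {
    return(read_physionet(path, channel, modality))
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*[:=]\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  subject <- list()
  for (f in c("id", "delivery_mode", "dataset")) {
    if (!is.null(meta[[f]])) subject[[f]] <- meta[[f]]
  }
  for (f in c("age", "bmi", "ga_recording", "ga_delivery")) {
    if (!is.null(meta[[f]])) subject[[f]] <- as.numeric(meta[[f]])
  }
  modality <- meta$modality %||% modality
  if (all(c("time_s", "value") %in% names(dat))) {
    fs <- 1 / stats::median(diff(dat$time_s))
    return(raw_recording(dat$value, round(fs, 6), modality, subject))
  }
  if ("value" %in% names(dat)) {
    if (is.null(meta$fs)) stop2("1-column signal file needs an '# fs:' header")
    return(raw_recording(dat$value, as.numeric(meta$fs), modality, subject))
  }
  stop2("malformed signal CSV: need columns (time_s, value) or (value)")
}

# Minimal PhysioNet-style record reader: text header `<record>.hea`
# ("name n_sig fs n_samp" then one line per signal: "file format gain ...
# description"), 16-bit little-endian interleaved samples in the .dat file.
read_physionet <- function(hea_path, channel = NULL, modality = "EHG") {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  if (length(hdr) < 3L) stop2("malformed PhysioNet header: ", hea_path)
  n_sig <- as.integer(hdr[2L])
  fs <- as.numeric(hdr[3L])
  if (!is.finite(fs)) stop2("sampling rate missing from header")
  sig_lines <- lines[2:(1 + n_sig)]
  descs <- vapply(sig_lines, function(l) {
    parts <- strsplit(trimws(l), "\\s+")[[1]]
    paste(parts[-(1:8)], collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  if (n_sig > 1L && is.null(channel)) {
    stop2("multichannel record: pass `channel` (1-", n_sig, "). Channels: ",
          paste(sprintf("[%d] %s", seq_len(n_sig), descs), collapse = "; "))
  }
  channel <- channel %||% 1L
  if (channel < 1L || channel > n_sig) stop2("channel out of range")
  parts <- strsplit(trimws(sig_lines[channel]), "\\s+")[[1]]
  fmt <- parts[2L]
  if (!startsWith(fmt, "16")) stop2("only format 16 .dat files are supported")
  gain <- as.numeric(strsplit(parts[3L], "[(/]")[[1]][1])
  if (!is.finite(gain) || gain == 0) gain <- 200
  dat_path <- file.path(dirname(hea_path), parts[1L])
  raw <- readBin(dat_path, "integer", n = file.size(dat_path) / 2L,
                 size = 2L, signed = TRUE, endian = "little")
  samples <- raw[seq(channel, length(raw), by = n_sig)] / gain
  raw_recording(samples, fs, modality, list(id = hdr[1L]))
}

#' Write a recording as a 2-column CSV
#'
#' Emits `time_s,value` rows preceded by metadata comment lines (`# fs:`,
#' `# modality:` and any subject fields), the canonical interchange format
#' of the package. A write/read round trip preserves the samples exactly.
#'
#' @param rec A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.10g", rec$fs), con)
  writeLines(sprintf("# modality: %s", rec$modality), con)
  for (f in names(rec$subject)) {
    writeLines(sprintf("# %s: %s", f, format(rec$subject[[f]], digits = 15)),
               con)
  }
  writeLines("time_s,value", con)
  tt <- (seq_along(rec$samples) - 1L) / rec$fs
  writeLines(paste(format(tt, digits = 15, trim = TRUE),
                   format(rec$samples, digits = 17, trim = TRUE), sep = ","),
             con)
  invisible(path)
}

#' Write an RR-interval series as CSV
#'
#' Columns `beat_time_s, rri_ms, label`; one row per interval, anchored at
#' the beat that ends it.
#'
#' @param rri An [rri_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rri <- function(rri, path) {
  stopifnot(inherits(rri, "rri_series"))
  utils::write.csv(data.frame(beat_time_s = rri$beat_times[-1L],
                              rri_ms = rri$intervals, label = rri$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' Extract corrected HRV metrics from one recording
#'
#' The full per-subject chain: zero-phase high-pass filter (cutoff by
#' modality), amplitude normalization, 5-minute segment selection, R-peak
#' detection, RR-interval construction, ectopic flagging and
#' duration-preserving correction, then [compute_hrv()].
#'
#' @param rec A [raw_recording()].
#' @param config A [pipeline_config()].
#' @return A list: `metrics` ([compute_hrv()] output), `segment`
#'   (selection), `rri` (corrected series), `n_flagged`.
#' @export
process_recording <- function(rec, config = pipeline_config()) {
  seg <- select_segment(rec, config$segment$quality_threshold,
                        config$segment$duration, config$segment$min_beats,
                        config)
  win <- crop_recording(rec, seg$start, seg$duration)
  win <- normalize_amplitude(highpass_filter(
    win, cutoff = segment_cutoff(config, rec$modality),
    order = config$filter$order))
  peaks <- detect_rpeaks(win, config$detection$min_height,
                         config$detection$refractory)
  rri <- peaks_to_rri(peaks)
  flags <- suppressWarnings(
    flag_ectopics(rri, config$ectopic$dev_threshold, config$ectopic$bounds))
  rri <- correct_ectopics(rri, flags)
  metrics <- compute_hrv(rri, config$spectral$fs_interp,
                         config$spectral$window_s, config$spectral$overlap,
                         config$spectral$detrend)
  list(metrics = metrics, segment = seg, rri = rri, n_flagged = sum(flags))
}

#' Run the full cohort pipeline
#'
#' Per subject: extract HRV metrics via [process_recording()]; failures
#' (e.g. undetectable R peaks) are logged as quality exclusions, not fatal.
#' Then: delivery-mode/quality exclusions, time to delivery, Lilliefors
#' normality gate on every variable, and the Spearman correlation table.
#'
#' @param recordings List of [raw_recording()] objects with subject
#'   metadata (`ga_recording`, `ga_delivery`, `delivery_mode` required).
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `cohort` (one row per
#'   retained subject: metadata, TTD, HRV metrics), `correlations`
#'   ([correlation_table()]), `normality` (Lilliefors statistic and p per
#'   variable), `exclusion_log`, `failures` (per-subject error messages),
#'   `config`.
#' @export
run_pipeline <- function(recordings, config = pipeline_config()) {
  rows <- list()
  failures <- character(0)
  for (rec in recordings) {
    sub <- rec$subject
    id <- sub$id %||% sprintf("subject%03d", length(rows) + length(failures) + 1L)
    res <- tryCatch(process_recording(rec, config), error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      rows[[id]] <- data.frame(
        id = id, age = sub$age %||% NA_real_, bmi = sub$bmi %||% NA_real_,
        ga_recording = sub$ga_recording %||% NA_real_,
        ga_delivery = sub$ga_delivery %||% NA_real_,
        delivery_mode = sub$delivery_mode %||% "spontaneous",
        dataset = sub$dataset %||% "default", quality_ok = FALSE,
        mean_rr = NA_real_, sdnn = NA_real_, rmssd = NA_real_,
        vlf_ln = NA_real_, lf_ln = NA_real_, hf_ln = NA_real_,
        lf_hf = NA_real_, stringsAsFactors = FALSE)
    } else {
      m <- res$metrics
      rows[[id]] <- data.frame(
        id = id, age = sub$age %||% NA_real_, bmi = sub$bmi %||% NA_real_,
        ga_recording = sub$ga_recording %||% NA_real_,
        ga_delivery = sub$ga_delivery %||% NA_real_,
        delivery_mode = sub$delivery_mode %||% "spontaneous",
        dataset = sub$dataset %||% "default", quality_ok = TRUE,
        mean_rr = m$mean_rr, sdnn = m$sdnn, rmssd = m$rmssd,
        vlf_ln = m$vlf_ln, lf_ln = m$lf_ln, hf_ln = m$hf_ln,
        lf_hf = m$lf_hf, stringsAsFactors = FALSE)
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  excl <- apply_exclusions(cohort)
  cohort <- excl$cohort
  cohort$ttd <- time_to_delivery(cohort$ga_delivery, cohort$ga_recording)
  if (nrow(cohort) < 3L) stop2("fewer than 3 usable subjects")

  vars <- c("ttd", names(hrv_metric_columns))
  normality <- do.call(rbind, lapply(vars, function(v) {
    x <- cohort[[v]]
    res <- tryCatch(
      lilliefors_test(x, n_mc = config$stats$n_mc, seed = config$seed),
      error = function(e) list(statistic = NA_real_, p = NA_real_))
    data.frame(variable = v, statistic = res$statistic, p = res$p,
               stringsAsFactors = FALSE)
  }))

  correlations <- correlation_table(cohort, adjust = config$stats$adjust,
                                    alpha = config$stats$alpha)
  structure(list(cohort = cohort, correlations = correlations,
                 normality = normality, exclusion_log = excl$log,
                 failures = failures, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects retained (excluded: %d induced, %d cesarean, %d poor R peaks)\n\n",
              nrow(x$cohort), x$exclusion_log[["induced"]],
              x$exclusion_log[["cesarean"]], x$exclusion_log[["poor_rpeaks"]]))
  print(x$correlations)
  invisible(x)
}
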