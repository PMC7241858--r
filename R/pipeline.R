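#' Run a configured analysis end to end
#'
#' Dispatches a run configuration to the package's computational modules and
#' writes tidy TSV outputs with a JSON provenance sidecar (config, seed,
#' package version, timestamp). This is the engine behind the command-line
#' wrapper (`inst/cli/mmse`); per-scale flags never abort a run.
#'
#' @param config a named list with at least `command` (one of `"compute"`,
#'   `"simulate"`, `"psd"`, `"surrogate"`, `"events"`, `"fixtures"`) and
#'   `output` (output stem). Further fields per command:
#'   \describe{
#'     \item{compute}{`input` (matrix-format stem), `variant`, `policy`,
#'       `m`, `r`, `taus` (integer vector), optional `bandstop_band`.}
#'     \item{simulate}{`preset` (see [make_fixtures()] presets) or explicit
#'       generator arguments (`n_trials`, `duration`, `fs`, `exponent`,
#'       `rhythm_freq`, `rhythm_amplitude`), `seed`; when `variant`/`policy`
#'       are present an entropy curve is computed on the simulated set.}
#'     \item{psd}{`input`, optional `exclude` band for the slope fit.}
#'     \item{surrogate}{`input`, `n_surrogates`, `seed`.}
#'     \item{events}{`input`, optional `min_cycles`, `bandstop`.}
#'     \item{fixtures}{`preset`, `seed`.}
#'   }
#' @return invisibly, a character vector of files written.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$command)) stop("config needs a `command` field")
  if (is.null(config$output)) stop("config needs an `output` stem")
  files <- switch(config$command,
                  compute = pipeline_compute(config),
                  simulate = pipeline_simulate(config),
                  psd = pipeline_psd(config),
                  surrogate = pipeline_surrogate(config),
                  events = pipeline_events(config),
                  fixtures = make_fixtures(config$preset, dirname(config$output),
                                           seed = config$seed %||% 1L),
                  stop("unknown command: ", config$command))
  sidecar <- paste0(config$output, "_run.json")
  jsonlite::write_json(
    list(config = config, package = "mmse",
         version = as.character(utils::packageVersion("mmse")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, sidecar))
}

write_tidy_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NaN")
  path
}

mmse_result_tidy <- function(res, channel = "ch1") {
  data.frame(channel = channel, tau = res$tau,
             variant = attr(res, "variant"), policy = attr(res, "policy"),
             entropy = res$entropy, bound = res$bound,
             scale_sd = res$scale_sd, label_hz = res$label_hz,
             flag = res$flag, stringsAsFactors = FALSE)
}

pipeline_compute <- function(config) {
  ds <- read_dataset(config$input, format = config$format %||% "matrix")
  taus <- as.integer(config$taus %||% 1:42)
  rows <- lapply(seq_along(ds$channels), function(ch) {
    res <- compute_mmse(dataset_channel(ds, ch), taus = taus,
                        variant = config$variant %||% "lowpass",
                        policy = config$policy %||% "scalewise",
                        m = config$m %||% 2L, r = config$r %||% 0.5,
                        bandstop_band = config$bandstop_band %||% c(8, 15))
    mmse_result_tidy(res, ds$channels[ch])
  })
  out <- paste0(config$output, "_mmse.tsv")
  write_tidy_tsv(do.call(rbind, rows), out)
  out
}

pipeline_simulate <- function(config) {
  ss <- gen_noise(n_trials = config$n_trials %||% 100,
                  duration = config$duration %||% 8,
                  fs = config$fs %||% 250,
                  exponent = config$exponent %||% 1,
                  seed = config$seed %||% 1L)
  amp <- config$rhythm_amplitude %||% 0
  if (amp > 0) ss <- add_rhythm(ss, config$rhythm_freq %||% 10, amp)
  files <- character(0)
  data_stem <- paste0(config$output, "_sim")
  files <- c(files, write_dataset(ss, data_stem),
             paste0(data_stem, ".json"))
  if (!is.null(config$variant)) {
    res <- compute_mmse(ss, taus = as.integer(config$taus %||% 1:42),
                        variant = config$variant,
                        policy = config$policy %||% "scalewise")
    files <- c(files, write_tidy_tsv(mmse_result_tidy(res),
                                     paste0(config$output, "_mmse.tsv")))
  }
  files
}

pipeline_psd <- function(config) {
  ds <- read_dataset(config$input, format = config$format %||% "matrix")
  rows <- lapply(seq_along(ds$channels), function(ch) {
    psd <- compute_psd(dataset_channel(ds, ch))
    fit <- fit_slope(psd, exclude = config$exclude %||% c(7, 13))
    list(psd = data.frame(channel = ds$channels[ch], freq = psd$freqs,
                          log10_power = psd$log_power),
         fit = data.frame(channel = ds$channels[ch], slope = fit$slope,
                          intercept = fit$intercept, r2 = fit$r2))
  })
  f1 <- write_tidy_tsv(do.call(rbind, lapply(rows, `[[`, "psd")),
                       paste0(config$output, "_psd.tsv"))
  f2 <- write_tidy_tsv(do.call(rbind, lapply(rows, `[[`, "fit")),
                       paste0(config$output, "_slope.tsv"))
  c(f1, f2)
}

pipeline_surrogate <- function(config) {
  ds <- read_dataset(config$input, format = config$format %||% "matrix")
  ss <- dataset_channel(ds, config$channel %||% 1L)
  surr <- surrogate_ensemble(ss, config$n_surrogates %||% 1L,
                             seed = config$seed %||% 1L)
  files <- character(0)
  for (i in seq_along(surr)) {
    stem <- sprintf("%s_surrogate%03d", config$output, i)
    files <- c(files, write_dataset(surr[[i]], stem), paste0(stem, ".json"))
  }
  files
}

pipeline_events <- function(config) {
  ds <- read_dataset(config$input, format = config$format %||% "matrix")
  ss <- dataset_channel(ds, config$channel %||% 1L)
  tfrs <- lapply(ss$segments, wavelet_tfr, fs = ss$fs)
  bg <- fit_background(tfrs)
  eps <- lapply(seq_along(tfrs), function(i) {
    e <- detect_episodes(tfrs[[i]], bg,
                         min_cycles = config$min_cycles %||% 1)
    if (nrow(e)) cbind(epoch = i, e) else NULL
  })
  eps <- do.call(rbind, eps[!vapply(eps, is.null, logical(1))])
  if (is.null(eps))
    eps <- data.frame(epoch = integer(0), mean_freq = numeric(0),
                      onset = integer(0), offset = integer(0),
                      duration_cycles = numeric(0), mean_amplitude = numeric(0))
  write_tidy_tsv(eps, paste0(config$output, "_episodes.tsv"))
}

#' Generate the package's standard simulation fixtures
#'
#' Seeded generation of the simulation sets used throughout validation, with
#' a JSON manifest sufficient to regenerate them byte-identically.
#'
#' @param preset one of `"fig4"` (10 Hz amplitude sweep on pink noise),
#'   `"fig5"` (frequency sweep 5/10/20/40 Hz at fixed amplitude),
#'   `"fig11a"` (2 x 2 short-segment slope x alpha factorial),
#'   `"events"` (burst stream plus ground truth),
#'   `"whitepink"` (exponents 0 and 1).
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return invisibly, the files written.
#' @export
make_fixtures <- function(preset = c("fig4", "fig5", "fig11a", "events",
                                     "whitepink"),
                          dir = ".", seed = 1L) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(ss, name) {
    stem <- file.path(dir, name)
    write_dataset(ss, stem)
    c(paste0(stem, ".tsv"), paste0(stem, ".json"))
  }
  if (preset == "fig4") {
    base <- gen_noise(seed = seed)
    for (a in seq(0, 7, by = 0.5))
      files <- c(files, emit(add_rhythm(base, 10, a),
                             sprintf("fig4_amp%04.1f", a)))
  } else if (preset == "fig5") {
    base <- gen_noise(seed = seed)
    for (f in c(5, 10, 20, 40))
      files <- c(files, emit(add_rhythm(base, f, 7),
                             sprintf("fig5_freq%02d", f)))
  } else if (preset == "fig11a") {
    sets <- gen_alpha_segments(seed = seed)
    for (nm in names(sets)) files <- c(files, emit(sets[[nm]],
                                                   paste0("fig11a_", nm)))
  } else if (preset == "events") {
    ev <- gen_event_stream(seed = seed)
    files <- c(files, emit(ev$data, "events_stream"))
    truth <- file.path(dir, "events_truth.tsv")
    write_tidy_tsv(ev$truth, truth)
    files <- c(files, truth)
  } else if (preset == "whitepink") {
    sets <- gen_slope_sweep(c(0, 1), seed = seed)
    for (nm in names(sets)) files <- c(files, emit(sets[[nm]],
                                                   paste0("whitepink_", nm)))
  }
  manifest <- file.path(dir, paste0(preset, "_manifest.json"))
  jsonlite::write_json(list(preset = preset, seed = seed,
                            package_version =
                              as.character(utils::packageVersion("mmse")),
                            files = basename(files)),
                       manifest, auto_unbox = TRUE)
  invisible(c(files, manifest))
}
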