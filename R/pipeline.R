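#' Experiment configuration
#'
#' Bundles every choice needed to run a full simulated experiment mirroring
#' the study design (mappings x gain multipliers x stimulus grid), with a
#' single master seed from which all per-condition seeds are derived.
#'
#' @param mappings Character vector of mapping kinds.
#' @param gain_multipliers Subset of `c(1, 2)`.
#' @param frequencies Sinusoid frequencies (Hz).
#' @param include_transients Run transient conditions too.
#' @param directions Transient directions.
#' @param n_transient_trials Trials per transient condition (20 by default,
#'   as in the study protocol; trials containing saccades near the stimulus
#'   are discarded by the analysis).
#' @param params A [vor_params()] object or preset name.
#' @param noise A [noise_spec()].
#' @param asymmetry On/off response asymmetry factor.
#' @param n_cycles Sinusoid cycles per condition, or `NULL` (default) to use
#'   as many 10-cycle presentations as needed so that, after the encoder
#'   warm-up and expected saccade losses, the per-frequency minimum cycle
#'   counts are met.
#' @param renormalize_mixed Passed to [build_mapping()].
#' @param estimate_efficacy Fit stimulation efficacy from the synthesized
#'   peak-velocity observations.
#' @param seed Master seed.
#' @return An object of class `vp_config`.
#' @export
experiment_config <- function(mappings = c("regular", "irregular", "mixed",
                                           "super_high_pass", "static"),
                              gain_multipliers = c(1, 2),
                              frequencies = c(0.2, 0.5, 1, 2, 5, 10, 20),
                              include_transients = TRUE,
                              directions = c("on", "off"),
                              n_transient_trials = 20L,
                              params = vor_params("monkey_G_like"),
                              noise = noise_spec(),
                              asymmetry = 0.8,
                              n_cycles = NULL,
                              renormalize_mixed = FALSE,
                              estimate_efficacy = TRUE,
                              seed = 1L) {
  if (is.character(params)) params <- vor_params(params)
  stopifnot(inherits(params, "vp_vor_params"), inherits(noise, "vp_noise"),
            all(gain_multipliers %in% c(1, 2)), all(frequencies > 0))
  bad <- setdiff(mappings, names(mapping_registry()))
  if (length(bad)) {
    stop("unknown mapping kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(mappings = mappings, gain_multipliers = gain_multipliers,
         frequencies = frequencies, include_transients = include_transients,
         directions = directions,
         n_transient_trials = as.integer(n_transient_trials),
         params = params, noise = noise, asymmetry = asymmetry,
         n_cycles = n_cycles, renormalize_mixed = renormalize_mixed,
         estimate_efficacy = estimate_efficacy, seed = as.integer(seed)),
    class = "vp_config"
  )
}

#' Run a full simulated experiment
#'
#' Executes every stage for every condition in the configuration: synthesize
#' a recording, preprocess, fit cycles (sinusoids) or compute transient
#' metrics, assemble per-mapping frequency-response tables, run the
#' saturation diagnostic, and optionally estimate stimulation efficacy from
#' the synthesized peak-velocity observations. Identical configuration and
#' seed give identical bundles. Failures in individual conditions are
#' collected in `$failures` without aborting the run.
#'
#' @param config An [experiment_config()].
#' @return An object of class `vp_results`: `cycle_fits` (all per-cycle
#'   fits), `frequency_response` (per mapping x gain), `transients`,
#'   `saturation`, `efficacy_fit`, `failures`, `provenance`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "vp_config"))
  grid <- tidyr::expand_grid(kind = config$mappings,
                             gain_x = config$gain_multipliers)
  n_stages <- nrow(grid) * (length(config$frequencies) +
    if (config$include_transients)
      length(config$directions) * config$n_transient_trials else 0L)
  seeds <- with_local_seed(config$seed,
                           sample.int(.Machine$integer.max, n_stages))
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seeds[seed_i]
  }
  failures <- list()
  note_failure <- function(label, e) {
    failures[[length(failures) + 1L]] <<- tibble::tibble(
      condition = label, error = conditionMessage(e))
  }

  cycle_fits <- list()
  transients <- list()
  for (i in seq_len(nrow(grid))) {
    mp <- build_mapping(grid$kind[i], grid$gain_x[i],
                        renormalize_mixed = config$renormalize_mixed)
    for (f in config$frequencies) {
      label <- paste0(grid$kind[i], "_x", grid$gain_x[i], "_", f, "Hz")
      tryCatch({
        st <- stimulus_spec("sinusoid", frequency = f,
                            n_cycles = config$n_cycles %||%
                              n_cycles_for(f, mp))
        rec <- synthesize_recording(st, mp, config$params, config$noise,
                                    asymmetry = config$asymmetry,
                                    seed = next_seed())
        fits <- fit_cycles(preprocess_eye(rec))
        fits$kind <- grid$kind[i]
        fits$gain_x <- grid$gain_x[i]
        cycle_fits[[label]] <- fits
      }, error = function(e) note_failure(label, e))
    }
    if (config$include_transients) {
      for (dir in config$directions) {
        label <- paste0(grid$kind[i], "_x", grid$gain_x[i], "_transient_", dir)
        tryCatch({
          st <- stimulus_spec("transient", direction = dir)
          trials <- purrr::map(seq_len(config$n_transient_trials), function(j) {
            preprocess_eye(synthesize_recording(
              st, mp, config$params, config$noise,
              asymmetry = config$asymmetry, seed = next_seed()))
          })
          tm <- transient_metrics(trials, st)
          tm$kind <- grid$kind[i]
          tm$gain_x <- grid$gain_x[i]
          tm$direction <- dir
          transients[[label]] <- tm
        }, error = function(e) note_failure(label, e))
      }
    }
  }
  cycle_fits <- dplyr::bind_rows(cycle_fits)

  freq_tables <- list()
  if (nrow(cycle_fits) > 0) {
    for (i in seq_len(nrow(grid))) {
      sub <- dplyr::filter(cycle_fits, .data$kind == grid$kind[i],
                           .data$gain_x == grid$gain_x[i])
      if (nrow(sub) == 0) next
      label <- paste0(grid$kind[i], "_x", grid$gain_x[i])
      tryCatch(freq_tables[[label]] <- summarize_response(sub),
               error = function(e) note_failure(label, e))
    }
  }

  sat <- tryCatch({
    conds <- tidyr::expand_grid(kind = config$mappings,
                                gain_x = config$gain_multipliers)
    conds$mapping <- purrr::map2(conds$kind, conds$gain_x, build_mapping,
                                 renormalize_mixed = config$renormalize_mixed)
    fmax <- max(config$frequencies)
    saturation_diagnostic(
      conds,
      stimulus_spec("sinusoid", frequency = fmax,
                    n_cycles = n_cycles_for(fmax, build_mapping("regular"))))
  }, error = function(e) { note_failure("saturation", e); NULL })

  eff <- NULL
  if (isTRUE(config$estimate_efficacy)) {
    eff <- tryCatch({
      obs_freqs <- utils::tail(sort(config$frequencies), 3)
      obs <- tidyr::expand_grid(kind = config$mappings[1],
                                gain_x = config$gain_multipliers,
                                frequency = obs_freqs)
      obs$mapping <- purrr::map2(obs$kind, obs$gain_x, build_mapping,
                                 renormalize_mixed = config$renormalize_mixed)
      obs$stimulus <- purrr::map2(obs$frequency, obs$mapping, function(f, m)
        stimulus_spec("sinusoid", frequency = f,
                      n_cycles = config$n_cycles %||% n_cycles_for(f, m)))
      pv <- peak_velocity_curve(obs, config$params)
      estimate_efficacy(pv, config$params)
    }, error = function(e) { note_failure("efficacy", e); NULL })
  }

  structure(
    list(cycle_fits = cycle_fits,
         frequency_response = freq_tables,
         transients = dplyr::bind_rows(transients),
         saturation = sat,
         efficacy_fit = eff,
         failures = dplyr::bind_rows(failures),
         provenance = list(config = config, seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("vorpulse")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "vp_results"
  )
}

#' @export
print.vp_results <- function(x, ...) {
  cat("<vp_results>\n")
  cat("  cycle fits:", nrow(x$cycle_fits), "cycles;",
      length(x$frequency_response), "frequency-response tables\n")
  cat("  transient conditions:", nrow(x$transients), "\n")
  if (!is.null(x$efficacy_fit)) {
    cat("  efficacy estimate:", signif(x$efficacy_fit$efficacy, 4), "\n")
  }
  if (nrow(x$failures)) cat("  FAILURES:", nrow(x$failures), "\n")
  invisible(x)
}

#' Write / read a recording as delimited text with a JSON sidecar
#'
#' The table is written as tab-separated text with a header row; all
#' recording metadata (sample rate, stimulus, ground truth when present) goes
#' to a JSON sidecar at `<path>.json`. readr writes shortest round-trip
#' representations, so a write-then-read cycle reproduces the numeric values
#' exactly.
#'
#' @param data A recording tibble (must contain `time_s`).
#' @param path Output file path.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the tibble with `sample_rate`, `stimulus` and `truth` attributes
#'   restored when the sidecar is present.
#' @export
write_recording <- function(data, path) {
  stopifnot(is.data.frame(data), "time_s" %in% names(data))
  readr::write_tsv(data, path)
  meta <- list(sample_rate = attr(data, "sample_rate"),
               warmup_s = attr(data, "warmup_s"))
  st <- attr(data, "stimulus")
  if (!is.null(st)) meta$stimulus <- unclass(st)
  tr <- attr(data, "truth")
  if (!is.null(tr)) {
    tr$params <- if (!is.null(tr$params)) unclass(tr$params)
    tr$mapping <- if (!is.null(tr$mapping)) {
      m <- unclass(tr$mapping)
      m$sigmoid <- unclass(m$sigmoid)
      m
    }
    tr$stimulus <- if (!is.null(tr$stimulus)) unclass(tr$stimulus)
    meta$truth <- tr
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  # base read.delim parses doubles with correctly-rounded strtod, so the
  # shortest-round-trip representations written by readr read back bitwise
  data <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                              check.names = FALSE))
  if (!"time_s" %in% names(data)) {
    stop("malformed recording file: missing `time_s` column in ", path,
         call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(data, "sample_rate") <- meta$sample_rate
    attr(data, "warmup_s") <- meta$warmup_s
    if (!is.null(meta$stimulus)) {
      attr(data, "stimulus") <- structure(meta$stimulus, class = "vp_stimulus")
    }
    if (!is.null(meta$truth)) attr(data, "truth") <- meta$truth
  } else {
    attr(data, "sample_rate") <- infer_fs(data$time_s)
  }
  data
}
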