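#' Pipeline configuration with frozen presets
#'
#' The two presets reproduce the published analysis settings and are frozen:
#' `"needle"` (decimation 3 to 14700 Hz; zero-phase 7th-order Butterworth
#' 3-6 kHz; TV-AR window 110 ms, overlap 50%, order 30; CUSUM detection) and
#' `"guidewire"` (decimation 4 to 11025 Hz; 10-scale Daubechies DWT
#' reconstruction of mid-frequency detail levels; TV-AR window 50 ms,
#' overlap 95%, order 20; event segmentation, 16 features, SVM). Changing
#' any preset value requires passing it through the explicit `override`
#' list.
#'
#' @param preset `"needle"` or `"guidewire"`.
#' @param override named list of explicit deviations from the preset
#'   (e.g. `list(decimation = 2, cusum = list(threshold_h = 4))`).
#' @param seed seed used by stochastic pipeline stages.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("needle", "guidewire"),
                            override = list(), seed = 1L) {
  preset <- match.arg(preset)
  cfg <- if (preset == "needle") {
    list(preset = "needle",
         decimation = 3L,
         filter = filter_spec("butterworth", low_hz = 3000, high_hz = 6000,
                              order = 7),
         tvar = tvar_config("needle"),
         n_freq = 128L,
         cusum = list(drift_k = 1.0, threshold_h = 5, baseline_s = 2.0,
                      sustain = 2L, clip_z = 4),
         velocity_mm_s = 3,
         seed = as.integer(seed))
  } else {
    list(preset = "guidewire",
         decimation = 4L,
         filter = filter_spec("dwt", wavelet_family = "db4", n_levels = 10,
                              keep_levels = 2:6),
         tvar = tvar_config("guidewire"),
         n_freq = 128L,
         delta_frac = 0.2,
         plateau_thresholds = NULL,      # auto: 2/5/10% of event MEP range
         svm = list(cost_grid = c(1, 10, 100),
                    gamma_grid = c(0.02, 1 / 16, 0.25)),
         seed = as.integer(seed))
  }
  for (nm in names(override)) {
    if (!nm %in% names(cfg))
      stop("unknown config field in override: ", nm, call. = FALSE)
    if (is.list(cfg[[nm]]) && is.list(override[[nm]]) &&
        !inherits(cfg[[nm]], c("filter_spec", "tvar_config"))) {
      cfg[[nm]][names(override[[nm]])] <- override[[nm]]
    } else {
      cfg[[nm]] <- override[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> preset '%s', decimation %d, seed %d\n",
              x$preset, x$decimation, x$seed))
  print(x$filter)
  print(x$tvar)
  invisible(x)
}

#' Read/write a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  plain <- lapply(cfg, function(v) if (is.list(v)) lapply(unclass(v), identity) else v)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ov <- raw[setdiff(names(raw), c("preset", "filter", "tvar", "seed"))]
  cfg <- pipeline_config(raw$preset, override = ov, seed = raw$seed %||% 1L)
  if (!is.null(raw$filter)) cfg$filter <- do.call(filter_spec, raw$filter[
    intersect(names(raw$filter), names(formals(filter_spec)))])
  if (!is.null(raw$tvar))
    cfg$tvar <- tvar_config(window_ms = raw$tvar$window_ms,
                            overlap = raw$tvar$overlap,
                            order = raw$tvar$order)
  cfg
}

# normalize the many accepted input forms to a list of audio recordings
# plus reference annotations; rows that fail to load become error entries
resolve_inputs <- function(input, time_cols) {
  if (inherits(input, "audio_recording")) input <- list(input)
  if (inherits(input, "aemid_dataset")) {
    recs <- lapply(seq_len(nrow(input$manifest)),
                   function(i) dataset_recording(input, i))
    ref <- input$manifest[, intersect(names(input$manifest), time_cols),
                          drop = FALSE]
    names(ref) <- sub("_ref$", "", names(ref))
    return(list(recs = recs, ref = if (ncol(ref)) ref else NULL,
                labels = input$manifest$label, errors = rep(NA_character_,
                                                            length(recs))))
  }
  if (is.character(input) && length(input) == 1L && file.exists(input) &&
      grepl("\\.csv$", input)) input <- read.csv(input, stringsAsFactors = FALSE)
  if (is.data.frame(input)) {
    recs <- vector("list", nrow(input))
    errors <- rep(NA_character_, nrow(input))
    for (i in seq_len(nrow(input))) {
      recs[i] <- list(tryCatch(
        read_wav(input$wav_path[i],
                 label = if ("label" %in% names(input)) input$label[i] else "unknown"),
        error = function(e) { errors[i] <<- conditionMessage(e); NULL }))
    }
    ref <- input[, intersect(names(input), time_cols), drop = FALSE]
    names(ref) <- sub("_ref$", "", names(ref))
    return(list(recs = recs, ref = if (ncol(ref)) ref else NULL,
                labels = if ("label" %in% names(input)) input$label else NULL,
                errors = errors))
  }
  stopifnot(is.list(input))
  list(recs = input,
       ref = NULL,
       labels = vapply(input, function(r) r$label %||% "unknown", ""),
       errors = rep(NA_character_, length(input)))
}

#' Run the needle entry/exit detection pipeline
#'
#' Chains decimation, zero-phase Butterworth band-pass, sliding-window TV-AR
#' fit, TV-MEP extraction and CUSUM detection for one or many recordings.
#' When reference annotations are available (manifest columns
#' `t_in_ref`/`t_out_ref`, or a synthetic dataset), detection error
#' statistics in seconds and millimetres are computed.
#'
#' @param input an [audio_recording()], list of them, an [gen_dataset()]
#'   result, a manifest data.frame, or a manifest CSV path with columns
#'   `wav_path` (+ optional `t_in_ref`, `t_out_ref`).
#' @param config a [pipeline_config()] (preset `"needle"`).
#' @param velocity_mm_s insertion velocity used for the mm conversion.
#' @return an object of class `needle_run`: `results` (one row per
#'   recording: `t_in`, `t_out`, `flagged`, `error`), `stats` (an
#'   `error_stats` or `NULL`), and the echoed `config`.
#' @export
run_needle_pipeline <- function(input, config = pipeline_config("needle"),
                                velocity_mm_s = config$velocity_mm_s) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- resolve_inputs(input, c("t_in_ref", "t_out_ref", "t_in", "t_out"))
  n <- length(inp$recs)
  res <- data.frame(id = seq_len(n), t_in = NA_real_, t_out = NA_real_,
                    flagged = TRUE, error = inp$errors,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (!is.na(res$error[i])) next
    det <- tryCatch({
      rec <- decimate_audio(inp$recs[[i]], config$decimation)
      rec <- bandpass_butterworth(rec, config$filter)
      mep <- mep_track(fit_tvar(rec, config$tvar))
      do.call(cusum_detect, c(list(mep), config$cusum))
    }, error = function(e) e)
    if (inherits(det, "error")) {
      res$error[i] <- conditionMessage(det)
    } else {
      res$t_in[i] <- det$t_in; res$t_out[i] <- det$t_out
      res$flagged[i] <- det$flagged
    }
  }
  stats <- NULL
  if (!is.null(inp$ref) && all(c("t_in", "t_out") %in% names(inp$ref))) {
    ok <- is.na(res$error) & !is.na(res$t_in) & !is.na(res$t_out)
    if (any(ok))
      stats <- detection_error_stats(res[ok, c("t_in", "t_out")],
                                     inp$ref[ok, , drop = FALSE],
                                     velocity_mm_s)
  }
  structure(list(results = res, stats = stats, config = config),
            class = "needle_run")
}

#' @export
print.needle_run <- function(x, ...) {
  cat(sprintf("<needle_run> %d recordings, %d detections\n",
              nrow(x$results), sum(!is.na(x$results$t_in))))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

# single-recording guide-wire feature extraction; returns the feature
# vector plus the intermediate objects
guidewire_features_one <- function(rec, config) {
  rec <- decimate_audio(rec, config$decimation)
  rec <- dwt_band_reconstruct(rec, config$filter)
  model <- fit_tvar(rec, config$tvar)
  mep <- mep_track(model)
  seg <- detect_event_bounds(rec, mep, delta_frac = config$delta_frac)
  if (is.null(seg)) stop("no supra-threshold event interval found", call. = FALSE)
  os <- detect_overshoot(mep, seg)
  pl <- detect_plateaus(mep, seg, thresholds = config$plateau_thresholds,
                        os = os)
  # spectrum evaluated over the event span only (features use no other window)
  keep <- which(model$times >= seg$t_on - model$hop_s &
                model$times <= seg$t_off + model$hop_s)
  sub <- model
  sub$coeffs <- model$coeffs[, keep, drop = FALSE]
  sub$sigma2 <- model$sigma2[keep]
  sub$times <- model$times[keep]
  sp <- tvar_spectrum(sub, config$n_freq)
  fv <- compute_features(mep, sp, seg, os, pl)
  list(features = fv, segment = seg, overshoot = os, plateaus = pl, mep = mep)
}

#' Run the guide-wire event characterization pipeline
#'
#' Chains decimation, wavelet-scale reconstruction, TV-AR fit, TV-MEP and
#' spectrum, event segmentation, overshoot/plateau analysis and the
#' 16-feature computation; optionally classifies each event with a trained
#' model and scores against the recordings' labels.
#'
#' @param input as in [run_needle_pipeline()] (labels taken from the
#'   dataset/manifest/recording labels when present).
#' @param config a [pipeline_config()] (preset `"guidewire"`).
#' @param model optional [train_classifier()] result.
#' @return an object of class `guidewire_run`: `features` (one row per
#'   recording, columns `F1..F16`), `labels`, `predicted`, `metrics`
#'   (a `confusion_metrics` when both available), `errors`, `config`.
#' @export
run_guidewire_pipeline <- function(input,
                                   config = pipeline_config("guidewire"),
                                   model = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  inp <- resolve_inputs(input, c("t_on_ref", "t_off_ref"))
  n <- length(inp$recs)
  feats <- matrix(NA_real_, n, 16, dimnames = list(NULL, paste0("F", 1:16)))
  errors <- inp$errors
  for (i in seq_len(n)) {
    if (!is.na(errors[i])) next
    out <- tryCatch(guidewire_features_one(inp$recs[[i]], config),
                    error = function(e) e)
    if (inherits(out, "error")) errors[i] <- conditionMessage(out)
    else feats[i, ] <- out$features
  }
  labels <- inp$labels
  truth <- if (!is.null(labels))
    ifelse(labels == "perforation", "perforation", "artefact") else NULL
  predicted <- rep(NA_character_, n)
  metrics <- NULL
  ok <- is.na(errors)
  if (!is.null(model) && any(ok)) {
    predicted[ok] <- classify_event(model, feats[ok, , drop = FALSE])
    if (!is.null(truth))
      metrics <- confusion_metrics(predicted[ok], truth[ok])
  }
  structure(list(features = as.data.frame(feats), labels = labels,
                 truth = truth, predicted = predicted, metrics = metrics,
                 errors = errors, config = config),
            class = "guidewire_run")
}

#' @export
print.guidewire_run <- function(x, ...) {
  cat(sprintf("<guidewire_run> %d recordings (%d failed)\n",
              nrow(x$features), sum(!is.na(x$errors))))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Export guide-wire features as CSV
#'
#' One row per recording: columns `F1..F16` plus `label` (when known) and
#' `predicted` (when a classifier was applied).
#'
#' @param run a [run_guidewire_pipeline()] result.
#' @param path output CSV path.
#' @export
write_features_csv <- function(run, path) {
  stopifnot(inherits(run, "guidewire_run"))
  d <- run$features
  if (!is.null(run$labels)) d$label <- run$labels
  if (any(!is.na(run$predicted))) d$predicted <- run$predicted
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' End-to-end synthetic guide-wire benchmark
#'
#' Generates a labelled synthetic corpus with the published composition
#' ratios (perforation : friction : bump = 560 : 165 : 150, balanced
#' training split 100 : 50 : 50 and test split 460 : 115 : 100) scaled by
#' `scale`, extracts features for every recording, trains the classifier on
#' the balanced split and scores the held-out test set.
#'
#' @param seed master seed for corpus generation.
#' @param scale composition scale factor (default 1/5, i.e. 112/33/30
#'   recordings of which 20/10/10 train).
#' @param config a guide-wire [pipeline_config()].
#' @return list with `metrics` (a `confusion_metrics`), `model`, `train`
#'   and `test` guidewire_run objects.
#' @export
guidewire_benchmark <- function(seed = 1L, scale = 1 / 5,
                                config = pipeline_config("guidewire")) {
  comp_train <- round(c(perforation = 100, friction = 50, bump = 50) * scale)
  comp_test <- round(c(perforation = 460, friction = 115, bump = 100) * scale)
  ds_train <- gen_dataset("guidewire", comp_train, seed = derive_seed(seed, 1))
  ds_test <- gen_dataset("guidewire", comp_test, seed = derive_seed(seed, 2))
  run_tr <- run_guidewire_pipeline(ds_train, config)
  ok_tr <- is.na(run_tr$errors)
  model <- train_classifier(run_tr$features[ok_tr, ], run_tr$truth[ok_tr],
                            cost_grid = config$svm$cost_grid,
                            gamma_grid = config$svm$gamma_grid)
  run_te <- run_guidewire_pipeline(ds_test, config, model = model)
  list(metrics = run_te$metrics, model = model,
       train = run_tr, test = run_te)
}
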