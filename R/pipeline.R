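# End-to-end pipeline: synthesize a cohort -> preprocess -> train the
# network -> predict -> evaluate, plus the interval-feature MLR baseline,
# with a manifest (config hash, seed, versions) for reproducibility.
# Every stage is an exported library function; the CLI script under
# inst/cli/ is a thin wrapper over run_pipeline() and the stage functions.

#' Pipeline configuration
#'
#' @param n_subjects number of synthetic subjects.
#' @param duration_s recording length per subject, seconds.
#' @param subject_sbp_intercepts,subject_dbp_intercepts per-subject BP
#'   intercepts (recycled); distinct values give the cohort the
#'   between-subject variability that separates calibration-based from
#'   calibration-free (LOSO) difficulty.
#' @param synth base [synth_config()] shared by all subjects (per-subject
#'   seed and intercepts are overridden).
#' @param channels input-signal combination, any non-empty subset of
#'   ecg/ppg/bcg.
#' @param stride_s window stride in seconds.
#' @param model_scale width multiplier for [bp_net_config()] (1 = the
#'   full-size network; smaller for CPU-scale runs).
#' @param bn_momentum batch-norm running-statistic momentum. The full-size
#'   default is 0.99; reduced CPU-scale runs see few updates per epoch, so
#'   0.9 is used here for the running statistics to converge within the
#'   first epochs (validation is evaluated in eval mode).
#' @param train a [train_config()].
#' @param mode `"calibration"` or `"loso"`.
#' @param holdout_subject LOSO held-out subject id (default: the last).
#' @param outlier_removal apply the mean +/- 1.96 SD target rule.
#' @param seed global seed; per-subject generator seeds derive from it.
#' @return list of class `bp_pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 3, duration_s = 120,
                            subject_sbp_intercepts = c(155, 165, 175),
                            subject_dbp_intercepts = c(85, 95, 105),
                            synth = synth_config(duration_s = duration_s),
                            channels = c("ecg", "ppg", "bcg"),
                            stride_s = 0.25,
                            model_scale = 1 / 8,
                            bn_momentum = 0.9,
                            train = train_config(batch_size = 64),
                            mode = c("calibration", "loso"),
                            holdout_subject = NULL,
                            outlier_removal = TRUE,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (length(channels) == 0 || !all(channels %in% c("ecg", "ppg", "bcg")))
    stop_cfg("channels must be a non-empty subset of ecg, ppg, bcg")
  structure(list(
    n_subjects = n_subjects, duration_s = duration_s,
    subject_sbp_intercepts = rep_len(subject_sbp_intercepts, n_subjects),
    subject_dbp_intercepts = rep_len(subject_dbp_intercepts, n_subjects),
    synth = synth, channels = channels, stride_s = stride_s,
    model_scale = model_scale, bn_momentum = bn_momentum,
    train = train, mode = mode,
    holdout_subject = holdout_subject, outlier_removal = outlier_removal,
    seed = as.integer(seed)
  ), class = "bp_pipeline_config")
}

#' Generate a multi-subject synthetic cohort
#'
#' @param cfg a [pipeline_config()].
#' @return list with `recordings`, `truths` (per subject, named `s1`, ...).
#' @export
make_cohort <- function(cfg) {
  recs <- list(); truths <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sc <- cfg$synth
    sc$duration_s <- cfg$duration_s
    sc$sbp_intercept <- cfg$subject_sbp_intercepts[s]
    sc$dbp_intercept <- cfg$subject_dbp_intercepts[s]
    sc$seed <- derive_seed(cfg$seed, 100L + s)
    validate_synth_config(sc)
    out <- generate_recording(sc)
    sid <- paste0("s", s)
    recs[[sid]] <- out$recording
    truths[[sid]] <- out$truth
  }
  list(recordings = recs, truths = truths)
}

#' Preprocess a cohort into a pooled windowed dataset
#'
#' Filter at native rate, resample to 125 Hz, segment with end-of-window
#' targets, pool subjects, optionally remove target outliers.
#'
#' @param recordings named list of `bp_recording`s.
#' @param cfg a [pipeline_config()].
#' @return a pooled `bp_windows`.
#' @export
preprocess_cohort <- function(recordings, cfg) {
  parts <- lapply(names(recordings), function(sid) {
    rec <- filter_recording(recordings[[sid]])
    rec <- resample_record(rec, 125)
    segment(rec, window_s = 5, stride_s = cfg$stride_s,
            channels = cfg$channels, subject_id = sid)
  })
  ds <- bind_windows(parts)
  if (cfg$outlier_removal) ds <- remove_outlier_targets(ds)
  ds
}

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[cufflessbp] ", fmt), ...))
}

#' Run the full pipeline
#'
#' synth -> preprocess -> split -> train -> predict -> evaluate, plus the
#' MLR baseline on native-rate fiducials. Writes evaluation reports and a
#' manifest when `outdir` is given; reruns with the same config and seed
#' reproduce the metrics exactly (single-threaded).
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory for JSON reports and the manifest
#'   (optional).
#' @param verbose print stage progress.
#' @return list with `deep` and `mlr` (`bp_eval_report`s), `net`,
#'   `history`, `splits`, `dataset`, `mlr_fit`, `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(cfg, "bp_pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }

  stage_msg(verbose, "synth: %d subject(s) x %g s", cfg$n_subjects, cfg$duration_s)
  cohort <- make_cohort(cfg)
  tick("synth")

  stage_msg(verbose, "preprocess: channels %s, stride %g s",
            paste(cfg$channels, collapse = "+"), cfg$stride_s)
  ds <- preprocess_cohort(cohort$recordings, cfg)
  stage_msg(verbose, "preprocess: %d windows kept (%d target outliers removed)",
            length(ds), attr(ds, "n_removed") %||% 0L)
  tick("preprocess")

  holdout <- cfg$holdout_subject %||% paste0("s", cfg$n_subjects)
  splits <- split_dataset(ds, cfg$train, mode = cfg$mode,
                          holdout_subject = if (cfg$mode == "loso") holdout)
  stage_msg(verbose, "split (%s): train %d / val %d / test %d", cfg$mode,
            length(splits$train), length(splits$val), length(splits$test))
  net <- bp_net(bp_net_config(in_channels = length(cfg$channels),
                              scale = cfg$model_scale,
                              bn_momentum = cfg$bn_momentum),
                seed = derive_seed(cfg$seed, 7L))
  fitres <- fit(net, splits$train, splits$val, cfg$train, verbose = verbose)
  stage_msg(verbose, "train: stopped at epoch %d (best %d)",
            fitres$history$stopped_epoch, fitres$history$best_epoch)
  tick("train")

  pred <- predict(fitres$net, splits$test)
  deep_report <- eval_report(splits$test$y_sbp, pred$sbp_hat,
                             splits$test$y_dbp, pred$dbp_hat,
                             n_subjects = length(unique(splits$test$subject_id)),
                             label = sprintf("CNN+BiGRU+attention (%s, %s)",
                                             paste(cfg$channels, collapse = "+"),
                                             cfg$mode))
  tick("predict_evaluate")

  stage_msg(verbose, "baseline: fiducial features + MLR")
  feats <- do.call(rbind, lapply(names(cohort$recordings), function(sid) {
    f <- extract_features(cohort$recordings[[sid]])
    f$subject_id <- sid
    f
  }))
  mlr_fit <- fit_mlr(feats)
  mlr_pred <- predict(mlr_fit, feats)
  mlr_report <- eval_report(feats$sbp, mlr_pred$sbp_hat,
                            feats$dbp, mlr_pred$dbp_hat,
                            n_subjects = length(unique(feats$subject_id)),
                            label = "MLR (rri, ptt, rji)")
  tick("baseline")

  manifest <- list(
    package = "cufflessbp",
    version = as.character(utils::packageVersion("cufflessbp")),
    r_version = R.version.string,
    seed = cfg$seed,
    config_hash = config_hash(pipeline_config_fingerprint(cfg)),
    timings_s = timings,
    n_windows = length(ds),
    n_cycles_mlr = nrow(feats)
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_eval_report(deep_report, file.path(outdir, "report_deep.json"))
    write_eval_report(mlr_report, file.path(outdir, "report_mlr.json"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(deep = deep_report, mlr = mlr_report, net = fitres$net,
       history = fitres$history, splits = splits, dataset = ds,
       mlr_fit = mlr_fit, manifest = manifest)
}

# stable, JSON-serializable view of the config for hashing
pipeline_config_fingerprint <- function(cfg) {
  fp <- unclass(cfg)
  fp$synth <- unclass(fp$synth)
  fp$train <- unclass(fp$train)
  fp
}

#' Scaled-down end-to-end demo
#'
#' Runs the whole pipeline on a small synthetic cohort with a reduced-width
#' network, suitable for a single CPU.
#'
#' @param outdir optional output directory for reports.
#' @param seed global seed.
#' @param verbose print stage progress.
#' @return see [run_pipeline()].
#' @export
demo_pipeline <- function(outdir = NULL, seed = 1L, verbose = TRUE) {
  cfg <- pipeline_config(
    n_subjects = 3, duration_s = 120,
    stride_s = 0.5, model_scale = 1 / 8,
    train = train_config(max_epochs = 12, patience = 5, batch_size = 64,
                         seed = seed),
    seed = seed
  )
  run_pipeline(cfg, outdir = outdir, verbose = verbose)
}
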