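#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. Each random stage
#' receives a sub-seed derived deterministically from the master seed and the
#' stage name, so adding or toggling stages never perturbs the others and a
#' config plus seed fully reproduces a run.
#'
#' @param seed Master seed (integer).
#' @param session A [session_config()]; its seed is replaced by the derived
#'   `simulate` sub-seed.
#' @param n_bins Normalized bin count for SDF tensors.
#' @param bin_width SDF count-window width (s).
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "behavior", "sdf", "correlate", "scaling", "decompose",
#'   "categorize", "decode", "speed")`.
#' @param decode_subset_size,decode_runs,decode_noise_sd Decoder settings.
#' @param ks_frac,ks_runs Scaling KS-bootstrap settings.
#' @param out_dir Optional output directory; when given, stage outputs are
#'   written as CSV/JSON together with a machine-readable manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            session = session_config(
                              n_trials = 60,
                              stereotypes = stereotype_mixture(
                                c(linear_increasing = 0.4,
                                  ramp_to_threshold_up = 0.4,
                                  unrelated_noise = 0.2),
                                n_units = 30)),
                            n_bins = 40,
                            bin_width = 0.1,
                            stages = c("simulate", "behavior", "sdf",
                                       "correlate", "scaling", "decompose",
                                       "categorize", "decode", "speed"),
                            decode_subset_size = 20,
                            decode_runs = 100,
                            decode_noise_sd = 0.5,
                            ks_frac = 0.1,
                            ks_runs = 500,
                            out_dir = NULL) {
  structure(list(seed = as.integer(seed), session = session, n_bins = n_bins,
                 bin_width = bin_width, stages = stages,
                 decode_subset_size = decode_subset_size,
                 decode_runs = decode_runs, decode_noise_sd = decode_noise_sd,
                 ks_frac = ks_frac, ks_runs = ks_runs, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order on a synthetic session:
#' simulate, behavioral summary, SDF tensors (measurement and warped
#' reproduction), correlation battery, temporal-scaling indices with KS
#' bootstrap, demixed + conventional PCA, response-type categorization, time
#' decoding, and speed-response functions. Identical config and seed give
#' identical numeric outputs. When `out_dir` is set, stage outputs are
#' written as CSV/JSON plus a `manifest.json` (stage, sub-seed, runtime,
#' files).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of stage results plus `manifest` (data.frame).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  manifest <- list()
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  note <- function(stage, seed, t0, files = character(0)) {
    manifest[[stage]] <<- data.frame(
      stage = stage, seed = seed,
      runtime_s = round(as.numeric(Sys.time()) - t0, 3),
      files = paste(files, collapse = ";"))
  }
  need <- function(stage, dep) {
    if (is.null(res[[dep]])) {
      stop(sprintf("stage '%s' needs upstream stage '%s'", stage, dep))
    }
  }
  has <- function(stage) stage %in% config$stages

  if (has("simulate")) {
    sd_ <- derive_seed(config$seed, "simulate"); t0 <- as.numeric(Sys.time())
    cfg <- config$session; cfg$seed <- sd_
    res$session <- generate_session(cfg)
    files <- character(0)
    if (!is.null(out_dir)) {
      files <- write_session_csv(res$session, out_dir)
    }
    note("simulate", sd_, t0, files)
  }

  if (has("behavior")) {
    need("behavior", "session"); t0 <- as.numeric(Sys.time())
    res$behavior <- behavior_summary(res$session$trials)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "behavior_summary.csv")
      utils::write.csv(res$behavior, f, row.names = FALSE); files <- f
    }
    note("behavior", NA, t0, files)
  }

  if (has("sdf")) {
    need("sdf", "session"); t0 <- as.numeric(Sys.time())
    warped <- warp_reproduction_trials(res$session$spikes)
    res$sdf_meas <- normalize_and_zscore(
      compute_sdf(res$session$spikes, "measurement", "begin",
                  config$bin_width), config$n_bins)
    res$sdf_repro <- normalize_and_zscore(
      compute_sdf(warped, "reproduction", "begin", config$bin_width),
      config$n_bins)
    note("sdf", NA, t0)
  }

  if (has("correlate")) {
    need("correlate", "sdf_meas"); t0 <- as.numeric(Sys.time())
    res$correlations <- list(
      pairwise = correlate(res$sdf_repro, mode = "pairwise_cells"),
      cross_phase = correlate(res$sdf_meas, res$sdf_repro,
                              mode = "cell_cross_phase"),
      stimulus_pairs = correlate(res$sdf_repro, mode = "cell_stimulus_pairs"))
    res$correlation_fractions <- vapply(res$correlations,
                                        significant_fraction, 1.0)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "correlation_fractions.json")
      jsonlite::write_json(as.list(res$correlation_fractions), f,
                           auto_unbox = TRUE, digits = NA)
      files <- f
    }
    note("correlate", NA, t0, files)
  }

  if (has("scaling")) {
    need("scaling", "sdf_repro")
    sd_ <- derive_seed(config$seed, "scaling"); t0 <- as.numeric(Sys.time())
    ref <- config$session$grid$mean
    res$scaling <- scaling_indices(res$sdf_repro, reference = ref)
    res$scaling_shuffled <- shuffled_scaling_indices(res$sdf_repro,
                                                     reference = ref,
                                                     seed = sd_)
    sd2 <- derive_seed(config$seed, "scaling_ks")
    short <- min(res$sdf_repro$stimuli)
    ks <- tryCatch(
      bootstrap_ks_scaling(
        res$scaling$index[res$scaling$stimulus == short],
        res$scaling_shuffled$index[res$scaling_shuffled$stimulus == short],
        frac = config$ks_frac, runs = config$ks_runs, seed = sd2),
      error = function(e) list(p_values = numeric(0), frac_significant = NaN))
    res$scaling_ks <- ks
    files <- character(0)
    if (!is.null(out_dir)) {
      f1 <- file.path(out_dir, "scaling_indices.csv")
      utils::write.csv(res$scaling, f1, row.names = FALSE)
      f2 <- file.path(out_dir, "scaling_ks.json")
      jsonlite::write_json(list(frac_significant = ks$frac_significant), f2,
                           auto_unbox = TRUE, digits = NA)
      files <- c(f1, f2)
    }
    note("scaling", sd_, t0, files)
  }

  if (has("decompose")) {
    need("decompose", "sdf_repro"); t0 <- as.numeric(Sys.time())
    res$decomp_meas <- demixed_pca(res$sdf_meas)
    res$decomp_repro <- demixed_pca(res$sdf_repro)
    res$conventional_repro <- conventional_pca(res$sdf_repro)
    res$trajectories <- trajectory_metrics(res$conventional_repro)
    note("decompose", NA, t0)
  }

  if (has("categorize")) {
    need("categorize", "decomp_meas"); t0 <- as.numeric(Sys.time())
    res$categories_meas <- categorize_units(res$decomp_meas, "measurement")
    res$categories_repro <- categorize_units(res$decomp_repro, "reproduction")
    res$transitions <- transition_table(res$categories_meas,
                                        res$categories_repro)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "categories_reproduction.csv")
      utils::write.csv(res$categories_repro, f, row.names = FALSE); files <- f
    }
    note("categorize", NA, t0, files)
  }

  if (has("decode")) {
    need("decode", "sdf_repro")
    sd_ <- derive_seed(config$seed, "decode"); t0 <- as.numeric(Sys.time())
    res$decode <- bootstrap_decode(res$sdf_repro,
                                   subset_size = min(config$decode_subset_size,
                                                     res$sdf_repro$n_units),
                                   runs = config$decode_runs,
                                   noise_sd = config$decode_noise_sd,
                                   seed = sd_)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "decode_slopes.json")
      jsonlite::write_json(list(slope_median = res$decode$slope_median,
                                slope_iqr = res$decode$slope_iqr), f,
                           auto_unbox = TRUE, digits = NA)
      files <- f
    }
    note("decode", sd_, t0, files)
  }

  if (has("speed")) {
    need("speed", "session")
    sd_ <- derive_seed(config$seed, "speed"); t0 <- as.numeric(Sys.time())
    trace <- session_speed_trace(res$session)
    res$speed <- lapply(seq_len(res$session$spikes$n_units), function(u) {
      st <- unit_session_spikes(res$session, u)
      sr <- tryCatch(speed_response_function(st, trace,
                                             seed = derive_seed(sd_, paste0("u", u))),
                     error = function(e) NULL)
      if (is.null(sr)) return(data.frame(unit = u, index = NA, p = NA,
                                         significant = NA))
      data.frame(unit = u, index = modulation_index(sr), p = sr$p,
                 significant = sr$significant)
    })
    res$speed <- do.call(rbind, res$speed)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "speed_modulation.csv")
      utils::write.csv(res$speed, f, row.names = FALSE); files <- f
    }
    note("speed", sd_, t0, files)
  }

  res$manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  invisible(res)
}

#' Write / read a session in plain CSV long format
#'
#' `spikes.csv` holds one row per spike (`trial_id`, `unit_id`,
#' `spike_time_s`, trial-relative), `trials.csv` the trial table including
#' phase markers, and `speed.csv` the per-trial speed traces.
#'
#' @param session A [generate_session()] result.
#' @param dir Output directory.
#' @return `write_session_csv` returns the written file paths;
#'   `read_session_csv` returns a list with `trials`, `spikes` (a
#'   [spike_data()]), and `speed`.
#' @export
write_session_csv <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_tr <- file.path(dir, "trials.csv")
  tr <- session$trials
  utils::write.csv(tr, f_tr, row.names = FALSE)
  rows <- list()
  for (u in seq_len(session$spikes$n_units)) {
    for (i in seq_len(nrow(tr))) {
      st <- session$spikes$spikes[[u]][[i]]
      if (length(st)) {
        rows[[length(rows) + 1L]] <- data.frame(trial_id = i, unit_id = u,
                                                spike_time_s = st)
      }
    }
  }
  f_sp <- file.path(dir, "spikes.csv")
  utils::write.csv(do.call(rbind, rows), f_sp, row.names = FALSE)
  f_sd <- file.path(dir, "speed.csv")
  sp <- do.call(rbind, lapply(seq_along(session$speed), function(i) {
    cbind(trial_id = i, session$speed[[i]])
  }))
  utils::write.csv(sp, f_sd, row.names = FALSE)
  c(f_tr, f_sp, f_sd)
}

#' @rdname write_session_csv
#' @param dir Directory containing `trials.csv`, `spikes.csv`, `speed.csv`.
#' @export
read_session_csv <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "trials.csv"))
  sp <- utils::read.csv(file.path(dir, "spikes.csv"))
  n_units <- max(sp$unit_id)
  spikes <- lapply(seq_len(n_units), function(u) {
    lapply(seq_len(nrow(tr)), function(i) {
      sort(sp$spike_time_s[sp$unit_id == u & sp$trial_id == i])
    })
  })
  speed_df <- utils::read.csv(file.path(dir, "speed.csv"))
  speed <- lapply(seq_len(nrow(tr)), function(i) {
    speed_df[speed_df$trial_id == i, c("time", "speed")]
  })
  list(trials = tr, spikes = spike_data(spikes, tr), speed = speed)
}
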