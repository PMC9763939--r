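# End-to-end orchestration: a single config (YAML file or list) describes
# the experiment layout (condition -> replicate -> input files) and the
# module parameter blocks; the run functions emit the CSV artifacts that
# are the pipeline's contract. Reruns with the same config and inputs are
# byte-identical.

default_config <- function() {
  list(
    seed = 1,
    output_dir = "migrquant-out",
    io = list(frame_interval_s = 10, expected_frames = 60),
    detection = list(object_diameter_um = 10, quality_threshold = 0.2,
                     pixel_size_um = 0.65),
    linking = list(linking_max_distance_um = 10,
                   gap_closing_max_distance_um = 15,
                   gap_closing_max_frame_gap = 2),
    metrics = list(max_distance_mode = "all_pairs", max_lag_fraction = 1),
    stats = list(reference = NULL),
    vesicles = list(method = c("grid", "maxima"), square_px = 3,
                    positivity_factor = 2, prominence = 200,
                    pixel_size_um = 0.1626),
    experiment = list(conditions = list())
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a run configuration
#'
#' @param config Path to a YAML file or a named list; entries override the
#'   package defaults block-wise.
#' @return Complete configuration list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  merge_config(default_config(), config)
}

read_or_track_input <- function(path, cfg) {
  acq <- acquisition_info(frame_interval = cfg$io$frame_interval_s,
                          n_frames = cfg$io$expected_frames)
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    stack <- read_stack_tiff(path)
    dp <- detection_params(cfg$detection$object_diameter_um,
                           cfg$detection$quality_threshold,
                           cfg$detection$pixel_size_um)
    lp <- linking_params(cfg$linking$linking_max_distance_um,
                         cfg$linking$gap_closing_max_distance_um,
                         cfg$linking$gap_closing_max_frame_gap)
    ts <- track_movie(stack, dp, lp, frame_interval = acq$frame_interval)
    ts$acquisition <- acq
    ts
  } else {
    read_spots_table(path, acquisition = acq)
  }
}

write_csv_sorted <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the migration-analysis pipeline
#'
#' For every input (spots CSV or TIFF movie, auto-detected by extension) of
#' every condition and replicate: track (if needed), keep complete tracks,
#' compute per-track metrics and curves; then aggregate the
#' confinement-ratio decay (replicate medians) and MSD (replicate means) per
#' condition and run the SuperPlot statistics on each scalar metric.
#'
#' @param config YAML path or list; see [load_config()]. The experiment block
#'   must map conditions to replicates to input file paths.
#' @return Invisibly, a list with `metrics`, `cr_decay`, `msd`,
#'   `superplots`, `dropped`; the same tables are written to
#'   `output_dir` as `metrics.csv`, `cr_decay.csv`, `msd.csv`,
#'   `superplot_summary.csv`, `dropped_tracks.csv`.
#' @export
run_migration_analysis <- function(config) {
  cfg <- load_config(config)
  conds <- cfg$experiment$conditions
  if (!length(conds)) stop("config has no experiment conditions")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- NULL
  cr_long <- NULL
  msd_long <- NULL
  dropped <- NULL
  for (cond in names(conds)) {
    reps <- conds[[cond]]
    for (rep_name in names(reps)) {
      paths <- unlist(reps[[rep_name]])
      ts_list <- lapply(paths, read_or_track_input, cfg = cfg)
      spots <- do.call(rbind, lapply(seq_along(ts_list), function(i) {
        s <- ts_list[[i]]$spots
        # keep ids unique across files of one replicate
        s$track_id <- s$track_id + (i - 1) * 1e6
        s
      }))
      ts <- track_set(spots, ts_list[[1]]$acquisition)
      ts <- filter_complete(ts, cfg$io$expected_frames)
      rep_report <- attr(ts, "filter_report")
      dropped <- rbind(dropped, data.frame(
        condition = cond, replicate = rep_name,
        n_kept = rep_report$n_kept, n_dropped = rep_report$n_dropped))
      if (rep_report$n_kept == 0)
        stop("zero complete tracks in replicate '", rep_name,
             "' of condition '", cond, "'")
      mt <- metrics_table(ts, replicate = rep_name,
                          mode = cfg$metrics$max_distance_mode)
      mt <- cbind(data.frame(condition = cond), mt)
      metrics <- rbind(metrics, mt)
      cr <- curves_table(ts, "cr_decay", replicate = rep_name)
      msd <- curves_table(ts, "msd", replicate = rep_name,
                          max_lag_fraction = cfg$metrics$max_lag_fraction)
      cr_long <- rbind(cr_long, cbind(data.frame(condition = cond), cr))
      msd_long <- rbind(msd_long, cbind(data.frame(condition = cond), msd))
    }
  }
  agg_by_cond <- function(long, stat) {
    out <- lapply(split(long, long$condition), function(d)
      cbind(data.frame(condition = d$condition[1]),
            aggregate_curves(d, stat = stat)))
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  }
  cr_agg <- agg_by_cond(cr_long, "median")
  msd_agg <- agg_by_cond(msd_long, "mean")
  scalar_metrics <- c("max_distance", "path_length_D", "median_speed",
                      "confinement_ratio_CR")
  superplots <- lapply(scalar_metrics, function(m) {
    df <- data.frame(condition = metrics$condition,
                     replicate = metrics$replicate, value = metrics[[m]])
    df <- df[!is.na(df$value), ]
    sp <- superplot_summary(df)
    summ <- sp$conditions
    summ$metric <- m
    if (!is.null(sp$anova)) {
      summ$anova_F <- sp$anova$F
      summ$anova_p <- sp$anova$p
    }
    summ
  })
  superplot_df <- do.call(rbind, superplots)
  write_csv_sorted(metrics, file.path(cfg$output_dir, "metrics.csv"))
  write_csv_sorted(cr_agg, file.path(cfg$output_dir, "cr_decay.csv"))
  write_csv_sorted(msd_agg, file.path(cfg$output_dir, "msd.csv"))
  write_csv_sorted(superplot_df,
                   file.path(cfg$output_dir, "superplot_summary.csv"))
  write_csv_sorted(dropped, file.path(cfg$output_dir, "dropped_tracks.csv"))
  invisible(list(metrics = metrics, cr_decay = cr_agg, msd = msd_agg,
                 superplots = superplot_df, dropped = dropped))
}

#' Run the vesicle-dispersion pipeline
#'
#' Scores every single-cell crop of every condition/replicate with the
#' requested method(s) and runs the replicate-median statistics per method.
#'
#' @param config YAML path or list. The experiment block maps conditions to
#'   replicates to crop TIFF paths (one cell per crop).
#' @return Invisibly, a list with `scores` (all per-cell rows including
#'   exclusions) and `superplots` (per method); written to `output_dir` as
#'   `vesicle_scores.csv` and `vesicle_summary.csv`.
#' @export
run_vesicle_analysis <- function(config) {
  cfg <- load_config(config)
  conds <- cfg$experiment$conditions
  if (!length(conds)) stop("config has no experiment conditions")
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  gp <- grid_params(cfg$vesicles$square_px, cfg$vesicles$positivity_factor)
  mp <- maxima_params(cfg$vesicles$prominence)
  scores <- NULL
  for (cond in names(conds)) {
    reps <- conds[[cond]]
    for (rep_name in names(reps)) {
      paths <- unlist(reps[[rep_name]])
      crops <- lapply(paths, function(pp) read_stack_tiff(pp)[[1]])
      names(crops) <- basename(paths)
      sc <- batch_score(crops, method = cfg$vesicles$method, gp = gp,
                        mp = mp, pixel_size = cfg$vesicles$pixel_size_um)
      sc <- cbind(data.frame(condition = cond, replicate = rep_name), sc)
      scores <- rbind(scores, sc)
    }
  }
  ok <- scores[scores$status == "ok", ]
  if (!nrow(ok)) stop("all cells were excluded; nothing to analyze")
  superplots <- lapply(split(ok, ok$method), function(d) {
    df <- data.frame(condition = d$condition, replicate = d$replicate,
                     value = d$median_pairwise_distance)
    sp <- superplot_summary(df)
    summ <- sp$conditions
    summ$method <- d$method[1]
    if (!is.null(sp$anova)) {
      summ$anova_F <- sp$anova$F
      summ$anova_p <- sp$anova$p
    }
    summ
  })
  summary_df <- do.call(rbind, superplots)
  rownames(summary_df) <- NULL
  write_csv_sorted(scores, file.path(cfg$output_dir, "vesicle_scores.csv"))
  write_csv_sorted(summary_df, file.path(cfg$output_dir, "vesicle_summary.csv"))
  invisible(list(scores = scores, superplots = summary_df))
}
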