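#' Synthetic benchmark scenario
#'
#' Describes one cell of the synthetic protocol: uniform random moving
#' points in `[-1, 1]^3`, a random similarity transform (uniform rotation,
#' scale uniform in `scale_range`, translation uniform per axis within
#' `translation_magnitude`), optional gross outliers appended to the
#' reference set (count relative to the inliers) and optional deletion of
#' moving points (partial overlap).
#'
#' @param n_points moving points per trial (default 200).
#' @param scale_range scale sampling interval (default `c(1, 5)`).
#' @param translation_magnitude per-axis bound for the uniform `t_pre`.
#' @param outlier_ratio outliers appended to the reference set as a
#'   fraction of the inlier count.
#' @param missing_ratio fraction of moving points deleted before
#'   registration (the reference set is built from the full set).
#' @param n_trials trials per cell (default 20).
#' @param seed base seed; trial `i` uses `seed + i`.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(n_points = 200, scale_range = c(1, 5),
                            translation_magnitude = 0.5,
                            outlier_ratio = 0, missing_ratio = 0,
                            n_trials = 20, seed = 1L) {
  stopifnot(n_points >= 3, length(scale_range) == 2L,
            scale_range[1] > 0, scale_range[2] >= scale_range[1],
            translation_magnitude >= 0, outlier_ratio >= 0,
            missing_ratio >= 0, missing_ratio < 1, n_trials >= 1)
  structure(list(n_points = as.integer(n_points), scale_range = scale_range,
                 translation_magnitude = translation_magnitude,
                 outlier_ratio = outlier_ratio,
                 missing_ratio = missing_ratio,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Uniform random points in the unit cube
#'
#' @param n number of points (at least 3).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [point_set()] with coordinates i.i.d. uniform in `[-1, 1]`.
#' @export
gen_random_points <- function(n, seed = NULL) {
  stopifnot(n >= 3)
  m <- with_seed(seed, matrix(stats::runif(3 * n, -1, 1), n, 3L))
  point_set(m, label = "moving", source = "synthetic")
}

#' Generate one synthetic registration trial
#'
#' Draws the moving set and a random similarity transform, builds the
#' reference set from the full (pre-deletion) moving set, deletes
#' `floor(missing_ratio * n)` random moving points, and appends
#' `floor(outlier_ratio * n)` uniform outliers within the reference
#' bounding box. The ground-truth transform is recorded with its
#' pre-rotation translation.
#'
#' @param cfg a [scenario_config()].
#' @param trial_index trial number (1-based); fixes the trial seed.
#' @return a list of class `registration_trial`: `moving`, `reference`,
#'   `ground_truth`, `seed`.
#' @export
gen_trial <- function(cfg, trial_index = 1L) {
  stopifnot(inherits(cfg, "scenario_config"), trial_index >= 1)
  seed <- cfg$seed + as.integer(trial_index)
  with_seed(seed, {
    n <- cfg$n_points
    X_full <- matrix(stats::runif(3 * n, -1, 1), n, 3L)
    R <- random_rotation()
    s <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
    t_pre <- stats::runif(3, -cfg$translation_magnitude,
                          cfg$translation_magnitude)
    gt <- similarity_transform(s = s, rotation = R, t_pre = t_pre)
    Y <- apply_transform(gt, X_full)
    X <- X_full
    n_del <- floor(cfg$missing_ratio * n)
    if (n_del > 0) X <- X[-sample.int(n, n_del), , drop = FALSE]
    n_out <- floor(cfg$outlier_ratio * n)
    if (n_out > 0) {
      lo <- apply(Y, 2L, min)
      hi <- apply(Y, 2L, max)
      outliers <- cbind(stats::runif(n_out, lo[1], hi[1]),
                        stats::runif(n_out, lo[2], hi[2]),
                        stats::runif(n_out, lo[3], hi[3]))
      Y <- rbind(unclass(Y), outliers)
    }
    structure(list(moving = point_set(X, "moving", "synthetic"),
                   reference = point_set(Y, "reference", "synthetic"),
                   ground_truth = gt, seed = seed),
              class = "registration_trial")
  })
}

#' Run a registration sweep over scenario cells
#'
#' Executes `n_trials` seeded registrations for every cell of a scenario
#' grid, evaluates the success criterion against the recorded ground truth,
#' and returns one row per trial plus a per-cell summary. Per-trial
#' failures (errors raised by a stage) are recorded as unsuccessful trials;
#' they never abort the sweep.
#'
#' @param cells list of [scenario_config()] objects (one per cell).
#' @param config a [registration_config()]; its seed is combined with each
#'   trial's seed.
#' @param verbose print one line per cell.
#' @return a list of class `sweep_result` with `trials` (data frame) and
#'   `summary` (per-cell success rate and median runtime).
#' @export
run_sweep <- function(cells, config = registration_config(), verbose = FALSE) {
  if (inherits(cells, "scenario_config")) cells <- list(cells)
  rows <- list()
  for (ci in seq_along(cells)) {
    cfg <- cells[[ci]]
    stopifnot(inherits(cfg, "scenario_config"))
    for (ti in seq_len(cfg$n_trials)) {
      trial <- gen_trial(cfg, ti)
      cfg_t <- config
      cfg_t$seed <- trial$seed
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(
        register_point_sets(trial$moving, trial$reference, cfg_t,
                            ground_truth = trial$ground_truth),
        error = function(e) e)
      elapsed <- proc.time()[["elapsed"]] - t0
      failed <- inherits(res, "error")
      rows[[length(rows) + 1L]] <- data.frame(
        cell = ci, n_points = cfg$n_points,
        outlier_ratio = cfg$outlier_ratio,
        missing_ratio = cfg$missing_ratio, trial = ti, seed = trial$seed,
        success = if (failed) FALSE else res$success,
        rotation_error_rad = if (failed) NA_real_ else res$rotation_error_rad,
        translation_rel_error = if (failed) NA_real_ else res$translation_rel_error,
        scale_abs_error = if (failed) NA_real_ else res$scale_abs_error,
        error = if (failed) conditionMessage(res) else "",
        runtime_s = elapsed)
    }
    if (verbose) {
      cell_rows <- do.call(rbind, rows)
      cell_rows <- cell_rows[cell_rows$cell == ci, ]
      message(sprintf(
        "cell %d (n=%d, outliers=%.2f, missing=%.2f): %d/%d success, median %.2fs",
        ci, cfg$n_points, cfg$outlier_ratio, cfg$missing_ratio,
        sum(cell_rows$success), nrow(cell_rows),
        stats::median(cell_rows$runtime_s)))
    }
  }
  trials <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(trials, trials$cell), function(d) {
    data.frame(cell = d$cell[1L], n_points = d$n_points[1L],
               outlier_ratio = d$outlier_ratio[1L],
               missing_ratio = d$missing_ratio[1L], n_trials = nrow(d),
               n_success = sum(d$success),
               success_rate = mean(d$success) * 100,
               median_runtime_s = stats::median(d$runtime_s))
  }))
  rownames(summary) <- NULL
  structure(list(trials = trials, summary = summary), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write sweep results to CSV/JSON
#'
#' @param x a [run_sweep()] result.
#' @param csv_path per-trial CSV file (optional).
#' @param json_path summary JSON file (optional).
#' @return `x`, invisibly.
#' @export
write_sweep <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "sweep_result"))
  if (!is.null(csv_path)) utils::write.csv(x$trials, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(x$summary, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  invisible(x)
}
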