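#' Pipeline run configuration
#'
#' Bundles everything one reproducible analysis run needs: the simulation
#' preset and overrides, whether to render and re-detect a voxel stack (the
#' full imaging route) or analyse the generator's trace tables directly
#' (the fast trace-level route), the processing mode, and the analysis
#' parameters.
#'
#' @param preset simulation preset name (see [preset()]).
#' @param overrides named list of [sim_config()] overrides.
#' @param seed integer seed (forwarded into the simulation config).
#' @param render render a voxel stack and run segmentation/tracking
#'   (default FALSE: trace-level analysis).
#' @param mode `"default"` or `"gal4"` analysis-window mode.
#' @param klar apply the klar clearing compensation.
#' @param out_dir output directory for artifacts (`NULL`: keep everything
#'   in memory, write nothing).
#' @param track,analysis,gastro named lists overriding [link_tracks()],
#'   trace-processing and gastrulation parameters.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = "control", overrides = list(), seed = 1L,
                       render = FALSE, mode = c("default", "gal4"),
                       klar = FALSE, out_dir = NULL,
                       track = list(), analysis = list(), gastro = list()) {
  mode <- match.arg(mode)
  structure(list(preset = preset, overrides = overrides,
                 seed = as.integer(seed), render = render, mode = mode,
                 klar = klar, out_dir = out_dir, track = track,
                 analysis = analysis, gastro = gastro),
            class = "run_config")
}

arg_or <- function(lst, name, default) {
  if (!is.null(lst[[name]])) lst[[name]] else default
}

#' Run the full analysis pipeline on one synthetic embryo
#'
#' Executes simulate -> (optionally render -> segment -> track ->
#' extract) -> trace processing -> gastrulation analysis, writing CSV/JSON
#' artifacts when `out_dir` is set. Rerunning with the same config and
#' seed reproduces every output exactly.
#'
#' @param rc a [run_config()].
#' @return object of class `run_report`: list with `events`
#'   ([detect_milestones()] result), `transition`
#'   ([detect_transition()] result), `fold` (cohort fold change around
#'   invagination), `classification` (per-nucleus data.frame),
#'   `fraction_increasing`, `n_active`, `truth` (generator ground truth),
#'   `activity` (the processed `ms2_activity`), and `fingerprint`.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  cfg <- do.call(preset,
                 c(list(name = rc$preset), rc$overrides,
                   list(seed = rc$seed)))
  sim <- simulate_traces(cfg)
  traj <- simulate_movement(cfg)
  out <- rc$out_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_sim_config(cfg, file.path(out, "config.yaml"))
    write_table_csv(sim$traces, file.path(out, "sim_traces.csv"))
    write_table_csv(sim$truth$nuclei, file.path(out, "ground_truth.csv"))
  }

  if (rc$render) {
    grid <- render_stack(traj, sim$traces, cfg)
    seg <- segment_movie(grid)
    tracks <- link_tracks(seg$detections,
                          arg_or(rc$track, "max_link_dist", 6.0),
                          arg_or(rc$track, "lookback", 2L))
    raw <- extract_traces(grid, tracks, seg$labels)
    move_tracks <- tracks
    if (!is.null(out)) {
      write_voxel_grid(grid, file.path(out, "stack.tif"))
      write_table_csv(tracks, file.path(out, "tracks.csv"))
    }
  } else {
    raw <- data.frame(track_id = sim$traces$nucleus,
                      frame = sim$traces$frame, t = sim$traces$t,
                      value = sim$traces$value)
    move_tracks <- data.frame(track_id = traj$nucleus, frame = traj$frame,
                              t = traj$t, x_um = traj$x, y_um = traj$y,
                              z_um = traj$z)
  }

  raw <- filter_track_length(raw, arg_or(rc$analysis, "min_track_frames", 10))
  act <- call_activity(raw,
                       on_ratio = arg_or(rc$analysis, "on_ratio", 1.2),
                       min_on_frames = arg_or(rc$analysis, "min_on_frames", 5),
                       smooth_width = arg_or(rc$analysis, "smooth_width", 3))
  act <- normalize_traces(act)
  act <- exclude_pre_window(act, mode = rc$mode,
                            analysis_start = rc$analysis$analysis_start)
  if (rc$klar)
    act <- compensate_klar(act, arg_or(rc$analysis, "klar_fraction", 0.11))

  active_ids <- act$nuclei$track_id[act$nuclei$active]
  mtracks <- move_tracks[move_tracks$track_id %in% active_ids, ,
                         drop = FALSE]
  events <- if (nrow(mtracks)) {
    prof <- movement_profile(mtracks, frame_interval = cfg$frame_interval,
                             movement_smooth = arg_or(rc$gastro,
                                                      "movement_smooth", 5))
    detect_milestones(prof,
                      peak_fraction = arg_or(rc$gastro, "peak_fraction", 0.2))
  } else {
    structure(list(found = FALSE, t_constriction = NA_real_,
                   t_invagination = NA_real_, t_end = NA_real_,
                   n_peaks = 0L), class = "gastrulation_events")
  }

  tab <- act$table
  sel <- !is.na(tab$normalized)
  transition <- NULL
  fold <- NA_real_
  classification <- NULL
  frac_inc <- NA_real_
  if (any(sel)) {
    mt <- tapply(tab$normalized[sel], tab$t[sel], mean)
    tvec <- as.numeric(names(mt)); yvec <- as.numeric(mt)
    # search for the level transition only after cohort onset is complete
    # (otherwise the changepoint locks onto the activation ramp), and on the
    # median-smoothed cohort mean, as level plots are read
    onsets <- act$nuclei$onset[act$nuclei$active]
    w_start <- arg_or(rc$gastro, "transition_window_start",
                      stats::median(onsets, na.rm = TRUE) +
                        3 * stats::mad(onsets, na.rm = TRUE) + 2)
    ysm <- run_median(yvec, arg_or(rc$gastro, "transition_smooth", 9))
    min_seg <- arg_or(rc$gastro, "min_seg", 5)
    accept_ratio <- arg_or(rc$gastro, "accept_ratio", 2)
    transition <- tryCatch({
      tr1 <- detect_transition(tvec, ysm, window = c(w_start, max(tvec)),
                               min_seg = min_seg,
                               accept_ratio = accept_ratio)
      # refine in a window symmetric around the first estimate: unequal
      # plateau lengths skew the changepoint of a jittered (ramped) step
      half <- min(tr1$t_transition - w_start, max(tvec) - tr1$t_transition)
      tr2 <- tryCatch(
        detect_transition(tvec, ysm,
                          window = tr1$t_transition + c(-half, half),
                          min_seg = min_seg, accept_ratio = accept_ratio),
        error = function(e) tr1)
      if (tr1$found && !tr2$found) tr1 else tr2
    }, error = function(e) NULL)
    t_ref <- if (events$found) events$t_invagination else
      if (!is.null(transition) && transition$found)
        transition$t_transition else NA_real_
    if (is.finite(t_ref)) {
      fold <- tryCatch(fold_change(tvec, yvec, t_ref,
                                   arg_or(rc$gastro, "window_pre", 15),
                                   arg_or(rc$gastro, "window_post", 15)),
                       error = function(e) NA_real_)
      classification <- classify_cohort(
        act, t_ref,
        window_pre = arg_or(rc$gastro, "window_pre", 15),
        window_post = arg_or(rc$gastro, "window_post", 15),
        increase_fold = arg_or(rc$gastro, "increase_fold", 1.7))
      frac_inc <- mean(classification$increasing, na.rm = TRUE)
    }
  }

  report <- structure(list(
    events = events, transition = transition, fold = fold,
    classification = classification, fraction_increasing = frac_inc,
    n_active = length(active_ids), truth = sim$truth, activity = act,
    fingerprint = list(package = "ms2gastrula",
                       version = as.character(utils::packageVersion("ms2gastrula")),
                       preset = rc$preset, seed = rc$seed, mode = rc$mode,
                       klar = rc$klar)
  ), class = "run_report")

  if (!is.null(out)) {
    if (!is.null(classification))
      write_table_csv(classification, file.path(out, "classification.csv"))
    jsonlite::write_json(report_json(report), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_json <- function(report) {
  ev <- report$events
  tr <- report$transition
  list(
    events = list(found = ev$found, t_constriction = ev$t_constriction,
                  t_invagination = ev$t_invagination, t_end = ev$t_end,
                  n_peaks = ev$n_peaks),
    transition = if (is.null(tr)) NULL else
      list(found = tr$found, t_transition = tr$t_transition,
           level_pre = tr$level_pre, level_post = tr$level_post,
           fold = tr$fold),
    fold = report$fold,
    fraction_increasing = report$fraction_increasing,
    n_active = report$n_active,
    fingerprint = report$fingerprint
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> preset %s, seed %d: %d active nuclei\n",
              x$fingerprint$preset, x$fingerprint$seed, x$n_active))
  print(x$events)
  if (!is.null(x$transition)) print(x$transition)
  if (is.finite(x$fold))
    cat(sprintf("  cohort fold change at invagination: %.2f\n", x$fold))
  if (is.finite(x$fraction_increasing))
    cat(sprintf("  fraction of active nuclei increasing: %.2f\n",
                x$fraction_increasing))
  invisible(x)
}

#' Run a cohort of simulated embryos and collect transition statistics
#'
#' Simulates `n_embryos` embryos of one preset, each with an independent
#' seed and a per-embryo Gaussian jitter of the gastrulation timing (all
#' three milestones shifted together, SD `invag_jitter_sd` min, emulating
#' embryo-to-embryo variation in developmental timing), runs the
#' trace-level pipeline on each and returns the detected invagination and
#' transition times next to the ground truth.
#'
#' @param preset_name preset passed to [preset()].
#' @param n_embryos cohort size.
#' @param base_seed integer; embryo e uses seed `base_seed * 1000 + e`.
#' @param invag_jitter_sd SD of the per-embryo timing shift, min.
#' @param overrides extra [sim_config()] overrides shared by all embryos.
#' @param ... forwarded to [run_config()].
#' @return data.frame with one row per embryo: `embryo`, `seed`,
#'   `true_t_inv`, `det_t_inv`, `t_transition` (NA when no transition was
#'   accepted), `fold`, `fraction_increasing`, `n_active`.
#' @export
simulate_cohort <- function(preset_name = "control", n_embryos = 10,
                            base_seed = 1, invag_jitter_sd = 2,
                            overrides = list(), ...) {
  base <- do.call(preset, c(list(name = preset_name), overrides))
  rows <- vector("list", n_embryos)
  for (e in seq_len(n_embryos)) {
    seed_e <- base_seed * 1000L + e
    jit <- with_seed(seed_e + 500L, stats::rnorm(1, 0, invag_jitter_sd))
    ov <- utils::modifyList(overrides, list(
      t_constriction = base$t_constriction + jit,
      t_invagination = base$t_invagination + jit,
      t_end = base$t_end + jit))
    need <- ceiling((ov$t_end + 4) * 60 / base$frame_interval) + 1
    ov$n_frames <- max(base$n_frames, need)
    rep <- run_pipeline(run_config(preset_name, overrides = ov,
                                   seed = seed_e, ...))
    tr <- rep$transition
    rows[[e]] <- data.frame(
      embryo = e, seed = seed_e,
      true_t_inv = base$t_invagination + jit,
      det_t_inv = rep$events$t_invagination,
      t_transition = if (!is.null(tr) && tr$found) tr$t_transition
                     else NA_real_,
      fold = rep$fold, fraction_increasing = rep$fraction_increasing,
      n_active = rep$n_active)
  }
  do.call(rbind, rows)
}
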