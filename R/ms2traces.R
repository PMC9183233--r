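#' Extract raw MS2 traces from a movie
#'
#' For every tracked nucleus and frame, measures the maximum spot-channel
#' intensity over the nucleus's voxels — the proxy of nascent-spot
#' fluorescence — together with the mean intensity of each channel over the
#' same voxels (consumed by the nuclear-level and chromatin-proxy
#' quantifications).
#'
#' @param grid a [voxel_grid()].
#' @param tracks data.frame from [link_tracks()] (`track_id`, `frame`,
#'   `label`).
#' @param labels list of `label_volume` objects, one per frame (see
#'   [segment_movie()]).
#' @return data.frame with `track_id`, `frame`, `t` (min into nc14),
#'   `value` (raw spot-channel maximum, AU), `mean_spot`, `mean_nuclear`.
#' @export
extract_traces <- function(grid, tracks, labels) {
  stopifnot(inherits(grid, "voxel_grid"))
  tt <- grid_times(grid)
  out <- vector("list", length(unique(tracks$frame)))
  i <- 0
  for (f in sort(unique(tracks$frame))) {
    lv <- labels[[f]]
    lab <- as.vector(lv$labels)
    sel <- lab > 0
    labv <- lab[sel]
    spotv <- as.vector(grid$spot[, , , f, drop = TRUE])[sel]
    nuclv <- as.vector(grid$nuclear[, , , f, drop = TRUE])[sel]
    mx <- tapply(spotv, labv, max)
    ms <- tapply(spotv, labv, mean)
    mn <- tapply(nuclv, labv, mean)
    rows <- tracks[tracks$frame == f, , drop = FALSE]
    key <- as.character(rows$label)
    if (anyNA(match(key, names(mx))))
      stop_config("track references a label missing from frame %d", f)
    i <- i + 1
    out[[i]] <- data.frame(track_id = rows$track_id, frame = f, t = tt[f],
                           value = as.numeric(mx[key]),
                           mean_spot = as.numeric(ms[key]),
                           mean_nuclear = as.numeric(mn[key]))
  }
  res <- do.call(rbind, out[seq_len(i)])
  res[order(res$track_id, res$frame), , drop = FALSE]
}

#' Drop short tracks
#'
#' Retains only nuclei tracked for strictly more than `min_track_frames`
#' frames (a 10-frame track is dropped; an 11-frame track is kept, with the
#' default of 10).
#'
#' @param traces data.frame with `track_id` (one row per nucleus-frame).
#' @param min_track_frames length threshold, frames (default 10).
#' @return the filtered data.frame.
#' @export
filter_track_length <- function(traces, min_track_frames = 10) {
  if (nrow(traces) == 0) return(traces)
  len <- table(traces$track_id)
  keep <- names(len)[len > min_track_frames]
  out <- traces[as.character(traces$track_id) %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

baseline_at <- function(fit, t) fit[["intercept"]] + fit[["slope"]] * t

#' Two-pass baseline fitting and activity calling
#'
#' Implements the two-pass segregation of active and inactive nuclei:
#'
#' 1. The mean over all nuclei is computed per time point and fitted to a
#'    straight line (pass-1 baseline). Each trace is median-smoothed
#'    (`smooth_width` frames) and a frame is ON when the smoothed value is
#'    at least `on_ratio` times the baseline at that time (inclusive). A
#'    nucleus is provisionally active when its total ON-frame count reaches
#'    `min_on_frames`.
#' 2. The baseline is refitted to the mean of the pass-1 inactive nuclei
#'    and ON frames and activity are recomputed against it.
#'
#' The relative photobleaching curve is the median-smoothed (width 5)
#' inactive-nuclei mean divided by its value at the first analysed time
#' point (1 at the window start). If pass 1 leaves no inactive nucleus the
#' pass-1 baseline is reused with a warning and the bleach curve falls back
#' to the fitted line.
#'
#' @param traces data.frame with `track_id`, `t` (min into nc14), `value`.
#' @param on_ratio ON threshold as a multiple of the baseline (default 1.2).
#' @param min_on_frames ON frames required for an active call (default 5,
#'   cumulative).
#' @param smooth_width trace median-filter width, frames (default 3).
#' @return object of class `ms2_activity`: list with `table` (input plus
#'   `smoothed`, `on`), `nuclei` (`track_id`, `n_on`, `active`, `onset`),
#'   `fits` (pass-1 and pass-2 line coefficients, `fallback` flag, `bleach`
#'   data.frame of `t` and `curve`), and the parameters used.
#' @export
call_activity <- function(traces, on_ratio = 1.2, min_on_frames = 5,
                          smooth_width = 3) {
  stopifnot(on_ratio > 1, min_on_frames >= 1)
  if (nrow(traces) == 0 || length(unique(traces$track_id)) == 0)
    stop_config("activity calling requires at least one nucleus")
  tab <- traces[order(traces$track_id, traces$t), , drop = FALSE]
  times <- sort(unique(tab$t))

  mean_all <- tapply(tab$value, tab$t, mean)
  fit1 <- fit_line(as.numeric(names(mean_all)), as.numeric(mean_all))

  tab$smoothed <- stats::ave(tab$value, tab$track_id,
                             FUN = function(v) run_median(v, smooth_width))
  call_pass <- function(fit) {
    on <- tab$smoothed >= on_ratio * baseline_at(fit, tab$t)
    n_on <- tapply(on, tab$track_id, sum)
    list(on = on, n_on = n_on, active = n_on >= min_on_frames)
  }
  p1 <- call_pass(fit1)

  inactive_ids <- names(p1$active)[!p1$active]
  fallback <- length(inactive_ids) == 0
  if (fallback) {
    warning("no inactive nuclei after pass 1; reusing the pass-1 baseline")
    fit2 <- fit1
    bleach_raw <- baseline_at(fit1, times)
  } else {
    sub <- tab[as.character(tab$track_id) %in% inactive_ids, , drop = FALSE]
    m_in <- tapply(sub$value, sub$t, mean)
    fit2 <- fit_line(as.numeric(names(m_in)), as.numeric(m_in))
    bleach_raw <- as.numeric(m_in[as.character(times)])
  }
  p2 <- call_pass(fit2)
  tab$on <- p2$on

  curve <- run_median(bleach_raw, 5) / bleach_raw[1]
  if (any(!is.finite(curve)) || any(curve <= 0))
    stop_config("bleach curve is non-positive; check the inactive cohort")

  ids <- names(p2$n_on)
  onset <- rep(NA_real_, length(ids))
  for (k in which(p2$active)) {
    sel <- tab$track_id == ids[k] & tab$on
    onset[k] <- min(tab$t[sel])
  }
  structure(list(
    table = tab,
    nuclei = data.frame(track_id = ids, n_on = as.integer(p2$n_on),
                        active = as.logical(p2$active), onset = onset,
                        row.names = NULL),
    fits = list(pass1 = fit1, pass2 = fit2, fallback = fallback,
                bleach = data.frame(t = times, curve = curve)),
    params = list(on_ratio = on_ratio, min_on_frames = min_on_frames,
                  smooth_width = smooth_width)
  ), class = "ms2_activity")
}

#' @export
print.ms2_activity <- function(x, ...) {
  cat(sprintf("<ms2_activity> %d nuclei (%d active), %d time points\n",
              nrow(x$nuclei), sum(x$nuclei$active),
              length(unique(x$table$t))))
  cat(sprintf("  pass-2 baseline: %.2f %+.4f * t; bleach at end: %.3f\n",
              x$fits$pass2[["intercept"]], x$fits$pass2[["slope"]],
              tail(x$fits$bleach$curve, 1)))
  invisible(x)
}

#' Baseline subtraction and photobleaching normalization
#'
#' For active nuclei, `normalized(t) = (value(t) - baseline2(t)) /
#' bleach_curve(t)`: the fitted pass-2 baseline is removed from the raw
#' spot-channel maximum and the remainder is divided by the relative decline
#' of the inactive-nuclei mean, compensating fluorophore loss. Inactive
#' nuclei get `NA`.
#'
#' @param activity an `ms2_activity` from [call_activity()].
#' @return the `ms2_activity` with a `normalized` column added to `table`.
#' @export
normalize_traces <- function(activity) {
  stopifnot(inherits(activity, "ms2_activity"))
  tab <- activity$table
  bl <- activity$fits$bleach
  curve <- bl$curve[match(tab$t, bl$t)]
  if (any(!is.finite(curve) | curve <= 0))
    stop_config("bleach curve non-positive or undefined at some time")
  act <- activity$nuclei$track_id[activity$nuclei$active]
  norm <- (tab$value - baseline_at(activity$fits$pass2, tab$t)) / curve
  norm[!(as.character(tab$track_id) %in% as.character(act))] <- NA_real_
  activity$table$normalized <- norm
  activity
}

#' Exclude early-active nuclei and truncate the analysis window
#'
#' Discards nuclei whose activity onset precedes the analysis start — 15
#' min into nc14 by default, 30 min in `gal4` mode where maternal Gal4
#' drives early stochastic activity — and truncates all remaining rows to
#' `t >= analysis_start`.
#'
#' @param activity an `ms2_activity`.
#' @param mode `"default"` (15 min) or `"gal4"` (30 min).
#' @param analysis_start override of the window start, min into nc14.
#' @return the filtered `ms2_activity`.
#' @export
exclude_pre_window <- function(activity, mode = c("default", "gal4"),
                               analysis_start = NULL) {
  stopifnot(inherits(activity, "ms2_activity"))
  mode <- match.arg(mode)
  if (is.null(analysis_start))
    analysis_start <- if (mode == "gal4") 30 else 15
  early <- with(activity$nuclei, active & !is.na(onset) &
                  onset < analysis_start)
  drop_ids <- activity$nuclei$track_id[early]
  keep <- !(as.character(activity$table$track_id) %in%
              as.character(drop_ids)) & activity$table$t >= analysis_start
  activity$table <- activity$table[keep, , drop = FALSE]
  activity$nuclei <- activity$nuclei[!early, , drop = FALSE]
  activity$fits$bleach <-
    activity$fits$bleach[activity$fits$bleach$t >= analysis_start, ,
                         drop = FALSE]
  activity$params$analysis_start <- analysis_start
  activity
}

#' Total transcriptional output per nucleus
#'
#' Sum of the normalized transcription values of each active nucleus over a
#' time window (AU). An empty window gives 0 with a warning.
#'
#' @param activity a normalized `ms2_activity` (see [normalize_traces()]).
#' @param window numeric `c(t_a, t_b)`, min into nc14 (inclusive).
#' @return data.frame with `track_id` and `total`.
#' @export
total_output <- function(activity, window) {
  stopifnot(inherits(activity, "ms2_activity"), length(window) == 2)
  tab <- activity$table
  sel <- tab$t >= window[1] & tab$t <= window[2] & !is.na(tab$normalized)
  act <- activity$nuclei$track_id[activity$nuclei$active]
  if (!any(sel)) {
    warning("empty window; totals are 0")
    return(data.frame(track_id = act, total = 0))
  }
  s <- tapply(tab$normalized[sel], tab$track_id[sel], sum)
  out <- data.frame(track_id = act,
                    total = as.numeric(s[as.character(act)]))
  out$total[is.na(out$total)] <- 0
  out
}

#' Compensate klar-depletion clearing
#'
#' klar-depleted embryos are optically clearer and report brighter
#' fluorescence; when enabled, normalized values are scaled by
#' `1 - klar_fraction` (default 0.89) to remove the excess.
#'
#' @param activity a normalized `ms2_activity`.
#' @param klar_fraction fractional excess brightness (default 0.11).
#' @param enabled apply the compensation (default TRUE); when FALSE the
#'   object is returned unchanged.
#' @return the `ms2_activity` with scaled `normalized` values.
#' @export
compensate_klar <- function(activity, klar_fraction = 0.11, enabled = TRUE) {
  stopifnot(inherits(activity, "ms2_activity"),
            klar_fraction >= 0, klar_fraction < 1)
  if (!enabled) return(activity)
  activity$table$normalized <- activity$table$normalized * (1 - klar_fraction)
  activity$params$klar_fraction <- klar_fraction
  activity
}
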