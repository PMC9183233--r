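#' Dorso-ventral movement profile of a nucleus cohort
#'
#' Mean ventral-signed Y velocity of the supplied tracks per frame
#' (um/min), median-smoothed. "Ventral positive" means movement toward the
#' ventral midline; each track's ventral direction is the sign of
#' `midline_y - y(first frame)`, with the midline defaulting to the mean
#' initial Y of the supplied tracks (appropriate for a cohort of MSE
#' stripes flanking the mesoderm). Pass tracks restricted to the
#' transcribing nuclei of one region, as the analysis does.
#'
#' @param tracks data.frame with `track_id`, `frame`, `y_um` (or `y`) and
#'   optionally `t` (min into nc14); if `t` is absent it is derived from
#'   `frame` and `frame_interval`.
#' @param frame_interval seconds per frame (used when `t` is absent).
#' @param movement_smooth median-filter width, frames (default 5).
#' @param midline_y DV position of the ventral midline, um (default: mean
#'   initial y of the tracks).
#' @param magnitude if TRUE, average `|dy|/dt` instead of signed velocity.
#' @return data.frame with `t` (min into nc14), `v` (um/min) and `n`
#'   (nuclei contributing per frame).
#' @export
movement_profile <- function(tracks, frame_interval = 15,
                             movement_smooth = 5, midline_y = NULL,
                             magnitude = FALSE) {
  ycol <- if ("y_um" %in% names(tracks)) "y_um" else "y"
  if (!all(c("track_id", "frame") %in% names(tracks)) ||
      !ycol %in% names(tracks))
    stop_config("tracks must carry track_id, frame and y coordinates")
  if (nrow(tracks) == 0) stop_config("no tracks supplied")
  tk <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  if (!"t" %in% names(tk))
    tk$t <- (tk$frame - 1) * frame_interval / 60
  first <- !duplicated(tk$track_id)
  if (is.null(midline_y)) midline_y <- mean(tk[[ycol]][first])
  vsign <- sign(midline_y - tk[[ycol]][first])
  vsign[vsign == 0] <- 1
  names(vsign) <- tk$track_id[first]

  dy <- stats::ave(tk[[ycol]], tk$track_id, FUN = function(v) c(NA, diff(v)))
  dt <- stats::ave(tk$t, tk$track_id, FUN = function(v) c(NA, diff(v)))
  vel <- dy / dt
  vel <- if (magnitude) abs(vel) else vel * vsign[as.character(tk$track_id)]
  ok <- is.finite(vel)
  mean_v <- tapply(vel[ok], tk$t[ok], mean)
  n_v <- tapply(vel[ok], tk$t[ok], length)
  out <- data.frame(t = as.numeric(names(mean_v)), v = as.numeric(mean_v),
                    n = as.integer(n_v))
  out <- out[order(out$t), , drop = FALSE]
  out$v <- run_median(out$v, movement_smooth)
  rownames(out) <- NULL
  out
}

# local maxima of a series with prominence >= prom_min; returns indices
find_peaks <- function(v, prom_min) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # prominence: height above the higher of the two flanking minima,
    # searching outward until a higher point or the series end
    left <- v[seq_len(i - 1)]
    right <- v[(i + 1):n]
    lh <- which(left > v[i])
    rh <- which(right > v[i])
    lmin <- if (length(lh)) min(left[(max(lh) + 1):(i - 1)]) else min(left)
    rmin <- if (length(rh)) min(right[seq_len(min(rh) - 1)]) else min(right)
    keep[k] <- (v[i] - max(lmin, rmin)) >= prom_min
  }
  cand[keep]
}

#' Detect gastrulation milestones from a movement profile
#'
#' Interprets the ventral-signed DV movement profile of transcribing MSE
#' nuclei. A single dominant ventral peak marks mesoderm invagination:
#' its onset (`t_invagination`) is the first time the ventral profile
#' reaches `peak_fraction` of the peak height and `t_end` the first time
#' after the peak it falls back below that level. When an earlier
#' opposite-signed (dorsal) peak exists — a tilted mount rolling during
#' apical constriction — `t_constriction` is the onset of that first peak
#' and `t_invagination` is the time of minimum movement magnitude between
#' the two peaks. A profile with no peak above the noise floor (e.g. no
#' invagination) returns `found = FALSE`.
#'
#' @param profile data.frame from [movement_profile()] (`t`, `v`).
#' @param peak_fraction onset/offset threshold as a fraction of peak height
#'   (default 0.2); also used as the peak prominence floor.
#' @param noise_floor minimum peak height (um/min) regarded as real
#'   movement (default 0.5).
#' @return object of class `gastrulation_events`: list with `found`,
#'   `t_constriction` (NA for a ventrally mounted embryo),
#'   `t_invagination`, `t_end`, `n_peaks`.
#' @export
detect_milestones <- function(profile, peak_fraction = 0.2,
                              noise_floor = 0.5) {
  stopifnot(all(c("t", "v") %in% names(profile)))
  t <- profile$t; v <- profile$v
  vmax <- max(abs(v))
  res <- list(found = FALSE, t_constriction = NA_real_,
              t_invagination = NA_real_, t_end = NA_real_, n_peaks = 0L)
  class(res) <- "gastrulation_events"
  if (vmax < noise_floor) return(res)
  peaks <- find_peaks(abs(v), prom_min = peak_fraction * vmax)
  peaks <- peaks[abs(v)[peaks] >= noise_floor]
  if (!length(peaks)) return(res)
  ventral_peaks <- peaks[v[peaks] > 0]
  if (!length(ventral_peaks)) return(res)
  pv <- ventral_peaks[which.max(v[ventral_peaks])]
  dorsal_peaks <- peaks[v[peaks] < 0 & peaks < pv]

  # onset of a peak: walk back from the peak to the last sample below the
  # threshold and interpolate the crossing; noise crossings long before the
  # peak are then irrelevant
  cross_up <- function(s, thr, peak_i) {
    below <- which(s[seq_len(peak_i)] < thr)
    if (!length(below)) return(t[1])
    i <- max(below)
    t[i] + (t[i + 1] - t[i]) * (thr - s[i]) / (s[i + 1] - s[i])
  }
  thr <- peak_fraction * v[pv]
  if (length(dorsal_peaks)) {
    pd <- dorsal_peaks[which.max(abs(v)[dorsal_peaks])]
    res$n_peaks <- 2L
    trough <- pd + which.min(abs(v)[pd:pv]) - 1L
    res$t_invagination <- t[trough]
    res$t_constriction <- cross_up(abs(v), peak_fraction * abs(v[pd]), pd)
  } else {
    res$n_peaks <- 1L
    res$t_invagination <- cross_up(v, thr, pv)
  }
  after <- which(v < thr & seq_along(v) > pv)
  res$t_end <- if (length(after)) {
    i <- after[1]
    t[i - 1] + (t[i] - t[i - 1]) * (thr - v[i - 1]) / (v[i] - v[i - 1])
  } else t[length(t)]
  res$found <- TRUE
  res
}

#' @export
print.gastrulation_events <- function(x, ...) {
  if (!x$found) {
    cat("<gastrulation_events> no significant movement detected\n")
  } else {
    cat(sprintf(
      "<gastrulation_events> constriction %s, invagination %.2f, end %.2f min (%d peak%s)\n",
      if (is.na(x$t_constriction)) "-" else sprintf("%.2f", x$t_constriction),
      x$t_invagination, x$t_end, x$n_peaks, if (x$n_peaks > 1) "s" else ""))
  }
  invisible(x)
}

#' Detect the transcription-level transition point
#'
#' Exhaustive two-plateau piecewise-constant changepoint fit of a mean
#' transcription trace: every admissible changepoint (each segment at least
#' `min_seg` samples) is scored by residual sum of squares and the best one
#' kept. The transition is accepted (`found = TRUE`) only when the
#' one-plateau residual exceeds the two-plateau residual by the
#' variance-ratio criterion `SSE0 / SSE1 >= accept_ratio`, mirroring the
#' requirement that a clear change in levels be observable.
#'
#' @param t time, min into nc14 (sorted).
#' @param y mean normalized transcription (same length).
#' @param window optional `c(t_a, t_b)` restricting the search.
#' @param min_seg minimum samples per plateau (default 5).
#' @param accept_ratio variance-ratio acceptance threshold (default 2).
#' @return object of class `transition_result`: list with `found`,
#'   `t_transition` (time of the first sample of the upper plateau),
#'   `level_pre`, `level_post`, `fold`, `sse1`, `sse0`.
#' @export
detect_transition <- function(t, y, window = NULL, min_seg = 5,
                              accept_ratio = 2) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (!is.null(window)) {
    sel <- t >= window[1] & t <= window[2]
    t <- t[sel]; y <- y[sel]
  }
  o <- order(t); t <- t[o]; y <- y[o]
  n <- length(y)
  if (n < 2 * min_seg)
    stop_config("series shorter than two minimum segments (%d < %d)",
                n, 2 * min_seg)
  sse0 <- sum((y - mean(y))^2)
  # cumulative sums give O(1) segment SSE per candidate changepoint
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  ks <- min_seg:(n - min_seg)           # last index of the first plateau
  s1 <- cs[ks]; s2 <- cs2[ks]
  sseL <- s2 - s1^2 / ks
  sR1 <- cs[n] - s1; sR2 <- cs2[n] - s2
  sseR <- sR2 - sR1^2 / (n - ks)
  sse <- sseL + sseR
  k <- ks[which.min(sse)]
  sse1 <- min(sse)
  lev_pre <- mean(y[1:k]); lev_post <- mean(y[(k + 1):n])
  found <- sse0 > 0 && (sse1 == 0 || sse0 / sse1 >= accept_ratio)
  res <- list(found = found, t_transition = t[k + 1],
              level_pre = lev_pre, level_post = lev_post,
              fold = if (lev_pre > 0) lev_post / lev_pre else NA_real_,
              sse1 = sse1, sse0 = sse0)
  class(res) <- "transition_result"
  res
}

#' @export
print.transition_result <- function(x, ...) {
  if (!x$found) {
    cat("<transition_result> no clear transition\n")
  } else {
    cat(sprintf(
      "<transition_result> %.2f min: %.1f -> %.1f AU (fold %.2f)\n",
      x$t_transition, x$level_pre, x$level_post, x$fold))
  }
  invisible(x)
}

#' Classify a nucleus as increasing at gastrulation
#'
#' A nucleus "increases" when (1) its mean normalized intensity in the
#' `window_post` minutes after invagination onset exceeds the cohort mean
#' over the same window, and (2) that post mean is at least
#' `increase_fold` (default 1.7) times its own mean in the `window_pre`
#' minutes before invagination onset.
#'
#' @param t,y one nucleus's time (min) and normalized trace.
#' @param cohort_post_mean mean of all active nuclei over the post window.
#' @param t_invagination invagination onset, min into nc14.
#' @param window_pre,window_post window lengths, min (default 15 each).
#' @param increase_fold fold threshold (default 1.7, inclusive).
#' @return list with `increasing` (flag; NA when either window is not
#'   covered), `mean_pre`, `mean_post`, `fold`.
#' @export
classify_increasing <- function(t, y, cohort_post_mean, t_invagination,
                                window_pre = 15, window_post = 15,
                                increase_fold = 1.7) {
  stopifnot(increase_fold > 1, window_pre > 0, window_post > 0)
  pre <- t >= t_invagination - window_pre & t < t_invagination & is.finite(y)
  post <- t >= t_invagination & t <= t_invagination + window_post &
    is.finite(y)
  if (!any(pre) || !any(post))
    return(list(increasing = NA, mean_pre = NA_real_, mean_post = NA_real_,
                fold = NA_real_))
  m_pre <- mean(y[pre]); m_post <- mean(y[post])
  fold <- if (m_pre > 0) m_post / m_pre else Inf
  list(increasing = (m_post > cohort_post_mean) &&
         (m_post >= increase_fold * m_pre),
       mean_pre = m_pre, mean_post = m_post, fold = fold)
}

#' Classify every active nucleus of a cohort
#'
#' Applies [classify_increasing()] to each active nucleus of a normalized
#' [call_activity()] object, using the cohort mean over the post window as
#' the first criterion's reference.
#'
#' @param activity a normalized `ms2_activity`.
#' @param t_invagination invagination onset, min into nc14.
#' @inheritParams classify_increasing
#' @return data.frame with `track_id`, `increasing`, `mean_pre`,
#'   `mean_post`, `fold`.
#' @export
classify_cohort <- function(activity, t_invagination, window_pre = 15,
                            window_post = 15, increase_fold = 1.7) {
  stopifnot(inherits(activity, "ms2_activity"))
  tab <- activity$table
  act <- activity$nuclei$track_id[activity$nuclei$active]
  post <- tab$t >= t_invagination & tab$t <= t_invagination + window_post &
    is.finite(tab$normalized)
  cohort_post <- mean(tab$normalized[post])
  res <- lapply(act, function(id) {
    s <- tab[tab$track_id == id, , drop = FALSE]
    cl <- classify_increasing(s$t, s$normalized, cohort_post,
                              t_invagination, window_pre, window_post,
                              increase_fold)
    data.frame(track_id = id, increasing = cl$increasing,
               mean_pre = cl$mean_pre, mean_post = cl$mean_post,
               fold = cl$fold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fold change of a mean trace around a reference time
#'
#' Ratio of the mean over `[t_ref, t_ref + window_post]` to the mean over
#' `[t_ref - window_pre, t_ref)`. Invariant under global rescaling of the
#' trace; a non-positive pre-window mean gives NA with a warning.
#'
#' @param t,y time (min) and trace values.
#' @param t_ref reference time (e.g. invagination onset), min.
#' @param window_pre,window_post window lengths, min (default 15).
#' @return scalar fold change.
#' @export
fold_change <- function(t, y, t_ref, window_pre = 15, window_post = 15) {
  pre <- t >= t_ref - window_pre & t < t_ref & is.finite(y)
  post <- t >= t_ref & t <= t_ref + window_post & is.finite(y)
  if (!any(pre) || !any(post)) stop_config("windows not covered by trace")
  m_pre <- mean(y[pre])
  if (m_pre <= 0) {
    warning("pre-window mean is non-positive; fold change undefined")
    return(NA_real_)
  }
  mean(y[post]) / m_pre
}

#' Pooled squared Pearson correlation
#'
#' R^2 of paired per-embryo quantities (e.g. detected invagination onset vs
#' detected transition time) after pooling all pairs; pairs with a missing
#' member (no detected transition) are excluded. Fewer than 3 complete
#' pairs gives NA; a degenerate (constant) variable gives 0 with a warning.
#'
#' @param x,y paired numeric vectors.
#' @return scalar R^2 in `[0, 1]`.
#' @export
correlate_pooled <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("degenerate variable; R^2 reported as 0")
    return(0)
  }
  stats::cor(x, y)^2
}
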