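# Shared fixture builders. Everything is generated in code; no files.

# small, fast config for trace-level tests
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_mse = 12, n_me = 12, n_ne = 12, n_frames = 280, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# geometry for rendering tests: well-separated nuclei, small volume
render_cfg <- function(n = 4, n_frames = 3, ...) {
  args <- utils::modifyList(
    list(n_mse = n, n_me = n, n_ne = n,
         stripe_geometry = list(y_me = 25, mse_offset = 10,
                                ne_offset = 18, x_pitch = 12),
         n_frames = max(n_frames, 8), noise_sd = 0,
         t_onset = 0.1, t_constriction = 0.5, t_invagination = 0.6,
         t_end = 1.2, seed = 7L),
    list(...))
  do.call(sim_config, args)
}

# synthetic trace table: cohort of flat nuclei at `baseline` plus optional
# probe rows; returns data.frame(track_id, frame, t, value)
flat_cohort <- function(n_nuclei = 20, n_frames = 60, baseline = 100,
                       frame_interval = 15) {
  tt <- (seq_len(n_frames) - 1) * frame_interval / 60
  data.frame(
    track_id = rep(seq_len(n_nuclei), each = n_frames),
    frame = rep(seq_len(n_frames), n_nuclei),
    t = rep(tt, n_nuclei),
    value = baseline
  )
}

# add one probe nucleus with a rectangular pulse of `ratio` x baseline
with_probe <- function(cohort, ratio, pulse_frames, baseline = 100,
                       id = max(cohort$track_id) + 1L) {
  nf <- max(cohort$frame)
  tt <- sort(unique(cohort$t))
  probe <- data.frame(track_id = id, frame = seq_len(nf), t = tt,
                      value = baseline)
  probe$value[pulse_frames] <- ratio * baseline
  rbind(cohort, probe)
}

# brute-force reimplementation of the written linking rule, structured
# independently of link_tracks (explicit per-frame loops, track registry)
link_tracks_oracle <- function(det, cap = 6, lookback = 2) {
  det <- det[order(det$frame), , drop = FALSE]
  det$row <- seq_len(nrow(det))
  tracks <- list()   # each: list(rows, last_frame, last_row)
  for (f in sort(unique(det$frame))) {
    rows <- det$row[det$frame == f]
    claim <- rep(NA_integer_, length(rows))
    for (k in seq_along(rows)) {
      r <- rows[k]
      p <- c(det$x_um[det$row == r], det$y_um[det$row == r],
             det$z_um[det$row == r])
      for (back in seq_len(lookback)) {
        cands <- which(vapply(tracks, function(tr) tr$last_frame == f - back,
                              logical(1)))
        if (!length(cands)) next
        dd <- vapply(cands, function(ti) {
          lr <- tracks[[ti]]$last_row
          q <- c(det$x_um[det$row == lr], det$y_um[det$row == lr],
                 det$z_um[det$row == lr])
          sqrt(sum((p - q)^2))
        }, numeric(1))
        ok <- dd < cap
        if (any(ok)) {
          cands <- cands[ok]; dd <- dd[ok]
          tie <- cands[dd == min(dd)]
          lr <- vapply(tie, function(ti) tracks[[ti]]$last_row, numeric(1))
          claim[k] <- tie[which.min(lr)]
          break
        }
      }
    }
    tab <- table(claim[!is.na(claim)])
    contested <- as.integer(names(tab)[tab > 1])
    for (k in seq_along(rows)) {
      r <- rows[k]
      if (!is.na(claim[k]) && !(claim[k] %in% contested)) {
        tr <- tracks[[claim[k]]]
        tr$rows <- c(tr$rows, r); tr$last_frame <- f; tr$last_row <- r
        tracks[[claim[k]]] <- tr
      } else {
        tracks[[length(tracks) + 1]] <- list(rows = r, last_frame = f,
                                             last_row = r)
      }
    }
  }
  out <- det[, c("frame", "label", "x_um", "y_um", "z_um", "row")]
  out$track_id <- NA_integer_
  for (i in seq_along(tracks))
    out$track_id[out$row %in% tracks[[i]]$rows] <- i
  out$row <- NULL
  out
}

# canonical signature of a track partition: sorted multiset of per-track
# detection sets, invariant to track id relabelling
partition_signature <- function(tracks) {
  keys <- paste(tracks$frame, tracks$label, sep = ":")
  sort(vapply(split(keys, tracks$track_id),
              function(k) paste(sort(k), collapse = "|"), character(1)))
}

# exhaustive two-plateau SSE changepoint search (independent oracle)
cp_oracle <- function(y, min_seg = 5) {
  n <- length(y)
  best <- Inf; bk <- NA
  for (k in min_seg:(n - min_seg)) {
    s <- sum((y[1:k] - mean(y[1:k]))^2) +
      sum((y[(k + 1):n] - mean(y[(k + 1):n]))^2)
    if (s < best) { best <- s; bk <- k }
  }
  list(k = bk, sse = best)
}

# digitized solid ellipsoid as a label_volume (semi-axes in um)
ellipsoid_volume <- function(a, b, c, voxel_xy = 0.5, voxel_z = 0.5,
                             pad = 2) {
  nx <- ceiling(2 * (a + pad) / voxel_xy)
  ny <- ceiling(2 * (b + pad) / voxel_xy)
  nz <- ceiling(2 * (c + pad) / voxel_z)
  cx <- nx / 2 * voxel_xy; cy <- ny / 2 * voxel_xy; cz <- nz / 2 * voxel_z
  xs <- (seq_len(nx) - 0.5) * voxel_xy
  ys <- (seq_len(ny) - 0.5) * voxel_xy
  zs <- (seq_len(nz) - 0.5) * voxel_z
  arr <- array(0L, c(ny, nx, nz))
  for (z in seq_len(nz)) {
    m <- outer(ys, xs, function(y, x)
      ((x - cx) / a)^2 + ((y - cy) / b)^2 + ((zs[z] - cz) / c)^2 <= 1)
    arr[, , z] <- ifelse(m, 1L, 0L)
  }
  ms2gastrula:::new_label_volume(arr, voxel_xy, voxel_z)
}
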