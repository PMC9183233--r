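#' Link per-frame detections into nucleus tracks
#'
#' Nearest-neighbour linking with a hard distance cap and a two-frame
#' lookback. Detections are processed frame by frame in increasing frame
#' order and, within a frame, in input order (lowest detection index
#' first). For each detection at frame t the candidate is the nearest
#' active track whose last detection lies at frame t-1 and strictly closer
#' than `max_link_dist` um (3D Euclidean distance); only when no t-1
#' candidate is in range is a track ending at t-2 considered, bridging a
#' one-frame gap. Ties at exactly equal distance are broken toward the
#' track holding the lower detection index. If two or more detections in
#' the same frame claim the same candidate, all of the claimants start new
#' tracks and the claimed track is left unextended. A detection with no
#' in-range candidate starts a new track, so every detection belongs to
#' exactly one track.
#'
#' @param detections data.frame with `frame`, `label`, `x_um`, `y_um`,
#'   `z_um` (one row per detection; `label` unique within a frame).
#' @param max_link_dist cap on the centroid separation, um (default 6).
#' @param lookback frames to look back (default 2).
#' @return data.frame `track_id`, `frame`, `x_um`, `y_um`, `z_um`, `label`,
#'   sorted by track and frame.
#' @export
link_tracks <- function(detections, max_link_dist = 6.0, lookback = 2L) {
  stopifnot(max_link_dist > 0, lookback >= 1)
  req <- c("frame", "label", "x_um", "y_um", "z_um")
  if (!all(req %in% names(detections)))
    stop_config("detections must carry columns %s",
                paste(req, collapse = ", "))
  if (anyDuplicated(detections[, c("frame", "label")]))
    stop_config("duplicate (frame, label) pairs in detections")
  n <- nrow(detections)
  if (n == 0)
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), label = integer(0)))

  det <- detections[order(detections$frame), , drop = FALSE]
  det$row <- seq_len(n)
  frames <- sort(unique(det$frame))
  track_of <- integer(n)            # track id per detection row
  last_frame <- integer(0)          # per track: frame of last detection
  last_row <- integer(0)            # per track: detection row of last det
  next_track <- 0L

  coords <- as.matrix(det[, c("x_um", "y_um", "z_um")])
  new_track <- function(row) {
    next_track <<- next_track + 1L
    track_of[row] <<- next_track
    last_frame[next_track] <<- det$frame[row]
    last_row[next_track] <<- row
  }

  for (f in frames) {
    rows <- which(det$frame == f)
    # candidate search against the track state before this frame
    claims <- integer(length(rows))    # claimed track id or 0
    for (k in seq_along(rows)) {
      row <- rows[k]
      cand <- 0L
      for (back in seq_len(lookback)) {
        pool <- which(last_frame == f - back)
        if (!length(pool)) next
        dd <- sqrt(colSums((t(coords[last_row[pool], , drop = FALSE]) -
                              coords[row, ])^2))
        ok <- dd < max_link_dist
        if (any(ok)) {
          pool <- pool[ok]; dd <- dd[ok]
          best <- which(dd == min(dd))
          # tie-break toward the track whose last detection row is lowest
          cand <- pool[best[order(last_row[pool[best]])[1]]]
          break
        }
      }
      claims[k] <- cand
    }
    dup <- claims[claims > 0][duplicated(claims[claims > 0])]
    for (k in seq_along(rows)) {
      row <- rows[k]
      if (claims[k] > 0L && !(claims[k] %in% dup)) {
        track_of[row] <- claims[k]
        last_frame[claims[k]] <- f
        last_row[claims[k]] <- row
      } else {
        new_track(row)
      }
    }
  }
  out <- data.frame(track_id = track_of, frame = det$frame,
                    x_um = det$x_um, y_um = det$y_um, z_um = det$z_um,
                    label = det$label)
  out[order(out$track_id, out$frame), , drop = FALSE]
}
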