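#' Preprocess one 3D frame of the nuclear channel
#'
#' Applies a 3x3x3 median filter (replicate borders) followed by percentile
#' contrast rescaling: the `p_low` and `p_high` intensity percentiles are
#' mapped linearly to 0 and 1 (values outside clipped). Rescaling each frame
#' to the same range makes a fixed downstream threshold robust to
#' photobleaching. A constant volume maps to the low bound (0).
#'
#' @param volume 3D numeric array `(ny, nx, nz)`.
#' @param p_low,p_high rescaling percentiles (defaults 1 and 99.8).
#' @return 3D array of the same dim, values in `[0, 1]`.
#' @export
preprocess_volume <- function(volume, p_low = 1, p_high = 99.8) {
  if (length(volume) == 0 || is.null(dim(volume)) || length(dim(volume)) != 3)
    stop_config("volume must be a non-empty 3D array")
  med <- array(median_filter3_cpp(as.numeric(volume), dim(volume)),
               dim(volume))
  q <- quantile(med, c(p_low, p_high) / 100, names = FALSE)
  if (q[2] <= q[1]) return(array(0, dim(volume)))
  out <- (med - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Fourier-domain blob enhancement
#'
#' Band-pass filter that emphasises round objects of a given radius: the
#' volume is transformed with a 3D FFT and multiplied by a log-Gaussian
#' radial transfer function centred on the spatial frequency
#' `1 / (2 * blob_radius)` with the given octave bandwidth. Frequencies are
#' computed in physical units, so the anisotropic voxel size (z sampled
#' `voxel_z / voxel_xy` times coarser) is handled exactly. The DC component
#' is removed; the filter is linear and shift invariant.
#'
#' @param volume 3D numeric array `(ny, nx, nz)`.
#' @param blob_radius target object radius, um (default 3).
#' @param voxel_xy,voxel_z voxel size, um.
#' @param bandwidth filter bandwidth in octaves (default 1).
#' @return filtered 3D array (real part), same dim.
#' @export
enhance_blobs <- function(volume, blob_radius = 3, voxel_xy = 0.36,
                          voxel_z = 1.0, bandwidth = 1) {
  d <- dim(volume)
  if (blob_radius <= 0) stop_config("blob_radius must be positive")
  if (2 * blob_radius > max(d[1] * voxel_xy, d[2] * voxel_xy, d[3] * voxel_z))
    stop_config("blob_radius exceeds the volume extent")
  fftfreq <- function(n, spacing) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
    if (n == 1) k <- 0
    k / (n * spacing)
  }
  fy <- fftfreq(d[1], voxel_xy)
  fx <- fftfreq(d[2], voxel_xy)
  fz <- fftfreq(d[3], voxel_z)
  r <- sqrt(outer(outer(fy^2, fx^2, `+`), fz^2, `+`))
  f0 <- 1 / (2 * blob_radius)
  H <- array(0, d)
  nonzero <- r > 0
  H[nonzero] <- exp(-(log2(r[nonzero] / f0))^2 / (2 * (bandwidth / 2)^2))
  out <- fft(fft(volume) * H, inverse = TRUE) / length(volume)
  array(Re(out), d)
}

# 2D hole fill per z-plane plus 3D fill (background components not touching
# the volume border become foreground)
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  for (z in seq_len(d[3]))
    mask[, , z] <- EBImage::fillHull(mask[, , z]) > 0
  bg <- label_components_cpp(!mask, d, 6L)
  bg <- array(bg, d)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                     bg[, , c(1, d[3])]))
  holes <- bg > 0 & !(bg %in% border)
  mask | holes
}

#' Segment nuclei in one preprocessed, blob-enhanced 3D frame
#'
#' Chain: fixed intensity threshold -> per-plane and 3D hole filling ->
#' size exclusion -> watershed on the anisotropic Euclidean distance
#' transform (seeds at distance maxima with minimum separation
#' `blob_radius`) -> size exclusion again -> one-voxel non-overlapping
#' thickening (contested voxels go to the physically nearer object).
#'
#' Size bounds default to 0.25x-4x the expected nucleus volume
#' `(4/3) pi blob_radius^3` expressed in voxels. A threshold outside the
#' data range yields an all-background result with a warning.
#'
#' @param volume enhanced 3D array (see [enhance_blobs()]).
#' @param threshold fixed intensity threshold; if `NULL`, Otsu's threshold
#'   is computed from this volume (use [auto_threshold()] once per movie and
#'   pass it here to hold it fixed).
#' @param voxel_xy,voxel_z voxel size, um.
#' @param blob_radius expected nucleus radius, um.
#' @param min_size,max_size object size bounds in voxels.
#' @return object of class `label_volume`: list with `labels` (3D integer
#'   array, 0 = background), `sizes` (named voxel counts) and the
#'   calibration.
#' @export
segment_nuclei <- function(volume, threshold = NULL, voxel_xy = 0.36,
                           voxel_z = 1.0, blob_radius = 3,
                           min_size = NULL, max_size = NULL) {
  d <- dim(volume)
  expected <- (4 / 3) * pi * blob_radius^3 / (voxel_xy^2 * voxel_z)
  if (is.null(min_size)) min_size <- 0.25 * expected
  if (is.null(max_size)) max_size <- 4 * expected
  if (is.null(threshold)) threshold <- auto_threshold(volume)

  if (threshold >= max(volume) || threshold < min(volume)) {
    warning("threshold outside data range; returning all background")
    return(new_label_volume(array(0L, d), voxel_xy, voxel_z))
  }
  mask <- volume > threshold
  mask <- fill_holes_3d(mask)

  drop_by_size <- function(labels, lo, hi) {
    if (!any(labels > 0)) return(labels)
    sz <- tabulate(labels)
    bad <- which(sz < lo | sz > hi)
    labels[labels %in% bad] <- 0L
    labels
  }
  # first pass removes debris only; clusters of touching nuclei exceed the
  # single-nucleus upper bound and must survive to be split by the watershed
  lab <- array(label_components_cpp(mask, d, 26L), d)
  lab <- drop_by_size(lab, min_size, Inf)
  mask <- lab > 0

  spacing <- c(voxel_xy, voxel_xy, voxel_z)
  edt <- edt3_cpp(mask, d, spacing)
  radii <- pmax(1L, as.integer(round(blob_radius / spacing)))
  seeds <- local_maxima_cpp(edt, mask, d, radii)
  lab <- array(watershed_seeded_cpp(-edt, seeds, mask, d), d)
  lab <- drop_by_size(lab, min_size, max_size)
  lab <- array(dilate_labels_cpp(lab, d, spacing), d)
  lab <- relabel_sequential(lab)
  new_label_volume(lab, voxel_xy, voxel_z)
}

#' Otsu threshold of a volume
#'
#' Computes Otsu's threshold on the intensity histogram of a (typically
#' first-frame, enhanced) volume; hold the value fixed for the whole movie
#' for reproducible segmentation.
#'
#' @param volume numeric array.
#' @param levels histogram resolution (default 256).
#' @return scalar threshold on the intensity scale of `volume`.
#' @export
auto_threshold <- function(volume, levels = 256) {
  rng <- range(volume)
  if (diff(rng) == 0) return(rng[1])
  v01 <- (volume - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(as.vector(v01),
                                      dim = c(length(v01), 1)),
                       range = c(0, 1), levels = levels)
  rng[1] + thr * diff(rng)
}

relabel_sequential <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

new_label_volume <- function(labels, voxel_xy, voxel_z) {
  storage.mode(labels) <- "integer"
  sizes <- if (any(labels > 0)) tabulate(labels) else integer(0)
  structure(list(labels = labels, sizes = sizes, voxel_xy = voxel_xy,
                 voxel_z = voxel_z),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d objects\n",
              paste(dim(x$labels), collapse = " x "),
              sum(x$sizes > 0)))
  invisible(x)
}

#' Physical centroids of labelled objects
#'
#' Centroid of each object as the mean of its voxel centers in physical
#' coordinates: a voxel with 0-based index i along an axis has its center at
#' `(i + 0.5) * voxel_size`, so single-voxel objects report that voxel's
#' physical center. All coordinates in um.
#'
#' @param lv a `label_volume` (see [segment_nuclei()]).
#' @param frame optional frame index recorded in the output.
#' @return data.frame with `frame`, `label`, `x_um`, `y_um`, `z_um`,
#'   `n_voxels`.
#' @export
measure_centroids <- function(lv, frame = NA_integer_) {
  stopifnot(inherits(lv, "label_volume"))
  lab <- lv$labels
  d <- dim(lab)
  keep <- which(lab > 0)
  if (!length(keep))
    return(data.frame(frame = integer(0), label = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), n_voxels = integer(0)))
  l <- lab[keep]
  k0 <- keep - 1L
  iy <- k0 %% d[1]
  ix <- (k0 %/% d[1]) %% d[2]
  iz <- k0 %/% (d[1] * d[2])
  n <- tabulate(l)
  agg <- function(v) rowsum(v, l)[, 1] / n[sort(unique(l))]
  ids <- sort(unique(l))
  data.frame(
    frame = frame, label = ids,
    x_um = agg((ix + 0.5) * lv$voxel_xy),
    y_um = agg((iy + 0.5) * lv$voxel_xy),
    z_um = agg((iz + 0.5) * lv$voxel_z),
    n_voxels = n[ids],
    row.names = NULL
  )
}

#' Segment and measure every frame of a movie's nuclear channel
#'
#' Convenience driver: preprocesses and blob-enhances each frame, derives
#' the fixed threshold from the first frame (Otsu, unless given), segments
#' all frames with it, and returns detections plus the label volumes.
#'
#' @param grid a [voxel_grid()].
#' @param blob_radius expected nucleus radius, um.
#' @param threshold optional fixed threshold overriding the first-frame Otsu.
#' @param ... forwarded to [segment_nuclei()].
#' @return list with `detections` (row-bound [measure_centroids()] output)
#'   and `labels` (list of `label_volume` per frame).
#' @export
segment_movie <- function(grid, blob_radius = 3, threshold = NULL, ...) {
  stopifnot(inherits(grid, "voxel_grid"))
  nf <- dim(grid$nuclear)[4]
  labels <- vector("list", nf)
  dets <- vector("list", nf)
  for (f in seq_len(nf)) {
    v <- preprocess_volume(grid$nuclear[, , , f, drop = TRUE])
    v <- enhance_blobs(v, blob_radius, grid$voxel_xy, grid$voxel_z)
    if (f == 1L && is.null(threshold)) threshold <- auto_threshold(v)
    lv <- segment_nuclei(v, threshold, grid$voxel_xy, grid$voxel_z,
                         blob_radius, ...)
    labels[[f]] <- lv
    dets[[f]] <- measure_centroids(lv, frame = f)
  }
  list(detections = do.call(rbind, dets), labels = labels,
       threshold = threshold)
}
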