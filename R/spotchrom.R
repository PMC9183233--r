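# separable 3D Gaussian blur with replicate padding; sigma in voxels per axis
gauss_blur3 <- function(vol, sigma) {
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    n <- d[ax]
    idx <- outer(seq_len(n), (-r):r, `+`)
    idx[idx < 1] <- 1L
    idx[idx > n] <- n
    smooth_line <- function(v) as.vector((matrix(v[idx], n) %*% k))
    vol <- switch(ax,
      apply(vol, c(2, 3), smooth_line),
      aperm(apply(vol, c(1, 3), smooth_line), c(2, 1, 3)),
      aperm(apply(vol, c(1, 2), smooth_line), c(2, 3, 1)))
  }
  vol
}

#' Difference-of-Gaussians spot detection in a nucleus subvolume
#'
#' Band-passes the spot-channel subvolume with the difference of two
#' normalized Gaussians (narrow minus wide; zero total weight, so the
#' response is invariant to adding a constant) and takes the global
#' maximum, refined to sub-voxel precision by the intensity-weighted
#' centroid of its 3x3x3 neighbourhood (positive DoG weights). No spot is
#' returned when the peak fails the significance test
#' `peak >= sig_k * sd(DoG)`, as for a uniform subvolume.
#'
#' @param subvol 3D numeric array `(ny, nx, nz)` of the spot channel.
#' @param voxel_xy,voxel_z voxel size, um.
#' @param dog_sigmas `c(narrow, wide)` Gaussian sigmas, um (narrow < wide).
#' @param sig_k significance threshold in DoG standard deviations
#'   (default 5).
#' @return `NULL` when no significant spot; otherwise list with `position`
#'   (x, y, z um relative to the subvolume origin), `voxel` (1-based
#'   `c(y, x, z)` index of the peak) and `dog_peak`.
#' @export
detect_spot_dog <- function(subvol, voxel_xy = 0.36, voxel_z = 1.0,
                            dog_sigmas = c(0.3, 0.9), sig_k = 5) {
  stopifnot(length(dim(subvol)) == 3, dog_sigmas[1] < dog_sigmas[2])
  svox <- function(s) s / c(voxel_xy, voxel_xy, voxel_z)
  dog <- gauss_blur3(subvol, svox(dog_sigmas[1])) -
    gauss_blur3(subvol, svox(dog_sigmas[2]))
  peak <- max(dog)
  # a (near-)uniform subvolume leaves only float residue in the band-pass
  if (diff(range(dog)) <= 1e-9 * max(diff(range(subvol)), 1)) return(NULL)
  if (!(peak > sig_k * stats::sd(dog))) return(NULL)
  w <- which(dog == peak, arr.ind = TRUE)[1, ]
  d <- dim(dog)
  ys <- max(1, w[1] - 1):min(d[1], w[1] + 1)
  xs <- max(1, w[2] - 1):min(d[2], w[2] + 1)
  zs <- max(1, w[3] - 1):min(d[3], w[3] + 1)
  nb <- pmax(dog[ys, xs, zs, drop = FALSE], 0)
  tot <- sum(nb)
  cy <- sum(slice.index(nb, 1) * nb) / tot
  cx <- sum(slice.index(nb, 2) * nb) / tot
  cz <- sum(slice.index(nb, 3) * nb) / tot
  pos_vox <- c(ys[1] - 1 + cy, xs[1] - 1 + cx, zs[1] - 1 + cz)
  list(position = c(x = (pos_vox[2] - 0.5) * voxel_xy,
                    y = (pos_vox[1] - 0.5) * voxel_xy,
                    z = (pos_vox[3] - 0.5) * voxel_z),
       voxel = c(y = unname(w[1]), x = unname(w[2]), z = unname(w[3])),
       dog_peak = peak)
}

#' Mean histone intensity in a window around the MS2 spot
#'
#' Arithmetic mean of a `window_px` x `window_px` pixel window of the
#' nuclear (histone) channel z-plane holding the spot, centred on the
#' spot's pixel — the chromatin-compaction proxy. Windows reaching beyond
#' the image border are clipped and average only the valid pixels.
#'
#' @param plane 2D numeric matrix `(ny, nx)`.
#' @param spot_px `c(row, col)` 1-based pixel of the spot.
#' @param window_px odd window side, pixels (default 5).
#' @return scalar mean intensity (AU).
#' @export
his_window_mean <- function(plane, spot_px, window_px = 5) {
  stopifnot(window_px >= 3, window_px %% 2 == 1)
  r <- (window_px - 1) / 2
  d <- dim(plane)
  ys <- max(1, spot_px[1] - r):min(d[1], spot_px[1] + r)
  xs <- max(1, spot_px[2] - r):min(d[2], spot_px[2] + r)
  mean(plane[ys, xs])
}

#' Spot mobility relative to the nucleus centroid
#'
#' Movement of the MS2 spot within its nucleus: per frame, the Euclidean
#' distance between consecutive offset vectors (spot minus nucleus
#' centroid) divided by the elapsed time (um/min), median-filtered over
#' `mobility_smooth` frames (default 8, i.e. 2 min at 15 s/frame).
#' Subtracting the centroid removes nuclear translation exactly, so rigid
#' co-motion gives zero and the measure is invariant to global drift.
#' Speeds are computed only between successive observed frames.
#'
#' @param spots data.frame with `frame`, `x`, `y`, `z` (um) of the spot.
#' @param centroids data.frame with `frame`, `x`, `y`, `z` (um) of the host
#'   nucleus centroid.
#' @param frame_interval seconds per frame.
#' @param mobility_smooth median-filter width, frames (default 8).
#' @return data.frame with `frame` (of the later member of each pair) and
#'   `rel_speed` (um/min).
#' @export
spot_mobility <- function(spots, centroids, frame_interval = 15,
                          mobility_smooth = 8) {
  m <- merge(spots, centroids, by = "frame", suffixes = c("_s", "_c"))
  m <- m[order(m$frame), , drop = FALSE]
  if (nrow(m) < 2) stop_config("need at least 2 frames with both positions")
  off <- cbind(m$x_s - m$x_c, m$y_s - m$y_c, m$z_s - m$z_c)
  d <- sqrt(rowSums((off[-1, , drop = FALSE] -
                       off[-nrow(off), , drop = FALSE])^2))
  dt_min <- diff(m$frame) * frame_interval / 60
  data.frame(frame = m$frame[-1],
             rel_speed = run_median(d / dt_min, mobility_smooth))
}

#' Mean nuclear intensity of a channel over time
#'
#' Per nucleus and frame, the mean intensity of the chosen channel over the
#' nucleus's voxels — used to follow nuclear factor levels. No bleaching
#' normalization is applied (there is no inactive reference region for
#' ubiquitous factors). With a `regions` assignment, per-region cohort
#' curves are also returned, weighting each nucleus equally.
#'
#' @param grid a [voxel_grid()].
#' @param labels list of `label_volume` per frame.
#' @param channel `"nuclear"` or `"spot"`.
#' @param regions optional named vector mapping label to region.
#' @return data.frame `frame`, `t`, `label`, `mean` (AU); with `regions`,
#'   a list also holding `by_region` (`frame`, `t`, `region`, `mean`).
#' @export
nuclear_factor_levels <- function(grid, labels,
                                  channel = c("nuclear", "spot"),
                                  regions = NULL) {
  channel <- match.arg(channel)
  stopifnot(inherits(grid, "voxel_grid"))
  tt <- grid_times(grid)
  out <- vector("list", length(labels))
  for (f in seq_along(labels)) {
    lab <- as.vector(labels[[f]]$labels)
    sel <- lab > 0
    if (!any(sel)) next
    v <- as.vector(grid[[channel]][, , , f, drop = TRUE])[sel]
    m <- tapply(v, lab[sel], mean)
    out[[f]] <- data.frame(frame = f, t = tt[f],
                           label = as.integer(names(m)),
                           mean = as.numeric(m))
  }
  per_nuc <- do.call(rbind, out)
  if (is.null(regions)) return(per_nuc)
  per_nuc$region <- regions[as.character(per_nuc$label)]
  byr <- stats::aggregate(mean ~ frame + t + region, data = per_nuc, FUN = mean)
  list(per_nucleus = per_nuc, by_region = byr)
}

#' Principal axis lengths of a nucleus
#'
#' Full axis lengths of the ellipsoid equivalent to a voxel set:
#' `4 * sqrt(eigenvalues)` of the covariance of the voxel centers in
#' physical coordinates, sorted descending. (A uniform solid ellipsoid
#' with semi-axis a has coordinate variance a^2/5 along that axis, so the
#' convention recovers roughly 0.89 of 2a; it matches the usual
#' equivalent-ellipse definition used for 2D region properties extended to
#' 3D.) A coplanar voxel set yields a zero third axis.
#'
#' @param lv a `label_volume`.
#' @param id object label.
#' @return numeric length-3 vector, um, descending.
#' @export
nuclear_axes <- function(lv, id) {
  stopifnot(inherits(lv, "label_volume"))
  d <- dim(lv$labels)
  keep <- which(lv$labels == id)
  if (length(keep) < 10)
    stop_config("object %d has fewer than 10 voxels", id)
  k0 <- keep - 1L
  xyz <- cbind(((k0 %/% d[1]) %% d[2] + 0.5) * lv$voxel_xy,
               (k0 %% d[1] + 0.5) * lv$voxel_xy,
               (k0 %/% (d[1] * d[2]) + 0.5) * lv$voxel_z)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  sort(4 * sqrt(ev), decreasing = TRUE)
}

dilate_mask_2d <- function(mask) {
  EBImage::dilate(mask, EBImage::makeBrush(3, shape = "box")) > 0
}

#' Contact length between a cell and the mesoderm
#'
#' Number of pixels shared between the cell thickened by one pixel and the
#' union of all ME cells, each thickened by one pixel (8-connected unit
#' square structuring element). Symmetric in its arguments by construction.
#'
#' @param label_img 2D integer label image (0 = background).
#' @param cell_id label of the query cell.
#' @param me_ids labels of the mesoderm cells.
#' @return integer pixel count.
#' @export
cell_contact_length <- function(label_img, cell_id, me_ids) {
  present <- unique(label_img[label_img > 0])
  if (!(cell_id %in% present) || !all(me_ids %in% present))
    stop_config("unknown cell id(s)")
  a <- dilate_mask_2d(label_img == cell_id)
  b <- dilate_mask_2d(matrix(label_img %in% setdiff(me_ids, cell_id),
                             nrow(label_img)))
  sum(a & b)
}

#' Area and eccentricity of labelled cells
#'
#' Per cell: pixel area (and um^2 when `pixel_size` is given) and the
#' eccentricity of the equivalent second-moment ellipse,
#' `sqrt(1 - lambda2 / lambda1)` for eigenvalues `lambda1 >= lambda2` of
#' the pixel-coordinate covariance — 0 for a disk, approaching 1 for an
#' elongated cell.
#'
#' @param label_img 2D integer label image.
#' @param pixel_size um/px (optional).
#' @return data.frame with `cell`, `area_px`, `area_um2` (NA without
#'   calibration), `eccentricity`.
#' @export
cell_shape_props <- function(label_img, pixel_size = NULL) {
  ids <- sort(unique(label_img[label_img > 0]))
  res <- lapply(ids, function(id) {
    px <- which(label_img == id, arr.ind = TRUE)
    ecc <- if (nrow(px) < 2) 0 else {
      ev <- eigen(stats::cov(px), symmetric = TRUE, only.values = TRUE)$values
      ev[ev < 0] <- 0
      if (ev[1] == 0) 0 else sqrt(1 - ev[2] / ev[1])
    }
    data.frame(cell = id, area_px = nrow(px),
               area_um2 = if (is.null(pixel_size)) NA_real_ else
                 nrow(px) * pixel_size^2,
               eccentricity = ecc)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
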