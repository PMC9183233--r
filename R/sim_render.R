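#' Two-channel 4D voxel grid
#'
#' Container for a calibrated two-channel time-lapse volume. `nuclear` and
#' `spot` are 4D arrays with dim `c(ny, nx, nz, n_frames)` holding the
#' histone-marker and MCP/MS2 channels. Physical calibration follows
#' confocal acquisition of the ventral embryo surface: `voxel_xy` um/px in
#' x/y, `voxel_z` um between slices, `frame_interval` seconds per frame.
#' `t0_nc14` is the (1-based) frame index at which nc14 starts; minutes into
#' nc14 of frame f are `(f - t0_nc14) * frame_interval / 60`.
#'
#' @param nuclear,spot 4D numeric arrays of equal dim.
#' @param voxel_xy,voxel_z,frame_interval calibration (um, um, s).
#' @param t0_nc14 frame index of nc14 start (default 1).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(nuclear, spot, voxel_xy, voxel_z, frame_interval,
                       t0_nc14 = 1L) {
  stopifnot(length(dim(nuclear)) == 4L, identical(dim(nuclear), dim(spot)),
            voxel_xy > 0, voxel_z > 0, frame_interval > 0)
  t0_nc14 <- as.integer(t0_nc14)
  if (t0_nc14 < 1L || t0_nc14 > dim(nuclear)[4])
    stop_config("t0_nc14 must be a valid frame index")
  structure(list(nuclear = nuclear, spot = spot, voxel_xy = voxel_xy,
                 voxel_z = voxel_z, frame_interval = frame_interval,
                 t0_nc14 = t0_nc14),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$nuclear)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %d frames, 2 channels\n",
              d[2], d[1], d[3], d[4]))
  cat(sprintf("  %.2f um/px xy, %.2f um z, %g s/frame, nc14 at frame %d\n",
              x$voxel_xy, x$voxel_z, x$frame_interval, x$t0_nc14))
  invisible(x)
}

#' Minutes into nc14 of each frame of a voxel grid
#' @param grid a [voxel_grid()].
#' @return numeric vector of length `n_frames`.
#' @export
grid_times <- function(grid) {
  (seq_len(dim(grid$nuclear)[4]) - grid$t0_nc14) * grid$frame_interval / 60
}

# add an anisotropic 3D Gaussian of peak `amp` at physical position (x,y,z)
# into `vol` (modified copy returned); evaluation restricted to +/- 3 sigma
add_blob <- function(vol, x, y, z, sigma_xy, sigma_z, amp, voxel_xy, voxel_z) {
  d <- dim(vol)
  cy <- y / voxel_xy + 0.5; cx <- x / voxel_xy + 0.5; cz <- z / voxel_z + 0.5
  ry <- ceiling(3 * sigma_xy / voxel_xy); rz <- ceiling(3 * sigma_z / voxel_z)
  ys <- max(1, floor(cy - ry)):min(d[1], ceiling(cy + ry))
  xs <- max(1, floor(cx - ry)):min(d[2], ceiling(cx + ry))
  zs <- max(1, floor(cz - rz)):min(d[3], ceiling(cz + rz))
  if (!length(ys) || !length(xs) || !length(zs)) return(vol)
  gy <- exp(-((ys - cy) * voxel_xy)^2 / (2 * sigma_xy^2))
  gx <- exp(-((xs - cx) * voxel_xy)^2 / (2 * sigma_xy^2))
  gz <- exp(-((zs - cz) * voxel_z)^2 / (2 * sigma_z^2))
  vol[ys, xs, zs] <- vol[ys, xs, zs] + amp * (gy %o% gx %o% gz)
  vol
}

#' Render a synthetic two-channel embryo movie
#'
#' Renders trajectories and traces into a [voxel_grid()]. The nuclear channel
#' is a sum of anisotropic 3D Gaussian blobs (half-maximum at
#' `nucleus_radius`) at the nucleus centroids. The spot channel carries a
#' uniform background equal to the generator's bleached background level
#' `b0 * max(0, 1 - bleach_rate t)`, a dim nuclear fill
#' (`fill_frac` of the trace value above background), and, per transcribing
#' nucleus and frame, one bright Gaussian punctum (`spot_sigma`) whose peak
#' equals the trace value above background; the punctum sits at a fixed
#' random offset inside its nucleus (stable across frames, seeded from the
#' config). Gaussian noise `render_noise_sd` is added to both channels and
#' the result is quantized to 16-bit integers.
#'
#' @param trajectories output of [simulate_movement()].
#' @param traces trace data.frame from [simulate_traces()].
#' @param cfg the [sim_config()] used to generate both.
#' @param nucleus_radius half-maximum radius of the nuclear blobs, um.
#' @param nuclear_amp peak nuclear-channel intensity per nucleus, AU.
#' @param spot_sigma punctum Gaussian sigma, um.
#' @param fill_frac dim nuclear fill of the spot channel as a fraction of
#'   the nuclear blob (0 disables).
#' @param render_noise_sd additive noise SD in both channels (defaults to
#'   `cfg$noise_sd`).
#' @return a [voxel_grid()]; attribute `spot_offsets` records the per-nucleus
#'   punctum offset (um) for ground-truth tests.
#' @export
render_stack <- function(trajectories, traces, cfg, nucleus_radius = 3,
                         nuclear_amp = 3000, spot_sigma = 0.5,
                         fill_frac = 0.1, render_noise_sd = cfg$noise_sd) {
  stopifnot(inherits(cfg, "sim_config"))
  frames <- if (nrow(trajectories) > 0) sort(unique(trajectories$frame))
            else seq_len(cfg$n_frames)
  nf <- length(frames)
  if (nrow(traces) > 0 && nrow(trajectories) > 0 &&
      (!setequal(unique(traces$frame), frames) ||
       !all(unique(traces$nucleus) %in% unique(trajectories$nucleus))))
    stop_config("trajectories and traces must share nuclei and frames")

  vx <- cfg$voxel_xy; vz <- cfg$voxel_z
  ny <- ceiling((max(trajectories$y, 0) + 5) / vx)
  nx <- ceiling((max(trajectories$x, 0) + 5) / vx)
  nz <- ceiling((max(trajectories$z, 0) + 4) / vz)
  nuclei <- sort(unique(trajectories$nucleus))
  if (length(nuclei) == 0) { ny <- 16; nx <- 16; nz <- 4 }

  sigma_xy <- nucleus_radius / sqrt(2 * log(2))
  sigma_z <- sigma_xy
  tt <- (frames - 1) * cfg$frame_interval / 60
  bg <- cfg$b0 * bleach_factor(cfg, tt)

  # fixed punctum offset per nucleus, uniform in a ball of half the radius
  offs <- with_seed(cfg$seed + 13L, {
    m <- matrix(rnorm(3 * length(nuclei)), ncol = 3)
    m <- m / pmax(sqrt(rowSums(m^2)), 1e-12) *
      (0.5 * nucleus_radius * runif(length(nuclei))^(1 / 3))
    rownames(m) <- nuclei
    m
  })

  nucl <- array(0, c(ny, nx, nz, nf))
  spot <- array(0, c(ny, nx, nz, nf))
  tr_split <- split(trajectories, trajectories$frame)
  val <- NULL
  if (nrow(traces) > 0) {
    val <- matrix(NA_real_, nrow = nf, ncol = length(nuclei),
                  dimnames = list(NULL, nuclei))
    val[cbind(traces$frame, match(traces$nucleus, nuclei))] <- traces$value
  }

  for (f in seq_len(nf)) {
    vn <- array(0, c(ny, nx, nz))
    vs <- array(bg[f], c(ny, nx, nz))
    pf <- tr_split[[as.character(frames[f])]]
    if (!is.null(pf)) {
      for (j in seq_len(nrow(pf))) {
        id <- as.character(pf$nucleus[j])
        vn <- add_blob(vn, pf$x[j], pf$y[j], pf$z[j],
                       sigma_xy, sigma_z, nuclear_amp, vx, vz)
        if (!is.null(val)) {
          excess <- val[f, id] - bg[f]
          if (is.finite(excess) && excess > 0) {
            if (fill_frac > 0)
              vs <- add_blob(vs, pf$x[j], pf$y[j], pf$z[j], sigma_xy,
                             sigma_z, fill_frac * excess, vx, vz)
            o <- offs[id, ]
            vs <- add_blob(vs, pf$x[j] + o[1], pf$y[j] + o[2],
                           pf$z[j] + o[3], spot_sigma, spot_sigma,
                           excess, vx, vz)
          }
        }
      }
    }
    nucl[, , , f] <- vn
    spot[, , , f] <- vs
  }
  if (render_noise_sd > 0) {
    noise <- with_seed(cfg$seed + 29L,
      list(n = rnorm(length(nucl), 0, render_noise_sd),
           s = rnorm(length(spot), 0, render_noise_sd)))
    nucl <- nucl + noise$n
    spot <- spot + noise$s
  }
  nucl[] <- pmin(pmax(round(nucl), 0), 65535)
  spot[] <- pmin(pmax(round(spot), 0), 65535)
  g <- voxel_grid(nucl, spot, vx, vz, cfg$frame_interval, 1L)
  attr(g, "spot_offsets") <- offs
  g
}
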