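#' Write a voxel grid as multi-page 16-bit TIFF plus YAML metadata
#'
#' Pages are ordered T, Z, C (channel order nuclear, spot), each page a
#' `(Y, X)` plane; the companion YAML sidecar records the dimensions and
#' calibration needed to reassemble the grid. Intensities are stored as
#' 16-bit integers; the roundtrip is bit exact.
#'
#' @param grid a [voxel_grid()].
#' @param path output TIFF path; metadata goes to `paste0(path, ".yaml")`.
#' @return `path`, invisibly.
#' @export
write_voxel_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$nuclear)
  pages <- list()
  for (f in seq_len(d[4]))
    for (z in seq_len(d[3])) {
      pages[[length(pages) + 1]] <- grid$nuclear[, , z, f] / 65535
      pages[[length(pages) + 1]] <- grid$spot[, , z, f] / 65535
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  yaml::write_yaml(list(ny = d[1], nx = d[2], nz = d[3], n_frames = d[4],
                        n_channels = 2L, page_order = "T,Z,C",
                        channels = c("nuclear", "spot"),
                        voxel_xy = grid$voxel_xy, voxel_z = grid$voxel_z,
                        frame_interval = grid$frame_interval,
                        t0_nc14 = grid$t0_nc14),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a voxel grid written by [write_voxel_grid()]
#' @param path TIFF path (YAML sidecar expected at `paste0(path, ".yaml")`).
#' @return a [voxel_grid()].
#' @export
read_voxel_grid <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  want <- meta$n_frames * meta$nz * meta$n_channels
  if (length(pages) != want)
    stop_config("malformed stack: expected %d pages, found %d",
                want, length(pages))
  nucl <- array(0, c(meta$ny, meta$nx, meta$nz, meta$n_frames))
  spot <- array(0, c(meta$ny, meta$nx, meta$nz, meta$n_frames))
  i <- 0
  for (f in seq_len(meta$n_frames))
    for (z in seq_len(meta$nz)) {
      nucl[, , z, f] <- round(pages[[i + 1]] * 65535)
      spot[, , z, f] <- round(pages[[i + 2]] * 65535)
      i <- i + 2
    }
  voxel_grid(nucl, spot, meta$voxel_xy, meta$voxel_z, meta$frame_interval,
             meta$t0_nc14)
}

#' Write/read analysis tables as CSV
#'
#' Plain CSV with a header and no row names; numeric columns roundtrip
#' within 1e-9 relative precision.
#'
#' @param df data.frame.
#' @param path file path.
#' @return `path` invisibly (write) or the data.frame (read).
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a simulation config as YAML
#' @param cfg a [sim_config()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
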