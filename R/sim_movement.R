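#' Simulate nuclear trajectories through gastrulation
#'
#' Produces per-nucleus centroid trajectories (um) on the deterministic
#' stripe layout of [initial_positions()]. The dorso-ventral (y) profile has
#' up to two phases, both half-cosine ramps (smooth, with zero velocity at
#' phase boundaries):
#'
#' * rolling (`t_constriction` to `t_invagination`): if
#'   `roll_amplitude > 0`, all MSE/NE nuclei drift dorsally (away from the
#'   ventral midline) by `roll_amplitude` um, emulating the apparent shift
#'   when a tilted embryo rolls inside the vitelline membrane during apical
#'   constriction;
#' * invagination (`t_invagination` to `t_end`): MSE and NE nuclei move
#'   ventrally (toward the midline) by `invagination_displacement` um —
#'   capped so each stripe stops about 4 um short of the midline — while
#'   ME nuclei descend in z as the mesoderm internalizes.
#'
#' Before `t_constriction` (and, absent rolling, before `t_invagination`)
#' y is constant. An optional per-frame positional jitter
#' (`move_jitter_sd`, default 0) roughens trajectories for recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param move_jitter_sd SD (um) of independent Gaussian jitter added to
#'   every coordinate of every frame (default 0: deterministic).
#' @return data.frame with `nucleus`, `region`, `stripe_side`, `frame`,
#'   `t` (min into nc14), `x`, `y`, `z` (um).
#' @export
simulate_movement <- function(cfg, move_jitter_sd = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- initial_positions(cfg)
  tt <- frame_times(cfg)
  nf <- cfg$n_frames
  n <- nrow(pos)
  y_me <- cfg$stripe_geometry$y_me

  roll <- cos_ramp((tt - cfg$t_constriction) /
                     (cfg$t_invagination - cfg$t_constriction))
  invag <- cos_ramp((tt - cfg$t_invagination) / (cfg$t_end - cfg$t_invagination))

  out <- vector("list", n)
  for (i in seq_len(n)) {
    ventral_dir <- -sign(pos$y[i] - y_me)   # unit step toward the midline
    y <- rep(pos$y[i], nf)
    z <- rep(pos$z[i], nf)
    if (pos$region[i] %in% c("MSE", "NE")) {
      if (cfg$roll_amplitude > 0)
        y <- y - ventral_dir * cfg$roll_amplitude * roll
      # stripes converge on the midline but keep their order: MSE stops
      # ~4 um short of it, NE ~12 um (outside the MSE's final position)
      clearance <- if (pos$region[i] == "MSE") 4 else 12
      eff <- min(cfg$invagination_displacement,
                 max(0, abs(pos$y[i] - y_me) - clearance))
      y <- y + ventral_dir * eff * invag
    } else {
      z <- z - 5 * invag   # mesoderm internalizes: nuclei descend in z
    }
    out[[i]] <- data.frame(
      nucleus = pos$nucleus[i], region = pos$region[i],
      stripe_side = pos$stripe_side[i], frame = seq_len(nf), t = tt,
      x = rep(pos$x[i], nf), y = y, z = z
    )
  }
  traj <- do.call(rbind, out)
  if (move_jitter_sd > 0) {
    traj[, c("x", "y", "z")] <- with_seed(cfg$seed + 7L,
      traj[, c("x", "y", "z")] +
        matrix(rnorm(3L * nrow(traj), 0, move_jitter_sd), ncol = 3))
  }
  rownames(traj) <- NULL
  traj
}
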