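#' Simulation configuration for synthetic embryos
#'
#' Builds and validates the parameter set of the synthetic embryo generator.
#' The generator emulates the ventral field of view of an nc14 Drosophila
#' embryo: two mesectoderm (MSE) stripes flanking the mesoderm (ME), with
#' neuroectoderm (NE) outside, bursty MS2 spot fluorescence that can step up
#' in amplitude at mesoderm invagination, shared photobleaching, and
#' dorso-ventral nuclear movement with an optional early "rolling" phase.
#'
#' Time is measured in minutes into nc14; frame 1 of a simulated movie is
#' t = 0.
#'
#' @param n_mse,n_me,n_ne nuclei per region (both MSE stripes together hold
#'   `n_mse` nuclei).
#' @param stripe_geometry list with `y_me` (DV position of the mesoderm
#'   midline, um), `mse_offset` and `ne_offset` (unsigned DV distances of the
#'   MSE and NE rows from the midline, um), and `x_pitch` (AP spacing of
#'   nuclei within a row, um).
#' @param frame_interval seconds per frame.
#' @param n_frames number of frames.
#' @param t_onset earliest MSE transcription onset, minutes into nc14.
#' @param onset_jitter_sd per-nucleus SD of transcription onset, minutes.
#' @param t_constriction,t_invagination,t_end gastrulation milestones,
#'   minutes into nc14.
#' @param roll_amplitude um of early dorsal drift during apical constriction
#'   (0 = perfectly ventral mounting, no rolling phase).
#' @param invagination_displacement um of ventral (toward-midline) MSE/NE
#'   movement during invagination.
#' @param p_on,p_off per-frame telegraph switching probabilities.
#' @param p_active fraction of MSE nuclei that ever transcribe.
#' @param amp_pre mean ON spot amplitude before the step (AU).
#' @param p_step fraction of MSE nuclei whose amplitude steps up at
#'   invagination.
#' @param step_factor amplitude multiplier after the step (>= 1).
#' @param step_jitter_sd per-nucleus SD of the step time, minutes.
#' @param b0 background fluorescence at t = 0 (AU).
#' @param bleach_rate fractional fluorescence loss per minute (shared by
#'   background and signal channels).
#' @param bleach_model `"linear"` (default; `max(0, 1 - rate * t)`, which the
#'   straight-line baseline fit inverts exactly) or `"exponential"`
#'   (`exp(-rate * t)`).
#' @param noise_sd additive Gaussian noise SD (AU).
#' @param voxel_xy,voxel_z voxel size, um.
#' @param seed integer RNG seed; identical configs (including seed) produce
#'   identical simulations.
#' @return an object of class `sim_config` (a validated named list).
#' @seealso [preset()], [simulate_traces()], [simulate_movement()],
#'   [render_stack()]
#' @export
sim_config <- function(n_mse = 48, n_me = 48, n_ne = 48,
                       stripe_geometry = list(y_me = 40, mse_offset = 12,
                                              ne_offset = 24, x_pitch = 6),
                       frame_interval = 15, n_frames = 280,
                       t_onset = 25, onset_jitter_sd = 4,
                       t_constriction = 42, t_invagination = 50, t_end = 62,
                       roll_amplitude = 0, invagination_displacement = 12,
                       p_on = 0.4, p_off = 0.2, p_active = 0.9,
                       amp_pre = 400, p_step = 0.4, step_factor = 2.0,
                       step_jitter_sd = 2, b0 = 200, bleach_rate = 0.003,
                       bleach_model = c("linear", "exponential"),
                       noise_sd = 20, voxel_xy = 0.36, voxel_z = 1.0,
                       seed = 1L) {
  bleach_model <- match.arg(bleach_model)
  cfg <- list(n_mse = n_mse, n_me = n_me, n_ne = n_ne,
              stripe_geometry = stripe_geometry,
              frame_interval = frame_interval, n_frames = n_frames,
              t_onset = t_onset, onset_jitter_sd = onset_jitter_sd,
              t_constriction = t_constriction,
              t_invagination = t_invagination, t_end = t_end,
              roll_amplitude = roll_amplitude,
              invagination_displacement = invagination_displacement,
              p_on = p_on, p_off = p_off, p_active = p_active,
              amp_pre = amp_pre, p_step = p_step, step_factor = step_factor,
              step_jitter_sd = step_jitter_sd, b0 = b0,
              bleach_rate = bleach_rate, bleach_model = bleach_model,
              noise_sd = noise_sd,
              voxel_xy = voxel_xy, voxel_z = voxel_z,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!(n_mse > 0 && n_me > 0 && n_ne > 0))
      stop_config("region nucleus counts must be positive")
    total_min <- (n_frames - 1) * frame_interval / 60
    if (!(t_onset < t_constriction && t_constriction <= t_invagination &&
          t_invagination < t_end))
      stop_config(
        "milestone ordering must satisfy t_onset < t_constriction <= t_invagination < t_end")
    if (t_end > total_min)
      stop_config("t_end (%.1f min) exceeds movie duration (%.1f min)",
                  t_end, total_min)
    if (p_step < 0 || p_step > 1 || p_on < 0 || p_on > 1 ||
        p_off < 0 || p_off > 1 || p_active < 0 || p_active > 1)
      stop_config("probabilities must lie in [0, 1]")
    if (step_factor < 1) stop_config("step_factor must be >= 1")
    if (bleach_rate < 0 || noise_sd < 0)
      stop_config("bleach_rate and noise_sd must be non-negative")
    if (voxel_xy <= 0 || voxel_z <= 0 || frame_interval <= 0)
      stop_config("voxel sizes and frame interval must be positive")
  })
  cfg
}

#' Named simulation presets
#'
#' Presets package the timing regimes of the three study conditions:
#' * `control`: invagination onset at 50 min into nc14, end of gastrulation
#'   at 62 min, 40% of MSE nuclei stepping twofold.
#' * `fog_like`: invagination delayed by 10 min (onset 60 min) with a
#'   correspondingly stretched movement phase, emulating slowed apical
#'   constriction; the transcription step follows the delayed invagination.
#' * `acat_like`: no invagination movement and no amplitude step, emulating
#'   loss of adherens-junction coupling where the mesoderm fails to
#'   invaginate.
#'
#' @param name one of `"control"`, `"fog_like"`, `"acat_like"`.
#' @param ... overrides forwarded to [sim_config()].
#' @return a validated [sim_config()] object.
#' @export
preset <- function(name = c("control", "fog_like", "acat_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    control = list(),
    fog_like = list(t_constriction = 48, t_invagination = 60, t_end = 75,
                    n_frames = 320),
    acat_like = list(invagination_displacement = 0, p_step = 0)
  )
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  nuclei: %d MSE / %d ME / %d NE; %d frames @ %gs\n",
              x$n_mse, x$n_me, x$n_ne, x$n_frames, x$frame_interval))
  cat(sprintf("  milestones (min into nc14): constriction %g, invagination %g, end %g\n",
              x$t_constriction, x$t_invagination, x$t_end))
  cat(sprintf("  step: %.0f%% of MSE x%.1f; bleach %.3f/min; noise sd %g; seed %d\n",
              100 * x$p_step, x$step_factor, x$bleach_rate, x$noise_sd,
              x$seed))
  invisible(x)
}

# frame times in minutes into nc14 (frame 1 = 0)
frame_times <- function(cfg) (seq_len(cfg$n_frames) - 1) * cfg$frame_interval / 60

# shared photobleaching factor at times t (minutes)
bleach_factor <- function(cfg, t) {
  model <- if (is.null(cfg$bleach_model)) "linear" else cfg$bleach_model
  switch(model,
         linear = pmax(0, 1 - cfg$bleach_rate * t),
         exponential = exp(-cfg$bleach_rate * t))
}

#' Deterministic initial nucleus layout
#'
#' Places nuclei on the stripe geometry of a [sim_config()]: mesoderm nuclei
#' in two rows around the ventral midline `y_me`, one MSE row at
#' `y_me - mse_offset` and one at `y_me + mse_offset`, and NE rows at
#' `+/- ne_offset`, all spaced `x_pitch` um apart along the AP (x) axis.
#' The layout is deterministic: positions at t = 0 are exactly these seeds.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `nucleus`, `region`, `stripe_side` (-1/0/+1),
#'   `x`, `y`, `z` (um).
#' @export
initial_positions <- function(cfg) {
  g <- cfg$stripe_geometry
  make_row <- function(region, side, n, y, z = 8) {
    if (n == 0) return(NULL)
    k <- seq_len(n)
    data.frame(region = region, stripe_side = side,
               x = 4 + (k - 1) * g$x_pitch, y = y, z = z)
  }
  split2 <- function(n) c(ceiling(n / 2), floor(n / 2))
  nm <- split2(cfg$n_mse); nn <- split2(cfg$n_ne); nme <- split2(cfg$n_me)
  pos <- rbind(
    make_row("ME", -1, nme[1], g$y_me - g$mse_offset / 3),
    make_row("ME", 1, nme[2], g$y_me + g$mse_offset / 3),
    make_row("MSE", -1, nm[1], g$y_me - g$mse_offset),
    make_row("MSE", 1, nm[2], g$y_me + g$mse_offset),
    make_row("NE", -1, nn[1], g$y_me - g$ne_offset),
    make_row("NE", 1, nn[2], g$y_me + g$ne_offset)
  )
  pos$nucleus <- seq_len(nrow(pos))
  pos[, c("nucleus", "region", "stripe_side", "x", "y", "z")]
}
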