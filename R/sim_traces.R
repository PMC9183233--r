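#' Simulate per-nucleus MS2 fluorescence traces
#'
#' Generates one spot-fluorescence proxy series per nucleus under the model
#'
#' \deqn{v(t) = (B_0 + S(t) A(t)) \cdot b(t) + \epsilon}
#'
#' where `b(t) = max(0, 1 - bleach_rate * t)` is the shared photobleaching
#' factor (fluorophore loss dims background and nascent-spot signal alike;
#' `bleach_model = "exponential"` uses `exp(-bleach_rate * t)` instead), `S(t)` is a two-state telegraph process switched per frame
#' with probabilities `p_on`/`p_off` and held at 0 before the nucleus's
#' transcription onset and for nuclei that never transcribe, `A(t)` is the
#' unbleached spot amplitude (`amp_pre`, stepping to
#' `step_factor * amp_pre` at the nucleus's step time for stepping MSE
#' nuclei), and `epsilon ~ N(0, noise_sd)`. Only MSE nuclei can transcribe;
#' a fraction `p_active` of them do, starting at `t_onset` plus a
#' per-nucleus non-negative jitter. A fraction `p_step` of MSE nuclei step
#' at `t_invagination` plus per-nucleus Gaussian jitter
#' (`step_jitter_sd`).
#'
#' With `noise_sd = 0` and `bleach_rate = 0` the trace of an always-ON
#' stepping nucleus is exactly `b0 + amp_pre` before the step and
#' `b0 + step_factor * amp_pre` after it.
#'
#' @param cfg a [sim_config()].
#' @return list with `traces` (data.frame: `nucleus`, `region`, `frame`,
#'   `t` min into nc14, `value` AU) and `truth` (see Details).
#' @details `truth` is a list with `nuclei` (per-nucleus data.frame:
#'   `nucleus`, `region`, `stripe_side`, `active`, `steps`, `true_onset`,
#'   `t_step`, `amp_pre`, `amp_post`) and `events`
#'   (`t_constriction`, `t_invagination`, `t_end`). Identical configs
#'   (including `seed`) give bitwise-identical output.
#' @export
simulate_traces <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    pos <- initial_positions(cfg)
    n <- nrow(pos)
    tt <- frame_times(cfg)
    nf <- cfg$n_frames

    is_mse <- pos$region == "MSE"
    active <- is_mse & (runif(n) < cfg$p_active)
    steps <- is_mse & (runif(n) < cfg$p_step)
    onset <- rep(NA_real_, n)
    onset[active] <- cfg$t_onset +
      abs(rnorm(sum(active), 0, cfg$onset_jitter_sd))
    t_step <- rep(NA_real_, n)
    t_step[steps] <- cfg$t_invagination +
      rnorm(sum(steps), 0, cfg$step_jitter_sd)

    bleach <- bleach_factor(cfg, tt)
    values <- matrix(0, nrow = nf, ncol = n)
    for (i in seq_len(n)) {
      S <- numeric(nf)
      if (active[i]) {
        started <- tt >= onset[i]
        if (any(started)) {
          first <- which(started)[1]
          s <- 1L
          for (f in first:nf) {
            S[f] <- s
            s <- if (s == 1L) {
              if (runif(1) < cfg$p_off) 0L else 1L
            } else {
              if (runif(1) < cfg$p_on) 1L else 0L
            }
          }
        }
      }
      A <- rep(cfg$amp_pre, nf)
      if (steps[i]) A[tt >= t_step[i]] <- cfg$amp_pre * cfg$step_factor
      values[, i] <- (cfg$b0 + S * A) * bleach
    }
    if (cfg$noise_sd > 0)
      values <- values + matrix(rnorm(nf * n, 0, cfg$noise_sd), nf, n)

    traces <- data.frame(
      nucleus = rep(pos$nucleus, each = nf),
      region = rep(pos$region, each = nf),
      frame = rep(seq_len(nf), times = n),
      t = rep(tt, times = n),
      value = as.vector(values)
    )
    truth_nuc <- data.frame(
      nucleus = pos$nucleus, region = pos$region,
      stripe_side = pos$stripe_side,
      active = active, steps = steps, true_onset = onset, t_step = t_step,
      amp_pre = ifelse(active, cfg$amp_pre, NA_real_),
      amp_post = ifelse(active,
                        ifelse(steps, cfg$amp_pre * cfg$step_factor,
                               cfg$amp_pre), NA_real_)
    )
    list(traces = traces,
         truth = list(nuclei = truth_nuc,
                      events = list(t_constriction = cfg$t_constriction,
                                    t_invagination = cfg$t_invagination,
                                    t_end = cfg$t_end)))
  })
}
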