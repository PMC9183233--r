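test_that("raw trace extraction reports the per-nucleus spot maximum", {
  cfg <- render_cfg(n = 2)
  traj <- simulate_movement(cfg)
  sim <- simulate_traces(cfg)
  g <- render_stack(traj, sim$traces, cfg, render_noise_sd = 0,
                    fill_frac = 0)
  seg <- segment_movie(g)
  tk <- link_tracks(seg$detections)
  tr <- extract_traces(g, tk, seg$labels)
  expect_true(all(c("track_id", "frame", "t", "value", "mean_spot",
                    "mean_nuclear") %in% names(tr)))
  expect_equal(nrow(tr), nrow(tk))
  # maxima are bounded by the true punctum peak and at least background
  tt <- grid_times(g)
  bg <- cfg$b0 * pmax(0, 1 - cfg$bleach_rate * tt)
  expect_true(all(tr$value >= floor(bg[tr$frame])))
  expect_true(all(tr$value >= tr$mean_spot))
  # a nucleus whose voxels share one value reports that value
  lv <- seg$labels[[1]]
  vox <- g$spot[, , , 1, drop = TRUE]
  vox[lv$labels == 1] <- 123
  g$spot[, , , 1] <- vox
  tr2 <- extract_traces(g, tk[tk$frame == 1 & tk$label == 1, , drop = FALSE],
                        seg$labels)
  expect_equal(tr2$value, 123)
  expect_error(
    extract_traces(g, data.frame(track_id = 1, frame = 1, label = 999),
                   seg$labels), "missing")
})

test_that("short-track filter uses strict 'more than' semantics", {
  mk <- function(id, n) data.frame(track_id = id, frame = seq_len(n))
  tab <- rbind(mk(1, 10), mk(2, 11), mk(3, 3))
  out <- filter_track_length(tab)
  expect_equal(sort(unique(out$track_id)), 2)
  expect_equal(nrow(filter_track_length(tab[0, ])), 0)
  # largest removed length over the 1..20 ladder is exactly 10
  ladder <- do.call(rbind, lapply(1:20, function(k) mk(k, k)))
  kept <- unique(filter_track_length(ladder)$track_id)
  expect_equal(max(setdiff(1:20, kept)), 10)
})

test_that("constant cohorts stay inactive; a sustained 1.3x pulse activates", {
  coh <- flat_cohort(n_nuclei = 30)
  act <- call_activity(coh)
  expect_false(any(act$nuclei$active))
  expect_true(all(!act$table$on))

  # 6-frame pulse at 1.3x baseline -> active
  up <- with_probe(coh, ratio = 1.3, pulse_frames = 20:25)
  act6 <- call_activity(up)
  probe <- act6$nuclei[act6$nuclei$track_id == "31", ]
  expect_true(probe$active)
  # onset is the first ON time
  expect_equal(probe$onset, unique(up$t[up$frame == 20]))

  # 4-frame pulse -> below min_on_frames, inactive
  up4 <- with_probe(coh, ratio = 1.3, pulse_frames = 20:23)
  act4 <- call_activity(up4)
  expect_false(act4$nuclei$active[act4$nuclei$track_id == "31"])

  expect_error(call_activity(coh[0, ]), "nucleus")
})

test_that("raising the ON ratio never converts inactive to active", {
  cfg <- small_cfg(seed = 5)
  sim <- simulate_traces(cfg)
  tr <- data.frame(track_id = sim$traces$nucleus, t = sim$traces$t,
                   value = sim$traces$value)
  a1 <- call_activity(tr, on_ratio = 1.2)
  a2 <- call_activity(tr, on_ratio = 1.5)
  flipped <- !a1$nuclei$active & a2$nuclei$active
  expect_false(any(flipped))
})

test_that("activity calling reaches a fixed point (pass-2 idempotence)", {
  cfg <- small_cfg(seed = 8)
  sim <- simulate_traces(cfg)
  tr <- data.frame(track_id = sim$traces$nucleus, t = sim$traces$t,
                   value = sim$traces$value)
  act <- call_activity(tr)
  # refit the baseline to the final inactive set: flags must not change
  inact <- act$nuclei$track_id[!act$nuclei$active]
  sub <- tr[as.character(tr$track_id) %in% inact, ]
  m <- tapply(sub$value, sub$t, mean)
  fit3 <- ms2gastrula:::fit_line(as.numeric(names(m)), as.numeric(m))
  on3 <- act$table$smoothed >=
    act$params$on_ratio * ms2gastrula:::baseline_at(fit3, act$table$t)
  n_on3 <- tapply(on3, act$table$track_id, sum)
  active3 <- n_on3 >= act$params$min_on_frames
  expect_equal(as.vector(active3[as.character(act$nuclei$track_id)]),
               act$nuclei$active)
})

test_that("activity calling recovers ground truth on a noisy cohort", {
  cfg <- sim_config(seed = 13)
  sim <- simulate_traces(cfg)
  tr <- data.frame(track_id = sim$traces$nucleus, t = sim$traces$t,
                   value = sim$traces$value)
  act <- call_activity(tr)
  truth <- sim$truth$nuclei$active
  called <- act$nuclei$active[match(sim$truth$nuclei$nucleus,
                                    act$nuclei$track_id)]
  sens <- sum(called & truth) / sum(truth)
  spec <- sum(!called & !truth) / sum(!truth)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("normalization inverts the generator exactly at zero noise", {
  cfg <- small_cfg(noise_sd = 0, p_active = 1, p_step = 1,
                   step_jitter_sd = 0, onset_jitter_sd = 0, seed = 4)
  sim <- simulate_traces(cfg)
  tr <- data.frame(track_id = sim$traces$nucleus, t = sim$traces$t,
                   value = sim$traces$value)
  act <- normalize_traces(call_activity(tr))
  tab <- act$table
  nuc <- sim$truth$nuclei
  for (id in nuc$nucleus[nuc$active]) {
    s <- tab[tab$track_id == id, ]
    v <- sim$traces[sim$traces$nucleus == id, ]
    bleach <- pmax(0, 1 - cfg$bleach_rate * v$t)
    SA <- v$value / bleach - cfg$b0   # = S(t) * A(t) by construction
    expect_equal(s$normalized, SA, tolerance = 1e-9)
  }
})

test_that("bleach normalization recovers the closed-form 100/0.8 example", {
  # inactive cohort declining linearly to 80% at the end; one active trace
  # at baseline + 100 throughout: normalized rises to 125 at the end
  nf <- 60
  tt <- (seq_len(nf) - 1) / 4
  b0 <- 500
  decline <- 1 - 0.2 * (tt / max(tt))
  coh <- do.call(rbind, lapply(1:25, function(id)
    data.frame(track_id = id, frame = seq_len(nf), t = tt,
               value = b0 * decline)))
  active <- data.frame(track_id = 26, frame = seq_len(nf), t = tt,
                       value = b0 * decline + 100)
  act <- normalize_traces(call_activity(rbind(coh, active)))
  s <- act$table[act$table$track_id == 26, ]
  expect_equal(s$normalized[1], 100, tolerance = 1e-6)
  expect_equal(s$normalized[nf], 125, tolerance = 1e-6)
  # without bleaching, normalized equals raw minus baseline exactly
  coh2 <- flat_cohort(25, baseline = b0)
  act2 <- normalize_traces(call_activity(with_probe(coh2, 1.3, 10:40,
                                                    baseline = b0)))
  s2 <- act2$table[act2$table$track_id == 26, ]
  expect_equal(s2$normalized[10:40], rep(0.3 * b0, 31), tolerance = 1e-9)
})

test_that("simulated bleaching is recovered within 2%", {
  cfg <- sim_config(seed = 17)
  sim <- simulate_traces(cfg)
  tr <- data.frame(track_id = sim$traces$nucleus, t = sim$traces$t,
                   value = sim$traces$value)
  act <- call_activity(tr)
  bl <- act$fits$bleach
  t_end <- max(bl$t)
  expect_equal(bl$curve[bl$t == t_end], 1 - cfg$bleach_rate * t_end,
               tolerance = 0.02)
})

test_that("pre-window exclusion drops early-onset nuclei by mode", {
  coh <- flat_cohort(n_nuclei = 30, n_frames = 200)
  early <- with_probe(coh, 1.5, 30:60, id = 31L)   # onset ~7.25 min
  late <- with_probe(early, 1.5, 90:130, id = 32L) # onset ~22.25 min
  act <- normalize_traces(call_activity(late))
  def <- exclude_pre_window(act)
  expect_false("31" %in% def$nuclei$track_id)
  expect_true("32" %in% def$nuclei$track_id)
  expect_true(all(def$table$t >= 15))
  gal <- exclude_pre_window(act, mode = "gal4")
  expect_false("32" %in% gal$nuclei$track_id)
})

test_that("total output sums normalized values over the window", {
  coh <- flat_cohort(25, baseline = 200)
  act <- normalize_traces(call_activity(with_probe(coh, 1.5, 11:20,
                                                   baseline = 200)))
  tot <- total_output(act, window = c(0, 100))
  # 10 frames at 0.5 * 200 = 100 each
  expect_equal(tot$total[tot$track_id == "26"], 1000, tolerance = 1e-9)
  # matches a brute-force sum over the same rows
  tab <- act$table
  brute <- sum(tab$normalized[tab$track_id == "26" & tab$t >= 0 &
                                tab$t <= 100], na.rm = TRUE)
  expect_equal(tot$total[tot$track_id == "26"], brute)
  expect_warning(tot0 <- total_output(act, window = c(900, 901)), "empty")
  expect_true(all(tot0$total == 0))
})

test_that("klar compensation scales normalized values by 0.89 and commutes with totals", {
  coh <- flat_cohort(25, baseline = 200)
  act <- normalize_traces(call_activity(with_probe(coh, 1.5, 11:20,
                                                   baseline = 200)))
  off <- compensate_klar(act, enabled = FALSE)
  expect_identical(off$table$normalized, act$table$normalized)
  on <- compensate_klar(act)
  expect_equal(on$table$normalized, act$table$normalized * 0.89)
  t1 <- total_output(on, c(0, 100))
  t2 <- total_output(act, c(0, 100))
  expect_equal(t1$total, t2$total * 0.89)
})
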