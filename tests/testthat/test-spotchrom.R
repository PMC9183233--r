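test_that("DoG spot detection finds the rendered punctum and rejects blanks", {
  cfg <- render_cfg(n = 2, p_active = 1, p_off = 0, onset_jitter_sd = 0)
  sim <- simulate_traces(cfg)
  id <- sim$truth$nuclei$nucleus[sim$truth$nuclei$active][1]
  traj <- simulate_movement(cfg)
  traj <- traj[traj$nucleus == id, ]
  traces <- sim$traces[sim$traces$nucleus == id, ]
  g <- render_stack(traj, traces, cfg, render_noise_sd = 0, fill_frac = 0)
  offs <- attr(g, "spot_offsets")
  f <- which(traces$value > cfg$b0 + 50)[1]   # a frame with an ON spot
  expect_false(is.na(f))
  sub <- g$spot[, , , f, drop = TRUE]
  sp <- detect_spot_dog(sub, cfg$voxel_xy, cfg$voxel_z)
  expect_false(is.null(sp))
  p <- traj[traj$frame == f, ]
  truth <- c(p$x, p$y, p$z) + offs[as.character(id), ]
  err <- abs(sp$position[c("x", "y", "z")] - truth)
  expect_lte(err[1], cfg$voxel_xy)
  expect_lte(err[2], cfg$voxel_xy)
  expect_lte(err[3], cfg$voxel_z)

  expect_null(detect_spot_dog(array(7, c(15, 15, 9))))
  # invariant to adding a constant
  sp2 <- detect_spot_dog(sub + 1000, cfg$voxel_xy, cfg$voxel_z)
  expect_equal(sp2$position, sp$position, tolerance = 1e-9)
})

test_that("histone window mean matches the brute-force average with border clipping", {
  m <- matrix(1:25, nrow = 5, byrow = FALSE)
  expect_equal(his_window_mean(m, c(3, 3), 5), 13)
  expect_equal(his_window_mean(matrix(4, 9, 9), c(5, 5), 5), 4)
  # corner spot: only the valid 3x3 quadrant is averaged
  expect_equal(his_window_mean(m, c(1, 1), 5), mean(m[1:3, 1:3]))
  set.seed(2)
  img <- matrix(rnorm(400), 20, 20)
  for (k in 1:20) {
    py <- sample(1:20, 1); px <- sample(1:20, 1)
    ys <- max(1, py - 2):min(20, py + 2)
    xs <- max(1, px - 2):min(20, px + 2)
    expect_equal(his_window_mean(img, c(py, px), 5), mean(img[ys, xs]))
  }
  expect_error(his_window_mean(m, c(3, 3), 4))
})

test_that("spot mobility is zero under rigid co-motion and drift invariant", {
  fr <- 1:30
  drift <- cbind(fr * 0.3, fr * -0.1, fr * 0.05)
  cen <- data.frame(frame = fr, x = 10 + drift[, 1], y = 5 + drift[, 2],
                    z = 3 + drift[, 3])
  sp <- cen
  sp$x <- sp$x + 1; sp$y <- sp$y - 0.5   # fixed offset
  mob <- spot_mobility(sp, cen)
  expect_true(all(mob$rel_speed == 0))

  # relative offset changing 0.5 um per 15 s frame -> 2 um/min
  sp2 <- cen
  sp2$x <- sp2$x + 0.5 * fr
  mob2 <- spot_mobility(sp2, cen, frame_interval = 15, mobility_smooth = 1)
  expect_true(all(abs(mob2$rel_speed - 2) < 1e-9))
  # invariant to an extra global drift applied to both
  sp3 <- sp2; cen3 <- cen
  sp3$y <- sp3$y + fr; cen3$y <- cen3$y + fr
  mob3 <- spot_mobility(sp3, cen3, frame_interval = 15, mobility_smooth = 1)
  expect_equal(mob3$rel_speed, mob2$rel_speed, tolerance = 1e-9)

  expect_error(spot_mobility(sp[1, ], cen[1, ]), "2 frames")
})

test_that("nuclear factor levels report per-nucleus means and region curves", {
  arr <- array(0L, c(10, 10, 4))
  arr[2:4, 2:4, 2] <- 1L
  arr[7:9, 7:9, 3] <- 2L
  lv <- ms2gastrula:::new_label_volume(arr, 0.36, 1)
  nuc <- array(5, c(10, 10, 4, 2))
  nuc[, , , 2] <- 11
  spot <- nuc
  g <- voxel_grid(nuc, spot, 0.36, 1, 15)
  out <- nuclear_factor_levels(g, list(lv, lv), "nuclear")
  expect_equal(out$mean, c(5, 5, 11, 11))
  withr <- nuclear_factor_levels(g, list(lv, lv), "nuclear",
                                 regions = c("1" = "MSE", "2" = "ME"))
  expect_equal(nrow(withr$by_region), 4)
  expect_true(all(withr$by_region$mean %in% c(5, 11)))
})

test_that("nuclear axes recover constructed ellipsoids and rotate invariantly", {
  sph <- ellipsoid_volume(3, 3, 3, voxel_xy = 0.25, voxel_z = 0.25)
  ax <- nuclear_axes(sph, 1L)
  # uniform ball of radius r: 4 * sqrt(r^2 / 5) = 1.789 r per axis
  expect_equal(ax, rep(4 * 3 / sqrt(5), 3), tolerance = 0.05)

  ell <- ellipsoid_volume(4, 2, 2, voxel_xy = 0.25, voxel_z = 0.25)
  ax2 <- nuclear_axes(ell, 1L)
  expect_equal(ax2[1], 4 * 4 / sqrt(5), tolerance = 0.05)
  expect_equal(ax2[2], 4 * 2 / sqrt(5), tolerance = 0.05)
  # axis-lengths are invariant under axis permutation (rigid 90-degree turn)
  swapped <- ms2gastrula:::new_label_volume(aperm(ell$labels, c(2, 1, 3)),
                                            0.25, 0.25)
  expect_equal(nuclear_axes(swapped, 1L), ax2, tolerance = 1e-9)
  expect_error(nuclear_axes(ms2gastrula:::new_label_volume(
    array(c(1L, rep(0L, 26)), c(3, 3, 3)), 1, 1), 1L), "fewer")
})

test_that("contact length equals the dilation-intersection oracle", {
  img <- matrix(0L, 20, 20)
  img[5:14, 3:6] <- 1L
  img[5:14, 8:11] <- 2L   # 1-px gap to cell 1
  img[17:19, 17:19] <- 3L
  brute <- function(im, a_id, b_ids) {
    d <- dim(im)
    dil <- function(mask) {
      out <- matrix(FALSE, d[1], d[2])
      for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
        ys <- max(1, y - 1):min(d[1], y + 1)
        xs <- max(1, x - 1):min(d[2], x + 1)
        out[y, x] <- any(mask[ys, xs])
      }
      out
    }
    sum(dil(im == a_id) & dil(matrix(im %in% b_ids, d[1])))
  }
  expect_equal(cell_contact_length(img, 1L, 2L), brute(img, 1, 2))
  expect_gt(cell_contact_length(img, 1L, 2L), 0)
  expect_equal(cell_contact_length(img, 1L, 3L), 0)
  # symmetry
  expect_equal(cell_contact_length(img, 2L, 1L),
               cell_contact_length(img, 1L, 2L))
  expect_error(cell_contact_length(img, 99L, 1L), "unknown")
  # random label images against the oracle
  set.seed(12)
  for (k in 1:5) {
    r <- matrix(0L, 20, 20)
    r[3:8, 3:8] <- 1L
    r[sample(9:14, 1):16, sample(7:12, 1):15] <- 2L
    expect_equal(cell_contact_length(r, 1L, 2L), brute(r, 1, 2))
  }
})

test_that("cell shape properties report area and moment eccentricity", {
  img <- matrix(0L, 60, 60)
  # digitized disk radius 10
  img[(row(img) - 20)^2 + (col(img) - 20)^2 <= 100] <- 1L
  img[45:54, 11:50] <- 2L   # 10 x 40 rectangle
  props <- cell_shape_props(img, pixel_size = 0.5)
  disk <- props[props$cell == 1, ]
  rect <- props[props$cell == 2, ]
  expect_lt(disk$eccentricity, 0.1)
  expect_equal(rect$area_px, 400)
  expect_equal(rect$area_um2, 100)
  # rectangle eccentricity from exact second moments of uniform rectangles
  lam <- c(var(rep(11:50, 10)), var(rep(45:54, 40)))
  expect_equal(rect$eccentricity, sqrt(1 - min(lam) / max(lam)),
               tolerance = 1e-9)
})
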