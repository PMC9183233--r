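test_that("median filter matches the exhaustive sort oracle", {
  set.seed(1)
  v <- array(runif(216), c(6, 6, 6))
  out <- ms2gastrula:::median_filter3_cpp(as.numeric(v), dim(v))
  out <- array(out, dim(v))
  for (z in 2:5) for (x in 2:5) for (y in 2:5) {
    nb <- v[(y - 1):(y + 1), (x - 1):(x + 1), (z - 1):(z + 1)]
    expect_identical(out[y, x, z], median(nb))
  }
  # constant volume is untouched by the filter and rescales to zero
  cv <- array(5, c(4, 4, 4))
  expect_true(all(preprocess_volume(cv) == 0))
  # a single bright voxel in flat background is removed
  sp <- array(0, c(7, 7, 7)); sp[4, 4, 4] <- 100
  ms <- array(ms2gastrula:::median_filter3_cpp(as.numeric(sp), dim(sp)),
              dim(sp))
  expect_true(all(ms == 0))
})

test_that("preprocess rejects empty or non-3D input", {
  expect_error(preprocess_volume(numeric(0)))
  expect_error(preprocess_volume(matrix(1, 2, 2)))
})

test_that("blob enhancement prefers spheres, is shift invariant, keeps blanks blank", {
  vx <- 0.5; vz <- 1
  d <- c(40, 40, 20)
  mk_sphere <- function(cy, cx, cz, r = 3) {
    arr <- array(0, d)
    for (z in seq_len(d[3])) {
      dz2 <- ((z - cz) * vz)^2
      m <- outer(seq_len(d[1]), seq_len(d[2]), function(y, x)
        ((y - cy) * vx)^2 + ((x - cx) * vx)^2 + dz2 <= r^2)
      arr[, , z] <- m * 1
    }
    arr
  }
  sph <- mk_sphere(20, 20, 10)
  plane <- array(0, d); plane[, , 10] <- 1
  fs <- enhance_blobs(sph, 3, vx, vz)
  fp <- enhance_blobs(plane, 3, vx, vz)
  expect_gt(max(fs), max(fp))

  sph2 <- mk_sphere(14, 26, 10)
  f2 <- enhance_blobs(sph2, 3, vx, vz)
  # response of the translated sphere is the translated response
  expect_equal(f2[14 + (-3:3), 26, 10], fs[20 + (-3:3), 20, 10],
               tolerance = 1e-8)

  expect_true(all(enhance_blobs(array(0, d), 3, vx, vz) == 0))
  expect_error(enhance_blobs(array(0, c(4, 4, 4)), blob_radius = 50,
                             voxel_xy = 0.36, voxel_z = 1), "extent")
})

test_that("segmentation recovers rendered nuclei with accurate centroids", {
  cfg <- render_cfg(n = 4)
  traj <- simulate_movement(cfg)
  sim <- simulate_traces(cfg)
  g <- render_stack(traj, sim$traces, cfg, render_noise_sd = 0)
  seg <- segment_movie(g)
  f1 <- traj[traj$frame == 1, ]
  lv <- seg$labels[[1]]
  expect_equal(max(lv$labels), 12L)
  hit <- lv$labels[cbind(floor(f1$y / cfg$voxel_xy) + 1,
                         floor(f1$x / cfg$voxel_xy) + 1,
                         floor(f1$z / cfg$voxel_z) + 1)]
  expect_equal(sort(unique(hit)), 1:12)
  det <- seg$detections[seg$detections$frame == 1, ]
  for (i in seq_len(nrow(f1))) {
    j <- which(hit[i] == det$label)
    expect_lte(abs(det$x_um[j] - f1$x[i]), cfg$voxel_xy)
    expect_lte(abs(det$y_um[j] - f1$y[i]), cfg$voxel_xy)
    expect_lte(abs(det$z_um[j] - f1$z[i]), cfg$voxel_z)
  }
  # no object below the size floor survives
  expected <- (4 / 3) * pi * 27 / (cfg$voxel_xy^2 * cfg$voxel_z)
  expect_true(all(lv$sizes >= 0.25 * expected))
})

test_that("touching nuclei are split by the watershed", {
  # two blobs 5 um apart: masks merge, watershed must separate them
  cfg <- render_cfg(n = 1)
  traj <- simulate_movement(cfg)
  traj <- traj[traj$nucleus == 1 & traj$frame == 1, ]
  traj2 <- traj
  traj2$nucleus <- 2L
  traj2$y <- traj2$y + 5
  both <- rbind(traj, traj2)
  g <- render_stack(both, data.frame(nucleus = integer(0), frame = integer(0),
                                     value = numeric(0)),
                    utils::modifyList(cfg, list(n_frames = 1)),
                    render_noise_sd = 0)
  v <- preprocess_volume(g$nuclear[, , , 1, drop = TRUE])
  e <- enhance_blobs(v, 3, cfg$voxel_xy, cfg$voxel_z)
  lv <- segment_nuclei(e, voxel_xy = cfg$voxel_xy, voxel_z = cfg$voxel_z)
  expect_equal(max(lv$labels), 2L)
  # the merged binary mask is a single component before the watershed
  thr <- auto_threshold(e)
  lab0 <- ms2gastrula:::label_components_cpp(e > thr, dim(e), 26L)
  expect_equal(max(lab0), 1L)
})

test_that("blank volumes and out-of-range thresholds give empty labelings", {
  blank <- array(0, c(20, 20, 8))
  lv <- suppressWarnings(segment_nuclei(blank, threshold = 0.5))
  expect_equal(sum(lv$labels), 0L)
  expect_warning(segment_nuclei(array(runif(800, 0, 0.1), c(10, 10, 8)),
                                threshold = 5), "threshold")
})

test_that("centroids follow the physical voxel-center convention", {
  arr <- array(0L, c(8, 8, 4))
  arr[3, 5, 2] <- 1L
  lv <- ms2gastrula:::new_label_volume(arr, 0.5, 2)
  cen <- measure_centroids(lv, frame = 1L)
  expect_equal(cen$y_um, 2.5 * 0.5)
  expect_equal(cen$x_um, 4.5 * 0.5)
  expect_equal(cen$z_um, 1.5 * 2)
  expect_equal(cen$n_voxels, 1L)

  ell <- ellipsoid_volume(3, 2, 2)
  cc <- measure_centroids(ell)
  d <- dim(ell$labels)
  expect_equal(cc$x_um, d[2] / 2 * ell$voxel_xy, tolerance = 0.05)
  expect_equal(cc$y_um, d[1] / 2 * ell$voxel_xy, tolerance = 0.05)
})

test_that("thickening never overwrites labelled voxels and watershed never merges", {
  set.seed(3)
  mask <- array(runif(1000) > 0.7, c(10, 10, 10))
  d <- dim(mask)
  lab <- array(ms2gastrula:::label_components_cpp(mask, d, 26L), d)
  spacing <- c(0.36, 0.36, 1)
  thick <- array(ms2gastrula:::dilate_labels_cpp(lab, d, spacing), d)
  expect_true(all(thick[lab > 0] == lab[lab > 0]))

  edt <- ms2gastrula:::edt3_cpp(mask, d, spacing)
  seeds <- ms2gastrula:::local_maxima_cpp(edt, mask, d, c(2L, 2L, 1L))
  ws <- ms2gastrula:::watershed_seeded_cpp(-edt, seeds, mask, d)
  expect_gte(length(unique(ws[ws > 0])), max(lab))
})

test_that("anisotropic distance transform matches brute force on a small mask", {
  set.seed(9)
  mask <- array(runif(150) > 0.4, c(5, 6, 5))
  spacing <- c(0.5, 0.7, 1.2)
  d <- dim(mask)
  edt <- array(ms2gastrula:::edt3_cpp(mask, d, spacing), d)
  coords <- which(!mask, arr.ind = TRUE)
  for (i in which(mask)) {
    z <- (i - 1) %/% (d[1] * d[2]) + 1
    rem <- (i - 1) %% (d[1] * d[2])
    x <- rem %/% d[1] + 1
    y <- rem %% d[1] + 1
    ref <- min(sqrt(((coords[, 1] - y) * spacing[1])^2 +
                      ((coords[, 2] - x) * spacing[2])^2 +
                      ((coords[, 3] - z) * spacing[3])^2))
    expect_equal(edt[y, x, z], ref, tolerance = 1e-9)
  }
})
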