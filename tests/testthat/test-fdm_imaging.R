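make_stack <- function(frames, frame_interval = 1) {
  arr <- array(0, c(dim(frames[[1]]), length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]]
  image_stack(arr, frame_interval)
}

test_that("temporal averaging is a sliding mean with the stated length contract", {
  const <- make_stack(replicate(6, matrix(5, 4, 4), simplify = FALSE))
  av <- temporal_average(const, 3)
  expect_equal(dim(av$data)[3], 4)
  expect_true(all(av$data == 5))
  expect_identical(temporal_average(const, 1), const)
  alt <- make_stack(lapply(1:6, function(k) matrix(ifelse(k %% 2, 0, 2),
                                                   3, 3)))
  expect_true(all(temporal_average(alt, 2)$data == 1))
  expect_error(temporal_average(const, 7), "window")
})

test_that("percent change follows the twofold-means-plus-100 convention with the earlier window as denominator", {
  # pixel stepping 100 -> 200 gives exactly +100; 200 -> 100 gives -50
  frames <- c(replicate(6, matrix(100, 4, 4), simplify = FALSE),
              replicate(6, matrix(200, 4, 4), simplify = FALSE))
  fdm <- frame_difference_pct(make_stack(frames), interval_minutes = 6,
                              avg_window = 3)
  expect_equal(max(fdm$pct, na.rm = TRUE), 100)
  down <- c(replicate(6, matrix(200, 4, 4), simplify = FALSE),
            replicate(6, matrix(100, 4, 4), simplify = FALSE))
  fd <- frame_difference_pct(make_stack(down), 6, 3)
  expect_equal(min(fd$pct, na.rm = TRUE), -50)
  # constant stack is identically zero
  const <- make_stack(replicate(12, matrix(7, 4, 4), simplify = FALSE))
  fc <- frame_difference_pct(const, 6, 3, intensity_floor = 1)
  expect_true(all(fc$pct == 0))
  # scaling the whole stack leaves pct unchanged
  sc <- make_stack(lapply(frames, function(m) m * 37.5))
  fs <- frame_difference_pct(sc, 6, 3)
  expect_equal(fs$pct, fdm$pct)
  # dim pixels are masked, not divided
  dim_stack <- make_stack(replicate(12, matrix(c(0, 100), 2, 2),
                                    simplify = FALSE))
  fm <- frame_difference_pct(dim_stack, 6, 3)
  expect_true(all(is.na(fm$pct[1, 1, ])))
  expect_error(frame_difference_pct(const, 2, 3), "overlap")
  expect_error(frame_difference_pct(make_stack(frames,
                                               frame_interval = 0.7), 6),
               "whole multiple")
})

test_that("segmentation recovers a planted disc to IoU 0.98 and a 1-px boundary", {
  mov <- cached("planted_clean", planted_movie(0, 1))
  mask <- cached("planted_clean_mask",
                 segment_cell(mov$channels$volume))
  truth <- mov$ground_truth$cell_mask
  for (k in c(1, 60)) {
    m <- mask$mask[, , k]
    expect_gt(sum(m & truth) / sum(m | truth), 0.98)
  }
  # boundary points lie within 1 px of the true circle
  ctr <- (dim(truth)[1] + 1) / 2
  b <- mask$boundary[[1]]
  rad <- sqrt((b[, 1] - ctr)^2 + (b[, 2] - ctr)^2)
  expect_lt(max(abs(rad - 40)), 1.6)
  expect_error(segment_cell(make_stack(replicate(3, matrix(0, 5, 5),
                                                 simplify = FALSE))),
               "segmentation failure")
})

test_that("planted protrusions are recovered exactly at the published thresholds on clean movies", {
  mov <- cached("planted_clean", planted_movie(0, 1))
  mask <- segment_cell(mov$channels$marker)
  fdm <- frame_difference_pct(mov$channels$marker)
  ev <- detect_protrusions(fdm, mask)
  sched <- planted_schedule()
  expect_equal(nrow(ev), 4)
  expect_true(all(abs(ev$onset_min - sched$onset) <= 1))
  expect_true(all(ang_diff(ev$angle_rad, sched$angle) <= 2 * pi / 120))
  # constant movie yields nothing
  const <- synth_movie(synth_config(duration = 30, seed = 5))
  cm <- segment_cell(const$channels$marker)
  cf <- frame_difference_pct(const$channels$marker)
  expect_equal(nrow(detect_protrusions(cf, cm)), 0)
})

test_that("the 5-minute duration filter rejects brief events", {
  sched <- data.frame(angle = 0, onset = 30, duration = 1, bump_size = 7,
                      amplitude_fold = 5)  # ~3-min suprathreshold track
  mov <- synth_movie(synth_config(duration = 70,
                                  protrusion_schedule = sched, seed = 2))
  mask <- segment_cell(mov$channels$marker)
  fdm <- frame_difference_pct(mov$channels$marker)
  expect_equal(nrow(detect_protrusions(fdm, mask, min_duration = 5)), 0)
  expect_gt(nrow(detect_protrusions(fdm, mask, min_duration = 0)), 0)
})

test_that("protrusion frequency is exact count arithmetic", {
  expect_equal(protrusion_frequency(pulsecoupler:::empty_events(), 60), 0)
  ev4 <- data.frame(id = 1:4)
  expect_equal(protrusion_frequency(ev4, 120), 2.0)
  mov <- cached("planted_clean", planted_movie(0, 1))
  mask <- segment_cell(mov$channels$marker)
  fdm <- frame_difference_pct(mov$channels$marker)
  ev <- detect_protrusions(fdm, mask)
  expect_equal(protrusion_frequency(ev, 120), 4 * 60 / 120)
})

test_that("the perimeter kymograph localizes hotspots and respects symmetry", {
  mov <- cached("planted_clean", planted_movie(0, 1))
  mask <- segment_cell(mov$channels$marker)
  fdm <- frame_difference_pct(mov$channels$marker)
  ky <- boundary_kymograph(fdm, mask, n_bins = 120)
  sched <- planted_schedule()
  binw <- 2 * pi / 120
  for (i in 1:4) {
    col <- which.min(abs(ky$times - (sched$onset[i] + 1)))
    v <- ky$values[, col]
    hot <- which(!is.na(v) & v >= 0.9 * max(v, na.rm = TRUE))
    center <- circ_mean(ky$angles[hot])
    expect_lte(ang_diff(center, sched$angle[i]), binw + 1e-9)
  }
  # rotationally symmetric pulsing ring: every column constant across bins
  n <- 80; ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  disc <- d2 <= 25^2
  frames <- lapply(1:16, function(k) {
    f <- matrix(0, n, n)
    f[disc] <- 100 * (1 + 0.5 * (k > 8))
    f
  })
  ring <- make_stack(frames)
  rm_ <- segment_cell(ring)
  rf <- frame_difference_pct(ring, 6, 3)
  rk <- boundary_kymograph(rf, rm_, n_bins = 40)
  for (j in seq_len(ncol(rk$values))) {
    v <- rk$values[, j]
    expect_lt(max(v, na.rm = TRUE) - min(v, na.rm = TRUE), 1e-9)
  }
})

test_that("interior flashes and boundary protrusions are separable event classes", {
  mov <- cached("planted_clean", planted_movie(0, 1))
  mask <- segment_cell(mov$channels$marker)
  fdm <- frame_difference_pct(mov$channels$marker)
  fl <- interior_flashes(fdm, mask)
  expect_equal(nrow(fl), 2)
  tf <- planted_flashes()
  expect_true(all(abs(sort(fl$onset_min) - tf$onset) <= 4))
  # flashes-only movie: nothing at the 100% boundary setting, flashes at 10%
  fmov <- synth_movie(synth_config(duration = 70,
                                   interior_flash_schedule =
                                     data.frame(angle = 1, onset = 25,
                                                duration = 4, size = 8,
                                                amplitude = 0.2),
                                   seed = 3))
  fm <- segment_cell(fmov$channels$marker)
  ff <- frame_difference_pct(fmov$channels$marker)
  expect_equal(nrow(detect_protrusions(ff, fm)), 0)
  expect_gte(nrow(interior_flashes(ff, fm)), 1)
  # boundary-only movie has no interior flashes
  bmov <- synth_movie(synth_config(
    duration = 70,
    protrusion_schedule = data.frame(angle = 0, onset = 15, duration = 6,
                                     bump_size = 7, amplitude_fold = 5),
    seed = 4))
  bm <- segment_cell(bmov$channels$marker)
  bf <- frame_difference_pct(bmov$channels$marker)
  expect_equal(nrow(interior_flashes(bf, bm)), 0)
})

test_that("detection at SNR 5 keeps precision and recall above 0.9 across seeds", {
  sched <- planted_schedule()
  prec <- rec <- numeric(5)
  for (s in seq_len(5)) {
    mov <- planted_movie(noise_sigma = 20, seed = 200 + s,
                         flashes = FALSE)
    mask <- segment_cell(mov$channels$marker)
    fdm <- frame_difference_pct(mov$channels$marker)
    ev <- detect_protrusions(fdm, mask)
    used <- rep(FALSE, nrow(ev)); tp <- 0
    for (i in 1:4) {
      ok <- which(!used & abs(ev$onset_min - sched$onset[i]) <= 4 &
                    ang_diff(ev$angle_rad, sched$angle[i]) <= 0.3)
      if (length(ok)) { tp <- tp + 1; used[ok[1]] <- TRUE }
    }
    prec[s] <- if (nrow(ev)) tp / nrow(ev) else 1
    rec[s] <- tp / 4
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})

test_that("detections are bitwise reproducible for fixed inputs", {
  mov <- cached("planted_clean", planted_movie(0, 1))
  mask <- segment_cell(mov$channels$marker)
  fdm <- frame_difference_pct(mov$channels$marker)
  expect_identical(detect_protrusions(fdm, mask),
                   detect_protrusions(fdm, mask))
})
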