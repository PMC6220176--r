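disc_masks <- function(n = 60, tt = 5) {
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  cell <- d2 <= 25^2; nuc <- d2 <= 10^2
  list(cell = array(cell, c(n, n, tt)),
       nuc = array(nuc, c(n, n, tt)),
       cyto = array(cell & !nuc, c(n, n, tt)))
}

test_that("C/N ratio is the masked-mean quotient, volume-normalizable", {
  m <- disc_masks()
  uni <- image_stack(array(80, c(60, 60, 5)), 1)
  expect_equal(cn_ratio(uni, m$nuc, m$cyto)$values, rep(1, 5))
  arr <- array(0, c(60, 60, 5))
  for (k in 1:5) { f <- matrix(0, 60, 60)
    f[m$nuc[, , 1]] <- 100; f[m$cyto[, , 1]] <- 150; arr[, , k] <- f }
  expect_equal(cn_ratio(image_stack(arr, 1), m$nuc, m$cyto)$values,
               rep(1.5, 5))
  # a shape artifact in the volume channel divides out exactly
  vol <- arr * 0.8
  norm <- cn_ratio(image_stack(arr, 1), m$nuc, m$cyto,
                   volume = image_stack(vol, 1))
  expect_equal(norm$values, rep(1, 5))
  empty <- array(FALSE, c(60, 60, 5))
  expect_error(cn_ratio(uni, empty, m$cyto), "frame 1")
})

test_that("volume normalization recovers a planted nuclear-exit step within 2%", {
  mov <- planted_movie(0, 1)
  gt <- mov$ground_truth
  tt <- dim(mov$channels$reporter$data)[3]
  nuc <- array(gt$nucleus_mask, c(dim(gt$nucleus_mask), tt))
  cyto <- array(gt$cell_mask & !gt$nucleus_mask,
                c(dim(gt$cell_mask), tt))
  cn <- cn_ratio(mov$channels$reporter, nuc, cyto,
                 volume = mov$channels$volume)
  rel <- cn$values / cn$values[1]
  truth <- gt$true_cn_trace$values / gt$true_cn_trace$values[1]
  expect_equal(rel, truth, tolerance = 0.02)
})

test_that("FRET ratio is linear in the acceptor channel", {
  m <- disc_masks()
  y <- image_stack(array(50, c(60, 60, 5)), 1)
  c_ <- image_stack(array(50, c(60, 60, 5)), 1)
  expect_equal(fret_ratio(y, c_, m$cell)$values, rep(1, 5))
  y2 <- image_stack(y$data * 2, 1)
  expect_equal(fret_ratio(y2, c_, m$cell)$values, rep(2, 5))
  zero <- image_stack(array(0, c(60, 60, 5)) + 1e-12, 1)
  expect_error(fret_ratio(y, image_stack(array(0, c(60, 60, 5)), 1),
                          m$cell), "zero CFP")
})

test_that("membrane normalization divides only above the floor", {
  a <- array(runif(4 * 4 * 3, 10, 20), c(4, 4, 3))
  bio <- image_stack(a, 1); mem <- image_stack(a, 1)
  out <- membrane_normalize(bio, mem, floor = 1)
  expect_true(all(out$data == 1))
  mem2 <- image_stack(a * 0 + c(0.5, rep(10, 15)), 1)
  out2 <- membrane_normalize(bio, mem2, floor = 1)
  expect_true(all(is.na(out2$data[1, 1, ])))
  expect_false(anyNA(out2$data[2:4, , ]))
  # planted 2x enrichment patch
  bio2 <- image_stack(a * 2, 1)
  expect_equal(membrane_normalize(bio2, mem, 1)$data,
               array(2, c(4, 4, 3)))
})

test_that("pulse calling implements the 20% fractional-increase rule exactly", {
  flat <- activity_trace(0:19, rep(1, 20))
  expect_equal(nrow(detect_pulses(flat, smoothing_window = 1)), 0)
  bump <- function(peak) activity_trace(0:19,
    c(rep(1, 6), 1 + (peak - 1) * c(0.3, 0.7, 1, 0.7, 0.3), rep(1, 9)))
  hit <- detect_pulses(bump(1.25), 0.20, smoothing_window = 1)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$fractional_increase, 0.25, tolerance = 1e-12)
  expect_false(hit$fused)
  expect_equal(nrow(detect_pulses(bump(1.15), 0.20,
                                  smoothing_window = 1)), 0)
  # scale invariance: multiplying by a positive constant changes nothing
  tr <- bump(1.4)
  tr2 <- activity_trace(tr$times, tr$values * 57)
  p1 <- detect_pulses(tr, smoothing_window = 1)
  p2 <- detect_pulses(tr2, smoothing_window = 1)
  expect_equal(p1$fractional_increase, p2$fractional_increase)
  expect_equal(p1$onset_time, p2$onset_time)
  expect_error(detect_pulses(activity_trace(c(0, 1, 3), c(1, 1, 1))),
               "non-uniform")
})

test_that("overlapping rises sharing a baseline merge into one fused pulse", {
  v <- c(rep(1, 4), 1.3, 1.5, 1.45, 1.6, rep(1, 8))
  tr <- activity_trace(seq_along(v) - 1, v)
  p <- detect_pulses(tr, 0.2, smoothing_window = 1)
  expect_equal(nrow(p), 1)
  expect_true(p$fused)
  expect_equal(p$peak, 1.6)
})

test_that("cross-correlation recovers shifts with the documented sign and tie conventions", {
  set.seed(5)
  base <- as.numeric(stats::filter(rnorm(200), rep(1 / 5, 5),
                                   circular = TRUE))
  a <- activity_trace(0:199, base)
  xc <- cross_correlation(a, a, max_lag = 20)
  expect_equal(xc$best_lag, 0)
  expect_equal(xc$best_r, 1)
  # b = a delayed by 3 frames -> positive best_lag = 3
  b <- activity_trace(0:199, c(rep(base[1], 3), base[1:197]))
  xb <- cross_correlation(a, b, max_lag = 20)
  expect_equal(xb$best_lag, 3)
  # anti-correlated at lag 0
  neg <- activity_trace(0:199, -base)
  xn <- cross_correlation(a, neg, max_lag = 20)
  expect_equal(xn$coefficients[xn$lags == 0], -1)
  # antisymmetry: swapping the traces negates the best lag
  xs <- cross_correlation(b, a, max_lag = 20)
  expect_equal(xs$best_lag, -xb$best_lag)
  expect_error(cross_correlation(a, b, max_lag = 150), "half")
})

test_that("half-maximum crossing is linearly interpolated and planted delays recovered", {
  # linear rise 1 -> 2 over 0..4 crosses half-max at exactly 2.0
  th <- pulsecoupler:::t_half_pulse(0:4, c(1, 1.25, 1.5, 1.75, 2),
                                    1L, 5L, 1, 2)
  expect_equal(th, 2.0)
  # identical traces give zero lag; a planted 5-min delay gives 5
  st <- synth_traces(true_lag = 5, n_pulses = 6, pulse_width = 6,
                     coupling_gain = 1, noise_sigma = 0, duration = 240,
                     seed = 21)
  same <- half_max_lag(st$protrusion, st$protrusion,
                       smoothing_window = 1)
  expect_equal(same$mean, 0)
  hm <- half_max_lag(st$protrusion, st$erk, pairing_window = 15,
                     smoothing_window = 1)
  expect_gt(hm$n, 0)
  expect_equal(hm$mean, 5, tolerance = 0.25)
})

test_that("pulse-magnitude correlation distinguishes coupling from shuffled pairs", {
  set.seed(77)
  mag <- runif(20, 0.5, 1.5)
  ev <- data.frame(fractional_increase = 0.5 * mag)
  expect_equal(pulse_magnitude_correlation(ev, mag), 1, tolerance = 1e-12)
  set.seed(88)
  expect_lt(abs(pulse_magnitude_correlation(ev, sample(mag))), 0.3)
  expect_error(pulse_magnitude_correlation(ev[1:2, , drop = FALSE],
                                           mag[1:2]),
               "insufficient")
  # planted coupling with mild noise stays above 0.9
  set.seed(9)
  ev2 <- data.frame(fractional_increase = 0.5 * mag +
                      rnorm(20, sd = 0.02))
  expect_gt(pulse_magnitude_correlation(ev2, mag), 0.9)
})
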