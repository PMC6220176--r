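test_that("periodic Laplacian annihilates constants, conserves mass, and has the analytic cosine eigenvalues", {
  expect_equal(periodic_laplacian(rep(3.7, 50), dx = 0.5), rep(0, 50))
  set.seed(1)
  for (rep in 1:5) {
    f <- rnorm(300)
    expect_lt(abs(sum(periodic_laplacian(f, dx = 2))),
              1e-10 * sum(abs(f)))
  }
  # cosine modes are eigenvectors with eigenvalue -(2/dx^2)(1 - cos(2 pi k/N))
  N <- 300; dx <- 1.5
  for (k in c(1, 7, 60)) {
    v <- cos(2 * pi * k * (0:(N - 1)) / N)
    lam <- -(2 / dx^2) * (1 - cos(2 * pi * k / N))
    expect_equal(periodic_laplacian(v, dx), lam * v, tolerance = 1e-10)
  }
  expect_error(periodic_laplacian(c(1, 2), 1), "at least 3")
})

test_that("drift matches an independent scalar transcription of the model equations", {
  p <- excitable_params(n_points = 3, D_X = 0, D_Y = 0)
  # single effective point (uniform field kills diffusion)
  X <- 0.7; Y <- 0.31; R <- 0.12
  st <- list(X = rep(X, 3), Y = rep(Y, 3), t = 0)
  d <- en_drift(st, p, rep(R, 3))
  dX_expect <- -p$a1 * X - p$a2 * (Y - R) * X +
    p$a3 * X^2 / (p$a4^2 + X^2) + p$a5
  dY_expect <- p$epsilon * (-Y + p$b1 * X)
  expect_equal(d$dX, rep(dX_expect, 3), tolerance = 1e-14)
  expect_equal(d$dY, rep(dY_expect, 3), tolerance = 1e-14)

  # origin with no basal production is a fixed point; with a5 > 0 only
  # the constant term survives
  p0 <- excitable_params(a5 = 0)
  z <- list(X = numeric(300), Y = numeric(300), t = 0)
  d0 <- en_drift(z, p0, 0)
  expect_equal(d0$dX, numeric(300))
  expect_equal(d0$dY, numeric(300))
  p5 <- excitable_params(a5 = 0.33)
  d5 <- en_drift(z, p5, 0)
  expect_equal(d5$dX, rep(0.33, 300))
  expect_equal(d5$dY, numeric(300))
  expect_error(en_drift(list(X = 1:5, Y = 1:5), p0), "n_points")
})

test_that("Euler-Maruyama step is deterministic Euler at zero noise, seed-reproducible, and obeys the Brownian variance law", {
  p <- en_preset("high_threshold", sigma_N = 0)
  st <- list(X = runif(300), Y = runif(300), t = 0)
  d <- en_drift(st, p, 0)
  s2 <- em_step(st, p, 0)
  expect_equal(s2$X, st$X + p$dt * d$dX, tolerance = 1e-14)
  expect_equal(s2$Y, st$Y + p$dt * d$dY, tolerance = 1e-14)
  expect_equal(s2$t, p$dt)

  pn <- en_preset("high_threshold")
  set.seed(42); a <- em_step(st, pn, 0)
  set.seed(42); b <- em_step(st, pn, 0)
  expect_identical(a, b)

  # pure-noise dynamics: Var[X(t)] = sigma^2 t
  pv <- excitable_params(D_X = 0, D_Y = 0, a1 = 0, a2 = 0, a3 = 0,
                         a5 = 0, b1 = 0, sigma_N = 0.5,
                         noise_corr_len = 0)
  vars <- vapply(c(11, 12), function(sd) {
    set.seed(sd)
    s <- list(X = numeric(300), Y = numeric(300), t = 0)
    for (i in 1:10000) s <- em_step(s, pv)
    var(s$X)
  }, numeric(1))
  expect_equal(mean(vars), 0.5^2 * 100, tolerance = 0.1)
})

test_that("the rest state solves the uniform drift and is found by the bracketing solver", {
  p0 <- excitable_params(a5 = 0)
  expect_equal(unname(find_rest_state(p0)), c(0, 0))

  p <- en_preset("high_threshold")
  r <- find_rest_state(p)
  expect_equal(r[["Y"]], p$b1 * r[["X"]], tolerance = 1e-12)
  d <- en_drift(list(X = rep(r[["X"]], p$n_points),
                     Y = rep(r[["Y"]], p$n_points), t = 0), p, 0)
  expect_lt(max(abs(d$dX)), 1e-9)
  expect_lt(max(abs(d$dY)), 1e-9)

  # brute-force bisection oracle on a dense grid
  g <- function(X) -p$a1 * X - p$a2 * p$b1 * X^2 +
    p$a3 * X^2 / (p$a4^2 + X^2) + p$a5
  grid <- seq(0, 1, length.out = 200001)
  gv <- g(grid)
  i <- which(gv[-length(gv)] > 0 & gv[-1] <= 0)[1]
  oracle <- uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-13)$root
  expect_equal(r[["X"]], oracle, tolerance = 1e-9)
})

test_that("deterministic trajectories stay at rest, are seed-reproducible, and converge under step halving", {
  p <- en_preset("high_threshold", sigma_N = 0)
  tr <- simulate_en(p, duration = 10, sample_every = 50)
  rest <- find_rest_state(p)
  expect_lt(max(abs(tr$X_kymo - rest[["X"]])), 1e-8)
  expect_equal(tr$mean_Y, rowMeans(tr$Y_kymo), tolerance = 1e-12)

  ps <- en_preset("high_threshold")
  a <- simulate_en(ps, duration = 5, sample_every = 10, seed = 99)
  b <- simulate_en(ps, duration = 5, sample_every = 10, seed = 99)
  expect_identical(a$X_kymo, b$X_kymo)
  expect_identical(a$Y_kymo, b$Y_kymo)

  # first-order convergence: halving a fine dt changes the sampled
  # fields by under 1e-4 relative, including through a firing excursion (dt 2.5e-4)
  kk <- data.frame(time = 1, amplitude = 2, center = 150, width = 60)
  p1 <- en_preset("high_threshold", sigma_N = 0, dt = 2.5e-4)
  p2 <- en_preset("high_threshold", sigma_N = 0, dt = 1.25e-4)
  t1 <- simulate_en(p1, duration = 15, sample_every = 4000, kicks = kk)
  t2 <- simulate_en(p2, duration = 15, sample_every = 8000, kicks = kk)
  relerr <- max(abs(t1$X_kymo - t2$X_kymo)) / max(abs(t2$X_kymo))
  expect_lt(relerr, 1e-4)
})

test_that("the stochastic high-threshold regime produces localized excursion patches", {
  run <- high_threshold_run(seed = 1)
  act <- run$traj$X_kymo > 1
  frac <- rowMeans(act)
  expect_gt(sum(frac > 0), 0)              # at least one excursion
  expect_true(any(frac > 0 & frac < 0.5))  # localized (< half perimeter)
})

test_that("stimulus protocols validate their segments and superpose", {
  expect_error(stimulus_protocol(list(list(t_start = 2, t_end = 1,
                                           profile = rep(1, 10)))),
               "t_start < t_end")
  expect_error(stimulus_protocol(list(list(t_start = 0, t_end = 1,
                                           profile = c(-1, 1)))),
               "finite")
  st <- stim_patch(0, 5, 2, center = 10, width = 4, n_points = 20)
  prof <- pulsecoupler:::stimulus_at(st, 1, 20)
  expect_equal(sum(prof > 0), 4)
  expect_equal(max(prof), 2)
  expect_equal(pulsecoupler:::stimulus_at(st, 6, 20), numeric(20))
  eg <- stim_egf(0, 20, spike = 3, plateau = 0.7, n_points = 10)
  expect_equal(pulsecoupler:::stimulus_at(eg, 1, 10), rep(3, 10))
  expect_equal(pulsecoupler:::stimulus_at(eg, 10, 10), rep(0.7, 10))
})

test_that("the threshold probe shows an all-or-none response on the high-threshold preset", {
  p <- en_preset("high_threshold", sigma_N = 0)
  tp <- threshold_probe(p, c(0, 0.2, 0.4, 0.8, 1.6, 3.2),
                        patch_width = 60, dead_time = 1)
  expect_true(tp$excitable)
  expect_equal(tp$curve$peak_excursion[1], 0)
  # responses monotone non-decreasing
  expect_true(all(diff(tp$curve$peak_excursion) >= -1e-9))
  sup <- tp$curve$peak_excursion[tp$curve$amplitude >= 1.6]
  sub <- tp$curve$peak_excursion[tp$curve$amplitude > 0 &
                                   tp$curve$amplitude <= 0.4]
  # two suprathreshold amplitudes differing 2x agree within 25%
  expect_lt((max(sup) - min(sup)) / min(sup), 0.25)
  expect_gt(min(sup), 5 * max(sub))
})

test_that("subthreshold perturbations decay monotonically after the kick transient", {
  p <- en_preset("high_threshold", sigma_N = 0)
  tr <- simulate_en(p, duration = 15, sample_every = 50,
                    kicks = data.frame(time = 0, amplitude = 0.3,
                                       center = 150, width = 60))
  rest <- find_rest_state(p)
  exc <- apply(tr$X_kymo, 1, max) - rest[["X"]]
  late <- exc[tr$times >= 2]
  expect_true(all(diff(late) <= 1e-6))
  expect_lt(late[length(late)], 0.05)
})

test_that("the refractory period is bracketed by the gap scan and recovers at long separations", {
  p <- en_preset("high_threshold", sigma_N = 0)
  rp <- refractory_period(p, probe_amplitude = 3,
                          gaps = c(4, 6, 8, 10, 13, 16, 20, 26),
                          patch_width = 60, dead_time = 1)
  expect_true(is.finite(rp$period))
  sc <- rp$scan
  i <- which(sc$gap == rp$period)
  expect_gte(sc$ratio[i], 0.8)
  expect_lt(sc$ratio[i - 1], 0.8)         # bracketing below
  expect_lt(sc$ratio[1], 0.5)             # strongly refractory at short gap
  expect_gt(sc$ratio[nrow(sc)], 0.95)     # full recovery at long gap
})

test_that("parameter validation enforces the stability bound and field checks", {
  expect_error(excitable_params(D_X = 100, dt = 0.01, dx = 1), "unstable")
  expect_error(excitable_params(n_points = 2), "n_points")
  expect_error(excitable_params(a4 = 0), "a4")
  expect_error(excitable_params(sigma_N = -1), "sigma_N")
  expect_error(simulate_en(en_preset("high_threshold"), duration = 10),
               "seed")
})
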