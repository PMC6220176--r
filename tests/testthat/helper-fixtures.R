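# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# standard 4-protrusion + 2-flash schedule used across imaging tests
planted_schedule <- function() {
  data.frame(angle = c(0, pi / 2, pi, 3 * pi / 2),
             onset = c(15, 40, 65, 90),
             duration = 6, bump_size = 7, amplitude_fold = 5)
}

planted_flashes <- function() {
  data.frame(angle = c(pi / 4, 5 * pi / 4), onset = c(30, 75),
             duration = 4, size = 8, amplitude = 0.2)
}

planted_movie <- function(noise_sigma = 0, seed = 1, flashes = TRUE) {
  cfg <- synth_config(duration = 120,
                      protrusion_schedule = planted_schedule(),
                      interior_flash_schedule =
                        if (flashes) planted_flashes() else NULL,
                      erk_delay = 5, erk_gain = 0.1,
                      noise_sigma = noise_sigma, seed = seed)
  synth_movie(cfg)
}

# minimal smallest-angle difference on the circle
ang_diff <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

# circular mean of angles weighted by w
circ_mean <- function(theta, w = rep(1, length(theta))) {
  atan2(sum(w * sin(theta)), sum(w * cos(theta))) %% (2 * pi)
}

# discrete Z pulses: excursions above hi (in units of c2) separated by
# returns below lo; peaks closer than min_sep minutes are merged
z_pulse_count <- function(z, hi = 0.5, lo = 0.1) {
  ev <- 0L; state <- "lo"
  for (v in z) {
    if (state == "lo" && v > hi) { ev <- ev + 1L; state <- "hi" }
    else if (state == "hi" && v < lo) state <- "lo"
  }
  ev
}

# peak times of a Z trace (runs above half its max), merging peaks closer
# than min_sep
z_peak_times <- function(z, t, min_sep = 4) {
  zm <- max(z)
  hi <- z > 0.5 * zm
  runs <- rle(hi)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  pt <- numeric(0)
  for (i in which(runs$values)) {
    seg <- starts[i]:ends[i]
    pt <- c(pt, t[seg[which.max(z[seg])]])
  }
  if (length(pt) < 2) return(pt)
  merged <- pt[1]
  for (p in pt[-1]) {
    if (p - merged[length(merged)] < min_sep) next
    merged <- c(merged, p)
  }
  merged
}

high_threshold_run <- function(seed = 1, duration = 240) {
  cached(paste0("high_", seed, "_", duration), {
    p <- en_preset("high_threshold")
    traj <- simulate_en(p, duration = duration, sample_every = 25,
                        seed = seed)
    erk <- suppressMessages(couple_en_to_erk(traj))
    list(traj = traj, erk = erk)
  })
}
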