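# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

#' Configuration for the synthetic movie generator
#'
#' Describes a roughly circular adherent cell with a nucleus, a schedule
#' of boundary protrusions (local intensity bumps that ramp up to an
#' `amplitude_fold`-fold enrichment), delayed nucleus-to-cytoplasm
#' reporter redistribution whose magnitude scales with protrusion size,
#' optional interior activity flashes, and additive Gaussian read noise.
#'
#' Each scheduled protrusion rises exponentially from 1x to
#' `amplitude_fold`x over `duration` minutes, holds for `duration`
#' minutes, and decays back over `duration` minutes.  The reporter
#' redistribution follows the same profile delayed by `erk_delay`; its
#' fractional C/N increase is `erk_gain * (amplitude_fold - 1)`.
#' Total reporter intensity is conserved per frame (nuclear loss equals
#' cytoplasmic gain), as for a real translocation reporter.
#'
#' @param image_size Height/width in pixels (square frames).
#' @param frame_interval Minutes per frame.
#' @param duration Total movie length in minutes.
#' @param cell_radius,nucleus_radius Pixels (`nucleus_radius <
#'   cell_radius`).
#' @param protrusion_schedule Data frame with columns `angle` (radians),
#'   `onset` (min), `duration` (min), `bump_size` (pixels),
#'   `amplitude_fold` (> 1).
#' @param interior_flash_schedule Optional data frame with columns
#'   `angle`, `onset`, `duration` (min), `size` (pixels), `amplitude`
#'   (fractional increase, e.g. 0.2).
#' @param erk_delay Minutes between protrusion onset and reporter
#'   response.
#' @param erk_gain Fractional C/N increase per unit protrusion magnitude.
#' @param noise_sigma Additive Gaussian noise s.d. (intensity units).
#' @param baseline_intensity Cytoplasmic baseline intensity.
#' @param seed Integer seed (mandatory; generation is bitwise
#'   reproducible).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(image_size = 120, frame_interval = 1,
                         duration = 120, cell_radius = 40,
                         nucleus_radius = 15,
                         protrusion_schedule = NULL,
                         interior_flash_schedule = NULL,
                         erk_delay = 5, erk_gain = 0.1,
                         noise_sigma = 0, baseline_intensity = 100,
                         seed = NULL) {
  if (is.null(seed)) stop("seed is mandatory for synthetic generation")
  if (nucleus_radius >= cell_radius)
    stop("nucleus_radius must be < cell_radius")
  if (is.null(protrusion_schedule))
    protrusion_schedule <- data.frame(angle = numeric(0), onset = numeric(0),
                                      duration = numeric(0),
                                      bump_size = numeric(0),
                                      amplitude_fold = numeric(0))
  ps <- protrusion_schedule
  if (nrow(ps) > 0) {
    if (any(ps$onset < 0 | ps$onset + 3 * ps$duration > duration))
      stop("invalid config: protrusion events (rise+hold+fall) must fit ",
           "within [0, duration]")
    if (any(ps$amplitude_fold <= 1))
      stop("invalid config: amplitude_fold must be > 1")
  }
  fs <- interior_flash_schedule
  if (!is.null(fs) && nrow(fs) > 0 &&
      any(fs$onset < 0 | fs$onset + fs$duration > duration))
    stop("invalid config: flash events must fit within [0, duration]")
  structure(list(image_size = as.integer(image_size),
                 frame_interval = frame_interval, duration = duration,
                 cell_radius = cell_radius,
                 nucleus_radius = nucleus_radius,
                 protrusion_schedule = ps,
                 interior_flash_schedule = fs,
                 erk_delay = erk_delay, erk_gain = erk_gain,
                 noise_sigma = noise_sigma,
                 baseline_intensity = baseline_intensity,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# normalized event profile: exponential rise over [0, G), hold over
# [G, 2G), exponential fall over [2G, 3G); in log-fold units so that
# fold^profile is the intensity factor
event_profile <- function(t, onset, G) {
  s <- t - onset
  p <- numeric(length(t))
  r <- s >= 0 & s < G
  p[r] <- s[r] / G
  h <- s >= G & s < 2 * G
  p[h] <- 1
  f <- s >= 2 * G & s < 3 * G
  p[f] <- 1 - (s[f] - 2 * G) / G
  p
}

#' Paired synthetic protrusion/ERK traces with a planted lag
#'
#' Generates a protrusion-activity trace as a sum of Gaussian bumps at
#' jittered regular onsets with variable amplitudes, and an ERK trace as
#' baseline 1 plus `coupling_gain`-scaled copies of each bump delayed by
#' `true_lag`, plus white noise.  Both traces and the full ground truth
#' (onsets, amplitudes, planted lag) are returned.
#'
#' @param true_lag Planted delay in minutes.
#' @param n_pulses Number of bumps.
#' @param pulse_width Bump FWHM in minutes.
#' @param coupling_gain ERK fractional response per unit bump amplitude
#'   (0 decouples the traces).
#' @param noise_sigma White-noise s.d. added to both traces.
#' @param duration Trace length in minutes.
#' @param frame_interval Sampling interval in minutes.
#' @param seed Integer seed (mandatory).
#' @return List with `protrusion` and `erk` ([activity_trace()]s) and
#'   `ground_truth` (onsets, amplitudes, `true_lag`, noise-free traces).
#' @export
synth_traces <- function(true_lag, n_pulses = 8, pulse_width = 6,
                         coupling_gain = 0.5, noise_sigma = 0,
                         duration = 360, frame_interval = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  slot <- duration / (n_pulses + 1)
  if (slot / 2 < pulse_width)
    stop("invalid config: schedule overcrowded (bumps would overlap by ",
         "more than half their width)")
  with_seed(seed, {
    onsets <- slot * seq_len(n_pulses) +
      stats::runif(n_pulses, -slot / 4, slot / 4)
    amps <- stats::runif(n_pulses, 0.5, 1.5)
    times <- seq(0, duration, by = frame_interval)
    sd_b <- pulse_width / (2 * sqrt(2 * log(2)))
    bump <- function(tt, o) exp(-(tt - o)^2 / (2 * sd_b^2))
    prot0 <- 1 + Reduce(`+`, lapply(seq_len(n_pulses), function(i)
      amps[i] * bump(times, onsets[i])))
    erk0 <- 1 + coupling_gain * Reduce(`+`, lapply(seq_len(n_pulses),
      function(i) amps[i] * bump(times, onsets[i] + true_lag)))
    prot <- prot0 + stats::rnorm(length(times), sd = noise_sigma)
    erk <- erk0 + stats::rnorm(length(times), sd = noise_sigma)
    list(protrusion = activity_trace(times, prot, "protrusion"),
         erk = activity_trace(times, erk, "ERK"),
         ground_truth = list(onsets = onsets, amplitudes = amps,
                             true_lag = true_lag,
                             protrusion_clean = prot0, erk_clean = erk0))
  })
}

# squared distance field to a point, on the pixel grid
dist2_field <- function(n, r0, c0) {
  outer((seq_len(n) - r0)^2, (seq_len(n) - c0)^2, `+`)
}

#' Render a ground-truthed synthetic time-lapse movie
#'
#' Draws a disc cell with a nucleus and renders four channels:
#' `marker` (protrusion biosensor with scheduled boundary bumps),
#' `reporter` (translocation reporter redistributing from nucleus to
#' cytoplasm with delay and magnitude coupling), `volume` (uniform volume
#' marker), and `membrane` (uniform membrane reference).  Interior
#' flashes alter interior intensity without touching the boundary.
#' Ground-truth masks, event tables and the exact C/N trace are returned.
#'
#' @param config A [synth_config()].
#' @return List with `channels` (named list of [image_stack()]s) and
#'   `ground_truth` (events, flashes, `true_cn_trace`, `true_lag`,
#'   `cell_mask`, `nucleus_mask`).
#' @export
synth_movie <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$image_size
  ctr <- (n + 1) / 2
  times <- seq(0, config$duration, by = config$frame_interval)
  tt <- length(times)
  d2 <- dist2_field(n, ctr, ctr)
  cell <- d2 <= config$cell_radius^2
  nuc <- d2 <= config$nucleus_radius^2
  cyto <- cell & !nuc
  base <- config$baseline_intensity

  # bump support regions (centered just inside the boundary)
  ps <- config$protrusion_schedule
  bump_regions <- lapply(seq_len(nrow(ps)), function(i) {
    rad <- config$cell_radius - 2
    r0 <- ctr - rad * sin(ps$angle[i])
    c0 <- ctr + rad * cos(ps$angle[i])
    (dist2_field(n, r0, c0) <= ps$bump_size[i]^2) & cell
  })
  fs <- config$interior_flash_schedule
  flash_regions <- if (is.null(fs)) list() else
    lapply(seq_len(nrow(fs)), function(i) {
      rad <- 0.4 * config$cell_radius
      r0 <- ctr - rad * sin(fs$angle[i])
      c0 <- ctr + rad * cos(fs$angle[i])
      (dist2_field(n, r0, c0) <= fs$size[i]^2) & cell
    })

  nuc_int <- 2 * base    # reporter is nuclear when ERK is off
  cyt_int <- base
  A_n <- sum(nuc); A_c <- sum(cyto)
  cn0 <- cyt_int / nuc_int

  marker <- array(0, c(n, n, tt))
  reporter <- array(0, c(n, n, tt))
  volume <- array(0, c(n, n, tt))
  membrane <- array(0, c(n, n, tt))
  true_cn <- numeric(tt)

  for (k in seq_len(tt)) {
    t <- times[k]
    fr <- matrix(0, n, n); fr[cell] <- base
    for (i in seq_len(nrow(ps))) {
      pr <- event_profile(t, ps$onset[i], ps$duration[i])
      if (pr > 0)
        fr[bump_regions[[i]]] <- base * ps$amplitude_fold[i]^pr
    }
    if (!is.null(fs)) for (i in seq_len(nrow(fs))) {
      if (t >= fs$onset[i] && t < fs$onset[i] + fs$duration[i])
        fr[flash_regions[[i]]] <- fr[flash_regions[[i]]] *
          (1 + fs$amplitude[i])
    }
    marker[, , k] <- fr

    # reporter: delayed, magnitude-coupled nucleus-to-cytoplasm transfer
    delta <- 0
    for (i in seq_len(nrow(ps))) {
      pr <- event_profile(t, ps$onset[i] + config$erk_delay,
                          ps$duration[i])
      delta <- delta + config$erk_gain * (ps$amplitude_fold[i] - 1) * pr
    }
    # fraction of nuclear signal moved so that C/N rises by factor 1+delta
    phi <- delta * cyt_int /
      (nuc_int * A_n / A_c + (1 + delta) * cyt_int)
    rep_fr <- matrix(0, n, n)
    rep_fr[nuc] <- nuc_int * (1 - phi)
    rep_fr[cyto] <- cyt_int + phi * nuc_int * A_n / A_c
    reporter[, , k] <- rep_fr
    true_cn[k] <- cn0 * (1 + delta)

    vol_fr <- matrix(0, n, n); vol_fr[cell] <- 1.5 * base
    volume[, , k] <- vol_fr
    mem_fr <- matrix(0, n, n); mem_fr[cell] <- base
    membrane[, , k] <- mem_fr
  }

  if (config$noise_sigma > 0) {
    with_seed(config$seed, {
      for (nm in c("marker", "reporter", "volume", "membrane")) {
        arr <- get(nm)
        arr <- arr + array(stats::rnorm(length(arr),
                                        sd = config$noise_sigma), dim(arr))
        arr[arr < 0] <- 0
        assign(nm, arr)
      }
    })
  }

  mk <- function(a, ch) image_stack(a, config$frame_interval, channel = ch)
  events <- if (nrow(ps)) data.frame(
    angle = ps$angle, onset = ps$onset, duration = ps$duration,
    area = vapply(bump_regions, sum, numeric(1)),
    magnitude = ps$amplitude_fold - 1) else
    data.frame(angle = numeric(0), onset = numeric(0),
               duration = numeric(0), area = numeric(0),
               magnitude = numeric(0))
  flashes <- if (!is.null(fs) && nrow(fs)) data.frame(
    angle = fs$angle, onset = fs$onset, duration = fs$duration,
    area = vapply(flash_regions, sum, numeric(1)),
    amplitude = fs$amplitude) else
    data.frame(angle = numeric(0), onset = numeric(0),
               duration = numeric(0), area = numeric(0),
               amplitude = numeric(0))
  list(channels = list(marker = mk(marker, "marker"),
                       reporter = mk(reporter, "reporter"),
                       volume = mk(volume, "volume"),
                       membrane = mk(membrane, "membrane")),
       ground_truth = list(
         events = events, flashes = flashes,
         true_cn_trace = activity_trace(times, true_cn, "true C/N"),
         true_lag = config$erk_delay,
         cell_mask = cell, nucleus_mask = nuc,
         times = times))
}

#' Render a movie from a simulated excitable-network trajectory
#'
#' Bridges the simulation to the imaging pipeline: the activator field
#' `X(theta, t)` becomes boundary-band biosensor enrichment at matching
#' angles, and the ERK state `Z(t)` becomes a global nucleus-to-cytoplasm
#' reporter redistribution.  Both are resampled to the movie frame
#' interval (displayed minutes).
#'
#' @param traj An `en_trajectory` from [simulate_en()].
#' @param erk An `erk_trace` from [couple_en_to_erk()] on the same time
#'   grid.
#' @param config A [synth_config()] providing geometry, noise and timing
#'   (its schedules are ignored).
#' @param marker_fold Peak biosensor fold-enrichment assigned to the
#'   trajectory's maximal activator excursion.
#' @param cn_gain Fractional C/N increase at `Z = c2`.
#' @return Same shape as [synth_movie()]; the ground truth carries the
#'   resampled activator kymograph and ERK trace.
#' @export
render_from_model <- function(traj, erk, config, marker_fold = 3,
                              cn_gain = 0.5) {
  stopifnot(inherits(traj, "en_trajectory"), inherits(erk, "erk_trace"))
  n <- config$image_size
  ctr <- (n + 1) / 2
  frames_min <- seq(0, min(max(traj$times_min), config$duration),
                    by = config$frame_interval)
  tt <- length(frames_min)
  idx <- vapply(frames_min, function(tm)
    which.min(abs(traj$times_min - tm)), integer(1))
  Xk <- traj$X_kymo[idx, , drop = FALSE]
  Zn <- erk$Z_norm[idx]
  rest <- find_rest_state(traj$params)
  Xe <- pmax(Xk - rest[["X"]], 0)
  xref <- max(Xe)
  # aliasing guard: excursions shorter than a frame cannot be rendered
  if (xref > 0) {
    act <- rowSums(Xe > 0.5 * xref) > 0
    if (any(act)) {
      runs <- rle(act)
      min_run <- min(runs$lengths[runs$values]) * config$frame_interval
      if (min_run < config$frame_interval * 2)
        warning("aliasing: excursions are barely resolved at this ",
                "frame interval")
    }
  }

  d2 <- dist2_field(n, ctr, ctr)
  cell <- d2 <= config$cell_radius^2
  nuc <- d2 <= config$nucleus_radius^2
  cyto <- cell & !nuc
  band <- cell & d2 > (config$cell_radius - 4)^2
  ij <- which(band, arr.ind = TRUE)
  ang <- pixel_angle(ij[, 1], ij[, 2], c(ctr, ctr))
  npts <- traj$params$n_points
  grid_bin <- pmin(pmax(1L, as.integer(floor(ang / (2 * pi) * npts)) + 1L),
                   npts)
  base <- config$baseline_intensity
  nuc_int <- 2 * base; cyt_int <- base
  A_n <- sum(nuc); A_c <- sum(cyto)
  cn0 <- cyt_int / nuc_int

  marker <- array(0, c(n, n, tt))
  reporter <- array(0, c(n, n, tt))
  true_cn <- numeric(tt)
  for (k in seq_len(tt)) {
    fr <- matrix(0, n, n); fr[cell] <- base
    if (xref > 0) {
      fold <- 1 + (marker_fold - 1) * Xe[k, grid_bin] / xref
      fr[band] <- base * fold
    }
    marker[, , k] <- fr
    delta <- cn_gain * Zn[k]
    phi <- delta * cyt_int /
      (nuc_int * A_n / A_c + (1 + delta) * cyt_int)
    rep_fr <- matrix(0, n, n)
    rep_fr[nuc] <- nuc_int * (1 - phi)
    rep_fr[cyto] <- cyt_int + phi * nuc_int * A_n / A_c
    reporter[, , k] <- rep_fr
    true_cn[k] <- cn0 * (1 + delta)
  }
  vol <- array(0, c(n, n, tt)); mem <- array(0, c(n, n, tt))
  for (k in seq_len(tt)) {
    f <- matrix(0, n, n); f[cell] <- 1.5 * base; vol[, , k] <- f
    g <- matrix(0, n, n); g[cell] <- base; mem[, , k] <- g
  }
  if (config$noise_sigma > 0) {
    with_seed(config$seed, {
      marker <- pmax(marker + array(stats::rnorm(length(marker),
        sd = config$noise_sigma), dim(marker)), 0)
      reporter <- pmax(reporter + array(stats::rnorm(length(reporter),
        sd = config$noise_sigma), dim(reporter)), 0)
    })
  }
  mk <- function(a, ch) image_stack(a, config$frame_interval, channel = ch)
  list(channels = list(marker = mk(marker, "marker"),
                       reporter = mk(reporter, "reporter"),
                       volume = mk(vol, "volume"),
                       membrane = mk(mem, "membrane")),
       ground_truth = list(
         X_kymo = Xk, Z_norm = Zn, times = frames_min,
         true_cn_trace = activity_trace(frames_min, true_cn, "true C/N"),
         cell_mask = cell, nucleus_mask = nuc))
}
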