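#' Parameters of the excitable activator--inhibitor network
#'
#' Constructs the parameter set of the two-species excitable network (EN)
#' defined on the perimeter of a circular cell, discretized as a periodic
#' 1-D grid.  The activator `X` is autocatalytic (sigmoidal self-activation
#' with maximal rate `a3` and half-saturation `a4`), decays linearly at rate
#' `a1`, and is suppressed by the inhibitor `Y` through the bilinear term
#' `a2 * (Y - R) * X`, where `R` is an external stimulus that effectively
#' lowers the inhibition.  The inhibitor relaxes toward `b1 * X` on the slow
#' time scale `1/epsilon`.  Zero-mean Gaussian white noise of intensity
#' `sigma_N` drives the activator equation only.
#'
#' Time is expressed in model time units; `time_scale` maps one model time
#' unit to displayed minutes when trajectories are compared with imaging
#' data (default 1, i.e. one model time unit is displayed as one minute).
#' Space is in model length units with `dx = 1` by default; no physical
#' micrometre calibration is implied.
#'
#' @param D_X,D_Y Diffusion coefficients of activator and inhibitor
#'   (length^2 / time).
#' @param a1 Activator linear decay rate (1/time).
#' @param a2 Inhibition coupling coefficient (1/(conc * time)).
#' @param a3 Autocatalysis maximal rate (conc/time).
#' @param a4 Autocatalysis half-saturation (conc).
#' @param a5 Basal activator production (conc/time).
#' @param epsilon Inhibitor relaxation rate (1/time); the inhibitor is the
#'   slow variable, so `epsilon` is typically well below 1.
#' @param b1 Inhibitor gain from the activator (dimensionless).  Raising
#'   `b1` raises the firing threshold.
#' @param sigma_N Standard deviation parameter of the white-noise input on
#'   the activator (conc/sqrt(time)).
#' @param noise_corr_len Spatial correlation length of the noise in grid
#'   points (Gaussian kernel standard deviation).  `0` gives spatially
#'   independent increments.  The per-point marginal standard deviation is
#'   `sigma_N` in either case; correlated noise only changes how coherent
#'   neighbouring increments are, which is what permits localized firings
#'   to nucleate without an inflated subthreshold noise floor.
#' @param n_points Number of grid points on the perimeter.
#' @param dt Integration time step (time).
#' @param dx Grid spacing (length).
#' @param time_scale Displayed minutes per model time unit.
#' @return An object of class `excitable_params` (a validated list).
#' @seealso [en_preset()] for the two calibrated regimes, [simulate_en()].
#' @export
excitable_params <- function(D_X = 30, D_Y = 2, a1 = 1, a2 = 1, a3 = 8,
                             a4 = 2, a5 = 0.04, epsilon = 0.3, b1 = 1.2,
                             sigma_N = 0.3, noise_corr_len = 10,
                             n_points = 300, dt = 0.01,
                             dx = 1, time_scale = 0.5) {
  p <- list(D_X = D_X, D_Y = D_Y, a1 = a1, a2 = a2, a3 = a3, a4 = a4,
            a5 = a5, epsilon = epsilon, b1 = b1, sigma_N = sigma_N,
            noise_corr_len = noise_corr_len,
            n_points = as.integer(n_points), dt = dt, dx = dx,
            time_scale = time_scale)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all excitable_params fields must be finite scalars; bad: ",
         paste(names(p)[!num], collapse = ", "))
  if (p$n_points < 3) stop("n_points must be >= 3")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$dx <= 0) stop("dx must be > 0")
  if (p$a4 <= 0) stop("a4 must be > 0")
  if (p$epsilon <= 0) stop("epsilon must be > 0")
  if (p$sigma_N < 0) stop("sigma_N must be >= 0")
  if (p$noise_corr_len < 0) stop("noise_corr_len must be >= 0")
  if (p$time_scale <= 0) stop("time_scale must be > 0")
  # explicit Euler stability bound for the diffusive part
  if (p$dt * max(p$D_X, p$D_Y) / p$dx^2 > 0.5)
    stop("unstable discretization: dt * max(D_X, D_Y) / dx^2 must be <= 0.5")
  structure(p, class = "excitable_params")
}

#' Named parameter presets for the two firing regimes
#'
#' Two calibrated regimes of the excitable network.  `"high_threshold"`
#' produces infrequent, spatially localized firings (discrete downstream
#' ERK pulses); `"low_threshold"` lowers the inhibitor gain `b1` and raises
#' the noise so firings are frequent and overlapping (sustained ERK
#' activation).  The inhibitor gain and the noise variance are the two
#' knobs that move the system between regimes; all other constants are
#' shared.  The calibration procedure is described in the package vignette.
#'
#' @param name `"high_threshold"` or `"low_threshold"`.
#' @param ... Overrides forwarded to [excitable_params()].
#' @return An `excitable_params` object.
#' @export
en_preset <- function(name = c("high_threshold", "low_threshold"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    high_threshold = list(b1 = 1.2, sigma_N = 0.30),
    low_threshold  = list(b1 = 0.6, sigma_N = 0.40)
  )
  args <- utils::modifyList(base, list(...))
  do.call(excitable_params, args)
}

#' @export
print.excitable_params <- function(x, ...) {
  cat("Excitable network parameters (", x$n_points, " grid points, dt = ",
      x$dt, ")\n", sep = "")
  flds <- c("D_X", "D_Y", "a1", "a2", "a3", "a4", "a5", "epsilon", "b1",
            "sigma_N")
  cat(paste0("  ", flds, " = ", unlist(x[flds]), collapse = "\n"), "\n")
  invisible(x)
}

#' Discrete Laplacian on a periodic 1-D grid
#'
#' Central-difference second derivative with wraparound indexing,
#' `(f[i-1] - 2 f[i] + f[i+1]) / dx^2`.  The operator annihilates constant
#' fields and conserves mass (its output sums to zero).
#'
#' @param field Numeric vector of length >= 3.
#' @param dx Grid spacing (> 0).
#' @return Numeric vector of the same length.
#' @export
periodic_laplacian <- function(field, dx = 1) {
  n <- length(field)
  if (n < 3) stop("invalid grid: field must have at least 3 points")
  if (!is.numeric(dx) || dx <= 0) stop("dx must be > 0")
  (field[c(2:n, 1)] - 2 * field + field[c(n, 1:(n - 1))]) / dx^2
}

#' Stimulus protocols for the excitable network
#'
#' A stimulus protocol is a list of time segments, each carrying a per-grid
#' amplitude profile for the external input `R`.  Outside every segment the
#' stimulus is zero.  Convenience constructors cover the standard protocols:
#' a sustained uniform step (`stim_uniform`), a transient uniform pulse
#' (the same constructor with a short window), and a localized patch
#' (`stim_patch`).
#'
#' @param segments List of lists with fields `t_start`, `t_end` and
#'   `profile` (numeric vector, one amplitude per grid point).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(segments = list()) {
  for (s in segments) {
    if (!all(c("t_start", "t_end", "profile") %in% names(s)))
      stop("each segment needs t_start, t_end and profile")
    if (s$t_start >= s$t_end) stop("segment must have t_start < t_end")
    if (any(!is.finite(s$profile)) || any(s$profile < 0))
      stop("profile amplitudes must be finite and >= 0")
  }
  structure(list(segments = segments), class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @param t_start,t_end Segment window (model time).
#' @param amplitude Stimulus amplitude.
#' @param n_points Grid size the profile must match.
#' @export
stim_uniform <- function(t_start, t_end, amplitude, n_points = 300) {
  stimulus_protocol(list(list(t_start = t_start, t_end = t_end,
                              profile = rep(amplitude, n_points))))
}

#' @rdname stimulus_protocol
#' @details
#' `stim_egf()` models growth-factor stimulation with receptor-level
#' adaptation: a brief strong onset spike (receptor activation peaking on
#' ligand addition) followed by a lower sustained plateau while the ligand
#' remains.  A long stimulus keeps the plateau until the end of the run; a
#' short (transient) stimulus ends at `t_off`, emulating ligand washout or
#' receptor inhibition.
#' @param t_on,t_off Stimulus window (model time); for a sustained stimulus
#'   set `t_off` to the run duration.
#' @param spike Amplitude of the onset spike.
#' @param plateau Amplitude of the adapted plateau.
#' @param spike_len Duration of the onset spike.
#' @export
stim_egf <- function(t_on, t_off, spike = 3, plateau = 0.7, spike_len = 2,
                     n_points = 300) {
  segs <- list(list(t_start = t_on, t_end = min(t_on + spike_len, t_off),
                    profile = rep(spike, n_points)))
  if (t_off > t_on + spike_len)
    segs <- c(segs, list(list(t_start = t_on + spike_len, t_end = t_off,
                              profile = rep(plateau, n_points))))
  stimulus_protocol(segs)
}

#' @rdname stimulus_protocol
#' @param center Index of the patch center.
#' @param width Patch width in grid points.
#' @export
stim_patch <- function(t_start, t_end, amplitude, center, width,
                       n_points = 300) {
  prof <- numeric(n_points)
  idx <- ((center - ceiling(width / 2)) + seq_len(width) - 1L) %% n_points + 1L
  prof[idx] <- amplitude
  stimulus_protocol(list(list(t_start = t_start, t_end = t_end,
                              profile = prof)))
}

# Stimulus profile at model time t (zeros outside all segments).
stimulus_at <- function(protocol, t, n_points) {
  prof <- numeric(n_points)
  if (is.null(protocol)) return(prof)
  for (s in protocol$segments) {
    if (t >= s$t_start && t < s$t_end) {
      if (length(s$profile) != n_points)
        stop("stimulus profile length (", length(s$profile),
             ") does not match n_points (", n_points, ")")
      prof <- prof + s$profile
    }
  }
  prof
}

# Precompute the circular-convolution machinery for spatially correlated
# noise.  Returns NULL for independent noise, else list(Kf, scale) with the
# kernel FFT and the factor restoring a unit marginal standard deviation.
noise_kernel <- function(n, corr_len) {
  if (corr_len <= 0) return(NULL)
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-0.5 * (d / corr_len)^2)
  k <- k / sum(k)
  list(Kf = stats::fft(k), scale = 1 / sqrt(sum(k^2)))
}

# One spatial noise field with unit marginal sd (correlated if nk not NULL).
draw_noise <- function(n, nk) {
  xi <- stats::rnorm(n)
  if (is.null(nk)) return(xi)
  Re(stats::fft(stats::fft(xi) * nk$Kf, inverse = TRUE)) / n * nk$scale
}

#' Deterministic drift of the excitable network
#'
#' Evaluates the reaction--diffusion right-hand side of the activator and
#' inhibitor equations at a given state:
#' `dX = D_X lap(X) - a1 X - a2 (Y - R) X + a3 X^2 / (a4^2 + X^2) + a5` and
#' `dY = D_Y lap(Y) + epsilon (-Y + b1 X)`.
#'
#' @param state List with numeric vectors `X` and `Y` (length `n_points`)
#'   and scalar time `t`.
#' @param params An [excitable_params()] object.
#' @param R_now Stimulus vector (length `n_points`), or a scalar recycled to
#'   the grid.
#' @return List with rate vectors `dX` and `dY`.
#' @export
en_drift <- function(state, params, R_now = 0) {
  n <- params$n_points
  if (length(state$X) != n || length(state$Y) != n)
    stop("invalid input: state vectors must have length n_points")
  if (length(R_now) == 1) R_now <- rep(R_now, n)
  if (length(R_now) != n)
    stop("invalid input: R_now must be scalar or length n_points")
  X <- state$X; Y <- state$Y
  dX <- params$D_X * periodic_laplacian(X, params$dx) -
    params$a1 * X - params$a2 * (Y - R_now) * X +
    params$a3 * X^2 / (params$a4^2 + X^2) + params$a5
  dY <- params$D_Y * periodic_laplacian(Y, params$dx) +
    params$epsilon * (-Y + params$b1 * X)
  list(dX = dX, dY = dY)
}

#' Single Euler--Maruyama step of the excitable network
#'
#' Advances the state by one step `dt`: deterministic explicit-Euler update
#' of the drift plus, on the activator only, independent Gaussian increments
#' `sqrt(dt) * sigma_N * xi` per grid point.  Draws from the R random number
#' stream, so results are reproducible under `set.seed()`.
#'
#' @inheritParams en_drift
#' @return The advanced state (list with `X`, `Y`, `t`).
#' @export
em_step <- function(state, params, R_now = 0) {
  d <- en_drift(state, params, R_now)
  X <- state$X + params$dt * d$dX
  if (params$sigma_N > 0) {
    nk <- noise_kernel(params$n_points, params$noise_corr_len)
    X <- X + sqrt(params$dt) * params$sigma_N *
      draw_noise(params$n_points, nk)
  }
  Y <- state$Y + params$dt * d$dY
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("numerical instability: non-finite state after step at t = ",
         format(state$t + params$dt))
  list(X = X, Y = Y, t = state$t + params$dt)
}

#' Spatially uniform rest state of the excitable network
#'
#' Finds the stable resting fixed point of the deterministic, spatially
#' uniform reduction of the network (diffusion vanishes on uniform fields).
#' Setting the inhibitor drift to zero forces `Y* = b1 X*`; the activator
#' rest value is then the first down-crossing root of the scalar drift,
#' located by a dense-grid sign scan refined with `uniroot`.
#'
#' @param params An [excitable_params()] object.
#' @param R Spatially uniform stimulus held during the rest-state search
#'   (default 0).
#' @return Named numeric vector `c(X = X_rest, Y = Y_rest)`.
#' @export
find_rest_state <- function(params, R = 0) {
  g <- function(X) {
    -params$a1 * X - params$a2 * (params$b1 * X - R) * X +
      params$a3 * X^2 / (params$a4^2 + X^2) + params$a5
  }
  if (params$a5 == 0 && R <= 0) {
    # origin solves the drift and is stable (linear decay dominates)
    return(c(X = 0, Y = 0))
  }
  x_hi <- max((params$a3 + params$a5) / params$a1, 10 * params$a4, 10) * 2
  grid <- seq(0, x_hi, length.out = 100000L)
  gv <- g(grid)
  down <- which(gv[-length(gv)] > 0 & gv[-1] <= 0)
  if (length(down) == 0)
    stop("no rest state: scalar drift has no down-crossing in [0, ",
         format(x_hi), "]")
  i <- down[1]
  root <- stats::uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-14)$root
  c(X = root, Y = params$b1 * root)
}

#' Simulate the stochastic excitable network on the perimeter ring
#'
#' Integrates the coupled activator--inhibitor equations with the
#' Euler--Maruyama scheme at fixed step `params$dt`, recording the fields
#' every `sample_every` steps.  The spatial mean of the inhibitor is stored
#' at each sample; it is the drive passed downstream to the ERK switch.
#'
#' @param params An [excitable_params()] object.
#' @param duration Total simulated time (model time units).
#' @param protocol Optional [stimulus_protocol()] supplying the external
#'   input `R`.
#' @param sample_every Record every this many steps (>= 1).
#' @param seed Integer seed; required when `sigma_N > 0`.  The global RNG
#'   state is restored on exit.
#' @param init Optional initial state `list(X=, Y=)`; defaults to the rest
#'   state from [find_rest_state()].
#' @param kicks Optional data frame with columns `time`, `amplitude`,
#'   `center`, `width`: instantaneous additions of `amplitude` to the
#'   activator on a contiguous patch, applied when the simulation crosses
#'   `time`.  Used by the threshold and refractory probes.
#' @return An `en_trajectory`: list with `times` (model time), `times_min`
#'   (displayed minutes), matrices `X_kymo` and `Y_kymo` (samples x grid),
#'   `mean_Y`, `seed`, and a copy of `params`.
#' @export
simulate_en <- function(params, duration, protocol = NULL, sample_every = 10,
                        seed = NULL, init = NULL, kicks = NULL) {
  stopifnot(inherits(params, "excitable_params"))
  if (duration <= 0) stop("duration must be > 0")
  sample_every <- as.integer(sample_every)
  if (sample_every < 1) stop("sample_every must be >= 1")
  if (params$sigma_N > 0 && is.null(seed))
    stop("seed is required for stochastic runs (sigma_N > 0)")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }

  n <- params$n_points
  dt <- params$dt
  dx2 <- params$dx^2
  nsteps <- as.integer(round(duration / dt))
  ip <- c(2:n, 1L); im <- c(n, 1:(n - 1L))

  if (is.null(init)) {
    rest <- find_rest_state(params)
    X <- rep(rest[["X"]], n); Y <- rep(rest[["Y"]], n)
  } else {
    X <- rep_len(init$X, n); Y <- rep_len(init$Y, n)
  }

  # precompute stimulus per step as (profile id, profile matrix)
  prof_ids <- integer(nsteps)
  profiles <- list(numeric(n))
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "stimulus_protocol"))
    for (s in protocol$segments) {
      if (length(s$profile) != n)
        stop("invalid input: stimulus profile length must equal n_points")
    }
    t_steps <- (seq_len(nsteps) - 1L) * dt
    key <- integer(nsteps)
    for (k in seq_along(protocol$segments)) {
      s <- protocol$segments[[k]]
      inseg <- t_steps >= s$t_start & t_steps < s$t_end
      key[inseg] <- key[inseg] + 2L^(k - 1L)
    }
    for (u in sort(unique(key))) {
      if (u == 0L) next
      prof <- numeric(n)
      for (k in seq_along(protocol$segments))
        if (bitwAnd(u, 2L^(k - 1L)) > 0)
          prof <- prof + protocol$segments[[k]]$profile
      profiles[[length(profiles) + 1L]] <- prof
      prof_ids[key == u] <- length(profiles) - 1L
    }
  }

  kick_steps <- integer(0)
  if (!is.null(kicks)) {
    kick_steps <- as.integer(round(kicks$time / dt))
    kick_steps[kick_steps < 0L] <- 0L
  }

  nsamp <- nsteps %/% sample_every
  X_kymo <- matrix(NA_real_, nsamp + 1L, n)
  Y_kymo <- matrix(NA_real_, nsamp + 1L, n)
  X_kymo[1L, ] <- X; Y_kymo[1L, ] <- Y
  sq_sig <- sqrt(dt) * params$sigma_N
  nk <- if (sq_sig > 0) noise_kernel(n, params$noise_corr_len) else NULL
  a42 <- params$a4^2
  row <- 1L

  for (step in seq_len(nsteps)) {
    if (length(kick_steps) && any(kick_steps == step - 1L)) {
      for (j in which(kick_steps == step - 1L)) {
        w <- as.integer(kicks$width[j])
        idx <- ((as.integer(kicks$center[j]) - ceiling(w / 2)) +
                  seq_len(w) - 1L) %% n + 1L
        X[idx] <- X[idx] + kicks$amplitude[j]
      }
    }
    lapX <- (X[ip] - 2 * X + X[im]) / dx2
    lapY <- (Y[ip] - 2 * Y + Y[im]) / dx2
    pid <- prof_ids[step]
    Rv <- if (pid > 0L) profiles[[pid + 1L]] else 0
    dX <- params$D_X * lapX - params$a1 * X - params$a2 * (Y - Rv) * X +
      params$a3 * X^2 / (a42 + X^2) + params$a5
    dY <- params$D_Y * lapY + params$epsilon * (-Y + params$b1 * X)
    X <- X + dt * dX
    if (sq_sig > 0) X <- X + sq_sig * draw_noise(n, nk)
    Y <- Y + dt * dY
    if (step %% sample_every == 0L) {
      row <- row + 1L
      if (!all(is.finite(X)) || !all(is.finite(Y)) || max(abs(X)) > 1e6)
        stop("numerical instability: state diverged at step ", step,
             " (t = ", format(step * dt), ")")
      X_kymo[row, ] <- X
      Y_kymo[row, ] <- Y
    }
  }

  times <- (0:nsamp) * dt * sample_every
  structure(list(times = times,
                 times_min = times * params$time_scale,
                 X_kymo = X_kymo, Y_kymo = Y_kymo,
                 mean_Y = rowMeans(Y_kymo),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 params = params),
            class = "en_trajectory")
}

#' @export
print.en_trajectory <- function(x, ...) {
  cat("Excitable-network trajectory: ", nrow(x$X_kymo), " samples x ",
      ncol(x$X_kymo), " grid points, t in [0, ",
      format(max(x$times)), "] (", format(max(x$times_min)),
      " displayed min)\n", sep = "")
  invisible(x)
}

#' Probe the firing threshold of the excitable network
#'
#' Applies instantaneous activator perturbations of increasing amplitude to
#' a contiguous patch of the resting deterministic system (noise forced to
#' zero) and records the peak activator excursion (spatial maximum of
#' `X - X_rest`, searched after a short dead time so the decaying
#' perturbation itself is not scored).  An excitable system shows an
#' all-or-none response: a sharp jump separates subthreshold decay from
#' full firings whose peaks, set by the excited branch of the fast
#' activator dynamics, are nearly amplitude-independent.  The spatial
#' maximum rather than the spatial mean is scored because the local firing
#' amplitude is the all-or-none quantity; the spatial mean also scales
#' with the width of the fired patch.
#'
#' @param params An [excitable_params()] object (`sigma_N` ignored).
#' @param amplitudes Increasing perturbation amplitudes to scan.
#' @param patch_width Width of the perturbed patch in grid points.
#' @param t_max Simulated time after the perturbation.
#' @param dead_time Interval after the kick excluded from the peak search,
#'   so the instantaneous perturbation itself (which decays within about
#'   one activator time constant) is not scored as a response.
#' @return A list of class `threshold_probe`: `curve` (data frame of
#'   amplitude and peak mean-activator excursion), `threshold` (midpoint of
#'   the bracketing pair, or `NA`), and `excitable` (logical diagnostic;
#'   `FALSE` means no all-or-none jump was found over the scanned range).
#' @export
threshold_probe <- function(params, amplitudes, patch_width = 20,
                            t_max = 40, dead_time = 1.5) {
  det <- do.call(excitable_params,
                 utils::modifyList(unclass(params), list(sigma_N = 0)))
  rest <- find_rest_state(det)
  peaks <- vapply(amplitudes, function(a) {
    if (a == 0) return(0)
    tr <- simulate_en(det, duration = t_max, sample_every = 5L,
                      kicks = data.frame(time = 0, amplitude = a,
                                         center = det$n_points %/% 2L,
                                         width = patch_width))
    max(tr$X_kymo[tr$times >= dead_time, ]) - rest[["X"]]
  }, numeric(1))
  curve <- data.frame(amplitude = amplitudes, peak_excursion = peaks)
  curve <- curve[order(curve$amplitude), ]
  pos <- curve[curve$amplitude > 0, ]
  ratio <- pos$peak_excursion[-1] / pmax(pos$peak_excursion[-nrow(pos)],
                                         .Machine$double.eps)
  jump <- which.max(ratio)
  excitable <- length(ratio) > 0 && max(ratio) >= 5
  thr <- if (excitable)
    mean(pos$amplitude[c(jump, jump + 1)]) else NA_real_
  structure(list(curve = curve, threshold = thr, excitable = excitable,
                 patch_width = patch_width),
            class = "threshold_probe")
}

#' Refractory period of the excitable network
#'
#' Fires the resting deterministic system with a suprathreshold patch
#' perturbation, repeats the identical perturbation after each candidate
#' gap, and compares the second response with the first.  Because the
#' excursions are plateau-like, the second response is isolated by
#' subtracting a reference run that received only the first kick; its peak
#' is then compared with the first-response peak of the reference run.
#' The refractory period is the smallest tested gap at which the second
#' response recovers to at least 80% of the first.
#'
#' @param params An [excitable_params()] object (noise forced to zero).
#' @param probe_amplitude Suprathreshold perturbation amplitude.
#' @param gaps Increasing candidate gaps (model time units).
#' @param patch_width Width of the perturbed patch.
#' @param settle Time allowed for the second response to develop.
#' @param dead_time Interval after each kick excluded from peak scoring.
#' @return List of class `refractory_scan`: `period` (smallest recovered
#'   gap, or `Inf` with all gaps refractory), `scan` (data frame of gap and
#'   recovery ratio).
#' @export
refractory_period <- function(params, probe_amplitude, gaps,
                              patch_width = 20, settle = 30,
                              dead_time = 1.5) {
  det <- do.call(excitable_params,
                 utils::modifyList(unclass(params), list(sigma_N = 0)))
  rest <- find_rest_state(det)
  t1 <- 1
  gaps <- sort(gaps)
  dur <- t1 + max(gaps) + settle
  ref <- simulate_en(det, duration = dur, sample_every = 5L,
                     kicks = data.frame(time = t1,
                                        amplitude = probe_amplitude,
                                        center = det$n_points %/% 2L,
                                        width = patch_width))
  mref <- rowMeans(ref$X_kymo)
  peak1 <- max(mref[ref$times >= t1 + dead_time]) - rest[["X"]]
  ratios <- vapply(gaps, function(g) {
    kk <- data.frame(time = c(t1, t1 + g),
                     amplitude = probe_amplitude,
                     center = det$n_points %/% 2L, width = patch_width)
    tr <- simulate_en(det, duration = t1 + g + settle, sample_every = 5L,
                      kicks = kk)
    mx <- rowMeans(tr$X_kymo)
    extra <- mx - mref[seq_along(mx)]
    win <- tr$times >= t1 + g + dead_time
    max(extra[win]) / peak1
  }, numeric(1))
  scan <- data.frame(gap = sort(gaps), ratio = ratios)
  ok <- which(!is.na(scan$ratio) & scan$ratio >= 0.8)
  period <- if (length(ok)) scan$gap[min(ok)] else Inf
  structure(list(period = period, scan = scan,
                 probe_amplitude = probe_amplitude),
            class = "refractory_scan")
}
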