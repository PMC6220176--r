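#' Parameters of the zero-order ultrasensitive ERK switch
#'
#' The active-ERK state `Z` evolves as
#' `dZ/dt = c1 * ( U_E (c2 - Z) / (c3 + (c2 - Z)) - c4 Z / (c3 + Z) - c5 Z )`,
#' a Goldbeter--Koshland covalent-modification cycle driven by the input
#' `U_E` with an extra linear loss (`c5`) that sharpens the decay of the
#' state after the drive is withdrawn.  When the shared Michaelis constant
#' `c3` is small relative to the convertible pool `c2`, both converting
#' reactions run near saturation and the steady-state response to `U_E`
#' becomes switch-like (zero-order ultrasensitivity).  The module is global:
#' there is no spatial diffusion of `Z`.
#'
#' @param c1 Overall rate scale (1/time).
#' @param c2 Total convertible ERK pool (conc).
#' @param c3 Shared Michaelis constant (conc).
#' @param c4 Maximal deactivation drive (conc/time-equivalent).
#' @param c5 Linear decay gain (1/conc-time-equivalent).
#' @return An object of class `erk_params`.
#' @export
erk_params <- function(c1 = 30, c2 = 1, c3 = 0.01, c4 = 0.3, c5 = 0.05) {
  p <- list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("all erk_params fields must be finite scalars")
  if (p$c1 <= 0 || p$c2 <= 0 || p$c3 <= 0)
    stop("c1, c2, c3 must be > 0")
  if (p$c4 < 0 || p$c5 < 0) stop("c4 and c5 must be >= 0")
  structure(p, class = "erk_params")
}

#' Right-hand side of the ERK switch equation
#'
#' @param Z Active-ERK level (conc); may be a vector.
#' @param U_E Activation drive (conc); scalar or vector matching `Z`.
#' @param params An [erk_params()] object.
#' @return The rate `dZ/dt`.
#' @export
erk_rhs <- function(Z, U_E, params) {
  if (any(!is.finite(Z)) || any(!is.finite(U_E)))
    stop("invalid input: Z and U_E must be finite")
  params$c1 * (U_E * (params$c2 - Z) / (params$c3 + (params$c2 - Z)) -
                 params$c4 * Z / (params$c3 + Z) -
                 params$c5 * Z)
}

#' Steady state of the ERK switch under constant drive
#'
#' Unique root of [erk_rhs()] in `[0, c2]`, found by bracketed bisection
#' (`uniroot`) to 1e-10 absolute tolerance.  The activation term decreases
#' and both loss terms increase in `Z` on the bracket, so the root is
#' unique.
#'
#' @param U_E Constant non-negative drive.
#' @param params An [erk_params()] object.
#' @return Scalar steady state `Z*` in `[0, c2]`.
#' @export
erk_steady_state <- function(U_E, params) {
  if (!is.finite(U_E) || U_E < 0) stop("U_E must be finite and >= 0")
  if (U_E == 0) return(0)
  f0 <- erk_rhs(0, U_E, params)
  f1 <- erk_rhs(params$c2, U_E, params)
  if (f0 == 0) return(0)
  if (f1 >= 0) return(params$c2)
  if (f0 < 0)
    stop("no steady state: rhs has no sign change on [0, c2]")
  stats::uniroot(function(z) erk_rhs(z, U_E, params), c(0, params$c2),
                 tol = 1e-12)$root
}

#' Steepness of the ERK dose--response curve
#'
#' Computes the steady-state response `Z*(U_E)` over a log-spaced drive grid
#' and returns the ratio `EC90 / EC10`, i.e. the fold-increase in drive
#' needed to go from 10% to 90% of the saturating response.  A Michaelian
#' (first-order) cycle gives 81; zero-order operation (`c3 << c2`) pushes
#' the ratio far below that.
#'
#' @param params An [erk_params()] object with `c4 > 0`.
#' @param U_range Drive range scanned, as multiples of `c4` (log-spaced).
#' @return Scalar ratio EC90/EC10, or `NA` (with a warning) if the response
#'   does not span 10--90% of its asymptote over the scanned range.
#' @export
ultrasensitivity_ratio <- function(params, U_range = c(1e-4, 1e4)) {
  if (params$c4 <= 0)
    stop("c4 must be > 0: without deactivation there is no sigmoid")
  z_top <- erk_steady_state(U_range[2] * params$c4 * 100, params)
  ec <- function(frac) {
    target <- frac * z_top
    f <- function(logu) erk_steady_state(exp(logu), params) - target
    lo <- log(U_range[1] * params$c4); hi <- log(U_range[2] * params$c4)
    if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
    exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }
  ec10 <- ec(0.1); ec90 <- ec(0.9)
  if (is.na(ec10) || is.na(ec90)) {
    warning("response does not span 10-90% of its asymptote over U_range")
    return(NA_real_)
  }
  ec90 / ec10
}

#' Integrate the ERK switch along a sampled drive
#'
#' Classical fixed-step fourth-order Runge--Kutta integration of the switch
#' equation, with the drive held piecewise-constant between its samples.
#' `dt_erk` substeps are taken inside each drive interval.  An accuracy
#' guard integrates the trajectory again at half the step and warns if the
#' median pointwise change exceeds 1e-3 of the pool `c2`.
#'
#' @param U_E Numeric vector of drive samples (>= 0), uniformly spaced.
#' @param times Sample times of the drive (uniform spacing), or `NULL` to
#'   use `dt_sample`.
#' @param params An [erk_params()] object.
#' @param Z0 Initial condition in `[0, c2]`.
#' @param dt_erk Integration substep; defaults to the drive sample interval.
#' @param dt_sample Drive sample interval when `times` is `NULL`.
#' @param check_accuracy Run the step-halving guard (default `TRUE`).
#' @return An `erk_trace`: list with `times`, `Z`, `Z_norm` (`Z/c2`), `U_E`,
#'   and `params`.
#' @export
simulate_erk <- function(U_E, times = NULL, params = erk_params(), Z0 = 0,
                         dt_erk = NULL, dt_sample = NULL,
                         check_accuracy = TRUE) {
  if (any(!is.finite(U_E)) || any(U_E < 0))
    stop("U_E must be finite and >= 0")
  if (Z0 < 0 || Z0 > params$c2) stop("Z0 must lie in [0, c2]")
  m <- length(U_E)
  if (is.null(times)) {
    if (is.null(dt_sample)) stop("supply times or dt_sample")
    times <- (seq_len(m) - 1) * dt_sample
  }
  if (length(times) != m) stop("times and U_E lengths differ")
  h_samp <- diff(times)
  if (m > 1 && (max(h_samp) - min(h_samp)) > 1e-9 * max(h_samp))
    stop("drive must be uniformly sampled")
  h_samp <- if (m > 1) h_samp[1] else stop("need at least 2 drive samples")
  if (is.null(dt_erk)) dt_erk <- h_samp
  nsub <- max(1L, as.integer(ceiling(h_samp / dt_erk - 1e-12)))

  integrate_once <- function(nsub) {
    h <- h_samp / nsub
    Z <- numeric(m); Z[1] <- Z0
    z <- Z0
    for (k in seq_len(m - 1)) {
      u <- U_E[k]  # piecewise-constant drive on [t_k, t_{k+1})
      for (s in seq_len(nsub)) {
        k1 <- erk_rhs(z, u, params)
        k2 <- erk_rhs(z + h / 2 * k1, u, params)
        k3 <- erk_rhs(z + h / 2 * k2, u, params)
        k4 <- erk_rhs(z + h * k3, u, params)
        z <- z + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        # [0, c2] is invariant for the exact flow; clip the integrator's
        # micro-overshoot so it cannot cross the pole at Z = c2 + c3
        z <- min(max(z, 0), params$c2)
      }
      Z[k + 1] <- z
    }
    Z
  }

  Z <- integrate_once(nsub)
  if (check_accuracy && m > 1) {
    Z2 <- integrate_once(2L * nsub)
    # median deviation in units of the pool: a too-coarse step shifts the
    # whole trajectory, whereas isolated flip-timing jitter (extreme
    # sensitivity when the drive sits exactly at the switch point) only
    # perturbs a few samples
    rel <- stats::median(abs(Z - Z2)) / params$c2
    if (rel > 1e-3)
      warning("dt_erk too coarse: step-halving change ", format(rel),
              " exceeds 1e-3; reduce dt_erk")
  }
  structure(list(times = times, Z = Z, Z_norm = Z / params$c2, U_E = U_E,
                 params = params),
            class = "erk_trace")
}

#' @export
print.erk_trace <- function(x, ...) {
  cat("ERK trace: ", length(x$times), " samples, Z in [",
      format(min(x$Z), digits = 4), ", ", format(max(x$Z), digits = 4),
      "] of pool c2 = ", x$params$c2, "\n", sep = "")
  invisible(x)
}

#' Couple an excitable-network trajectory to the ERK switch
#'
#' Drives the ERK switch with the spatial mean of the inhibitor recorded in
#' the trajectory, `U_E(t) = mean_Y(t)`.  Transient negative excursions of
#' the drive are floored at zero (the switch equation presumes a
#' non-negative activation drive); the number of floored samples is
#' reported via a message when nonzero.
#'
#' @param traj An `en_trajectory` from [simulate_en()].
#' @param params An [erk_params()] object.
#' @param Z0 Initial active-ERK level; defaults to the steady state under
#'   the initial drive.
#' @param dt_erk Integration substep, forwarded to [simulate_erk()];
#'   defaults to the smaller of the trajectory sample interval and
#'   `0.05 / c1`, so the switch dynamics are resolved even when the
#'   trajectory is sampled coarsely.
#' @return An `erk_trace` whose `U_E` is the drive actually used.
#' @export
couple_en_to_erk <- function(traj, params = erk_params(), Z0 = NULL,
                             dt_erk = NULL) {
  stopifnot(inherits(traj, "en_trajectory"))
  if (length(traj$mean_Y) < 2) stop("invalid input: empty trajectory")
  drive <- traj$mean_Y
  n_floored <- sum(drive < 0)
  if (n_floored > 0) {
    message("couple_en_to_erk: floored ", n_floored,
            " negative drive samples at 0")
    drive[drive < 0] <- 0
  }
  if (is.null(Z0)) Z0 <- erk_steady_state(drive[1], params)
  if (is.null(dt_erk))
    dt_erk <- min(diff(traj$times[1:2]), 0.05 / params$c1)
  simulate_erk(drive, times = traj$times, params = params, Z0 = Z0,
               dt_erk = dt_erk)
}
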