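#' Uniformly sampled activity trace
#'
#' @param times Strictly increasing, uniformly spaced times in minutes.
#' @param values Finite numeric values (ratio or intensity).
#' @param label Optional label.
#' @return An object of class `activity_trace`.
#' @export
activity_trace <- function(times, values, label = "") {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (length(times) >= 2) {
    dtv <- diff(times)
    if (any(dtv <= 0)) stop("times must be strictly increasing")
    if ((max(dtv) - min(dtv)) > 1e-9 * max(dtv))
      stop("invalid input: non-uniform sampling")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  structure(list(times = times, values = values, label = label),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat("Trace", if (nzchar(x$label)) paste0(" [", x$label, "]"), ": ",
      length(x$times), " samples, ",
      format(x$times[1]), "-", format(x$times[length(x$times)]),
      " min\n", sep = "")
  invisible(x)
}

# mean of a frame over a logical mask, with frame-naming errors
masked_mean <- function(arr, mask, k, what) {
  m <- mask[, , k]
  if (!any(m)) stop("invalid mask: empty ", what, " mask in frame ", k)
  mean(arr[, , k][m])
}

# accept either a cell_mask or a raw logical array
mask_array <- function(m) {
  if (inherits(m, "cell_mask")) m$mask else m
}

#' Cytoplasmic-to-nuclear ratio of a translocation reporter
#'
#' Per frame, the mean reporter intensity over the cytoplasmic mask
#' divided by the mean over the nuclear mask.  When a volume-marker stack
#' is supplied the reporter ratio is divided by the same ratio computed on
#' the volume channel, cancelling shape-driven apparent redistribution.
#'
#' @param reporter An [image_stack()] of the translocation reporter.
#' @param nuc_mask,cyto_mask Logical `H x W x T` arrays (disjoint,
#'   non-empty per frame).
#' @param volume Optional volume-marker [image_stack()].
#' @return An [activity_trace()] of the (normalized) C/N ratio.
#' @export
cn_ratio <- function(reporter, nuc_mask, cyto_mask, volume = NULL) {
  stopifnot(inherits(reporter, "image_stack"))
  nuc_mask <- mask_array(nuc_mask); cyto_mask <- mask_array(cyto_mask)
  tt <- dim(reporter$data)[3]
  vals <- vapply(seq_len(tt), function(k) {
    r <- masked_mean(reporter$data, cyto_mask, k, "cytoplasmic") /
      masked_mean(reporter$data, nuc_mask, k, "nuclear")
    if (!is.null(volume)) {
      rv <- masked_mean(volume$data, cyto_mask, k, "cytoplasmic") /
        masked_mean(volume$data, nuc_mask, k, "nuclear")
      r <- r / rv
    }
    r
  }, numeric(1))
  activity_trace((seq_len(tt) - 1) * reporter$frame_interval, vals,
                 label = "C/N ratio")
}

#' FRET ratio trace (acceptor over donor)
#'
#' Per frame, mean YFP intensity over the cell mask divided by mean CFP
#' intensity, the standard proxy for FRET efficiency of a ratiometric
#' reporter.
#'
#' @param yfp,cfp Frame-aligned [image_stack()]s.
#' @param mask A [segment_cell()] result or logical array.
#' @return An [activity_trace()].
#' @export
fret_ratio <- function(yfp, cfp, mask) {
  stopifnot(inherits(yfp, "image_stack"), inherits(cfp, "image_stack"))
  if (!identical(dim(yfp$data), dim(cfp$data)))
    stop("invalid input: YFP and CFP stacks differ in shape")
  mask <- mask_array(mask)
  tt <- dim(yfp$data)[3]
  vals <- vapply(seq_len(tt), function(k) {
    dn <- masked_mean(cfp$data, mask, k, "cell")
    if (dn == 0) stop("invalid input: zero CFP mean in frame ", k)
    masked_mean(yfp$data, mask, k, "cell") / dn
  }, numeric(1))
  activity_trace((seq_len(tt) - 1) * yfp$frame_interval, vals,
                 label = "FRET ratio")
}

#' Normalize a biosensor stack to a membrane marker
#'
#' Pixelwise `biosensor / marker` wherever the marker is at or above
#' `floor`; pixels below the floor are masked (`NA`), never divided.
#'
#' @param biosensor,membrane_marker Aligned [image_stack()]s.
#' @param floor Marker intensity floor.
#' @return An [image_stack()]-shaped object whose data may contain `NA`
#'   at masked pixels.
#' @export
membrane_normalize <- function(biosensor, membrane_marker, floor) {
  if (!identical(dim(biosensor$data), dim(membrane_marker$data)))
    stop("invalid input: stacks differ in shape")
  out <- biosensor$data / membrane_marker$data
  out[membrane_marker$data < floor] <- NA_real_
  structure(list(data = out, frame_interval = biosensor$frame_interval,
                 pixel_size = biosensor$pixel_size,
                 channel = paste0(biosensor$channel, "/",
                                  membrane_marker$channel)),
            class = "image_stack")
}

# indices of local minima/maxima of v (plateaus collapse to their first
# point); returns list(min = ..., max = ...)
local_extrema <- function(v) {
  n <- length(v)
  s <- sign(diff(v))
  # carry the last nonzero slope through plateaus
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  mins <- integer(0); maxs <- integer(0)
  if (all(s == 0)) return(list(min = mins, max = maxs))  # constant trace
  if (n >= 2) {
    if (s[which(s != 0)[1]] > 0) mins <- 1L else maxs <- 1L
    for (i in seq_len(length(s) - 1)) {
      if (s[i] > 0 && s[i + 1] < 0) maxs <- c(maxs, i + 1L)
      if (s[i] < 0 && s[i + 1] > 0) mins <- c(mins, i + 1L)
    }
    if (s[length(s)] > 0) maxs <- c(maxs, n) else mins <- c(mins, n)
  }
  list(min = mins, max = maxs)
}

#' Call pulses in an activity trace
#'
#' After optional moving-average smoothing, local minima define candidate
#' baselines and subsequent local maxima define peaks; a pulse is emitted
#' when the fractional increase `(peak - baseline) / baseline` exceeds
#' `min_fractional_increase` (default 0.20, the 20% rule).  Peaks that
#' share a baseline minimum (overlapping rises) are merged into a single
#' event flagged `fused`, keeping the higher peak (ties resolved toward
#' the earlier peak).  Deterministic.
#'
#' @param trace An [activity_trace()] with at least 5 samples.
#' @param min_fractional_increase Calling threshold (default 0.20).
#' @param smoothing_window Moving-average window in frames (default 3;
#'   `1` disables smoothing).
#' @return Data frame of pulses: `onset_time`, `peak_time`, `baseline`,
#'   `peak`, `fractional_increase`, `fused`.
#' @export
detect_pulses <- function(trace, min_fractional_increase = 0.20,
                          smoothing_window = 3) {
  stopifnot(inherits(trace, "activity_trace"))
  v <- trace$values
  if (length(v) < 5) stop("trace too short (need >= 5 samples)")
  w <- as.integer(smoothing_window)
  if (w > 1) {
    v <- stats::filter(v, rep(1 / w, w), sides = 2)
    v <- as.numeric(v)
    # shrink the ends instead of dropping them
    for (i in which(is.na(v))) {
      lo <- max(1, i - w %/% 2); hi <- min(length(v), i + w %/% 2)
      v[i] <- mean(trace$values[lo:hi])
    }
  }
  ex <- local_extrema(v)
  if (length(ex$max) == 0 || length(ex$min) == 0) return(empty_pulses())

  # alternating extrema sequence; merge insignificant internal dips:
  # a local min whose rise to the following peak stays at or below the
  # calling threshold does not separate two events -- the two rises are
  # fused into one (the higher peak wins, ties toward the earlier peak)
  idx <- sort(c(ex$min, ex$max))
  is_max <- idx %in% ex$max
  fused_flag <- rep(FALSE, length(idx))
  repeat {
    merged <- FALSE
    internal <- which(!is_max)
    internal <- internal[internal > 1 & internal < length(idx)]
    for (j in internal) {
      if (!is_max[j - 1] || !is_max[j + 1]) next
      dipv <- v[idx[j]]
      rise <- (min(v[idx[j - 1]], v[idx[j + 1]]) - dipv) / dipv
      if (rise <= min_fractional_increase) {
        drop_max <- if (v[idx[j + 1]] > v[idx[j - 1]]) j - 1 else j + 1
        keep_max <- if (drop_max == j - 1) j + 1 else j - 1
        fused_flag[keep_max] <- TRUE
        idx <- idx[-c(j, drop_max)]
        fused_flag <- fused_flag[-c(j, drop_max)]
        is_max <- is_max[-c(j, drop_max)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }

  out <- list()
  for (j in which(is_max)) {
    if (j == 1) next
    b <- idx[j - 1]; pk <- idx[j]
    frac <- (v[pk] - v[b]) / v[b]
    if (frac <= min_fractional_increase) next
    out[[length(out) + 1]] <- data.frame(
      onset_time = trace$times[b], peak_time = trace$times[pk],
      baseline = v[b], peak = v[pk], fractional_increase = frac,
      fused = fused_flag[j], onset_idx = b, peak_idx = pk)
  }
  if (length(out) == 0) return(empty_pulses())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "smoothed_values") <- v
  res
}

empty_pulses <- function() {
  data.frame(onset_time = numeric(0), peak_time = numeric(0),
             baseline = numeric(0), peak = numeric(0),
             fractional_increase = numeric(0), fused = logical(0),
             onset_idx = integer(0), peak_idx = integer(0))
}

#' Cross-correlation between two traces over integer-frame lags
#'
#' Pearson correlation of the overlapping segments of `a` and `b` after
#' shifting `b` by each lag in `[-max_lag, +max_lag]`.  Positive `best_lag`
#' means `b` follows (lags behind) `a`.  Lags with zero-variance overlap
#' are flagged `NA` and excluded from the argmax; ties are broken toward
#' the smallest absolute lag, then toward the negative lag.
#'
#' @param a,b [activity_trace()]s on identical sampling grids.
#' @param max_lag Maximum lag in minutes (< half the trace duration).
#' @return A `correlogram`: data frame attrs with `lags` (minutes),
#'   `coefficients`, plus `best_lag` and `best_r` fields.
#' @export
cross_correlation <- function(a, b, max_lag) {
  stopifnot(inherits(a, "activity_trace"), inherits(b, "activity_trace"))
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9)
    stop("invalid input: traces must share one sampling grid")
  n <- length(a$values)
  dt <- a$times[2] - a$times[1]
  if (max_lag >= (a$times[n] - a$times[1]) / 2)
    stop("max_lag must be below half the trace duration")
  L <- as.integer(floor(max_lag / dt + 1e-9))
  lags <- (-L):L
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      x <- a$values[1:(n - l)]; y <- b$values[(1 + l):n]
    } else {
      x <- a$values[(1 - l):n]; y <- b$values[1:(n + l)]
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  ok <- which(!is.na(r))
  if (length(ok) == 0) stop("all lags have zero-variance overlap")
  best <- ok[order(-r[ok], abs(lags[ok]), lags[ok])][1]
  structure(list(lags = lags * dt, coefficients = r,
                 best_lag = lags[best] * dt, best_r = r[best]),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("Correlogram over lags [", min(x$lags), ", ", max(x$lags),
      "] min: best lag ", x$best_lag, " min (r = ",
      signif(x$best_r, 3), ")\n", sep = "")
  invisible(x)
}

# first rising-edge crossing of the half-maximum level of one pulse,
# linearly interpolated between samples
t_half_pulse <- function(times, values, onset_idx, peak_idx,
                         baseline, peak) {
  target <- baseline + 0.5 * (peak - baseline)
  for (i in seq(onset_idx + 1L, peak_idx)) {
    if (values[i - 1] < target && values[i] >= target) {
      f <- (target - values[i - 1]) / (values[i] - values[i - 1])
      return(times[i - 1] + f * (times[i] - times[i - 1]))
    }
  }
  NA_real_
}

#' Half-maximum lag between paired protrusion and ERK pulses
#'
#' Calls pulses in both traces, pairs each ERK pulse with the nearest
#' preceding protrusion peak within `pairing_window` minutes, and for each
#' pair reports the lag between the half-maximal rising-edge crossings
#' (linearly interpolated).  Positive lags mean the ERK pulse trails the
#' protrusion.
#'
#' @param protrusion,erk [activity_trace()]s on one grid.
#' @param pairing_window Maximum peak-to-peak separation for pairing
#'   (minutes).
#' @param ... Passed to [detect_pulses()] (thresholds, smoothing).
#' @return List with `lags` (per pair), `mean`, `sem`, `n`, and the
#'   number of `unmatched` ERK pulses.
#' @export
half_max_lag <- function(protrusion, erk, pairing_window = 15, ...) {
  pp <- detect_pulses(protrusion, ...)
  pe <- detect_pulses(erk, ...)
  if (nrow(pp) == 0 || nrow(pe) == 0)
    return(list(lags = numeric(0), mean = NA_real_, sem = NA_real_,
                n = 0L, unmatched = nrow(pe),
                diagnostic = "no pulse pairs found"))
  vs_p <- attr(pp, "smoothed_values"); vs_e <- attr(pe, "smoothed_values")
  lags <- numeric(0); unmatched <- 0L
  for (i in seq_len(nrow(pe))) {
    dtp <- pe$peak_time[i] - pp$peak_time
    cand <- which(dtp >= 0 & dtp <= pairing_window)
    if (length(cand) == 0) { unmatched <- unmatched + 1L; next }
    j <- cand[which.min(dtp[cand])]
    th_e <- t_half_pulse(erk$times, vs_e, pe$onset_idx[i], pe$peak_idx[i],
                         pe$baseline[i], pe$peak[i])
    th_p <- t_half_pulse(protrusion$times, vs_p, pp$onset_idx[j],
                         pp$peak_idx[j], pp$baseline[j], pp$peak[j])
    if (is.na(th_e) || is.na(th_p)) { unmatched <- unmatched + 1L; next }
    lags <- c(lags, th_e - th_p)
  }
  n <- length(lags)
  list(lags = lags, mean = if (n) mean(lags) else NA_real_,
       sem = if (n > 1) stats::sd(lags) / sqrt(n) else NA_real_,
       n = n, unmatched = unmatched)
}

#' Correlation between ERK pulse magnitude and protrusion magnitude
#'
#' @param erk_events Pulse data frame from [detect_pulses()].
#' @param protrusion_magnitudes Numeric vector paired with the rows of
#'   `erk_events`.
#' @return Pearson correlation coefficient.
#' @export
pulse_magnitude_correlation <- function(erk_events, protrusion_magnitudes) {
  if (nrow(erk_events) != length(protrusion_magnitudes))
    stop("events and magnitudes must be paired one-to-one")
  if (nrow(erk_events) < 3)
    stop("insufficient data: need at least 3 pairs")
  stats::cor(erk_events$fractional_increase, protrusion_magnitudes)
}
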