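#' Time-lapse image stack
#'
#' Container for a single-channel time-lapse movie.  Frames are stored as
#' an `H x W x T` numeric array (rows, columns, time); pixel coordinates
#' are 1-based with the origin at the top-left, rows increasing downward.
#'
#' @param data Numeric `H x W x T` array of non-negative intensities
#'   (arbitrary units), `T >= 2`.
#' @param frame_interval Minutes per frame (> 0).
#' @param pixel_size Optional physical size of a pixel.
#' @param channel Optional channel label.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, frame_interval, pixel_size = NULL,
                        channel = "") {
  if (length(dim(data)) != 3) stop("data must be an H x W x T array")
  if (dim(data)[3] < 2) stop("stack needs at least 2 frames")
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(data = data, frame_interval = frame_interval,
                 pixel_size = pixel_size, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("Image stack", if (nzchar(x$channel)) paste0(" [", x$channel, "]"),
      ": ", d[1], " x ", d[2], " px, ", d[3], " frames @ ",
      x$frame_interval, " min\n", sep = "")
  invisible(x)
}

#' Sliding-window temporal average of a stack
#'
#' Averages `window` consecutive frames to suppress rapid cell-boundary
#' undulations before frame differencing.  Output has `T - window + 1`
#' frames; each averaged frame keeps the timestamp of the window start.
#'
#' @param stack An [image_stack()].
#' @param window Frames to average (the frame-difference pipeline uses
#'   2--4; `1` is the identity).
#' @return An [image_stack()] of averaged frames.
#' @export
temporal_average <- function(stack, window = 3) {
  stopifnot(inherits(stack, "image_stack"))
  window <- as.integer(window)
  d <- dim(stack$data)
  if (window < 1) stop("window must be >= 1")
  if (window > d[3]) stop("invalid input: window exceeds stack length")
  if (window == 1) return(stack)
  tt <- d[3] - window + 1L
  out <- array(0, c(d[1], d[2], tt))
  # cumulative sum along time keeps this O(H W T)
  acc <- array(0, c(d[1], d[2]))
  cs <- array(0, c(d[1], d[2], d[3] + 1L))
  for (k in seq_len(d[3])) {
    acc <- acc + stack$data[, , k]
    cs[, , k + 1L] <- acc
  }
  for (k in seq_len(tt))
    out[, , k] <- (cs[, , k + window] - cs[, , k]) / window
  image_stack(out, stack$frame_interval, stack$pixel_size, stack$channel)
}

#' Frame-difference percent-change stack
#'
#' The frame difference method (FDM): for every pixel, the percent change
#' between two temporal-average windows separated by `interval_minutes`,
#' `pct = 100 * (mean_later - mean_earlier) / mean_earlier`.  A value of
#' +100 therefore marks a twofold intensity increase over the interval.
#' Pixels whose earlier-window mean falls below `intensity_floor` are
#' masked (`NA`), never silently zeroed, so background percentages stay
#' bounded.
#'
#' Frame `i` of the result compares the earlier window starting at stack
#' frame `i` with the later window starting at `i + span`; its timestamp
#' is the midpoint between the two window centers.
#'
#' @param stack An [image_stack()].
#' @param interval_minutes Separation between the two windows; must be a
#'   whole multiple of the frame interval and at least `avg_window` frames
#'   (so the windows do not overlap).
#' @param avg_window Frames averaged per window (2--4 in practice;
#'   default 3).
#' @param intensity_floor Denominator floor; default 1% of the stack
#'   maximum.
#' @return An object of class `fdm_stack` with fields `pct` (H x W x T'
#'   array, `NA` where masked), `times` (minutes, midpoint convention),
#'   `span_frames`, `avg_window`, `floor_used`, `frame_interval`.
#' @export
frame_difference_pct <- function(stack, interval_minutes = 6,
                                 avg_window = 3, intensity_floor = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  k_real <- interval_minutes / stack$frame_interval
  k <- as.integer(round(k_real))
  if (abs(k_real - k) > 1e-9 || k < 1)
    stop("invalid input: interval_minutes must be a whole multiple of the ",
         "frame interval")
  avg_window <- as.integer(avg_window)
  if (k < avg_window)
    stop("invalid input: windows overlap (interval shorter than avg_window)")
  if (is.null(intensity_floor)) intensity_floor <- 0.01 * max(stack$data)
  avgd <- temporal_average(stack, avg_window)
  ta <- dim(avgd$data)[3]
  tt <- ta - k
  if (tt < 1) stop("invalid input: stack too short for this interval")
  d <- dim(stack$data)
  pct <- array(NA_real_, c(d[1], d[2], tt))
  for (i in seq_len(tt)) {
    earlier <- avgd$data[, , i]
    later <- avgd$data[, , i + k]
    p <- 100 * (later - earlier) / earlier
    p[earlier < intensity_floor] <- NA_real_
    pct[, , i] <- p
  }
  times <- (seq_len(tt) - 1 + (avg_window - 1) / 2 + k / 2) *
    stack$frame_interval
  structure(list(pct = pct, times = times, span_frames = k,
                 avg_window = avg_window, floor_used = intensity_floor,
                 interval_minutes = interval_minutes,
                 frame_interval = stack$frame_interval),
            class = "fdm_stack")
}

#' @export
print.fdm_stack <- function(x, ...) {
  d <- dim(x$pct)
  cat("FDM stack: ", d[1], " x ", d[2], " px, ", d[3], " frames, ",
      x$interval_minutes, "-min interval, window ", x$avg_window,
      ", floor ", signif(x$floor_used, 3), "\n", sep = "")
  invisible(x)
}

# map an fdm frame index to the stack frame used for mask alignment
# (the later-window start, i.e. the moment the change has occurred)
fdm_mask_frame <- function(fdm, i) i + fdm$span_frames

#' Segment the cell in every frame
#'
#' Automatic single-cell segmentation: per frame, an Otsu threshold on the
#' normalized intensities, the largest connected foreground component,
#' hole filling, and an ordered boundary contour.  Deterministic.
#'
#' @param stack An [image_stack()] in which the cell is brighter than the
#'   background.
#' @return An object of class `cell_mask`: `mask` (H x W x T logical),
#'   `boundary` (per-frame matrix of boundary points, columns `row`,
#'   `col`, ordered along the contour), `centroid` (T x 2 matrix).
#' @export
segment_cell <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  mask <- array(FALSE, d)
  boundary <- vector("list", d[3])
  centroid <- matrix(NA_real_, d[3], 2,
                     dimnames = list(NULL, c("row", "col")))
  for (k in seq_len(d[3])) {
    fr <- stack$data[, , k]
    rng <- range(fr)
    if (rng[2] <= rng[1])
      stop("segmentation failure: frame ", k, " has no contrast")
    fn <- (fr - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(fn)
    m <- fn > th
    lab <- EBImage::bwlabel(m)
    if (max(lab) == 0)
      stop("segmentation failure: empty foreground in frame ", k)
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
    m <- EBImage::fillHull(m) > 0
    mask[, , k] <- m
    oc <- EBImage::ocontour(EBImage::Image(m * 1))[[1]]
    # ocontour returns 0-based (dim1, dim2) points
    boundary[[k]] <- cbind(row = oc[, 1] + 1, col = oc[, 2] + 1)
    ij <- which(m, arr.ind = TRUE)
    centroid[k, ] <- colMeans(ij)
  }
  structure(list(mask = mask, boundary = boundary, centroid = centroid),
            class = "cell_mask")
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged with a small union-find pass.
label8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  H <- nrow(lab); W <- ncol(lab)
  merge_pairs <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    if (!any(sel)) return(invisible())
    prs <- unique(cbind(a[sel], b[sel]))
    for (q in seq_len(nrow(prs))) {
      ri <- findp(prs[q, 1]); rj <- findp(prs[q, 2])
      if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    }
  }
  merge_pairs(lab[-H, -W], lab[-1, -1])   # down-right diagonal
  merge_pairs(lab[-H, -1], lab[-1, -W])   # down-left diagonal
  roots <- vapply(seq_len(n), findp, integer(1))
  compact <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- compact[lab[lab > 0]]
  out
}

# angle of image points around a centroid, counter-clockwise from the +x
# axis with y pointing up (i.e. decreasing row index), in [0, 2*pi)
pixel_angle <- function(row, col, centroid) {
  a <- atan2(centroid[1] - row, col - centroid[2])
  (a + 2 * pi) %% (2 * pi)
}

# binary brush of radius r (odd-sized disc)
disc_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

# Group suprathreshold pixels into spatiotemporal events: 8-connected
# components per frame, linked across consecutive frames by >= 1 px
# overlap (no gap closing).  `bin` and `vals` are H x W x T' arrays;
# `times` are the fdm timestamps; `centroids` give the cell centroid per
# fdm frame.
track_events <- function(bin, vals, times, frame_interval, centroids,
                         min_duration, min_area) {
  tt <- dim(bin)[3]
  labs <- vector("list", tt)
  node_frame <- integer(0); node_area <- integer(0)
  node_mag <- numeric(0); node_row <- numeric(0); node_col <- numeric(0)
  node_of <- vector("list", tt)  # per frame: label -> global node id
  for (k in seq_len(tt)) {
    lab <- label8(bin[, , k])
    labs[[k]] <- lab
    nl <- max(lab)
    ids <- integer(nl)
    if (nl > 0) {
      for (l in seq_len(nl)) {
        sel <- lab == l
        ids[l] <- length(node_frame) + 1L
        node_frame <- c(node_frame, k)
        node_area <- c(node_area, sum(sel))
        v <- vals[, , k][sel]
        node_mag <- c(node_mag, sum(v, na.rm = TRUE))
        ij <- which(sel, arr.ind = TRUE)
        node_row <- c(node_row, mean(ij[, 1]))
        node_col <- c(node_col, mean(ij[, 2]))
      }
    }
    node_of[[k]] <- ids
  }
  nn <- length(node_frame)
  if (nn == 0) return(empty_events())
  parent <- seq_len(nn)
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(tt - 1L)) {
    a <- labs[[k]]; b <- labs[[k + 1L]]
    sel <- a > 0 & b > 0
    if (!any(sel)) next
    prs <- unique(cbind(a[sel], b[sel]))
    for (q in seq_len(nrow(prs))) {
      ri <- findp(node_of[[k]][prs[q, 1]])
      rj <- findp(node_of[[k + 1L]][prs[q, 2]])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(nn), findp, integer(1))
  ev <- lapply(split(seq_len(nn), roots), function(ix) {
    fr <- node_frame[ix]
    f1 <- min(fr); f2 <- max(fr)
    area_pf <- tapply(node_area[ix], fr, sum)
    pk <- as.integer(names(area_pf))[which.max(area_pf)]
    sel_pk <- ix[fr == pk]
    w <- node_area[sel_pk]
    pr <- sum(node_row[sel_pk] * w) / sum(w)
    pc <- sum(node_col[sel_pk] * w) / sum(w)
    data.frame(first_frame = f1, last_frame = f2,
               onset_min = times[f1], end_min = times[f2],
               duration_min = (f2 - f1 + 1) * frame_interval,
               peak_area_px = max(area_pf),
               peak_row = pr, peak_col = pc, peak_frame = pk,
               magnitude = sum(node_mag[ix]))
  })
  ev <- do.call(rbind, ev)
  ev$angle_rad <- pixel_angle(ev$peak_row, ev$peak_col,
                              colMeans(centroids))
  ev <- ev[ev$duration_min >= min_duration &
             ev$peak_area_px >= min_area, , drop = FALSE]
  ev <- ev[order(ev$onset_min), , drop = FALSE]
  ev$id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev[, c("id", "onset_min", "end_min", "duration_min", "peak_area_px",
         "angle_rad", "magnitude", "first_frame", "last_frame",
         "peak_frame", "peak_row", "peak_col")]
}

empty_events <- function() {
  data.frame(id = integer(0), onset_min = numeric(0), end_min = numeric(0),
             duration_min = numeric(0), peak_area_px = integer(0),
             angle_rad = numeric(0), magnitude = numeric(0),
             first_frame = integer(0), last_frame = integer(0),
             peak_frame = integer(0), peak_row = numeric(0),
             peak_col = numeric(0))
}

#' Detect boundary protrusions in an FDM stack
#'
#' Binarizes the percent-change stack at `threshold_pct` (default 100,
#' i.e. a twofold increase over the differencing interval) inside a band
#' of `band_px` pixels along the cell boundary, groups suprathreshold
#' pixels by 8-connectivity within each frame, links groups across
#' consecutive frames by pixel overlap, and filters tracks by minimum
#' duration (default 5 min) and minimum peak area.
#'
#' @param fdm An `fdm_stack` from [frame_difference_pct()].
#' @param mask A [segment_cell()] result aligned with the original stack.
#' @param threshold_pct Percent-change threshold (default 100).
#' @param min_duration Minimum event duration in minutes (default 5).
#' @param min_area Minimum peak area in pixels (default 25).
#' @param band_px Width of the boundary band in pixels (default 3).
#' @return Data frame of events (one row each) with onset/end time,
#'   duration, peak area, angular position on the perimeter (radians,
#'   counter-clockwise from the +x axis at the cell centroid), and the
#'   integrated percent-change magnitude; sorted by onset.
#' @export
detect_protrusions <- function(fdm, mask, threshold_pct = 100,
                               min_duration = 5, min_area = 25,
                               band_px = 3) {
  stopifnot(inherits(fdm, "fdm_stack"), inherits(mask, "cell_mask"))
  tt <- dim(fdm$pct)[3]
  if (fdm_mask_frame(fdm, tt) > dim(mask$mask)[3])
    stop("invalid input: mask has fewer frames than the FDM stack needs")
  d <- dim(fdm$pct)
  bin <- array(FALSE, d)
  cents <- matrix(NA_real_, tt, 2)
  br <- disc_brush(band_px)
  for (i in seq_len(tt)) {
    mf <- fdm_mask_frame(fdm, i)
    m <- mask$mask[, , mf]
    band <- m & !(EBImage::erode(m, br) > 0)
    p <- fdm$pct[, , i]
    bin[, , i] <- band & !is.na(p) & p >= threshold_pct
    cents[i, ] <- mask$centroid[mf, ]
  }
  track_events(bin, fdm$pct, fdm$times, fdm$frame_interval, cents,
               min_duration, min_area)
}

#' Detect interior activity flashes
#'
#' Transient activity patches away from the cell boundary, detected at a
#' lower percent-change threshold (default 10) after eroding the cell mask
#' by `boundary_margin` pixels so that boundary-driven signal is excluded.
#' Tracking is identical to [detect_protrusions()], but no minimum
#' duration is applied by default.
#'
#' @inheritParams detect_protrusions
#' @param threshold_pct Percent-change threshold (default 10).
#' @param boundary_margin Pixels eroded off the mask boundary (>= 1;
#'   default 10, deep enough that boundary protrusions reaching a few
#'   pixels inward are excluded).
#' @param min_duration Minimum duration in minutes (default 0).
#' @param min_area Minimum peak area in pixels (default 5).
#' @return Data frame of flash events, same shape as
#'   [detect_protrusions()].
#' @export
interior_flashes <- function(fdm, mask, threshold_pct = 10,
                             boundary_margin = 10, min_duration = 0,
                             min_area = 5) {
  stopifnot(inherits(fdm, "fdm_stack"), inherits(mask, "cell_mask"))
  if (boundary_margin < 1) stop("boundary_margin must be >= 1")
  tt <- dim(fdm$pct)[3]
  if (fdm_mask_frame(fdm, tt) > dim(mask$mask)[3])
    stop("invalid input: mask has fewer frames than the FDM stack needs")
  d <- dim(fdm$pct)
  bin <- array(FALSE, d)
  cents <- matrix(NA_real_, tt, 2)
  br <- disc_brush(boundary_margin)
  for (i in seq_len(tt)) {
    mf <- fdm_mask_frame(fdm, i)
    interior <- EBImage::erode(mask$mask[, , mf], br) > 0
    if (!any(interior))
      stop("invalid input: erosion by boundary_margin emptied the mask")
    p <- fdm$pct[, , i]
    bin[, , i] <- interior & !is.na(p) & p >= threshold_pct
    cents[i, ] <- mask$centroid[mf, ]
  }
  track_events(bin, fdm$pct, fdm$times, fdm$frame_interval, cents,
               min_duration, min_area)
}

#' Protrusion frequency
#'
#' @param events Event data frame from [detect_protrusions()].
#' @param total_time Observation time in minutes (> 0).
#' @return Events per hour.
#' @export
protrusion_frequency <- function(events, total_time) {
  if (total_time <= 0) stop("total_time must be > 0")
  nrow(events) * 60 / total_time
}

#' Kymograph around the cell perimeter
#'
#' Samples the percent-change (or intensity) values in a narrow band along
#' the cell boundary and resamples them by angular position into `n_bins`
#' bins, counter-clockwise from the +x axis at the cell centroid.  Each
#' bin takes the maximum value over its band pixels (a small search normal
#' to the boundary).  Rows are perimeter bins, columns are frames.
#'
#' @param x An `fdm_stack` (uses `pct`) or [image_stack()] (uses raw
#'   intensities).
#' @param mask A [segment_cell()] result.
#' @param n_bins Number of perimeter bins (default 120).
#' @param band_px Band width in pixels (default 3).
#' @return A `perimeter_kymograph`: list with `values` (n_bins x T'
#'   matrix), `times`, `angles` (bin centers, radians).
#' @export
boundary_kymograph <- function(x, mask, n_bins = 120, band_px = 3) {
  stopifnot(inherits(mask, "cell_mask"))
  if (inherits(x, "fdm_stack")) {
    vals <- x$pct; times <- x$times
    mf <- function(i) fdm_mask_frame(x, i)
  } else if (inherits(x, "image_stack")) {
    vals <- x$data
    times <- (seq_len(dim(vals)[3]) - 1) * x$frame_interval
    mf <- function(i) i
  } else stop("x must be an fdm_stack or image_stack")
  tt <- dim(vals)[3]
  if (mf(tt) > dim(mask$mask)[3])
    stop("invalid input: mask has fewer frames than needed")
  kymo <- matrix(NA_real_, n_bins, tt)
  br <- disc_brush(band_px)
  breaks <- seq(0, 2 * pi, length.out = n_bins + 1)
  for (i in seq_len(tt)) {
    m <- mask$mask[, , mf(i)]
    if (nrow(mask$boundary[[mf(i)]]) < 8)
      stop("invalid input: degenerate boundary (< 8 points)")
    band <- m & !(EBImage::erode(m, br) > 0)
    ij <- which(band, arr.ind = TRUE)
    ang <- pixel_angle(ij[, 1], ij[, 2], mask$centroid[mf(i), ])
    v <- vals[, , i][band]
    b <- findInterval(ang, breaks, rightmost.closed = TRUE)
    agg <- tapply(v, factor(b, levels = seq_len(n_bins)),
                  function(z) if (all(is.na(z))) NA_real_
                              else max(z, na.rm = TRUE))
    kymo[, i] <- as.numeric(agg)
  }
  structure(list(values = kymo, times = times,
                 angles = (breaks[-1] + breaks[-(n_bins + 1)]) / 2),
            class = "perimeter_kymograph")
}

#' @export
print.perimeter_kymograph <- function(x, ...) {
  cat("Perimeter kymograph: ", nrow(x$values), " bins x ",
      ncol(x$values), " frames\n", sep = "")
  invisible(x)
}
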