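#' Smoothed negative derivative of a melting trace
#'
#' Applies Savitzky-Golay (order-2 local polynomial) smoothing followed
#' by a central-difference negative derivative, the standard -dF/dT
#' representation in which each melting transition appears as a peak at
#' its Tm.
#'
#' @param trace tibble for one sample and one channel with columns
#'   `temperature` (strictly increasing) and `fluorescence`; extra
#'   columns (`sample_id`, `channel`) are carried through.
#' @param smooth_window smoothing window in degrees C (>= grid step).
#' @return Tibble with columns `sample_id`, `channel`, `temperature`,
#'   `neg_dfdt`, same length as the input.
#' @examples
#' tr <- render_channel(data.frame(tm = 59.6, amplitude = 1, width = 0.5),
#'                      channel = "FAM", sample_id = "s1")
#' d <- negative_derivative(tr)
#' d$temperature[which.max(d$neg_dfdt)]
#' @export
negative_derivative <- function(trace, smooth_window = 0.5) {
  trace <- as.data.frame(trace)
  t <- trace$temperature
  f <- trace$fluorescence
  if (length(t) < 5L) stop("trace too short (< 5 points)", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("temperature grid must be strictly increasing", call. = FALSE)
  }
  h <- median(diff(t))
  if (smooth_window < h) {
    stop("smooth_window must be at least one grid step", call. = FALSE)
  }
  np <- round(smooth_window / h)
  if (np %% 2L == 0L) np <- np + 1L
  np <- max(np, 5L)
  np <- min(np, if (length(t) %% 2L == 1L) length(t) else length(t) - 1L)
  s <- signal::sgolayfilt(f, p = 2, n = np)
  n <- length(s)
  d <- numeric(n)
  d[2:(n - 1)] <- -(s[3:n] - s[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- -(s[2] - s[1]) / (t[2] - t[1])
  d[n] <- -(s[n] - s[n - 1]) / (t[n] - t[n - 1])
  out <- tibble(
    sample_id = if ("sample_id" %in% names(trace)) trace$sample_id[1] else NA_character_,
    channel = if ("channel" %in% names(trace)) trace$channel[1] else NA_character_,
    temperature = t, neg_dfdt = d)
  # noise scale of the derivative: robust estimate of the raw
  # fluorescence noise (second differences; signal curvature is tiny at
  # the grid step) propagated through the smoothing + differencing
  # operator via its impulse-response gain
  sigma_f <- mad(diff(f, differences = 2)) / sqrt(6)
  attr(out, "noise_scale") <- sigma_f * deriv_operator_gain(np, h)
  out
}

# l2 gain of the Savitzky-Golay + central-difference pipeline for white
# input noise, from the impulse response of the linear operator
deriv_operator_gain <- function(np, h) {
  len <- 4L * np + 9L
  e <- numeric(len)
  e[(len + 1L) %/% 2L] <- 1
  s <- signal::sgolayfilt(e, p = 2, n = np)
  r <- (s[3:len] - s[1:(len - 2L)]) / (2 * h)
  sqrt(sum(r^2))
}

#' Detect melt peaks on a negative-derivative curve
#'
#' Local maxima (grid edges excluded) are kept when (a) their height
#' reaches `min_height_frac` of the curve's global maximum, (b) their
#' height clears an absolute floor of `floor_mult` times the curve's
#' noise scale (propagated from the raw fluorescence by
#' [negative_derivative()], or re-estimated from successive differences
#' when absent), and (c) their topographic prominence exceeds a tiny
#' numerical guard, which suppresses flat channels and baseline ramps
#' whose "maxima" ride on a constant offset with essentially zero
#' prominence.  Maxima
#' closer than `min_separation` are pruned keeping the higher peak.
#' Each retained peak's Tm and height are refined by parabolic
#' interpolation through the maximum and its two neighbours, giving
#' sub-grid accuracy.
#'
#' @param curve output of [negative_derivative()].
#' @param min_height_frac relative height threshold in (0, 1).
#' @param min_separation minimum peak separation in degrees C.
#' @param floor_mult multiplier of the noise scale for the absolute
#'   floor.
#' @param min_height_abs optional explicit absolute floor (overrides the
#'   noise-based floor when larger).
#' @return Tibble of peak calls (`sample_id`, `channel`, `tm`, `height`,
#'   `prominence`), sorted by descending Tm; zero rows when nothing
#'   qualifies.
#' @export
detect_peaks <- function(curve, min_height_frac = 0.25,
                         min_separation = 1.5, floor_mult = 5,
                         min_height_abs = NULL) {
  stopifnot(min_height_frac > 0, min_height_frac < 1, min_separation > 0)
  curve <- as.data.frame(curve)
  t <- curve$temperature
  d <- curve$neg_dfdt
  n <- length(d)
  empty <- tibble(sample_id = character(0), channel = character(0),
                  tm = numeric(0), height = numeric(0),
                  prominence = numeric(0))
  if (n < 3L) return(empty)

  idx <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  if (length(idx) == 0L) return(empty)

  sigma <- attr(curve, "noise_scale")
  if (is.null(sigma)) sigma <- mad(diff(d)) / sqrt(2)
  abs_floor <- max(floor_mult * sigma, min_height_abs %||% 0, 1e-6)
  thresh <- max(min_height_frac * max(d), abs_floor)
  idx <- idx[d[idx] >= thresh]
  if (length(idx) == 0L) return(empty)

  # prominence guard against floating-point ripple on analytically flat
  # channels (a constant baseline offset passes the relative height gate
  # but has essentially zero prominence); real peaks, even shoulders of
  # much stronger neighbours, are many orders of magnitude above this
  prom_floor <- 1e-6

  prominence_at <- function(i) {
    # min down to the nearest higher point (or boundary) on each side
    lmin <- {
      j <- i - 1L; m <- d[i]
      while (j >= 1L && d[j] <= d[i]) { m <- min(m, d[j]); j <- j - 1L }
      m
    }
    rmin <- {
      j <- i + 1L; m <- d[i]
      while (j <= n && d[j] <= d[i]) { m <- min(m, d[j]); j <- j + 1L }
      m
    }
    d[i] - max(lmin, rmin)
  }
  prom <- vapply(idx, prominence_at, numeric(1))
  keep <- prom >= prom_floor
  idx <- idx[keep]
  prom <- prom[keep]
  if (length(idx) == 0L) return(empty)

  # greedy separation pruning, highest first
  ord <- order(d[idx], decreasing = TRUE)
  idx <- idx[ord]
  prom <- prom[ord]
  kept_sel <- logical(length(idx))
  kept <- integer(0)
  for (k in seq_along(idx)) {
    if (all(abs(t[idx[k]] - t[kept]) >= min_separation)) {
      kept <- c(kept, idx[k])
      kept_sel[k] <- TRUE
    }
  }
  prominence <- prom[kept_sel]

  # parabolic refinement through the maximum and its neighbours
  refine <- function(i) {
    y0 <- d[i - 1]; y1 <- d[i]; y2 <- d[i + 1]
    denom <- y0 - 2 * y1 + y2
    off <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / denom
    off <- max(min(off, 0.5), -0.5)
    h <- (t[i + 1] - t[i - 1]) / 2
    c(tm = t[i] + off * h, height = y1 - 0.25 * (y0 - y2) * off)
  }
  ref <- t(vapply(kept, refine, numeric(2)))

  out <- tibble(
    sample_id = if ("sample_id" %in% names(curve)) curve$sample_id[1] else NA_character_,
    channel = if ("channel" %in% names(curve)) curve$channel[1] else NA_character_,
    tm = ref[, "tm"], height = ref[, "height"], prominence = prominence)
  arrange(out, dplyr::desc(tm))
}

#' Call peaks on every (sample, channel) trace of a long trace table
#'
#' @param traces long tibble (`sample_id`, `channel`, `temperature`,
#'   `fluorescence`).
#' @inheritParams negative_derivative
#' @inheritParams detect_peaks
#' @return Long tibble of peak calls across all samples and channels.
#' @export
call_peaks <- function(traces, smooth_window = 0.5,
                       min_height_frac = 0.25, min_separation = 1.5,
                       floor_mult = 5, min_height_abs = NULL) {
  traces <- as.data.frame(traces)
  keys <- unique(traces[, c("sample_id", "channel")])
  bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    tr <- traces[traces$sample_id == keys$sample_id[i] &
                   traces$channel == keys$channel[i], ]
    detect_peaks(
      negative_derivative(tr, smooth_window = smooth_window),
      min_height_frac = min_height_frac,
      min_separation = min_separation,
      floor_mult = floor_mult, min_height_abs = min_height_abs)
  }))
}
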