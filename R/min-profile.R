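## Time-resolved axial MinD intensity profiles: container, TSV I/O, a
## synthetic pole-to-pole oscillation generator emulating EYFP-MinD
## time-lapse profile series, and conversion to a binding-probability
## field for the mind_profile tether mode.

#' MinD axial profile series
#'
#' A stack of 1D fluorescence intensity profiles along the long cell axis,
#' one per movie frame, as obtained by averaging a MinD channel across the
#' cell width at each time point.  Axial coordinates are relative cell
#' length in \[0, 1\].
#'
#' @param frame_times numeric vector of frame times in seconds, strictly
#'   increasing.
#' @param axial_bins numeric vector of axial bin centres in \[0, 1\],
#'   strictly increasing, spanning the cell (first bin <= 0.1, last
#'   >= 0.9).
#' @param intensities numeric matrix, frames x bins, arbitrary
#'   fluorescence units, nonnegative; every frame must contain at least
#'   one strictly positive bin.
#' @return an object of class `min_profile_series`.
#' @export
min_profile_series <- function(frame_times, axial_bins, intensities) {
  intensities <- as.matrix(intensities)
  if (length(frame_times) != nrow(intensities))
    stop("frame_times length must equal the number of intensity rows")
  if (length(axial_bins) != ncol(intensities))
    stop("axial_bins length must equal the number of intensity columns")
  if (any(diff(frame_times) <= 0))
    stop("frame times must be strictly increasing")
  if (any(diff(axial_bins) <= 0))
    stop("axial bins must be strictly increasing")
  if (min(axial_bins) < 0 || max(axial_bins) > 1)
    stop("axial bins must lie in [0, 1]")
  if (axial_bins[1] > 0.1 || axial_bins[length(axial_bins)] < 0.9)
    stop("axial bins must cover the cell length")
  if (any(intensities < 0)) stop("negative intensity in profile series")
  if (any(apply(intensities, 1L, max) <= 0))
    stop("every frame needs at least one strictly positive intensity")
  dimnames(intensities) <- NULL
  structure(list(frame_times = as.numeric(frame_times),
                 axial_bins = as.numeric(axial_bins),
                 intensities = intensities),
            class = "min_profile_series")
}

#' @export
print.min_profile_series <- function(x, ...) {
  cat(sprintf(
    "<min_profile_series: %d frames x %d axial bins, t = %g..%g s>\n",
    nrow(x$intensities), ncol(x$intensities),
    min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' @export
plot.min_profile_series <- function(x, ...) {
  matplot(x$axial_bins, t(x$intensities), type = "l", lty = 1,
          col = grey(seq(0, 0.8, length.out = nrow(x$intensities))),
          xlab = "relative axial position", ylab = "intensity (a.u.)", ...)
  invisible(x)
}

## nominal duration of one cyclic repeat: span plus one frame spacing
profile_duration <- function(series) {
  tt <- series$frame_times
  dt <- if (length(tt) > 1) (max(tt) - min(tt)) / (length(tt) - 1) else 1
  (max(tt) - min(tt)) + dt
}

#' Read / write a MinD profile series as TSV
#'
#' Format: a header row `time` followed by the axial bin coordinates; one
#' row per frame holding the frame time (seconds) and the per-bin
#' intensities.
#'
#' @param path file path.
#' @return `read_min_profile`: a [min_profile_series()];
#'   `write_min_profile`: the path, invisibly.
#' @export
read_min_profile <- function(path) {
  if (!file.size(path)) stop("empty profile file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("malformed profile file (need a header and at least one frame): ",
         path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "time")
    stop("malformed profile file at line 1: first column must be 'time'")
  bins <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(bins))
    stop("malformed profile file at line 1: non-numeric bin coordinate")
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], "\t",
                                              fixed = TRUE)[[1]]))
    if (anyNA(v) || length(v) != length(bins) + 1L)
      stop("malformed profile file at line ", i)
    v
  })
  m <- do.call(rbind, rows)
  min_profile_series(m[, 1], bins, m[, -1, drop = FALSE])
}

#' @rdname read_min_profile
#' @param series a [min_profile_series()].
#' @export
write_min_profile <- function(series, path) {
  stopifnot(inherits(series, "min_profile_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time", format(series$axial_bins, digits = 15)),
                   collapse = "\t"), con)
  for (i in seq_along(series$frame_times))
    writeLines(paste(format(c(series$frame_times[i],
                              series$intensities[i, ]), digits = 15),
                     collapse = "\t"), con)
  invisible(path)
}

#' Synthesize a pole-to-pole MinD oscillation profile series
#'
#' Generates an idealized EYFP-MinD-style profile movie: within each
#' half-period the intensity forms a polar cap, maximal at one pole and
#' decaying toward mid-cell; the occupied pole switches every
#' half-period.  Frames are spaced `frame_dt` seconds apart (7 s by
#' default, a typical Min time-lapse interval; the full oscillation
#' period is `period_s`).  The default cap is a linear wedge that falls
#' to zero at `1/sharpness` cell lengths from the active pole (mid-cell
#' for the default `sharpness = 2`), the shape the membrane-bound MinD
#' zone takes in time-averaged profile schematics; `shape =
#' "exponential"` gives a smooth cap `exp(-sharpness * u)` instead.
#'
#' @param period_s full pole-to-pole-and-back oscillation period, seconds.
#' @param n_frames number of frames; the default covers exactly one
#'   period, which makes the cyclic time wrap of [profile_to_field()]
#'   seamless.
#' @param n_bins number of axial bins (>= 8).
#' @param shape polar-cap decay: `"linear"` wedge or `"exponential"`.
#' @param sharpness decay rate of the polar cap in inverse cell lengths
#'   (see above); larger values confine MinD closer to the pole.
#' @param frame_dt frame spacing, seconds.
#' @param noise_sd multiplicative Gaussian noise s.d. (0 = noise-free);
#'   emulates measurement noise in extracted profiles.
#' @param seed optional seed for the noise.
#' @return a [min_profile_series()].
#' @export
#' @examples
#' prof <- synthesize_min_oscillation(period_s = 84)
#' prof
synthesize_min_oscillation <- function(period_s = 84, n_frames = NULL,
                                       n_bins = 40L,
                                       shape = c("linear", "exponential"),
                                       sharpness = 2, frame_dt = 7,
                                       noise_sd = 0, seed = NULL) {
  shape <- match.arg(shape)
  if (period_s <= 0) stop("period_s must be positive")
  if (n_bins < 8L) stop("need at least 8 axial bins")
  if (is.null(n_frames)) n_frames <- max(2L, round(period_s / frame_dt))
  if (!is.null(seed)) set.seed(seed)
  times <- (seq_len(n_frames) - 1L) * frame_dt
  bins <- (seq_len(n_bins) - 0.5) / n_bins
  I <- matrix(0, n_frames, n_bins)
  for (i in seq_len(n_frames)) {
    phase <- (times[i] %% period_s) / period_s
    pole <- if (phase < 0.5) 0 else 1
    u <- abs(bins - pole)
    I[i, ] <- if (shape == "linear") pmax(0, 1 - sharpness * u)
              else exp(-sharpness * u)
    if (max(I[i, ]) <= 0) I[i, which.min(u)] <- 1  # degenerate sharpness
  }
  if (noise_sd > 0) {
    I <- I * pmax(0, 1 + matrix(rnorm(length(I), sd = noise_sd),
                                nrow(I), ncol(I)))
    dead <- apply(I, 1L, max) <= 0
    I[dead, 1L] <- 1e-12   # keep every frame minimally positive
  }
  min_profile_series(times, bins, I)
}

#' Convert a profile series to a time-varying binding field
#'
#' Returns the function used by [binding_probability()] in `mind_profile`
#' mode: intensities are max-normalized per frame (so the pole cap
#' saturates at `p_max` every half-cycle regardless of total fluorescence
#' drift), linearly interpolated in the axial coordinate, and looked up by
#' nearest frame in time with cyclic wrap over the series duration.
#'
#' @param series a [min_profile_series()].
#' @param p_max peak binding probability.
#' @param wrap cyclically wrap query times over the series duration
#'   (default).  With `wrap = FALSE`, query times outside the recorded
#'   range are an error.
#' @return `function(x_rel, t_s)` mapping relative axial position(s) in
#'   \[0, 1\] and a scalar time in seconds to binding probabilities in
#'   \[0, `p_max`\].
#' @export
profile_to_field <- function(series, p_max, wrap = TRUE) {
  stopifnot(inherits(series, "min_profile_series"))
  I <- series$intensities / apply(series$intensities, 1L, max)
  bins <- series$axial_bins
  tt <- series$frame_times
  dur <- profile_duration(series)
  function(x_rel, t_s) {
    stopifnot(length(t_s) == 1L)
    if (any(x_rel < 0 | x_rel > 1))
      stop("relative axial position outside [0, 1]")
    if (!wrap && (t_s < min(tt) || t_s > max(tt) + dur - (max(tt) - min(tt))))
      stop("query time outside the recorded series (wrap disabled)")
    tau <- (t_s - tt[1]) %% dur
    d <- abs(tt - tt[1] - tau)
    d <- pmin(d, dur - d)
    f <- which.min(d)
    y <- approx(bins, I[f, ], xout = pmin(pmax(x_rel, bins[1]),
                                          bins[length(bins)]),
                method = "linear")$y
    p_max * y
  }
}
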