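## In-vivo style quantification on 1D data: nucleoid separation depth (R)
## and distance (D) from axial intensity profiles, and mean squared
## displacement / apparent diffusion from 2D focus tracks.

#' Nucleoid separation depth and distance from an intensity profile
#'
#' Quantifies how far two nucleoid lobes are separated in a 1D axial
#' intensity profile (e.g. DAPI fluorescence averaged across the cell
#' width).  After moving-average smoothing, peaks are detected by
#' topographic prominence.  If two dominant peaks with an interior valley
#' exist, the profile is split at the valley and
#' \itemize{
#'   \item `D` = distance between the intensity-weighted centres of mass
#'     of the two lobes (in the profile's position units), and
#'   \item `R` = 1 - I_valley / mean(I_peak1, I_peak2), a dimensionless
#'     separation depth in \[0, 1\] (0: no valley, 1: fully resolved
#'     lobes).
#' }
#' Otherwise a single nucleoid is reported with `R = D = 0`.  `R` and `D`
#' are invariant under rescaling of the intensities, and `D` is invariant
#' under translation of the position axis.
#'
#' @param positions numeric vector of axial positions (monotonically
#'   increasing; microns or relative units), length >= 8.
#' @param intensities nonnegative intensity values, same length.
#' @param smoothing_window moving-average window (samples, odd; 1 = no
#'   smoothing).
#' @param min_prominence minimum peak prominence, as a fraction of the
#'   maximum smoothed intensity.
#' @return an object of class `separation_result`: list with `R`, `D`,
#'   `n_nucleoids`, peak/valley positions.
#' @export
#' @examples
#' x <- seq(-2, 2, length.out = 200)
#' y <- dnorm(x, -1, 0.2) + dnorm(x, 1, 0.2)
#' nucleoid_separation(x, y)
nucleoid_separation <- function(positions, intensities,
                                smoothing_window = 3L,
                                min_prominence = 0.05) {
  if (length(positions) < 8L) stop("need at least 8 profile samples")
  if (length(intensities) != length(positions))
    stop("positions and intensities differ in length")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  s <- moving_average(intensities, smoothing_window)
  pk <- find_peaks(s, min_prominence * max(s))
  one <- structure(list(R = 0, D = 0, n_nucleoids = 1L,
                        peaks = positions[pk], valley = NA_real_),
                   class = "separation_result")
  if (length(pk) < 2L) return(one)
  ## two dominant peaks, in axial order
  top <- sort(pk[order(s[pk], decreasing = TRUE)[1:2]])
  vi <- top[1] + which.min(s[top[1]:top[2]]) - 1L
  if (s[vi] >= min(s[top])) return(one)  # no interior valley
  Rdepth <- 1 - s[vi] / mean(s[top])
  li <- seq_len(vi)
  ri <- seq.int(vi, length(s))
  wcm <- function(i) sum(positions[i] * s[i]) / sum(s[i])
  structure(list(R = max(0, min(1, Rdepth)),
                 D = abs(wcm(ri) - wcm(li)),
                 n_nucleoids = 2L, peaks = positions[top],
                 valley = positions[vi]),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  if (x$n_nucleoids == 1L)
    cat("<separation: single nucleoid (R = 0, D = 0)>\n")
  else
    cat(sprintf("<separation: 2 nucleoids, R = %.3f, D = %.4g>\n", x$R, x$D))
  invisible(x)
}

## centered moving average with edge replication
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(as.numeric(x))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[h + seq_along(x)]
}

## indices of local maxima with topographic prominence >= min_prom
find_peaks <- function(s, min_prom) {
  n <- length(s)
  cand <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1L) s[i - 1L] else -Inf
    r <- if (i < n) s[i + 1L] else -Inf
    s[i] > l && s[i] >= r
  }, logical(1)))
  keep <- vapply(cand, function(i) {
    ## prominence: height above the higher of the two key saddles
    left <- s[seq_len(i)]
    right <- s[seq.int(i, n)]
    hl <- which(left > s[i])
    hr <- which(right > s[i])
    saddle_l <- if (length(hl)) min(left[seq.int(max(hl), i)]) else min(left)
    saddle_r <- if (length(hr)) min(right[seq_len(min(hr))]) else min(right)
    (s[i] - max(saddle_l, saddle_r)) >= min_prom
  }, logical(1))
  cand[keep]
}

#' Mean squared displacement of 2D focus tracks
#'
#' Time- and ensemble-averaged MSD: for each lag, squared displacements
#' are averaged over all frame pairs within each track, then averaged
#' across tracks; the standard error is taken across tracks.
#'
#' @param tracks a `data.frame` with columns `track_id`, `t`, `x`, `y`
#'   (as produced by [simulate_focus_tracks()]), frames uniformly spaced
#'   within each track.
#' @param max_lag largest lag (in frames); must be smaller than the
#'   shortest track.
#' @return `data.frame` with columns `lag`, `lag_time`, `msd`, `stderr`,
#'   `n_pairs`.
#' @export
msd_curve <- function(tracks, max_lag = 10L) {
  if (!nrow(tracks)) stop("no tracks supplied")
  need <- c("track_id", "t", "x", "y")
  if (!all(need %in% names(tracks)))
    stop("tracks need columns ", paste(need, collapse = ", "))
  byid <- split(tracks[c("t", "x", "y")], tracks$track_id)
  nmin <- min(vapply(byid, nrow, integer(1)))
  if (max_lag >= nmin)
    stop("max_lag must be smaller than the shortest track length (", nmin, ")")
  dt <- diff(byid[[1]]$t[1:2])
  per_track <- vapply(byid, function(tr) {
    n <- nrow(tr)
    vapply(seq_len(max_lag), function(k) {
      dx <- tr$x[(k + 1):n] - tr$x[1:(n - k)]
      dy <- tr$y[(k + 1):n] - tr$y[1:(n - k)]
      mean(dx^2 + dy^2)
    }, numeric(1))
  }, numeric(max_lag))
  per_track <- matrix(per_track, nrow = max_lag)
  npairs <- vapply(seq_len(max_lag), function(k)
    sum(vapply(byid, nrow, integer(1)) - k), numeric(1))
  data.frame(lag = seq_len(max_lag),
             lag_time = seq_len(max_lag) * dt,
             msd = rowMeans(per_track),
             stderr = apply(per_track, 1L, sd) / sqrt(ncol(per_track)),
             n_pairs = npairs)
}

#' Apparent diffusion coefficient from an MSD curve
#'
#' Least-squares slope of the MSD over the initial lags, divided by 4
#' (2D convention): MSD(t) = 4 D t for free Brownian motion.
#'
#' @param msd a `data.frame` from [msd_curve()].
#' @param fit_lags number of initial lags used in the fit (>= 2).
#' @return list with `D` (units of position^2 / s), `slope`, `intercept`
#'   and a `degenerate` flag (TRUE when the MSD is identically zero, in
#'   which case `D = 0`).
#' @export
apparent_diffusion <- function(msd, fit_lags = 4L) {
  if (fit_lags < 2L) stop("need at least 2 lags to fit")
  fit_lags <- min(fit_lags, nrow(msd))
  sub <- msd[seq_len(fit_lags), ]
  if (all(sub$msd == 0))
    return(list(D = 0, slope = 0, intercept = 0, degenerate = TRUE))
  fit <- lm(msd ~ lag_time, data = sub)
  list(D = unname(coef(fit)[2]) / 4, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), degenerate = FALSE)
}

#' Simulate 2D Brownian focus tracks
#'
#' Gaussian-step random walks in the plane with diffusion coefficient
#' `D0` (per-coordinate step variance `2 * D0 * dt`), optionally
#' reflected inside a disc of radius `confinement_radius` centred at the
#' origin.  A synthetic stand-in for tracked fluorescent replication-fork
#' foci.
#'
#' @param n_tracks number of tracks.
#' @param n_frames frames per track.
#' @param dt frame spacing, seconds (50 ms default).
#' @param D0 diffusion coefficient, position units^2 per second.
#' @param confinement_radius disc radius (Inf = unconfined).
#' @param seed optional seed.
#' @return `data.frame` with columns `track_id`, `t`, `x`, `y`.
#' @export
simulate_focus_tracks <- function(n_tracks, n_frames, dt = 0.05, D0 = 0.01,
                                  confinement_radius = Inf, seed = NULL) {
  stopifnot(n_tracks >= 1, n_frames >= 2, dt > 0, D0 >= 0,
            confinement_radius > 0)
  if (!is.null(seed)) set.seed(seed)
  sdstep <- sqrt(2 * D0 * dt)
  one <- function(id) {
    x <- cumsum(c(0, rnorm(n_frames - 1L, sd = sdstep)))
    y <- cumsum(c(0, rnorm(n_frames - 1L, sd = sdstep)))
    if (is.finite(confinement_radius)) {
      x <- numeric(n_frames); y <- numeric(n_frames)
      for (i in seq.int(2L, n_frames)) {
        x[i] <- x[i - 1L] + rnorm(1L, sd = sdstep)
        y[i] <- y[i - 1L] + rnorm(1L, sd = sdstep)
        r <- sqrt(x[i]^2 + y[i]^2)
        if (r > confinement_radius) {   # radial reflection at the wall
          f <- (2 * confinement_radius - r) / r
          x[i] <- x[i] * f; y[i] <- y[i] * f
        }
      }
    }
    data.frame(track_id = id, t = (seq_len(n_frames) - 1L) * dt, x = x, y = y)
  }
  do.call(rbind, lapply(seq_len(n_tracks), one))
}
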