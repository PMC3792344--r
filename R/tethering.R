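## Membrane tethering fields and the bind/release rules of the Brownian
## ratchet.  Tethering sites live on the lateral walls (y/z boundaries);
## the pole caps (x extremes) carry no sites.  Binding probability depends
## on the axial position (and, for dynamic fields, on time) only;
## eligibility depends on lateral wall proximity only.

#' Tethering-field specification
#'
#' Defines the per-MCS binding probability p(x, t) for unbound monomers at
#' the lateral membrane, and the release statistics of bound monomers.
#' Modes:
#' \describe{
#'   \item{`none`}{no tethering (p = 0 everywhere).}
#'   \item{`uniform`}{p = `p_max` everywhere along the cell.}
#'   \item{`static_gradient`}{p = `p_max * (2|x/Lx - 1/2|)^steepness`:
#'     zero at mid-cell, maximal at the poles.  `steepness = 0` recovers
#'     the uniform field.}
#'   \item{`oscillating_gradient`}{the static profile restricted to one
#'     axial half of the cell; the active half alternates every `period`
#'     MCS (so a full pole-to-pole cycle lasts `2 * period`).}
#'   \item{`mind_profile`}{p = `p_max` times a measured or synthetic MinD
#'     axial intensity profile series, max-normalized per frame,
#'     interpolated in x and looked up by nearest frame in (cyclically
#'     wrapped) time; see [profile_to_field()].}
#' }
#' A monomer that binds is immobilized for a geometrically distributed
#' number of MCS with mean `dwell_mean` (memoryless release).
#'
#' @param mode one of `"none"`, `"uniform"`, `"static_gradient"`,
#'   `"oscillating_gradient"`, `"mind_profile"`.
#' @param p_max binding probability per MCS per eligible monomer, in
#'   \[0, 1\].
#' @param steepness dimensionless gradient exponent s >= 0 (1 = linear).
#' @param dwell_mean mean immobilization time, MCS; `Inf` = permanent.
#' @param period half-cycle of the oscillating gradient, MCS.
#' @param border_distance a monomer is tether-eligible when its cube lies
#'   within this many lattice units of a lateral (y or z) wall.
#' @param profile a [min_profile_series()] (required for, and only
#'   meaningful in, `mind_profile` mode).
#' @param mcs_per_second simulation-time mapping for `mind_profile` mode;
#'   defaults so that one full oscillation of the profile series spans
#'   `2 * period` MCS, matching the idealized oscillating gradient.
#' @return an object of class `tether_field`.
#' @export
#' @examples
#' tether_field("static_gradient")
#' tether_field("oscillating_gradient", p_max = 0.1, period = 1e4)
tether_field <- function(mode = c("none", "uniform", "static_gradient",
                                  "oscillating_gradient", "mind_profile"),
                         p_max = 0.1, steepness = 1, dwell_mean = 100,
                         period = 1e4, border_distance = 1,
                         profile = NULL, mcs_per_second = NULL) {
  mode <- match.arg(mode)
  if (p_max < 0 || p_max > 1) stop("p_max must be in [0, 1]")
  if (steepness < 0) stop("steepness must be >= 0")
  if (dwell_mean <= 0) stop("dwell_mean must be positive")
  if (period <= 0) stop("period must be positive")
  if (border_distance < 1) stop("border_distance must be >= 1")
  if (mode == "mind_profile") {
    if (is.null(profile)) stop("mind_profile mode requires a profile series")
    stopifnot(inherits(profile, "min_profile_series"))
    if (is.null(mcs_per_second)) {
      dur <- profile_duration(profile)
      mcs_per_second <- 2 * period / dur
    }
  } else if (!is.null(profile)) {
    stop("a profile series is only meaningful in mind_profile mode")
  }
  structure(list(mode = mode, p_max = p_max, steepness = steepness,
                 dwell_mean = dwell_mean, period = period,
                 border_distance = border_distance, profile = profile,
                 mcs_per_second = mcs_per_second),
            class = "tether_field")
}

#' @export
print.tether_field <- function(x, ...) {
  cat(sprintf("<tether_field: %s", x$mode))
  if (x$mode != "none") {
    cat(sprintf(", p_max=%g, dwell=%g MCS, d_b=%g", x$p_max, x$dwell_mean,
                x$border_distance))
    if (x$mode %in% c("static_gradient", "oscillating_gradient"))
      cat(sprintf(", steepness=%g", x$steepness))
    if (x$mode == "oscillating_gradient")
      cat(sprintf(", half-cycle=%g MCS", x$period))
    if (x$mode == "mind_profile")
      cat(sprintf(", %d frames, %g MCS/s", nrow(x$profile$intensities),
                  x$mcs_per_second))
  }
  cat(">\n")
  invisible(x)
}

## serialize for the C++ kernel
field_to_cpp <- function(field, box) {
  mode <- match(field$mode, c("none", "uniform", "static_gradient",
                              "oscillating_gradient", "mind_profile")) - 1L
  out <- list(mode = mode, p_max = field$p_max,
              steepness = field$steepness, period = field$period)
  if (field$mode == "mind_profile") {
    out$prof_intensity <- field$profile$intensities
    out$prof_bins <- field$profile$axial_bins
    out$prof_times <- field$profile$frame_times
    out$mcs_per_second <- field$mcs_per_second
  }
  out
}

#' Is a monomer at the lateral membrane?
#'
#' TRUE iff the monomer cube lies within `d_b` lattice units of a lateral
#' (y or z) wall.  The pole caps at the x extremes carry no tethering
#' sites, so proximity to them does not count.
#'
#' @param position integer 3-vector (or matrix, one position per row) of
#'   monomer lower-corner lattice positions.
#' @param box a [confinement_box()].
#' @param d_b border distance in lattice units (default 1: cube touching a
#'   lateral wall).
#' @return logical vector.
#' @export
is_at_border <- function(position, box, d_b = 1) {
  if (is.null(dim(position))) position <- matrix(position, nrow = 1L)
  dy <- pmin(position[, 2], box$Ly - 1L - position[, 2])
  dz <- pmin(position[, 3], box$Lz - 1L - position[, 3])
  dy < d_b | dz < d_b
}

#' Binding probability of the tethering field
#'
#' Evaluates p(x, t) for a tethering field at axial coordinate(s)
#' `x_axial` (continuous, in \[0, Lx\]; monomer cubes are evaluated at
#' their centre x + 0.5) and MCS time(s) `mcs`.  This is the reference
#' implementation of the field; the simulation kernel evaluates the same
#' definition in compiled code.
#'
#' @param x_axial numeric vector of axial positions in lattice units.
#' @param mcs scalar MCS time.
#' @param field a [tether_field()].
#' @param box a [confinement_box()].
#' @return numeric vector of probabilities per MCS.
#' @export
binding_probability <- function(x_axial, mcs, field, box) {
  stopifnot(inherits(field, "tether_field"))
  if (any(x_axial < 0 | x_axial > box$Lx))
    stop("axial position outside the box")
  Lx <- box$Lx
  switch(field$mode,
    none = rep(0, length(x_axial)),
    uniform = rep(field$p_max, length(x_axial)),
    static_gradient =
      field$p_max * (2 * abs(x_axial / Lx - 0.5))^field$steepness,
    oscillating_gradient = {
      p <- field$p_max * (2 * abs(x_axial / Lx - 0.5))^field$steepness
      left_active <- (floor(mcs / field$period) %% 2) == 0
      active <- if (left_active) x_axial < Lx / 2 else x_axial > Lx / 2
      ifelse(active, p, 0)
    },
    mind_profile = {
      f <- profile_to_field(field$profile, field$p_max)
      f(x_axial / Lx, mcs / field$mcs_per_second)
    })
}
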