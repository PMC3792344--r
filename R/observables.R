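## Per-run and ensemble observables: relative axial centre of mass, axial
## density profiles, radius of gyration, ensemble summaries of final CM
## positions, and the force-distance probe of the inter-polymer repulsion.

#' Relative axial centre of mass
#'
#' Mean monomer-centre x coordinate minus mid-cell, divided by the cell
#' length: 0 at mid-cell, -0.5/+0.5 at the pole faces.
#'
#' @param polymer integer matrix of monomer positions (one ring), as
#'   returned by [polymer_positions()].
#' @param box a [confinement_box()].
#' @return numeric scalar in \[-0.5, 0.5\].
#' @export
center_of_mass_rel <- function(polymer, box) {
  (mean(polymer[, 1]) + 0.5 - box$Lx / 2) / box$Lx
}

#' Axial density profile of a polymer
#'
#' Fraction of monomers per axial bin (monomer centres binned along x);
#' sums to 1.
#'
#' @inheritParams center_of_mass_rel
#' @param n_bins number of bins; must divide `Lx` (default one bin per
#'   lattice unit).
#' @return numeric vector of length `n_bins` with attribute `breaks`.
#' @export
density_profile <- function(polymer, box, n_bins = box$Lx) {
  if (box$Lx %% n_bins != 0L) stop("n_bins must divide Lx")
  w <- box$Lx / n_bins
  centers <- polymer[, 1] + 0.5
  idx <- pmin(floor(centers / w), n_bins - 1L) + 1L
  p <- tabulate(idx, nbins = n_bins) / nrow(polymer)
  attr(p, "breaks") <- seq(0, box$Lx, by = w)
  p
}

#' Radius of gyration
#'
#' Root-mean-square distance of monomer centres from their 3D centroid,
#' in lattice units.
#'
#' @param polymer integer matrix of monomer positions (one ring).
#' @return numeric scalar.
#' @export
radius_of_gyration <- function(polymer) {
  cen <- sweep(polymer + 0.5, 2L, colMeans(polymer + 0.5))
  sqrt(mean(rowSums(cen^2)))
}

#' Summarize final centre-of-mass positions across runs
#'
#' Pools the final relative axial CM of an ensemble of replicate runs into
#' the segregation summary: the distribution (histogram) of the
#' right-labelled polymer's final CM, its moments, and the separation
#' statistic Delta = mean |cm_rel| over both polymers.
#'
#' @param runs a `seg_ensemble` from [run_experiment()], or a list of
#'   `seg_run` objects sharing one configuration.
#' @param breaks histogram break specification (passed to [hist()]).
#' @return an object of class `ensemble_summary`: list with `n_runs`,
#'   `final_cm` (data.frame with columns `left`, `right`, `abs_mean`),
#'   `histogram` (probability masses over `breaks`), `mean`, `sd` (of the
#'   right polymer's final CM) and `delta`.
#' @export
summarize_ensemble <- function(runs, breaks = seq(-0.5, 0.5, by = 0.05)) {
  finals <- ensemble_finals(runs)
  if (nrow(finals) < 2L) stop("need at least 2 runs to summarize")
  h <- hist(finals$right, breaks = breaks, plot = FALSE)
  structure(list(
    n_runs = nrow(finals), final_cm = finals,
    histogram = list(breaks = h$breaks,
                     mass = h$counts / sum(h$counts)),
    mean = mean(finals$right), sd = sd(finals$right),
    delta = mean(finals$abs_mean)), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<ensemble_summary: %d runs, right-CM mean %+0.3f (sd %.3f), ",
    "Delta = %.3f>\n"), x$n_runs, x$mean, x$sd, x$delta))
  invisible(x)
}

## final CM table from an ensemble or list of runs
ensemble_finals <- function(runs) {
  if (inherits(runs, "seg_ensemble")) return(runs$finals)
  if (inherits(runs, "seg_run")) runs <- list(runs)
  if (!length(runs)) stop("no runs supplied")
  cfg <- lapply(runs, function(r)
    list(box = r$state$box, N = r$state$N, mcs = r$state$mcs,
         excl = r$state$interchain_exclusion))
  if (length(unique(vapply(cfg, function(x) paste(deparse(x), collapse = ""),
                           character(1)))) != 1L)
    stop("runs with mixed configurations cannot be pooled")
  do.call(rbind, lapply(runs, function(r) {
    st <- r$state
    cm <- vapply(seq_len(st$n_polymers), function(p)
      center_of_mass_rel(polymer_positions(st, p), st$box), numeric(1))
    right <- if (!is.null(st$labels)) st$labels$right else which.max(cm)
    data.frame(left = cm[-right][1], right = cm[right],
               abs_mean = mean(abs(cm)))
  }))
}

#' Force-distance probe of the inter-polymer repulsion
#'
#' Measures the effective repulsion between the two polymers the way a
#' tug-of-war experiment would: apply an attractive coupling U = f * d
#' between the polymers (d = axial CM separation in lattice units, f in
#' kT per lattice unit), let the system equilibrate, and record the mean
#' separation at which the applied attraction balances the repulsion.
#' Axial moves are accepted with Metropolis probability
#' `min(1, exp(-f * delta_d))` on top of all hard constraints.
#'
#' @param forces numeric vector of applied forces f >= 0.
#' @param field a [tether_field()] (e.g. `"none"` for the purely entropic
#'   system or an oscillating gradient).
#' @param box,N,seed,n_mix passed to [init_overlapping_rings()]; each
#'   force point re-equilibrates from a fresh overlapping configuration.
#' @param n_mcs_eq equilibration MCS discarded before sampling.
#' @param n_mcs_sample MCS over which the separation is averaged (sampled
#'   every MCS).
#' @param n_blocks number of blocks for the batch-means standard error.
#' @param interchain_exclusion as in [seg_state()].
#' @return a `data.frame` of class `force_distance_curve` with columns
#'   `force`, `mean_distance`, `stderr`, `n_samples`.
#' @export
force_distance_curve <- function(forces, field = tether_field("none"),
                                 box = confinement_box(), N = 80L,
                                 seed = NULL, n_mcs_eq = 2e4,
                                 n_mcs_sample = 5e4, n_mix = 50000L,
                                 n_blocks = 20L,
                                 interchain_exclusion = TRUE) {
  if (any(forces < 0)) stop("forces must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(forces, function(f) {
    st <- init_overlapping_rings(box, N, n_mix = n_mix,
                                 interchain_exclusion = interchain_exclusion)
    r <- run_mcs(st, field, n_mcs = n_mcs_eq, force = f)
    r <- run_mcs(r$state, field, n_mcs = n_mcs_sample, force = f,
                 record_every = 1)
    d <- abs(r$cm$cm_rel_1 - r$cm$cm_rel_2) * box$Lx
    d <- d[-1]  # drop the pre-sweep sample
    blocks <- split(d, cut(seq_along(d), n_blocks, labels = FALSE))
    bm <- vapply(blocks, mean, numeric(1))
    data.frame(force = f, mean_distance = mean(d),
               stderr = sd(bm) / sqrt(length(bm)), n_samples = length(d))
  })
  structure(do.call(rbind, out),
            class = c("force_distance_curve", "data.frame"))
}

#' @export
plot.force_distance_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add)
    plot(x$mean_distance, x$force, type = "b", col = col,
         xlab = "CM separation (lattice units)",
         ylab = "balancing force (kT / lattice unit)", ...)
  else {
    lines(x$mean_distance, x$force, type = "b", col = col, ...)
  }
  invisible(x)
}
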