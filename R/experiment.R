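## Experiment orchestration: named simulation conditions, replicate
## ensembles with documented seeding, condition comparison, config files,
## and deterministic fixture generation.

#' Default simulation configuration
#'
#' The study conditions: an 80 x 10 x 10 box, rings of N = 80, weak and
#' transient tethering (`p_max = 0.03` per MCS, mean dwell 100 MCS, so a
#' pole-proximal membrane monomer is held roughly three-quarters of the
#' time and released many times per oscillation), a linear gradient
#' (steepness 1), border distance 1, oscillation half-cycle 2500 MCS
#' (the Min cycle is fast compared with chromosome relaxation), a 5e4 MCS
#' mixing phase producing an entangled mid-cell initial state, and a 5e5
#' MCS run budget, by which the CM trajectories have reached their
#' steady-state positions.
#'
#' @return a named list of configuration values.
#' @export
default_config <- function() {
  list(Lx = 80L, Ly = 10L, Lz = 10L, N = 80L,
       p_max = 0.03, steepness = 1, dwell_mean = 100, period = 2500,
       border_distance = 1, n_mcs = 5e5, n_mix = 50000L,
       mind_period_s = 84, mind_shape = "linear", mind_sharpness = 2,
       mind_n_bins = 40L, mind_frame_dt = 7, mind_noise_sd = 0.1,
       mind_seed = 421L)
}

#' Map a named condition to a simulator configuration
#'
#' Conditions differ from the base configuration only in the fields their
#' names imply:
#' \describe{
#'   \item{`no_tether`}{tethering off; purely entropic repulsion.}
#'   \item{`uniform`}{tethering sites uniform along the cell.}
#'   \item{`static_gradient`}{static polar gradient.}
#'   \item{`oscillating_gradient`}{pole-to-pole alternating gradient.}
#'   \item{`mind_profile`}{gradient driven by a synthetic MinD oscillation
#'     profile series (period matched to the idealized oscillation).}
#'   \item{`entropy_off_gradient`}{static gradient with inter-polymer
#'     excluded volume disabled.}
#'   \item{`dwell_x10`}{static gradient with 10-fold longer dwell time.}
#'   \item{`steepness_sweep`}{static gradient at a given `steepness`.}
#' }
#'
#' @param condition condition name.
#' @param base base configuration, see [default_config()].
#' @param steepness gradient exponent used by `steepness_sweep`.
#' @param profile optional [min_profile_series()] for `mind_profile`
#'   (a noise-free synthetic series is generated when omitted).
#' @return list with elements `field` (a [tether_field()]),
#'   `interchain_exclusion`, `box`, `N`, `n_mcs`, `n_mix`, `condition`.
#' @export
condition_config <- function(condition, base = default_config(),
                             steepness = base$steepness, profile = NULL) {
  conditions <- c("no_tether", "uniform", "static_gradient",
                  "oscillating_gradient", "mind_profile",
                  "entropy_off_gradient", "dwell_x10", "steepness_sweep")
  if (!condition %in% conditions)
    stop("unknown condition '", condition, "'; valid: ",
         paste(conditions, collapse = ", "))
  tf <- function(mode, dwell = base$dwell_mean, s = base$steepness,
                 prof = NULL)
    tether_field(mode, p_max = base$p_max, steepness = s,
                 dwell_mean = dwell, period = base$period,
                 border_distance = base$border_distance, profile = prof)
  field <- switch(condition,
    no_tether = tether_field("none"),
    uniform = tf("uniform"),
    static_gradient = tf("static_gradient"),
    oscillating_gradient = tf("oscillating_gradient"),
    mind_profile = {
      if (is.null(profile))
        profile <- synthesize_min_oscillation(
          period_s = base$mind_period_s, n_bins = base$mind_n_bins,
          shape = base$mind_shape, sharpness = base$mind_sharpness,
          frame_dt = base$mind_frame_dt, noise_sd = base$mind_noise_sd,
          seed = base$mind_seed)
      tf("mind_profile", prof = profile)
    },
    entropy_off_gradient = tf("static_gradient"),
    dwell_x10 = tf("static_gradient", dwell = 10 * base$dwell_mean),
    steepness_sweep = tf("static_gradient", s = steepness))
  list(condition = condition, field = field,
       interchain_exclusion = condition != "entropy_off_gradient",
       box = confinement_box(base$Lx, base$Ly, base$Lz), N = base$N,
       n_mcs = base$n_mcs, n_mix = base$n_mix)
}

#' Experiment specification
#'
#' @param condition condition name, see [condition_config()].
#' @param n_replicates independent runs.
#' @param seed_base replicate i uses seed `seed_base + i`.
#' @param n_mcs MCS budget per run (overrides the base config).
#' @param base base configuration list.
#' @param record_every CM-trace recording interval, MCS.
#' @param trailing_window final positions are time-averaged over this many
#'   trailing MCS of the recorded trace (a lower-noise estimate of the
#'   steady-state position than the last configuration alone); ignored
#'   when no trace is recorded.
#' @param output_dir optional directory for per-run CSV traces, the
#'   ensemble JSON summary and the manifest.
#' @param ... passed to [condition_config()] (`steepness`, `profile`).
#' @return list of class `experiment_spec`.
#' @export
experiment_spec <- function(condition, n_replicates = 64L, seed_base = 1L,
                            n_mcs = NULL, base = default_config(),
                            record_every = 1000, trailing_window = 5e4,
                            output_dir = NULL, ...) {
  cfg <- condition_config(condition, base = base, ...)
  if (!is.null(n_mcs)) cfg$n_mcs <- n_mcs
  structure(list(condition = condition, config = cfg, base = base,
                 n_replicates = as.integer(n_replicates),
                 seed_base = as.integer(seed_base),
                 record_every = record_every,
                 trailing_window = trailing_window,
                 output_dir = output_dir),
            class = "experiment_spec")
}

#' Run a replicate ensemble of segregation simulations
#'
#' Executes `n_replicates` independent runs of the spec's condition, each
#' seeded with `seed_base + replicate` (initialization and trajectory
#' together), and collects final CM positions and CM traces.  When the
#' spec has an `output_dir`, per-run traces (CSV), an ensemble summary
#' (JSON) and a manifest recording the full configuration and seeds are
#' written there.
#'
#' `left`/`right` in `finals` refer to the polymer measured on the left
#' or right side at the end of the run (the rings occasionally slide past
#' one another, so the t = 0 labels stored in the state need not match
#' the final sides).
#'
#' @param spec an [experiment_spec()].
#' @param progress print one line per replicate to stderr.
#' @return an object of class `seg_ensemble`: list with `spec`, `finals`
#'   (data.frame: `replicate`, `seed`, `left`, `right`, `abs_mean`),
#'   `traces` (per-replicate CM data.frames), `delta` (mean of
#'   `abs_mean`), and `drift` (mean absolute CM drift per polymer over
#'   the trailing 20% of the trajectory, a steady-state diagnostic).
#' @export
run_experiment <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  cfg <- spec$config
  finals <- vector("list", spec$n_replicates)
  traces <- vector("list", spec$n_replicates)
  for (i in seq_len(spec$n_replicates)) {
    seed <- spec$seed_base + i
    st <- init_overlapping_rings(cfg$box, cfg$N, seed = seed,
                                 n_mix = cfg$n_mix,
                                 interchain_exclusion =
                                   cfg$interchain_exclusion)
    r <- run_mcs(st, cfg$field, n_mcs = cfg$n_mcs,
                 record_every = spec$record_every)
    st <- r$state
    if (!is.null(r$cm) && spec$trailing_window > 0) {
      keep <- r$cm$mcs > max(r$cm$mcs) - spec$trailing_window
      cm <- colMeans(r$cm[keep, -1, drop = FALSE])
    } else {
      cm <- vapply(1:2, function(p)
        center_of_mass_rel(polymer_positions(st, p), st$box), numeric(1))
    }
    finals[[i]] <- data.frame(replicate = i, seed = seed,
                              left = min(cm), right = max(cm),
                              abs_mean = mean(abs(cm)))
    traces[[i]] <- r$cm
    if (progress)
      message(sprintf("[%s] replicate %d/%d: |cm| = %.3f", spec$condition,
                      i, spec$n_replicates, finals[[i]]$abs_mean))
  }
  finals <- do.call(rbind, finals)
  drift <- trailing_drift(traces)
  ens <- structure(list(spec = spec, finals = finals, traces = traces,
                        delta = mean(finals$abs_mean), drift = drift),
                   class = "seg_ensemble")
  if (!is.null(spec$output_dir)) write_ensemble(ens, spec$output_dir)
  ens
}

## mean absolute CM change per polymer over the trailing 20% of the trace
trailing_drift <- function(traces) {
  if (is.null(traces[[1]])) return(NA_real_)
  mean(vapply(traces, function(tr) {
    n <- nrow(tr)
    i0 <- max(1L, floor(0.8 * n))
    mean(abs(as.matrix(tr[n, -1, drop = FALSE]) -
             as.matrix(tr[i0, -1, drop = FALSE])))
  }, numeric(1)))
}

#' @export
print.seg_ensemble <- function(x, ...) {
  cat(sprintf(
    "<seg_ensemble: %s, %d replicates x %g MCS, Delta = %.3f>\n",
    x$spec$condition, x$spec$n_replicates, x$spec$config$n_mcs, x$delta))
  invisible(x)
}

#' @export
plot.seg_ensemble <- function(x, what = c("traces", "finals"), ...) {
  what <- match.arg(what)
  if (what == "traces") {
    tr <- x$traces[[1]]
    matplot(tr$mcs, as.matrix(tr[, -1]), type = "l", lty = 1,
            ylim = c(-0.5, 0.5), xlab = "MCS",
            ylab = "CM position (relative to cell length)", ...)
    for (t2 in x$traces[-1])
      matplot(t2$mcs, as.matrix(t2[, -1]), type = "l", lty = 1,
              add = TRUE, ...)
    abline(h = 0, lty = 3)
  } else {
    hist(x$finals$right, breaks = seq(-0.5, 0.5, by = 0.05),
         xlab = "final CM of right polymer", main = x$spec$condition, ...)
  }
  invisible(x)
}

write_ensemble <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ens$traces))
    if (!is.null(ens$traces[[i]]))
      utils::write.csv(ens$traces[[i]],
                       file.path(dir, sprintf("run_%03d.csv", i)),
                       row.names = FALSE)
  utils::write.csv(ens$finals, file.path(dir, "finals.csv"),
                   row.names = FALSE)
  cfg <- ens$spec$base
  manifest <- list(
    condition = ens$spec$condition,
    n_replicates = ens$spec$n_replicates,
    seed_base = ens$spec$seed_base,
    seeds = ens$finals$seed,
    n_mcs = ens$spec$config$n_mcs,
    config = cfg,
    field = unclass(ens$spec$config$field[
      c("mode", "p_max", "steepness", "dwell_mean", "period",
        "border_distance")]),
    interchain_exclusion = ens$spec$config$interchain_exclusion,
    config_hash = config_hash(ens$spec),
    package_version = as.character(packageVersion("minratchet")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(
    list(delta = ens$delta, drift = ens$drift,
         mean_right = mean(ens$finals$right),
         sd_right = sd(ens$finals$right)),
    file.path(dir, "ensemble.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

config_hash <- function(spec) {
  s <- paste(deparse(spec[c("condition", "config", "base")]), collapse = "")
  ## small rolling hash; stable across sessions
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %% 1e9
}

#' Time to half separation
#'
#' Per replicate, the first recorded MCS at which the run's mean |cm_rel|
#' reaches `threshold` (`Inf` when never reached).  Used to compare
#' segregation speed between conditions.
#'
#' @param ens a `seg_ensemble` with recorded traces.
#' @param threshold the |cm_rel| level to reach; typically half of a
#'   reference condition's final separation.
#' @return numeric vector, one value per replicate.
#' @export
time_to_half_separation <- function(ens, threshold) {
  vapply(ens$traces, function(tr) {
    m <- rowMeans(abs(as.matrix(tr[, -1, drop = FALSE])))
    i <- which(m >= threshold)
    if (length(i)) tr$mcs[min(i)] else Inf
  }, numeric(1))
}

#' Compare segregation between conditions
#'
#' Pairwise one-sided rank tests (Mann-Whitney) on the per-replicate
#' final mean |cm_rel| (the separation statistic), reporting effect
#' direction, the difference of ensemble Delta values, and significance.
#' Final-CM distributions are bounded and non-Gaussian, so a rank test is
#' used rather than a t test.
#'
#' @param ... two or more `seg_ensemble` objects (or a single list of
#'   them), run on identical base configurations.
#' @param alpha significance level.
#' @return `data.frame` of class `condition_comparison` with one row per
#'   ordered pair: `a`, `b`, `delta_a`, `delta_b`, `effect`
#'   (`delta_a - delta_b`), `p_greater` (one-sided: a > b), and
#'   `significant`.
#' @export
compare_conditions <- function(..., alpha = 0.05) {
  ens <- list(...)
  if (length(ens) == 1L && !inherits(ens[[1]], "seg_ensemble"))
    ens <- ens[[1]]
  if (length(ens) < 2L) stop("need at least two ensembles to compare")
  for (e in ens) stopifnot(inherits(e, "seg_ensemble"))
  key <- vapply(ens, function(e)
    paste(e$spec$base$Lx, e$spec$base$N, e$spec$config$n_mcs), character(1))
  if (length(unique(key)) != 1L)
    stop("ensembles were run on different base configurations")
  nm <- vapply(ens, function(e) e$spec$condition, character(1))
  out <- list()
  for (i in seq_along(ens)) for (j in seq_along(ens)) {
    if (i == j) next
    a <- ens[[i]]$finals$abs_mean
    b <- ens[[j]]$finals$abs_mean
    p <- wilcox.test(a, b, alternative = "greater", exact = FALSE)$p.value
    out[[length(out) + 1L]] <- data.frame(
      a = nm[i], b = nm[j], delta_a = mean(a), delta_b = mean(b),
      effect = mean(a) - mean(b), p_greater = p,
      significant = p < alpha)
  }
  structure(do.call(rbind, out),
            class = c("condition_comparison", "data.frame"))
}

## ---- config files ----------------------------------------------------------

#' Read / write a flat run configuration file
#'
#' Flat YAML key-value files holding the fields of [default_config()]
#' plus optional `condition`, `n_replicates`, `seed_base`.
#'
#' @param path file path.
#' @return `read_run_config`: named list merged over [default_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed config file: ", path)
  base <- default_config()
  unknown <- setdiff(names(cfg),
                     c(names(base), "condition", "n_replicates", "seed_base"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  base[names(cfg)] <- cfg
  base
}

#' @rdname read_run_config
#' @param config a named list of configuration values.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## ---- fixtures --------------------------------------------------------------

#' Generate the deterministic test fixture bundle
#'
#' Writes small plain-text inputs used by tests and examples: a ring-of-4
#' state in a 6x6x6 box, a 2-frame MinD profile, a two-Gaussian intensity
#' profile, and 100 Brownian focus tracks.  Byte-identical for the same
#' seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return invisibly, the paths written.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  paths <- character()
  ## ring of 4 in a small cube
  box <- confinement_box(6, 6, 6)
  st <- seg_state(box, ring_template(box, 4L, 1L, 1L), n_polymers = 1L)
  p <- file.path(dir, "ring4_state.tsv")
  write_state(st, p); paths <- c(paths, p)
  ## 2-frame MinD profile
  prof <- min_profile_series(c(0, 7), (1:10 - 0.5) / 10,
                             rbind(exp(-4 * ((1:10 - 0.5) / 10)),
                                   exp(-4 * (1 - (1:10 - 0.5) / 10))))
  p <- file.path(dir, "min_profile_2frame.tsv")
  write_min_profile(prof, p); paths <- c(paths, p)
  ## two-Gaussian intensity profile
  x <- seq(-2, 2, length.out = 101)
  y <- exp(-(x + 1)^2 / (2 * 0.2^2)) + exp(-(x - 1)^2 / (2 * 0.2^2))
  p <- file.path(dir, "two_gaussian_profile.csv")
  utils::write.csv(data.frame(position = x, intensity = y), p,
                   row.names = FALSE); paths <- c(paths, p)
  ## Brownian tracks
  tr <- simulate_focus_tracks(100L, 20L, dt = 0.05, D0 = 0.01, seed = seed)
  p <- file.path(dir, "brownian_tracks.csv")
  utils::write.csv(tr, p, row.names = FALSE); paths <- c(paths, p)
  invisible(paths)
}
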