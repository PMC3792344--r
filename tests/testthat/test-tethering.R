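test_that("border eligibility is lateral-only", {
  box <- confinement_box()
  expect_true(is_at_border(c(40L, 0L, 4L), box))    # touching y = 0 wall
  expect_true(is_at_border(c(40L, 9L, 4L), box))    # touching y = Ly wall
  expect_true(is_at_border(c(40L, 4L, 0L), box))    # touching z = 0 wall
  expect_false(is_at_border(c(40L, 4L, 4L), box))   # box centre
  ## the pole caps are not tether-eligible
  expect_false(is_at_border(c(0L, 4L, 4L), box))
  expect_false(is_at_border(c(79L, 4L, 4L), box))
  ## wider border distance reaches one layer further in
  expect_true(is_at_border(c(40L, 1L, 4L), box, d_b = 2))
  expect_false(is_at_border(c(40L, 1L, 4L), box, d_b = 1))
})

test_that("binding probability implements each field mode", {
  box <- confinement_box()
  x <- c(0, 20, 40, 60, 80)
  f0 <- tether_field("none")
  expect_equal(binding_probability(x, 0, f0, box), rep(0, 5))
  fu <- tether_field("uniform", p_max = 0.2)
  expect_equal(binding_probability(x, 0, fu, box), rep(0.2, 5))
  fs <- tether_field("static_gradient", p_max = 0.2, steepness = 1)
  expect_equal(binding_probability(40, 0, fs, box), 0)          # mid-cell
  expect_equal(binding_probability(c(0, 80), 0, fs, box),
               c(0.2, 0.2))                                     # poles
  expect_equal(binding_probability(20, 0, fs, box), 0.1)        # linear
  ## steepness bends the profile but keeps the endpoints
  fs2 <- tether_field("static_gradient", p_max = 0.2, steepness = 2)
  expect_equal(binding_probability(20, 0, fs2, box), 0.05)
  expect_equal(binding_probability(c(0, 40, 80), 0, fs2, box), c(0.2, 0, 0.2))
  ## steepness 0 degenerates to the uniform field
  fs0 <- tether_field("static_gradient", p_max = 0.2, steepness = 0)
  expect_equal(binding_probability(c(3, 41), 0, fs0, box), c(0.2, 0.2))
  expect_error(binding_probability(81, 0, fs, box), "outside")
})

test_that("oscillating gradient activates the two halves alternately and equally", {
  box <- confinement_box()
  fo <- tether_field("oscillating_gradient", p_max = 0.2, period = 100)
  ## first half-cycle: left half active, right half silent
  expect_gt(binding_probability(10, 0, fo, box), 0)
  expect_equal(binding_probability(70, 0, fo, box), 0)
  ## second half-cycle: sides swap
  expect_equal(binding_probability(10, 150, fo, box), 0)
  expect_gt(binding_probability(70, 150, fo, box), 0)
  ## equal active time for both halves over a full period, and symmetry of
  ## the time-averaged field about mid-cell
  ts <- seq(0, 199)
  pl <- vapply(ts, function(t) binding_probability(10, t, fo, box), numeric(1))
  pr <- vapply(ts, function(t) binding_probability(70, t, fo, box), numeric(1))
  expect_equal(sum(pl > 0), 100L)
  expect_equal(sum(pr > 0), 100L)
  expect_equal(mean(pl), mean(pr))
})

test_that("compiled field evaluation matches the R reference on a grid", {
  box <- confinement_box()
  xs <- 0:79
  prof <- synthesize_min_oscillation(period_s = 84, sharpness = 4)
  fields <- list(
    tether_field("uniform", p_max = 0.15),
    tether_field("static_gradient", p_max = 0.15, steepness = 0.5),
    tether_field("oscillating_gradient", p_max = 0.15, period = 1234),
    tether_field("mind_profile", p_max = 0.15, profile = prof,
                 mcs_per_second = 50))
  for (f in fields) {
    for (mcs in c(1, 700, 2500, 9999)) {
      cpp <- drop(minratchet:::.field_probability_cpp(minratchet:::field_to_cpp(f, box),
                                         c(box$Lx, box$Ly, box$Lz),
                                         xs, mcs))
      ref <- binding_probability(xs + 0.5, mcs, f, box)
      expect_equal(cpp, ref, tolerance = 1e-12)
    }
  }
})

test_that("frozen-system limit: saturating field binds everything at once", {
  st <- init_overlapping_rings(seed = 2, n_mix = 100)
  f <- tether_field("uniform", p_max = 1, dwell_mean = Inf,
                    border_distance = 10)
  r <- run_mcs(st, f, n_mcs = 1)
  expect_true(all(r$state$bound))
  pos1 <- r$state$pos
  r2 <- run_mcs(r$state, f, n_mcs = 50)
  expect_identical(r2$state$pos, pos1)   # frozen: no move ever accepted
  expect_equal(r2$accepted, 0)
})

test_that("a bound monomer does not move until its release time", {
  st <- ring4_state(box = confinement_box(10, 10, 10), x0 = 4L, y0 = 4L,
                    z0 = 4L)
  st$bound[2] <- TRUE
  st$release[2] <- 30   # released once the clock passes 30 MCS
  set.seed(9)
  r <- run_mcs(st, tether_field("none"), n_mcs = 29,
               record_positions_every = 1)
  expect_true(all(r$pos_samples[, 2, ] == st$pos[2, ]))
  expect_true(r$state$bound[2])
  r2 <- run_mcs(r$state, tether_field("none"), n_mcs = 500)
  expect_false(r2$state$bound[2])
  expect_false(all(r2$state$pos[2, ] == st$pos[2, ]))
})

test_that("mode 'none' and p_max = 0 give bit-identical trajectories", {
  st <- init_overlapping_rings(seed = 21, n_mix = 100)
  set.seed(55)
  a <- run_mcs(st, tether_field("none"), n_mcs = 400)
  for (mode in c("uniform", "static_gradient", "oscillating_gradient")) {
    set.seed(55)
    b <- run_mcs(st, tether_field(mode, p_max = 0), n_mcs = 400)
    expect_identical(b$state$pos, a$state$pos)
    expect_false(any(b$state$bound))
  }
})

test_that("realized dwell times are geometric with the requested mean", {
  st <- init_overlapping_rings(seed = 4, n_mix = 200)
  f <- tether_field("uniform", p_max = 0.3, dwell_mean = 25)
  set.seed(12)
  r <- run_mcs(st, f, n_mcs = 4000, log_bindings = TRUE)
  dw <- r$bind_log$dwell
  expect_gt(length(dw), 1e4)
  expect_lt(abs(mean(dw) - 25) / 25, 0.05)
  ## geometric shape: sd ~ sqrt(mean*(mean-1))
  expect_lt(abs(sd(dw) - sqrt(25 * 24)) / sqrt(25 * 24), 0.1)
  ## every bound monomer's release obeys the drawn dwell
  expect_true(all(r$bind_log$dwell >= 1))
})

test_that("binding events follow the gradient shape along the axis", {
  st <- init_overlapping_rings(seed = 14, n_mix = 200)
  f <- tether_field("static_gradient", p_max = 0.2, dwell_mean = 10)
  set.seed(77)
  r <- run_mcs(st, f, n_mcs = 20000, log_bindings = TRUE)
  obs <- r$bind_events
  exp_counts <- r$bind_expected   # sum over exposure of p(x, t)
  keep <- exp_counts >= 5
  expect_gt(sum(obs), 5e3)
  ## conditional on exposure, binding is Bernoulli(p(x)): chi-square GOF
  chi <- sum((obs[keep] - exp_counts[keep])^2 / exp_counts[keep])
  p <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
  ## and no events at all where the field vanishes (mid-cell bins)
  expect_equal(sum(obs[exp_counts == 0]), 0)
})
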