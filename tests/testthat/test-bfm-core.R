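test_that("allowed bond set matches its independent characterisation", {
  bs <- allowed_bond_set()
  expect_equal(nrow(bs), 108L)
  expect_true(all(rowSums(bs^2) %in% c(4, 5, 6, 9, 10)))
  ## set equality with the squared-length derivation
  expect_identical(vec_key(bs), vec_key(bond_set_by_norm()))
  expect_true(bond_allowed(c(2, 0, 0)))
  expect_true(bond_allowed(c(-2, 1, -1)))
  expect_false(bond_allowed(c(4, 0, 0)))
  expect_false(bond_allowed(c(1, 1, 1)))
  expect_false(bond_allowed(c(2, 2, 2)))
})

test_that("overlapping-ring initialization honours its contract", {
  box <- confinement_box()
  st <- init_overlapping_rings(box, N = 80, seed = 11, n_mix = 300)
  expect_silent(validate_state(st))
  cm <- vapply(1:2, function(p)
    mean(polymer_positions(st, p)[, 1]) + 0.5, numeric(1))
  expect_true(all(abs(cm - box$Lx / 2) <= 1.0))
  ## both rings occupy 8 sites per monomer, no collisions
  occ <- occupancy_map(st)
  expect_equal(sum(occ == 1L) + sum(occ == 2L) + 2L * sum(occ == 3L),
               2L * 80L * 8L)
  expect_equal(sum(occ == 3L), 0L)  # exclusion on: no shared sites
  ## axial extents overlap by at least half of the smaller extent
  ext <- lapply(1:2, function(p) range(polymer_positions(st, p)[, 1]))
  ov <- min(ext[[1]][2], ext[[2]][2]) - max(ext[[1]][1], ext[[2]][1]) + 2
  expect_gte(ov, 0.5 * min(diff(ext[[1]]) + 2, diff(ext[[2]]) + 2))
  ## labels are a partition of the two polymers
  expect_setequal(unlist(st$labels), 1:2)
})

test_that("initialization is deterministic given the seed", {
  a <- init_overlapping_rings(seed = 5, n_mix = 200)
  b <- init_overlapping_rings(seed = 5, n_mix = 200)
  expect_identical(a$pos, b$pos)
  expect_identical(a$labels, b$labels)
  c <- init_overlapping_rings(seed = 6, n_mix = 200)
  expect_false(identical(a$pos, c$pos))
})

test_that("initialization fails clearly when the box cannot hold the rings", {
  expect_error(init_overlapping_rings(confinement_box(10, 10, 10), N = 80),
               "axial span")
  expect_error(init_overlapping_rings(confinement_box(80, 6, 6), N = 80),
               "lateral")
  expect_error(init_overlapping_rings(confinement_box(), N = 82),
               "divisible by 4")
})

test_that("single-move acceptance rules reject each forbidden case", {
  st <- ring4_state()  # ring in the box corner
  ## (a) wall: monomer 1 at the origin cannot move into the wall
  expect_false(attempt_move(st, 1, 1, c(-1, 0, 0))$accepted)
  expect_false(attempt_move(st, 1, 1, c(0, -1, 0))$accepted)
  ## (b) bond stretch: moving monomer 1 away from monomer 2 would need a
  ## (3,0,0) -> fine, but away from both neighbours (+z keeps bonds) --
  ## moving +x gives bonds (1,0,0) [invalid] to monomer 2
  expect_false(attempt_move(st, 1, 1, c(1, 0, 0))$accepted)
  ## +z is allowed: both bonds become (2,0,-1)-type, still in the set
  mv <- attempt_move(st, 1, 1, c(0, 0, 1))
  expect_true(mv$accepted)
  expect_equal(mv$state$pos[1, ], c(x = 0L, y = 0L, z = 1L))
  expect_silent(validate_state(mv$state))
  ## (c) tethered monomer never moves
  st2 <- st
  st2$bound[1] <- TRUE; st2$release[1] <- Inf
  expect_false(attempt_move(st2, 1, 1, c(0, 0, 1))$accepted)
  ## (d) excluded volume: a second ring right next to the first blocks it
  st3 <- seg_state(confinement_box(8, 8, 8),
                   rbind(ring4_positions(0L, 0L, 0L),
                         ring4_positions(0L, 0L, 2L)), n_polymers = 2L)
  expect_false(attempt_move(st3, 1, 1, c(0, 0, 1))$accepted)
  ## the same move is allowed once inter-chain exclusion is off
  st4 <- seg_state(confinement_box(8, 8, 8),
                   rbind(ring4_positions(0L, 0L, 0L),
                         ring4_positions(0L, 0L, 2L)), n_polymers = 2L,
                   interchain_exclusion = FALSE)
  expect_true(attempt_move(st4, 1, 1, c(0, 0, 1))$accepted)
  ## rejection leaves the state untouched
  expect_identical(attempt_move(st, 1, 1, 2)$state$pos, st$pos)
  ## index errors
  expect_error(attempt_move(st, 1, 9, 1), "monomer index")
  expect_error(attempt_move(st, 3, 1, 1), "polymer index")
})

test_that("compiled kernel agrees with the R reference move-by-move", {
  ## replay every logged proposal through the pure-R attempt_move and
  ## compare acceptance decisions and final configuration
  set.seed(33)
  st <- ring4_state()
  run <- run_mcs(st, tether_field("none"), n_mcs = 300, log_moves = TRUE)
  replay <- st
  for (i in seq_len(nrow(run$move_log))) {
    m <- run$move_log$monomer[i]
    out <- attempt_move(replay, (m - 1) %/% replay$N + 1,
                        (m - 1) %% replay$N + 1,
                        run$move_log$direction[i])
    expect_identical(out$accepted, run$move_log$accepted[i] == 1L)
    replay <- out$state
  }
  expect_identical(replay$pos, run$state$pos)
})

test_that("kernel agrees with the R reference for two interacting rings", {
  set.seed(91)
  st <- seg_state(confinement_box(8, 8, 8),
                  rbind(ring4_positions(0L, 0L, 0L),
                        ring4_positions(0L, 0L, 2L)), n_polymers = 2L)
  run <- run_mcs(st, tether_field("none"), n_mcs = 200, log_moves = TRUE)
  replay <- st
  for (i in seq_len(nrow(run$move_log))) {
    m <- run$move_log$monomer[i]
    out <- attempt_move(replay, (m - 1) %/% replay$N + 1,
                        (m - 1) %% replay$N + 1,
                        run$move_log$direction[i])
    expect_identical(out$accepted, run$move_log$accepted[i] == 1L)
    replay <- out$state
  }
  expect_identical(replay$pos, run$state$pos)
})

test_that("run_mcs preserves every invariant, in all exclusion modes", {
  for (excl in c(TRUE, FALSE)) {
    st <- init_overlapping_rings(seed = 17, n_mix = 200,
                                 interchain_exclusion = excl)
    r <- run_mcs(st, tether_field("static_gradient"), n_mcs = 2000)
    expect_silent(validate_state(r$state))
    expect_equal(r$state$mcs, 2000)
    expect_equal(nrow(r$state$pos), 160L)
  }
  ## n_mcs = 0 is the identity
  st <- ring4_state()
  expect_identical(run_mcs(st, n_mcs = 0)$state, st)
})

test_that("identical seed gives an identical trajectory", {
  st <- init_overlapping_rings(seed = 3, n_mix = 100)
  set.seed(101)
  a <- run_mcs(st, tether_field("oscillating_gradient"), n_mcs = 1000,
               record_every = 100)
  set.seed(101)
  b <- run_mcs(st, tether_field("oscillating_gradient"), n_mcs = 1000,
               record_every = 100)
  expect_identical(a$state$pos, b$state$pos)
  expect_identical(a$cm, b$cm)
})

test_that("state snapshots round-trip through plain text", {
  st <- init_overlapping_rings(seed = 8, n_mix = 100)
  st$mcs <- 123
  path <- tempfile(fileext = ".tsv")
  write_state(st, path)
  st2 <- read_state(path)
  expect_identical(st2$pos, st$pos)
  expect_equal(st2$mcs, 123)
  expect_identical(st2$box, st$box)
  expect_silent(validate_state(st2))
})

test_that("ring-of-4 state-space enumeration has the expected structure", {
  ## counts frozen from an independent brute-force enumeration
  en4 <- minratchet:::.ring4_enumerate_cpp(4L)
  expect_equal(en4$n_states, 286992)
  expect_equal(sum(en4$pos_counts), en4$n_states)
  expect_equal(sum(en4$bond_counts), 4 * en4$n_states)
  ## the marginal is symmetric under the cube's reflections
  pc <- array(en4$pos_counts, dim = c(4, 4, 4))
  expect_equal(pc, pc[4:1, , ])
  expect_equal(pc, aperm(pc, c(2, 1, 3)))
})
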