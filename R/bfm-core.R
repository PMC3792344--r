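## Bond-fluctuation-method core: box, bond set, ring construction,
## system state, single-move reference implementation, and the MCS loop.
##
## Lattice conventions: a monomer at integer position (x, y, z) occupies the
## 8 corner sites of the unit cube [x, x+1] x [y, y+1] x [z, z+1].  The box
## [0, Lx] x [0, Ly] x [0, Lz] is hard-walled, so positions range 0..L-1 on
## each axis.  The long (segregation) axis is x.

#' Rod-shaped confinement box
#'
#' The default 80 x 10 x 10 box has the 1:8 aspect ratio of an *E. coli*
#' cell; with rings of N = 80 monomers each chain fills roughly 8% of the
#' box volume and the free-chain radius of gyration exceeds the lateral box
#' size, so the chains are strongly confined.
#'
#' @param Lx,Ly,Lz positive integer box edge lengths in lattice units;
#'   `Lx` is the long cell axis.
#' @return an object of class `seg_box`.
#' @export
#' @examples
#' confinement_box()          # the standard cell geometry
#' confinement_box(6, 6, 6)   # small cube used for exactness tests
confinement_box <- function(Lx = 80L, Ly = 10L, Lz = 10L) {
  Lx <- as.integer(Lx); Ly <- as.integer(Ly); Lz <- as.integer(Lz)
  if (any(is.na(c(Lx, Ly, Lz))) || any(c(Lx, Ly, Lz) < 3L))
    stop("box edges must be integers >= 3 lattice units")
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz), class = "seg_box")
}

#' @export
print.seg_box <- function(x, ...) {
  cat(sprintf("<confinement box %d x %d x %d (aspect %.2g:1)>\n",
              x$Lx, x$Ly, x$Lz, x$Lx / max(x$Ly, x$Lz)))
  invisible(x)
}

#' The allowed bond-vector set of the bond-fluctuation method
#'
#' All permutations and sign combinations of (2,0,0), (2,1,0), (2,1,1),
#' (2,2,1), (3,0,0) and (3,1,0): 108 vectors with squared lengths in
#' \{4, 5, 6, 9, 10\}.  Restricting ring bonds to this set (together with
#' excluded volume) guarantees that chains can never cross each other
#' during single-monomer unit moves.
#'
#' @return an integer matrix with 108 rows and columns `dx`, `dy`, `dz`.
#' @export
allowed_bond_set <- function() {
  base <- rbind(c(2, 0, 0), c(2, 1, 0), c(2, 1, 1),
                c(2, 2, 1), c(3, 0, 0), c(3, 1, 0))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- matrix(0L, 0L, 3L)
  for (i in seq_len(nrow(base)))
    for (j in seq_len(nrow(perms)))
      for (k in seq_len(nrow(signs)))
        out <- rbind(out, as.integer(base[i, perms[j, ]] * signs[k, ]))
  out <- unique(out)
  colnames(out) <- c("dx", "dy", "dz")
  out
}

#' Test bond vectors for membership in the allowed set
#'
#' @param v an integer 3-vector or a matrix with one bond vector per row.
#' @return logical vector of membership.
#' @export
bond_allowed <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  q <- rowSums(v^2)
  q %in% c(4, 5, 6, 9, 10)
}

## ---- system state ----------------------------------------------------------

#' Assemble a system state from monomer positions
#'
#' Low-level constructor; most users should call
#' [init_overlapping_rings()].  Monomers of polymer 1 occupy rows
#' `1..N`, polymer 2 rows `N+1..2N`; each polymer is a closed ring in row
#' order.
#'
#' @param box a [confinement_box()].
#' @param pos integer matrix (`n_polymers * N` x 3) of lattice positions
#'   (lower cube corners, 0-based).
#' @param n_polymers 1 or 2.
#' @param interchain_exclusion if `FALSE`, excluded volume between the two
#'   polymers is ignored (each chain remains self-avoiding); used for runs
#'   probing segregation without entropic repulsion.
#' @param validate run the full invariant check (bond set, self-avoidance,
#'   confinement).
#' @return an object of class `seg_state`.
#' @export
seg_state <- function(box, pos, n_polymers = 2L, interchain_exclusion = TRUE,
                      validate = TRUE) {
  stopifnot(inherits(box, "seg_box"))
  pos <- matrix(as.integer(pos), ncol = 3L,
                dimnames = list(NULL, c("x", "y", "z")))
  n_polymers <- as.integer(n_polymers)
  if (nrow(pos) %% n_polymers != 0L)
    stop("number of monomers not divisible by n_polymers")
  N <- nrow(pos) %/% n_polymers
  st <- structure(list(
    box = box, pos = pos, n_polymers = n_polymers, N = N,
    polymer = rep(seq_len(n_polymers), each = N),
    bound = rep(FALSE, nrow(pos)), release = rep(Inf, nrow(pos)),
    mcs = 0, interchain_exclusion = isTRUE(interchain_exclusion),
    labels = NULL), class = "seg_state")
  if (validate) validate_state(st)
  st
}

#' @export
print.seg_state <- function(x, ...) {
  cm <- vapply(seq_len(x$n_polymers), function(p)
    center_of_mass_rel(polymer_positions(x, p), x$box), numeric(1))
  cat(sprintf(
    "<seg_state: %d ring%s of N=%d in %dx%dx%d box, mcs=%g>\n",
    x$n_polymers, if (x$n_polymers > 1) "s" else "", x$N,
    x$box$Lx, x$box$Ly, x$box$Lz, x$mcs))
  cat(sprintf("  cm_rel: %s   tethered: %d/%d   interchain exclusion: %s\n",
              paste(sprintf("%+.3f", cm), collapse = " "),
              sum(x$bound), nrow(x$pos), x$interchain_exclusion))
  invisible(x)
}

#' Extract the positions of one polymer
#'
#' @param state a `seg_state`.
#' @param polymer polymer index (1 or 2), or one of `"left"`/`"right"` if
#'   labels have been assigned.
#' @return integer matrix `N` x 3.
#' @export
polymer_positions <- function(state, polymer = 1L) {
  if (is.character(polymer)) {
    if (is.null(state$labels)) stop("state has no left/right labels")
    polymer <- state$labels[[polymer]]
  }
  state$pos[state$polymer == polymer, , drop = FALSE]
}

#' Rebuild the lattice occupancy map of a state
#'
#' Returns the per-site occupancy as an integer array (0 = empty, otherwise
#' the owning polymer's bit mask), rebuilt from scratch from the monomer
#' positions.  Used by [validate_state()] and tests.
#'
#' @inheritParams polymer_positions
#' @return integer array of dimension `(Lx+1, Ly+1, Lz+1)`.
#' @export
occupancy_map <- function(state) {
  b <- state$box
  occ <- array(0L, dim = c(b$Lx + 1L, b$Ly + 1L, b$Lz + 1L))
  for (m in seq_len(nrow(state$pos))) {
    bit <- bitwShiftL(1L, state$polymer[m] - 1L)
    p <- state$pos[m, ]
    for (i in 0:1) for (j in 0:1) for (k in 0:1) {
      cur <- occ[p[1] + i + 1L, p[2] + j + 1L, p[3] + k + 1L]
      if (bitwAnd(cur, bit) != 0L)
        stop(sprintf("site (%d,%d,%d) doubly occupied within polymer %d",
                     p[1] + i, p[2] + j, p[3] + k, state$polymer[m]))
      occ[p[1] + i + 1L, p[2] + j + 1L, p[3] + k + 1L] <- bitwOr(cur, bit)
    }
  }
  occ
}

#' Validate every invariant of a system state
#'
#' Checks confinement, ring-bond validity (cyclically, including the
#' closing bond), intra-polymer self-avoidance, inter-polymer excluded
#' volume (when enabled), and the tether-state contract.  Errors with a
#' diagnostic on the first violation.
#'
#' @param state a `seg_state`.
#' @return `state`, invisibly, if valid.
#' @export
validate_state <- function(state) {
  b <- state$box
  pos <- state$pos
  if (any(pos < 0L) ||
      any(pos[, 1] > b$Lx - 1L) || any(pos[, 2] > b$Ly - 1L) ||
      any(pos[, 3] > b$Lz - 1L))
    stop("monomer cube extends outside the confinement box")
  for (p in seq_len(state$n_polymers)) {
    rp <- polymer_positions(state, p)
    nb <- rp[c(2:nrow(rp), 1L), , drop = FALSE] - rp
    bad <- which(!bond_allowed(nb))
    if (length(bad))
      stop(sprintf("polymer %d: bond %d -> %d not in the allowed set",
                   p, bad[1], bad[1] %% nrow(rp) + 1L))
  }
  occ <- occupancy_map(state)  # errors on intra-polymer overlap
  if (state$interchain_exclusion && state$n_polymers == 2L &&
      any(occ == 3L))
    stop("inter-polymer excluded-volume violation")
  if (any(state$bound & state$release <= state$mcs))
    stop("bound monomer with expired release time")
  invisible(state)
}

## ---- ring construction -----------------------------------------------------

## Four-pass rectangular ring template: m = N/4 monomers per axial pass,
## passes laid out on a 2x2 arrangement of lateral lanes spaced 2 lattice
## units apart, consecutive passes joined by (0,+-2,0)/(0,0,+-2) bonds.
ring_template <- function(box, N, lane_y, lane_z, x0 = NULL) {
  if (N %% 4L != 0L)
    stop("ring construction requires N divisible by 4 (got ", N, ")")
  m <- N %/% 4L
  span <- 2L * (m - 1L)
  if (is.null(x0)) x0 <- (box$Lx - 1L - span) %/% 2L
  if (x0 < 0L || x0 + span > box$Lx - 1L)
    stop(sprintf(paste0(
      "no valid ring configuration: N=%d needs an axial span of %d ",
      "lattice units but the box provides %d"), N, span + 1L, box$Lx))
  lanes <- cbind(y = c(lane_y, lane_y + 2L, lane_y + 2L, lane_y),
                 z = c(lane_z, lane_z, lane_z + 2L, lane_z + 2L))
  if (lane_y < 0L || lane_y + 2L > box$Ly - 1L ||
      lane_z < 0L || lane_z + 2L > box$Lz - 1L)
    stop("no valid ring configuration: lateral box too small for the ring template")
  pos <- matrix(0L, N, 3L)
  idx <- 1L
  for (pass in 1:4) {
    xs <- if (pass %% 2L == 1L) seq(x0, x0 + span, by = 2L)
          else seq(x0 + span, x0, by = -2L)
    if (m == 1L) xs <- x0
    for (x in xs) {
      pos[idx, ] <- c(x, lanes[pass, "y"], lanes[pass, "z"])
      idx <- idx + 1L
    }
  }
  pos
}

#' Initialize two overlapping rings at mid-cell
#'
#' Builds the mixed initial condition of a segregation run: two valid ring
#' polymers whose axial centres of mass lie within `cm_tol` lattice units
#' of mid-cell and whose axial extents overlap.  Construction is a
#' deterministic interleaved template (two four-pass rectangular rings
#' sharing the same axial window, stacked in different lateral lanes),
#' followed by `n_mix` MCS of Monte-Carlo mixing during which any move
#' that would take either axial CM outside the `cm_tol` window is
#' rejected.  Deterministic given the RNG seed.
#'
#' @param box a [confinement_box()].
#' @param N monomers per ring (divisible by 4); default 80.
#' @param seed optional integer seed passed to [set.seed()].
#' @param n_mix MCS of constrained mixing applied to roughen the template.
#' @param cm_tol half-width, in lattice units, of the axial CM window
#'   around mid-cell enforced during construction.
#' @param interchain_exclusion as in [seg_state()].
#' @return a `seg_state` with `left`/`right` polymer labels assigned by the
#'   sign of the axial CM offset (RNG tie-break).
#' @export
#' @examples
#' st <- init_overlapping_rings(confinement_box(), N = 80, seed = 1,
#'                              n_mix = 50)
#' st
init_overlapping_rings <- function(box = confinement_box(), N = 80L,
                                   seed = NULL, n_mix = 50000L, cm_tol = 1,
                                   interchain_exclusion = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N)
  if (box$Ly < 8L || box$Lz < 6L)
    stop("no valid double-ring configuration: lateral box too small ",
         "for two interleaved ring templates")
  ## ring 1 in lower lateral lanes, ring 2 two units above: cubes touch but
  ## never overlap, both rings share the same axial window
  ly1 <- max(0L, (box$Ly - 1L) %/% 2L - 4L)
  lz <- max(0L, ((box$Lz - 1L) - 2L) %/% 2L)
  p1 <- ring_template(box, N, ly1, lz)
  p2 <- ring_template(box, N, ly1 + 4L, lz)
  st <- seg_state(box, rbind(p1, p2), n_polymers = 2L,
                  interchain_exclusion = interchain_exclusion)
  if (n_mix > 0) {
    st <- run_mcs(st, tether_field("none"), n_mcs = n_mix,
                  cm_window = cm_tol)$state
    st$mcs <- 0
  }
  cm <- vapply(1:2, function(p)
    axial_cm(polymer_positions(st, p)), numeric(1))
  if (any(abs(cm - box$Lx / 2) > cm_tol + 1e-9))
    stop("initialization failed to keep both centres of mass at mid-cell")
  ext <- lapply(1:2, function(p) range(polymer_positions(st, p)[, 1]))
  ov <- min(ext[[1]][2], ext[[2]][2]) - max(ext[[1]][1], ext[[2]][1]) + 2L
  if (ov < 0.5 * min(diff(ext[[1]]) + 2L, diff(ext[[2]]) + 2L))
    stop("initialization failed: axial extents of the two rings do not overlap")
  right <- if (cm[1] == cm[2]) sample(1:2, 1L) else which.max(cm)
  st$labels <- list(left = c(2L, 1L)[right], right = right)
  st
}

## axial CM in lattice units (monomer centres)
axial_cm <- function(pos) mean(pos[, 1]) + 0.5

## ---- single move (reference implementation) --------------------------------

#' Attempt a single elementary Monte-Carlo move
#'
#' Pure-R reference implementation of the elementary move used by the fast
#' simulation kernel: displace one monomer by one lattice unit along one
#' axis.  The move is accepted iff the monomer is not tethered, the
#' displaced cube stays inside the box, the advancing face sites are
#' unoccupied (cross-polymer occupancy ignored when the state has
#' `interchain_exclusion = FALSE`), and both ring bonds remain in the
#' allowed set.  Rejection leaves the state unchanged.
#'
#' @param state a `seg_state`.
#' @param polymer polymer index.
#' @param monomer monomer index within the polymer (1..N).
#' @param direction integer 1..6 coding +x, -x, +y, -y, +z, -z, or a unit
#'   lattice 3-vector.
#' @return `list(accepted = logical, state = seg_state)`.
#' @export
attempt_move <- function(state, polymer, monomer, direction) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  if (length(direction) == 3L) {
    d <- which(apply(dirs, 1L, function(r) all(r == direction)))
    if (length(d) != 1L) stop("direction must be a unit lattice vector")
  } else d <- as.integer(direction)
  if (d < 1L || d > 6L) stop("direction out of range")
  if (polymer < 1L || polymer > state$n_polymers) stop("polymer index out of range")
  if (monomer < 1L || monomer > state$N) stop("monomer index out of range")
  m <- (polymer - 1L) * state$N + monomer
  reject <- list(accepted = FALSE, state = state)
  if (state$bound[m]) return(reject)
  b <- state$box
  new <- state$pos[m, ] + dirs[d, ]
  if (new[1] < 0L || new[1] > b$Lx - 1L || new[2] < 0L ||
      new[2] > b$Ly - 1L || new[3] < 0L || new[3] > b$Lz - 1L)
    return(reject)
  prev <- (polymer - 1L) * state$N + (monomer - 2L) %% state$N + 1L
  nxt  <- (polymer - 1L) * state$N + monomer %% state$N + 1L
  if (!bond_allowed(state$pos[prev, ] - new) ||
      !bond_allowed(state$pos[nxt, ] - new))
    return(reject)
  ## occupancy of the 8 target sites, excluding this monomer's own cube
  others <- setdiff(seq_len(nrow(state$pos)), m)
  if (!state$interchain_exclusion)
    others <- others[state$polymer[others] == polymer]
  op <- state$pos[others, , drop = FALSE]
  clash <- abs(op[, 1] - new[1]) < 2L & abs(op[, 2] - new[2]) < 2L &
           abs(op[, 3] - new[3]) < 2L
  if (any(clash)) return(reject)
  state$pos[m, ] <- as.integer(new)
  list(accepted = TRUE, state = state)
}

## ---- MCS loop --------------------------------------------------------------

#' Run Monte-Carlo steps
#'
#' Advances a system by `n_mcs` Monte-Carlo steps using the compiled
#' kernel.  One MCS consists of `M` attempted single-monomer moves (`M` =
#' total monomer count), each proposing a uniformly random monomer and one
#' of the 6 axial unit directions; after every MCS the tether field is
#' updated (releases, then stochastic binding of unbound border monomers).
#' All randomness is drawn from R's RNG, so a run is reproducible under
#' [set.seed()].
#'
#' @param state a `seg_state`.
#' @param field a [tether_field()]; `tether_field("none")` disables
#'   tethering.
#' @param n_mcs number of Monte-Carlo steps (>= 0).
#' @param record_every record the relative axial CM of every polymer every
#'   this many MCS (0 = off).  The initial state is always included.
#' @param record_positions_every record full monomer positions at this MCS
#'   interval (0 = off).
#' @param force attractive inter-polymer force coupling f >= 0: axial moves
#'   are additionally accepted with Metropolis probability
#'   `min(1, exp(-f * delta_d))` where `d` is the axial CM separation in
#'   lattice units (energies in kT).  `force = 0` adds no energy term and
#'   consumes no extra randomness.
#' @param cm_window if positive, reject any move that would take either
#'   polymer's axial CM further than this many lattice units from mid-cell
#'   (used by the initializer).
#' @param log_bindings record binding events and the per-axial-position
#'   expected binding intensity (for field-shape checks).
#' @param max_bind_log cap on logged binding events.
#' @param log_moves record every proposal (monomer, direction, accepted);
#'   intended for small runs and replay tests.
#' @return an object of class `seg_run`: a list with the advanced `state`,
#'   the recorded `cm` trace (`data.frame` with `mcs` and one column per
#'   polymer), `pos_samples` (3 x M x n array, if requested), binding and
#'   move logs, and acceptance counters.
#' @export
run_mcs <- function(state, field = tether_field("none"), n_mcs,
                    record_every = 0, record_positions_every = 0,
                    force = 0, cm_window = 0,
                    log_bindings = FALSE, max_bind_log = 200000L,
                    log_moves = FALSE) {
  stopifnot(inherits(state, "seg_state"), inherits(field, "tether_field"))
  if (n_mcs < 0) stop("n_mcs must be >= 0")
  if (n_mcs == 0)
    return(structure(list(state = state, cm = NULL), class = "seg_run"))
  res <- .bfm_run_cpp(state$pos, state$n_polymers, state$N,
                      c(state$box$Lx, state$box$Ly, state$box$Lz),
                      state$bound, state$release, state$mcs, n_mcs,
                      field_to_cpp(field, state$box), field$dwell_mean,
                      field$border_distance, state$interchain_exclusion,
                      force, cm_window, record_every,
                      record_positions_every, log_bindings,
                      as.integer(max_bind_log), log_moves)
  state$pos <- res$pos
  colnames(state$pos) <- c("x", "y", "z")
  state$bound <- res$bound
  state$release <- res$release
  state$mcs <- res$mcs
  out <- list(state = state, accepted = res$accepted,
              attempted = res$attempted)
  if (!is.null(res$cm_rel)) {
    cm <- data.frame(mcs = res$cm_mcs)
    for (p in seq_len(state$n_polymers))
      cm[[paste0("cm_rel_", p)]] <- res$cm_rel[, p]
    out$cm <- cm
  }
  if (!is.null(res$pos_samples)) {
    out$pos_samples <- res$pos_samples
    out$pos_mcs <- res$pos_mcs
  }
  if (!is.null(res$bind_log)) {
    out$bind_log <- as.data.frame(res$bind_log)
    out$bind_events <- res$bind_events
    out$bind_expected <- res$bind_expected
  }
  if (!is.null(res$move_log)) out$move_log <- as.data.frame(res$move_log)
  structure(out, class = "seg_run")
}

#' @export
print.seg_run <- function(x, ...) {
  cat(sprintf("<seg_run: advanced to mcs=%g, acceptance %.1f%%>\n",
              x$state$mcs,
              if (!is.null(x$attempted) && x$attempted > 0)
                100 * x$accepted / x$attempted else NA_real_))
  print(x$state)
  invisible(x)
}

## ---- snapshots -------------------------------------------------------------

#' Write / read a state snapshot as plain text
#'
#' Tab-separated table with columns `polymer_id`, `monomer_index`, `x`,
#' `y`, `z` plus header comments recording the box, MCS clock and
#' exclusion flag.  Snapshots store geometry only; tether states are
#' reset on reload (tethers are transient and re-form within a few MCS).
#'
#' @param state a `seg_state`.
#' @param path file path.
#' @return `write_state`: the path, invisibly. `read_state`: a `seg_state`.
#' @export
write_state <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# box\t%d\t%d\t%d",
                     state$box$Lx, state$box$Ly, state$box$Lz), con)
  writeLines(sprintf("# mcs\t%g", state$mcs), con)
  writeLines(sprintf("# interchain_exclusion\t%d",
                     as.integer(state$interchain_exclusion)), con)
  writeLines("polymer_id\tmonomer_index\tx\ty\tz", con)
  df <- data.frame(polymer_id = state$polymer,
                   monomer_index = sequence(rep(state$N, state$n_polymers)),
                   state$pos)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  gethdr <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)]
    if (!length(ln)) stop("malformed snapshot: missing '", key, "' header")
    as.numeric(strsplit(ln, "\t")[[1]][-1])
  }
  bx <- gethdr("box")
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("polymer_id", "monomer_index", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("malformed snapshot: expected columns ", paste(need, collapse = ", "))
  df <- df[order(df$polymer_id, df$monomer_index), ]
  st <- seg_state(confinement_box(bx[1], bx[2], bx[3]),
                  as.matrix(df[, c("x", "y", "z")]),
                  n_polymers = length(unique(df$polymer_id)),
                  interchain_exclusion = gethdr("interchain_exclusion") == 1)
  st$mcs <- gethdr("mcs")
  st
}
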