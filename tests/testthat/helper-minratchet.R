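## shared test utilities

## a valid 4-monomer square ring (bonds (2,0,0)/(0,2,0)) at a given corner
ring4_positions <- function(x0 = 0L, y0 = 0L, z0 = 0L) {
  rbind(c(x0, y0, z0), c(x0 + 2L, y0, z0),
        c(x0 + 2L, y0 + 2L, z0), c(x0, y0 + 2L, z0))
}

ring4_state <- function(box = confinement_box(6, 6, 6), ...) {
  seg_state(box, ring4_positions(...), n_polymers = 1L)
}

## independent derivation of the BFM bond set: scan all integer vectors
## with components in -3..3 and keep squared lengths {4,5,6,9,10}
bond_set_by_norm <- function() {
  g <- as.matrix(expand.grid(dx = -3:3, dy = -3:3, dz = -3:3))
  g[rowSums(g^2) %in% c(4, 5, 6, 9, 10), , drop = FALSE]
}

## canonical string form of a set of integer row-vectors, for set equality
vec_key <- function(m) sort(apply(m, 1L, paste, collapse = ","))

## small ensembles for statistical fixtures
fake_ensemble <- function(abs_mean, right = abs_mean, condition = "x",
                          n_mcs = 1000) {
  structure(list(
    spec = list(condition = condition,
                base = list(Lx = 80L, N = 80L),
                config = list(n_mcs = n_mcs),
                n_replicates = length(abs_mean)),
    finals = data.frame(replicate = seq_along(abs_mean),
                        seed = seq_along(abs_mean),
                        left = -right, right = right, abs_mean = abs_mean),
    traces = NULL, delta = mean(abs_mean), drift = NA_real_),
    class = "seg_ensemble")
}
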