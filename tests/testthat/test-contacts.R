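# frozen single-conformation ensemble with nucleosomes at given coordinates
frozen_ensemble <- function(nuc_xyz, n_snap = 1) {
  n <- nrow(nuc_xyz)
  pos <- generate_regular_positions(22, n)
  ch <- build_chain(pos)
  # keep only topology metadata; coordinates are synthetic
  coords <- array(0, c(ch$n_beads, 3, n_snap))
  for (k in seq_len(n_snap)) {
    base <- matrix(0, ch$n_beads, 3)
    base[, 1] <- cumsum(c(0, ch$bonds$r0))
    base[ch$nuc_bead_index, ] <- nuc_xyz
    coords[, , k] <- base
  }
  structure(list(chain = ch, coords = coords, time = seq_len(n_snap),
                 replica = rep(1L, n_snap), kinetic = rep(0, n_snap),
                 potential = rep(0, n_snap), config = sim_config(),
                 seed = 0L),
            class = "ensemble")
}

test_that("contact probability has the declared logistic form", {
  expect_equal(contact_probability(0, lc = 20, w = 0.5), 1, tolerance = 1e-9)
  expect_equal(contact_probability(20, lc = 20, w = 2.5), 0.5)
  expect_equal(contact_probability(1e4, lc = 20, w = 2.5), 0)
  r <- seq(0, 100, by = 0.5)
  p <- contact_probability(r, lc = 26.25, w = 2.5)
  expect_true(all(diff(p) <= 0))
  expect_error(contact_probability(-1, 10), "non-negative")
  expect_error(contact_probability(1, 0), "positive")
})

test_that("lc presets carry the two protocol length scales", {
  expect_equal(lc_preset("microc"), 11.25)
  expect_equal(lc_preset("microc-xl"), 26.25)
})

test_that("simulated maps conserve reads, symmetry, and seed determinism", {
  set.seed(99)
  xyz <- matrix(rnorm(30, sd = 3), 10, 3)
  ens <- frozen_ensemble(xyz)
  m <- generate_map(ens, lc = 26, n_reads = 5000, seed = 4)
  expect_equal(sum(m$counts[upper.tri(m$counts)]), 5000)
  expect_identical(m$counts, t(m$counts))
  expect_true(all(diag(m$counts) == 0))
  m2 <- generate_map(ens, lc = 26, n_reads = 5000, seed = 4)
  expect_identical(m$counts, m2$counts)
  expect_false(identical(
    m$counts, generate_map(ens, lc = 26, n_reads = 5000, seed = 5)$counts))
})

test_that("frozen-conformation counts match the acceptance-probability oracle", {
  set.seed(7)
  xyz <- matrix(rnorm(24, sd = 2), 8, 3)
  ens <- frozen_ensemble(xyz)
  lc <- 15; w <- 2.5
  n_reads <- 2e5
  m <- generate_map(ens, lc = lc, n_reads = n_reads, w = w, seed = 1)
  # oracle: expected counts proportional to p(r_ij)
  d <- as.matrix(dist(xyz)) * 2.5
  p <- contact_probability(d[upper.tri(d)], lc, w)
  expected <- n_reads * p / sum(p)
  got <- m$counts[upper.tri(m$counts)]
  # multinomial: compare with generous per-cell tolerance
  expect_gt(stats::cor(got, expected), 0.999)
  expect_lt(max(abs(got - expected) / (sqrt(expected) + 1)), 5)
})

test_that("well-separated clusters receive zero inter-cluster reads", {
  xyz <- rbind(matrix(rnorm(15, sd = 1), 5, 3),
               matrix(rnorm(15, sd = 1), 5, 3) + c(1000, 0, 0))
  ens <- frozen_ensemble(xyz)
  m <- generate_map(ens, lc = 11.25, n_reads = 3000, seed = 2)
  inter <- m$counts[1:5, 6:10]
  expect_true(all(inter == 0))
})

test_that("an absurdly small lc aborts on vanishing acceptance", {
  xyz <- matrix(seq(0, 900, length.out = 30), 10, 3)
  ens <- frozen_ensemble(xyz)
  expect_error(generate_map(ens, lc = 1e-3, n_reads = 100, w = 0.01,
                            seed = 1),
               "acceptance")
})

test_that("larger lc shifts reads toward larger separations", {
  # fixed ensemble of a short fiber; fraction of long-range reads is
  # non-decreasing in lc across the preset grid
  ch <- build_chain(generate_regular_positions(22, 40))
  cfg <- sim_config(equil_time = 300, run_time = 1000, snapshot_every = 25,
                    n_replicas = 3L)
  ens <- run_dynamics(ch, cfg, seed = 8)
  frac_far <- vapply(c(7.5, 22.5, 45, 60), function(lc) {
    m <- generate_map(ens, lc = lc, n_reads = 3e4, seed = 11)
    idx <- which(upper.tri(m$counts), arr.ind = TRUE)
    s <- abs(idx[, 1] - idx[, 2])
    sum(m$counts[upper.tri(m$counts)][s > 10]) / 3e4
  }, numeric(1))
  expect_true(all(diff(frac_far) >= 0))
  # and the mean read separation is non-decreasing too
  mean_sep <- vapply(c(11.25, 26.25), function(lc) {
    m <- generate_map(ens, lc = lc, n_reads = 3e4, seed = 12)
    idx <- which(upper.tri(m$counts), arr.ind = TRUE)
    s <- abs(idx[, 1] - idx[, 2])
    sum(s * m$counts[upper.tri(m$counts)]) / 3e4
  }, numeric(1))
  expect_gte(mean_sep[2], mean_sep[1])
})

test_that("binned maps attribute reads to bp bins and normalize occupancy", {
  ch <- build_chain(generate_regular_positions(22, 30))
  cfg <- sim_config(equil_time = 200, run_time = 600, snapshot_every = 30,
                    n_replicas = 2L)
  ens <- run_dynamics(ch, cfg, seed = 3)
  # one bin covering the region: all reads in one cell
  b1 <- bin_map(ens, bin_bp = ch$region_length, lc = 26.25, n_reads = 1000,
                seed = 1)
  expect_equal(nrow(b1$counts), 1)
  expect_equal(sum(b1$counts), 1000)
  # uniform occupancy: normalization only rescales
  b <- bin_map(ens, bin_bp = 507, lc = 26.25, n_reads = 20000, seed = 2)
  bn <- bin_map(ens, bin_bp = 507, lc = 26.25, n_reads = 20000, seed = 2,
                normalize = TRUE)
  expect_true(all(b$occupancy == b$occupancy[1]))
  expect_equal(bn$counts / max(bn$counts), b$counts / max(b$counts),
               tolerance = 1e-9)
  # all-bead maps include DNA beads
  ba <- bin_map(ens, bin_bp = 507, lc = 26.25, n_reads = 5000,
                include_all_beads = TRUE, seed = 3)
  expect_gt(sum(ba$participants), sum(b$participants))
  expect_error(bin_map(ens, bin_bp = 50, lc = 26.25, n_reads = 10),
               ">= 100")
  expect_error(bin_map(ens, bin_bp = 1e6, lc = 26.25, n_reads = 10),
               "larger than the region")
})
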