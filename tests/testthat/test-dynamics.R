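test_that("initial conformations respect bonds and overlap limits", {
  ch <- build_chain(generate_regular_positions(22, 8))
  # straight: collinear at rest lengths
  s <- init_conformation(ch, "straight")
  bl <- sqrt(rowSums((s[ch$bonds$j, ] - s[ch$bonds$i, ])^2))
  expect_equal(bl, ch$bonds$r0)
  expect_true(all(s[, 2] == 0) && all(s[, 3] == 0))
  # saw: bonds at rest length, no >20% overlaps, seeds differ
  w1 <- init_conformation(ch, "saw", seed = 1)
  w2 <- init_conformation(ch, "saw", seed = 2)
  bl1 <- sqrt(rowSums((w1[ch$bonds$j, ] - w1[ch$bonds$i, ])^2))
  expect_equal(bl1, ch$bonds$r0, tolerance = 1e-12)
  d <- as.matrix(dist(w1))
  lim <- 0.8 * outer(ch$diameter, ch$diameter, "+") / 2
  nonadj <- abs(row(d) - col(d)) > 1
  expect_true(all(d[nonadj] >= lim[nonadj] - 1e-9))
  expect_false(identical(w1, w2))
})

test_that("forces are the exact negative gradient of the energy", {
  pos <- generate_regular_positions(22, 4)
  ch <- build_chain(pos)
  cfg <- sim_config(eps_n = 0.7)   # exercise the attraction branch too
  set.seed(11)
  conf <- init_conformation(ch, "saw", seed = 5) +
    matrix(rnorm(ch$n_beads * 3, sd = 0.05), ch$n_beads, 3)
  fe <- compute_forces(ch, conf, cfg)
  h <- 1e-6
  num <- matrix(0, ch$n_beads, 3)
  for (i in seq_len(ch$n_beads)) {
    for (d in 1:3) {
      cp <- conf; cm <- conf
      cp[i, d] <- cp[i, d] + h
      cm[i, d] <- cm[i, d] - h
      num[i, d] <- -(potential_energy(ch, cp, cfg) -
                       potential_energy(ch, cm, cfg)) / (2 * h)
    }
  }
  expect_lt(max(abs(num - fe$forces)) / max(abs(fe$forces)), 1e-6)
})

test_that("a straight chain at rest lengths is force-free", {
  ch <- build_chain(generate_regular_positions(22, 5))
  conf <- init_conformation(ch, "straight")
  fe <- compute_forces(ch, conf)
  expect_equal(max(abs(fe$forces)), 0)
})

test_that("overlapping-pair repulsion obeys Newton's third law", {
  ch <- build_dna_chain(3)
  conf <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.5, 0, 0))  # beads 1,3 at 1.5 > cutoff
  conf[3, ] <- c(0.9, 0, 0)                             # now 1 and 3 overlap
  fe <- compute_forces(ch, conf, sim_config(k_bond = 0, k_bend = 0))
  f13 <- fe$forces[c(1, 3), ]
  expect_equal(f13[1, ], -f13[2, ], tolerance = 1e-12)
  expect_true(f13[1, 1] < 0 && f13[2, 1] > 0)  # repulsive along the center line
  expect_error(compute_forces(ch, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)),
                              sim_config()),
               "coincident")
})

test_that("the thermostat reproduces equipartition within 5%", {
  ch <- build_dna_chain(40)
  cfg <- sim_config(equil_time = 100, run_time = 1000, snapshot_every = 10,
                    n_replicas = 2L)
  ens <- run_dynamics(ch, cfg, seed = 9)
  ke_per_dof <- mean(ens$kinetic) / (3 * ch$n_beads)
  expect_equal(ke_per_dof, 0.5, tolerance = 0.05)
})

test_that("energy is conserved with the thermostat off", {
  ch <- build_dna_chain(30)
  cfg <- sim_config(gamma = 0, dt = 0.001, equil_time = 0, run_time = 1,
                    snapshot_every = 0.001, n_replicas = 1L)
  ens <- run_dynamics(ch, cfg, seed = 2)
  E <- ens$kinetic + ens$potential
  expect_equal(length(E), 1000)
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})

test_that("bond lengths follow the harmonic Boltzmann distribution", {
  ch <- build_dna_chain(20)
  cfg <- sim_config(eps = 0, k_bend = 0, equil_time = 200, run_time = 4000,
                    snapshot_every = 5, n_replicas = 2L)
  ens <- run_dynamics(ch, cfg, seed = 13)
  bl <- c(vapply(seq_len(n_snapshots(ens)), function(k) {
    x <- ens$coords[, , k]
    sqrt(rowSums(diff(x)^2))
  }, numeric(ch$n_beads - 1)))
  # p(r) ~ r^2 exp(-k/2 (r-1)^2); KS distance against the theoretical CDF
  r <- seq(0.5, 1.5, by = 1e-4)
  dens <- r^2 * exp(-100 * (r - 1)^2)
  cdf <- cumsum(dens) / sum(dens)
  theo <- stats::approxfun(r, cdf, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(bl, theo))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("ensembles are bit-identical under a fixed seed", {
  ch <- build_chain(generate_regular_positions(22, 6))
  cfg <- sim_config(equil_time = 20, run_time = 100, snapshot_every = 10,
                    n_replicas = 2L)
  e1 <- run_dynamics(ch, cfg, seed = 3)
  e2 <- run_dynamics(ch, cfg, seed = 3)
  expect_identical(e1$coords, e2$coords)
  expect_equal(n_snapshots(e1), 2 * 10)
  expect_false(identical(e1$coords,
                         run_dynamics(ch, cfg, seed = 4)$coords))
})

test_that("snapshot accounting follows the protocol", {
  ch <- build_dna_chain(10)
  cfg <- sim_config(equil_time = 50, run_time = 330, snapshot_every = 25,
                    n_replicas = 3L)
  ens <- run_dynamics(ch, cfg, seed = 1)
  expect_equal(n_snapshots(ens), 3 * floor(330 / 25))
  expect_equal(unique(ens$replica), 1:3)
  expect_true(all(ens$time > 0 & ens$time <= 330))
})

test_that("persistence length responds to the bending stiffness limits", {
  # freely jointed limit: lp below 1.5 sigma
  ch <- build_dna_chain(30)
  cfg0 <- sim_config(k_bend = 0, equil_time = 100, run_time = 800,
                     snapshot_every = 20, n_replicas = 4L)
  ens0 <- run_dynamics(ch, cfg0, seed = 21)
  lp0 <- estimate_persistence_length(ens0, max_s = 10)
  expect_lt(lp0$lp_sigma, 1.5)
  # rigid-rod limit: correlations stay near 1 over the whole chain
  cfgR <- sim_config(k_bend = 2000, equil_time = 100, run_time = 500,
                     snapshot_every = 20, n_replicas = 2L)
  ensR <- run_dynamics(ch, cfgR, seed = 22)
  lpR <- estimate_persistence_length(ensR, max_s = 20)
  expect_gt(lpR$lp_sigma, 3 * 29)   # lp >> contour length
  expect_gt(min(lpR$correlations$c), 0.9)
  # defined for bare DNA only
  nch <- build_chain(generate_regular_positions(22, 5))
  ensN <- run_dynamics(nch, sim_config(equil_time = 10, run_time = 50,
                                       snapshot_every = 10,
                                       n_replicas = 1L), seed = 1)
  expect_error(estimate_persistence_length(ensN), "bare DNA")
})

test_that("nucleosome attraction increases nucleosome contacts", {
  ch <- build_chain(generate_regular_positions(22, 12))
  mk <- function(eps_n) {
    cfg <- sim_config(eps_n = eps_n, equil_time = 300, run_time = 1500,
                      snapshot_every = 25, n_replicas = 3L)
    mean_nuc_contacts(run_dynamics(ch, cfg, seed = 17))
  }
  c0 <- mk(0); c2 <- mk(2)
  expect_gt(c2, c0)
})
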