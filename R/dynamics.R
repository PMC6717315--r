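#' Simulation configuration
#'
#' Parameters of the Langevin-dynamics sampler, in reduced units: length
#' sigma = 2.5 nm, energy kT = 1, bead mass m = 1, time unit tau (mapped to
#' ~80 microseconds of real time; metadata only).  Defaults are a
#' desk-scale protocol; `protocol = "full"` gives the production-scale
#' protocol (50e3 tau per replica, snapshots every 250 tau, 20 replicas,
#' 2000 configurations in total).
#'
#' @param dt timestep in tau (stability: <= 0.01 with the default spring
#'   constant).
#' @param gamma friction per unit mass, 1/tau.
#' @param kT thermal energy (reduced; 1).
#' @param k_bond harmonic bond constant, kT/sigma^2.
#' @param k_bend Kratky-Porod bending constant, kT; 20 kT calibrates the
#'   DNA persistence length to 50 nm = 20 sigma (verified by
#'   [estimate_persistence_length()]).
#' @param eps WCA repulsion strength, kT.
#' @param eps_n nucleosome-nucleosome attraction depth, kT (0 = excluded
#'   volume only, the default model).
#' @param attr_cut_factor cutoff of the attractive interaction, in units of
#'   the nucleosome contact distance.
#' @param equil_time,run_time,snapshot_every,n_replicas protocol, in tau.
#' @param protocol `"desk"` (default) or `"full"`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, gamma = 2, kT = 1,
                       k_bond = 200, k_bend = 20, eps = 1, eps_n = 0,
                       attr_cut_factor = 1.8,
                       equil_time = NULL, run_time = NULL,
                       snapshot_every = NULL, n_replicas = NULL,
                       protocol = c("desk", "full")) {
  protocol <- match.arg(protocol)
  def <- if (protocol == "desk")
    list(equil_time = 500, run_time = 5000, snapshot_every = 50,
         n_replicas = 10L)
  else
    list(equil_time = 122, run_time = 50000, snapshot_every = 250,
         n_replicas = 20L)
  if (dt <= 0) stop("'dt' must be positive")
  structure(list(dt = dt, gamma = gamma, kT = kT, k_bond = k_bond,
                 k_bend = k_bend, eps = eps, eps_n = eps_n,
                 attr_cut_factor = attr_cut_factor,
                 equil_time = equil_time %||% def$equil_time,
                 run_time = run_time %||% def$run_time,
                 snapshot_every = snapshot_every %||% def$snapshot_every,
                 n_replicas = as.integer(n_replicas %||% def$n_replicas),
                 sigma_nm = 2.5, tau_us = 80, protocol = protocol),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %s protocol: dt=%g tau, gamma=%g, ",
                     "k_bond=%g, K_bend=%g, eps=%g, eps_n=%g\n",
                     "  equil %g tau, run %g tau, snapshot every %g tau, ",
                     "%d replicas\n"),
              x$protocol, x$dt, x$gamma, x$k_bond, x$k_bend, x$eps, x$eps_n,
              x$equil_time, x$run_time, x$snapshot_every, x$n_replicas))
  invisible(x)
}

#' Initial conformation for a chain
#'
#' `"straight"` places beads collinearly at bond rest lengths.  `"saw"`
#' grows a self-avoiding walk whose bend angles are drawn from the
#' equilibrium Boltzmann distribution of the Kratky-Porod potential
#' (`p(cos phi) ~ exp(K cos phi)` for bonds joined by a bending triplet,
#' uniform on the sphere at freely rotating joints), so the walk starts
#' with equilibrium tangent statistics and only the excluded-volume
#' swelling remains to relax.  A bead is rejected if it overlaps any
#' previous bead by more than 20% of their contact distance; bounded
#' retries, then restart, then error.
#'
#' @param chain a `bead_chain`.
#' @param mode `"saw"` or `"straight"`.
#' @param seed integer seed.
#' @param config a [sim_config()]; its `k_bend` sets the bend-angle
#'   distribution of the `"saw"` mode.
#' @return numeric matrix `n_beads x 3` (sigma units).
#' @export
init_conformation <- function(chain, mode = c("saw", "straight"), seed = 1L,
                              config = sim_config()) {
  stopifnot(inherits(chain, "bead_chain"))
  mode <- match.arg(mode)
  n <- chain$n_beads
  x <- matrix(0, n, 3)
  if (n == 1L) return(x)
  r0 <- chain$bonds$r0
  if (mode == "straight") {
    x[, 1] <- cumsum(c(0, r0))
    return(x)
  }
  d <- chain$diameter
  K <- config$k_bend / config$kT
  # bond b is stiff iff a bending triplet is centred on bead b (its tail)
  stiff <- logical(n - 1L)
  if (nrow(chain$triplets)) stiff[chain$triplets[, 2]] <- TRUE

  # inverse-CDF draw of cos(phi) between successive tangents:
  # p(c) ~ exp(K c) on [-1, 1]; K = 0 reduces to the uniform sphere
  draw_cos <- function(K) {
    u <- runif(1)
    if (K < 1e-8) return(2 * u - 1)
    1 + log(u + (1 - u) * exp(-2 * K)) / K
  }
  turn <- function(dir, cphi) {
    # unit vector at angle acos(cphi) from dir, uniform azimuth
    sphi <- sqrt(max(0, 1 - cphi^2))
    psi <- runif(1, 0, 2 * pi)
    ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * dir) * dir; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
            dir[3] * e1[1] - dir[1] * e1[3],
            dir[1] * e1[2] - dir[2] * e1[1])
    cphi * dir + sphi * (cos(psi) * e1 + sin(psi) * e2)
  }

  with_seed(seed, {
    for (restart in 1:25) {
      ok <- TRUE
      x[1, ] <- 0
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      x[2, ] <- r0[1] * dir
      for (i in seq_len(n - 2L) + 2L) {
        b <- i - 1L                       # bond being placed
        placed <- FALSE
        for (try in 1:60) {
          nd <- turn(dir, draw_cos(if (stiff[b]) K else 0))
          cand <- x[i - 1, ] + r0[b] * nd
          prev <- seq_len(i - 2L)         # bonded predecessor touches by design
          dx <- x[prev, 1, drop = TRUE] - cand[1]
          dy <- x[prev, 2, drop = TRUE] - cand[2]
          dz <- x[prev, 3, drop = TRUE] - cand[3]
          lim <- (0.8 * (d[prev] + d[i]) / 2)^2
          if (any(dx * dx + dy * dy + dz * dz < lim)) next
          x[i, ] <- cand; dir <- nd; placed <- TRUE; break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(x)
    }
    stop("failed to place a self-avoiding initial conformation")
  })
}

chain_cpp_args <- function(chain, config) {
  list(diam = as.numeric(chain$diameter),
       isnuc = as.integer(chain$kind == "NUC"),
       bond_i = as.integer(chain$bonds$i - 1L),
       bond_j = as.integer(chain$bonds$j - 1L),
       bond_r0 = as.numeric(chain$bonds$r0),
       ang_i = as.integer(chain$triplets[, 1] - 1L),
       ang_j = as.integer(chain$triplets[, 2] - 1L),
       ang_k = as.integer(chain$triplets[, 3] - 1L),
       k_bond = config$k_bond, k_bend = config$k_bend,
       eps = config$eps, eps_n = config$eps_n,
       attr_cut_factor = config$attr_cut_factor)
}

#' Forces and potential energy of a conformation
#'
#' Exact negative gradient of the total potential: harmonic bonds
#' `U = k/2 (r - r0)^2`, Kratky-Porod bends `U = K (1 + cos theta)` on
#' DNA-DNA-DNA triplets, WCA excluded volume with additive contact
#' distances (1-2 bonded pairs excluded), and an optional cut-shifted
#' Lennard-Jones attraction of depth `eps_n` between nucleosome beads.
#'
#' @param chain a `bead_chain`.
#' @param conf `n_beads x 3` coordinate matrix (sigma).
#' @param config a [sim_config()].
#' @return list with `forces` (`n_beads x 3`) and `energy` (scalar, kT).
#' @export
compute_forces <- function(chain, conf, config = sim_config()) {
  stopifnot(inherits(chain, "bead_chain"), is.matrix(conf),
            nrow(conf) == chain$n_beads, ncol(conf) == 3)
  a <- chain_cpp_args(chain, config)
  res <- cpp_energy_forces(conf, a$diam, a$isnuc, a$bond_i, a$bond_j,
                           a$bond_r0, a$ang_i, a$ang_j, a$ang_k,
                           a$k_bond, a$k_bend, a$eps, a$eps_n,
                           a$attr_cut_factor)
  list(forces = res$forces, energy = res$energy)
}

#' Total potential energy of a conformation
#' @inheritParams compute_forces
#' @return scalar energy in kT.
#' @export
potential_energy <- function(chain, conf, config = sim_config()) {
  compute_forces(chain, conf, config)$energy
}

#' Sample an ensemble of conformations by Langevin dynamics
#'
#' Runs `n_replicas` independent Langevin trajectories (BAOAB integrator,
#' implicit-solvent thermostat, constant NVT), each from an independent
#' initial conformation, discarding `equil_time` and then recording a
#' snapshot every `snapshot_every` for `run_time`.  Total snapshots =
#' `n_replicas * floor(run_time / snapshot_every)`.  Identical seed and
#' config give a bit-identical ensemble.
#'
#' @param chain a `bead_chain`.
#' @param config a [sim_config()].
#' @param seed integer seed (drives initial conformations, velocities and
#'   thermostat noise for all replicas).
#' @param init initial-conformation mode, see [init_conformation()].
#' @param verbose print per-replica progress.
#' @return an object of class `ensemble`: list with `chain`, `coords`
#'   (array `n_beads x 3 x n_snapshots`, sigma units), `time` (tau),
#'   `replica`, `kinetic` and `potential` (kT per snapshot), `config`,
#'   `seed`.
#' @export
run_dynamics <- function(chain, config = sim_config(), seed = 1L,
                         init = c("saw", "straight"), verbose = FALSE) {
  stopifnot(inherits(chain, "bead_chain"), inherits(config, "sim_config"))
  init <- match.arg(init)
  a <- chain_cpp_args(chain, config)
  n_equil <- round(config$equil_time / config$dt)
  n_run <- round(config$run_time / config$dt)
  snap_every <- max(1L, round(config$snapshot_every / config$dt))

  per_rep <- n_run %/% snap_every
  coords <- array(NA_real_, c(chain$n_beads, 3, per_rep * config$n_replicas))
  tim <- rep <- ke <- pe <- numeric(per_rep * config$n_replicas)

  for (r in seq_len(config$n_replicas)) {
    rs <- derive_seed(seed, r)
    conf0 <- init_conformation(chain, init, seed = rs, config = config)
    out <- cpp_run(conf0, a$diam, a$isnuc, a$bond_i, a$bond_j, a$bond_r0,
                   a$ang_i, a$ang_j, a$ang_k, a$k_bond, a$k_bend,
                   a$eps, a$eps_n, a$attr_cut_factor,
                   config$dt, config$gamma, config$kT,
                   as.integer(n_equil), as.integer(n_run),
                   as.integer(snap_every), as.numeric(rs))
    if (out$n_snap != per_rep)
      stop("internal error: snapshot count mismatch")
    sl <- ((r - 1) * per_rep + 1):(r * per_rep)
    coords[, , sl] <- out$snapshots[, , seq_len(per_rep), drop = FALSE]
    tim[sl] <- out$time
    rep[sl] <- r
    ke[sl] <- out$kinetic
    pe[sl] <- out$potential
    if (verbose)
      message(sprintf("replica %d/%d done (%d snapshots)", r,
                      config$n_replicas, per_rep))
  }
  structure(list(chain = chain, coords = coords, time = tim, replica = rep,
                 kinetic = ke, potential = pe, config = config, seed = seed),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d snapshots of %d beads (%d replicas)\n",
              dim(x$coords)[3], x$chain$n_beads, max(x$replica)))
  invisible(x)
}

#' Number of snapshots in an ensemble
#' @param ensemble an `ensemble`.
#' @return integer count.
#' @export
n_snapshots <- function(ensemble) dim(ensemble$coords)[3]

#' Estimate DNA persistence length from an ensemble
#'
#' Fits the exponential decay of the tangent-tangent correlation
#' `<t(i) . t(i+s)> = exp(-s b / lp)` along a bare DNA chain, over contour
#' separations up to `max_s` bonds, by weighted least squares on the log
#' scale through the origin.  Each separation is weighted by the inverse
#' sampling variance of its log-correlation, estimated from the scatter of
#' per-replica correlation curves (replicas are independent trajectories,
#' so this downweights the slow-to-sample large-separation tail in
#' proportion to its actual noise).  A bootstrap over replicas gives the
#' standard error.  Defined for pure-DNA chains only.
#'
#' @param ensemble an `ensemble` of a chain with no nucleosome beads.
#' @param max_s maximum bond separation used in the fit (default 40,
#'   i.e. contour 40 sigma = 2 lp at calibration).
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return list of class `lp_estimate`: `lp_sigma`, `lp_nm`, `se_sigma`,
#'   `correlations` (data.frame `s`, `c`).
#' @export
estimate_persistence_length <- function(ensemble, max_s = 40L,
                                        n_boot = 200L, seed = 1L) {
  stopifnot(inherits(ensemble, "ensemble"))
  chain <- ensemble$chain
  if (any(chain$kind == "NUC"))
    stop("persistence-length estimator is defined for bare DNA chains only")
  nb <- chain$n_beads - 1L
  if (nb < 3L) stop("chain too short for tangent correlations")
  max_s <- min(max_s, nb - 1L)
  nsnap <- n_snapshots(ensemble)

  # per-snapshot mean tangent correlation at each separation
  corr_one <- function(k) {
    xyz <- ensemble$coords[, , k]
    t_ <- diff(xyz)                        # nb x 3 bond vectors
    t_ <- t_ / sqrt(rowSums(t_^2))
    vapply(seq_len(max_s), function(s) {
      i <- seq_len(nb - s)
      mean(rowSums(t_[i, , drop = FALSE] * t_[i + s, , drop = FALSE]))
    }, numeric(1))
  }
  cs <- vapply(seq_len(nsnap), corr_one, numeric(max_s))  # max_s x nsnap
  cs <- matrix(cs, nrow = max_s)

  # replica-block means: independent samples of the correlation curve
  reps <- unique(ensemble$replica)
  block <- vapply(reps, function(r)
    rowMeans(cs[, ensemble$replica == r, drop = FALSE]), numeric(max_s))
  block <- matrix(block, nrow = max_s)
  nrep <- length(reps)

  fit_lp <- function(cols) {
    cbar <- rowMeans(block[, cols, drop = FALSE])
    s <- seq_len(max_s)
    keep <- cbar > 0
    if (sum(keep) < 3) return(NA_real_)
    # weights: 1 / var(log c) ~ c^2 / var(c_mean), from replica scatter
    w <- if (length(cols) > 1) {
      v <- apply(block[, cols, drop = FALSE], 1, stats::var) / length(cols)
      ifelse(v > 0, cbar^2 / v, 0)
    } else rep(1, max_s)
    if (all(w[keep] == 0)) w[keep] <- 1
    lg <- rep(0, max_s)
    lg[keep] <- log(cbar[keep])
    sl <- sum((w * s * lg)[keep]) / sum((w * s^2)[keep])
    -1 / sl
  }
  lp <- fit_lp(seq_len(nrep))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    fit_lp(sample.int(nrep, nrep, replace = TRUE))
  }, numeric(1)))
  structure(list(lp_sigma = lp, lp_nm = lp * 2.5,
                 se_sigma = sd(boots, na.rm = TRUE),
                 correlations = data.frame(s = seq_len(max_s),
                                           c = rowMeans(block))),
            class = "lp_estimate")
}

#' @export
print.lp_estimate <- function(x, ...) {
  cat(sprintf("<lp_estimate> lp = %.2f sigma = %.1f nm (boot SE %.2f sigma)\n",
              x$lp_sigma, x$lp_nm, x$se_sigma))
  invisible(x)
}

#' Mean nucleosome-nucleosome contact count of an ensemble
#'
#' Counts, per snapshot, nucleosome pairs whose centers lie within
#' `cutoff_sigma` (default 1.5 contact distances, i.e. 6 sigma = 15 nm),
#' averaged over snapshots.  Used to probe the effect of the attraction
#' depth `eps_n`.
#'
#' @param ensemble an `ensemble`.
#' @param cutoff_sigma 3D distance cutoff in sigma.
#' @return mean contact count per snapshot.
#' @export
mean_nuc_contacts <- function(ensemble, cutoff_sigma = 6) {
  idx <- ensemble$chain$nuc_bead_index
  if (length(idx) < 2) return(0)
  nsnap <- n_snapshots(ensemble)
  cut2 <- cutoff_sigma^2
  mean(vapply(seq_len(nsnap), function(k) {
    xyz <- ensemble$coords[idx, , k]
    sum(dist(xyz)^2 < cut2)
  }, numeric(1)))
}
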