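#' Nucleosome-indexed contact map
#'
#' Symmetric non-negative integer count matrix of nucleosome-nucleosome
#' interaction reads, with zero diagonal.
#'
#' @param counts square matrix; symmetrized as the elementwise maximum of
#'   the two triangles if not already symmetric, with a warning.
#' @param lc cross-linker length scale in nm used to generate the map
#'   (NA for maps without one, e.g. planted fixtures).
#' @param provenance `"simulated"` or `"experimental"`.
#' @return an object of class `contact_map`.
#' @export
contact_map <- function(counts, lc = NA_real_,
                        provenance = c("simulated", "experimental")) {
  provenance <- match.arg(provenance)
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("contact map must be square")
  if (any(counts < 0)) stop("contact map counts must be non-negative")
  if (!isTRUE(all.equal(counts, t(counts), check.attributes = FALSE))) {
    warning("asymmetric contact matrix; symmetrizing with pmax of triangles")
    counts <- pmax(counts, t(counts))
  }
  diag(counts) <- 0
  dimnames(counts) <- NULL
  structure(list(n = nrow(counts), counts = counts, lc = lc,
                 provenance = provenance),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d nucleosomes, %g reads (%s%s)\n",
              x$n, x$n, sum(x$counts[upper.tri(x$counts)]), x$provenance,
              if (is.finite(x$lc)) sprintf(", lc = %g nm", x$lc) else ""))
  invisible(x)
}

#' Cross-linker length-scale presets
#'
#' Fitted length scales for the two experimental protocols: standard
#' MicroC (short formaldehyde cross-links, lc = 11.25 nm) and MicroC XL
#' (longer cross-linkers, lc = 26.25 nm).
#'
#' @param name `"microc"` or `"microc-xl"`.
#' @return lc in nm.
#' @export
lc_preset <- function(name = c("microc", "microc-xl")) {
  name <- match.arg(name)
  c("microc" = 11.25, "microc-xl" = 26.25)[[name]]
}

#' Contact probability as a function of 3D separation
#'
#' Logistic acceptance function of the cross-linking observation model:
#' \eqn{p(r) = 1 / (1 + \exp((r - l_c)/w))}.  Monotone non-increasing in `r`,
#' equal to 1/2 at \eqn{r = l_c}; `w` sets the softness of the crossover
#' (default 2.5 nm, one DNA bead).
#'
#' @param r 3D separation in nm (vectorized).
#' @param lc cross-linker length scale in nm (> 0).
#' @param w softness in nm (> 0).
#' @return acceptance probabilities in `[0, 1]`.
#' @export
contact_probability <- function(r, lc, w = 2.5) {
  if (any(r < 0)) stop("'r' must be non-negative")
  if (lc <= 0 || w <= 0) stop("'lc' and 'w' must be positive")
  stats::plogis(-(r - lc) / w)
}

# draw accepted (i, j, snapshot) contact triples until n_reads accepted;
# participants: bead indices eligible for pair draws
draw_contacts <- function(coords, participants, lc, w, n_reads, sigma_nm) {
  np <- length(participants)
  if (np < 2) stop("need at least 2 participating beads")
  nsnap <- dim(coords)[3]
  acc_i <- integer(0); acc_j <- integer(0)
  proposed <- 0; accepted <- 0
  batch <- max(10000L, as.integer(n_reads * 2L))
  repeat {
    i <- sample.int(np, batch, replace = TRUE)
    j <- sample.int(np, batch, replace = TRUE)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    s <- sample.int(nsnap, length(i), replace = TRUE)
    bi <- participants[i]; bj <- participants[j]
    idx_i <- cbind(bi, 1L, s); idx_j <- cbind(bj, 1L, s)
    dx <- coords[idx_i] - coords[idx_j]
    idx_i[, 2] <- 2L; idx_j[, 2] <- 2L
    dy <- coords[idx_i] - coords[idx_j]
    idx_i[, 2] <- 3L; idx_j[, 2] <- 3L
    dz <- coords[idx_i] - coords[idx_j]
    r_nm <- sigma_nm * sqrt(dx * dx + dy * dy + dz * dz)
    ok <- runif(length(r_nm)) < contact_probability(r_nm, lc, w)
    proposed <- proposed + length(keep)
    accepted <- accepted + sum(ok)
    acc_i <- c(acc_i, i[ok]); acc_j <- c(acc_j, j[ok])
    if (length(acc_i) >= n_reads) break
    if (proposed > 1e6 && accepted / proposed < 1e-6)
      stop("contact acceptance rate below 1e-6; lc far too small for the geometry")
  }
  acc_i <- acc_i[seq_len(n_reads)]; acc_j <- acc_j[seq_len(n_reads)]
  lo <- pmin(acc_i, acc_j); hi <- pmax(acc_i, acc_j)
  list(i = lo, j = hi)
}

#' Generate a simulated MicroC contact map from an ensemble
#'
#' Stochastic cross-linking observation model: repeatedly draw a snapshot
#' uniformly at random and an unordered nucleosome pair uniformly at
#' random, and accept the pair as a contact with probability
#' [contact_probability()] of their 3D separation, until `n_reads`
#' contacts have been accepted.  The read total is conserved exactly, so a
#' simulated map can be depth-matched to an experimental one.
#'
#' @param ensemble an `ensemble` whose chain contains nucleosomes.
#' @param lc cross-linker length scale in nm; see [lc_preset()].
#' @param n_reads total number of accepted contacts (>= 1).
#' @param w softness of the acceptance function in nm.
#' @param seed integer seed.
#' @return a [contact_map()] (`provenance = "simulated"`).
#' @export
generate_map <- function(ensemble, lc, n_reads, w = 2.5, seed = 1L) {
  stopifnot(inherits(ensemble, "ensemble"))
  stop_if_not_scalar_count(n_reads, "n_reads")
  if (n_reads < 1) stop("'n_reads' must be >= 1")
  idx <- ensemble$chain$nuc_bead_index
  if (length(idx) < 2) stop("chain must contain at least 2 nucleosomes")
  sigma_nm <- ensemble$config$sigma_nm %||% 2.5
  pairs <- with_seed(seed,
    draw_contacts(ensemble$coords, idx, lc, w, n_reads, sigma_nm))
  n <- length(idx)
  m <- matrix(0L, n, n)
  tab <- table((pairs$i - 1L) * n + pairs$j)
  m[as.integer(names(tab))] <- as.integer(tab)
  m <- m + t(m)
  contact_map(m, lc = lc, provenance = "simulated")
}

#' Binned contact map with occupancy normalization
#'
#' Sorts simulated contacts into regular base-pair bins (as in
#' conventional Hi-C display).  With `include_all_beads = TRUE`, linker
#' DNA beads also participate in pair draws, so contacts from all regions
#' of the fiber are represented - including nucleosome-depleted regions.
#' With `normalize = TRUE`, entries are divided by the product of the two
#' bins' participating-bead occupancies (scaled to preserve the map
#' total), correcting for variation in nucleosome occupancy.
#'
#' @inheritParams generate_map
#' @param bin_bp bin width in bp (>= 100; must not exceed the region).
#' @param include_all_beads include DNA beads in pair draws.
#' @param normalize divide by expected occupancy products.
#' @return an object of class `binned_map`: `bin_bp`, `counts` (matrix,
#'   numeric if normalized), `occupancy` (nucleosome beads per bin),
#'   `participants` (participating beads per bin), `normalized`, `lc`.
#' @export
bin_map <- function(ensemble, bin_bp, lc, n_reads,
                    include_all_beads = FALSE, normalize = FALSE,
                    w = 2.5, seed = 1L) {
  stopifnot(inherits(ensemble, "ensemble"))
  chain <- ensemble$chain
  if (bin_bp < 100) stop("'bin_bp' must be >= 100")
  if (bin_bp > chain$region_length)
    stop("bin larger than the region")
  part <- if (include_all_beads) seq_len(chain$n_beads)
          else chain$nuc_bead_index
  if (length(part) < 2) stop("need at least 2 participating beads")
  sigma_nm <- ensemble$config$sigma_nm %||% 2.5
  pairs <- with_seed(seed,
    draw_contacts(ensemble$coords, part, lc, w, n_reads, sigma_nm))

  edges <- seq(0, chain$region_length, by = bin_bp)
  nbin <- as.integer(ceiling(chain$region_length / bin_bp))
  bin_of <- function(beads)
    pmin(findInterval(chain$bead_to_bp[beads], edges), nbin)
  bi <- bin_of(part[pairs$i]); bj <- bin_of(part[pairs$j])
  lo <- pmin(bi, bj); hi <- pmax(bi, bj)
  m <- matrix(0, nbin, nbin)
  tab <- table((lo - 1L) * nbin + hi)
  m[as.integer(names(tab))] <- as.numeric(tab)
  m[lower.tri(m)] <- 0
  m <- m + t(m)
  diag(m) <- diag(m) / 2   # same-bin contacts counted once

  occupancy <- tabulate(bin_of(chain$nuc_bead_index), nbins = nbin)
  participants <- tabulate(bin_of(part), nbins = nbin)
  if (normalize) {
    expected <- outer(participants, participants)
    scale <- sum(m) / sum(m / pmax(expected, 1) * (expected > 0))
    m <- ifelse(expected > 0, m / expected, NA_real_) * scale
  }
  structure(list(bin_bp = bin_bp, counts = m, occupancy = occupancy,
                 participants = participants, normalized = normalize,
                 lc = lc),
            class = "binned_map")
}

#' @export
print.binned_map <- function(x, ...) {
  cat(sprintf("<binned_map> %d bins of %g bp (%snormalized, lc = %g nm)\n",
              nrow(x$counts), x$bin_bp, if (x$normalized) "" else "not ",
              x$lc))
  invisible(x)
}
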