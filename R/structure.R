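#' Radius of gyration of a point set
#'
#' Root-mean-square distance of points from their centroid, all points
#' weighted equally (DNA and nucleosome beads on the same footing).
#'
#' @param coords numeric matrix (n x 3), sigma units.
#' @return Rg in sigma.
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("need at least one point")
  ctr <- colMeans(coords)
  sqrt(mean(rowSums((coords - rep(ctr, each = nrow(coords)))^2)))
}

# sliding-window Rg for every start position, one snapshot, via prefix sums:
# Rg^2 = mean|x|^2 - |mean x|^2 over the window, O(n) per L.
window_rg_snapshot <- function(xyz, L) {
  n <- nrow(xyz)
  s1 <- rbind(0, apply(xyz, 2, cumsum))          # (n+1) x 3
  s2 <- c(0, cumsum(rowSums(xyz^2)))
  i0 <- 0:(n - L)                                 # window covers i0+1 .. i0+L
  msq <- (s2[i0 + L + 1] - s2[i0 + 1]) / L
  mx <- (s1[i0 + L + 1, , drop = FALSE] - s1[i0 + 1, , drop = FALSE]) / L
  rg2 <- pmax(msq - rowSums(mx^2), 0)
  sqrt(rg2)
}

#' Radius of gyration versus subchain length
#'
#' For each window length L, computes Rg over every sliding window of L
#' consecutive beads (first beads 1..L, then 2..L+1, ...), averaged over
#' window positions and snapshots, and fits `Rg ~ L^alpha` on the log-log
#' scale.
#'
#' @param ensemble an `ensemble`.
#' @param L_values window lengths in beads (each <= n_beads).
#' @return object of class `rg_curve`: data.frame `L`, `Rg_mean`, `Rg_sd`
#'   (SD over windows and snapshots), with attributes `alpha` and
#'   `alpha_se`.
#' @export
rg_vs_length <- function(ensemble, L_values) {
  stopifnot(inherits(ensemble, "ensemble"))
  n <- ensemble$chain$n_beads
  L_values <- sort(unique(as.integer(L_values)))
  if (any(L_values < 2) || any(L_values > n))
    stop("window lengths must be in [2, n_beads]")
  nsnap <- n_snapshots(ensemble)
  rows <- lapply(L_values, function(L) {
    vals <- unlist(lapply(seq_len(nsnap), function(k)
      window_rg_snapshot(ensemble$coords[, , k], L)))
    data.frame(L = L, Rg_mean = mean(vals), Rg_sd = sd(vals))
  })
  out <- do.call(rbind, rows)
  fit <- lm(log(Rg_mean) ~ log(L), data = out)
  structure(out, alpha = unname(coef(fit)[2]),
            alpha_se = unname(summary(fit)$coefficients[2, 2]),
            class = c("rg_curve", "data.frame"))
}

#' Fitted size-scaling exponent of an rg_curve
#' @param curve an [rg_vs_length()] result.
#' @return list with `alpha` and `se`.
#' @export
rg_scaling_exponent <- function(curve) {
  stopifnot(inherits(curve, "rg_curve"))
  list(alpha = attr(curve, "alpha"), se = attr(curve, "alpha_se"))
}

#' Local compaction profile Rg/lambda
#'
#' Slides a fixed window of `L` beads along the fiber; at each position the
#' window Rg (averaged over snapshots and replicas) is divided by
#' `lambda = sqrt(Nd + 4*Nn)`, the square root of the window contour length
#' in sigma (DNA beads contribute 1 sigma, nucleosome beads 4 sigma), where
#' `Nd` and `Nn` are the DNA and nucleosome bead counts in the window.
#' Rg/lambda is a dimensionless local compaction: ~0.88 for a bare-DNA
#' window at the calibrated stiffness, lower when a few nucleosomes
#' introduce turning points, higher again when many nucleosomes stiffen
#' the chain sterically.
#'
#' @param ensemble an `ensemble`.
#' @param L window length in beads (default 11).
#' @return object of class `local_rg_profile`: data.frame `position`
#'   (window start bead), `Rg_mean`, `Rg_se` (SE over snapshots), `Nn`,
#'   `Nd`, `lambda`, `rg_over_lambda`.
#' @export
local_rg_profile <- function(ensemble, L = 11L) {
  stopifnot(inherits(ensemble, "ensemble"))
  chain <- ensemble$chain
  n <- chain$n_beads
  L <- as.integer(L)
  if (L < 2 || L > n) stop("'L' must be in [2, n_beads]")
  nsnap <- n_snapshots(ensemble)
  per_snap <- vapply(seq_len(nsnap), function(k)
    window_rg_snapshot(ensemble$coords[, , k], L),
    numeric(n - L + 1L))                       # (n-L+1) x nsnap
  per_snap <- matrix(per_snap, nrow = n - L + 1L)
  isn <- as.integer(chain$kind == "NUC")
  cs <- c(0, cumsum(isn))
  i0 <- 0:(n - L)
  Nn <- cs[i0 + L + 1] - cs[i0 + 1]
  Nd <- L - Nn
  lambda <- sqrt(Nd + 4 * Nn)
  structure(data.frame(position = i0 + 1L,
                       Rg_mean = rowMeans(per_snap),
                       Rg_se = apply(per_snap, 1, sd) / sqrt(nsnap),
                       Nn = Nn, Nd = Nd, lambda = lambda,
                       rg_over_lambda = rowMeans(per_snap) / lambda),
            L = L, class = c("local_rg_profile", "data.frame"))
}

#' Linker-length statistics by genomic context
#'
#' Assigns every linker (by its bp midpoint) to genomic context
#' categories and summarizes each category: histogram of lengths, the
#' proportions of linkers (among those <= 200 bp, longer ones being
#' treated as artifacts) falling in the short (<= 3 bp), medium (4-49 bp)
#' and long (50-200 bp) ranges with binomial standard errors, and the mean
#' length.  Categories: `all`; `gene_body` (midpoint inside a gene of
#' length >= 1 kbp); `upstream500` (within the 500 bp upstream of a
#' TSS, strand-aware); `nongenic` (in neither, considering all genes);
#' `active_gene` / `inactive_gene` (gene bodies split by activity flag);
#' `boundary` (the linker immediately following a boundary nucleosome).
#'
#' @param positions a [nuc_positions()] object.
#' @param genes optional [gene_annotation()].
#' @param boundaries optional [boundary_set()] of nucleosome indices.
#' @return object of class `linker_stats`: named list of per-category
#'   lists with `n`, `mean_bp`, `fractions` (3-vector), `se` (3-vector),
#'   `lengths`.
#' @export
linker_stats <- function(positions, genes = NULL, boundaries = NULL) {
  stopifnot(inherits(positions, "nuc_positions"))
  fp <- positions$footprint_bp
  st <- positions$starts
  nl <- length(st) - 1L
  if (nl < 1) stop("need at least 2 nucleosomes to have linkers")
  lstart <- st[-length(st)] + fp
  lend <- st[-1]
  len <- lend - lstart
  mid <- (lstart + lend) / 2

  in_any <- function(pts, a, b) {
    # is each point inside any [a_i, b_i)?
    if (length(a) == 0) return(rep(FALSE, length(pts)))
    vapply(pts, function(p) any(p >= a & p < b), logical(1))
  }

  cats <- list(all = rep(TRUE, nl))
  if (!is.null(genes)) {
    gi <- genes$intervals
    big <- gi[gi$end - gi$start >= 1000, , drop = FALSE]
    tss <- ifelse(big$strand == "+", big$start, big$end)
    up_a <- ifelse(big$strand == "+", big$start - 500, big$end)
    up_b <- ifelse(big$strand == "+", big$start, big$end + 500)
    cats$gene_body <- in_any(mid, big$start, big$end)
    cats$upstream500 <- in_any(mid, up_a, up_b)
    cats$nongenic <- !in_any(mid, gi$start, gi$end) &
      !cats$upstream500
    cats$active_gene <- in_any(mid, big$start[big$active],
                               big$end[big$active])
    cats$inactive_gene <- in_any(mid, big$start[!big$active],
                                 big$end[!big$active])
  }
  if (!is.null(boundaries)) {
    bl <- boundaries$positions
    bl <- bl[bl >= 1 & bl <= nl]          # linker after boundary nucleosome
    cats$boundary <- seq_len(nl) %in% bl
  }

  summarize <- function(sel) {
    l <- len[sel]
    keep <- l <= 200
    lk <- l[keep]
    m <- length(lk)
    frac <- if (m) c(short = mean(lk <= 3), mid = mean(lk >= 4 & lk <= 49),
                     long = mean(lk >= 50))
            else c(short = NA_real_, mid = NA_real_, long = NA_real_)
    list(n = m,
         mean_bp = if (m) mean(lk) else NA_real_,
         fractions = frac,
         se = if (m) sqrt(frac * (1 - frac) / m) else frac,
         lengths = lk)
  }
  structure(lapply(cats, summarize), class = "linker_stats")
}

#' @export
print.linker_stats <- function(x, ...) {
  cat("<linker_stats>\n")
  for (nm in names(x)) {
    s <- x[[nm]]
    cat(sprintf("  %-13s n=%5d  mean %5.1f bp  [1-3] %.2f  [4-49] %.2f  [50-200] %.2f\n",
                nm, s$n, s$mean_bp, s$fractions[1], s$fractions[2],
                s$fractions[3]))
  }
  invisible(x)
}
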