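#' Mean reads versus nucleosome separation, P(s)
#'
#' For each genomic separation `s` (in nucleosomes), the mean read count
#' over all pairs at that separation, including zero cells:
#' `mean_reads[s] = sum_{|i-j|=s} counts[i,j] / (n - s)`.
#'
#' @param map a [contact_map()] with n >= 3.
#' @return object of class `ps_curve`: data.frame with columns `s`
#'   (1 .. n-1) and `mean_reads`.
#' @export
reads_vs_separation <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  n <- map$n
  if (n < 3) stop("map must have n >= 3")
  cnt <- map$counts
  mean_reads <- vapply(seq_len(n - 1L), function(s) {
    i <- seq_len(n - s)
    mean(cnt[cbind(i, i + s)])
  }, numeric(1))
  structure(data.frame(s = seq_len(n - 1L), mean_reads = mean_reads),
            class = c("ps_curve", "data.frame"))
}

#' Fit a power law to a P(s) curve
#'
#' Least-squares fit of `log(mean_reads)` against `log(s)` within
#' `[s_lo, s_hi]`, reported as a positive decay exponent alpha
#' (`mean_reads ~ s^-alpha`).  If any mean in range is zero, points are
#' first aggregated into log-spaced bins (geometric-mean `s`, arithmetic
#' mean of `mean_reads`) so zero cells do not break the log fit.  The
#' default ranges of interest are s = 2-10 (short-range regime) and
#' s = 10-100 (long-range regime).
#'
#' @param curve a [reads_vs_separation()] result.
#' @param s_lo,s_hi fit range in nucleosomes (inclusive).
#' @param bins_per_decade log-binning density used when zeros are present.
#' @return object of class `power_law_fit`: `alpha` (positive for decay),
#'   `stderr`, `s_range`, `n_points`.
#' @export
fit_power_law <- function(curve, s_lo = 10, s_hi = 100,
                          bins_per_decade = 8) {
  stopifnot(inherits(curve, "ps_curve") || is.data.frame(curve))
  d <- curve[curve$s >= s_lo & curve$s <= s_hi, , drop = FALSE]
  if (nrow(d) == 0) stop("no points in fit range")
  if (any(d$mean_reads == 0)) {
    edges <- 10^seq(log10(s_lo), log10(s_hi),
                    length.out = max(3, ceiling(log10(s_hi / s_lo) *
                                                  bins_per_decade) + 1))
    bin <- cut(d$s, breaks = unique(c(edges[1] - 1e-9, edges[-1])),
               labels = FALSE)
    d <- do.call(rbind, lapply(split(d, bin), function(g)
      data.frame(s = exp(mean(log(g$s))), mean_reads = mean(g$mean_reads))))
  }
  d <- d[d$mean_reads > 0, , drop = FALSE]
  if (nrow(d) < 3) stop("fewer than 3 positive points in fit range")
  fit <- lm(log(mean_reads) ~ log(s), data = d)
  sm <- suppressWarnings(summary(fit))   # noiseless inputs fit perfectly
  structure(list(alpha = -unname(coef(fit)[2]),
                 stderr = unname(sm$coefficients[2, 2]),
                 s_range = c(s_lo, s_hi), n_points = nrow(d)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha = %.3f (SE %.3f) on s in [%g, %g], %d points\n",
              x$alpha, x$stderr, x$s_range[1], x$s_range[2], x$n_points))
  invisible(x)
}

#' P(s) decay exponents across a grid of cross-linker length scales
#'
#' Generates one simulated map per `lc` value from the same ensemble and
#' fits the decay exponent in `[s_lo, s_hi]`.  The default grid is
#' lc = 7.5 to 60 nm in steps of 7.5 nm.  Larger cross-linkers lift
#' long-range reads, so the fitted exponent decreases with lc.
#'
#' @inheritParams generate_map
#' @param lc_grid lc values in nm.
#' @param s_lo,s_hi fit range (default the 10-100 long-range regime).
#' @return data.frame with columns `lc`, `alpha`, `stderr`.
#' @export
lc_sweep <- function(ensemble, n_reads, lc_grid = seq(7.5, 60, by = 7.5),
                     s_lo = 10, s_hi = 100, w = 2.5, seed = 1L) {
  res <- lapply(seq_along(lc_grid), function(k) {
    m <- generate_map(ensemble, lc = lc_grid[k], n_reads = n_reads, w = w,
                      seed = derive_seed(seed, k))
    f <- fit_power_law(reads_vs_separation(m), s_lo = s_lo,
                       s_hi = min(s_hi, m$n - 1))
    data.frame(lc = lc_grid[k], alpha = f$alpha, stderr = f$stderr)
  })
  do.call(rbind, res)
}
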