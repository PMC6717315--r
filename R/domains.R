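#' Insulation profile of a contact map
#'
#' The insulation value at nucleosome i is the mean read count between the
#' `window` nucleosomes on its left (positions i-window+1 .. i) and the
#' `window` nucleosomes on its right (positions i+1 .. i+window).  Lower
#' values mean stronger insulation; minima mark candidate domain
#' boundaries.  Values are defined for `window <= i <= n - window` and NA
#' elsewhere.
#'
#' @param map a [contact_map()].
#' @param window half-window size in nucleosomes (default 6, matching the
#'   4-50 nucleosome domain scale).
#' @return object of class `insulation_profile`: `values` (length n, NA
#'   outside the defined range) and `window`.
#' @export
insulation_profile <- function(map, window = 6L) {
  stopifnot(inherits(map, "contact_map"))
  window <- as.integer(window)
  if (window < 1) stop("'window' must be >= 1")
  n <- map$n
  if (n <= 2L * window)
    stop(sprintf("map too small: need n > 2*window (n = %d, window = %d)",
                 n, window))
  vals <- rep(NA_real_, n)
  cnt <- map$counts
  for (i in window:(n - window)) {
    vals[i] <- mean(cnt[(i - window + 1L):i, (i + 1L):(i + window)])
  }
  structure(list(values = vals, window = window),
            class = "insulation_profile")
}

#' @export
print.insulation_profile <- function(x, ...) {
  ok <- is.finite(x$values)
  cat(sprintf("<insulation_profile> %d nucleosomes (window %d), mean %.3g\n",
              length(x$values), x$window, mean(x$values[ok])))
  invisible(x)
}

# topographic prominence of local minima in v (NA-padded allowed).
# For minimum m: walk left/right to the nearest strictly lower value (or the
# end of the defined range), track the maximum barrier passed on each side;
# prominence = min(left barrier, right barrier) - v[m].
minima_prominence <- function(v) {
  idx <- which(is.finite(v))
  if (length(idx) < 3) return(data.frame(pos = integer(0), prom = numeric(0)))
  lo <- idx[1]; hi <- idx[length(idx)]
  pos <- integer(0); prom <- numeric(0)
  for (m in idx[c(-1, -length(idx))]) {
    if (!(v[m] <= v[m - 1] && v[m] <= v[m + 1])) next
    if (v[m] == v[m - 1]) next        # plateau: keep only leftmost point
    left_bar <- -Inf
    k <- m - 1L
    while (k >= lo && v[k] >= v[m]) {
      left_bar <- max(left_bar, v[k]); k <- k - 1L
    }
    if (k < lo && left_bar == -Inf) left_bar <- v[m]
    right_bar <- -Inf
    k <- m + 1L
    while (k <= hi && v[k] >= v[m]) {
      right_bar <- max(right_bar, v[k]); k <- k + 1L
    }
    if (k > hi && right_bar == -Inf) right_bar <- v[m]
    pos <- c(pos, m)
    prom <- c(prom, min(left_bar, right_bar) - v[m])
  }
  data.frame(pos = pos, prom = prom)
}

#' Boundary set
#'
#' @param positions nucleosome indices (1-based), strictly increasing.
#' @param strengths per-boundary non-negative scores (topographic
#'   prominence of the insulation minimum when produced by
#'   [call_boundaries()]).
#' @return object of class `boundary_set`.
#' @export
boundary_set <- function(positions, strengths = rep(0, length(positions))) {
  positions <- as.integer(positions)
  o <- order(positions)
  positions <- positions[o]; strengths <- as.numeric(strengths)[o]
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop("boundary positions must be strictly increasing")
  if (any(strengths < 0)) stop("boundary strengths must be >= 0")
  structure(list(positions = positions, strengths = strengths),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("<boundary_set> %d boundaries\n", length(x$positions)))
  invisible(x)
}

#' Call domain boundaries from an insulation profile
#'
#' Boundaries are local minima of the insulation profile with topographic
#' prominence at least `prominence`, thinned greedily (strongest first) so
#' accepted boundaries are at least `min_separation` nucleosomes apart.
#' Boundary strength is the prominence of the minimum.
#'
#' @param profile an [insulation_profile()].
#' @param prominence minimum prominence; default is 10% of the range of
#'   the defined profile values (0 calls every local minimum).
#' @param min_separation minimal spacing between called boundaries
#'   (default 4 nucleosomes, the lower end of the 4-50 nucleosome domain
#'   size range).
#' @return a [boundary_set()]; possibly empty.
#' @export
call_boundaries <- function(profile, prominence = NULL, min_separation = 4L) {
  stopifnot(inherits(profile, "insulation_profile"))
  v <- profile$values
  ok <- is.finite(v)
  if (!any(ok)) return(boundary_set(integer(0)))
  if (is.null(prominence))
    prominence <- 0.1 * diff(range(v[ok]))
  cand <- minima_prominence(v)
  cand <- cand[cand$prom >= prominence & cand$prom > 0, , drop = FALSE]
  if (nrow(cand) == 0) return(boundary_set(integer(0)))
  cand <- cand[order(-cand$prom, cand$pos), , drop = FALSE]
  keep <- integer(0)
  for (r in seq_len(nrow(cand))) {
    p <- cand$pos[r]
    if (all(abs(p - cand$pos[keep]) >= min_separation))
      keep <- c(keep, r)
  }
  sel <- cand[keep, , drop = FALSE]
  boundary_set(sel$pos, sel$prom)
}

#' Match predicted against reference boundaries
#'
#' Greedy one-to-one matching: candidate pairs within `tolerance`
#' nucleosomes are accepted in order of increasing distance (ties broken
#' toward the lower reference, then predicted, index), each boundary used
#' at most once.  A correct prediction is a predicted boundary within
#' `tolerance` (default 1) nucleosomes of a reference boundary.
#'
#' @param predicted,reference [boundary_set()] objects.
#' @param tolerance maximum index distance for a match (default 1).
#' @return list: `matched`, `missing` (unmatched reference), `extra`
#'   (unmatched predicted), `recall`, `precision`.
#' @export
match_boundaries <- function(predicted, reference, tolerance = 1L) {
  stopifnot(inherits(predicted, "boundary_set"),
            inherits(reference, "boundary_set"))
  if (tolerance < 0) stop("'tolerance' must be >= 0")
  p <- predicted$positions; r <- reference$positions
  if (length(p) == 0 || length(r) == 0) {
    m <- 0L
  } else {
    d <- abs(outer(p, r, "-"))
    cand <- which(d <= tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      o <- order(d[cand], r[cand[, 2]], p[cand[, 1]])
      cand <- cand[o, , drop = FALSE]
      used_p <- logical(length(p)); used_r <- logical(length(r))
      m <- 0L
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_r[j]) {
          used_p[i] <- used_r[j] <- TRUE
          m <- m + 1L
        }
      }
    } else m <- 0L
  }
  list(matched = m,
       missing = length(r) - m,
       extra = length(p) - m,
       recall = if (length(r)) m / length(r) else NA_real_,
       precision = if (length(p)) m / length(p) else NA_real_)
}

#' Monte-Carlo null p-value for boundary agreement
#'
#' Tests whether the observed number of matched boundaries could arise by
#' chance: random boundary sets with the same count as `predicted` are
#' drawn uniformly without replacement from the valid positions
#' (preserving the minimum separation of the predicted set), and the
#' p-value is the fraction of random sets whose matched count against
#' `reference` is at least the observed one.  The add-one estimator
#' `(1 + exceed) / (1 + n_mc)` is reported, so a result with no
#' exceedances is the upper bound `1 / (n_mc + 1)`.
#'
#' @param predicted,reference non-empty [boundary_set()] objects.
#' @param n_nucleosomes map size; random positions are drawn from
#'   `1 .. n_nucleosomes - 1`.
#' @param n_mc Monte-Carlo samples (>= 1000).
#' @param tolerance match tolerance (default 1).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
boundary_null_pvalue <- function(predicted, reference, n_nucleosomes,
                                 n_mc = 10000L, tolerance = 1L, seed = 1L) {
  stopifnot(inherits(predicted, "boundary_set"),
            inherits(reference, "boundary_set"))
  if (length(predicted$positions) == 0 || length(reference$positions) == 0)
    stop("both boundary sets must be non-empty")
  if (n_mc < 1000) stop("'n_mc' must be >= 1000")
  k <- length(predicted$positions)
  valid <- seq_len(n_nucleosomes - 1L)
  if (k > length(valid)) stop("more boundaries than available positions")
  min_sep <- if (k > 1) min(diff(predicted$positions)) else 1L
  observed <- match_boundaries(predicted, reference, tolerance)$matched
  ref <- reference
  # uniform sampling of k positions with pairwise gaps >= min_sep via the
  # gap transform: draw unconstrained combinations from a shrunken range,
  # then re-expand; exact and rejection-free
  m_eff <- length(valid) - (k - 1L) * (min_sep - 1L)
  if (m_eff < k)
    stop("cannot place random boundaries with the required separation")
  shift <- (seq_len(k) - 1L) * (min_sep - 1L)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_mc)) {
      pos <- sort(sample.int(m_eff, k)) + shift
      m <- match_boundaries(boundary_set(pos), ref, tolerance)$matched
      if (m >= observed) cnt <- cnt + 1L
    }
    cnt
  })
  (1 + exceed) / (1 + n_mc)
}

#' Correlate two insulation profiles
#'
#' Spearman rank correlation between two profiles of equal length and
#' window, over all defined indices or only at boundary positions.
#'
#' @param a,b [insulation_profile()] objects with equal length and window.
#' @param at `"all"` or `"boundaries"`.
#' @param boundaries a [boundary_set()]; required when `at = "boundaries"`.
#' @return list with `rho` and `p` (large-sample p-value).
#' @export
compare_insulation <- function(a, b, at = c("all", "boundaries"),
                               boundaries = NULL) {
  stopifnot(inherits(a, "insulation_profile"),
            inherits(b, "insulation_profile"))
  at <- match.arg(at)
  if (length(a$values) != length(b$values))
    stop("profiles must have equal length")
  if (a$window != b$window)
    stop("profiles must share the same window")
  idx <- which(is.finite(a$values) & is.finite(b$values))
  if (at == "boundaries") {
    if (is.null(boundaries)) stop("'boundaries' required when at = 'boundaries'")
    idx <- intersect(idx, boundaries$positions)
  }
  if (length(idx) < 3) stop("fewer than 3 comparable indices")
  ct <- suppressWarnings(
    cor.test(a$values[idx], b$values[idx], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
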