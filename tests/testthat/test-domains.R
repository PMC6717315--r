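# brute-force insulation for the oracle: mean of counts between left and
# right windows, computed pair by pair
insulation_brute <- function(counts, window) {
  n <- nrow(counts)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- (i - window + 1):i
    b <- (i + 1):(i + window)
    if (a[1] < 1 || b[window] > n) next
    acc <- c()
    for (x in a) for (y in b) acc <- c(acc, counts[x, y])
    vals[i] <- mean(acc)
  }
  vals
}

test_that("insulation of a uniform map is exactly constant", {
  n <- 15
  cnt <- matrix(3, n, n); diag(cnt) <- 0
  m <- contact_map(cnt)
  prof <- insulation_profile(m, window = 3)
  vals <- prof$values[is.finite(prof$values)]
  # window spans touching the diagonal contain structural zeros, but all
  # defined positions must agree exactly
  expect_true(all(vals == vals[1]))
})

test_that("insulation matches the brute-force oracle on a planted map", {
  m <- generate_planted_domain_map(12, 6, reads = 3000,
                                   intra_over_inter = 10, seed = 2)
  prof <- insulation_profile(m, window = 3)
  expect_equal(prof$values, insulation_brute(m$counts, 3))
  # unique minimum at the block boundary
  expect_equal(which.min(prof$values), 6)
})

test_that("insulation window preconditions are enforced", {
  m <- generate_planted_domain_map(10, 5, reads = 100,
                                   intra_over_inter = 5, seed = 1)
  expect_error(insulation_profile(m, window = 5), "too small")
  expect_error(insulation_profile(m, window = 0), ">= 1")
})

test_that("boundary calling recovers planted boundaries exactly", {
  planted <- c(12, 25, 31, 44)
  m <- generate_planted_domain_map(60, planted, reads = 2e5,
                                   intra_over_inter = 8, seed = 3)
  prof <- insulation_profile(m, window = 5)
  b <- call_boundaries(prof, min_separation = 4)
  expect_equal(b$positions, planted)
  expect_true(all(b$strengths > 0))
})

test_that("constant profiles yield no boundaries and thresholds are monotone", {
  flat <- structure(list(values = c(NA, rep(2, 20), NA), window = 1L),
                    class = "insulation_profile")
  expect_length(call_boundaries(flat)$positions, 0)

  m <- generate_planted_domain_map(60, c(15, 30, 45), reads = 5e4,
                                   intra_over_inter = 4, seed = 5)
  prof <- insulation_profile(m, window = 5)
  lo <- call_boundaries(prof, prominence = 0.1)
  hi <- call_boundaries(prof, prominence = 0.2)
  expect_lte(length(hi$positions), length(lo$positions))
})

test_that("boundary matching honors the within-1-nucleosome rule", {
  ref <- boundary_set(seq(10, 100, by = 10))
  # identical sets
  r <- match_boundaries(ref, ref, tolerance = 1)
  expect_equal(r$matched, 10)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)
  # offset by exactly 1: all match at tolerance 1
  off1 <- boundary_set(ref$positions + 1)
  r1 <- match_boundaries(off1, ref, tolerance = 1)
  expect_equal(r1$matched, 10)
  # offset by 2: none match at tolerance 1
  off2 <- boundary_set(ref$positions + 2)
  r2 <- match_boundaries(off2, ref, tolerance = 1)
  expect_equal(r2$matched, 0)
  expect_equal(r2$missing, 10)
  expect_equal(r2$extra, 10)
})

test_that("matching is one-to-one and nearest-first", {
  # two predictions flank one reference: only one may match
  r <- match_boundaries(boundary_set(c(9, 11)), boundary_set(10), tolerance = 1)
  expect_equal(r$matched, 1)
  expect_equal(r$extra, 1)
  # exact match beats distance-1 match
  r2 <- match_boundaries(boundary_set(c(10, 11)), boundary_set(c(10)),
                         tolerance = 1)
  expect_equal(r2$matched, 1)
})

# exhaustive null distribution of the matched count for small n
pvalue_brute <- function(predicted, reference, n, tolerance = 1) {
  k <- length(predicted)
  obs <- match_boundaries(boundary_set(predicted), boundary_set(reference),
                          tolerance)$matched
  sets <- utils::combn(n - 1, k)
  min_sep <- if (k > 1) min(diff(predicted)) else 1
  hits <- 0; tot <- 0
  for (c_ in seq_len(ncol(sets))) {
    pos <- sets[, c_]
    if (k > 1 && min(diff(pos)) < min_sep) next
    tot <- tot + 1
    m <- match_boundaries(boundary_set(pos), boundary_set(reference),
                          tolerance)$matched
    if (m >= obs) hits <- hits + 1
  }
  hits / tot
}

test_that("Monte-Carlo boundary p-value matches exhaustive enumeration", {
  # n <= 8, one boundary
  for (case in list(list(p = 3, r = 3, n = 8), list(p = 2, r = 6, n = 8),
                    list(p = 4, r = 4, n = 6))) {
    exact <- pvalue_brute(case$p, case$r, case$n)
    mc <- boundary_null_pvalue(boundary_set(case$p), boundary_set(case$r),
                               case$n, n_mc = 20000, seed = 1)
    expect_equal(mc, exact, tolerance = 0.02)
  }
  # two boundaries with separation constraint
  exact2 <- pvalue_brute(c(2, 5), c(2, 5), 8)
  mc2 <- boundary_null_pvalue(boundary_set(c(2, 5)), boundary_set(c(2, 5)),
                              8, n_mc = 20000, seed = 2)
  expect_equal(mc2, exact2, tolerance = 0.02)
})

test_that("perfect agreement gives the 1/(n_mc+1) upper bound", {
  b <- boundary_set(seq(10, 190, by = 10))
  p <- boundary_null_pvalue(b, b, 200, n_mc = 1000, seed = 3)
  expect_equal(p, 1 / 1001)
})

test_that("null-calibrated p-values are roughly uniform", {
  set.seed(99)
  ps <- vapply(1:40, function(i) {
    pred <- boundary_set(sort(sample(seq(5, 195, by = 5), 8)))
    ref <- boundary_set(sort(sample(1:199, 8)))
    boundary_null_pvalue(pred, ref, 200, n_mc = 1000, seed = 100 + i)
  }, numeric(1))
  # independent sets: p should neither pile up near 0 nor near 1
  expect_gt(mean(ps > 0.1), 0.5)
  expect_gt(mean(ps < 0.9), 0.25)
  expect_gt(mean(ps), 0.25)
})

test_that("insulation comparison behaves at the rank-correlation limits", {
  v <- c(NA, NA, 3, 1, 4, 1, 5, 9, 2, 6, NA, NA)
  a <- structure(list(values = v, window = 2L), class = "insulation_profile")
  b <- structure(list(values = -v, window = 2L), class = "insulation_profile")
  expect_equal(compare_insulation(a, a)$rho, 1)
  expect_equal(compare_insulation(a, b)$rho, -1)
  short <- structure(list(values = c(NA, 1, 2, NA), window = 1L),
                     class = "insulation_profile")
  expect_error(compare_insulation(short, short), "fewer than 3")
})

test_that("independent long profiles decorrelate", {
  mk <- function(seed) {
    set.seed(seed)
    structure(list(values = rnorm(1000), window = 3L),
              class = "insulation_profile")
  }
  r <- compare_insulation(mk(1), mk(2))
  expect_lt(abs(r$rho), 0.1)
})
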