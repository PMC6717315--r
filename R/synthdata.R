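#' Linker-length mixture specification
#'
#' Describes the distribution of linker DNA lengths (the gaps between
#' consecutive nucleosome footprints) as a finite mixture over integer base
#' pairs.  Three component kinds are supported: a point mass, a discrete
#' uniform over an integer range, and a discretized (integer-binned)
#' lognormal truncated to an integer range.
#'
#' @param components list of components; each a list with elements
#'   `weight` (mixture probability), `kind` (one of `"point"`, `"range"`,
#'   `"lognormal"`), and kind-specific parameters: `value` for point,
#'   `lo`/`hi` for range, `meanlog`/`sdlog`/`lo`/`hi` for lognormal.
#' @param min_linker,max_linker support bounds in bp; sampled linkers are
#'   guaranteed to fall inside `[min_linker, max_linker]`.
#' @return an object of class `linker_spec`.
#' @seealso [default_linker_spec()], [sample_linker_lengths()]
#' @export
linker_spec <- function(components, min_linker = 0L, max_linker = 200L) {
  if (!is.list(components) || length(components) == 0L)
    stop("'components' must be a non-empty list")
  w <- vapply(components, function(cc) as.numeric(cc$weight), numeric(1))
  if (any(!is.finite(w)) || any(w < 0))
    stop("component weights must be finite and non-negative")
  if (abs(sum(w) - 1) > 1e-9)
    stop(sprintf("component weights must sum to 1 (got %.12f)", sum(w)))
  for (cc in components) {
    kind <- match.arg(cc$kind, c("point", "range", "lognormal"))
    sup <- switch(kind,
      point = c(cc$value, cc$value),
      range = c(cc$lo, cc$hi),
      lognormal = c(cc$lo, cc$hi))
    if (any(!is.finite(sup)) || any(sup < 0) || any(sup != floor(sup)))
      stop("component bp parameters must be non-negative integers")
    if (sup[1] > sup[2]) stop("component range is empty (lo > hi)")
    if (sup[1] < min_linker || sup[2] > max_linker)
      stop("component support outside [min_linker, max_linker]")
  }
  structure(list(components = components,
                 min_linker = as.integer(min_linker),
                 max_linker = as.integer(max_linker)),
            class = "linker_spec")
}

#' Probability mass function of a linker spec
#'
#' @param spec a [linker_spec()].
#' @return data.frame with columns `bp` (integers `min_linker:max_linker`)
#'   and `prob` (summing to 1).
#' @export
linker_pmf <- function(spec) {
  stopifnot(inherits(spec, "linker_spec"))
  bp <- spec$min_linker:spec$max_linker
  prob <- numeric(length(bp))
  for (cc in spec$components) {
    p <- switch(cc$kind,
      point = as.numeric(bp == cc$value),
      range = as.numeric(bp >= cc$lo & bp <= cc$hi) / (cc$hi - cc$lo + 1),
      lognormal = {
        q <- plnorm(bp + 0.5, cc$meanlog, cc$sdlog) -
             plnorm(pmax(bp - 0.5, 0), cc$meanlog, cc$sdlog)
        q[bp < cc$lo | bp > cc$hi] <- 0
        if (sum(q) <= 0) stop("lognormal component has zero mass on its range")
        q / sum(q)
      })
    prob <- prob + cc$weight * p
  }
  data.frame(bp = bp, prob = prob)
}

#' Mean linker length implied by a spec
#' @param spec a [linker_spec()].
#' @return mean in bp.
#' @export
linker_spec_mean <- function(spec) {
  pmf <- linker_pmf(spec)
  sum(pmf$bp * pmf$prob)
}

#' Default genome-wide linker-length spec
#'
#' A three-component mixture emulating the multimodal linker-length
#' distribution of yeast chromatin: about 25% of linkers at 1-3 bp, a broad
#' peak (discretized lognormal, mode 16 bp) over 4-49 bp, and about 12% of
#' long NDR-like linkers at 50-200 bp, with an overall mean of ~28.7 bp.
#' Linkers above 200 bp are excluded (treated as unmappable-region
#' artifacts).  The lognormal width is solved numerically so the overall
#' mean equals `mean_bp`.
#'
#' @param mean_bp target overall mean linker length in bp (default 28.7).
#' @return a [linker_spec()].
#' @export
default_linker_spec <- function(mean_bp = 28.7) {
  w <- c(short = 0.25, mid = 0.63, long = 0.12)
  mean_short <- 2        # uniform on 1..3
  mean_long <- 125       # uniform on 50..200
  target_mid <- (mean_bp - w[["short"]] * mean_short -
                   w[["long"]] * mean_long) / w[["mid"]]
  mid_mean <- function(sdlog) {
    bp <- 4:49
    q <- plnorm(bp + 0.5, log(16) + sdlog^2, sdlog) -
         plnorm(bp - 0.5, log(16) + sdlog^2, sdlog)
    sum(bp * q) / sum(q)
  }
  sdlog <- uniroot(function(s) mid_mean(s) - target_mid,
                   interval = c(0.05, 1.5), tol = 1e-10)$root
  linker_spec(list(
    list(weight = w[["short"]], kind = "range", lo = 1L, hi = 3L),
    list(weight = w[["mid"]], kind = "lognormal",
         meanlog = log(16) + sdlog^2, sdlog = sdlog, lo = 4L, hi = 49L),
    list(weight = w[["long"]], kind = "range", lo = 50L, hi = 200L)),
    min_linker = 0L, max_linker = 200L)
}

#' Sample linker lengths from a mixture spec
#'
#' @param spec a [linker_spec()].
#' @param n number of linkers to draw (>= 1).
#' @param seed integer seed; identical seeds give identical samples.
#' @return integer vector of length `n`.
#' @export
sample_linker_lengths <- function(spec, n, seed) {
  stopifnot(inherits(spec, "linker_spec"))
  stop_if_not_scalar_count(n, "n")
  if (n < 1) stop("'n' must be >= 1")
  pmf <- linker_pmf(spec)
  with_seed(seed,
    sample(pmf$bp, size = n, replace = TRUE, prob = pmf$prob))
}

#' Nucleosome position set
#'
#' Ordered, non-overlapping nucleosome footprints within a genomic region,
#' in 0-based half-open (BED) coordinates.  The linker length between
#' nucleosomes i and i+1 is `starts[i+1] - (starts[i] + footprint_bp)`.
#'
#' @param starts 0-based footprint start coordinates, strictly increasing.
#' @param region_length region length in bp.
#' @param footprint_bp nucleosome footprint (default 147 bp, the canonical
#'   wrapped length).
#' @param region_name region label (BED chrom field).
#' @return an object of class `nuc_positions`.
#' @export
nuc_positions <- function(starts, region_length,
                          footprint_bp = 147L, region_name = "region") {
  starts <- as.numeric(starts)
  if (length(starts) < 1L) stop("no nucleosomes")
  if (is.unsorted(starts, strictly = TRUE))
    stop("nucleosome starts must be strictly increasing")
  if (length(starts) > 1L && any(diff(starts) < footprint_bp))
    stop("overlapping nucleosome footprints")
  if (starts[1] < 0 || starts[length(starts)] + footprint_bp > region_length)
    stop("nucleosome footprint outside [0, region_length)")
  structure(list(region_name = region_name,
                 region_length = as.numeric(region_length),
                 footprint_bp = as.integer(footprint_bp),
                 starts = starts),
            class = "nuc_positions")
}

#' @export
print.nuc_positions <- function(x, ...) {
  ll <- linker_lengths(x)
  cat(sprintf("<nuc_positions> %s: %d nucleosomes in %g bp (footprint %d bp)\n",
              x$region_name, length(x$starts), x$region_length, x$footprint_bp))
  if (length(ll))
    cat(sprintf("  linkers: mean %.1f bp, range [%g, %g]\n",
                mean(ll), min(ll), max(ll)))
  invisible(x)
}

#' Linker lengths of a position set
#' @param positions a [nuc_positions()] object.
#' @return numeric vector of length `n_nucleosomes - 1` (bp).
#' @export
linker_lengths <- function(positions) {
  stopifnot(inherits(positions, "nuc_positions"))
  if (length(positions$starts) < 2L) return(numeric(0))
  diff(positions$starts) - positions$footprint_bp
}

#' Generate nucleosome positions by tiling sampled linkers
#'
#' Tiles a region left to right: the first footprint starts at 0 and each
#' subsequent start follows after a linker drawn from `spec`, until no
#' further footprint fits.
#'
#' @inheritParams sample_linker_lengths
#' @param region_length region length in bp (> `footprint_bp`).
#' @param footprint_bp footprint length (default 147).
#' @param region_name region label.
#' @return a [nuc_positions()] object.
#' @export
generate_positions <- function(spec, region_length, footprint_bp = 147L,
                               seed = 1L, region_name = "synthetic") {
  stopifnot(inherits(spec, "linker_spec"))
  if (region_length <= footprint_bp)
    stop("region too short for a single nucleosome")
  mu <- max(linker_spec_mean(spec), 1)
  est <- ceiling(region_length / (footprint_bp + mu)) + 50L
  linkers <- sample_linker_lengths(spec, est, seed)
  k <- 2L
  while (sum(footprint_bp + linkers) < region_length) {
    linkers <- c(linkers,
                 sample_linker_lengths(spec, est, derive_seed(seed, k)))
    k <- k + 1L
  }
  starts <- cumsum(c(0, footprint_bp + linkers))
  starts <- starts[starts + footprint_bp <= region_length]
  nuc_positions(starts, region_length, footprint_bp, region_name)
}

#' Generate a regularly spaced nucleosome array
#'
#' Periodic tiling with a fixed linker (default geometry of in-vitro
#' reconstituted regular fibers); the region length is the minimal
#' container, ending flush with the final footprint.
#'
#' @param linker_bp fixed linker length in bp.
#' @param n_nucleosomes number of nucleosomes (>= 1).
#' @param footprint_bp footprint length (default 147).
#' @param region_name region label.
#' @return a [nuc_positions()] object.
#' @export
generate_regular_positions <- function(linker_bp, n_nucleosomes,
                                       footprint_bp = 147L,
                                       region_name = "regular") {
  stop_if_not_scalar_count(n_nucleosomes, "n_nucleosomes")
  if (n_nucleosomes < 1) stop("'n_nucleosomes' must be >= 1")
  stop_if_not_scalar_count(linker_bp, "linker_bp")
  starts <- (seq_len(n_nucleosomes) - 1) * (footprint_bp + linker_bp)
  nuc_positions(starts, starts[n_nucleosomes] + footprint_bp,
                footprint_bp, region_name)
}

#' Generate irregular positions with a matched bead count
#'
#' Samples linkers from `spec` until the resulting bead chain (one
#' nucleosome bead per footprint plus `round(linker/bp_per_bead)` DNA
#' beads per linker, no flanking DNA) reaches `n_beads_target` beads.
#' Used to build irregular/regular fiber pairs of equal bead count for
#' compaction comparisons, where bead count rather than genomic span must
#' match.
#'
#' @inheritParams generate_positions
#' @param n_beads_target desired chain size in beads.
#' @param bp_per_bead base pairs per DNA bead (default 8).
#' @return a [nuc_positions()] object whose [build_chain()] result has at
#'   least `n_beads_target` beads (overshoot at most the final linker's
#'   beads plus one nucleosome).
#' @export
generate_matched_positions <- function(spec, n_beads_target,
                                       footprint_bp = 147L, bp_per_bead = 8L,
                                       seed = 1L,
                                       region_name = "synthetic_matched") {
  stopifnot(inherits(spec, "linker_spec"))
  stop_if_not_scalar_count(n_beads_target, "n_beads_target")
  mu <- max(linker_spec_mean(spec), 1)
  est <- ceiling(n_beads_target / (1 + mu / bp_per_bead)) + 50L
  linkers <- sample_linker_lengths(spec, est, seed)
  k <- 2L
  repeat {
    beads <- 1L + cumsum(1L + round_half_up(linkers / bp_per_bead))
    if (max(beads) >= n_beads_target) break
    linkers <- c(linkers,
                 sample_linker_lengths(spec, est, derive_seed(seed, k)))
    k <- k + 1L
  }
  n_link <- which(beads >= n_beads_target)[1]
  use <- linkers[seq_len(n_link)]
  starts <- cumsum(c(0, footprint_bp + use))
  nuc_positions(starts, max(starts) + footprint_bp, footprint_bp,
                region_name)
}

#' Gene annotation set
#'
#' @param intervals data.frame with columns `start`, `end` (0-based
#'   half-open bp), `strand` (`"+"`/`"-"`), `active` (logical).
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(intervals) {
  need <- c("start", "end", "strand", "active")
  if (!all(need %in% names(intervals)))
    stop("intervals must have columns start, end, strand, active")
  if (any(intervals$end <= intervals$start))
    stop("gene intervals must satisfy start < end")
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes (%d active)\n",
              nrow(x$intervals), sum(x$intervals$active)))
  invisible(x)
}

#' Generate non-overlapping toy gene annotations
#'
#' Places `n_genes` non-overlapping genes of length >= 1 kbp at random
#' within the region, with random strands and activity flags.  Useful as a
#' fixture for linker-context classification.
#'
#' @param region_length region length in bp.
#' @param n_genes number of genes (>= 0).
#' @param seed integer seed.
#' @param min_len,max_len gene length bounds in bp (min 1000).
#' @return a [gene_annotation()] object.
#' @export
generate_toy_genes <- function(region_length, n_genes, seed = 1L,
                               min_len = 1000L, max_len = 2500L) {
  stop_if_not_scalar_count(n_genes, "n_genes")
  if (min_len < 1000L) stop("genes must be at least 1 kbp")
  if (n_genes == 0L)
    return(gene_annotation(data.frame(start = numeric(0), end = numeric(0),
                                      strand = character(0),
                                      active = logical(0))))
  with_seed(seed, {
    lens <- sample(min_len:max_len, n_genes, replace = TRUE)
    slack <- region_length - sum(lens)
    if (slack < 0)
      stop(sprintf("region of %g bp cannot fit %d genes", region_length,
                   n_genes))
    # distribute the remaining space as random inter-gene gaps
    cuts <- sort(sample(0:slack, n_genes, replace = TRUE))
    starts <- cuts + cumsum(c(0, lens[-n_genes]))
    gene_annotation(data.frame(
      start = starts, end = starts + lens,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      active = sample(c(TRUE, FALSE), n_genes, replace = TRUE)))
  })
}

#' Generate a contact map with planted domains
#'
#' Block-model fixture for boundary calling: nucleosome pairs within the
#' same planted domain interact with `intra_over_inter` times the weight of
#' between-domain pairs; `reads` contacts are drawn multinomially.
#'
#' @param n_nucleosomes map size.
#' @param boundary_positions nucleosome indices (1-based, strictly inside
#'   `(0, n_nucleosomes)`) after which a new domain starts.
#' @param reads total read count.
#' @param intra_over_inter within/between interaction ratio (> 1).
#' @param seed integer seed.
#' @return a [contact_map()] with `provenance = "simulated"`.
#' @export
generate_planted_domain_map <- function(n_nucleosomes, boundary_positions,
                                        reads, intra_over_inter, seed = 1L) {
  stop_if_not_scalar_count(n_nucleosomes, "n_nucleosomes")
  stop_if_not_scalar_count(reads, "reads")
  b <- sort(unique(as.integer(boundary_positions)))
  if (length(b) && (any(b <= 0) || any(b >= n_nucleosomes)))
    stop("boundary positions must lie strictly inside (0, n_nucleosomes)")
  if (intra_over_inter <= 1)
    stop("'intra_over_inter' must exceed 1 (no planted structure otherwise)")
  dom <- findInterval(seq_len(n_nucleosomes) - 1L, b) # domain id per nucleosome
  ut <- which(upper.tri(matrix(0, n_nucleosomes, n_nucleosomes)))
  ij <- arrayInd(ut, c(n_nucleosomes, n_nucleosomes))
  w <- ifelse(dom[ij[, 1]] == dom[ij[, 2]], intra_over_inter, 1)
  cnt <- with_seed(seed, as.vector(rmultinom(1, reads, w)))
  m <- matrix(0L, n_nucleosomes, n_nucleosomes)
  m[ut] <- cnt
  m <- m + t(m)
  contact_map(m, lc = NA_real_, provenance = "simulated")
}
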