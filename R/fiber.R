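#' Build the bead-spring heteropolymer for a nucleosome position set
#'
#' Converts nucleosome positions into the coarse-grained chain topology:
#' each nucleosome (histone octamer plus wrapped DNA) becomes one 10-nm
#' sphere (diameter 4 sigma), and each stretch of linker DNA becomes
#' `round(bp / bp_per_bead)` 2.5-nm DNA beads (diameter 1 sigma, one bead
#' per ~8 bp).  Rounding is half-up, so linkers shorter than
#' `bp_per_bead/2` produce zero DNA beads and a direct nucleosome-
#' nucleosome bond - a common case, since ~25% of yeast linkers are 1-3 bp.
#' Consecutive beads are bonded with rest length equal to the sum of their
#' radii (DNA-DNA 1 sigma, DNA-NUC 2.5 sigma, NUC-NUC 4 sigma), so bonded
#' beads touch at rest.  Bending triplets carry the Kratky-Porod stiffness
#' and are placed on DNA-DNA-DNA triples only: the DNA-nucleosome-DNA
#' junction acts as a freely rotating joint.  Flanking DNA before the
#' first and after the last nucleosome is included.
#'
#' @param positions a [nuc_positions()] object (non-overlap is enforced by
#'   that constructor; overlapping input is an error).
#' @param bp_per_bead base pairs per DNA bead (default 8).
#' @return an object of class `bead_chain` with elements:
#'   \describe{
#'     \item{n_beads}{bead count}
#'     \item{kind}{character vector, `"DNA"` or `"NUC"` per bead}
#'     \item{diameter}{per-bead diameter in sigma (1 or 4)}
#'     \item{bonds}{data.frame `i`, `j` (1-based, consecutive), `r0` (sigma)}
#'     \item{triplets}{integer matrix (n_triplets x 3) of DNA-only bends}
#'     \item{nuc_bead_index}{bead index of each nucleosome (genomic order)}
#'     \item{bead_to_bp}{genomic bp midpoint per bead}
#'     \item{region_length, region_name, footprint_bp}{provenance}
#'   }
#' @export
build_chain <- function(positions, bp_per_bead = 8L) {
  stopifnot(inherits(positions, "nuc_positions"))
  if (bp_per_bead < 1) stop("'bp_per_bead' must be >= 1")
  fp <- positions$footprint_bp
  starts <- positions$starts
  n_nuc <- length(starts)

  # segments: flank, nuc, linker, nuc, ..., flank
  kind <- character(0)
  mid <- numeric(0)
  nuc_idx <- integer(n_nuc)

  add_dna <- function(a, b) {
    # linker spanning [a, b); n beads share the span evenly
    nb <- round_half_up((b - a) / bp_per_bead)
    if (nb <= 0) return(invisible(NULL))
    m <- a + (seq_len(nb) - 0.5) * (b - a) / nb
    kind <<- c(kind, rep("DNA", nb))
    mid <<- c(mid, m)
    invisible(NULL)
  }

  add_dna(0, starts[1])
  for (i in seq_len(n_nuc)) {
    kind <- c(kind, "NUC")
    mid <- c(mid, starts[i] + fp / 2)
    nuc_idx[i] <- length(kind)
    nxt <- if (i < n_nuc) starts[i + 1] else positions$region_length
    add_dna(starts[i] + fp, nxt)
  }

  n <- length(kind)
  diameter <- ifelse(kind == "NUC", 4, 1)
  if (n > 1L) {
    i <- seq_len(n - 1L)
    bonds <- data.frame(i = i, j = i + 1L,
                        r0 = (diameter[i] + diameter[i + 1L]) / 2)
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  }
  trip <- if (n >= 3L) {
    j <- 2:(n - 1L)
    ok <- kind[j - 1L] == "DNA" & kind[j] == "DNA" & kind[j + 1L] == "DNA"
    cbind(j[ok] - 1L, j[ok], j[ok] + 1L)
  } else matrix(integer(0), 0, 3)

  structure(list(n_beads = n, kind = kind, diameter = diameter,
                 bonds = bonds, triplets = trip,
                 nuc_bead_index = nuc_idx, bead_to_bp = mid,
                 region_length = positions$region_length,
                 region_name = positions$region_name,
                 footprint_bp = fp),
            class = "bead_chain")
}

#' Build a bare DNA chain (no nucleosomes)
#'
#' Convenience constructor for calibration runs (persistence-length
#' recovery, bare-window compaction): a linear chain of `n_beads` DNA
#' beads with bonds at 1 sigma and bending triplets throughout.
#'
#' @param n_beads number of DNA beads.
#' @param bp_per_bead base pairs per bead (metadata only; default 8).
#' @return a `bead_chain`.
#' @export
build_dna_chain <- function(n_beads, bp_per_bead = 8L) {
  stop_if_not_scalar_count(n_beads, "n_beads")
  if (n_beads < 1) stop("'n_beads' must be >= 1")
  n <- as.integer(n_beads)
  kind <- rep("DNA", n)
  diameter <- rep(1, n)
  bonds <- if (n > 1L) {
    i <- seq_len(n - 1L)
    data.frame(i = i, j = i + 1L, r0 = rep(1, n - 1L))
  } else data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  trip <- if (n >= 3L) cbind(1:(n - 2L), 2:(n - 1L), 3:n)
          else matrix(integer(0), 0, 3)
  structure(list(n_beads = n, kind = kind, diameter = diameter,
                 bonds = bonds, triplets = trip,
                 nuc_bead_index = integer(0),
                 bead_to_bp = (seq_len(n) - 0.5) * bp_per_bead,
                 region_length = n * bp_per_bead,
                 region_name = "bare_dna", footprint_bp = 147L),
            class = "bead_chain")
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf("<bead_chain> %s: %d beads (%d NUC, %d DNA), %d bonds, %d bends\n",
              x$region_name, x$n_beads, sum(x$kind == "NUC"),
              sum(x$kind == "DNA"), nrow(x$bonds), nrow(x$triplets)))
  invisible(x)
}

#' Export a chain as an annotated bead table
#'
#' @param chain a `bead_chain`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_chain_table <- function(chain, path) {
  stopifnot(inherits(chain, "bead_chain"))
  df <- data.frame(bead = seq_len(chain$n_beads), kind = chain$kind,
                   diameter_sigma = chain$diameter,
                   bp_midpoint = chain$bead_to_bp)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
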