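# Readers and writers for the plain-text formats the pipeline touches.
# Conventions: BED is 0-based half-open; nucleosome-indexed artifacts
# (dense maps, pair lists, boundary tables) are written 0-based with the
# index origin stated in the header, and converted to the package's
# 1-based indices on read.

#' Write nucleosome positions as BED3
#' @param positions a [nuc_positions()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_positions <- function(positions, path) {
  stopifnot(inherits(positions, "nuc_positions"))
  df <- data.frame(chrom = positions$region_name,
                   start = format(positions$starts, scientific = FALSE,
                                  trim = TRUE),
                   end = format(positions$starts + positions$footprint_bp,
                                scientific = FALSE, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read nucleosome positions from BED3
#'
#' Footprints must be non-overlapping and of one uniform width (the
#' inferred footprint); violations are reported with the offending line
#' number.
#'
#' @param path BED3 file (chrom, start, end; 0-based half-open).
#' @param region_length region length in bp; defaults to the largest end
#'   coordinate.
#' @return a [nuc_positions()] object.
#' @export
read_positions <- function(path, region_length = NULL) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               colClasses = c("character", "numeric", "numeric")),
    error = function(e) stop(sprintf("no nucleosomes in '%s'", path),
                             call. = FALSE))
  if (nrow(df) == 0) stop(sprintf("no nucleosomes in '%s'", path))
  o <- order(df[[2]])
  df <- df[o, ]
  widths <- df[[3]] - df[[2]]
  if (length(unique(widths)) != 1L) {
    bad <- o[which(widths != widths[1])[1]]
    stop(sprintf("mixed footprint widths in '%s' (line %d: %g bp vs %g bp)",
                 path, bad, widths[widths != widths[1]][1], widths[1]))
  }
  if (nrow(df) > 1L) {
    ov <- which(diff(df[[2]]) < widths[1])
    if (length(ov))
      stop(sprintf("overlapping nucleosomes in '%s' (line %d overlaps its predecessor)",
                   path, o[ov[1] + 1L]))
  }
  nuc_positions(df[[2]],
                region_length %||% max(df[[3]]),
                footprint_bp = widths[1],
                region_name = df[[1]][1])
}

#' Write gene annotations as BED6
#'
#' The score column carries the activity flag (1 = active, 0 = inactive).
#'
#' @param genes a [gene_annotation()] object.
#' @param path output path.
#' @param chrom chromosome/region label.
#' @return the path, invisibly.
#' @export
write_genes <- function(genes, path, chrom = "region") {
  stopifnot(inherits(genes, "gene_annotation"))
  gi <- genes$intervals
  df <- data.frame(chrom = chrom, start = gi$start, end = gi$end,
                   name = sprintf("gene%d", seq_len(nrow(gi))),
                   score = as.integer(gi$active), strand = gi$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene annotations (BED6 or GFF3)
#'
#' BED6: the score column is interpreted as the activity flag.  GFF3
#' (via rtracklayer, if installed): `gene`-type records, 1-based GFF
#' coordinates converted to 0-based half-open, all genes marked active
#' unless an `active` attribute is present.
#'
#' @param path input path.
#' @param format `"bed"` or `"gff3"`.
#' @return a [gene_annotation()] object.
#' @export
read_genes <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#")
    if (ncol(df) < 6) stop("BED6 with score and strand columns required")
    return(gene_annotation(data.frame(
      start = df[[2]], end = df[[3]], strand = df[[6]],
      active = df[[5]] != 0)))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("GFF3 import requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  act <- if ("active" %in% names(S4Vectors::mcols(gr)))
    as.logical(gr$active) else rep(TRUE, length(gr))
  gene_annotation(data.frame(
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    active = act))
}

#' Write a contact map
#'
#' Dense format: tab-separated integer matrix under a single header line
#' `#n=<count> lc=<nm>`.  Pairs format: header then `i j count` triples
#' (0-based indices, upper triangle).
#'
#' @param map a [contact_map()].
#' @param path output path.
#' @param format `"dense"` or `"pairs"`.
#' @return the path, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("dense", "pairs")) {
  stopifnot(inherits(map, "contact_map"))
  format <- match.arg(format)
  hdr <- sprintf("#n=%d lc=%s index_origin=0", map$n,
                 if (is.finite(map$lc)) format(map$lc) else "NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (format == "dense") {
    write.table(map$counts, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    ut <- which(upper.tri(map$counts) & map$counts > 0, arr.ind = TRUE)
    df <- data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L,
                     count = map$counts[ut])
    write.table(df[order(df$i, df$j), ], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a contact map
#'
#' Accepts the dense and pairs formats of [write_contact_map()].  Dense
#' input must be square; asymmetric input is symmetrized (elementwise max
#' of the triangles) with a warning; the diagonal is zeroed; negative
#' counts are an error.  Pair indices are 0-based.
#'
#' @param path input path.
#' @param format `"dense"` or `"pairs"`; `"auto"` detects from the column
#'   count.
#' @param n map size, required for pairs input without a header.
#' @return a [contact_map()] (`provenance = "experimental"`).
#' @export
read_contact_map <- function(path, format = c("auto", "dense", "pairs"),
                             n = NULL) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L)
  lc <- NA_real_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("n=([0-9]+)", first))[[1]]
    if (length(m) == 2) n <- as.integer(m[2])
    m <- regmatches(first, regexec("lc=([0-9.]+)", first))[[1]]
    if (length(m) == 2) lc <- as.numeric(m[2])
  }
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#")
  if (format == "auto") {
    # 3 columns means a pair list, except the ambiguous 3 x 3 dense case
    format <- if (ncol(df) == 3 &&
                  (nrow(df) != 3 || isTRUE(n > 3))) "pairs" else "dense"
  }
  if (format == "dense") {
    mat <- as.matrix(df)
    if (nrow(mat) != ncol(mat))
      stop(sprintf("dense contact map must be square (got %d x %d)",
                   nrow(mat), ncol(mat)))
  } else {
    if (ncol(df) != 3) stop("pairs format requires 3 columns: i j count")
    if (is.null(n)) n <- max(df[[1]], df[[2]]) + 1L
    mat <- matrix(0, n, n)
    mat[cbind(df[[1]] + 1L, df[[2]] + 1L)] <- df[[3]]
    mat <- pmax(mat, t(mat))
  }
  if (any(mat < 0)) stop("negative counts in contact map")
  contact_map(mat, lc = lc, provenance = "experimental")
}

#' Write an insulation profile as TSV
#' @param profile an [insulation_profile()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_insulation <- function(profile, path) {
  stopifnot(inherits(profile, "insulation_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#window=%d index_origin=0", profile$window), con)
  df <- data.frame(nucleosome = seq_along(profile$values) - 1L,
                   insulation = profile$values)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called boundaries as BED
#'
#' Each boundary is written as the footprint interval of its nucleosome,
#' with the strength in the score column.
#'
#' @param boundaries a [boundary_set()].
#' @param positions the [nuc_positions()] the map indices refer to.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_boundaries <- function(boundaries, positions, path) {
  stopifnot(inherits(boundaries, "boundary_set"),
            inherits(positions, "nuc_positions"))
  b <- boundaries$positions
  df <- data.frame(chrom = positions$region_name,
                   start = positions$starts[b],
                   end = positions$starts[b] + positions$footprint_bp,
                   name = sprintf("boundary%d", seq_along(b)),
                   score = signif(boundaries$strengths, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export an ensemble as extended XYZ
#'
#' One frame per snapshot; the element label encodes the bead kind
#' (`D` = DNA, `N` = nucleosome), coordinates in sigma.
#'
#' @param ensemble an `ensemble`.
#' @param path output path.
#' @param frames snapshot indices to write (default all).
#' @return the path, invisibly.
#' @export
write_xyz <- function(ensemble, path, frames = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  frames <- frames %||% seq_len(n_snapshots(ensemble))
  lab <- ifelse(ensemble$chain$kind == "NUC", "N", "D")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in frames) {
    writeLines(as.character(ensemble$chain$n_beads), con)
    writeLines(sprintf("frame=%d time=%g replica=%d", k, ensemble$time[k],
                       ensemble$replica[k]), con)
    xyz <- ensemble$coords[, , k]
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}
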