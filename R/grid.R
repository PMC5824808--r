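#' Genome segment grid
#'
#' A `genome_grid` records autosome lengths and the shared segment boundaries
#' produced by joint segmentation of all samples of a patient. Coordinates are
#' 0-based half-open; chromosome names carry no "chr" prefix; sex chromosomes
#' are excluded throughout (allele-specific states are confounded on X/Y).
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param boundaries Named list (same names) of strictly increasing interior
#'   boundary positions, each within `(0, length)`. Chromosome start and end
#'   are implicit boundaries and must not be listed.
#' @return An object of class `genome_grid`.
#' @export
genome_grid <- function(chrom_lengths, boundaries = NULL) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must have unique names")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(boundaries)) {
    boundaries <- lapply(chrom_lengths, function(x) numeric(0))
  }
  if (!setequal(names(boundaries), names(chrom_lengths)))
    stop("boundaries must be named by chromosome")
  boundaries <- boundaries[names(chrom_lengths)]
  for (ch in names(chrom_lengths)) {
    b <- boundaries[[ch]]
    if (length(b) && (is.unsorted(b, strictly = TRUE) ||
                      any(b <= 0) || any(b >= chrom_lengths[[ch]])))
      stop("boundaries on chromosome ", ch,
           " must be strictly increasing and inside (0, length)")
  }
  structure(list(chrom_lengths = chrom_lengths, boundaries = boundaries),
            class = "genome_grid")
}

#' Segment table of a grid
#'
#' Expands a grid into one row per segment with `chrom`, `start`, `end`.
#'
#' @param grid A `genome_grid`.
#' @return data.frame of segments in genome order.
#' @export
grid_segments <- function(grid) {
  stopifnot(inherits(grid, "genome_grid"))
  out <- lapply(names(grid$chrom_lengths), function(ch) {
    b <- c(0, grid$boundaries[[ch]], grid$chrom_lengths[[ch]])
    data.frame(chrom = ch, start = b[-length(b)], end = b[-1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Desk-scale toy genome
#'
#' Default simulation genome: 4 chromosomes of 50 Mb each, cut into 2 Mb loci
#' (100 loci genome wide). Every locus exceeds the 1 Mb minimum detectable
#' lesion size the crypt-level arrays support.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param locus_bp Locus (grid segment) size in bp; must divide `chrom_len`.
#' @return A `genome_grid`.
#' @export
toy_genome_grid <- function(n_chrom = 4, chrom_len = 50e6, locus_bp = 2e6) {
  if (chrom_len %% locus_bp != 0) stop("locus_bp must divide chrom_len")
  lens <- stats::setNames(rep(chrom_len, n_chrom), as.character(seq_len(n_chrom)))
  bnds <- lapply(lens, function(L) seq(locus_bp, L - locus_bp, by = locus_bp))
  genome_grid(lens, bnds)
}

#' @export
print.genome_grid <- function(x, ...) {
  n_seg <- sum(vapply(x$boundaries, length, 1L)) + length(x$chrom_lengths)
  cat(sprintf("genome_grid: %d chromosomes, %d segments, %.1f Mb total\n",
              length(x$chrom_lengths), n_seg, sum(x$chrom_lengths) / 1e6))
  invisible(x)
}
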