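#' Genetic length of the ten sorghum chromosomes
#'
#' Chromosome lengths (cM) of the consensus sorghum genetic map used as the
#' default simulated genome; they sum to 1545.1 cM. The same table ships as a
#' plain-text fixture in \code{inst/extdata/sorghum_chr_lengths.tsv}.
#'
#' @return Named numeric vector of ten chromosome lengths in centimorgans.
#' @export
sorghum_chr_lengths <- function() {
  c(chr1 = 186.3, chr2 = 226.5, chr3 = 168.2, chr4 = 169.4, chr5 = 118.5,
    chr6 = 165.2, chr7 = 132.6, chr8 = 131.7, chr9 = 134.6, chr10 = 112.1)
}

#' Construct a genetic map
#'
#' A genetic map holds, per chromosome, ordered locus identifiers and strictly
#' increasing centimorgan positions, plus the recombination scaling factor
#' already applied to it (1 for a base map).
#'
#' @param chrom Integer vector, chromosome index (1-based) per locus.
#' @param id Character vector of locus identifiers.
#' @param pos Numeric vector of within-chromosome cM positions.
#' @param lengths Numeric vector of chromosome lengths (cM), one per
#'   chromosome; defaults to the maximum position per chromosome.
#' @param factor Recombination scaling multiplier already applied (default 1).
#'
#' @return An object of class \code{genetic_map}.
#' @export
genetic_map <- function(chrom, id, pos, lengths = NULL, factor = 1) {
  chrom <- as.integer(chrom)
  pos <- as.numeric(pos)
  stopifnot(length(chrom) == length(pos), length(id) == length(pos))
  if (is.unsorted(chrom)) stop("loci must be grouped by chromosome, in order")
  nchr <- max(chrom)
  if (is.null(lengths)) lengths <- vapply(seq_len(nchr), function(c)
    max(pos[chrom == c]), numeric(1))
  if (length(lengths) != nchr) stop("one length per chromosome required")
  for (c in seq_len(nchr)) {
    p <- pos[chrom == c]
    if (length(p) == 0L) stop("chromosome ", c, " has no loci")
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing")
    if (p[1] <= 0 || p[length(p)] > lengths[c] + 1e-9)
      stop("positions must lie in (0, length]")
  }
  if (factor <= 0) stop("factor must be positive")
  cnt <- tabulate(chrom, nchr)
  structure(list(
    chrom = chrom, id = as.character(id), pos = pos,
    lengths = as.numeric(lengths),
    chr_start = c(0L, cumsum(cnt)[-nchr]),  # 0-based offsets
    chr_len = cnt,
    factor = as.numeric(factor)
  ), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf(
    "genetic_map: %d chromosomes, %d loci, %.1f cM total, factor %g\n",
    length(x$lengths), length(x$pos), sum(x$lengths), x$factor))
  invisible(x)
}

#' Number of loci of a genetic map
#' @param map A \code{genetic_map}.
#' @return Integer locus count.
#' @export
n_loci <- function(map) length(map$pos)

#' Rescale a genetic map to emulate an increased recombination rate
#'
#' Multiplies every locus position and chromosome length by \code{factor},
#' preserving locus identity and order. Because the expected crossover count
#' per chromosome is proportional to its genetic length, a 2-, 4-, or 8-fold
#' map expansion realises a 2-, 4-, or 8-fold recombination-rate increase.
#'
#' @param map A base \code{genetic_map} (\code{map$factor} must be 1).
#' @param factor Positive multiplier.
#' @return The scaled \code{genetic_map} with \code{factor} recorded.
#' @export
scale_map <- function(map, factor) {
  stopifnot(inherits(map, "genetic_map"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("factor must be a positive scalar")
  if (map$factor != 1) stop("scaling is always applied to the base map")
  map$pos <- map$pos * factor
  map$lengths <- map$lengths * factor
  map$factor <- factor
  map
}

#' Write a genetic map as a PLINK-dialect .map file
#'
#' Four whitespace-separated columns: chromosome, locus id, cM position, and a
#' base-pair column fixed at 0. Positions are written with full precision so
#' that \code{read_genetic_map} round-trips exactly.
#'
#' @param map A \code{genetic_map}.
#' @param file Output path.
#' @export
write_genetic_map <- function(map, file) {
  stopifnot(inherits(map, "genetic_map"))
  lines <- sprintf("%d\t%s\t%s\t0", map$chrom, map$id,
                   sprintf("%.17g", map$pos))
  writeLines(lines, file)
  invisible(file)
}

#' Read a PLINK-dialect .map file
#'
#' @param file Path to a four-column map file (chromosome, id, cM, bp).
#' @param lengths Optional chromosome lengths; defaults to the last position
#'   of each chromosome.
#' @param factor Scaling factor carried by the map (default 1).
#' @return A \code{genetic_map}.
#' @export
read_genetic_map <- function(file, lengths = NULL, factor = 1) {
  tab <- read.table(file, header = FALSE,
                    colClasses = c("integer", "character", "numeric", "NULL"))
  genetic_map(tab[[1]], tab[[2]], tab[[3]], lengths = lengths,
              factor = factor)
}
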