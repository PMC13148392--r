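#' Construct a population of diploid individuals
#'
#' Haplotypes are stored as two integer matrices (loci x individuals) with
#' 0/1 allele coding; genotype dosage at a locus is the sum of the two
#' haplotype alleles, in \{0, 1, 2\}.
#'
#' @param h1,h2 Integer matrices, loci x individuals.
#' @param map The \code{genetic_map} the loci refer to.
#' @param inbred Logical vector flagging fully homozygous individuals.
#' @param generation Generation label (free text).
#' @return An object of class \code{population}.
#' @export
new_population <- function(h1, h2, map, inbred = NULL, generation = "") {
  stopifnot(inherits(map, "genetic_map"),
            nrow(h1) == n_loci(map), nrow(h2) == n_loci(map),
            ncol(h1) == ncol(h2))
  if (is.null(inbred)) inbred <- rep(FALSE, ncol(h1))
  stopifnot(length(inbred) == ncol(h1))
  structure(list(h1 = h1, h2 = h2, map = map, inbred = inbred,
                 generation = as.character(generation)),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals, %d loci, generation '%s'\n",
              n_ind(x), nrow(x$h1), x$generation))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A \code{population}.
#' @return Integer count.
#' @export
n_ind <- function(pop) ncol(pop$h1)

#' Extract one individual from a population
#'
#' @param pop A \code{population}.
#' @param i Individual index.
#' @return An object of class \code{individual}: a list with haplotype
#'   vectors \code{h1}, \code{h2} and the \code{inbred} flag.
#' @export
get_individual <- function(pop, i) {
  structure(list(h1 = pop$h1[, i], h2 = pop$h2[, i],
                 inbred = pop$inbred[i]), class = "individual")
}

#' Assemble individuals into a population
#'
#' @param inds List of \code{individual} objects defined on \code{map}.
#' @param map A \code{genetic_map}.
#' @param generation Generation label.
#' @return A \code{population}.
#' @export
as_population <- function(inds, map, generation = "") {
  h1 <- vapply(inds, `[[`, integer(n_loci(map)), "h1")
  h2 <- vapply(inds, `[[`, integer(n_loci(map)), "h2")
  new_population(matrix(h1, nrow = n_loci(map)),
                 matrix(h2, nrow = n_loci(map)), map,
                 inbred = vapply(inds, `[[`, logical(1), "inbred"),
                 generation = generation)
}

#' Genotype dosage matrix of a population
#'
#' @param pop A \code{population}.
#' @param loci Integer locus indices (default: all loci).
#' @return Numeric matrix, individuals x loci, entries in \{0, 1, 2\}.
#' @export
dosage_matrix <- function(pop, loci = seq_len(nrow(pop$h1))) {
  cpp_dosage(pop$h1, pop$h2, as.integer(loci))
}

#' Allele frequencies at a set of loci
#' @param pop A \code{population}.
#' @param loci Integer locus indices (default: all loci).
#' @return Numeric vector of allele-1 frequencies computed from haplotypes.
#' @export
allele_freq <- function(pop, loci = seq_len(nrow(pop$h1))) {
  (rowSums(pop$h1[loci, , drop = FALSE]) +
     rowSums(pop$h2[loci, , drop = FALSE])) / (2 * n_ind(pop))
}
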