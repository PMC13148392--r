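#' Meiosis parameters for the gamma interference model
#'
#' Crossovers are simulated as a stationary gamma renewal process on the
#' four-strand bundle with chiasma rate 2 per Morgan; each chiasma is
#' transmitted to a given gamete with probability 1/2 (thinning, no chromatid
#' interference). The gamma shape \code{interference_nu} controls crossover
#' interference: \code{interference_nu = 1} gives the no-interference
#' (Poisson, Haldane) limit, larger values suppress nearby crossovers.
#'
#' @param interference_nu Positive gamma shape parameter (default 2.6, the
#'   conventional default of gamma-model breeding simulators).
#' @param obligate_crossover If \code{TRUE}, a chromosome that received no
#'   crossover gets one placed uniformly at random (default \code{FALSE}).
#' @return An object of class \code{meiosis_params}.
#' @export
meiosis_params <- function(interference_nu = 2.6, obligate_crossover = FALSE) {
  if (!is.numeric(interference_nu) || interference_nu <= 0)
    stop("interference_nu must be positive")
  structure(list(interference_nu = as.numeric(interference_nu),
                 obligate_crossover = isTRUE(obligate_crossover)),
            class = "meiosis_params")
}

#' Sample crossover positions on one chromosome
#'
#' Draws the crossover positions transmitted to a single gamete for a
#' chromosome of the given genetic length. The first chiasma distance is
#' drawn from the equilibrium residual distribution of the renewal process,
#' so the process is stationary along the chromosome. With
#' \code{interference_nu = 1} the returned count is exactly
#' Poisson(\code{length_cm} / 100).
#'
#' @param length_cm Chromosome length in centimorgans (> 0).
#' @param params A \code{\link{meiosis_params}} object.
#' @param n Number of independent meioses to draw (default 1).
#' @return A sorted numeric vector of positions in (0, \code{length_cm}), or
#'   a list of such vectors when \code{n > 1}.
#' @export
crossover_positions <- function(length_cm, params = meiosis_params(), n = 1) {
  if (!is.numeric(length_cm) || length(length_cm) != 1L || length_cm <= 0)
    stop("length_cm must be a positive scalar")
  res <- cpp_crossover_positions(length_cm, params$interference_nu,
                                 params$obligate_crossover, as.integer(n))
  if (n == 1L) res[[1]] else res
}

# Gametes for arbitrary parent indices of a population (workhorse used by all
# crossing operators). Returns a loci x length(parents) integer matrix.
population_gametes <- function(pop, parents, params) {
  map <- pop$map
  cpp_gametes(pop$h1, pop$h2, as.integer(parents), map$pos,
              map$chr_start, map$chr_len, map$lengths,
              params$interference_nu, params$obligate_crossover)
}

#' Simulate one gamete of an individual
#'
#' Per chromosome, crossover positions are drawn from the gamma interference
#' model, the starting parental strand is chosen by a fair coin, and alleles
#' are copied switching strands at each crossover (a crossover at position x
#' takes effect for loci with position greater than x). Chromosomes segregate
#' independently.
#'
#' @param parent An \code{individual} (see \code{\link{get_individual}}).
#' @param map The \code{genetic_map} the haplotypes are defined on.
#' @param params A \code{\link{meiosis_params}} object.
#' @return Integer haplotype vector over all map loci.
#' @export
meiosis_gamete <- function(parent, map, params = meiosis_params()) {
  pop <- single_parent_population(parent, map)
  as.vector(population_gametes(pop, 1L, params))
}

single_parent_population <- function(parent, map) {
  new_population(matrix(as.integer(parent$h1), ncol = 1),
                 matrix(as.integer(parent$h2), ncol = 1),
                 map, inbred = isTRUE(parent$inbred))
}

new_individual <- function(h1, h2) {
  structure(list(h1 = as.integer(h1), h2 = as.integer(h2),
                 inbred = all(h1 == h2)), class = "individual")
}

#' Cross two individuals
#'
#' The offspring receives one independently simulated gamete from each
#' parent. No mutation occurs: the child carries no allele absent from its
#' parents at any locus.
#'
#' @param mother,father \code{individual} objects defined on \code{map}.
#' @inheritParams meiosis_gamete
#' @return An \code{individual}.
#' @export
make_cross <- function(mother, father, map, params = meiosis_params()) {
  new_individual(meiosis_gamete(mother, map, params),
                 meiosis_gamete(father, map, params))
}

#' Self an individual
#'
#' The offspring receives two independent gametes from the same parent.
#'
#' @param parent An \code{individual} defined on \code{map}.
#' @inheritParams meiosis_gamete
#' @return An \code{individual}.
#' @export
self_individual <- function(parent, map, params = meiosis_params()) {
  make_cross(parent, parent, map, params)
}

#' Produce a doubled haploid
#'
#' A single gamete is duplicated into both haplotypes, giving a fully
#' homozygous individual in one step.
#'
#' @param parent An \code{individual} defined on \code{map}.
#' @inheritParams meiosis_gamete
#' @return An \code{individual} with \code{inbred = TRUE}.
#' @export
make_dh <- function(parent, map, params = meiosis_params()) {
  g <- meiosis_gamete(parent, map, params)
  new_individual(g, g)
}

# Population-scale crossing: one offspring per (mother, father) pair.
cross_population <- function(pop, mothers, fathers, params,
                             generation = "") {
  h1 <- population_gametes(pop, mothers, params)
  h2 <- population_gametes(pop, fathers, params)
  new_population(h1, h2, pop$map,
                 inbred = colSums(h1 != h2) == 0L, generation = generation)
}

# Population-scale selfing: one offspring per parent index.
self_population <- function(pop, parents, params, generation = "") {
  cross_population(pop, parents, parents, params, generation)
}

# Population-scale DH production: one DH per parent index.
dh_population <- function(pop, parents, params, generation = "") {
  g <- population_gametes(pop, parents, params)
  new_population(g, g, pop$map, inbred = rep(TRUE, ncol(g)),
                 generation = generation)
}
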