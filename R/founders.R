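#' Specification of the synthetic founder population
#'
#' The founder generator replaces the resequencing-derived sorghum genome with
#' a synthetic stand-in that reproduces the statistical features downstream
#' stages rely on: fully homozygous founders, an (approximately) U-shaped
#' allele-frequency spectrum, and linkage disequilibrium that decays with
#' centimorgan distance. LD is built by mixing a small set of ancestral
#' haplotypes through generations of random mating before extracting doubled
#' haploids.
#'
#' @param n_founders Number of fully homozygous founders (default 3000).
#' @param n_loci_per_chr Loci per chromosome (default 10000).
#' @param n_ancestral_haplotypes Ancestral haplotypes seeding the mixing
#'   population (default 40).
#' @param mixing_generations Generations of random mating used to establish
#'   cM-scaled LD (default 50).
#' @param maf_floor Truncation bound of the ancestral allele-frequency
#'   spectrum, in [0, 0.5) (default 0.1).
#' @param pericentromeric_fraction Fraction of loci placed inside the
#'   pericentromeric cM window (default 0.7); 0 gives uniform placement.
#' @param pericentromeric_window Width of that window as a fraction of the
#'   chromosome's genetic length, centred mid-chromosome (default 0.05).
#' @param rng_seed Optional integer seed applied by \code{sample_founders}.
#' @return An object of class \code{founder_spec}.
#' @export
founder_spec <- function(n_founders = 3000, n_loci_per_chr = 10000,
                         n_ancestral_haplotypes = 100,
                         mixing_generations = 30,
                         maf_floor = 0.1,
                         pericentromeric_fraction = 0.7,
                         pericentromeric_window = 0.05,
                         rng_seed = NULL) {
  if (n_founders < 2) stop("n_founders must be at least 2")
  if (n_loci_per_chr < 1) stop("n_loci_per_chr must be at least 1")
  if (n_ancestral_haplotypes < 2)
    stop("n_ancestral_haplotypes must be at least 2")
  if (mixing_generations < 0) stop("mixing_generations must be >= 0")
  if (maf_floor < 0 || maf_floor >= 0.5) stop("maf_floor must be in [0, 0.5)")
  if (pericentromeric_fraction < 0 || pericentromeric_fraction > 1)
    stop("pericentromeric_fraction must be in [0, 1]")
  if (pericentromeric_window <= 0 || pericentromeric_window > 1)
    stop("pericentromeric_window must be in (0, 1]")
  structure(list(n_founders = as.integer(n_founders),
                 n_loci_per_chr = as.integer(n_loci_per_chr),
                 n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
                 mixing_generations = as.integer(mixing_generations),
                 maf_floor = as.numeric(maf_floor),
                 pericentromeric_fraction = as.numeric(pericentromeric_fraction),
                 pericentromeric_window = as.numeric(pericentromeric_window),
                 rng_seed = rng_seed),
            class = "founder_spec")
}

#' Default sorghum-style genetic map
#'
#' Builds a ten-chromosome map with the consensus sorghum chromosome lengths
#' (summing to 1545.1 cM) and \code{spec$n_loci_per_chr} randomly placed loci
#' per chromosome (the last locus is pinned to the chromosome length).
#'
#' By default locus placement mimics the genetic-map position of SNPs from a
#' resequencing panel: crossovers concentrate in the distal euchromatin while
#' most of the physical genome — and hence most SNPs — lies in
#' pericentromeric regions that span only a small part of the genetic map.
#' A fraction \code{pericentromeric_fraction} of the loci is therefore
#' placed inside a central window covering \code{pericentromeric_window} of
#' the chromosome's genetic length, and the remainder is uniform along the
#' chromosome. Setting \code{pericentromeric_fraction = 0} gives fully
#' uniform placement.
#'
#' @param spec A \code{\link{founder_spec}} (locus count and placement
#'   profile are read from it).
#' @return A \code{genetic_map} with \code{factor = 1}.
#' @export
make_default_map <- function(spec = founder_spec()) {
  lens <- unname(sorghum_chr_lengths())
  nl <- spec$n_loci_per_chr
  w <- spec$pericentromeric_fraction
  win <- spec$pericentromeric_window
  chrom <- rep(seq_along(lens), each = nl)
  pos <- unlist(lapply(lens, function(len) {
    ncent <- round(nl * w)
    draw <- function() {
      p <- sort(c(runif(ncent, len * (0.5 - win / 2), len * (0.5 + win / 2)),
                  runif(nl - ncent, 0, len)))
      p[nl] <- len
      p
    }
    p <- draw()
    # ties have probability zero but floating-point duplicates are repaired
    while (any(duplicated(p)) || p[1] <= 0) p <- draw()
    p
  }))
  id <- paste0("chr", chrom, "_", rep(seq_len(nl), length(lens)))
  genetic_map(chrom, id, pos, lengths = lens, factor = 1)
}

#' Generate a synthetic founder population
#'
#' Procedure: (1) per-locus ancestral allele frequencies are drawn from a
#' U-shaped Beta(0.2, 0.2) spectrum truncated to
#' [\code{maf_floor}, 1 - \code{maf_floor}]; (2) independent ancestral
#' haplotypes are created by per-locus Bernoulli draws, conditioned on each
#' locus segregating among the ancestors (every locus starts as a SNP;
#' fixation can still arise by drift during mixing); (3) each haplotype
#' enters a random-mating population as one homozygous diploid, and the
#' population of \code{n_ancestral_haplotypes} diploids is mixed for
#' \code{mixing_generations} generations using the gamma-model meiosis, which
#' establishes LD decaying with cM distance; (4) each founder is produced as
#' a doubled haploid of a random individual of the mixed population. Loci
#' that drift to fixation are retained (no minor-allele-frequency filtering).
#'
#' @param spec A \code{\link{founder_spec}}.
#' @param map A base \code{genetic_map} (\code{factor} 1) whose locus count
#'   matches \code{spec}.
#' @param params Meiosis parameters used during mixing.
#' @return A \code{population} of fully homozygous founders.
#' @export
sample_founders <- function(spec = founder_spec(), map = make_default_map(spec),
                            params = meiosis_params()) {
  stopifnot(inherits(spec, "founder_spec"), inherits(map, "genetic_map"))
  if (map$factor != 1) stop("founders must be generated on the base map")
  L <- n_loci(map)
  if (L != spec$n_loci_per_chr * length(map$lengths))
    stop("map locus count does not match founder_spec")
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)

  # truncated U-shaped ancestral frequency spectrum
  lo <- stats::pbeta(spec$maf_floor, 0.2, 0.2)
  hi <- stats::pbeta(1 - spec$maf_floor, 0.2, 0.2)
  p <- qbeta(runif(L, lo, hi), 0.2, 0.2)

  nh <- spec$n_ancestral_haplotypes
  haps <- matrix(rbinom(L * nh, 1L, rep(p, nh)), nrow = L)
  # loci are SNPs: condition the draw on segregating among the ancestors
  # (fixation may still arise later through drift during mixing)
  rs <- rowSums(haps)
  while (any(rs == 0L | rs == nh)) {
    bad <- which(rs == 0L | rs == nh)
    haps[bad, ] <- rbinom(length(bad) * nh, 1L, rep(p[bad], nh))
    rs[bad] <- rowSums(haps[bad, , drop = FALSE])
  }
  storage.mode(haps) <- "integer"

  # each ancestral haplotype starts as one homozygous diploid, so with zero
  # mixing generations founders are exact copies of ancestral haplotypes
  pop <- new_population(haps, haps, map, inbred = rep(TRUE, nh),
                        generation = "ancestral")
  for (g in seq_len(spec$mixing_generations)) {
    mothers <- sample.int(nh, nh, replace = TRUE)
    fathers <- sample.int(nh, nh, replace = TRUE)
    pop <- cross_population(pop, mothers, fathers, params,
                            generation = paste0("mix", g))
  }
  parents <- sample.int(nh, spec$n_founders, replace = TRUE)
  dh_population(pop, parents, params, generation = "founders")
}
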