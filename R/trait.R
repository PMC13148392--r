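#' Sample an additive trait architecture
#'
#' QTL are sampled uniformly without replacement within each chromosome, raw
#' additive effects are drawn from a standard normal distribution, and all
#' effects are rescaled by one constant so that the variance of genetic
#' values in the founder population equals 1 (the additive genetic variance
#' of the base trait). The environmental variance is fixed from the target
#' narrow-sense heritability as \code{sigma_e2 = (1 - h2) / h2}, and is kept
#' constant for the whole breeding program. Only additive effects are
#' modelled; QTL that happen to be monomorphic in the founders are retained
#' and simply contribute no variance.
#'
#' @param map A \code{genetic_map}.
#' @param n_qtl_per_chr Number of QTL per chromosome.
#' @param h2 Target narrow-sense heritability in (0, 1).
#' @param founders Founder \code{population} used for calibration.
#' @param max_retries Number of QTL resampling attempts if all sampled QTL
#'   are monomorphic (default 10).
#' @return An object of class \code{trait_architecture} with fields
#'   \code{qtl} (global locus indices), \code{effects}, \code{sigma_e2},
#'   \code{h2}.
#' @export
sample_architecture <- function(map, n_qtl_per_chr, h2, founders,
                                max_retries = 10) {
  stopifnot(inherits(map, "genetic_map"), inherits(founders, "population"))
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
  if (n_ind(founders) == 0) stop("founder population is empty")
  nchr <- length(map$lengths)
  if (any(map$chr_len < n_qtl_per_chr))
    stop("not enough loci per chromosome for the requested QTL count")
  for (attempt in seq_len(max_retries)) {
    qtl <- unlist(lapply(seq_len(nchr), function(c) {
      map$chr_start[c] + sort(sample.int(map$chr_len[c], n_qtl_per_chr))
    }))
    a <- rnorm(length(qtl))
    gv <- qtl_values(founders, qtl, a)
    v <- pop_var(gv)
    if (v > 0) {
      a <- a / sqrt(v)
      arch <- structure(list(qtl = as.integer(qtl), effects = a,
                             n_qtl_per_chr = as.integer(n_qtl_per_chr),
                             sigma_e2 = (1 - h2) / h2, h2 = h2),
                        class = "trait_architecture")
      return(arch)
    }
  }
  stop("degenerate architecture: all sampled QTL monomorphic in founders")
}

# variance with denominator n (population variance)
pop_var <- function(x) mean((x - mean(x))^2)

qtl_values <- function(pop, qtl, effects) {
  as.vector(cpp_dosage_mult(pop$h1, pop$h2, as.integer(qtl), effects))
}

#' True genetic values of a population
#'
#' Value of individual j is the dosage-weighted sum of QTL effects,
#' \eqn{\sum_i a_i d_{ij}} with dosage \eqn{d_{ij} \in \{0, 1, 2\}}.
#'
#' @param pop A \code{population}.
#' @param arch A \code{trait_architecture}.
#' @return Numeric vector of genetic values.
#' @export
genetic_values <- function(pop, arch) {
  qtl_values(pop, arch$qtl, arch$effects)
}

#' Phenotypes under the calibrated environmental variance
#'
#' Phenotype = genetic value + e with e ~ N(0, \code{sigma_e2}) i.i.d.;
#' \code{sigma_e2} is the value fixed at founder calibration, so realised
#' heritability drifts with the genetic variance as selection proceeds.
#'
#' @inheritParams genetic_values
#' @return Numeric vector of phenotypes.
#' @export
phenotypes <- function(pop, arch) {
  gv <- genetic_values(pop, arch)
  gv + rnorm(length(gv), 0, sqrt(arch$sigma_e2))
}

#' Genic variance at the trait QTL
#'
#' The expected additive variance under Hardy-Weinberg and linkage
#' equilibrium, \eqn{\sum_i 2 p_i (1 - p_i) a_i^2}, with allele frequencies
#' computed from the current haplotypes.
#'
#' @inheritParams genetic_values
#' @return Non-negative scalar.
#' @export
genic_variance <- function(pop, arch) {
  n <- n_ind(pop)
  p <- as.vector(cpp_dosage_tmult(pop$h1, pop$h2, as.integer(arch$qtl),
                                  rep(1 / (2 * n), n)))
  sum(2 * p * (1 - p) * arch$effects^2)
}

#' Genetic variance of a population
#'
#' The realised variance (denominator n) of true genetic values in the
#' current population.
#'
#' @inheritParams genetic_values
#' @return Non-negative scalar.
#' @export
genetic_variance <- function(pop, arch) {
  pop_var(genetic_values(pop, arch))
}

#' Sample a SNP chip disjoint from the trait QTL
#'
#' Markers are sampled uniformly without replacement per chromosome from the
#' loci that are not QTL, without any minor-allele-frequency filtering.
#'
#' @param map A \code{genetic_map}.
#' @param arch A \code{trait_architecture} whose QTL are excluded.
#' @param markers_per_chr Number of markers per chromosome.
#' @return An object of class \code{snp_chip} with global locus indices in
#'   \code{loci}.
#' @export
sample_chip <- function(map, arch, markers_per_chr) {
  nchr <- length(map$lengths)
  loci <- unlist(lapply(seq_len(nchr), function(c) {
    all_idx <- map$chr_start[c] + seq_len(map$chr_len[c])
    avail <- setdiff(all_idx, arch$qtl)
    if (length(avail) < markers_per_chr)
      stop("not enough non-QTL loci on chromosome ", c)
    sort(sample(avail, markers_per_chr))
  }))
  structure(list(loci = as.integer(loci),
                 markers_per_chr = as.integer(markers_per_chr)),
            class = "snp_chip")
}

#' Write a trait architecture as a text table
#'
#' Tab-separated columns: chromosome, locus id, additive effect; a header
#' comment records \code{sigma_e2} and \code{h2}.
#'
#' @param arch A \code{trait_architecture}.
#' @param map The \code{genetic_map} the QTL indices refer to.
#' @param file Output path.
#' @export
write_architecture <- function(arch, map, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# sigma_e2=%.17g h2=%.17g", arch$sigma_e2, arch$h2),
             con)
  writeLines(sprintf("%d\t%s\t%.17g", map$chrom[arch$qtl],
                     map$id[arch$qtl], arch$effects), con)
  invisible(file)
}
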