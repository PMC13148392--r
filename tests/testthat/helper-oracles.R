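# Independent R-level oracle for the stationary gamma renewal crossover
# process: vectorised, shares no code with the C++ path it checks.
r_renewal_crossovers <- function(length_cm, nu, n) {
  scale <- 50 / nu
  lapply(seq_len(n), function(i) {
    x <- runif(1) * rgamma(1, nu + 1, scale = scale)
    out <- numeric(0)
    while (x < length_cm) {
      if (runif(1) < 0.5) out <- c(out, x)
      x <- x + rgamma(1, nu, scale = scale)
    }
    out
  })
}

# Recombinant fraction between two loci `d` cM apart at the start/end of a
# d-cM chromosome, by brute-force renewal simulation (odd retained count).
r_recombinant_fraction <- function(d, nu, n) {
  scale <- 50 / nu
  # vectorised: simulate enough inter-arrival draws to cover d
  first <- runif(n) * rgamma(n, nu + 1, scale = scale)
  counts <- integer(n)
  x <- first
  alive <- x < d
  while (any(alive)) {
    counts[alive] <- counts[alive] + rbinom(sum(alive), 1L, 0.5)
    x[alive] <- x[alive] + rgamma(sum(alive), nu, scale = scale)
    alive <- x < d
  }
  mean(counts %% 2L == 1L)
}

# A deterministic two-chromosome toy map for unit tests.
toy_map <- function(loci_per_chr = 5, lengths = c(100, 80)) {
  chrom <- rep(seq_along(lengths), each = loci_per_chr)
  pos <- unlist(lapply(lengths, function(len)
    seq(len / loci_per_chr, len, length.out = loci_per_chr)))
  genetic_map(chrom, paste0("m", seq_along(chrom)), pos, lengths = lengths)
}

# Small homozygous population with given haplotype matrix (loci x n).
homozygous_population <- function(H, map) {
  storage.mode(H) <- "integer"
  new_population(H, H, map, inbred = rep(TRUE, ncol(H)))
}

small_founders <- function(seed = 1, n_founders = 120, loci = 200) {
  set.seed(seed)
  fs <- founder_spec(n_founders = n_founders, n_loci_per_chr = loci)
  map <- make_default_map(fs)
  list(spec = fs, map = map, pop = sample_founders(fs, map))
}
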