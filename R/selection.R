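#' Genotype a population on a SNP chip
#'
#' @param pop A \code{population}.
#' @param chip A \code{snp_chip}.
#' @return Numeric dosage matrix, individuals x markers, entries in
#'   \{0, 1, 2\} (only \{0, 2\} for doubled-haploid populations).
#' @export
genotype_chip <- function(pop, chip) {
  if (length(chip$loci) == 0L) stop("chip has no markers")
  dosage_matrix(pop, chip$loci)
}

#' Indices of the n largest values
#'
#' Ties are broken by the lowest index, making selection deterministic across
#' platforms.
#'
#' @param values Numeric vector of selection criteria.
#' @param n Number of individuals to select.
#' @return Integer vector of \code{n} indices.
#' @export
select_top <- function(values, n) {
  if (n > length(values)) stop("cannot select more individuals than exist")
  if (n < 1) stop("n must be at least 1")
  order(-as.numeric(values), seq_along(values))[seq_len(n)]
}

#' Assemble a training set
#'
#' @param M Numeric dosage matrix, individuals x markers.
#' @param y Numeric phenotype vector.
#' @param generations Generation label(s): one per record, or a single label
#'   recycled.
#' @return An object of class \code{training_set}.
#' @export
training_set <- function(M, y, generations = "") {
  M <- as.matrix(M)
  if (nrow(M) != length(y)) stop("genotype and phenotype row counts differ")
  if (anyNA(M) || anyNA(y)) stop("training data must not contain NA")
  if (length(generations) == 1L) generations <- rep(generations, length(y))
  if (length(generations) != length(y))
    stop("one generation label per record required")
  structure(list(M = M, y = as.numeric(y),
                 generations = as.character(generations)),
            class = "training_set")
}

#' Merge the most recent generations into a rolling training set
#'
#' @param history List of entries, each a list with elements \code{generation}
#'   (label), \code{M} (dosages), and \code{y} (phenotypes), ordered oldest
#'   to newest.
#' @param window Number of most recent generations to keep (default 3).
#' @return A \code{training_set} concatenating the retained generations,
#'   oldest first.
#' @export
rolling_training_set <- function(history, window = 3) {
  if (length(history) == 0L) stop("history is empty")
  keep <- history[max(1L, length(history) - window + 1L):length(history)]
  M <- do.call(rbind, lapply(keep, `[[`, "M"))
  y <- unlist(lapply(keep, `[[`, "y"))
  gen <- unlist(lapply(keep, function(h) rep(h$generation, length(h$y))))
  training_set(M, y, gen)
}

# Restricted maximum likelihood for delta = sigma_e2 / sigma_u2 from the
# spectrum of the (double-centred) genomic covariance Gs = Zc Zc'. The
# intercept direction has eigenvalue 0 and a zero score, so the restricted
# likelihood runs over k - 1 dimensions: one zero-eigenvalue term is dropped
# from the log-determinant.
reml_delta <- function(Gs, ys) {
  k <- length(ys)
  Gs <- Gs - rep(colMeans(Gs), each = k)
  Gs <- Gs - rowMeans(Gs)
  yc <- ys - mean(ys)
  eig <- eigen(Gs, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  eta2 <- as.vector(crossprod(eig$vectors, yc))^2
  scale <- max(mean(d), .Machine$double.eps)
  crit <- function(ld) {
    delta <- exp(ld)
    (k - 1) * log(sum(eta2 / (d + delta))) +
      sum(log(d + delta)) - log(delta)
  }
  lo <- log(scale) - 18
  hi <- log(scale) + 18
  opt <- optimize(crit, c(lo, hi), tol = 1e-8)
  delta <- exp(opt$minimum)
  # the lower boundary means a near-noiseless signal: accept a floored delta;
  # the upper boundary means no marker signal and triggers the fallback
  if (opt$minimum <= lo + 0.5) delta <- max(delta, 1e-6 * scale)
  converged <- opt$minimum < hi - 0.5
  sigma_u2 <- sum(eta2 / (d + delta)) / (k - 1)
  list(delta = delta, sigma_u2 = sigma_u2, sigma_e2 = delta * sigma_u2,
       converged = converged, eig = eig, d = d)
}

#' Train an RRBLUP genomic prediction model
#'
#' Fits the ridge-regression BLUP model y = 1mu + Z u + e with marker effects
#' u ~ N(0, sigma_u2 I) and residuals e ~ N(0, sigma_e2 I), where Z is the
#' column-mean-centred dosage matrix. The shrinkage parameter
#' lambda = sigma_e2 / sigma_u2 is estimated by restricted maximum likelihood
#' via the spectral decomposition of Z Z' (the efficient mixed-model
#' parameterisation), and marker effects are obtained from the mixed-model
#' equations at the REML optimum. Training is deterministic: identical
#' training sets give bit-identical models.
#'
#' Because lambda is a ratio of variance components and therefore free of the
#' sample size, for very large training sets it can be estimated on an
#' evenly spaced subset of the individuals (a submatrix of Z Z') before the
#' effects are solved at full size by Cholesky factorisation; \code{reml_n}
#' bounds the size of the spectral subsystem (default \code{Inf}: full REML).
#'
#' @param ts A \code{\link{training_set}}.
#' @param reml_n Maximum number of individuals entering the spectral REML
#'   subsystem.
#' @param lambda Optional fixed shrinkage parameter; skips REML.
#' @param map_factor Recombination scaling factor in force when the training
#'   data were generated (stored as model metadata).
#' @return An object of class \code{gs_model} with intercept, marker
#'   effects, training column means, lambda, variance components, and
#'   training metadata.
#' @export
train_rrblup <- function(ts, reml_n = Inf, lambda = NULL, map_factor = 1) {
  stopifnot(inherits(ts, "training_set"))
  n <- nrow(ts$M)
  m <- ncol(ts$M)
  if (n < 2) stop("at least two training records required")
  if (m < 1) stop("at least one marker required")
  centers <- colMeans(ts$M)
  mu <- mean(ts$y)
  gens <- unique(ts$generations)

  if (pop_var(ts$y) == 0) {
    return(new_gs_model(ts$y[1], rep(0, m), centers, Inf, 0, 0, gens,
                        map_factor, n))
  }

  yc <- ts$y - mu
  # Gram matrix of the centred dosages without materialising them:
  # (M - 1c')(M - 1c')' = MM' - a1' - 1a' + (c'c) 11', a = Mc
  G <- tcrossprod(ts$M)
  a <- as.vector(ts$M %*% centers)
  cc <- sum(centers^2)
  G <- G - rep(a, times = n)
  G <- G - rep(a, each = n)
  G <- G + cc
  dim(G) <- c(n, n)

  fit <- NULL
  if (is.null(lambda)) {
    if (n <= reml_n) {
      fit <- reml_delta(G, ts$y)
    } else {
      idx <- unique(round(seq(1, n, length.out = reml_n)))
      fit <- reml_delta(G[idx, idx], ts$y[idx])
      fit$eig <- NULL  # subsample spectrum cannot solve the full system
    }
    if (!fit$converged) {
      warning("REML did not converge; falling back to lambda = m")
      fit <- list(delta = m, sigma_u2 = NA_real_, sigma_e2 = NA_real_,
                  eig = NULL)
    }
    lambda <- fit$delta
  } else {
    fit <- list(sigma_u2 = NA_real_, sigma_e2 = NA_real_, eig = NULL)
  }

  if (!is.null(fit$eig)) {
    w <- fit$eig$vectors %*%
      (as.vector(crossprod(fit$eig$vectors, yc)) / (fit$d + lambda))
  } else {
    w <- chol_solve_ridge(G, lambda, yc)
  }
  u <- as.vector(crossprod(ts$M, w)) - centers * sum(w)
  new_gs_model(mu, u, centers, lambda, fit$sigma_u2, fit$sigma_e2, gens,
               map_factor, n)
}

# Solve (G + lambda I) w = yc by Cholesky, escalating a small relative
# diagonal jitter if rounding in the centred Gram matrix leaves it
# numerically indefinite. Deterministic. G is modified in place (all
# callers pass a locally owned matrix that is not reused).
chol_solve_ridge <- function(G, lambda, yc) {
  jitter <- 1e-8 * (mean(diag(G)) + 1)
  cpp_add_diag(G, lambda + jitter)
  for (k in 1:6) {
    R <- tryCatch(chol(G), error = function(e) NULL)
    if (!is.null(R))
      return(backsolve(R, backsolve(R, yc, transpose = TRUE)))
    cpp_add_diag(G, 99 * jitter)
    jitter <- jitter * 100
  }
  stop("mixed-model equations are numerically singular")
}

# Fast RRBLUP training path operating directly on a population's haplotypes
# (used by the breeding scheme for single-generation DH training sets).
# Mathematically identical to train_rrblup on genotype_chip(pop, chip):
# markers fixed in the population have zero centred columns and exactly
# zero estimated effects, so only segregating markers enter the linear
# algebra. Depending on their number the solve runs in the individual
# dimension (Gram matrix by exact bit counting for fully inbred
# populations) or in the marker dimension (primal ridge equations, exact
# by ridge duality).
train_rrblup_pop <- function(pop, loci, y, reml_n = Inf, map_factor = 1) {
  n <- n_ind(pop)
  m <- length(loci)
  loci <- as.integer(loci)
  centers <- as.vector(cpp_dosage_tmult(pop$h1, pop$h2, loci,
                                        rep(1 / n, n)))
  mu <- mean(y)
  gens <- pop$generation
  if (pop_var(y) == 0)
    return(new_gs_model(y[1], rep(0, m), centers, Inf, 0, 0, gens,
                        map_factor, n))
  seg <- which(centers > 0 & centers < 2)
  if (all(pop$inbred) == FALSE) {
    # general diploid fallback: a constant column can also sit at dosage 1
    V <- cpp_dosage(pop$h1, pop$h2, loci)
    seg <- which(col_vars(V) > 0)
  }
  if (length(seg) == 0L)
    return(new_gs_model(mu, rep(0, m), centers, Inf, 0, 0, gens,
                        map_factor, n))
  yc <- y - mu
  ms <- length(seg)
  idx <- if (n <= reml_n) seq_len(n)
         else unique(round(seq(1, n, length.out = reml_n)))
  u <- rep(0, m)

  if (ms <= 0.55 * n) {
    # marker-side path: centred dosages of segregating markers only
    Zc <- cpp_dosage(pop$h1, pop$h2, loci[seg])
    Zc <- Zc - rep(centers[seg], each = n)
    fit <- reml_delta(tcrossprod(Zc[idx, , drop = FALSE]), y[idx])
    if (!fit$converged)
      fit <- list(delta = m, sigma_u2 = NA_real_, sigma_e2 = NA_real_)
    lambda <- fit$delta
    C <- crossprod(Zc)
    u[seg] <- chol_solve_ridge(C, lambda, as.vector(crossprod(Zc, yc)))
  } else {
    G <- if (all(pop$inbred)) cpp_gram_dh(pop$h1, loci[seg])
         else tcrossprod(cpp_dosage(pop$h1, pop$h2, loci[seg]))
    a <- as.vector(cpp_dosage_mult(pop$h1, pop$h2, loci[seg],
                                   centers[seg]))
    cpp_center_gram(G, a, sum(centers[seg]^2))
    fit <- if (n <= reml_n) reml_delta(G, y)
           else { f <- reml_delta(G[idx, idx], y[idx]); f$eig <- NULL; f }
    if (!fit$converged)
      fit <- list(delta = m, sigma_u2 = NA_real_, sigma_e2 = NA_real_,
                  eig = NULL)
    lambda <- fit$delta
    w <- if (!is.null(fit$eig)) {
      fit$eig$vectors %*%
        (as.vector(crossprod(fit$eig$vectors, yc)) / (fit$d + lambda))
    } else {
      chol_solve_ridge(G, lambda, yc)
    }
    u[seg] <- as.vector(cpp_dosage_tmult(pop$h1, pop$h2, loci[seg],
                                         as.vector(w))) -
      centers[seg] * sum(w)
  }
  new_gs_model(mu, u, centers, lambda, fit$sigma_u2, fit$sigma_e2, gens,
               map_factor, n)
}

# column variances without matrixStats (only used on the rare non-inbred
# fallback path)
col_vars <- function(V) {
  n <- nrow(V)
  colMeans(V^2) - colMeans(V)^2
}

# GEBVs for a population straight from haplotypes.
predict_gebv_pop <- function(model, pop, loci) {
  model$intercept - sum(model$centers * model$effects) +
    as.vector(cpp_dosage_mult(pop$h1, pop$h2, as.integer(loci),
                              model$effects))
}

new_gs_model <- function(intercept, effects, centers, lambda, sigma_u2,
                         sigma_e2, generations, map_factor, n_train) {
  structure(list(intercept = intercept, effects = effects,
                 centers = centers, lambda = lambda, sigma_u2 = sigma_u2,
                 sigma_e2 = sigma_e2, training_generations = generations,
                 map_factor_at_training = map_factor, n_train = n_train),
            class = "gs_model")
}

#' @export
print.gs_model <- function(x, ...) {
  cat(sprintf(
    "gs_model: %d markers, lambda %.4g, trained on %d records (%s), map factor %g\n",
    length(x$effects), x$lambda, x$n_train,
    paste(x$training_generations, collapse = ", "),
    x$map_factor_at_training))
  invisible(x)
}

#' Genomic estimated breeding values
#'
#' GEBV = intercept + centred dosages times marker effects, centring by the
#' column means of the training set stored in the model.
#'
#' @param model A \code{gs_model}.
#' @param M Numeric dosage matrix, individuals x markers (same marker order
#'   as the training chip).
#' @return Numeric vector of GEBVs.
#' @export
predict_gebv <- function(model, M) {
  M <- as.matrix(M)
  if (ncol(M) != length(model$effects))
    stop("marker count does not match the model")
  model$intercept - sum(model$centers * model$effects) +
    as.vector(M %*% model$effects)
}

#' Prediction accuracy
#'
#' Pearson correlation between estimated and true breeding values; returns
#' \code{NA} when either vector is constant.
#'
#' @param gebv Numeric vector of predictions.
#' @param true_values Numeric vector of true genetic values.
#' @return Scalar correlation, or \code{NA_real_}.
#' @export
accuracy <- function(gebv, true_values) {
  if (pop_var(gebv) == 0 || pop_var(true_values) == 0) return(NA_real_)
  cor(gebv, true_values)
}

#' Write a genomic prediction model as a text table
#'
#' Comment header with intercept, lambda, training generations, and the map
#' factor at training; then tab-separated locus id and effect.
#'
#' @param model A \code{gs_model}.
#' @param map The \code{genetic_map} of the simulated genome.
#' @param chip The \code{snp_chip} the model was trained on.
#' @param file Output path.
#' @export
write_gs_model <- function(model, map, chip, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# intercept=%.17g lambda=%.17g map_factor=%.17g",
            model$intercept, model$lambda, model$map_factor_at_training),
    sprintf("# training_generations=%s",
            paste(model$training_generations, collapse = ","))), con)
  writeLines(sprintf("%s\t%.17g", map$id[chip$loci], model$effects), con)
  invisible(file)
}
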