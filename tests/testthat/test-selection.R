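test_that("select_top picks the largest values with index tie-breaking", {
  expect_identical(select_top(c(3, 1, 2), 2), c(1L, 3L))
  expect_identical(select_top(c(5, 5, 5, 5), 2), c(1L, 2L))
  expect_identical(select_top(rep(0, 30), 30), 1:30)
  expect_identical(sort(select_top(rnorm(10), 10)), 1:10)
  expect_error(select_top(1:5, 6), "more individuals")
})

test_that("chip genotyping returns dosages and flags DH homozygosity", {
  f <- small_founders(seed = 51, n_founders = 50, loci = 60)
  arch <- sample_architecture(f$map, 10, 0.5, f$pop)
  chip <- sample_chip(f$map, arch, 20)
  expect_false(any(chip$loci %in% arch$qtl))
  expect_identical(length(chip$loci), 200L)
  M <- genotype_chip(f$pop, chip)
  expect_true(all(M %in% c(0, 2)))  # DH population
  expect_equal(unname(colMeans(M) / 2), unname(allele_freq(f$pop, chip$loci)))
  empty <- structure(list(loci = integer(0)), class = "snp_chip")
  expect_error(genotype_chip(f$pop, empty), "no markers")
})

test_that("rrblup interpolates noiseless single-marker data", {
  set.seed(52)
  n <- 60
  x <- rbinom(n, 2, 0.5)
  M <- cbind(x, matrix(1, n, 3))  # other markers constant
  y <- 2 + 3 * (x - mean(x))
  model <- train_rrblup(training_set(M, y, "g"))
  gebv <- predict_gebv(model, M)
  expect_gt(cor(gebv, y), 1 - 1e-6)
})

test_that("infinite shrinkage collapses GEBVs to the training mean", {
  set.seed(53)
  M <- matrix(rbinom(200, 2, 0.5), 20)
  y <- rnorm(20)
  model <- train_rrblup(training_set(M, y, "g"), lambda = 1e12)
  expect_equal(max(abs(model$effects)), 0, tolerance = 1e-6)
  expect_equal(predict_gebv(model, M), rep(mean(y), 20), tolerance = 1e-4)
})

test_that("constant phenotypes give a zero-effect model", {
  M <- matrix(rbinom(100, 2, 0.5), 10)
  model <- train_rrblup(training_set(M, rep(4.2, 10), "g"))
  expect_identical(model$effects, rep(0, 10))
  expect_equal(predict_gebv(model, M), rep(4.2, 10))
})

test_that("REML recovers the simulated shrinkage within a factor of two", {
  set.seed(54)
  n <- 500; m <- 200
  hits <- 0; reps <- 50
  for (r in seq_len(reps)) {
    sigma_u2 <- exp(runif(1, -3, 0))
    sigma_e2 <- exp(runif(1, -1, 1))
    M <- matrix(rbinom(n * m, 2, 0.5), n)
    Zc <- M - rep(colMeans(M), each = n)
    y <- 1 + as.vector(Zc %*% rnorm(m, 0, sqrt(sigma_u2))) +
      rnorm(n, 0, sqrt(sigma_e2))
    model <- train_rrblup(training_set(M, y, "g"))
    truth <- sigma_e2 / sigma_u2
    if (model$lambda > truth / 2 && model$lambda < truth * 2)
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("training is deterministic and fitted values are reproduced", {
  set.seed(55)
  M <- matrix(rbinom(600, 2, 0.4), 30)
  y <- rnorm(30)
  ts <- training_set(M, y, "g")
  m1 <- train_rrblup(ts)
  m2 <- train_rrblup(ts)
  expect_identical(m1, m2)
  # predicting the training set reproduces the fitted values
  fitted <- m1$intercept +
    as.vector((M - rep(m1$centers, each = 30)) %*% m1$effects)
  expect_equal(predict_gebv(m1, M), fitted)
  # permutation equivariance of prediction
  perm <- sample(30)
  expect_equal(predict_gebv(m1, M[perm, ]), fitted[perm])
})

test_that("subsampled-REML path stays close to the full spectral path", {
  set.seed(56)
  n <- 400; m <- 150
  M <- matrix(rbinom(n * m, 2, 0.5), n)
  Zc <- M - rep(colMeans(M), each = n)
  y <- as.vector(Zc %*% rnorm(m, 0, 0.1)) + rnorm(n)
  full <- train_rrblup(training_set(M, y, "g"))
  sub <- train_rrblup(training_set(M, y, "g"), reml_n = 200)
  expect_equal(log(sub$lambda), log(full$lambda), tolerance = 0.7)
  expect_gt(cor(predict_gebv(sub, M), predict_gebv(full, M)), 0.99)
})

test_that("population fast path matches generic RRBLUP training", {
  f <- small_founders(seed = 60, n_founders = 150, loci = 80)
  arch <- sample_architecture(f$map, 10, 0.5, f$pop)
  chip <- sample_chip(f$map, arch, 30)
  set.seed(61)
  y <- phenotypes(f$pop, arch)
  M <- genotype_chip(f$pop, chip)
  generic <- train_rrblup(training_set(M, y, "founders"))
  fast <- recombsim:::train_rrblup_pop(f$pop, chip$loci, y)
  expect_equal(fast$lambda, generic$lambda, tolerance = 1e-6)
  expect_equal(fast$effects, generic$effects, tolerance = 1e-8)
  expect_equal(fast$centers, unname(generic$centers), tolerance = 1e-12)
  expect_equal(recombsim:::predict_gebv_pop(fast, f$pop, chip$loci),
               predict_gebv(generic, M), tolerance = 1e-8)
})

test_that("accuracy is the Pearson correlation with NA for constants", {
  x <- rnorm(50)
  expect_equal(accuracy(x, x), 1)
  expect_equal(accuracy(-x, x), -1)
  expect_true(is.na(accuracy(rep(1, 50), x)))
  set.seed(57)
  expect_lt(abs(accuracy(rnorm(1000), rnorm(1000))), 0.1)
})

test_that("rolling training sets keep the most recent generations", {
  mk <- function(g, val) list(generation = g,
                              M = matrix(val, 2, 3), y = c(val, val))
  h5 <- lapply(1:5, function(i) mk(paste0("g", i), i))
  ts <- rolling_training_set(h5, window = 3)
  expect_identical(unique(ts$generations), c("g3", "g4", "g5"))
  expect_identical(nrow(ts$M), 6L)
  ts1 <- rolling_training_set(h5, window = 1)
  expect_identical(unique(ts1$generations), "g5")
  ts_all <- rolling_training_set(h5[1:3], window = 3)
  expect_identical(nrow(ts_all$M), 6L)
})

test_that("higher marker density does not reduce first-cycle accuracy", {
  set.seed(58)
  reps <- 20
  acc <- matrix(NA, reps, 2)
  for (r in seq_len(reps)) {
    fs <- founder_spec(n_founders = 250, n_loci_per_chr = 60)
    map <- make_default_map(fs)
    pop <- sample_founders(fs, map)
    arch <- sample_architecture(map, 5, 0.5, pop)
    gv <- genetic_values(pop, arch)
    y <- phenotypes(pop, arch)
    for (k in 1:2) {
      chip <- sample_chip(map, arch, c(5, 40)[k])
      M <- genotype_chip(pop, chip)
      model <- train_rrblup(training_set(M, y, "g"))
      acc[r, k] <- accuracy(predict_gebv(model, M), gv)
    }
  }
  expect_gte(mean(acc[, 2] - acc[, 1]), 0)
})

test_that("gs model serialises with metadata", {
  set.seed(59)
  f <- small_founders(seed = 59, n_founders = 40, loci = 30)
  arch <- sample_architecture(f$map, 5, 0.5, f$pop)
  chip <- sample_chip(f$map, arch, 10)
  M <- genotype_chip(f$pop, chip)
  model <- train_rrblup(training_set(M, phenotypes(f$pop, arch), "bi10"),
                        map_factor = 1)
  tf <- tempfile()
  write_gs_model(model, f$map, chip, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("training_generations=bi10", lines)))
  tab <- read.table(tf, sep = "\t", comment.char = "#")
  expect_equal(tab[[2]], model$effects)
  unlink(tf)
})
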