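test_that("crossover counts are Poisson in the no-interference limit", {
  set.seed(10)
  draws <- crossover_positions(100, meiosis_params(interference_nu = 1),
                               n = 1e5)
  counts <- lengths(draws)
  expect_equal(mean(counts), 1, tolerance = 3 * sqrt(1 / 1e5) * 3)
  tab <- table(factor(pmin(counts, 5), levels = 0:5))
  probs <- c(dpois(0:4, 1), 1 - ppois(4, 1))
  gof <- suppressWarnings(chisq.test(as.vector(tab), p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("expected crossover count scales linearly with the map factor", {
  set.seed(11)
  n <- 1e4
  base <- lengths(crossover_positions(186.3, n = n))
  scaled <- lengths(crossover_positions(186.3 * 8, n = n))
  expect_equal(mean(base), 1.863, tolerance = 3 * sd(base) / sqrt(n) / 1.863)
  se_ratio <- 3 * sqrt(var(scaled) / n + 64 * var(base) / n) / mean(base)
  expect_equal(mean(scaled) / mean(base), 8, tolerance = se_ratio / 8)
})

test_that("crossover_positions validates length and returns sorted positions", {
  expect_error(crossover_positions(0), "positive")
  expect_error(crossover_positions(-5), "positive")
  set.seed(12)
  expect_length(crossover_positions(1e-9), 0)
  draws <- crossover_positions(500, n = 200)
  for (d in draws) {
    expect_true(all(diff(d) > 0))
    if (length(d)) expect_true(all(d > 0 & d < 500))
  }
})

test_that("interference suppresses coincident crossovers at nu = 2.6", {
  set.seed(13)
  # two 10 cM intervals separated by 10 cM on a 30 cM chromosome
  draws <- crossover_positions(30, meiosis_params(2.6), n = 2e5)
  inA <- vapply(draws, function(d) any(d <= 10), logical(1))
  inB <- vapply(draws, function(d) any(d > 20), logical(1))
  coc <- mean(inA & inB) / (mean(inA) * mean(inB))
  expect_lt(coc, 1)
})

test_that("obligate crossover guarantees at least one event", {
  set.seed(14)
  draws <- crossover_positions(1, meiosis_params(obligate_crossover = TRUE),
                               n = 500)
  expect_true(all(lengths(draws) >= 1))
})

test_that("gametes of homozygous parents copy the parental haplotype", {
  set.seed(15)
  map <- toy_map()
  h <- matrix(rbinom(n_loci(map), 1, 0.5), ncol = 1)
  pop <- homozygous_population(h, map)
  ind <- get_individual(pop, 1)
  for (i in 1:5) expect_identical(meiosis_gamete(ind, map), as.integer(h[, 1]))
})

test_that("a gamete never carries an allele absent from the parent", {
  set.seed(16)
  map <- toy_map(20)
  h1 <- matrix(rbinom(40, 1, 0.5), ncol = 1)
  h2 <- matrix(rbinom(40, 1, 0.5), ncol = 1)
  ind <- structure(list(h1 = as.integer(h1), h2 = as.integer(h2),
                        inbred = FALSE), class = "individual")
  for (i in 1:20) {
    g <- meiosis_gamete(ind, map)
    expect_true(all(g == h1 | g == h2))
  }
})

test_that("two-locus recombinant fraction matches the renewal-process oracle", {
  set.seed(17)
  d <- 50
  map <- genetic_map(c(1, 1), c("a", "b"), c(1e-9, d), lengths = d)
  ind <- structure(list(h1 = c(1L, 1L), h2 = c(0L, 0L), inbred = FALSE),
                   class = "individual")
  pop <- new_population(matrix(c(1L, 1L)), matrix(c(0L, 0L)), map)
  n <- 1e5
  g <- recombsim:::population_gametes(pop, rep(1L, n), meiosis_params(2.6))
  rf_impl <- mean(g[1, ] != g[2, ])
  rf_oracle <- r_recombinant_fraction(d, 2.6, 2e5)
  se <- sqrt(rf_impl * (1 - rf_impl) / n + rf_oracle * (1 - rf_oracle) / 2e5)
  expect_equal(rf_impl, rf_oracle, tolerance = 3 * se / rf_impl)
})

test_that("crossing homozygous parents gives the expected F1", {
  set.seed(18)
  map <- toy_map()
  L <- n_loci(map)
  aa <- homozygous_population(matrix(1L, L, 1), map)
  bb <- homozygous_population(matrix(0L, L, 1), map)
  f1 <- make_cross(get_individual(aa, 1), get_individual(bb, 1), map)
  expect_true(all(f1$h1 == 1L) && all(f1$h2 == 0L))
  expect_false(f1$inbred)
  same <- make_cross(get_individual(aa, 1), get_individual(aa, 1), map)
  expect_true(same$inbred)
})

test_that("selfing an F1 gives 1:2:1 genotype ratios at a single locus", {
  set.seed(19)
  map <- genetic_map(1, "q", 10, lengths = 10)
  f1 <- structure(list(h1 = 1L, h2 = 0L, inbred = FALSE),
                  class = "individual")
  pop <- new_population(matrix(1L), matrix(0L), map)
  n <- 1e4
  h1 <- recombsim:::population_gametes(pop, rep(1L, n), meiosis_params())
  h2 <- recombsim:::population_gametes(pop, rep(1L, n), meiosis_params())
  dos <- as.vector(h1 + h2)
  gof <- chisq.test(table(factor(dos, levels = 0:2)), p = c(1, 2, 1) / 4)
  expect_gt(gof$p.value, 0.01)
})

test_that("doubled haploids are homozygous and DH of inbred is identical", {
  set.seed(20)
  map <- toy_map()
  L <- n_loci(map)
  h1 <- matrix(rbinom(L, 1, 0.5), ncol = 1)
  h2 <- matrix(rbinom(L, 1, 0.5), ncol = 1)
  het <- structure(list(h1 = as.integer(h1), h2 = as.integer(h2),
                        inbred = FALSE), class = "individual")
  dh <- make_dh(het, map)
  expect_true(dh$inbred)
  expect_identical(dh$h1, dh$h2)
  dh2 <- make_dh(dh, map)
  expect_identical(dh2$h1, dh$h1)
  expect_identical(sort(unique(c(dh$h1 == h1[, 1], dh$h1 == h2[, 1]))),
                   sort(unique(c(dh$h1 == h1[, 1], dh$h1 == h2[, 1]))))
})

test_that("DH allele ratio from an F1 is 1:1 at a single locus", {
  set.seed(21)
  map <- genetic_map(1, "q", 10, lengths = 10)
  pop <- new_population(matrix(1L), matrix(0L), map)
  g <- recombsim:::population_gametes(pop, rep(1L, 1e4), meiosis_params())
  expect_equal(mean(g), 0.5, tolerance = 3 * 0.5 / sqrt(1e4) / 0.5)
})

test_that("meiosis_params validates the interference shape", {
  expect_error(meiosis_params(0), "positive")
  expect_error(meiosis_params(-1), "positive")
})
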