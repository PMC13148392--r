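tiny_cfg <- function(..., h2 = 0.5) {
  scenario_config(n_qtl_per_chr = 10, h2 = h2, markers_per_chr = 15,
                  n_select = 5, n_crosses = 10, dh_per_f2 = 10,
                  burn_in_cycles = 3, post_cycles = 3, n_replicates = 2,
                  loci_per_chr = 25, ...)
}

test_that("scenario_config enforces the population structure", {
  cfg <- tiny_cfg()
  expect_identical(cfg$pop_size, cfg$n_crosses * cfg$dh_per_f2)
  expect_error(scenario_config(n_select = 50, n_crosses = 4, dh_per_f2 = 10),
               "n_select")
})

test_that("run_cycle produces the configured number of inbred DH lines", {
  set.seed(71)
  cfg <- tiny_cfg()
  map <- make_default_map(cfg$founder)
  pop <- sample_founders(cfg$founder, map)
  arch <- sample_architecture(map, cfg$n_qtl_per_chr, cfg$h2, pop)
  nxt <- run_cycle(pop, phenotypes(pop, arch), cfg)
  expect_identical(n_ind(nxt), cfg$pop_size)
  expect_true(all(nxt$inbred))
  expect_true(all(nxt$h1 == nxt$h2))
})

test_that("burn-in raises the mean genetic value across cycles", {
  set.seed(72)
  cfg <- tiny_cfg()
  cfg$burn_in_cycles <- 6L
  deltas <- replicate(20, {
    st <- run_burn_in(cfg)
    m <- st$burnin_means
    m[length(m)] - m[1]
  })
  expect_gt(mean(deltas), 0)
})

test_that("higher heritability gives at least the burn-in gain of lower h2", {
  gains <- matrix(NA, 12, 2)
  for (r in seq_len(12)) {
    for (k in 1:2) {
      set.seed(730 + r)  # paired founders and trait draw
      cfg <- tiny_cfg(h2 = c(0.9, 0.2)[k])
      st <- run_burn_in(cfg)
      gains[r, k] <- st$burnin_means[cfg$burn_in_cycles] -
        st$burnin_means[1]
    }
  }
  expect_gte(mean(gains[, 1] - gains[, 2]), 0)
})

test_that("cycle-0 records are standardised to mean 0 and variance 1", {
  set.seed(74)
  res <- run_long_term(tiny_cfg(rng_seed = 7))
  c0 <- res$records[res$records$cycle == 0, ]
  expect_equal(c0$mean_genetic_value, rep(0, nrow(c0)), tolerance = 1e-12)
  expect_equal(c0$genetic_variance, rep(1, nrow(c0)), tolerance = 1e-12)
})

test_that("bulmer column is recomputable from the variance columns", {
  set.seed(75)
  res <- run_long_term(tiny_cfg(rng_seed = 8))
  rec <- res$records
  ok <- !is.na(rec$bulmer)
  expect_equal(rec$bulmer[ok],
               rec$genetic_variance[ok] / (rec$genic_variance[ok] / 2),
               tolerance = 1e-12)
})

test_that("run results are reproducible bit-for-bit from the base seed", {
  cfg <- tiny_cfg(rng_seed = 9)
  a <- run_long_term(cfg)
  b <- run_long_term(cfg)
  expect_identical(a$records, b$records)
})

test_that("arms share their burn-in and pair across factors", {
  cfg <- tiny_cfg(rng_seed = 10)
  res <- run_arms(cfg, data.frame(map_factor = c(1, 8),
                                  selection = "phenotypic",
                                  name = c("f1", "f8")))
  # identical burn-in implies identical cycle-0 genic variance
  g0a <- res$f1$records$genic_variance[res$f1$records$cycle == 0]
  g0b <- res$f8$records$genic_variance[res$f8$records$cycle == 0]
  expect_identical(g0a, g0b)
})

test_that("genomic arms train on the configured cadence", {
  cfg <- tiny_cfg(selection = "genomic", rng_seed = 11)
  cfg$training_interval <- 2L
  res <- run_long_term(cfg)
  r1 <- res$records[res$records$replicate == 1, ]
  expect_identical(r1$trained_this_cycle[1:2], c(TRUE, FALSE))
  expect_false(r1$trained_this_cycle[4])  # off-cadence cycle never trains
  # accuracy is defined while variance remains; after complete fixation the
  # correlation is undefined and later cycles are frozen without training
  expect_true(all(!is.na(r1$accuracy) | r1$genetic_variance == 0))
})

test_that("merged-training benchmark with window 1 reduces to plain GS", {
  cfg <- tiny_cfg(selection = "genomic", map_factor = 4, rng_seed = 12)
  merged <- run_merged_training(cfg, window = 1)
  plain <- run_long_term(tiny_cfg(selection = "genomic", map_factor = 1,
                                  rng_seed = 12))
  expect_equal(merged$benchmark$records$mean_genetic_value,
               plain$records$mean_genetic_value)
})

test_that("merged-training arms record accuracy under both map factors", {
  cfg <- tiny_cfg(selection = "genomic", map_factor = 4, rng_seed = 13)
  res <- run_merged_training(cfg, window = 3)
  expect_named(res, c("treatment", "benchmark"))
  for (arm in res) {
    trained <- arm$records$trained_this_cycle[arm$records$cycle < 3]
    expect_true(all(trained))
    # accuracy defined at least while variance remains (tiny populations can
    # exhaust variance, where the correlation is undefined by design)
    expect_true(any(!is.na(arm$records$accuracy)))
  }
})

test_that("model reuse records metadata and paired factor arms", {
  cfg <- tiny_cfg(selection = "genomic", rng_seed = 14)
  cfg$n_replicates <- 3L
  tab <- run_model_reuse(cfg, factors = c(1, 8))
  expect_identical(nrow(tab), 6L)
  expect_true(all(tab$map_factor_at_training == 1))
  expect_equal(tab$delta, tab$accuracy_next_gen - tab$accuracy_at_training)
  # accuracy at training is shared across factor arms of a replicate
  by_rep <- split(tab$accuracy_at_training, tab$replicate)
  for (v in by_rep) expect_equal(v[1], v[2])
})

test_that("first-cycle accuracy experiment reports both generations", {
  cfg <- tiny_cfg(selection = "genomic", rng_seed = 16)
  cfg$n_replicates <- 2L
  tab <- run_first_cycle_accuracy(cfg, factors = c(1, 8))
  expect_identical(nrow(tab), 4L)
  ok <- !is.na(tab$accuracy_first_cycle)
  expect_true(all(abs(tab$accuracy_first_cycle[ok]) <= 1))
  # training-generation accuracy is shared across the factor arms
  expect_equal(tab$accuracy_training_gen[1], tab$accuracy_training_gen[2])
})

test_that("replicate_and_summarize attaches per-cycle means and variance", {
  cfg <- tiny_cfg(rng_seed = 15)
  res <- replicate_and_summarize(cfg)
  expect_identical(nrow(res$summary$per_cycle),
                   cfg$post_cycles + 1L)
  expect_equal(res$summary$final_gain_variance,
               var(final_gains(res)))
})
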