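#' Configure a breeding-program scenario
#'
#' Defines one arm of the simulated doubled-haploid recurrent-selection
#' program: a burn-in of phenotypic selection on the base map, then
#' \code{post_cycles} cycles under the requested map factor and selection
#' mode. Each cycle selects the \code{n_select} best individuals, generates
#' \code{n_crosses} random crosses among them, selfs each F1 once, and
#' produces \code{dh_per_f2} doubled haploids per F2, so the population size
#' is \code{n_crosses * dh_per_f2} throughout.
#'
#' @param n_qtl_per_chr QTL per chromosome (10, 100, or 1000 in the study
#'   grid; default 100).
#' @param h2 Narrow-sense heritability of the founder trait (default 0.5).
#' @param map_factor Recombination scaling factor applied after burn-in
#'   (default 1).
#' @param markers_per_chr SNP-chip markers per chromosome (default 500).
#' @param selection \code{"phenotypic"} or \code{"genomic"}.
#' @param training_interval Cycles between RRBLUP refits (1 = every cycle).
#' @param training_window Number of most recent generations merged into the
#'   training set (1 = current generation only; 3 = rolling three-generation
#'   window).
#' @param n_select Individuals selected per cycle (default 30).
#' @param n_crosses Crosses per cycle (default 60).
#' @param dh_per_f2 Doubled haploids per F2 (default 50).
#' @param burn_in_cycles Phenotypic-selection burn-in cycles (default 10).
#' @param post_cycles Cycles simulated after the burn-in (default 15).
#' @param n_replicates Independent replicate programs (default 100).
#' @param loci_per_chr Simulated loci per chromosome; \code{NULL} (default)
#'   simulates exactly the candidate QTL plus, for genomic selection, the
#'   chip markers — statistically equivalent to sampling them from a dense
#'   uniformly placed SNP set.
#' @param founder Optional \code{\link{founder_spec}} override.
#' @param meiosis A \code{\link{meiosis_params}} object.
#' @param reml_n Size cap of the spectral REML subsystem used by
#'   \code{\link{train_rrblup}} during scheme runs (default 1000).
#' @param rng_seed Base seed from which per-replicate seeds are derived.
#' @return An object of class \code{scenario_config}.
#' @export
scenario_config <- function(n_qtl_per_chr = 100, h2 = 0.5, map_factor = 1,
                            markers_per_chr = 500,
                            selection = c("phenotypic", "genomic"),
                            training_interval = 1, training_window = 1,
                            n_select = 30, n_crosses = 60, dh_per_f2 = 50,
                            burn_in_cycles = 10, post_cycles = 15,
                            n_replicates = 100, loci_per_chr = NULL,
                            founder = NULL, meiosis = meiosis_params(),
                            reml_n = 1000, rng_seed = NULL) {
  selection <- match.arg(selection)
  pop_size <- n_crosses * dh_per_f2
  if (n_select > pop_size) stop("n_select exceeds the population size")
  if (n_select < 2) stop("n_select must be at least 2")
  if (training_interval < 1) stop("training_interval must be at least 1")
  if (is.null(loci_per_chr))
    loci_per_chr <- n_qtl_per_chr +
      if (selection == "genomic") markers_per_chr else 0
  if (loci_per_chr < n_qtl_per_chr)
    stop("loci_per_chr must be at least n_qtl_per_chr")
  if (is.null(founder))
    founder <- founder_spec(n_founders = pop_size,
                            n_loci_per_chr = loci_per_chr)
  structure(list(
    n_qtl_per_chr = as.integer(n_qtl_per_chr), h2 = h2,
    map_factor = map_factor, markers_per_chr = as.integer(markers_per_chr),
    selection = selection, training_interval = as.integer(training_interval),
    training_window = as.integer(training_window),
    n_select = as.integer(n_select), n_crosses = as.integer(n_crosses),
    dh_per_f2 = as.integer(dh_per_f2), pop_size = as.integer(pop_size),
    burn_in_cycles = as.integer(burn_in_cycles),
    post_cycles = as.integer(post_cycles),
    n_replicates = as.integer(n_replicates),
    loci_per_chr = as.integer(loci_per_chr), founder = founder,
    meiosis = meiosis, reml_n = reml_n, rng_seed = rng_seed),
    class = "scenario_config")
}

#' One cycle of selection, crossing, selfing, and DH production
#'
#' Selects the top \code{cfg$n_select} individuals on the supplied selection
#' criteria, draws \code{cfg$n_crosses} random parent pairs among them
#' (distinct parents within a cross; pairs may repeat), selfs each F1 once,
#' and generates \code{cfg$dh_per_f2} doubled haploids from each F2.
#'
#' @param pop Current \code{population} (its map, including any scaling
#'   factor, drives meiosis).
#' @param selection_values Numeric vector of selection criteria (phenotypes
#'   or GEBVs), one per individual.
#' @param cfg A \code{\link{scenario_config}}.
#' @param generation Label for the new generation.
#' @return The next DH \code{population} of size \code{cfg$pop_size}.
#' @export
run_cycle <- function(pop, selection_values, cfg, generation = "") {
  sel <- select_top(selection_values, cfg$n_select)
  mothers <- sel[sample.int(cfg$n_select, cfg$n_crosses, replace = TRUE)]
  fathers <- sel[sample.int(cfg$n_select, cfg$n_crosses, replace = TRUE)]
  repeat {
    clash <- mothers == fathers
    if (!any(clash)) break
    fathers[clash] <- sel[sample.int(cfg$n_select, sum(clash),
                                     replace = TRUE)]
  }
  f1 <- cross_population(pop, mothers, fathers, cfg$meiosis, "F1")
  f2 <- self_population(f1, seq_len(cfg$n_crosses), cfg$meiosis, "F2")
  dh_population(f2, rep(seq_len(cfg$n_crosses), each = cfg$dh_per_f2),
                cfg$meiosis, generation)
}

#' Run the burn-in phase of a breeding program
#'
#' Generates founders and the genetic map, calibrates the trait architecture
#' to unit additive variance in the founders, and performs
#' \code{cfg$burn_in_cycles} cycles of phenotypic selection on the base map
#' (the founder generation is selected in the first cycle). Returns the
#' burn-in-end DH population together with the standardisation constants
#' (mean and standard deviation of its genetic values) used for all later
#' reporting.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @param keep_history Keep chip genotypes and phenotypes of the last
#'   generations selected during burn-in (needed for merged training sets).
#' @return List with elements \code{pop}, \code{arch}, \code{chip} (or
#'   \code{NULL}), \code{map}, \code{std} (mean, sd), \code{burnin_means}
#'   (mean genetic value of each generation selected during burn-in), and
#'   \code{history}.
#' @export
run_burn_in <- function(cfg, keep_history = cfg$training_window > 1) {
  map <- make_default_map(cfg$founder)
  founders <- sample_founders(cfg$founder, map, cfg$meiosis)
  arch <- sample_architecture(map, cfg$n_qtl_per_chr, cfg$h2, founders)
  chip <- NULL
  if (cfg$selection == "genomic" || keep_history) {
    if (any(map$chr_len - cfg$n_qtl_per_chr < cfg$markers_per_chr))
      stop("not enough non-QTL loci for the chip; raise loci_per_chr")
    chip <- sample_chip(map, arch, cfg$markers_per_chr)
  }
  pop <- founders
  history <- list()
  burnin_means <- numeric(cfg$burn_in_cycles)
  for (cycle in seq_len(cfg$burn_in_cycles)) {
    gv <- genetic_values(pop, arch)
    y <- gv + rnorm(length(gv), 0, sqrt(arch$sigma_e2))
    burnin_means[cycle] <- mean(gv)
    if (keep_history) {
      history <- c(history, list(list(generation = pop$generation,
                                      M = genotype_chip(pop, chip), y = y)))
      if (length(history) > cfg$training_window - 1L)
        history <- history[-1L]
    }
    pop <- run_cycle(pop, y, cfg, generation = paste0("burnin", cycle))
  }
  gv <- genetic_values(pop, arch)
  s <- sqrt(pop_var(gv))
  if (s == 0) stop("genetic variance exhausted during burn-in")
  list(pop = pop, arch = arch, chip = chip, map = map,
       std = c(mean = mean(gv), sd = s), burnin_means = burnin_means,
       history = history)
}

should_train <- function(cycle, interval) cycle %% interval == 0L

# Post-burn-in phase for one arm. `state` comes from run_burn_in; arm
# settings (map factor, selection mode, cadence, window) are read from cfg.
run_post_phase <- function(state, cfg) {
  arch <- state$arch
  chip <- state$chip
  pop <- state$pop
  if (cfg$map_factor != 1)
    pop$map <- scale_map(state$map, cfg$map_factor)
  m0 <- state$std["mean"]
  s0 <- state$std["sd"]
  genomic <- cfg$selection == "genomic"
  history <- state$history
  model <- NULL

  nrec <- cfg$post_cycles + 1L
  rec <- data.frame(cycle = seq_len(nrec) - 1L,
                    mean_genetic_value_raw = numeric(nrec),
                    mean_genetic_value = numeric(nrec),
                    genetic_variance = numeric(nrec),
                    genic_variance = numeric(nrec),
                    bulmer = numeric(nrec),
                    accuracy = NA_real_,
                    trained_this_cycle = FALSE)

  merged <- genomic && cfg$training_window > 1L
  shared <- state$shared_cycle0
  for (cycle in 0:cfg$post_cycles) {
    gv <- genetic_values(pop, arch)
    y <- if (cycle == 0L && !is.null(shared)) shared$y
         else gv + rnorm(length(gv), 0, sqrt(arch$sigma_e2))
    trained <- FALSE
    if (merged && cycle < cfg$post_cycles) {
      history <- c(history, list(list(generation = pop$generation,
                                      M = genotype_chip(pop, chip),
                                      y = y)))
      if (length(history) > cfg$training_window)
        history <- history[-1L]
    }
    if (genomic && cycle < cfg$post_cycles &&
        should_train(cycle, cfg$training_interval)) {
      model <- if (cycle == 0L && !is.null(shared) && !merged) {
        shared$model
      } else if (merged) {
        train_rrblup(rolling_training_set(history, cfg$training_window),
                     reml_n = cfg$reml_n, map_factor = pop$map$factor)
      } else {
        train_rrblup_pop(pop, chip$loci, y, reml_n = cfg$reml_n,
                         map_factor = pop$map$factor)
      }
      trained <- TRUE
    }
    gvar <- pop_var(gv)
    genic <- genic_variance(pop, arch)
    i <- cycle + 1L
    rec$mean_genetic_value_raw[i] <- mean(gv) - m0
    rec$mean_genetic_value[i] <- (mean(gv) - m0) / s0
    rec$genetic_variance[i] <- gvar / s0^2
    rec$genic_variance[i] <- genic / s0^2
    rec$bulmer[i] <- bulmer_effect(gvar, genic)
    rec$trained_this_cycle[i] <- trained
    gebv <- if (genomic && !is.null(model))
      predict_gebv_pop(model, pop, chip$loci) else NULL
    if (!is.null(gebv))
      rec$accuracy[i] <- accuracy(gebv, gv)
    # after complete fixation of the trait, every later generation is a
    # clone of this one statistically: freeze the remaining records
    if (gvar == 0 && genic == 0 && cycle < cfg$post_cycles) {
      for (j in (cycle + 1L):cfg$post_cycles + 1L) {
        rec[j, ] <- rec[i, ]
        rec$cycle[j] <- j - 1L
        rec$trained_this_cycle[j] <- FALSE
      }
      break
    }
    if (cycle < cfg$post_cycles) {
      values <- if (genomic) gebv else y
      pop <- run_cycle(pop, values, cfg,
                       generation = paste0("cycle", cycle + 1L))
    }
  }
  rec
}

derive_replicate_seeds <- function(cfg) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  sample.int(2147483646L, cfg$n_replicates)
}

restore_rng <- function(state) assign(".Random.seed", state, envir = globalenv())

#' Run replicated arms of a breeding experiment with a shared burn-in
#'
#' Each replicate derives its own seed from \code{cfg$rng_seed}, runs the
#' burn-in once, and then replays every arm from the identical
#' post-burn-in random-number state. Arms therefore share founders, burn-in
#' trajectory, and standardisation constants within a replicate, which makes
#' across-arm contrasts (gain ratios, cadence effects) seed-paired.
#'
#' @param cfg Base \code{\link{scenario_config}}.
#' @param arms Data frame with one row per arm; recognised columns
#'   \code{map_factor}, \code{selection}, \code{training_interval},
#'   \code{training_window} override the base configuration, and an optional
#'   \code{name} column labels the arm.
#' @return Named list of \code{run_result} objects (per-arm records with a
#'   \code{replicate} column).
#' @export
run_arms <- function(cfg, arms) {
  arms <- as.data.frame(arms)
  if (is.null(arms$name))
    arms$name <- paste0("arm", seq_len(nrow(arms)))
  arm_cfgs <- lapply(seq_len(nrow(arms)), function(i) {
    ac <- cfg
    for (field in intersect(c("map_factor", "selection", "training_interval",
                              "training_window", "post_cycles"),
                            names(arms)))
      ac[[field]] <- arms[[field]][i]
    ac
  })
  keep_history <- any(vapply(arm_cfgs, `[[`, numeric(1),
                             "training_window") > 1)
  burn_cfg <- cfg
  if (any(vapply(arm_cfgs, `[[`, character(1), "selection") == "genomic"))
    burn_cfg$selection <- "genomic"
  seeds <- derive_replicate_seeds(cfg)
  out <- lapply(seq_len(nrow(arms)), function(i)
    vector("list", cfg$n_replicates))
  names(out) <- arms$name
  # when every arm trains on single generations, the cycle-0 phenotypes and
  # model are identical across arms and are computed once per replicate
  share_cycle0 <- !keep_history &&
    all(vapply(arm_cfgs, `[[`, character(1), "selection") == "genomic")
  for (r in seq_len(cfg$n_replicates)) {
    set.seed(seeds[r])
    state <- run_burn_in(burn_cfg, keep_history = keep_history)
    if (share_cycle0) {
      gv0 <- genetic_values(state$pop, state$arch)
      y0 <- gv0 + rnorm(length(gv0), 0, sqrt(state$arch$sigma_e2))
      state$shared_cycle0 <- list(
        y = y0,
        model = train_rrblup_pop(state$pop, state$chip$loci, y0,
                                 reml_n = cfg$reml_n, map_factor = 1))
    }
    rng <- .Random.seed
    for (i in seq_len(nrow(arms))) {
      restore_rng(rng)
      rec <- run_post_phase(state, arm_cfgs[[i]])
      rec$replicate <- r
      out[[i]][[r]] <- rec
    }
  }
  lapply(seq_len(nrow(arms)), function(i) {
    res <- list(records = do.call(rbind, out[[i]]), cfg = arm_cfgs[[i]],
                name = arms$name[i])
    class(res) <- "run_result"
    res
  }) -> results
  names(results) <- arms$name
  results
}

#' Run one replicated long-term scenario
#'
#' Burn-in, map rescaling, and \code{cfg$post_cycles} cycles of phenotypic or
#' genomic selection, replicated \code{cfg$n_replicates} times with
#' independent seeds; per-cycle metrics are standardised so that the
#' burn-in-end generation has mean genetic value 0 and genetic variance 1.
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @return A \code{run_result}: list with \code{records} (one row per
#'   replicate and cycle) and \code{cfg}.
#' @export
run_long_term <- function(cfg) {
  run_arms(cfg, data.frame(map_factor = cfg$map_factor,
                           selection = cfg$selection,
                           training_interval = cfg$training_interval,
                           training_window = cfg$training_window,
                           name = "scenario"))[[1]]
}

#' @export
print.run_result <- function(x, ...) {
  fg <- final_gains(x)
  cat(sprintf(
    "run_result '%s': %d replicates x %d cycles; mean final gain %.3f\n",
    x$name, max(x$records$replicate), max(x$records$cycle),
    mean(fg)))
  invisible(x)
}

#' Per-replicate gain at the final recorded cycle
#'
#' Gains are reported on the founder scale by default: the base trait is
#' calibrated to unit additive variance in the founders, and the
#' burn-in-end population mean is subtracted, so a gain of 1 is one founder
#' additive standard deviation. \code{scale = "standardized"} instead
#' divides each replicate's gain by its burn-in-end genetic standard
#' deviation.
#'
#' @param result A \code{run_result}.
#' @param scale \code{"founder"} (default) or \code{"standardized"}.
#' @return Numeric vector, one value per replicate.
#' @export
final_gains <- function(result, scale = c("founder", "standardized")) {
  scale <- match.arg(scale)
  rec <- result$records
  last <- rec[rec$cycle == max(rec$cycle), ]
  col <- if (scale == "founder") "mean_genetic_value_raw"
         else "mean_genetic_value"
  last[[col]][order(last$replicate)]
}

#' Gain ratio between two runs
#'
#' Ratio of the replicate-mean standardised final-cycle genetic gains of an
#' increased-recombination run over a baseline run.
#'
#' @param increased,baseline \code{run_result} objects.
#' @return Scalar ratio.
#' @export
gain_ratio <- function(increased, baseline) {
  mean(final_gains(increased)) / mean(final_gains(baseline))
}

#' Run a scenario and attach replicate summaries
#'
#' @param cfg A \code{\link{scenario_config}}.
#' @return A \code{run_result} with an additional \code{summary} element:
#'   per-cycle replicate means and the across-replicate variance of the
#'   final-cycle gain.
#' @export
replicate_and_summarize <- function(cfg) {
  res <- run_long_term(cfg)
  res$summary <- list(
    per_cycle = build_summary(list(res)),
    final_gain_variance = replicate_variance(final_gains(res)))
  res
}

#' Model reuse across a recombination-rate change
#'
#' Trains an RRBLUP model on the burn-in-end DH generation, selects on its
#' GEBVs, then completes one cycle under each requested map factor
#' (seed-paired across factors) and reapplies the unchanged model to the
#' resulting generation. Reports the accuracy in the training generation, in
#' the next generation, and their difference (next minus training).
#'
#' @param cfg A genomic \code{\link{scenario_config}}.
#' @param factors Map factors to test (default \code{c(1, 2, 4, 8)}).
#' @return Data frame with one row per replicate and factor: columns
#'   \code{replicate}, \code{factor}, \code{accuracy_at_training},
#'   \code{accuracy_next_gen}, \code{delta}, and
#'   \code{map_factor_at_training} (model metadata, always 1).
#' @export
run_model_reuse <- function(cfg, factors = c(1, 2, 4, 8)) {
  stopifnot(cfg$selection == "genomic")
  seeds <- derive_replicate_seeds(cfg)
  rows <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    set.seed(seeds[r])
    state <- run_burn_in(cfg)
    pop0 <- state$pop
    gv0 <- genetic_values(pop0, state$arch)
    y0 <- phenotypes(pop0, state$arch)
    model <- train_rrblup_pop(pop0, state$chip$loci, y0,
                              reml_n = cfg$reml_n, map_factor = 1)
    gebv0 <- predict_gebv_pop(model, pop0, state$chip$loci)
    acc0 <- accuracy(gebv0, gv0)
    rng <- .Random.seed
    rows[[r]] <- do.call(rbind, lapply(factors, function(f) {
      restore_rng(rng)
      pop <- pop0
      if (f != 1) pop$map <- scale_map(state$map, f)
      nxt <- run_cycle(pop, gebv0, cfg, generation = "reuse1")
      acc1 <- accuracy(predict_gebv_pop(model, nxt, state$chip$loci),
                       genetic_values(nxt, state$arch))
      data.frame(replicate = r, factor = f, accuracy_at_training = acc0,
                 accuracy_next_gen = acc1, delta = acc1 - acc0,
                 map_factor_at_training = model$map_factor_at_training)
    }))
  }
  do.call(rbind, rows)
}

#' First-cycle prediction accuracy under a recombination-rate change
#'
#' Per replicate: after the burn-in, an RRBLUP model is trained on the
#' burn-in-end DH generation and its in-generation accuracy recorded; the 30
#' best GEBVs are selected and one full cycle is completed under each
#' requested map factor (seed-paired). A fresh model is then trained on each
#' resulting first-cycle generation and its in-generation accuracy recorded.
#'
#' @param cfg A genomic \code{\link{scenario_config}}.
#' @param factors Map factors applied to the first post-burn-in cycle.
#' @return Data frame with columns \code{replicate}, \code{factor},
#'   \code{accuracy_training_gen} (burn-in-end generation, base map), and
#'   \code{accuracy_first_cycle}.
#' @export
run_first_cycle_accuracy <- function(cfg, factors = c(1, 2, 4, 8)) {
  stopifnot(cfg$selection == "genomic")
  seeds <- derive_replicate_seeds(cfg)
  rows <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    set.seed(seeds[r])
    state <- run_burn_in(cfg)
    pop0 <- state$pop
    gv0 <- genetic_values(pop0, state$arch)
    y0 <- phenotypes(pop0, state$arch)
    model0 <- train_rrblup_pop(pop0, state$chip$loci, y0,
                               reml_n = cfg$reml_n, map_factor = 1)
    gebv0 <- predict_gebv_pop(model0, pop0, state$chip$loci)
    acc0 <- accuracy(gebv0, gv0)
    rng <- .Random.seed
    rows[[r]] <- do.call(rbind, lapply(factors, function(f) {
      restore_rng(rng)
      pop <- pop0
      if (f != 1) pop$map <- scale_map(state$map, f)
      nxt <- run_cycle(pop, gebv0, cfg, generation = "cycle1")
      gv1 <- genetic_values(nxt, state$arch)
      y1 <- phenotypes(nxt, state$arch)
      m1 <- train_rrblup_pop(nxt, state$chip$loci, y1,
                             reml_n = cfg$reml_n, map_factor = f)
      acc1 <- accuracy(predict_gebv_pop(m1, nxt, state$chip$loci), gv1)
      data.frame(replicate = r, factor = f, accuracy_training_gen = acc0,
                 accuracy_first_cycle = acc1)
    }))
  }
  do.call(rbind, rows)
}

#' Merged multi-generation training sets across a recombination change
#'
#' Maintains a rolling three-generation training set that spans the
#' recombination-rate change: the model used at the burn-in-end generation is
#' trained on the final burn-in generations, and after the map is rescaled
#' the newest DH generation replaces the oldest one in the training set each
#' cycle. A benchmark arm keeps the base map. Both arms retrain every cycle
#' and are seed-paired.
#'
#' @param cfg A genomic \code{\link{scenario_config}}; its
#'   \code{map_factor} defines the treatment arm and \code{post_cycles}
#'   should be small (3 in the reference design).
#' @param window Rolling window size in generations (default 3).
#' @return Named list of two \code{run_result} objects, \code{treatment}
#'   and \code{benchmark}.
#' @export
run_merged_training <- function(cfg, window = 3) {
  stopifnot(cfg$selection == "genomic")
  cfg$training_window <- as.integer(window)
  run_arms(cfg, data.frame(
    map_factor = c(cfg$map_factor, 1),
    selection = "genomic",
    training_interval = 1L,
    training_window = as.integer(window),
    name = c("treatment", "benchmark")))
}
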