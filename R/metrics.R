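#' Bulmer effect of a DH population
#'
#' Ratio of the realised genetic variance to half the genic variance; the
#' halving accounts for the fully inbred state of doubled haploids, whose
#' expected equilibrium variance is twice the Hardy-Weinberg value. Values
#' below 1 indicate selection-induced negative covariance between QTL.
#'
#' @param genetic_var Realised genetic variance (>= 0).
#' @param genic_var Genic variance (> 0; 0 flags fixation and yields
#'   \code{NA}).
#' @return Scalar, or \code{NA_real_} when the genic variance is 0.
#' @export
bulmer_effect <- function(genetic_var, genic_var) {
  ifelse(genic_var == 0, NA_real_, genetic_var / (genic_var / 2))
}

#' Across-replicate variance of final genetic gains
#'
#' Sample variance (denominator n - 1) of the per-replicate final-cycle
#' standardised gains.
#'
#' @param final_gains Numeric vector, one gain per replicate.
#' @return Scalar variance.
#' @export
replicate_variance <- function(final_gains) var(final_gains)

#' Cumulative gain per unit of genetic variance lost
#'
#' (gain_t - gain_0) / (var_0 - var_t) on the standardised scale; reported
#' as \code{NA} for cycles where the variance has not decreased.
#'
#' @param gain Standardised mean genetic values per cycle.
#' @param variance Standardised genetic variances per cycle.
#' @return Numeric vector of the same length.
#' @export
gain_per_variance_lost <- function(gain, variance) {
  lost <- variance[1] - variance
  ifelse(lost > 0, (gain - gain[1]) / lost, NA_real_)
}

#' Summarise replicated runs per cycle
#'
#' Aggregates each run's records into per-cycle replicate means and attaches,
#' at the final cycle, the across-replicate variance of the gain and (when a
#' baseline run is named) the gain ratio against it. Deterministic given its
#' inputs and invariant to replicate order.
#'
#' @param results List of \code{run_result} objects (named, or carrying
#'   \code{name} elements).
#' @param baseline Optional name of the run serving as gain-ratio baseline.
#' @return Data frame keyed by (scenario, cycle) with columns
#'   \code{mean_gain}, \code{mean_genetic_variance},
#'   \code{mean_genic_variance}, \code{mean_bulmer}, \code{mean_accuracy},
#'   \code{replicate_variance_final_gain}, \code{gain_ratio}.
#' @export
build_summary <- function(results, baseline = NULL) {
  if (inherits(results, "run_result")) results <- list(results)
  nm <- names(results)
  if (is.null(nm))
    nm <- vapply(results, function(r) r$name, character(1))
  names(results) <- nm
  base_gain <- if (!is.null(baseline)) {
    if (!baseline %in% nm) stop("baseline run not found: ", baseline)
    mean(final_gains(results[[baseline]]))
  } else NA_real_
  out <- lapply(nm, function(id) {
    rec <- results[[id]]$records
    cyc <- sort(unique(rec$cycle))
    agg <- function(col) vapply(cyc, function(c)
      mean(rec[[col]][rec$cycle == c]), numeric(1))
    acc <- vapply(cyc, function(c) {
      v <- rec$accuracy[rec$cycle == c]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    df <- data.frame(scenario = id, cycle = cyc,
                     mean_gain = agg("mean_genetic_value_raw"),
                     mean_genetic_variance = agg("genetic_variance"),
                     mean_genic_variance = agg("genic_variance"),
                     mean_bulmer = agg("bulmer"),
                     mean_accuracy = acc,
                     replicate_variance_final_gain = NA_real_,
                     gain_ratio = NA_real_)
    fin <- df$cycle == max(cyc)
    df$replicate_variance_final_gain[fin] <-
      replicate_variance(final_gains(results[[id]]))
    if (!is.na(base_gain) && base_gain != 0)
      df$gain_ratio[fin] <- mean(final_gains(results[[id]])) / base_gain
    df
  })
  do.call(rbind, out)
}

#' Write per-cycle records or a summary table as CSV
#'
#' @param x A \code{run_result} (its \code{records} are written) or a data
#'   frame such as the output of \code{\link{build_summary}}.
#' @param file Output path.
#' @export
write_records_csv <- function(x, file) {
  df <- if (inherits(x, "run_result")) x$records else as.data.frame(x)
  write.table(df, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}
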