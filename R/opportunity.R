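## Opportunity-for-selection indices: the standardised variance
## var(x)/mean(x)^2 of a fitness component across focal males, with
## percentile bootstrap confidence intervals.  I uses reproductive success
## T, I_S mating success M (pre-copulatory), I_P paternity share P
## (post-copulatory).

#' Opportunity for selection of a fitness component
#'
#' The standardised variance `var(x) / mean(x)^2` (sample variance, n - 1
#' denominator).  Scale-invariant: multiplying all values by a positive
#' constant leaves the index unchanged.
#'
#' @param values Numeric vector of per-male measurements (length >= 2,
#'   nonzero mean).
#' @return A nonnegative scalar.
#' @export
opportunity_index <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop_polysel("opportunity_index: need at least 2 non-missing values")
  }
  m <- mean(values)
  if (m == 0) {
    stop_polysel("opportunity_index: undefined for mean zero")
  }
  var(values) / m^2
}

#' Percentile bootstrap confidence interval
#'
#' Resamples `values` with replacement `n_boot` times, applies `statistic`,
#' and returns the 2.5/97.5 percentile bounds.  Resamples on which the
#' statistic is undefined (e.g. an opportunity index of an all-zero
#' resample) are dropped and counted.
#'
#' @param statistic Function of a numeric vector returning a scalar.
#' @param values Numeric vector to resample.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed for reproducible resampling.
#' @param conf Confidence level (default 0.95).
#' @return A list with `point`, `lower`, `upper`, `n_boot`, `n_dropped`
#'   and `seed`.
#' @export
bootstrap_ci <- function(statistic, values, n_boot = 10000, seed = NULL,
                         conf = 0.95) {
  if (n_boot < 1) stop_polysel("bootstrap_ci: n_boot must be >= 1")
  point <- statistic(values)
  n <- length(values)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      res <- tryCatch(statistic(values[sample.int(n, n, replace = TRUE)]),
                      error = function(e) NA_real_)
      if (is.null(res) || !is.finite(res)) NA_real_ else res
    }, numeric(1))
  })
  dropped <- sum(is.na(boots))
  boots <- boots[!is.na(boots)]
  if (length(boots) == 0) {
    stop_polysel("bootstrap_ci: every resample was degenerate")
  }
  alpha <- (1 - conf) / 2
  qs <- quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(point = point, lower = qs[1], upper = qs[2], n_boot = n_boot,
       n_dropped = dropped, seed = seed)
}

#' Opportunity-for-selection indices with bootstrap intervals
#'
#' Computes I (on reproductive success T), I_S (on mating success M) and
#' I_P (on paternity share P) across the focal males of each treatment,
#' each with a percentile bootstrap confidence interval.  Indices are
#' standardised across groups within treatments; the bootstrap resamples
#' focal males (or whole groups with `unit = "group"` — with one focal per
#' group the two coincide here, but the option is kept explicit).
#'
#' @param summaries Focal-male summary data frame from
#'   [compute_male_summaries()].
#' @param n_boot,seed,conf Passed to [bootstrap_ci()].
#' @param unit Resampling unit, `"male"` (default) or `"group"`.
#' @return A data frame with one row per (treatment, index): columns
#'   `treatment`, `index`, `point`, `lower`, `upper`, `n`, `n_boot`,
#'   `n_dropped`.
#' @export
selection_indices <- function(summaries, n_boot = 10000, seed = NULL,
                              conf = 0.95, unit = c("male", "group")) {
  unit <- match.arg(unit)
  comps <- list(I = "T", I_S = "M", I_P = "P")
  out <- list()
  for (tr in unique(summaries$treatment)) {
    sub <- summaries[summaries$treatment == tr, ]
    for (idx in names(comps)) {
      vals <- sub[[comps[[idx]]]]
      vals <- vals[!is.na(vals)]
      ci <- bootstrap_ci(opportunity_index, vals, n_boot = n_boot,
                         seed = seed, conf = conf)
      out[[length(out) + 1L]] <- data.frame(
        treatment = tr, index = idx, point = ci$point, lower = ci$lower,
        upper = ci$upper, n = length(vals), n_boot = n_boot,
        n_dropped = ci$n_dropped, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two bootstrap intervals for overlap
#'
#' The convention for the population-level indices is conservative: a
#' difference is called significant only when the two confidence intervals
#' do not overlap at all.
#'
#' @param a,b Lists or one-row data frames with `lower` and `upper`.
#' @return A list with `significant` (logical) and `overlap` (numeric
#'   overlap width, negative when disjoint).
#' @export
compare_indices <- function(a, b) {
  overlap <- min(a$upper, b$upper) - max(a$lower, b$lower)
  list(significant = overlap < 0, overlap = overlap)
}
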