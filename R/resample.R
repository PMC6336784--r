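## Focal-male resampling estimator for twice-mated-female (trio) data.
## Each female mated exactly two males whose paternity shares are known.
## To mimic a focal-male design, each iteration picks one of the two males
## per trio (so every trio contributes exactly one male per iteration),
## pools the chosen shares within a treatment across remating intervals,
## and computes the standardised variance in paternity share
## I_P = var(share) / mean(share)^2.  Repeating this yields a distribution
## of I_P per treatment.

#' Read a mating-trio table
#'
#' @param path CSV/TSV with columns `female_id`, `treatment`,
#'   `first_share`, `second_share` and optionally `interval` (remating
#'   interval label).
#' @return Validated trio data frame (shares in `[0, 1]`, one row per
#'   female).
#' @export
read_trios <- function(path) {
  tr <- read_table_checked(path, c("female_id", "treatment", "first_share",
                                   "second_share"))
  full <- read.csv(path, sep = delim_for(path), stringsAsFactors = FALSE)
  if ("interval" %in% names(full)) tr$interval <- full$interval
  validate_trios(tr)
}

validate_trios <- function(trios) {
  shares <- c(trios$first_share, trios$second_share)
  if (any(shares < 0 | shares > 1, na.rm = TRUE)) {
    stop_polysel("trio shares must lie in [0, 1]")
  }
  key <- paste(trios$treatment, trios$female_id)
  if (anyDuplicated(key)) {
    stop_polysel("duplicate female within treatment in trio table: ",
                 key[which(duplicated(key))[1]])
  }
  trios
}

#' Resampled standardised variance in paternity share
#'
#' Runs the focal-male resampling estimator on a trio table: per
#' iteration, one male (first or second) is drawn uniformly for every
#' trio, and I_P is computed from the chosen shares pooled within each
#' treatment.  Iterations in which every chosen share is zero (I_P
#' undefined) are dropped and counted.
#'
#' @param trios Trio data frame (see [read_trios()]).
#' @param n_iter Number of resampling iterations (default 1000).
#' @param seed Integer seed.
#' @param conf Level for the percentile interval of the I_P distribution.
#' @return A list of class `"ip_resampling"` with per-treatment elements:
#'   `values` (the retained I_P draws), `mean`, `lower`, `upper`,
#'   `n_dropped`; plus `n_iter` and `seed`.
#' @export
resample_focal_ip <- function(trios, n_iter = 1000, seed = NULL,
                              conf = 0.95) {
  trios <- validate_trios(trios)
  if (n_iter < 1) stop_polysel("resample_focal_ip: n_iter must be >= 1")
  trts <- unique(trios$treatment)
  for (tr in trts) {
    if (sum(trios$treatment == tr) < 2) {
      stop_polysel("resample_focal_ip: need >= 2 trios in ", tr)
    }
  }
  shares <- as.matrix(trios[, c("first_share", "second_share")])
  picks <- with_seed(seed, {
    matrix(sample.int(2L, n_iter * nrow(trios), replace = TRUE),
           nrow = n_iter)
  })
  alpha <- (1 - conf) / 2
  res <- lapply(trts, function(tr) {
    idx <- which(trios$treatment == tr)
    vals <- vapply(seq_len(n_iter), function(it) {
      x <- shares[cbind(idx, picks[it, idx])]
      m <- mean(x)
      if (m == 0) NA_real_ else var(x) / m^2
    }, numeric(1))
    dropped <- sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    list(values = vals, mean = mean(vals),
         lower = quantile(vals, alpha, names = FALSE),
         upper = quantile(vals, 1 - alpha, names = FALSE),
         n_dropped = dropped)
  })
  names(res) <- trts
  structure(c(res, list(n_iter = n_iter, seed = seed)),
            class = "ip_resampling")
}

#' @export
print.ip_resampling <- function(x, ...) {
  cat("Focal-male resampling of I_P\n")
  trts <- setdiff(names(x), c("n_iter", "seed"))
  for (tr in trts) {
    cat(sprintf("  %s: mean %.3f (%.3f, %.3f), %d iterations dropped\n",
                tr, x[[tr]]$mean, x[[tr]]$lower, x[[tr]]$upper,
                x[[tr]]$n_dropped))
  }
  invisible(x)
}
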