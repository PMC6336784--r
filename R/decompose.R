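## Delta-method decomposition of the variance in relative male
## reproductive success.  With T = M * N * P holding exactly for the
## summarised males, divide each component by its treatment mean and
## apportion var(T_rel) into the component variances var(M), var(P),
## var(N), the three pairwise covariances (each entering once), and a
## residual D that closes the ledger exactly:
##   var(T) = var(M) + var(P) + var(N) + cov(M,P) + cov(M,N) + cov(N,P) + D.
## D absorbs the higher-order terms of the expansion (and any covariance
## double-counting convention), so the identity holds on every input by
## construction.

#' Residual of the variance-decomposition ledger
#'
#' @param var_T Variance of relative reproductive success.
#' @param var_M,var_P,var_N Variances of the relative components.
#' @param cov_MP,cov_MN,cov_NP Pairwise covariances (single-counted).
#' @return `D = var_T - (var_M + var_P + var_N + cov_MP + cov_MN + cov_NP)`.
#' @export
decomposition_residual <- function(var_T, var_M, var_P, var_N,
                                   cov_MP, cov_MN, cov_NP) {
  var_T - (var_M + var_P + var_N + cov_MP + cov_MN + cov_NP)
}

#' Delta-method variance decomposition of male reproductive success
#'
#' Divides T, M, P and N by their means across the focal males of one
#' treatment and decomposes the variance in relative reproductive success
#' into component variances, pairwise covariances and the residual `D`
#' (see [decomposition_residual()]).  Males with undefined `P` or `N`
#' (never mated) are excluded and counted.
#'
#' @param summaries Focal-male summary rows for a single treatment (a
#'   `treatment` column with more than one value is an error; use
#'   [decompose_by_treatment()] for several).
#' @param percent_denominator Denominator for the percentage column:
#'   `"var_T"` (default) or `"component_sum"`.  The percentages are
#'   descriptive; the ledger itself is the result.
#' @return A list of class `"variance_decomposition"` with the seven
#'   ledger terms, `D`, a `table` data frame (term, value, percent) and
#'   `n_used` / `n_excluded`.
#' @export
decompose_variance <- function(summaries,
                               percent_denominator = c("var_T",
                                                       "component_sum")) {
  percent_denominator <- match.arg(percent_denominator)
  if ("treatment" %in% names(summaries) &&
      length(unique(summaries$treatment)) > 1) {
    stop_polysel("decompose_variance: pass one treatment at a time")
  }
  ok <- summaries$M > 0 & !is.na(summaries$P) & !is.na(summaries$N)
  n_excluded <- sum(!ok)
  sub <- summaries[ok, ]
  if (nrow(sub) < 3) {
    stop_polysel("decompose_variance: need >= 3 males that mated")
  }
  rel <- function(x) x / mean(x)
  Tr <- rel(sub$T); Mr <- rel(sub$M); Pr <- rel(sub$P); Nr <- rel(sub$N)
  var_T <- var(Tr); var_M <- var(Mr); var_P <- var(Pr); var_N <- var(Nr)
  cov_MP <- cov(Mr, Pr); cov_MN <- cov(Mr, Nr); cov_NP <- cov(Nr, Pr)
  D <- decomposition_residual(var_T, var_M, var_P, var_N,
                              cov_MP, cov_MN, cov_NP)
  denom <- if (percent_denominator == "var_T") var_T else
    var_M + var_P + var_N + cov_MP + cov_MN + cov_NP
  terms <- c(var_T = var_T, var_M = var_M, var_P = var_P, var_N = var_N,
             cov_MP = cov_MP, cov_MN = cov_MN, cov_NP = cov_NP, D = D)
  tab <- data.frame(term = names(terms), value = unname(terms),
                    percent = unname(terms) / denom * 100,
                    stringsAsFactors = FALSE)
  structure(list(var_T = var_T, var_M = var_M, var_P = var_P,
                 var_N = var_N, cov_MP = cov_MP, cov_MN = cov_MN,
                 cov_NP = cov_NP, D = D, table = tab,
                 percent_denominator = percent_denominator,
                 n_used = nrow(sub), n_excluded = n_excluded),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition of relative male reproductive success\n")
  cat(sprintf("  males used: %d (excluded: %d)\n", x$n_used, x$n_excluded))
  tab <- x$table
  tab$value <- sprintf("%8.3f", tab$value)
  tab$percent <- sprintf("%6.1f", tab$percent)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Decomposition per treatment
#'
#' @param summaries Focal-male summaries for one or more treatments.
#' @param ... Passed to [decompose_variance()].
#' @return Named list of `variance_decomposition` objects.
#' @export
decompose_by_treatment <- function(summaries, ...) {
  trs <- unique(summaries$treatment)
  setNames(lapply(trs, function(tr) {
    decompose_variance(summaries[summaries$treatment == tr, ], ...)
  }), trs)
}
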