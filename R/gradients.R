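## Bateman-gradient machinery.  The Bateman gradient is the least-squares
## slope of relative reproductive success (T standardised to mean 1) on
## mating success M; it is reported mean-standardised (slope * mean(M),
## i.e. the slope on M / mean(M)) or variance-standardised (slope * sd(M),
## the s'max / Jones' index scale).  The two are linked by
## beta_var = beta_mean * CV(M), and CV(M) = sqrt(I_S), so the univariate
## Jones' index beta_mean * sqrt(I_S) equals the variance-standardised
## slope.  Multivariate gradients regress relative T jointly on
## mean-standardised M, P and N; s'max variants use z-scored predictors.
## Reported slopes come from the standardised least-squares fits; p-values
## for the T-gradients are additionally computed from a refit with
## square-root (Box-Cox) transformed T, which stabilises the variance of
## the count response.

## Assemble a model data frame, dropping covariates that are constant (a
## single replicate level, say) so lm() keeps full rank.
build_model_frame <- function(y, predictors, covariates = NULL) {
  dat <- data.frame(.y = y, predictors, check.names = FALSE)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) > 1,
                   logical(1))
    covariates <- covariates[keep]
    if (ncol(covariates) > 0) {
      for (nm in names(covariates)) {
        if (is.character(covariates[[nm]])) {
          covariates[[nm]] <- factor(covariates[[nm]])
        }
      }
      dat <- cbind(dat, covariates)
    }
  }
  dat
}

check_full_rank <- function(fit, terms) {
  est <- coef(fit)
  bad <- names(est)[is.na(est)]
  bad <- bad[vapply(bad, function(b) any(startsWith(b, terms)), logical(1))]
  if (length(bad) > 0) {
    stop_polysel("rank-deficient fit: collinear predictor(s) ",
                 paste(bad, collapse = ", "))
  }
  invisible(fit)
}

term_stats <- function(fit, term) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    stop_polysel("term ", term, " missing from fit")
  }
  list(estimate = sm[term, 1], se = sm[term, 2], t = sm[term, 3],
       p = sm[term, 4])
}

#' Univariate Bateman gradient
#'
#' Least-squares slope of relative reproductive success (`T / mean(T)`) on
#' mating success `M`, with optional covariates, reported on the mean- and
#' variance-standardised scales.
#'
#' @param T Numeric vector of reproductive success (e.g. daughters sired).
#' @param M Numeric vector of mating success (unique mates).
#' @param covariates Optional data frame of covariates (character columns
#'   are treated as factors; constant columns are dropped).
#' @return A list with the raw slope (`beta_raw`), the mean-standardised
#'   gradient `beta_mean` (= `beta_raw * mean(M)`), the
#'   variance-standardised gradient `beta_var` (= `beta_raw * sd(M)`,
#'   the univariate s'max / Jones' index), standard errors and t/p for
#'   each scale from the standardised fit, `p_boxcox` from a square-root
#'   transformed refit, and `n`.
#' @export
bateman_univariate <- function(T, M, covariates = NULL) {
  keep <- !(is.na(T) | is.na(M))
  T <- T[keep]; M <- M[keep]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  if (length(T) < 3) stop_polysel("bateman_univariate: need >= 3 males")
  if (sd(M) == 0) {
    stop_polysel("bateman_univariate: zero variance in mating success")
  }
  T_rel <- T / mean(T)
  dat <- build_model_frame(T_rel, data.frame(M = M), covariates)
  fit <- lm(.y ~ ., data = dat)
  check_full_rank(fit, "M")
  st <- term_stats(fit, "M")
  dat_bc <- dat
  dat_bc$.y <- sqrt(T)
  st_bc <- term_stats(lm(.y ~ ., data = dat_bc), "M")
  list(beta_raw = st$estimate, se_raw = st$se,
       beta_mean = st$estimate * mean(M), se_mean = st$se * mean(M),
       beta_var = st$estimate * sd(M), se_var = st$se * sd(M),
       t = st$t, p = st$p,
       t_boxcox = st_bc$t, p_boxcox = st_bc$p,
       mean_M = mean(M), sd_M = sd(M), n = length(T))
}

#' Multivariate Bateman gradients
#'
#' Partial regression gradients of relative reproductive success on the
#' three components of male fitness: mating success `M`, paternity share
#' `P` and mate productivity `N`, each mean-standardised (divided by its
#' mean), controlling for the others and for covariates.  The s'max
#' (maximum standardised selection differential) variants come from the
#' same model with variance-standardised (z-scored) predictors; for each
#' component the two scales are linked by the coefficient of variation:
#' `beta_var = beta_mean * CV`.
#'
#' @param T,M,P,N Numeric vectors over focal males.
#' @param covariates Optional covariate data frame (conventionally vial
#'   fecundity and replicate).
#' @return A data frame with one row per component (`M`, `P`, `N`):
#'   mean-standardised `estimate`, `se`, `t`, `p`; variance-standardised
#'   `estimate_smax`, `se_smax`; and `p_boxcox` from the square-root
#'   transformed refit.
#' @export
bateman_multivariate <- function(T, M, P, N, covariates = NULL) {
  keep <- !(is.na(T) | is.na(M) | is.na(P) | is.na(N))
  T <- T[keep]; M <- M[keep]; P <- P[keep]; N <- N[keep]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  }
  if (length(T) < 5) stop_polysel("bateman_multivariate: need >= 5 males")
  comps <- list(M = M, P = P, N = N)
  sds <- vapply(comps, sd, numeric(1))
  ## constant components carry no selection and are absorbed by the
  ## intercept; drop them and report NA rows rather than failing
  varying <- names(comps)[sds > 0]
  if (length(varying) == 0) {
    stop_polysel("bateman_multivariate: all components constant")
  }
  T_rel <- T / mean(T)
  mean_std <- as.data.frame(lapply(comps[varying],
                                   function(x) x / mean(x)))
  var_std <- as.data.frame(lapply(comps[varying],
                                  function(x) (x - mean(x)) / sd(x)))
  dat_mu <- build_model_frame(T_rel, mean_std, covariates)
  fit_mu <- lm(.y ~ ., data = dat_mu)
  check_full_rank(fit_mu, varying)
  dat_sg <- build_model_frame(T_rel, var_std, covariates)
  fit_sg <- lm(.y ~ ., data = dat_sg)
  dat_bc <- dat_mu
  dat_bc$.y <- sqrt(T)
  fit_bc <- lm(.y ~ ., data = dat_bc)
  rows <- lapply(c("M", "P", "N"), function(term) {
    if (!term %in% varying) {
      return(data.frame(component = term, estimate = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_,
                        estimate_smax = NA_real_, se_smax = NA_real_,
                        p_boxcox = NA_real_, stringsAsFactors = FALSE))
    }
    mu <- term_stats(fit_mu, term)
    sg <- term_stats(fit_sg, term)
    bc <- term_stats(fit_bc, term)
    data.frame(component = term, estimate = mu$estimate, se = mu$se,
               t = mu$t, p = mu$p, estimate_smax = sg$estimate,
               se_smax = sg$se, p_boxcox = bc$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- length(T)
  out
}

#' Full gradient set per treatment
#'
#' Convenience wrapper computing, for each treatment in a focal-male
#' summary table, the univariate Bateman gradient of T on M (mean- and
#' variance-standardised), the univariate post-copulatory gradient of T on
#' P, the Jones' indices (gradient times the square root of the matching
#' opportunity index), and the multivariate mean-standardised and s'max
#' gradients.
#'
#' @param summaries Data frame from [compute_male_summaries()].
#' @param covariates Character vector of summary columns used as
#'   covariates (default vial fecundity and replicate).
#' @return A tidy data frame of coefficients: `treatment`, `gradient`,
#'   `component`, `standardisation`, `estimate`, `se`, `t`, `p`,
#'   `p_boxcox`, `n`.
#' @export
gradient_set <- function(summaries,
                         covariates = c("vial_fecundity", "replicate_id")) {
  out <- list()
  add <- function(treatment, gradient, component, standardisation,
                  estimate, se, t, p, p_boxcox, n) {
    out[[length(out) + 1L]] <<- data.frame(
      treatment = treatment, gradient = gradient, component = component,
      standardisation = standardisation, estimate = estimate, se = se,
      t = t, p = p, p_boxcox = p_boxcox, n = n, stringsAsFactors = FALSE)
  }
  for (tr in unique(summaries$treatment)) {
    sub <- summaries[summaries$treatment == tr & summaries$M > 0, ]
    covs <- sub[, intersect(covariates, names(sub)), drop = FALSE]
    uni_M <- bateman_univariate(sub$T, sub$M, covs)
    add(tr, "univariate", "M", "mean", uni_M$beta_mean, uni_M$se_mean,
        uni_M$t, uni_M$p, uni_M$p_boxcox, uni_M$n)
    add(tr, "univariate", "M", "variance", uni_M$beta_var, uni_M$se_var,
        uni_M$t, uni_M$p, uni_M$p_boxcox, uni_M$n)
    uni_P <- bateman_univariate(sub$T, sub$P, covs)
    add(tr, "univariate", "P", "mean", uni_P$beta_mean, uni_P$se_mean,
        uni_P$t, uni_P$p, uni_P$p_boxcox, uni_P$n)
    add(tr, "univariate", "P", "variance", uni_P$beta_var, uni_P$se_var,
        uni_P$t, uni_P$p, uni_P$p_boxcox, uni_P$n)
    ## Jones' indices via the opportunity-index route (equal to the
    ## variance-standardised slopes by the CV identity)
    jones_pre <- uni_M$beta_mean * sqrt(opportunity_index(sub$M))
    jones_post <- uni_P$beta_mean * sqrt(opportunity_index(sub$P))
    add(tr, "jones", "M", "variance", jones_pre, uni_M$se_var,
        uni_M$t, uni_M$p, uni_M$p_boxcox, uni_M$n)
    add(tr, "jones", "P", "variance", jones_post, uni_P$se_var,
        uni_P$t, uni_P$p, uni_P$p_boxcox, uni_P$n)
    multi <- bateman_multivariate(sub$T, sub$M, sub$P, sub$N, covs)
    for (i in seq_len(nrow(multi))) {
      add(tr, "multivariate", multi$component[i], "mean",
          multi$estimate[i], multi$se[i], multi$t[i], multi$p[i],
          multi$p_boxcox[i], attr(multi, "n"))
      add(tr, "multivariate", multi$component[i], "variance",
          multi$estimate_smax[i], multi$se_smax[i], multi$t[i], multi$p[i],
          multi$p_boxcox[i], attr(multi, "n"))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repetitive-mating gradient on paternity share
#'
#' Linear model of mean-standardised paternity share (`P / mean(P)`,
#' within treatment) on the average number of repetitive matings per mate,
#' with replicate as the only covariate.  Significance of the repetitive
#' term is additionally assessed with a quasi-binomial GLM on the raw
#' daughter counts (sired vs not sired), which respects the proportion
#' scale and its overdispersion.
#'
#' @param summaries Data frame from [compute_male_summaries()].
#' @param covariates Character vector of covariate columns (default
#'   replicate only; vial fecundity is deliberately excluded from this
#'   gradient).
#' @return A data frame with one row per treatment: `estimate`, `se`, `t`,
#'   `p` from the linear fit and `p_quasibinomial` from the GLM.
#' @export
repetitive_gradient <- function(summaries, covariates = "replicate_id") {
  rows <- lapply(unique(summaries$treatment), function(tr) {
    sub <- summaries[summaries$treatment == tr & summaries$M > 0 &
                       !is.na(summaries$P), ]
    if (nrow(sub) < 3) {
      stop_polysel("repetitive_gradient: need >= 3 males in ", tr)
    }
    covs <- sub[, intersect(covariates, names(sub)), drop = FALSE]
    P_std <- sub$P / mean(sub$P)
    dat <- build_model_frame(P_std, data.frame(rate = sub$repetitive_rate),
                             covs)
    if (sd(sub$repetitive_rate) == 0) {
      return(data.frame(treatment = tr, estimate = 0, se = NA_real_,
                        t = NA_real_, p = NA_real_,
                        p_quasibinomial = NA_real_, n = nrow(sub),
                        stringsAsFactors = FALSE))
    }
    fit <- lm(.y ~ ., data = dat)
    check_full_rank(fit, "rate")
    st <- term_stats(fit, "rate")
    sired <- round(sub$T)
    unsired <- pmax(round(sub$M * sub$N) - sired, 0)
    p_qb <- tryCatch({
      datq <- dat
      datq$.y <- NULL
      gfit <- glm(cbind(sired, unsired) ~ ., family = quasibinomial(),
                  data = datq)
      summary(gfit)$coefficients["rate", 4]
    }, error = function(e) NA_real_)
    data.frame(treatment = tr, estimate = st$estimate, se = st$se,
               t = st$t, p = st$p, p_quasibinomial = p_qb, n = nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-treatment gradient difference
#'
#' Tests whether a gradient differs between two treatments by fitting a
#' pooled model with a treatment-by-predictor interaction (responses and
#' predictors standardised within treatment first, so the interaction
#' coefficient is the difference of within-treatment slopes) and reading
#' the t-test on the interaction term.
#'
#' @param summaries Data frame from [compute_male_summaries()] with
#'   exactly two treatments.
#' @param gradient `"bateman"` (relative T on M) or `"repetitive"`
#'   (standardised P on repetitive rate).
#' @param covariates Covariate columns for the pooled model.
#' @return A list with `difference`, `se`, `t`, `p`, `df`.
#' @export
compare_gradients <- function(summaries, gradient = c("bateman",
                                                      "repetitive"),
                              covariates = "replicate_id") {
  gradient <- match.arg(gradient)
  trs <- unique(summaries$treatment)
  if (length(trs) != 2) {
    stop_polysel("compare_gradients: need exactly 2 treatments")
  }
  sub <- summaries[summaries$M > 0 & !is.na(summaries$P), ]
  parts <- lapply(trs, function(tr) {
    s <- sub[sub$treatment == tr, ]
    if (gradient == "bateman") {
      data.frame(y = s$T / mean(s$T), x = s$M / mean(s$M),
                 treatment = tr, replicate_id = s$replicate_id,
                 vial_fecundity = s$vial_fecundity,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(y = s$P / mean(s$P), x = s$repetitive_rate,
                 treatment = tr, replicate_id = s$replicate_id,
                 vial_fecundity = s$vial_fecundity,
                 stringsAsFactors = FALSE)
    }
  })
  dat <- do.call(rbind, parts)
  dat$treatment <- factor(dat$treatment, levels = trs)
  covs <- dat[, intersect(covariates, names(dat)), drop = FALSE]
  mf <- build_model_frame(dat$y, data.frame(x = dat$x,
                                            treatment = dat$treatment),
                          covs)
  fit <- lm(.y ~ . + x:treatment, data = mf)
  sm <- summary(fit)$coefficients
  iname <- grep("^x:treatment", rownames(sm), value = TRUE)
  if (length(iname) != 1) {
    stop_polysel("compare_gradients: interaction term not identifiable")
  }
  list(difference = sm[iname, 1], se = sm[iname, 2], t = sm[iname, 3],
       p = sm[iname, 4], df = fit$df.residual)
}

#' Adjusted paternity share
#'
#' Rescales an observed paternity share to the realised level of sperm
#' competition: `adjusted = pcs * (n - 1) / (pcs * (n - 2) + 1)`, where
#' `n` is the number of males that mated with the female in question.
#' At `n = 2` the observed share is returned unchanged, and a share of 1
#' is a fixed point for every `n`.
#'
#' @param pcs_obs Observed paternity share(s) in `[0, 1]`.
#' @param n Number of males (>= 2) that mated with the same female(s).
#' @return Adjusted share(s) in `[0, 1]`.
#' @export
adjusted_pcs <- function(pcs_obs, n) {
  if (any(pcs_obs < 0 | pcs_obs > 1, na.rm = TRUE)) {
    stop_polysel("adjusted_pcs: shares must lie in [0, 1]")
  }
  if (any(n < 2, na.rm = TRUE)) {
    stop_polysel("adjusted_pcs: n must be >= 2 (monogamous females are ",
                 "excluded before adjustment)")
  }
  pcs_obs * (n - 1) / (pcs_obs * (n - 2) + 1)
}

#' Per-male mean adjusted paternity share
#'
#' Applies [adjusted_pcs()] female by female and averages within focal
#' males.  Females that were strictly monogamous (one mate in total) or
#' never mated with the focal male are excluded and counted.
#'
#' @param events,paternity,roster The standard experiment tables.
#' @return A data frame with one row per focal male: `male_id`,
#'   `group_id`, `treatment`, `adjusted_share` (mean over his eligible
#'   mates), `n_females_used`, `n_females_excluded`.
#' @export
adjusted_pcs_by_male <- function(events, paternity, roster) {
  roster <- validate_roster(roster)
  events <- validate_events(events, roster)
  poly <- female_polyandry(events)
  rows <- lapply(unique(roster$group_id), function(g) {
    ros <- roster[roster$group_id == g, ]
    focal <- ros$id[ros$role == "focal"]
    ev <- events[events$group_id == g, ]
    mates <- unique(ev$female_id[ev$male_id == focal])
    pa <- paternity[paternity$group_id == g, ]
    pg <- poly[poly$group_id == g, ]
    used <- 0L; excl <- 0L; vals <- numeric(0)
    for (f in mates) {
      n_males <- pg$n_mates[pg$female_id == f]
      rec <- pa[pa$female_id == f, ]
      tot <- rec$daughters_focal + rec$daughters_other
      if (length(n_males) == 0 || n_males < 2 || nrow(rec) == 0 ||
          tot == 0) {
        excl <- excl + 1L
        next
      }
      vals <- c(vals, adjusted_pcs(rec$daughters_focal / tot, n_males))
      used <- used + 1L
    }
    data.frame(male_id = focal, group_id = g, treatment = ros$treatment[1],
               adjusted_share = if (used > 0) mean(vals) else NA_real_,
               n_females_used = used, n_females_excluded = excl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
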