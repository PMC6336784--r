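## Mating-network statistics.  Each vial's mating matrix is the binary
## male-by-female incidence of unique mating pairs.  A male's sperm
## competition intensity (SCI) is the harmonic mean of his mates'
## polyandry counts: SCI_i = M_i / sum_j (1 / k_j) over his M_i mates with
## k_j partners each.  The SCI correlation (SCIC) is the least-squares
## slope of mean-standardised SCI on mean-standardised M across all males
## (focal and rivals).  Its null distribution under random pairing is
## obtained by resampling, within each vial, a uniform binary matrix with
## the observed row and column sums — preserving every male's and female's
## mating success while shuffling who mates with whom.

#' Build per-group mating matrices
#'
#' @param events Mating-event data frame.
#' @param roster Roster data frame; defines the full male and female
#'   complement of each group (so never-mated individuals appear as
#'   all-zero rows/columns).
#' @return Named list (by group) of binary male-by-female matrices; each
#'   carries the copulation-count matrix as attribute `"counts"`.
#' @export
mating_matrices <- function(events, roster) {
  roster <- validate_roster(roster)
  events <- validate_events(events, roster)
  out <- list()
  for (g in unique(roster$group_id)) {
    ros <- roster[roster$group_id == g, ]
    males <- ros$id[ros$sex == "male"]
    females <- ros$id[ros$sex == "female"]
    cnt <- matrix(0L, length(males), length(females),
                  dimnames = list(males, females))
    ev <- events[events$group_id == g, ]
    if (nrow(ev) > 0) {
      for (i in seq_len(nrow(ev))) {
        cnt[ev$male_id[i], ev$female_id[i]] <-
          cnt[ev$male_id[i], ev$female_id[i]] + 1L
      }
    }
    bin <- (cnt > 0) * 1L
    attr(bin, "counts") <- cnt
    out[[g]] <- bin
  }
  out
}

#' Sperm competition intensity of one male
#'
#' Harmonic mean of the polyandry counts of a male's mates:
#' `SCI = M_i / sum_j (1 / k_j)`.
#'
#' @param male Male identifier (row name) or row index.
#' @param matrix Binary mating matrix for his group.
#' @return SCI scalar; `NA` for a male with no mates.
#' @export
sperm_competition_intensity <- function(male, matrix) {
  row <- matrix[male, ]
  mates <- which(row > 0)
  if (length(mates) == 0) return(NA_real_)
  k <- colSums(matrix > 0)[mates]
  length(mates) / sum(1 / k)
}

## Vectorised SCI for all males of one binary matrix.
sci_all_males <- function(matrix) {
  k <- colSums(matrix)
  invk <- ifelse(k > 0, 1 / k, 0)
  M <- rowSums(matrix)
  denom <- as.vector(matrix %*% invk)
  ifelse(M > 0, M / denom, NA_real_)
}

#' Per-male SCI table
#'
#' @param matrices List of binary mating matrices from
#'   [mating_matrices()].
#' @return Data frame with `group_id`, `male_id`, `M` and `SCI` for every
#'   male (rivals included); males with `M = 0` carry `NA` SCI.
#' @export
male_sci_table <- function(matrices) {
  gids <- names(matrices) %||% paste0("group", seq_along(matrices))
  rows <- lapply(seq_along(matrices), function(i) {
    mat <- matrices[[i]]
    ids <- rownames(mat) %||% paste0(gids[i], "_m", seq_len(nrow(mat)))
    data.frame(group_id = gids[i], male_id = ids,
               M = rowSums(mat), SCI = sci_all_males(mat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sperm competition intensity correlation (SCIC)
#'
#' Least-squares slope of SCI on mating success across all males of a
#' treatment, both divided by their means.  Males that never mated are
#' excluded (their SCI is undefined).  A constant SCI across males gives a
#' slope of exactly 0; the degenerate flag is raised when the predictor
#' (M) has no variation, as in a fully saturated mating matrix where every
#' male mates every female, and then the slope is undefined.
#'
#' @param x List of binary mating matrices for one treatment, or a data
#'   frame with columns `M` and `SCI` (one row per male).
#' @return A list with `slope` (`NA` when degenerate), `degenerate`
#'   (logical) and `n_males`.
#' @export
scic <- function(x) {
  tab <- if (is.data.frame(x)) x else male_sci_table(x)
  tab <- tab[tab$M > 0 & !is.na(tab$SCI), ]
  if (nrow(tab) < 2) return(list(slope = NA_real_, degenerate = TRUE,
                                 n_males = nrow(tab)))
  M_std <- tab$M / mean(tab$M)
  S_std <- tab$SCI / mean(tab$SCI)
  if (var(M_std) == 0) {
    return(list(slope = NA_real_, degenerate = TRUE, n_males = nrow(tab)))
  }
  list(slope = cov(M_std, S_std) / var(M_std), degenerate = FALSE,
       n_males = nrow(tab))
}

#' Enumerate binary matrices with fixed margins
#'
#' Depth-first enumeration of every binary matrix with the given row and
#' column sums, stopping early if the family exceeds `cap`.
#'
#' @param row_sums,col_sums Integer margin vectors (equal totals).
#' @param cap Abort threshold; if the family is larger than `cap` the
#'   function returns `NULL`.
#' @return List of matrices, or `NULL` when the family exceeds `cap`.
#' @export
enumerate_fixed_margin <- function(row_sums, col_sums, cap = 10000) {
  nr <- length(row_sums); nc <- length(col_sums)
  if (sum(row_sums) != sum(col_sums)) {
    stop_polysel("enumerate_fixed_margin: margin totals differ")
  }
  if (any(row_sums < 0 | row_sums > nc) || any(col_sums < 0 |
                                               col_sums > nr)) {
    stop_polysel("enumerate_fixed_margin: infeasible margins")
  }
  env <- new.env()
  env$out <- vector("list", 64)
  env$n <- 0L
  env$overflow <- FALSE
  cur <- matrix(0L, nr, nc)
  rec <- function(i, rem) {
    if (env$overflow) return()
    if (i > nr) {
      if (all(rem == 0)) {
        env$n <- env$n + 1L
        if (env$n > cap) { env$overflow <- TRUE; return() }
        if (env$n > length(env$out)) {
          env$out <- c(env$out, vector("list", length(env$out)))
        }
        env$out[[env$n]] <- cur + 0L
      }
      return()
    }
    r <- row_sums[i]
    rows_left <- nr - i
    if (r == 0) {
      if (all(rem <= rows_left)) rec(i + 1L, rem)
      return()
    }
    avail <- which(rem > 0)
    if (length(avail) < r) return()
    sets <- if (r == length(avail)) list(avail) else
      combn(avail, r, simplify = FALSE)
    for (s in sets) {
      rem2 <- rem
      rem2[s] <- rem2[s] - 1L
      if (any(rem2 > rows_left)) next
      cur[i, ] <<- 0L
      cur[i, s] <<- 1L
      rec(i + 1L, rem2)
      if (env$overflow) return()
    }
    cur[i, ] <<- 0L
  }
  rec(1L, as.integer(col_sums))
  if (env$overflow) return(NULL)
  env$out[seq_len(env$n)]
}

#' Sample binary matrices with the margins of an observed matrix
#'
#' Draws `n` matrices uniformly from the family of binary matrices sharing
#' the observed row and column sums.  When the family has at most `cap`
#' members it is enumerated and sampled exactly; otherwise a
#' checkerboard-swap Markov chain is run (burn-in and thinning default to
#' 100 times the number of 1-entries).
#'
#' @param matrix Observed binary matrix.
#' @param n Number of draws.
#' @param method `"auto"`, `"enumerate"` or `"swap"`.
#' @param cap Enumeration threshold for `"auto"`.
#' @param thin,burn Swap-chain thinning and burn-in (steps); defaults
#'   `100 * sum(matrix)` and the same, respectively.
#' @param seed Optional integer seed.
#' @return List of `n` matrices with the observed margins.
#' @export
sample_fixed_margin <- function(matrix, n, method = c("auto", "enumerate",
                                                      "swap"),
                                cap = 10000, thin = NULL, burn = NULL,
                                seed = NULL) {
  method <- match.arg(method)
  storage.mode(matrix) <- "integer"
  with_seed(seed, {
    fam <- NULL
    if (method %in% c("auto", "enumerate")) {
      fam <- enumerate_fixed_margin(rowSums(matrix), colSums(matrix),
                                    cap = cap)
      if (is.null(fam) && method == "enumerate") {
        stop_polysel("sample_fixed_margin: family exceeds cap; use swap")
      }
    }
    if (!is.null(fam)) {
      fam <- lapply(fam, function(m) {
        dimnames(m) <- dimnames(matrix)
        m
      })
      fam[sample.int(length(fam), n, replace = TRUE)]
    } else {
      ones <- sum(matrix)
      thin <- thin %||% max(1L, 100L * ones)
      burn <- burn %||% thin
      flat <- swap_chain(matrix, as.integer(n), as.integer(burn),
                         as.integer(thin))
      lapply(seq_len(n), function(i) {
        m <- base::matrix(flat[i, ], nrow(matrix), ncol(matrix))
        dimnames(m) <- dimnames(matrix)
        m
      })
    }
  })
}

#' Randomization null for the SCIC
#'
#' Tests the observed SCIC of a treatment against the null hypothesis of
#' random pairing given each vial's margins: for every randomisation, each
#' vial's binary mating matrix is replaced by a uniform draw from the
#' matrices with the same per-male and per-female mating success (unique
#' partners), and the SCIC is recomputed over all vials.  Vials whose
#' margins admit a single matrix cannot be shuffled; they are passed
#' through unchanged and flagged.
#'
#' @param matrices List of binary mating matrices for one treatment.
#' @param n_rand Number of randomisations (default 1000).
#' @param seed Integer seed.
#' @param cap,thin,burn Passed to [sample_fixed_margin()].
#' @return A list of class `"scic_randomization"`: `observed`,
#'   `null_values` (length `n_rand`), `p_lower` (share of null <=
#'   observed), `p_upper`, `p_two_sided`, `n_randomisations`, `seed`, and
#'   `vial_unique` (logical per vial: margins admit only one matrix).
#' @export
randomize_scic <- function(matrices, n_rand = 1000, seed = NULL,
                           cap = 10000, thin = NULL, burn = NULL) {
  obs <- scic(matrices)
  draws <- with_seed(seed, {
    lapply(matrices, function(mat) {
      storage.mode(mat) <- "integer"
      fam <- enumerate_fixed_margin(rowSums(mat), colSums(mat), cap = cap)
      if (!is.null(fam) && length(fam) == 1) {
        list(unique = TRUE, draws = NULL, mat = mat)
      } else if (!is.null(fam)) {
        fam <- lapply(fam, function(m) {
          dimnames(m) <- dimnames(mat)
          m
        })
        idx <- sample.int(length(fam), n_rand, replace = TRUE)
        list(unique = FALSE, draws = fam[idx], mat = mat)
      } else {
        ones <- sum(mat)
        th <- thin %||% max(1L, 100L * ones)
        bu <- burn %||% th
        flat <- swap_chain(mat, as.integer(n_rand), as.integer(bu),
                           as.integer(th))
        ds <- lapply(seq_len(n_rand), function(i) {
          matrix(flat[i, ], nrow(mat), ncol(mat), dimnames = dimnames(mat))
        })
        list(unique = FALSE, draws = ds, mat = mat)
      }
    })
  })
  null_values <- vapply(seq_len(n_rand), function(t) {
    mats_t <- lapply(draws, function(d) {
      if (d$unique) d$mat else d$draws[[t]]
    })
    scic(mats_t)$slope
  }, numeric(1))
  ## margin preservation is a hard invariant of the null
  stopifnot(all(vapply(seq_along(draws), function(v) {
    d <- draws[[v]]
    if (d$unique) return(TRUE)
    all(vapply(d$draws[seq_len(min(5, n_rand))], function(m) {
      all(rowSums(m) == rowSums(d$mat)) && all(colSums(m) == colSums(d$mat))
    }, logical(1)))
  }, logical(1))))
  p_lower <- mean(null_values <= obs$slope)
  p_upper <- mean(null_values >= obs$slope)
  structure(list(observed = obs$slope, null_values = null_values,
                 p_lower = p_lower, p_upper = p_upper,
                 p_two_sided = min(1, 2 * min(p_lower, p_upper)),
                 n_randomisations = n_rand, seed = seed,
                 vial_unique = vapply(draws, `[[`, logical(1), "unique"),
                 degenerate = obs$degenerate),
            class = "scic_randomization")
}

#' @export
print.scic_randomization <- function(x, ...) {
  cat("SCIC randomization test\n")
  cat(sprintf("  observed SCIC: %.4f\n", x$observed))
  cat(sprintf("  randomisations: %d (vials fixed by margins: %d/%d)\n",
              x$n_randomisations, sum(x$vial_unique),
              length(x$vial_unique)))
  cat(sprintf("  p_lower = %.3f, p_upper = %.3f, p_two_sided = %.3f\n",
              x$p_lower, x$p_upper, x$p_two_sided))
  invisible(x)
}

#' Regressions of fitness components on SCI
#'
#' Per treatment: (i) an overdispersed count model (quasi-Poisson) of
#' focal-male reproductive success `T` on mean-standardised `M` and SCI
#' with vial fecundity and replicate as covariates, and (ii) a
#' quasi-binomial share model of paternity (daughters sired vs not) on
#' mean-standardised SCI with the same covariates.
#'
#' @param summaries Focal-male summaries ([compute_male_summaries()]).
#' @param events,roster The corresponding raw tables (used to compute each
#'   focal male's SCI from his group's mating matrix).
#' @return Data frame of coefficients: `treatment`, `model` (`"T"` or
#'   `"P"`), `term`, `estimate`, `se`, `t`, `p`.
#' @export
sci_regressions <- function(summaries, events, roster) {
  mats <- mating_matrices(events, roster)
  sci_tab <- male_sci_table(mats)
  focal_sci <- sci_tab[match(summaries$male_id, sci_tab$male_id), "SCI"]
  summaries$SCI <- focal_sci
  rows <- list()
  for (tr in unique(summaries$treatment)) {
    sub <- summaries[summaries$treatment == tr & summaries$M > 0 &
                       !is.na(summaries$SCI), ]
    if (nrow(sub) < 4) {
      stop_polysel("sci_regressions: too few males in ", tr)
    }
    if (sd(sub$SCI) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, model = "T", term = "SCI_std",
        estimate = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
        note = "SCI constant: inestimable", stringsAsFactors = FALSE)
      next
    }
    dat <- data.frame(T = round(sub$T),
                      M_std = sub$M / mean(sub$M),
                      SCI_std = sub$SCI / mean(sub$SCI),
                      vial_fecundity = sub$vial_fecundity,
                      replicate_id = factor(sub$replicate_id))
    if (length(unique(dat$replicate_id)) < 2) dat$replicate_id <- NULL
    fit_T <- glm(T ~ ., family = quasipoisson(), data = dat)
    sm <- summary(fit_T)$coefficients
    for (term in setdiff(rownames(sm), "(Intercept)")) {
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, model = "T", term = term, estimate = sm[term, 1],
        se = sm[term, 2], t = sm[term, 3], p = sm[term, 4], note = "",
        stringsAsFactors = FALSE)
    }
    sired <- round(sub$T)
    unsired <- pmax(round(sub$M * sub$N) - sired, 0)
    datP <- dat
    datP$T <- NULL
    datP$M_std <- NULL
    fit_P <- glm(cbind(sired, unsired) ~ ., family = quasibinomial(),
                 data = datP)
    smP <- summary(fit_P)$coefficients
    for (term in setdiff(rownames(smP), "(Intercept)")) {
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr, model = "P", term = term, estimate = smP[term, 1],
        se = smP[term, 2], t = smP[term, 3], p = smP[term, 4], note = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
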