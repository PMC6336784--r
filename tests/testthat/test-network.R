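mk_mat <- function(v, nr, males = NULL, females = NULL) {
  m <- matrix(as.integer(v), nrow = nr, byrow = TRUE)
  rownames(m) <- males %||% paste0("m", seq_len(nrow(m)))
  colnames(m) <- females %||% paste0("f", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("SCI is the harmonic mean of the mates' polyandry", {
  # both mates have k = 2
  m <- mk_mat(c(1, 1, 0,
                1, 1, 0,
                0, 0, 1), 3)
  expect_equal(sperm_competition_intensity("m1", m), 2)
  # mates with k = 1 and k = 3: 2 / (1 + 1/3) = 1.5
  m2 <- mk_mat(c(1, 1, 0,
                 0, 1, 0,
                 0, 1, 1), 3)
  expect_equal(sperm_competition_intensity("m1", m2), 1.5)
  # single mate with k = 4
  m3 <- mk_mat(rep(1, 4), 4, females = "f1")
  expect_equal(sperm_competition_intensity("m1", m3), 4)
  # unmated male undefined
  m4 <- mk_mat(c(0, 0, 1, 1), 2)
  expect_true(is.na(sperm_competition_intensity("m1", m4)))
})

test_that("SCIC handles constant SCI, saturation and constructed slopes", {
  # constant SCI across males with varying M: slope exactly 0
  tab <- data.frame(M = c(1, 2, 3, 4), SCI = 2)
  expect_equal(scic(tab)$slope, 0)
  expect_false(scic(tab)$degenerate)
  # fully saturated matrix: everyone mates everyone, M constant
  sat <- mk_mat(rep(1, 16), 4)
  res <- scic(list(g1 = sat))
  expect_true(res$degenerate)
  expect_true(is.na(res$slope))
  # constructed standardised relation SCI_std = 1 - 0.2 (M_std - 1)
  M <- c(1, 2, 3, 4, 2, 3)
  M_std <- M / mean(M)
  SCI <- (1 - 0.2 * (M_std - 1)) * 5   # any positive scale
  expect_equal(scic(data.frame(M = M, SCI = SCI))$slope, -0.2,
               tolerance = 1e-12)
  # matrix route agrees with the brute-force oracle
  set.seed(50)
  mats <- lapply(1:5, function(i) {
    mk_mat(rbinom(16, 1, 0.5), 4,
           males = paste0("g", i, "m", 1:4),
           females = paste0("g", i, "f", 1:4))
  })
  res2 <- scic(mats)
  if (!res2$degenerate) {
    expect_equal(res2$slope, scic_oracle(mats), tolerance = 1e-12)
  }
})

test_that("mating matrices have event-derived margins", {
  sim <- simulate_experiment(sim_config(n_groups = 4), seed = 51)
  mats <- mating_matrices(sim$events, sim$roster)
  poly <- female_polyandry(sim$events)
  for (g in names(mats)) {
    k <- colSums(mats[[g]])
    pg <- poly[poly$group_id == g, ]
    expect_equal(unname(k[pg$female_id]), pg$n_mates)
    cnt <- attr(mats[[g]], "counts")
    expect_equal(sum(cnt), sum(sim$events$group_id == g))
  }
})

test_that("fixed-margin enumeration is exhaustive on known families", {
  # 2x2 with margins (1,1)/(1,1): identity and anti-diagonal
  fam <- enumerate_fixed_margin(c(1, 1), c(1, 1))
  expect_length(fam, 2)
  # all-2 margins on 4x4: the classic count is 90
  fam2 <- enumerate_fixed_margin(rep(2, 4), rep(2, 4))
  expect_length(fam2, 90)
  # every member hits the margins
  expect_true(all(vapply(fam2, function(m) {
    all(rowSums(m) == 2) && all(colSums(m) == 2)
  }, logical(1))))
  expect_equal(anyDuplicated(vapply(fam2, paste, character(1),
                                    collapse = "")), 0L)
  # cap triggers NULL
  expect_null(enumerate_fixed_margin(rep(3, 6), rep(3, 6), cap = 10))
})

test_that("swap sampler preserves margins and is seed-deterministic", {
  m <- mk_mat(c(1, 1, 0, 0,
                1, 0, 1, 0,
                0, 1, 1, 1,
                1, 1, 0, 1), 4)
  d1 <- sample_fixed_margin(m, 20, method = "swap", seed = 52)
  d2 <- sample_fixed_margin(m, 20, method = "swap", seed = 52)
  expect_identical(d1, d2)
  for (s in d1) {
    expect_equal(rowSums(s), rowSums(m))
    expect_equal(colSums(s), colSums(m))
  }
})

test_that("swap chain visits the enumerated family uniformly", {
  m <- mk_mat(c(1, 1, 0,
                1, 0, 0,
                0, 0, 1), 3)   # margins (2,1,1)/(2,1,1)
  fam <- enumerate_fixed_margin(rowSums(m), colSums(m))
  keys <- vapply(fam, paste, character(1), collapse = "")
  draws <- sample_fixed_margin(m, 5000, method = "swap", seed = 53)
  got <- vapply(draws, paste, character(1), collapse = "")
  expect_true(all(got %in% keys))
  counts <- table(factor(got, levels = keys))
  expect_gt(chisq.test(counts)$p.value, 1e-4)
})

test_that("margin-unique vials yield a degenerate null at the observed", {
  # staircase margins admit exactly one matrix
  stair <- mk_mat(c(1, 1, 1,
                    1, 1, 0,
                    1, 0, 0), 3)
  expect_length(enumerate_fixed_margin(rowSums(stair), colSums(stair)), 1)
  res <- randomize_scic(list(g1 = stair, g2 = stair), n_rand = 50,
                        seed = 54)
  expect_true(all(res$vial_unique))
  expect_false(res$degenerate)
  expect_true(all(res$null_values == res$observed))
  expect_equal(res$p_lower, 1)
  expect_equal(res$p_upper, 1)
})

test_that("randomized SCIC null is deterministic and honest about margins", {
  sim <- simulate_experiment(sim_config(n_groups = 6), seed = 55)
  mats <- mating_matrices(sim$events, sim$roster)
  r1 <- randomize_scic(mats, n_rand = 100, seed = 56)
  r2 <- randomize_scic(mats, n_rand = 100, seed = 56)
  expect_identical(r1$null_values, r2$null_values)
  expect_length(r1$null_values, 100)
  expect_true(r1$p_lower >= 0 && r1$p_lower <= 1)
  expect_true(r1$p_upper >= 0 && r1$p_upper <= 1)
  expect_equal(r1$p_lower + r1$p_upper >= 1, TRUE)  # tails overlap at ties
})

test_that("null SCIC range narrows as the mating matrix saturates", {
  widths <- vapply(c(24, 4), function(refr) {
    sim <- simulate_experiment(sim_config(n_groups = 15,
                                          refractory_mean = refr),
                               seed = 57)
    mats <- mating_matrices(sim$events, sim$roster)
    r <- randomize_scic(mats, n_rand = 200, seed = 58)
    diff(range(r$null_values))
  }, numeric(1))
  expect_lte(widths[2], widths[1])
})

test_that("SCI regressions match an independent IRLS fit", {
  sim <- simulate_experiment(sim_config(n_groups = 25), seed = 59)
  s <- compute_male_summaries(sim$events, sim$paternity, sim$roster)
  tab <- sci_regressions(s, sim$events, sim$roster)
  # rebuild the T model by hand with plain Fisher scoring (log link)
  mats <- mating_matrices(sim$events, sim$roster)
  sci <- male_sci_table(mats)
  sub <- s[s$M >= 1, ]
  sub$SCI <- sci$SCI[match(sub$male_id, sci$male_id)]
  X <- model.matrix(~ M_std + SCI_std + vial_fecundity + replicate_id,
                    data.frame(M_std = sub$M / mean(sub$M),
                               SCI_std = sub$SCI / mean(sub$SCI),
                               vial_fecundity = sub$vial_fecundity,
                               replicate_id = factor(sub$replicate_id)))
  y <- round(sub$T)
  beta <- rep(0, ncol(X)); beta[1] <- log(mean(y))
  for (i in 1:50) {
    eta <- as.vector(X %*% beta)
    mu <- exp(eta)
    W <- mu
    z <- eta + (y - mu) / mu
    beta <- solve(t(X) %*% (W * X), t(X) %*% (W * z))
  }
  got <- tab[tab$model == "T" & tab$treatment == "control", ]
  expect_equal(got$estimate[got$term == "SCI_std"],
               unname(beta["SCI_std", 1]), tolerance = 1e-6)
  expect_equal(got$estimate[got$term == "M_std"],
               unname(beta["M_std", 1]), tolerance = 1e-6)
})

test_that("fair-raffle simulation puts a negative SCI gradient on P", {
  sim <- simulate_experiment(sim_config(n_groups = 100,
                                        refractory_mean = 4), seed = 60)
  s <- compute_male_summaries(sim$events, sim$paternity, sim$roster)
  tab <- sci_regressions(s, sim$events, sim$roster)
  est <- tab$estimate[tab$model == "P" & tab$term == "SCI_std"]
  expect_lt(est, 0)
})

test_that("swap sampler agrees with an independent curveball null model", {
  skip_if_not_installed("vegan")
  m <- mk_mat(c(1, 1, 0, 0,
                0, 1, 1, 0,
                1, 0, 1, 1,
                0, 1, 0, 1), 4)
  fam <- enumerate_fixed_margin(rowSums(m), colSums(m))
  keys <- vapply(fam, paste, character(1), collapse = "")
  mine <- sample_fixed_margin(m, 3000, method = "swap", seed = 80)
  k1 <- vapply(mine, function(d) paste(as.integer(d), collapse = ""),
               character(1))
  nm <- vegan::nullmodel(m, "curveball")
  sims <- stats::simulate(nm, nsim = 3000, seed = 81, thin = 100)
  k2 <- vapply(seq_len(dim(sims)[3]), function(i) {
    paste(as.integer(sims[, , i]), collapse = "")
  }, character(1))
  t1 <- table(factor(k1, levels = keys))
  t2 <- table(factor(k2, levels = keys))
  expect_true(all(k2 %in% keys))
  # both uniform over the same family: two-sample chi-square is quiet
  expect_gt(suppressWarnings(chisq.test(rbind(t1, t2))$p.value), 1e-4)
})
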