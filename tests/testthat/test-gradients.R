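test_that("proportional T and M give a mean-standardised gradient of 1", {
  M <- c(1, 2, 3, 4, 2, 3)
  T <- 7 * M                       # relative T equals relative M
  g <- suppressWarnings(bateman_univariate(T, M))  # perfect fit
  expect_equal(g$beta_mean, 1, tolerance = 1e-12)
})

test_that("permuting M against T gives gradients centred on zero", {
  set.seed(10)
  M <- rep(1:4, 8)
  T <- 5 * M + rnorm(32, sd = 2)
  slopes <- vapply(1:100, function(i) {
    bateman_univariate(T, sample(M))$beta_mean
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 0.1)
})

test_that("variance-standardised slope equals mean slope times CV", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    M <- rpois(n, 3) + 1
    T <- 2 * M + rnorm(n)
    g <- bateman_univariate(T, M)
    # two routes: sd-multiplied slope vs Jones route via sqrt(I_S)
    expect_equal(g$beta_var, g$beta_mean * sqrt(opportunity_index(M)),
                 tolerance = 1e-10)
  }
})

test_that("zero variance in mating success is an error", {
  expect_error(bateman_univariate(c(1, 2, 3), c(2, 2, 2)),
               "zero variance")
})

test_that("constant P and N reduce the multivariate to the univariate", {
  set.seed(12)
  M <- rpois(20, 3) + 1
  P <- rep(0.5, 20)
  N <- rep(30, 20)
  T <- M * N * P
  multi <- suppressWarnings(bateman_multivariate(T, M, P, N))
  uni <- suppressWarnings(bateman_univariate(T, M))
  expect_equal(multi$estimate[multi$component == "M"],
               uni$beta_mean, tolerance = 1e-10)
  expect_true(all(is.na(multi$estimate[multi$component %in% c("P", "N")])))
})

test_that("multivariate coefficients equal a normal-equation solve", {
  set.seed(13)
  n <- 20
  M <- rpois(n, 3) + 1
  P <- runif(n, 0.2, 0.9)
  N <- runif(n, 20, 50)
  T <- M * N * P * exp(rnorm(n, sd = 0.1))
  multi <- bateman_multivariate(T, M, P, N)
  X <- cbind(1, M / mean(M), P / mean(P), N / mean(N))
  beta <- solve(t(X) %*% X, t(X) %*% (T / mean(T)))
  expect_equal(multi$estimate, as.numeric(beta[2:4]), tolerance = 1e-8)
})

test_that("known coefficients are recovered on a synthetic design", {
  set.seed(14)
  n <- 60
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  # shift to positive scales so mean-standardisation is stable
  M <- 10 + x1; P <- 10 + x2; N <- 10 + x3
  y_rel <- 1 + 1 * (M / mean(M) - 1) + 2 * (P / mean(P) - 1) -
    1 * (N / mean(N) - 1) + rnorm(n, sd = 0.005)
  T <- y_rel * 50
  multi <- bateman_multivariate(T, M, P, N)
  truth <- c(1, 2, -1)
  for (i in 1:3) {
    expect_lt(abs(multi$estimate[i] - truth[i]), 3 * multi$se[i])
  }
})

test_that("collinear varying predictors raise a named failure", {
  set.seed(15)
  M <- rpois(20, 3) + 1
  P <- M / 10                      # exactly collinear with M
  N <- runif(20, 20, 50)
  T <- M * N * P
  expect_error(bateman_multivariate(T, M, P, N), "collinear")
})

test_that("repetitive-mating gradient recovers constructed slopes", {
  s <- fake_summaries(24, seed = 16)
  # constant P: slope exactly 0
  s0 <- s; s0$P <- 0.4
  g0 <- suppressWarnings(repetitive_gradient(s0))
  expect_equal(g0$estimate, 0, tolerance = 1e-12)
  # P = a + b*(rate - mean rate) gives slope b/a on the standardised scale
  s1 <- s
  a <- 0.5; b <- 0.1
  s1$P <- a + b * (s1$repetitive_rate - mean(s1$repetitive_rate))
  g1 <- suppressWarnings(repetitive_gradient(s1, covariates = character(0)))
  expect_equal(g1$estimate, b / a, tolerance = 1e-10)
})

test_that("last-male advantage under high polyandry rewards re-mating", {
  cfg <- sim_config(n_groups = 100, refractory_mean = 4,
                    last_male_weight = 3)
  sim <- simulate_experiment(cfg, seed = 17)
  s <- compute_male_summaries(sim$events, sim$paternity, sim$roster)
  g <- repetitive_gradient(s)
  expect_gt(g$estimate, 0)
})

test_that("adjusted paternity share follows its closed form", {
  expect_equal(adjusted_pcs(0.3, 2), 0.3)          # n = 2 identity
  expect_equal(adjusted_pcs(1, 2), 1)              # share 1 fixed point
  expect_equal(adjusted_pcs(1, 5), 1)
  expect_equal(adjusted_pcs(0.5, 3), 2 / 3)        # 0.5*2 / (0.5*1 + 1)
  expect_error(adjusted_pcs(1.2, 3), "\\[0, 1\\]")
  expect_error(adjusted_pcs(0.5, 1), ">= 2")
  # stays a share
  set.seed(18)
  p <- runif(50); n <- sample(2:5, 50, replace = TRUE)
  a <- adjusted_pcs(p, n)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("per-male adjustment excludes monogamous and unshared females", {
  # fA: mated by focal and r1 (n = 2); fB: only focal (monogamous,
  # excluded); fC: only rivals (not a focal mate)
  ev <- data.frame(
    group_id = "g1", replicate_id = "rep1", treatment = "control",
    day = 1L, order = 1:4,
    male_id = c("m_focal", "m_r1", "m_focal", "m_r2"),
    female_id = c("fA", "fA", "fB", "fC"), stringsAsFactors = FALSE)
  pa <- data.frame(group_id = "g1", female_id = c("fA", "fB", "fC"),
                   daughters_focal = c(4L, 6L, 0L),
                   daughters_other = c(4L, 0L, 5L),
                   stringsAsFactors = FALSE)
  res <- adjusted_pcs_by_male(ev, pa, tiny_roster())
  expect_equal(res$n_females_used, 1L)
  expect_equal(res$n_females_excluded, 1L)         # fB monogamous
  expect_equal(res$adjusted_share, adjusted_pcs(0.5, 2))
})

test_that("pooled interaction model detects a gradient difference", {
  set.seed(19)
  mk <- function(b, tr, seed) {
    s <- fake_summaries(30, seed = seed, treatment = tr)
    s$T <- 50 + s$M * b * 10 + rnorm(30, sd = 0.5)
    s
  }
  s <- rbind(mk(2, "control", 20), mk(0.2, "high", 21))
  cmp <- compare_gradients(s, "bateman")
  expect_lt(cmp$p, 0.05)
  # proportional T in both arms: relative slope is 1 everywhere, so the
  # interaction should find nothing
  mk_prop <- function(tr, seed) {
    s2 <- fake_summaries(30, seed = seed, treatment = tr)
    s2$T <- s2$M * 10 + rnorm(30, sd = 3)
    s2
  }
  s2 <- rbind(mk_prop("control", 22), mk_prop("high", 23))
  cmp2 <- compare_gradients(s2, "bateman")
  expect_gt(cmp2$p, 0.05)
})
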