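# Small hand-built fixtures used across test files.  All data are
# constructed in code; nothing is read from disk except where a test
# writes its own temporary file first.

# One group: focal mates female A twice and B once; rival r1 mates B and C.
# A produced 10 daughters (6 by the focal), B 5 (1 by the focal), C 8
# (all by rivals).
tiny_roster <- function() {
  data.frame(
    group_id = "g1", treatment = "control",
    id = c("m_focal", "m_r1", "m_r2", "m_r3", "fA", "fB", "fC", "fD"),
    sex = c(rep("male", 4), rep("female", 4)),
    role = c("focal", "rival", "rival", "rival", rep("female", 4)),
    stringsAsFactors = FALSE)
}

tiny_events <- function() {
  data.frame(
    group_id = "g1", replicate_id = "rep1", treatment = "control",
    day = c(1L, 1L, 2L, 1L, 2L),
    order = c(1L, 2L, 1L, 3L, 2L),
    male_id = c("m_focal", "m_focal", "m_focal", "m_r1", "m_r1"),
    female_id = c("fA", "fB", "fA", "fB", "fC"),
    stringsAsFactors = FALSE)
}

tiny_paternity <- function() {
  data.frame(
    group_id = "g1",
    female_id = c("fA", "fB", "fC"),
    daughters_focal = c(6L, 1L, 0L),
    daughters_other = c(4L, 4L, 8L),
    stringsAsFactors = FALSE)
}

# Deterministic multi-male summary table for gradient/decomposition tests.
fake_summaries <- function(n = 20, seed = 1, treatment = "control") {
  set.seed(seed)
  M <- sample(1:4, n, replace = TRUE)
  P <- runif(n, 0.2, 0.9)
  N <- runif(n, 20, 60)
  data.frame(
    male_id = sprintf("m%02d", seq_len(n)),
    group_id = sprintf("g%02d", seq_len(n)),
    replicate_id = rep(c("rep1", "rep2"), length.out = n),
    treatment = treatment,
    mating_frequency = M + rpois(n, 1),
    M = M,
    repetitive_rate = 1 + runif(n),
    N = N,
    P = P,
    T = M * N * P,
    mean_share_per_mate = P,
    vial_fecundity = round(N * 4),
    stringsAsFactors = FALSE)
}

# Enumerate, for a list of binary matrices, the exact SCIC value (oracle
# used against the vectorised implementation).
scic_oracle <- function(mats) {
  M <- c(); S <- c()
  for (mat in mats) {
    for (i in seq_len(nrow(mat))) {
      mi <- sum(mat[i, ])
      if (mi == 0) next
      ks <- colSums(mat)[mat[i, ] > 0]
      M <- c(M, mi)
      S <- c(S, mi / sum(1 / ks))
    }
  }
  Ms <- M / mean(M); Ss <- S / mean(S)
  sum((Ms - mean(Ms)) * (Ss - mean(Ss))) / sum((Ms - mean(Ms))^2)
}
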