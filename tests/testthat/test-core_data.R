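test_that("focal-male summary reproduces hand-computed components", {
  s <- compute_male_summaries(tiny_events(), tiny_paternity(),
                              tiny_roster())
  expect_equal(nrow(s), 1)
  expect_equal(s$M, 2L)
  expect_equal(s$mating_frequency, 3L)
  expect_equal(s$repetitive_rate, 1.5)
  expect_equal(s$N, 7.5)            # mean of 10 and 5
  expect_equal(s$P, 7 / 15)         # pooled 7 sired of 15 produced
  expect_equal(s$T, 7)
  # multiplicative identity under the pooled definitions
  expect_equal(s$T, s$M * s$N * s$P)
  expect_equal(s$vial_fecundity, 23)
  expect_equal(s$mean_share_per_mate, mean(c(6 / 10, 1 / 5)))
})

test_that("degenerate and boundary males are summarised correctly", {
  ev <- tiny_events()
  ev <- ev[ev$male_id != "m_focal", ]            # focal never mates
  pa <- tiny_paternity()
  pa$daughters_focal <- 0L
  s <- compute_male_summaries(ev, pa, tiny_roster())
  expect_equal(s$M, 0L)
  expect_equal(s$T, 0)
  expect_true(is.na(s$P) && is.na(s$N) && is.na(s$repetitive_rate))

  # sole mate, full paternity
  ev2 <- tiny_events()[1, ]
  pa2 <- data.frame(group_id = "g1", female_id = "fA",
                    daughters_focal = 9L, daughters_other = 0L)
  s2 <- compute_male_summaries(ev2, pa2, tiny_roster())
  expect_equal(s2$P, 1)
  expect_equal(s2$T, 9)
})

test_that("inconsistent paternity (focal daughters from a non-mate) fails", {
  pa <- tiny_paternity()
  pa$daughters_focal[pa$female_id == "fC"] <- 2L   # focal never mated fC
  expect_error(compute_male_summaries(tiny_events(), pa, tiny_roster()),
               "never mated")
  # but zero focal daughters from a non-mate is legitimate
  expect_silent(compute_male_summaries(tiny_events(), tiny_paternity(),
                                       tiny_roster()))
})

test_that("readers and writers round-trip and validate", {
  d <- withr::local_tempdir()
  ep <- file.path(d, "events.csv")
  pp <- file.path(d, "paternity.csv")
  rp <- file.path(d, "roster.csv")
  write_mating_events(tiny_events(), ep)
  write_paternity(tiny_paternity(), pp)
  write_roster(tiny_roster(), rp)
  ros <- read_roster(rp)
  ev <- read_mating_events(ep, ros)
  expect_equal(ev, polysel:::validate_events(tiny_events()), ignore_attr = TRUE)
  expect_equal(read_paternity(pp), tiny_paternity(), ignore_attr = TRUE)
  expect_equal(ros, tiny_roster(), ignore_attr = TRUE)

  # tab-separated via extension
  et <- file.path(d, "events.tsv")
  write.table(tiny_events(), et, sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_equal(read_mating_events(et), polysel:::validate_events(tiny_events()),
               ignore_attr = TRUE)

  # missing column
  bad <- tiny_events()
  bad$male_id <- NULL
  write.csv(bad, ep, row.names = FALSE)
  expect_error(read_mating_events(ep), "missing column")

  # unknown id against the roster
  bad2 <- tiny_events()
  bad2$female_id[1] <- "fZ"
  write_mating_events(bad2, ep)
  expect_error(read_mating_events(ep, ros), "not in the roster")

  # duplicate (group, day, order)
  bad3 <- tiny_events()
  bad3$order[2] <- bad3$order[1]
  write_mating_events(bad3, ep)
  expect_error(read_mating_events(ep), "duplicate copulation order")
})

test_that("roster validation enforces the one-focal design", {
  ros <- tiny_roster()
  ros$role[2] <- "focal"
  expect_error(polysel:::validate_roster(ros), "exactly one focal")
  ros2 <- tiny_roster()
  ros2$id[2] <- ros2$id[1]
  expect_error(polysel:::validate_roster(ros2), "duplicate ids")
})

test_that("T = M*N*P and copulation conservation hold on simulated data", {
  sim <- simulate_experiment(sim_config(n_groups = 8), seed = 7)
  s <- compute_male_summaries(sim$events, sim$paternity, sim$roster)
  mated <- s[s$M >= 1, ]
  expect_equal(mated$T, mated$M * mated$N * mated$P, tolerance = 1e-12)
  expect_true(all(s$mating_frequency >= s$M))
  # conservation: per-female copulation counts sum to the event count
  poly <- female_polyandry(sim$events)
  expect_equal(sum(poly$n_copulations), nrow(sim$events))
})
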