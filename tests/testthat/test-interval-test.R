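# contacts + dataset for directed-pair checks, from minute-resolution events
pair_fixture <- function(l_min, f_min, n_stations = 1, station = "st01") {
  ev <- list(
    station_id = rep_len(station, length(l_min) + length(f_min)),
    species = rep(c("roe_deer", "sika_deer"), c(length(l_min), length(f_min))),
    minutes = c(l_min, f_min))
  contacts_from_minutes(ev, n_stations = n_stations)
}

test_that("intervals pair each follower with the most recent preceding leader", {
  # leader 12:00, follower 13:30 -> one 1.5 h interval
  fx <- pair_fixture(l_min = 12 * 60, f_min = 13.5 * 60)
  expect_equal(leader_follower_intervals(fx$contacts, "roe_deer", "sika_deer",
                                         fx$dataset), 1.5)
  # leader 12:00, followers 13:00 and 14:00, leader 13:30:
  # second follower pairs with the 13:30 leader
  fx <- pair_fixture(l_min = c(12, 13.5) * 60, f_min = c(13, 14) * 60)
  expect_setequal(leader_follower_intervals(fx$contacts, "roe_deer", "sika_deer",
                                            fx$dataset), c(1.0, 0.5))
  # follower before any leader at its station contributes nothing
  fx <- pair_fixture(l_min = 14 * 60, f_min = 13 * 60)
  expect_length(leader_follower_intervals(fx$contacts, "roe_deer", "sika_deer",
                                          fx$dataset), 0)
})

test_that("first-after-leader pairing keeps only the first qualifying follower", {
  fx <- pair_fixture(l_min = 12 * 60, f_min = c(13, 13.2, 18) * 60)
  expect_length(leader_follower_intervals(fx$contacts, "roe_deer", "sika_deer",
                                          fx$dataset, "most_recent"), 3)
  expect_equal(leader_follower_intervals(fx$contacts, "roe_deer", "sika_deer",
                                         fx$dataset, "first_after_leader"), 1)
})

test_that("intervals never cross stations", {
  ev <- data.frame(station_id = c("st01", "st02"),
                   species = c("roe_deer", "sika_deer"),
                   minutes = c(12 * 60, 13 * 60))
  fx <- contacts_from_minutes(ev, n_stations = 2)
  expect_length(leader_follower_intervals(fx$contacts, "roe_deer", "sika_deer",
                                          fx$dataset), 0)
})

test_that("interval pairing matches a quadratic brute force on random streams", {
  set.seed(55)
  for (k in 1:200) {
    nl <- sample(0:15, 1); nf <- sample(0:15, 1)
    st <- sample(1:3, nl + nf, replace = TRUE)
    mins <- sample(0:20000, nl + nf)  # distinct event times inside the window
    ev <- data.frame(station_id = sprintf("st%02d", st),
                     species = rep(c("roe_deer", "sika_deer"), c(nl, nf)),
                     minutes = mins)
    fx <- contacts_from_minutes(ev, n_stations = 3)
    for (mode in c("most_recent", "first_after_leader")) {
      got <- sort(leader_follower_intervals(fx$contacts, "roe_deer", "sika_deer",
                                            fx$dataset, mode))
      want <- sort(unlist(lapply(1:3, function(s) {
        sel <- st == s
        brute_intervals(mins[sel & ev$species == "roe_deer"],
                        mins[sel & ev$species == "sika_deer"],
                        pairing = mode)
      })))
      expect_equal(got, want, info = sprintf("case %d mode %s", k, mode))
    }
  }
})

test_that("max_lag_hours caps intervals when set", {
  fx <- pair_fixture(l_min = 0, f_min = c(60, 60 * 50))
  expect_length(leader_follower_intervals(fx$contacts, "roe_deer", "sika_deer",
                                          fx$dataset), 2)
  expect_equal(leader_follower_intervals(fx$contacts, "roe_deer", "sika_deer",
                                         fx$dataset, max_lag_hours = 24), 1)
})

test_that("randomized follower events respect windows, counts and other species", {
  sim <- simulate_survey(preset_paper_like(seed = 3, attraction = FALSE))
  ct <- filter_independent(sim$dataset)
  act <- activity_pattern(ct, "sika_deer")
  rnd <- randomize_follower(ct, "sika_deer", act, sim$dataset, seed = 99)

  # non-follower rows are untouched
  keep <- ct$species != "sika_deer"
  expect_equal(as.data.frame(rnd)[keep, ], as.data.frame(ct)[keep, ])
  # per-station follower counts conserved
  expect_equal(table(rnd$station_id[rnd$species == "sika_deer"]),
               table(ct$station_id[ct$species == "sika_deer"]))
  # every randomized timestamp inside its station's deployment window
  dep <- sim$dataset$deployments
  i <- match(rnd$station_id, dep$station_id)
  expect_true(all(rnd$timestamp >= dep$start[i] & rnd$timestamp < dep$end[i]))
  # time-of-day values are drawn from the follower's observed clock times
  tod <- as.numeric(rnd$timestamp[rnd$species == "sika_deer"]) %% 86400
  expect_true(all(tod %in% act$clock_times))
})

test_that("a degenerate point-mass activity pattern pins every randomized time", {
  ev <- data.frame(station_id = "st01",
                   species = c("roe_deer", rep("sika_deer", 5)),
                   minutes = c(100, 6 * 60 + 24 * 60 * (0:4)))
  fx <- contacts_from_minutes(ev, n_stations = 1)
  act <- activity_pattern(fx$contacts, "sika_deer")
  expect_true(all(act$clock_times == 6 * 3600))
  rnd <- randomize_follower(fx$contacts, "sika_deer", act, fx$dataset, seed = 5)
  tod <- as.numeric(rnd$timestamp[rnd$species == "sika_deer"]) %% 86400
  expect_true(all(tod == 6 * 3600))
})

test_that("a follower with no contacts randomizes to an identical table", {
  ev <- data.frame(station_id = "st01", species = "roe_deer", minutes = c(0, 2000))
  fx <- contacts_from_minutes(ev, n_stations = 1)
  act <- structure(list(species = "sika_deer", clock_times = 3600,
                        method = "empirical", kappa = 50),
                   class = "activity_pattern")
  rnd <- randomize_follower(fx$contacts, "sika_deer", act, fx$dataset, seed = 5)
  expect_equal(rnd, fx$contacts)
})

test_that("the two-sided randomization p-value formula behaves at its landmarks", {
  expect_equal(interval_p_value(0.5), 1)
  expect_equal(interval_p_value(0.019), 0.038)
  expect_equal(interval_p_value(0), 0)
  expect_equal(interval_p_value(1), 0)
  expect_equal(interval_p_value(c(0.25, 0.75)), c(0.5, 0.5))
})

test_that("null distributions are reproducible and order-independent", {
  sim <- simulate_survey(preset_paper_like(seed = 8))
  ct <- filter_independent(sim$dataset)
  n1 <- null_distribution(ct, "roe_deer", "sika_deer", sim$dataset,
                          reps = 25, seed = 17)
  n2 <- null_distribution(ct, "roe_deer", "sika_deer", sim$dataset,
                          reps = 25, seed = 17)
  expect_identical(n1$null_medians, n2$null_medians)
  # a single-replicate call reproduces the first replicate of a longer run
  n3 <- null_distribution(ct, "roe_deer", "sika_deer", sim$dataset,
                          reps = 1, seed = 17)
  expect_identical(n3$null_medians[1], n1$null_medians[1])

  # one pair's test is the same run alone or within the full 12-pair set
  t_alone <- interval_test(ct, "roe_deer", "sika_deer", sim$dataset,
                           reps = 25, seed = 17)
  set_res <- run_all_pairs(ct, sim$dataset, reps = 25, seed = 17)
  expect_identical(set_res[["roe_deer->sika_deer"]]$null_medians,
                   t_alone$null_medians)
  expect_identical(set_res[["roe_deer->sika_deer"]]$p_two_sided,
                   t_alone$p_two_sided)
})

test_that("run_all_pairs produces one result per ordered pair", {
  sim <- simulate_survey(preset_paper_like(seed = 9))
  ct <- filter_independent(sim$dataset)
  res4 <- run_all_pairs(ct, sim$dataset, reps = 5, seed = 1)
  expect_length(res4, 12)
  expect_length(run_all_pairs(ct, sim$dataset,
                              species = c("roe_deer", "sika_deer"),
                              reps = 5, seed = 1), 2)
  df <- as.data.frame(res4)
  expect_equal(nrow(df), 12)
  expect_true(all(df$leader != df$follower))
})

test_that("untestable pairs are flagged with an absent p-value", {
  ev <- data.frame(station_id = "st01", species = c("roe_deer", "sika_deer"),
                   minutes = c(2000, 100))  # follower precedes the only leader
  fx <- contacts_from_minutes(ev, n_stations = 1)
  res <- interval_test(fx$contacts, "roe_deer", "sika_deer", fx$dataset,
                       reps = 5, seed = 1)
  expect_false(res$testable)
  expect_true(is.na(res$p_two_sided))
  expect_match(res$reason, "no observed")
})

test_that("observed medians are invariant to a constant time shift of the survey", {
  set.seed(77)
  ev <- data.frame(station_id = sprintf("st%02d", sample(1:2, 40, replace = TRUE)),
                   species = sample(c("roe_deer", "sika_deer"), 40, replace = TRUE),
                   minutes = round(runif(40, 0, 20000)))
  fx1 <- contacts_from_minutes(ev, n_stations = 2)
  ev2 <- ev; ev2$minutes <- ev$minutes + 500
  fx2 <- contacts_from_minutes(ev2, n_stations = 2)
  i1 <- leader_follower_intervals(fx1$contacts, "roe_deer", "sika_deer", fx1$dataset)
  i2 <- leader_follower_intervals(fx2$contacts, "roe_deer", "sika_deer", fx2$dataset)
  expect_equal(i1, i2)
})

test_that("medians use the even-count mean-of-central-pair convention", {
  fx <- pair_fixture(l_min = 0, f_min = c(60, 180))
  res <- interval_test(fx$contacts, "roe_deer", "sika_deer", fx$dataset,
                       reps = 3, seed = 2)
  expect_equal(res$observed_median_hours, 2)  # {1 h, 3 h} -> 2 h
  fx3 <- pair_fixture(l_min = 0, f_min = c(60, 120, 9 * 60))
  res3 <- interval_test(fx3$contacts, "roe_deer", "sika_deer", fx3$dataset,
                        reps = 3, seed = 2)
  expect_equal(res3$observed_median_hours, 2)  # {1, 2, 9} h -> 2 h
})
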