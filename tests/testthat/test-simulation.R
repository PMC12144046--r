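sim_fixture <- function(worth = c(a = 8, b = 4, c = 2, d = 1, e = 0.5),
                        n_subjects = 8, noise = 0.3, seed = 2) {
  generate_choices(worth, n_subjects = n_subjects, style = "consumption",
                   noise = noise, seed = seed) |>
    aggregate_sessions() |> apply_threshold(0.5)
}

test_that("randomized completion fills exactly the missing target cells", {
  oc <- sim_fixture()
  # nothing missing: output is the input
  expect_equal(as.data.frame(randomize_unknowns(oc, "c", seed = 1)),
               as.data.frame(oc))

  drop <- (oc$option_a == "c" & oc$option_b == "d") |
    (oc$option_a == "d" & oc$option_b == "c")
  holed <- oc[!drop, ]
  attr(holed, "options") <- choice_options(oc)
  attr(holed, "subjects") <- choice_subjects(oc)
  filled <- randomize_unknowns(holed, "c", seed = 4)
  expect_equal(nrow(filled), nrow(oc))
  new_rows <- dplyr::anti_join(filled, holed,
                               by = c("subject", "option_a", "option_b"))
  expect_equal(nrow(new_rows), 8)
  expect_true(all(new_rows$result %in% c("A_WINS", "B_WINS")))

  # reproducible from the seed, variable across seeds
  f2 <- randomize_unknowns(holed, "c", seed = 4)
  expect_equal(as.data.frame(filled), as.data.frame(f2))
  f3 <- randomize_unknowns(holed, "c", seed = 5)
  expect_false(identical(filled$result, f3$result))

  expect_error(randomize_unknowns(holed, "zzz"),
               class = "prefrank_validation_error")
  expect_error(randomize_unknowns(holed, "c", tested_against = "d"),
               class = "prefrank_validation_error")
})

test_that("a complete tested-against set reproduces the full-data position every run", {
  oc <- sim_fixture()
  sim <- simulate_positions(oc, target = "c",
                            tested_against = c("a", "b", "d", "e"),
                            runs = 10, seed = 1)
  expect_equal(sim$true_positive_frequency, 1)
  expect_true(all(sim$runs$position == sim$true_position))
  expect_equal(sim$discarded_runs, 0)
})

test_that("simulations are deterministic given a seed", {
  oc <- sim_fixture()
  s1 <- simulate_positions(oc, "c", c("a", "b"), runs = 15, seed = 7)
  s2 <- simulate_positions(oc, "c", c("a", "b"), runs = 15, seed = 7)
  expect_equal(s1$runs, s2$runs)
  expect_equal(s1$worths, s2$worths)
  s3 <- simulate_positions(oc, "c", c("a", "b"), runs = 15, seed = 8)
  expect_false(identical(s1$runs$position, s3$runs$position))
})

test_that("position frequencies form a distribution and true positives are counted", {
  oc <- sim_fixture()
  sim <- simulate_positions(oc, "c", c("a", "b"), runs = 40, seed = 11)
  expect_equal(sum(sim$position_frequencies$frequency), 1)
  expect_true(all(sim$runs$position >= 1 &
                    sim$runs$position <= length(sim$options)))
  expect_equal(sim$true_positive_count,
               sum(sim$runs$position == sim$true_position))
  expect_equal(sim$true_positive_frequency, sim$true_positive_count / 40)
})

test_that("informed mode discards every run above the intransitivity cutoff", {
  oc <- sim_fixture(noise = 0.6, seed = 9)
  sim <- simulate_positions(oc, "c", c("a", "b"), runs = 60, seed = 3,
                            mode = "informed", intransitivity_cutoff = 0.05)
  kept <- sim$runs[sim$runs$retained, ]
  expect_true(all(kept$i_ratio <= 0.05))
  expect_equal(sim$discarded_runs, sum(sim$runs$i_ratio > 0.05))

  # complete tested-against set has nothing to randomize: transitivity of the
  # observed data is preserved, so a cutoff of 0 discards nothing
  w3 <- rlang::set_names(c(4, 2, 1), c("x", "y", "z"))
  oc3 <- generate_choices(w3, n_subjects = 6, seed = 12) |>
    aggregate_sessions() |> apply_threshold(0.5)
  if (intransitivity_ratio(oc3) == 0) {
    sim3 <- simulate_positions(oc3, "y", c("x", "z"), runs = 10, seed = 2,
                               mode = "informed", intransitivity_cutoff = 0)
    expect_equal(sim3$discarded_runs, 0)
  }
})

test_that("an unreachable cutoff raises an empty-result error", {
  # the observed non-target options already contain a 3-cycle, so every
  # completion has a positive intransitivity ratio
  cyc <- matrix(c(NA, 1, -1, NA,
                  NA, NA, 1, NA,
                  NA, NA, NA, NA,
                  NA, NA, NA, NA), 4, 4, byrow = TRUE,
                dimnames = list(letters[1:4], letters[1:4]))
  cyc[1, 4] <- 1  # target d observed only against a
  oc <- tournament_from_matrix(cyc)
  expect_error(
    simulate_positions(oc, "d", tested_against = "a", runs = 5, seed = 1,
                       mode = "informed", intransitivity_cutoff = 0),
    class = "prefrank_empty_result")
})

test_that("the best run minimizes (I-ratio, CE) lexicographically", {
  fake <- structure(list(
    runs = tibble::tibble(run = 1:3, position = c(2L, 3L, 2L),
                          i_ratio = c(0.05, 0, 0), ce = c(40, 45, 31),
                          retained = TRUE)), class = "position_sim")
  best <- select_best_run(fake)
  expect_equal(best$run, 3)

  one <- structure(list(runs = fake$runs[1, ]), class = "position_sim")
  expect_equal(select_best_run(one)$run, 1)

  oc <- sim_fixture()
  sim <- simulate_positions(oc, "c", c("a", "b"), runs = 40, seed = 13)
  kept <- sim$runs[sim$runs$retained, ]
  oracle <- kept[order(kept$i_ratio, kept$ce, kept$run), ][1, ]
  expect_equal(select_best_run(sim)$run, oracle$run)
})

test_that("confidence intervals have the normal-approximation width", {
  runs <- tibble::tibble(run = rep(1:4, each = 2),
                         option = rep(c("a", "b"), 4),
                         worth = rep(c(0.6, 0.4), 4))
  ci <- summarize_ci(runs)
  expect_equal(ci$lower, ci$upper)  # constant worth: zero width

  withr::with_seed(5, {
    w <- stats::rnorm(6, 0.5, 0.05)
    runs1 <- tibble::tibble(run = 1:6, option = "a", worth = w)
    runs2 <- tibble::tibble(run = 1:12, option = "a", worth = rep(w, 2))
    ci1 <- summarize_ci(runs1)
    ci2 <- summarize_ci(runs2)
    # doubling k by duplicating the run set shrinks the width by the exact
    # finite-sample factor sqrt((k-1)/(2k-1)) -> 1/sqrt(2) as k grows
    expect_equal(ci2$upper - ci2$lower,
                 (ci1$upper - ci1$lower) * sqrt(5 / 11), tolerance = 1e-6)
    # matches a direct recomputation
    expect_equal(ci1$upper, mean(w) + stats::qnorm(0.975) * stats::sd(w) / sqrt(6))
  })
  expect_error(summarize_ci(runs[runs$run == 1, ]),
               class = "prefrank_validation_error")
})

test_that("the run-count cutoff separates separable targets and flags twins", {
  oc <- sim_fixture(worth = c(a = 12, b = 5, c = 2, d = 1), n_subjects = 10,
                    noise = 0.1, seed = 21)
  # complete information needs a single run
  full <- determine_cutoff(oc, "b", c("a", "c", "d"), max_runs = 16, seed = 1)
  expect_equal(full$cutoff_runs, 1L)
  expect_false(full$ambiguous)

  cut <- determine_cutoff(oc, "b", c("a", "c"), max_runs = 256, seed = 5)
  expect_lte(cut$cutoff_runs, 256)
  expect_false(cut$ambiguous)

  # exchangeable twins cannot separate: b and b2 have identical observed
  # records and only their mutual comparison is randomized, so their worth
  # distributions across runs are mirror images
  twin <- dplyr::bind_rows(lapply(paste0("s", 1:10), function(s)
    tibble::tibble(subject = s,
                   option_a = c("a", "a", "a", "b", "b2"),
                   option_b = c("b", "b2", "c", "c", "c"),
                   result = "A_WINS")))
  amb <- determine_cutoff(twin, "b", c("a", "c"), max_runs = 8, seed = 1)
  expect_true(amb$ambiguous)
  expect_equal(amb$cutoff_runs, 8L)
})

test_that("simulation summaries mirror the results-table layout and export cleanly", {
  oc <- sim_fixture()
  sim <- simulate_positions(oc, "c", c("a", "b"), runs = 25, seed = 19)
  tab <- simulation_table(sim)
  expect_named(tab, c("item", "simulated_position", "worth_value", "i_ratio",
                      "ce_pct", "true_positive_frequency",
                      "true_positive_count", "tested_against"))
  best <- select_best_run(sim)
  expect_equal(tab$simulated_position, best$position)
  expect_equal(tab$tested_against, "a, b")

  tsv <- tempfile(fileext = ".tsv")
  write_simulation(sim, tsv, "tsv")
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 1)
  js <- tempfile(fileext = ".json")
  write_simulation(sim, js, "json")
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$summary$true_positive_frequency,
               sim$true_positive_frequency, tolerance = 1e-12)
  expect_equal(nrow(parsed$runs), 25)
})
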