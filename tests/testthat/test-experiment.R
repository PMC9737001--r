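test_that("experiment plans validate their preconditions", {
  expect_error(experiment_plan(replications = 0), ">= 1")
  expect_error(experiment_plan(years = 2, warmup_years = 2), "smaller")
  expect_error(experiment_plan(scenario_ids = c(0, 40)), "0-26")
  p <- experiment_plan(c(22, 0, 22), replications = 2)
  expect_identical(p$scenario_ids, c(0L, 22L))
})

test_that("a fixed-seed experiment regenerates byte-identical outputs", {
  cfg <- busy_little_hospital()
  plan1 <- experiment_plan(c(0), replications = 1, years = 1,
                           warmup_years = 0, base_seed = 5,
                           output_dir = withr::local_tempdir())
  plan2 <- experiment_plan(c(0), replications = 1, years = 1,
                           warmup_years = 0, base_seed = 5,
                           output_dir = withr::local_tempdir())
  ex1 <- suppressWarnings(run_experiment(plan1, cfg))
  ex2 <- suppressWarnings(run_experiment(plan2, cfg))
  f1 <- file.path(plan1$output_dir, "results.csv")
  f2 <- file.path(plan2$output_dir, "results.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(ex1$results, ex2$results)
})

test_that("experiment results carry efficiencies for patient scenarios", {
  cfg <- busy_little_hospital()
  plan <- experiment_plan(c(0, 16), replications = 2, years = 1,
                          warmup_years = 0, base_seed = 3)
  ex <- suppressWarnings(run_experiment(plan, cfg))
  expect_identical(nrow(ex$results), 2L)
  r16 <- ex$results[ex$results$scenario == 16, ]
  expect_gt(r16$affected_patients, 0)
  expect_false(is.na(r16$event_efficiency))
  expect_true(is.na(ex$results$event_efficiency[ex$results$scenario == 0]))
  # provenance carries everything needed to regenerate
  expect_identical(ex$provenance$base_seed, 3L)
  expect_identical(ex$provenance$replications, 2L)
  # tidy/glance interface
  expect_identical(nrow(generics::tidy(ex)), 2L)
  g <- generics::glance(ex)
  expect_identical(g$n_scenarios, 2L)
})

test_that("ranking orders published values correctly", {
  tb <- tibble::tibble(scenario = c(0, 22, 6),
                       n_congestion_events = c(111.75, 39.55, 21.35))
  expect_identical(rank_scenarios(tb, "events")$scenario, c(6, 22, 0))

  eff <- tibble::tibble(scenario = c(22, 24, 26),
                        event_efficiency = c(0.23, 0.21, 0.17))
  expect_identical(rank_scenarios(eff, "event_efficiency")$scenario,
                   c(22, 24, 26))

  one <- tibble::tibble(scenario = 5, n_congestion_events = 3)
  expect_identical(rank_scenarios(one, "events")$scenario, 5)

  expect_error(rank_scenarios(tb, "nonsense"))
  expect_error(rank_scenarios(tb, "time_efficiency"), "lack")
})
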