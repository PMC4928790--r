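test_that("simulation is reproducible from its seed", {
  cfg <- doc_scenario("null")
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(a$assessments, c$assessments))
  expect_error(simulate_cohort(cfg), "seed")
  # the caller's RNG stream is untouched
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(simulate_cohort(cfg, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("generated cohorts respect the structural invariants", {
  for (name in c("null", "paper-like", "strong-separation")) {
    sim <- simulate_cohort(doc_scenario(name), seed = 17)
    maxes <- crsr_max_levels()
    for (s in crsr_subscales()) {
      expect_true(all(sim$assessments[[s]] %in% 0:maxes[[s]]))
    }
    days_ok <- tapply(sim$assessments$day, sim$assessments$patient,
                      function(d) length(d) >= 3 && !is.unsorted(d, strictly = TRUE))
    expect_true(all(days_ok))
    first <- first_assessments(sim$assessments)
    expect_false(anyNA(first[paste0("mbt_", 1:10)]))
    expect_true(all(unlist(first[paste0("mbt_", 1:10)]) %in% 0:1))
    expect_equal(sim$cohort$n_crsr,
                 as.integer(table(sim$assessments$patient)[sim$cohort$patient]))
  }
})

test_that("outcome constraints hold by construction", {
  cfg <- doc_generator_config(n_uws = 8, n_mcs = 0, p_emerge_uws = 1)
  sim <- simulate_cohort(cfg, seed = 3)
  last <- sim$assessments |>
    dplyr::group_by(patient) |>
    dplyr::slice_max(day, n = 1) |>
    dplyr::ungroup()
  expect_true(all(last$motor == 6 | last$communication == 2))
  expect_true(all(sim$cohort$outcome == "Non DOC"))

  cfg0 <- doc_generator_config(n_uws = 8, n_mcs = 0, p_emerge_uws = 0)
  sim0 <- simulate_cohort(cfg0, seed = 3)
  expect_false(any(sim0$assessments$motor == 6 |
                     sim0$assessments$communication == 2))
  # initial diagnosis matches the intended class
  expect_true(all(crsr_diagnose(first_assessments(sim0$assessments)) == "UWS"))
})

test_that("unattainable constraints hit the rejection limit", {
  bad <- doc_generator_config(
    n_uws = 2, n_mcs = 0, p_emerge_uws = 1,
    trajectory = tibble::tibble(
      class = c("UWS", "UWS"), outcome = c("emerged", "remaining"),
      t50_mean = 500, t50_sd = 0, tau = 5
    ),
    max_attempts = 25
  )
  expect_error(simulate_cohort(bad, seed = 1), "Rejection limit")
})

test_that("reference scenarios are named and sized as documented", {
  expect_error(doc_scenario("nope"), "Unknown scenario")
  pl <- doc_scenario("paper-like")
  sim <- simulate_cohort(pl, seed = 2)
  expect_equal(nrow(sim$cohort), 33)
  expect_equal(sum(sim$cohort$diagnosis == "UWS"), 20)
  expect_equal(sum(sim$cohort$diagnosis == "MCS"), 13)
  cl <- classify_outcome(sim$cohort)
  expect_equal(sum(cl$primary_class == "emerged"), 21) # 11 UWS + 10 MCS
  nul <- doc_scenario("null")
  expect_equal(nul$mbt_p$p_emerged, nul$mbt_p$p_remaining)
})

test_that("MBT item frequencies match their configured probabilities", {
  cfg <- doc_generator_config(
    n_uws = 30, n_mcs = 0, p_emerge_uws = 0.5,
    match_diagnosis = FALSE, enforce_outcome = FALSE
  )
  p1 <- cfg$mbt_p$p_emerged[1]
  draws <- unlist(lapply(1:40, function(i) {
    sim <- simulate_cohort(cfg, seed = 100 + i)
    cl <- classify_outcome(sim$cohort)
    first <- first_assessments(sim$assessments)
    first$mbt_1[first$patient %in% cl$patient[cl$primary_class == "emerged"]]
  }))
  phat <- mean(draws)
  band <- 2.807 * sqrt(p1 * (1 - p1) / length(draws)) # 99.5% binomial band
  expect_gt(length(draws), 300)
  expect_lt(abs(phat - p1), band)
})

test_that("emergence fractions follow the configured probabilities", {
  cfg <- doc_generator_config(
    n_uws = 12, n_mcs = 10, p_emerge_uws = 0.55, p_emerge_mcs = 0.77,
    match_diagnosis = FALSE, enforce_outcome = FALSE
  )
  fr <- sapply(1:80, function(i) {
    sim <- simulate_cohort(cfg, seed = 200 + i)
    cl <- classify_outcome(sim$cohort)
    c(uws = mean(cl$primary_class[cl$diagnosis == "UWS"] == "emerged"),
      mcs = mean(cl$primary_class[cl$diagnosis == "MCS"] == "emerged"))
  })
  se_uws <- sqrt(0.55 * 0.45 / (80 * 12))
  se_mcs <- sqrt(0.77 * 0.23 / (80 * 10))
  expect_lt(abs(mean(fr["uws", ]) - 0.55), 2.807 * se_uws)
  expect_lt(abs(mean(fr["mcs", ]) - 0.77), 2.807 * se_mcs)
})

test_that("analytic ground-truth helpers expose the generator's geometry", {
  cfg <- doc_generator_config(
    n_uws = 10, n_mcs = 0,
    trajectory = tibble::tibble(
      class = c("UWS", "UWS"), outcome = c("emerged", "remaining"),
      t50_mean = c(20, 70), t50_sd = c(0, 0), tau = c(5, 15)
    )
  )
  # single-cell crossing has a closed form
  expect_equal(latent_crossing_day(cfg, "motor", 6),
               20 + 5 * qlogis(5.5 / 6))
  expect_equal(latent_crossing_day(cfg, "communication", 2),
               20 + 5 * qlogis(1.5 / 2))
  sep <- separation_day(cfg)
  expect_true(sep > 5 && sep < 25)
  # a larger margin is never attained earlier
  expect_gte(separation_day(cfg, margin = 1), sep)
  expect_error(latent_crossing_day(cfg, "motor", 9), "range")
  # noiseless scores reconstruct the latent trajectory
  sim <- simulate_cohort(doc_generator_config(n_uws = 4, n_mcs = 0,
                                              noise_eps = 0),
                         seed = 9)
  expect_equal(noiseless_scores(sim)[crsr_subscales()],
               sim$assessments[crsr_subscales()])
})
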