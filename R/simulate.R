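#' Configuration for the synthetic DOC cohort generator
#'
#' Assembles the generator's parameters with defaults emulating an acute
#' neurorehabilitation cohort: 20 UWS and 13 MCS patients, emergence
#' probabilities 0.55 (UWS) and 0.77 (MCS), a weekly-jittered assessment
#' schedule (first assessment 11.2 +/- 6 days after insult truncated to
#' \[1, 28\], inter-assessment interval 7.5 +/- 2.9 days truncated at 2,
#' follow-up 52 +/- 18 days), a shared logistic latent recovery
#' L(t) = 1 / (1 + exp(-(t - t50) / tau)) per patient mapped to each
#' subscale as round(L * max level) with +/-1 ordinal noise, and
#' outcome-conditional Bernoulli MBT items whose default rates follow the
#' observed item frequencies in emerged vs remaining patients.
#'
#' @param n_uws,n_mcs Cohort sizes by initial diagnosis.
#' @param p_emerge_uws,p_emerge_mcs Emergence probabilities by class.
#' @param trajectory Tibble with columns `class` (`"UWS"`/`"MCS"`),
#'   `outcome` (`"emerged"`/`"remaining"`), `t50_mean`, `t50_sd`, `tau`
#'   and optionally `tau_sd` (days); per-patient slopes are drawn from a
#'   truncated normal when `tau_sd > 0`.
#' @param noise_eps Probability of a +/-1 ordinal perturbation per score.
#' @param schedule Named list: `first_mean`, `first_sd`, `first_range`,
#'   `interval_mean`, `interval_sd`, `interval_min`, `followup_mean`,
#'   `followup_sd`, `followup_min` (all days).
#' @param mbt_p Tibble with `item` (1-10), `p_emerged`, `p_remaining`.
#' @param match_diagnosis Resample until the first assessment's CRS-R
#'   diagnosis matches the intended class.
#' @param enforce_outcome Resample until emergers satisfy the emergence
#'   rule (motor 6 or communication 2) at the last assessment and
#'   non-emergers never do.
#' @param exact_emergence Fix the number of emergers per class at
#'   `round(p * n)` instead of drawing Bernoulli outcomes.
#' @param max_attempts Rejection-sampling cap per patient.
#' @return A `doc_generator_config` list.
#' @export
doc_generator_config <- function(
    n_uws = 20, n_mcs = 13,
    p_emerge_uws = 0.55, p_emerge_mcs = 0.77,
    trajectory = default_trajectory(),
    noise_eps = 0.1,
    schedule = list(first_mean = 11.2, first_sd = 6, first_range = c(1, 28),
                    interval_mean = 7.5, interval_sd = 2.9, interval_min = 2,
                    followup_mean = 52, followup_sd = 18, followup_min = 21),
    mbt_p = default_mbt_p(),
    match_diagnosis = TRUE,
    enforce_outcome = TRUE,
    exact_emergence = FALSE,
    max_attempts = 1000) {
  probs <- c(p_emerge_uws, p_emerge_mcs, mbt_p$p_emerged, mbt_p$p_remaining)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (noise_eps < 0 || noise_eps > 1) abort("`noise_eps` must lie in [0, 1].")
  if (!"tau_sd" %in% names(trajectory)) trajectory$tau_sd <- 0
  if (any(trajectory$t50_sd < 0) || any(trajectory$tau <= 0) ||
      any(trajectory$tau_sd < 0)) {
    abort("Trajectory SDs must be >= 0 and tau > 0.")
  }
  structure(
    list(n_uws = n_uws, n_mcs = n_mcs,
         p_emerge_uws = p_emerge_uws, p_emerge_mcs = p_emerge_mcs,
         trajectory = trajectory, noise_eps = noise_eps, schedule = schedule,
         mbt_p = mbt_p, match_diagnosis = match_diagnosis,
         enforce_outcome = enforce_outcome, exact_emergence = exact_emergence,
         max_attempts = max_attempts),
    class = "doc_generator_config"
  )
}

default_trajectory <- function() {
  tibble(
    class = c("UWS", "UWS", "MCS", "MCS"),
    outcome = c("emerged", "remaining", "emerged", "remaining"),
    t50_mean = c(34, 60, 18, 18),
    t50_sd = c(9, 20, 6, 6),
    tau = c(7, 25, 7, 45),
    tau_sd = c(2, 8, 2, 10)
  )
}

default_mbt_p <- function() {
  tibble(
    item = 1:10,
    p_emerged = c(0.86, 0.81, 0.90, 0.95, 0.90, 0.86, 0.76, 0.05, 0.05, 0.05),
    p_remaining = c(0.33, 0.25, 0.33, 0.50, 0.42, 0.33, 0.42, 0.50, 0.25, 0.50)
  )
}

#' Named reference scenarios for simulation studies
#'
#' Three pre-configured generator settings:
#' * `"null"` - the two outcome groups are statistically identical: shared
#'   trajectory parameters, shared MBT rates, outcome labels assigned at
#'   random and not enforced on the data. Between-group tests are exact
#'   nulls; use for type-I-error calibration.
#' * `"paper-like"` - the default cohort structure (20 UWS / 13 MCS,
#'   emergence 0.55 / 0.77, fixed at 11 and 10 emergers respectively,
#'   group mean curves separating around day 20).
#' * `"strong-separation"` - a single-diagnosis (UWS) cohort of 33 with 21
#'   emergers, assessed early (about day 5) while all first CRS-R scores
#'   still sit at floor/reflex levels, with near-deterministic positive
#'   MBT signs in emergers; raw first scores carry no signal but the MBT
#'   weighting and the longitudinal split are strongly informative. Use
#'   for power and recovery checks.
#'
#' @param name Scenario name.
#' @return A `doc_generator_config`.
#' @examples
#' doc_scenario("paper-like")
#' @export
doc_scenario <- function(name = c("null", "paper-like", "strong-separation")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(sprintf(
                     "Unknown scenario `%s` (available: null, paper-like, strong-separation).",
                     name[1])))
  switch(
    name,
    "null" = doc_generator_config(
      p_emerge_uws = 0.5, p_emerge_mcs = 0.5,
      trajectory = tibble(
        class = c("UWS", "UWS", "MCS", "MCS"),
        outcome = c("emerged", "remaining", "emerged", "remaining"),
        t50_mean = 30, t50_sd = 8, tau = 10
      ),
      mbt_p = tibble(item = 1:10, p_emerged = 0.4, p_remaining = 0.4),
      match_diagnosis = FALSE, enforce_outcome = FALSE
    ),
    "paper-like" = doc_generator_config(exact_emergence = TRUE),
    "strong-separation" = doc_generator_config(
      n_uws = 33, n_mcs = 0, p_emerge_uws = 21 / 33,
      trajectory = tibble(
        class = c("UWS", "UWS", "MCS", "MCS"),
        outcome = c("emerged", "remaining", "emerged", "remaining"),
        t50_mean = c(22, 80, 22, 80),
        t50_sd = c(3, 8, 3, 8),
        tau = c(5, 12, 5, 12)
      ),
      noise_eps = 0.05,
      schedule = list(first_mean = 5, first_sd = 2, first_range = c(3, 9),
                      interval_mean = 7.5, interval_sd = 2.9, interval_min = 2,
                      followup_mean = 55, followup_sd = 10, followup_min = 38),
      mbt_p = tibble(
        item = 1:10,
        p_emerged = c(rep(0.95, 5), rep(0.9, 2), rep(0.05, 3)),
        p_remaining = c(rep(0.05, 5), rep(0.05, 2), rep(0.8, 3))
      ),
      exact_emergence = TRUE
    )
  )
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v >= lower && v <= upper) break
    }
    out[i] <- v
  }
  out
}

#' Simulate a synthetic DOC cohort
#'
#' Draws a full cohort under a generator configuration: per patient an
#' outcome by class, a latent logistic recovery trajectory, a
#' weekly-jittered integer-day assessment schedule (always at least
#' three assessments, strictly increasing days), ordinal subscale scores,
#' and one outcome-conditional MBT evaluation attached to the first
#' assessment. Rejection sampling enforces the configured consistency
#' constraints (initial diagnosis matching the intended class; emergence
#' by the last assessment for emergers and never for non-emergers) and
#' errors if `max_attempts` is exhausted.
#'
#' @param config A [doc_generator_config()] (or scenario from
#'   [doc_scenario()]).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return List with `cohort` (one row per patient, [read_cohort()]
#'   schema plus the realised latent parameters `t50` and `tau`, kept so
#'   recovery studies can compute ground truth) and `assessments` (long
#'   scores; first-assessment rows carry `mbt_1` .. `mbt_10`).
#' @examples
#' sim <- simulate_cohort(doc_scenario("paper-like"), seed = 1)
#' nrow(sim$cohort)
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "doc_generator_config"))
  if (missing(seed)) abort("`seed` is required.")
  with_seed(seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  classes <- rep(c("UWS", "MCS"), times = c(config$n_uws, config$n_mcs))
  n <- length(classes)
  outcomes <- character(n)
  for (cl in c("UWS", "MCS")) {
    idx <- which(classes == cl)
    p <- if (cl == "UWS") config$p_emerge_uws else config$p_emerge_mcs
    if (length(idx) == 0) next
    if (config$exact_emergence) {
      k <- round(p * length(idx))
      lab <- rep(c("emerged", "remaining"), times = c(k, length(idx) - k))
      outcomes[idx] <- sample(lab)
    } else {
      outcomes[idx] <- ifelse(rbinom(length(idx), 1, p) == 1,
                              "emerged", "remaining")
    }
  }
  patients <- purrr::map(seq_len(n), function(i) {
    simulate_patient(sprintf("S%02d", i), classes[i], outcomes[i], config)
  })
  cohort <- purrr::map(patients, "cohort_row") |> purrr::list_rbind()
  assessments <- purrr::map(patients, "assessments") |> purrr::list_rbind()
  list(cohort = cohort, assessments = assessments)
}

simulate_patient <- function(id, class, outcome, config) {
  traj <- config$trajectory
  pars <- traj[traj$class == class & traj$outcome == outcome, ]
  if (nrow(pars) != 1) {
    abort(sprintf("No trajectory parameters for class %s / outcome %s.",
                  class, outcome))
  }
  sch <- config$schedule
  maxes <- crsr_max_levels()
  for (attempt in seq_len(config$max_attempts)) {
    t50 <- rtrunc_norm(1, pars$t50_mean, pars$t50_sd, lower = 1)
    tau <- if (pars$tau_sd > 0) {
      rtrunc_norm(1, pars$tau, pars$tau_sd, lower = max(1, pars$tau / 3))
    } else {
      pars$tau
    }
    first <- round(rtrunc_norm(1, sch$first_mean, sch$first_sd,
                               sch$first_range[1], sch$first_range[2]))
    followup <- round(rtrunc_norm(1, sch$followup_mean, sch$followup_sd,
                                  lower = max(sch$followup_min, first + 4)))
    days <- first
    while (tail(days, 1) < followup) {
      gap <- max(sch$interval_min,
                 round(rnorm(1, sch$interval_mean, sch$interval_sd)))
      days <- c(days, tail(days, 1) + gap)
    }
    while (length(days) < 3) {
      days <- c(days, tail(days, 1) +
                  max(sch$interval_min, round(sch$interval_mean)))
    }
    latent <- plogis((days - t50) / tau)
    scores <- purrr::map(crsr_subscales(), function(s) {
      base <- round(latent * maxes[[s]])
      shift <- sample(c(-1L, 0L, 1L), length(base), replace = TRUE,
                      prob = c(config$noise_eps / 2, 1 - config$noise_eps,
                               config$noise_eps / 2))
      pmin(pmax(base + shift, 0L), maxes[[s]])
    }) |>
      setNames(crsr_subscales()) |>
      as_tibble()
    if (config$match_diagnosis &&
        crsr_diagnose(scores[1, ]) != class) next
    if (config$enforce_outcome) {
      emergent <- scores$motor == 6 | scores$communication == 2
      if (outcome == "emerged" && !emergent[length(emergent)]) next
      if (outcome == "remaining" && any(emergent)) next
    }
    p_items <- if (outcome == "emerged") config$mbt_p$p_emerged else
      config$mbt_p$p_remaining
    mbt <- rbinom(10, 1, p_items)
    last_dx <- crsr_diagnose(scores[nrow(scores), ])
    outcome_label <- if (outcome == "emerged") {
      "Non DOC"
    } else if (last_dx == "UWS") "UWS" else "MCS"
    p_home <- if (outcome == "emerged") 0.8 else 0.25
    p_walk <- if (outcome == "emerged") 0.7 else 0.25
    cohort_row <- tibble(
      patient = id,
      age = round(rtrunc_norm(1, 48, 17, 18, 85)),
      diagnosis = class,
      t50 = t50,
      tau = tau,
      lesions = NA_character_,
      etiology = NA_character_,
      delay_first_crsr = days[1],
      n_crsr = length(days),
      delay_last_crsr = days[length(days)],
      rehab_duration = days[length(days)] - days[1],
      outcome = outcome_label,
      return_home = ifelse(rbinom(1, 1, p_home) == 1, "Yes", "No"),
      walk = ifelse(rbinom(1, 1, p_walk) == 1, "Yes", "No")
    )
    assessments <- bind_cols(tibble(patient = id, day = days), scores)
    for (it in 1:10) {
      assessments[[paste0("mbt_", it)]] <-
        c(mbt[it], rep(NA_integer_, length(days) - 1))
    }
    return(list(cohort_row = cohort_row, assessments = assessments))
  }
  abort(sprintf(
    "Rejection limit (%d) reached for patient %s (%s, %s): constraints unattainable under the configured trajectories.",
    config$max_attempts, id, class, outcome
  ))
}

#' First assessment with MBT per patient
#'
#' Extracts each patient's first CRS-R assessment and its attached MBT
#' evaluation from a long assessment table - the input shape required by
#' [crsr_prediction()], [mbt_prediction()] and [increment_sweep()].
#'
#' @param assessments Long assessment tibble with optional `mbt_*`
#'   columns.
#' @return Tibble with one row per patient.
#' @export
first_assessments <- function(assessments) {
  assessments |>
    group_by(.data$patient) |>
    arrange(.data$day, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Analytic separation day of a generator configuration
#'
#' The day at which the configured expected subscale curves of the two
#' outcome groups (class-size-weighted mixtures of
#' `max_level * plogis((t - t50_mean)/tau)`) first differ by `margin`
#' score points - the generator's own notion of when the groups become
#' distinguishable, used as ground truth in recovery checks.
#'
#' @param config A [doc_generator_config()].
#' @param subscale Subscale whose expected curves are compared (default
#'   motor).
#' @param margin Score-point difference defining separation; the default,
#'   half a score level, is the smallest mean difference that can alter
#'   any rounded ordinal score.
#' @param window,step Search grid.
#' @return Day (numeric), or `NA` if the margin is never reached.
#' @export
separation_day <- function(config, subscale = "motor", margin = 0.5,
                           window = c(0, 100), step = 0.5) {
  subscale <- match.arg(subscale, crsr_subscales())
  max_s <- crsr_max_levels()[[subscale]]
  grid <- seq(window[1], window[2], by = step)
  curve <- function(outcome) {
    w <- class_weights(config, outcome)
    rows <- config$trajectory[config$trajectory$outcome == outcome, ]
    sapply(grid, function(t) {
      sum(w * max_s * plogis((t - rows$t50_mean) / rows$tau))
    })
  }
  diff <- curve("emerged") - curve("remaining")
  idx <- which(diff >= margin)
  if (length(idx) == 0) return(NA_real_)
  grid[idx[1]]
}

class_weights <- function(config, outcome) {
  rows <- config$trajectory[config$trajectory$outcome == outcome, ]
  p <- ifelse(rows$class == "UWS", config$p_emerge_uws, config$p_emerge_mcs)
  if (outcome == "remaining") p <- 1 - p
  n <- ifelse(rows$class == "UWS", config$n_uws, config$n_mcs)
  w <- n * p
  if (sum(w) == 0) return(rep(0, length(w)))
  w / sum(w)
}

#' Analytic cutoff-crossing day of a generator configuration
#'
#' The day at which the noiseless generated score
#' `round(max_level * L(t))` of the given class/outcome cell (at its mean
#' t50) first reaches `level`: `t50_mean + tau * qlogis((level - 0.5) /
#' max_level)`. With the default motor cutoff this is the generator's
#' ground-truth emergence day.
#'
#' @param config A [doc_generator_config()].
#' @param subscale Subscale (default motor).
#' @param level Score level (default the emergence cutoff 6).
#' @param outcome Outcome cell (default `"emerged"`).
#' @return Day (numeric, class-size-weighted mean across classes).
#' @export
latent_crossing_day <- function(config, subscale = "motor", level = 6,
                                outcome = "emerged") {
  subscale <- match.arg(subscale, crsr_subscales())
  max_s <- crsr_max_levels()[[subscale]]
  if (level <= 0 || level > max_s) abort("`level` outside the subscale range.")
  rows <- config$trajectory[config$trajectory$outcome == outcome, ]
  w <- class_weights(config, outcome)
  sum(w * (rows$t50_mean + rows$tau * qlogis((level - 0.5) / max_s)))
}

#' Noiseless scores implied by a simulated cohort's latent trajectories
#'
#' Recomputes, for every assessment of a simulated cohort, the score the
#' generator would have produced without ordinal noise:
#' `round(L(day) * max_level)` from the patient's realised `t50` and
#' `tau`. Used as ground truth in recovery studies - e.g. the
#' cutoff-attainment day of the noiseless group curve is the generator's
#' own crossing day, against which the noisy-data estimate is compared.
#'
#' @param sim Result of [simulate_cohort()].
#' @return Assessment tibble (`patient`, `day`, five subscales) with
#'   noise-free scores.
#' @export
noiseless_scores <- function(sim) {
  cohort <- sim$cohort
  if (!all(c("t50", "tau") %in% names(cohort))) {
    abort("`sim$cohort` must carry the generator's `t50` and `tau` columns.")
  }
  out <- sim$assessments[c("patient", "day")]
  idx <- match(out$patient, cohort$patient)
  latent <- plogis((out$day - cohort$t50[idx]) / cohort$tau[idx])
  maxes <- crsr_max_levels()
  for (s in crsr_subscales()) out[[s]] <- round(latent * maxes[[s]])
  out
}
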