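# Small builders used across the suite.

profile_row <- function(auditory = 0, visual = 0, motor = 0, oromotor = 0,
                        communication = 0) {
  tibble::tibble(auditory = auditory, visual = visual, motor = motor,
                 oromotor = oromotor, communication = communication)
}

# The reflex-level profile: every subscale at its reflexive score.
reflex_profile <- function() profile_row(1, 1, 2, 1, 0)

mbt_row <- function(present = integer()) {
  items <- as.integer(1:10 %in% present)
  tibble::as_tibble(setNames(as.list(items), paste0("mbt_", 1:10)))
}

# Random valid profiles for property tests.
random_profiles <- function(n) {
  maxes <- crsr_max_levels()
  tibble::as_tibble(lapply(maxes, function(m) sample(0:m, n, replace = TRUE)))
}

# A tiny two-group cohort whose patients all share the same first profile,
# with MBT items fixed per group.
two_group_first_scores <- function(n1, n2, profile = reflex_profile(),
                                   items1 = 1, items2 = integer()) {
  first <- dplyr::bind_cols(
    tibble::tibble(patient = paste0("P", seq_len(n1 + n2))),
    profile[rep(1, n1 + n2), ]
  )
  mbt <- dplyr::bind_rows(mbt_row(items1)[rep(1, n1), ],
                          mbt_row(items2)[rep(1, n2), ])
  cohort <- tibble::tibble(
    patient = first$patient,
    diagnosis = "UWS",
    outcome = rep(c("Non DOC", "UWS"), times = c(n1, n2))
  )
  list(first = dplyr::bind_cols(first, mbt),
       comparisons = doc_comparisons(classify_outcome(cohort)))
}

# Assessment table for one patient following y = f(day).
traj_assessments <- function(patient, days, f) {
  scores <- f(days)
  tibble::tibble(patient = patient, day = days,
                 auditory = pmin(scores, 4), visual = pmin(scores, 5),
                 motor = pmin(scores, 6), oromotor = pmin(scores, 3),
                 communication = pmin(scores, 2))
}
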