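#' CRS-R subscale conventions
#'
#' The Coma Recovery Scale-Revised (CRS-R) scores six subscales; the five
#' analysed here are auditory (0-4), visual (0-5), motor (0-6), oromotor
#' (0-3) and communication (0-2). The arousal subscale (0-3) is recorded but
#' excluded from every analysis, as is the total score. `crsr_subscales()`
#' returns the analysis subscales in canonical order; the other helpers
#' return named integer vectors over those subscales.
#'
#' The *reflex level* is the highest score on each subscale that still
#' denotes purely reflexive behaviour: 1, 1, 2, 1 for the auditory, visual,
#' motor and oromotor functions and 0 (none) for communication. MBT-based
#' weighting (see [weight_profile()]) only ever fires at the reflex level.
#'
#' @return Character vector of subscale names, or a named integer vector
#'   keyed by subscale.
#' @examples
#' crsr_subscales()
#' crsr_reflex_levels()
#' @export
crsr_subscales <- function() {
  c("auditory", "visual", "motor", "oromotor", "communication")
}

#' @rdname crsr_subscales
#' @export
crsr_max_levels <- function() {
  c(auditory = 4L, visual = 5L, motor = 6L, oromotor = 3L, communication = 2L)
}

#' @rdname crsr_subscales
#' @export
crsr_reflex_levels <- function() {
  c(auditory = 1L, visual = 1L, motor = 2L, oromotor = 1L, communication = 0L)
}

#' Minimally-conscious-state score thresholds
#'
#' Lowest score on each CRS-R subscale that marks a minimally conscious
#' state: any one subscale at or above its threshold yields an MCS
#' diagnosis. These are the standard CRS-R conventions (reproducible
#' movement to command, visual fixation, localisation to noxious
#' stimulation, intelligible verbalization, intentional communication);
#' they sit one level above the reflex band. The table is overridable in
#' [crsr_diagnose()] for sensitivity analyses.
#'
#' @return Named integer vector over the five analysis subscales.
#' @export
crsr_mcs_thresholds <- function() {
  c(auditory = 3L, visual = 2L, motor = 3L, oromotor = 3L, communication = 1L)
}

# Validate a data frame of subscale scores; allows non-integer values when
# integer = FALSE (MBT-weighted profiles are real-valued).
validate_scores <- function(scores, integer = TRUE, arg = "scores") {
  subs <- crsr_subscales()
  if (!is.data.frame(scores)) {
    abort(sprintf("`%s` must be a data frame with columns %s.",
                  arg, paste(subs, collapse = ", ")))
  }
  missing_cols <- setdiff(subs, names(scores))
  if (length(missing_cols) > 0) {
    abort(sprintf("`%s` is missing subscale column(s): %s.",
                  arg, paste(missing_cols, collapse = ", ")))
  }
  maxes <- crsr_max_levels()
  for (s in subs) {
    v <- scores[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("Subscale `%s` must be numeric.", s))
    }
    bad <- !is.na(v) & (v < 0 | v > maxes[[s]] | (integer & v != floor(v)))
    if (any(bad)) {
      abort(sprintf(
        "Subscale `%s` has out-of-range score(s): %s (allowed %s 0..%d).",
        s, paste(unique(v[bad]), collapse = ", "),
        if (integer) "integers" else "values", maxes[[s]]
      ))
    }
  }
  if ("arousal" %in% names(scores)) {
    v <- scores[["arousal"]]
    bad <- !is.na(v) & (v < 0 | v > 3)
    if (any(bad)) abort("Subscale `arousal` has out-of-range score(s) (allowed 0..3).")
  }
  invisible(scores)
}

#' Diagnose consciousness level from CRS-R subscale scores
#'
#' Applies the CRS-R diagnostic rules row-wise. Emergence from DOC is
#' defined by functional object use (motor score 6) or functional
#' communication (communication score 2). Otherwise the profile is MCS if
#' any subscale reaches its MCS threshold (see [crsr_mcs_thresholds()]),
#' else UWS. The arousal subscale, when present, is ignored.
#'
#' @param scores Data frame with integer columns `auditory`, `visual`,
#'   `motor`, `oromotor`, `communication` (one row per assessment).
#' @param thresholds Named integer vector of MCS thresholds; defaults to
#'   the standard convention.
#' @return Character vector, one of `"UWS"`, `"MCS"`, `"EMERGED"` per row.
#' @examples
#' crsr_diagnose(data.frame(auditory = 3, visual = 1, motor = 2,
#'                          oromotor = 1, communication = 0))
#' @export
crsr_diagnose <- function(scores, thresholds = crsr_mcs_thresholds()) {
  validate_scores(scores)
  subs <- crsr_subscales()
  if (!all(subs %in% names(thresholds))) {
    abort("`thresholds` must name all five analysis subscales.")
  }
  emerged <- scores$motor == 6 | scores$communication == 2
  mcs <- rep(FALSE, nrow(scores))
  for (s in subs) {
    mcs <- mcs | (scores[[s]] >= thresholds[[s]])
  }
  dplyr::case_when(emerged ~ "EMERGED", mcs ~ "MCS", TRUE ~ "UWS")
}
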