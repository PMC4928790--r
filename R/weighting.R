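#' Motor Behaviour Tool item conventions
#'
#' The MBT scores ten binary bedside items: items 1-5 are positive signs
#' (subtle non-reflex motor behaviour that standard CRS-R quoting rules
#' overlook), items 6-7 are negative signs (concomitant conditions masking
#' motor or verbal output), and items 8-10 are reflex signs.
#' `mbt_item_roles()` returns the fixed role of each item;
#' `mbt_subscale_map()` gives, for each CRS-R subscale, the positive items
#' that raise it: items 1, 3 and 5 raise all five subscales, item 2 raises
#' the auditory and visual subscales, and item 4 the motor and oromotor
#' subscales.
#'
#' @return `mbt_item_roles()`: tibble with `item` (1-10) and `role`;
#'   `mbt_subscale_map()`: named list of item-index vectors keyed by
#'   subscale.
#' @export
mbt_item_roles <- function() {
  tibble(
    item = 1:10,
    role = rep(c("positive", "negative", "reflex"), times = c(5, 2, 3))
  )
}

#' @rdname mbt_item_roles
#' @export
mbt_subscale_map <- function() {
  list(
    auditory = c(1L, 2L, 3L, 5L),
    visual = c(1L, 2L, 3L, 5L),
    motor = c(1L, 3L, 4L, 5L),
    oromotor = c(1L, 3L, 4L, 5L),
    communication = c(1L, 3L, 5L)
  )
}

mbt_cols <- function() paste0("mbt_", 1:10)

validate_mbt <- function(mbt, arg = "mbt") {
  cols <- mbt_cols()
  if (!is.data.frame(mbt) || !all(cols %in% names(mbt))) {
    abort(sprintf("`%s` must be a data frame with columns %s.",
                  arg, paste(cols, collapse = ", ")))
  }
  for (cc in cols) {
    v <- mbt[[cc]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      abort(sprintf("MBT column `%s` must be binary (0/1).", cc))
    }
  }
  invisible(mbt)
}

#' Does the MBT assessment fire a subscale's weighting?
#'
#' A subscale's weighting fires when at least one of the positive MBT
#' items mapped to that subscale (see [mbt_subscale_map()]) is present.
#' Negative (6-7) and reflex (8-10) items never enter weighting.
#'
#' @param mbt Data frame with binary columns `mbt_1` .. `mbt_10` (one row
#'   per assessment).
#' @param subscale One of the five analysis subscales.
#' @return Logical vector, one element per row of `mbt`.
#' @examples
#' mbt_fires(data.frame(t(setNames(c(0,1,0,0,0,0,0,0,0,0), paste0("mbt_", 1:10)))),
#'           "visual")
#' @export
mbt_fires <- function(mbt, subscale) {
  validate_mbt(mbt)
  subscale <- match.arg(subscale, crsr_subscales())
  items <- mbt_subscale_map()[[subscale]]
  as.logical(rowSums(as.matrix(mbt[paste0("mbt_", items)]) == 1) > 0)
}

#' Weight CRS-R subscale scores by positive MBT signs
#'
#' Implements the MBT weighting principle: when a CRS-R subscale is quoted
#' exactly at its reflex level (auditory 1, visual 1, motor 2, oromotor 1,
#' communication 0) and at least one mapped positive MBT item is present,
#' the score is incremented by `delta` (a step in (0, 1), typically on the
#' 0.1 grid), so the weighted score approaches - but never reaches - the
#' next level, which carries the first clinical sign of consciousness.
#' Scores away from the reflex level are never altered, so the integer
#' floor of a weighted profile always equals the raw profile.
#'
#' @param scores Data frame of integer subscale scores (rows align with
#'   `mbt`).
#' @param mbt Data frame with binary `mbt_1` .. `mbt_10` columns.
#' @param delta Increment in \[0, 1); 0 returns the profile unchanged.
#' @return Tibble of real-valued weighted subscale scores with logical
#'   columns `<subscale>_fired` recording where the weighting applied.
#' @examples
#' mbt <- data.frame(t(setNames(c(1, rep(0, 9)), paste0("mbt_", 1:10))))
#' weight_profile(data.frame(auditory = 1, visual = 1, motor = 2,
#'                           oromotor = 1, communication = 0), mbt, 0.5)
#' @export
weight_profile <- function(scores, mbt, delta) {
  validate_scores(scores)
  validate_mbt(mbt)
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta >= 1) {
    abort("`delta` must be a single value in [0, 1).")
  }
  if (nrow(scores) != nrow(mbt)) {
    abort("`scores` and `mbt` must have the same number of rows.")
  }
  reflex <- crsr_reflex_levels()
  out <- as_tibble(scores[crsr_subscales()])
  for (s in crsr_subscales()) {
    fired <- out[[s]] == reflex[[s]] & mbt_fires(mbt, s)
    out[[s]] <- as.numeric(out[[s]]) + delta * fired
    out[[paste0(s, "_fired")]] <- fired
  }
  out
}

#' Progressive-increment critical-point sweep
#'
#' For each outcome comparison, each CRS-R subscale and each increment
#' `delta` on the grid, weights the patients' first-assessment subscale
#' scores by their first MBT evaluation ([weight_profile()]) and runs a
#' Mann-Whitney U test between the comparison's two groups on the weighted
#' scores. Within one comparison at one delta, p-values are
#' Holm-corrected across the five subscales. The *critical increment* for
#' a (comparison, subscale) is the smallest delta whose corrected p-value
#' falls below `alpha`. Degenerate (empty-sided) comparisons are returned
#' flagged, without p-values.
#'
#' Because weighting adds strictly less than one level, any `delta > 0`
#' induces the same ordering of patients; the Mann-Whitney p-value is
#' therefore constant across the grid and the sweep's role is to confirm
#' whether the weighted scores discriminate at all (in which case the
#' critical increment is the smallest grid value) - see the package
#' vignette.
#'
#' @param first_scores Tibble with one row per patient: `patient`, the
#'   five subscale columns (first CRS-R assessment) and `mbt_1` ..
#'   `mbt_10` (first MBT evaluation).
#' @param comparisons Comparison table from [doc_comparisons()].
#' @param deltas Ascending increment grid (default 0.1 .. 0.9).
#' @param alpha Family-wise significance level (default 0.05).
#' @param exact_max Passed to [mw_utest()].
#' @return Long tibble: `comparison`, `subscale`, `delta`, `statistic`
#'   (U), `p_raw`, `p_holm`, `critical` (smallest significant delta for
#'   that comparison and subscale), `degenerate`.
#' @export
increment_sweep <- function(first_scores, comparisons,
                            deltas = seq(0.1, 0.9, by = 0.1),
                            alpha = 0.05, exact_max = 12) {
  validate_scores(first_scores)
  validate_mbt(first_scores)
  if (is.unsorted(deltas, strictly = TRUE) ||
      any(deltas <= 0) || any(deltas >= 1)) {
    abort("`deltas` must be strictly ascending values in (0, 1).")
  }
  rows <- purrr::pmap(comparisons, function(comparison, lhs_ids, rhs_ids,
                                            n_lhs, n_rhs, degenerate, ...) {
    grid <- tidyr::expand_grid(
      comparison = comparison, subscale = crsr_subscales(), delta = deltas
    )
    if (degenerate) {
      return(mutate(grid, statistic = NA_real_, p_raw = NA_real_,
                    degenerate = TRUE))
    }
    i_lhs <- match(lhs_ids, first_scores$patient)
    i_rhs <- match(rhs_ids, first_scores$patient)
    res <- purrr::map(deltas, function(d) {
      w <- weight_profile(first_scores, first_scores, d)
      purrr::map(crsr_subscales(), function(s) {
        t <- mw_utest(w[[s]][i_lhs], w[[s]][i_rhs], exact_max = exact_max)
        tibble(comparison = comparison, subscale = s, delta = d,
               statistic = t$statistic, p_raw = t$p_value,
               degenerate = FALSE)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    res
  })
  out <- purrr::list_rbind(rows) |>
    group_by(.data$comparison, .data$delta) |>
    mutate(p_holm = holm_adjust(.data$p_raw)) |>
    group_by(.data$comparison, .data$subscale) |>
    mutate(critical = !is.na(.data$p_holm) & .data$p_holm < alpha &
             .data$delta == suppressWarnings(
               min(.data$delta[!is.na(.data$p_holm) & .data$p_holm < alpha]))) |>
    ungroup() |>
    arrange(match(.data$comparison, comparisons$comparison),
            match(.data$subscale, crsr_subscales()), .data$delta)
  out
}

#' Smallest discriminating increment per comparison and subscale
#'
#' Reduces an [increment_sweep()] result to one row per (comparison,
#' subscale) with the critical delta (NA when no increment reaches
#' significance).
#'
#' @param sweep Result of [increment_sweep()].
#' @return Tibble with `comparison`, `subscale`, `critical_delta`.
#' @export
critical_deltas <- function(sweep) {
  sweep |>
    group_by(.data$comparison, .data$subscale) |>
    summarise(
      critical_delta = if (any(.data$critical, na.rm = TRUE)) {
        min(.data$delta[which(.data$critical)])
      } else NA_real_,
      .groups = "drop"
    )
}
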