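#' Outcome prediction from first CRS-R subscale scores
#'
#' For each outcome comparison and each of the five CRS-R subscales, runs
#' a Mann-Whitney U test on the raw first-assessment subscale scores
#' between the comparison's groups, Holm-corrected across the five
#' subscales within a comparison.
#'
#' @param first_scores Tibble with `patient` and the five subscale columns
#'   (first assessment per patient).
#' @param comparisons Comparison table from [doc_comparisons()].
#' @param exact_max Passed to [mw_utest()].
#' @return Long tibble: `comparison`, `subscale`, `statistic`, `p_raw`,
#'   `p_holm`, `degenerate`.
#' @export
crsr_prediction <- function(first_scores, comparisons, exact_max = 12) {
  validate_scores(first_scores)
  rows <- purrr::pmap(comparisons, function(comparison, lhs_ids, rhs_ids,
                                            n_lhs, n_rhs, degenerate, ...) {
    if (degenerate) {
      return(tibble(comparison = comparison, subscale = crsr_subscales(),
                    statistic = NA_real_, p_raw = NA_real_, degenerate = TRUE))
    }
    i_lhs <- match(lhs_ids, first_scores$patient)
    i_rhs <- match(rhs_ids, first_scores$patient)
    purrr::map(crsr_subscales(), function(s) {
      t <- mw_utest(first_scores[[s]][i_lhs], first_scores[[s]][i_rhs],
                    exact_max = exact_max)
      tibble(comparison = comparison, subscale = s, statistic = t$statistic,
             p_raw = t$p_value, degenerate = FALSE)
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(rows) |>
    group_by(.data$comparison) |>
    mutate(p_holm = holm_adjust(.data$p_raw)) |>
    ungroup() |>
    relocate("p_holm", .after = "p_raw")
}

#' Default predictor orientation for MBT items
#'
#' For the positive and negative signs (items 1-7) the predictor-positive
#' state is item present and the outcome-positive state is emergence; for
#' the reflex signs (items 8-10) the outcome-positive state is remaining
#' in DOC, since reflex behaviours indicate deeper consciousness
#' impairment and poorer outcome.
#'
#' @return Tibble with `item` and `disease_positive`
#'   (`"lhs"` = the comparison's better-outcome side, `"rhs"` = the other).
#' @export
mbt_orientation <- function() {
  tibble(item = 1:10,
         disease_positive = rep(c("lhs", "rhs"), times = c(7, 3)))
}

#' Outcome prediction from MBT items
#'
#' For each outcome comparison and each of the ten binary MBT items, runs
#' a Mann-Whitney U test on the item values between the comparison's
#' groups (retained for Bernoulli data rather than replaced by a 2x2
#' exact test, for fidelity to the design), Holm-corrected across
#' the ten items within a comparison. Where the corrected p-value falls
#' below `alpha`, the predictor performance (sensitivity, specificity,
#' Yule's Q; see [binary_predictor_metrics()]) is reported under the item's
#' orientation; elsewhere the metrics are NA.
#'
#' @param first_mbt Tibble with `patient` and binary `mbt_1` .. `mbt_10`
#'   columns (first MBT evaluation per patient).
#' @param comparisons Comparison table from [doc_comparisons()].
#' @param alpha Significance level gating the metric report (default 0.05).
#' @param orientation Orientation table, see [mbt_orientation()].
#' @param exact_max Passed to [mw_utest()].
#' @return Long tibble: `comparison`, `item`, `statistic`, `p_raw`,
#'   `p_holm`, `sensitivity`, `specificity`, `yules_q`, `degenerate`.
#' @export
mbt_prediction <- function(first_mbt, comparisons, alpha = 0.05,
                           orientation = mbt_orientation(), exact_max = 12) {
  validate_mbt(first_mbt)
  rows <- purrr::pmap(comparisons, function(comparison, lhs_ids, rhs_ids,
                                            n_lhs, n_rhs, degenerate, ...) {
    if (degenerate) {
      return(tibble(comparison = comparison, item = 1:10,
                    statistic = NA_real_, p_raw = NA_real_, degenerate = TRUE))
    }
    i_lhs <- match(lhs_ids, first_mbt$patient)
    i_rhs <- match(rhs_ids, first_mbt$patient)
    purrr::map(1:10, function(it) {
      x <- first_mbt[[paste0("mbt_", it)]][i_lhs]
      y <- first_mbt[[paste0("mbt_", it)]][i_rhs]
      t <- mw_utest(x, y, exact_max = exact_max)
      tibble(comparison = comparison, item = it, statistic = t$statistic,
             p_raw = t$p_value, degenerate = FALSE)
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(rows) |>
    group_by(.data$comparison) |>
    mutate(p_holm = holm_adjust(.data$p_raw)) |>
    ungroup()
  metrics <- purrr::pmap(out, function(comparison, item, p_holm, degenerate, ...) {
    if (degenerate || is.na(p_holm) || p_holm >= alpha) {
      return(tibble(sensitivity = NA_real_, specificity = NA_real_,
                    yules_q = NA_real_))
    }
    cmp <- comparisons[comparisons$comparison == comparison, ]
    i_lhs <- match(cmp$lhs_ids[[1]], first_mbt$patient)
    i_rhs <- match(cmp$rhs_ids[[1]], first_mbt$patient)
    v <- first_mbt[[paste0("mbt_", item)]]
    side <- orientation$disease_positive[orientation$item == item]
    pos <- if (side == "lhs") v[i_lhs] else v[i_rhs]
    neg <- if (side == "lhs") v[i_rhs] else v[i_lhs]
    binary_predictor_metrics(sum(pos == 1), sum(neg == 1),
                             sum(pos == 0), sum(neg == 0))[, 1:3]
  }) |> purrr::list_rbind()
  bind_cols(out, metrics) |>
    relocate("degenerate", .after = dplyr::last_col())
}

#' Descriptive comparison of emerged vs remaining patients
#'
#' Produces the descriptive group comparison for a classified cohort:
#' group sizes and subclass counts, group means and standard deviations
#' (n-1 denominator) for the continuous demographics (age, number of
#' CRS-R assessments, delay insult to first CRS-R, delay insult to last
#' CRS-R, rehabilitation duration), lesion-site and aetiology-category
#' tallies, and the two secondary endpoints (functional walking ability,
#' return home) with `NA` endpoints excluded pairwise. Continuous
#' variables are tested with the Mann-Whitney U test and the secondary
#' endpoints with Fisher's exact test (two-sided); p-values are
#' Holm-corrected across that family of seven tests.
#'
#' @param cohort Cohort tibble (see [read_cohort()]); classified on the
#'   fly when `subclass` is absent.
#' @return Named list of tibbles: `groups` (sizes and subclass counts),
#'   `continuous`, `lesions`, `etiology`, `endpoints`.
#' @examples
#' doc_descriptives(doc_cohort())$continuous
#' @export
doc_descriptives <- function(cohort) {
  cohort <- classify_outcome(cohort)
  grp <- function(g) cohort[cohort$primary_class == g, ]
  rem <- grp("remaining")
  eme <- grp("emerged")
  n_all <- nrow(cohort)

  groups <- subclass_counts(cohort) |>
    mutate(
      diagnosis = ifelse(.data$subclass %in% c("a", "c", "d"), "UWS", "MCS"),
      primary_class = ifelse(.data$subclass %in% c("a", "b"),
                             "emerged", "remaining"),
      pct_of_diagnosis = .data$n / ifelse(.data$diagnosis == "UWS",
                                          sum(cohort$diagnosis == "UWS"),
                                          sum(cohort$diagnosis == "MCS"))
    )

  cont_vars <- c(
    age = "Age (years)",
    n_crsr = "Number of CRS-R",
    delay_first_crsr = "Delay insult-first CRS-R (days)",
    delay_last_crsr = "Delay insult-last CRS-R (days)",
    rehab_duration = "Rehabilitation duration (days)"
  )
  grp_mean <- function(v) if (length(v) == 0) NA_real_ else mean(v)
  grp_sd <- function(v) if (length(v) < 2) NA_real_ else sd(v)
  continuous <- purrr::imap(cont_vars, function(label, v) {
    t <- if (nrow(rem) == 0 || nrow(eme) == 0) {
      list(statistic = NA_real_, p_value = NA_real_)
    } else {
      mw_utest(rem[[v]], eme[[v]])
    }
    tibble(
      variable = label,
      remaining_mean = grp_mean(rem[[v]]), remaining_sd = grp_sd(rem[[v]]),
      emerged_mean = grp_mean(eme[[v]]), emerged_sd = grp_sd(eme[[v]]),
      statistic = t$statistic, p_raw = t$p_value
    )
  }) |> purrr::list_rbind()

  endpoint_vars <- c(walk = "Functional walking ability",
                     return_home = "Return home")
  endpoints <- purrr::imap(endpoint_vars, function(label, v) {
    r <- rem[[v]][!is.na(rem[[v]])]
    e <- eme[[v]][!is.na(eme[[v]])]
    tab <- rbind(c(sum(r == "Yes"), sum(r == "No")),
                 c(sum(e == "Yes"), sum(e == "No")))
    p <- if (any(rowSums(tab) == 0)) NA_real_ else fisher.test(tab)$p.value
    tibble(
      variable = label,
      remaining_yes = sum(r == "Yes"), remaining_n = length(r),
      emerged_yes = sum(e == "Yes"), emerged_n = length(e),
      p_raw = p
    )
  }) |> purrr::list_rbind()

  fam <- holm_adjust(c(continuous$p_raw, endpoints$p_raw))
  continuous$p_holm <- fam[seq_len(nrow(continuous))]
  endpoints$p_holm <- fam[nrow(continuous) + seq_len(nrow(endpoints))]

  # "Midbrain" aggregates the brainstem tokens (mesencephalon and pons).
  region_groups <- list(
    Frontal = "F", Temporal = "T", Parietal = "P", Occipital = "O",
    `Basal Ganglia` = "BG", Midbrain = c("Mes", "Pons"),
    `Diffuse axonal injury` = "DAI"
  )
  sites <- lesion_sites(cohort)
  lesions <- purrr::imap(region_groups, function(codes, label) {
    ids <- unique(sites$patient[sites$region %in% codes])
    tibble(
      region = label,
      remaining_n = sum(rem$patient %in% ids),
      remaining_pct = sum(rem$patient %in% ids) / nrow(rem),
      emerged_n = sum(eme$patient %in% ids),
      emerged_pct = sum(eme$patient %in% ids) / nrow(eme)
    )
  }) |> purrr::list_rbind()

  etiology <- cohort |>
    mutate(category = map_etiology(.data$etiology)) |>
    count(.data$category, .data$primary_class) |>
    tidyr::pivot_wider(names_from = "primary_class", values_from = "n",
                       values_fill = 0L)
  for (cc in c("remaining", "emerged")) {
    if (!cc %in% names(etiology)) etiology[[cc]] <- 0L
  }
  etiology <- etiology |>
    mutate(remaining_pct = .data$remaining / nrow(rem),
           emerged_pct = .data$emerged / nrow(eme))

  list(
    groups = groups,
    n = tibble(remaining = nrow(rem), emerged = nrow(eme), total = n_all),
    continuous = continuous,
    lesions = lesions,
    etiology = etiology,
    endpoints = endpoints
  )
}

#' Correlation between assessment count and care duration
#'
#' Convenience helper for exploring the association between the number of
#' CRS-R evaluations and a duration column of the cohort table; the
#' duration column and the correlation method are configurable.
#'
#' @param cohort Cohort tibble.
#' @param duration One of the cohort's duration columns (default
#'   `rehab_duration`).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate` and `p_value`.
#' @export
crsr_count_correlation <- function(cohort, duration = "rehab_duration",
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!duration %in% names(cohort)) {
    abort(sprintf("No column `%s` in cohort.", duration))
  }
  ct <- stats::cor.test(cohort$n_crsr, cohort[[duration]], method = method,
                        exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}
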