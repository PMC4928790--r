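#' End-to-end analysis runs
#'
#' Thin orchestration over the package's analysis stages, mirroring the
#' three statistical steps of the acute-phase outcome-prediction pipeline:
#' `run_descriptives()` produces the descriptive group comparison;
#' `run_prediction()` the first-assessment prediction battery (raw CRS-R
#' subscores, MBT items with performance metrics, and the MBT-weighted
#' increment sweep with critical deltas); `run_glm()` the longitudinal
#' modelling outputs (combinatorial coefficient tests, group curves,
#' discrimination times, cutoff-attainment times); `run_simulation()`
#' generates a cohort from a scenario name or config. Each returns plain
#' tibbles (in a named list) that can be written with
#' [write_result_table()].
#'
#' @param cohort Cohort tibble.
#' @param assessments Long assessment tibble with `mbt_*` columns on the
#'   first-assessment rows.
#' @param alpha Significance level.
#' @param deltas Increment grid for the sweep.
#' @param window Analysis day window for the longitudinal model.
#' @param grid_step Day-grid step for group curves.
#' @param subsets Degree subsets for the combinatorial tests (default:
#'   baseline+slope only, the subset of clinical interest; pass
#'   `all_degree_subsets()` for the full battery).
#' @param curve_degrees Degrees used for the group-curve fits (default
#'   full cubic).
#' @param curve_window Day range for curve evaluation (default: window
#'   start to the last observed assessment day).
#' @param lilliefors_nsim,seed Monte-Carlo settings for the normality
#'   check.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_descriptives <- function(cohort) {
  doc_descriptives(cohort)
}

#' @rdname pipeline
#' @export
run_prediction <- function(cohort, assessments, alpha = 0.05,
                           deltas = seq(0.1, 0.9, by = 0.1)) {
  cohort <- classify_outcome(cohort)
  comparisons <- doc_comparisons(cohort)
  first <- first_assessments(assessments)
  if (!all(mbt_cols() %in% names(first)) || anyNA(first[mbt_cols()])) {
    abort(paste("MBT columns are missing from the first assessments;",
                "the MBT prediction and the weighted sweep cannot run."))
  }
  list(
    raw = crsr_prediction(first, comparisons),
    mbt = mbt_prediction(first, comparisons, alpha = alpha),
    sweep = increment_sweep(first, comparisons, deltas = deltas,
                            alpha = alpha),
    comparisons = select(comparisons, "comparison", "n_lhs", "n_rhs",
                         "degenerate")
  )
}

#' @rdname pipeline
#' @export
run_glm <- function(cohort, assessments, window = c(0, 100), grid_step = 1,
                    subsets = list(c(0, 1)), curve_degrees = 0:3,
                    curve_window = NULL, alpha = 0.05,
                    lilliefors_nsim = 0, seed = NULL) {
  cohort <- classify_outcome(cohort)
  counts <- assessments |> count(.data$patient)
  too_few <- counts$patient[counts$n < 3]
  if (length(too_few) > 0) {
    warn(sprintf("Excluding %d patient(s) with fewer than three assessments: %s.",
                 length(too_few), paste(too_few, collapse = ", ")))
    assessments <- filter(assessments, !.data$patient %in% too_few)
    cohort <- filter(cohort, !.data$patient %in% too_few)
  }
  comparisons <- doc_comparisons(cohort)
  basis <- poly_basis(window = window)
  tests <- coef_group_tests(assessments, comparisons, basis,
                            subsets = subsets,
                            lilliefors_nsim = lilliefors_nsim, seed = seed)
  fits <- fit_trajectories(assessments, basis, degrees = curve_degrees,
                           cap_by_n = TRUE)
  groups <- split(cohort$patient, cohort$primary_class)
  single_class <- length(groups) < 2
  # Evaluate curves only where the fits interpolate for most patients:
  # polynomial fits extrapolate badly past a patient's last assessment, so
  # the default upper bound is the smaller group-wise median last day.
  if (is.null(curve_window)) {
    last_days <- assessments |>
      group_by(.data$patient) |>
      summarise(last = max(.data$day)) |>
      left_join(select(cohort, "patient", "primary_class"), by = "patient")
    upper <- min(tapply(last_days$last, last_days$primary_class, stats::median))
    curve_window <- c(window[1], upper)
  }
  curves <- group_curves(fits, groups, grid_step = grid_step,
                         curve_window = curve_window)
  disc <- if (single_class) {
    tibble(subscale = crsr_subscales(), day = NA_real_)
  } else {
    discrimination_time(curves)
  }
  cutoffs <- bind_rows(cutoff_attainment_time(curves, "motor"),
                       cutoff_attainment_time(curves, "communication"))
  list(tests = tests, curves = curves, discrimination = disc,
       cutoffs = cutoffs)
}

#' @rdname pipeline
#' @param scenario Scenario name (see [doc_scenario()]) or a
#'   [doc_generator_config()].
#' @export
run_simulation <- function(scenario, seed) {
  config <- if (inherits(scenario, "doc_generator_config")) scenario else
    doc_scenario(scenario)
  simulate_cohort(config, seed = seed)
}

#' Write pipeline results to a directory
#'
#' Writes every tibble of a `run_*()` result list as a deterministically
#' formatted CSV (see [write_result_table()]) named after its list entry.
#' Existing files are not overwritten unless `force = TRUE`.
#'
#' @param results Named list of tibbles (nested lists are flattened with
#'   `.`-joined names).
#' @param dir Output directory (created if absent).
#' @param force Overwrite existing files.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir, force = FALSE) {
  flat <- list()
  flatten <- function(x, prefix = "") {
    for (nm in names(x)) {
      full <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      if (is.data.frame(x[[nm]])) {
        flat[[full]] <<- x[[nm]]
      } else if (is.list(x[[nm]])) {
        flatten(x[[nm]], full)
      }
    }
  }
  flatten(results)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (nm in names(flat)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(path) && !force) {
      abort(sprintf("Output `%s` exists; use force = TRUE to overwrite.", path))
    }
    df <- flat[[nm]]
    df <- df[!vapply(df, is.list, logical(1))]
    write_result_table(df, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
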