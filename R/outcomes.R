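#' Classify discharge outcome into primary classes and subclasses
#'
#' Patients are divided into two primary classes - those who emerged from
#' DOC by discharge (class 1) and those remaining in DOC (class 2) - and
#' six subclasses crossing the initial diagnosis with the discharge state:
#' (a) UWS to non-DOC, (b) MCS to non-DOC, (c) UWS remaining UWS, (d) UWS
#' to MCS, (e) MCS worsening to UWS, (f) MCS remaining MCS.
#'
#' @param cohort Data frame with columns `diagnosis` (initial diagnosis,
#'   `"UWS"` or `"MCS"`) and `outcome` (discharge state, `"Non DOC"`,
#'   `"MCS"` or `"UWS"`).
#' @return The cohort tibble with `subclass` (`"a"`..`"f"`) and
#'   `primary_class` (`"emerged"` / `"remaining"`) columns appended.
#' @examples
#' classify_outcome(data.frame(diagnosis = "UWS", outcome = "Non DOC"))
#' @export
classify_outcome <- function(cohort) {
  if (!all(c("diagnosis", "outcome") %in% names(cohort))) {
    abort("`cohort` must have `diagnosis` and `outcome` columns.")
  }
  dx <- as.character(cohort$diagnosis)
  out <- as.character(cohort$outcome)
  bad_dx <- !dx %in% c("UWS", "MCS")
  if (any(bad_dx)) {
    abort(sprintf("Invalid initial diagnosis in row(s) %s (must be UWS or MCS).",
                  paste(which(bad_dx), collapse = ", ")))
  }
  bad_out <- !out %in% c("Non DOC", "NonDOC", "MCS", "UWS")
  if (any(bad_out)) {
    abort(sprintf("Invalid outcome in row(s) %s (must be Non DOC, MCS or UWS).",
                  paste(which(bad_out), collapse = ", ")))
  }
  out[out == "NonDOC"] <- "Non DOC"
  subclass <- dplyr::case_when(
    dx == "UWS" & out == "Non DOC" ~ "a",
    dx == "MCS" & out == "Non DOC" ~ "b",
    dx == "UWS" & out == "UWS" ~ "c",
    dx == "UWS" & out == "MCS" ~ "d",
    dx == "MCS" & out == "UWS" ~ "e",
    dx == "MCS" & out == "MCS" ~ "f"
  )
  cohort |>
    as_tibble() |>
    mutate(
      subclass = subclass,
      primary_class = ifelse(subclass %in% c("a", "b"), "emerged", "remaining")
    )
}

#' Enumerate the nine outcome comparisons
#'
#' Returns the fixed battery of nine group comparisons: the global
#' class 1 vs class 2 contrast, four contrasts within the UWS patients
#' (a vs c, a vs d, c vs d, a vs c+d) and four within the MCS patients
#' (b vs e, b vs f, e vs f, b vs e+f). The left-hand side is always the
#' better-outcome group. Comparisons with an empty side are retained and
#' flagged `degenerate`, never dropped.
#'
#' @param cohort A classified cohort (see [classify_outcome()]) with a
#'   `patient` identifier column.
#' @return Tibble with one row per comparison: `comparison` label, list
#'   columns `lhs_ids` / `rhs_ids` of patient identifiers, group sizes
#'   `n_lhs` / `n_rhs`, and a `degenerate` flag.
#' @examples
#' doc_comparisons(classify_outcome(doc_cohort()))
#' @export
doc_comparisons <- function(cohort) {
  if (!"subclass" %in% names(cohort)) cohort <- classify_outcome(cohort)
  if (!"patient" %in% names(cohort)) {
    abort("`cohort` must have a `patient` identifier column.")
  }
  ids <- function(...) {
    cl <- c(...)
    cohort$patient[cohort$subclass %in% cl]
  }
  spec <- list(
    list("class1 vs class2", c("a", "b"), c("c", "d", "e", "f")),
    list("a vs c", "a", "c"),
    list("a vs d", "a", "d"),
    list("c vs d", "c", "d"),
    list("a vs c+d", "a", c("c", "d")),
    list("b vs e", "b", "e"),
    list("b vs f", "b", "f"),
    list("e vs f", "e", "f"),
    list("b vs e+f", "b", c("e", "f"))
  )
  purrr::map(spec, function(cmp) {
    lhs <- ids(cmp[[2]])
    rhs <- ids(cmp[[3]])
    tibble(
      comparison = cmp[[1]],
      lhs_ids = list(lhs), rhs_ids = list(rhs),
      n_lhs = length(lhs), n_rhs = length(rhs),
      degenerate = length(lhs) == 0 || length(rhs) == 0
    )
  }) |>
    purrr::list_rbind()
}

# Sizes per subclass; used by descriptives and tests.
subclass_counts <- function(cohort) {
  if (!"subclass" %in% names(cohort)) cohort <- classify_outcome(cohort)
  counts <- table(factor(cohort$subclass, levels = letters[1:6]))
  tibble(subclass = letters[1:6], n = as.integer(counts))
}
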