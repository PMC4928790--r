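cohort_columns <- c(
  "patient", "age", "diagnosis", "lesions", "etiology",
  "delay_first_crsr", "n_crsr", "delay_last_crsr", "rehab_duration",
  "outcome", "return_home", "walk"
)

#' Read a cohort table
#'
#' Reads a delimited per-patient cohort table (comma- or tab-separated,
#' sniffed from the header line) with one row per patient: identifier,
#' age, initial diagnosis, lesion-localisation string, aetiology, delay
#' from insult to first CRS-R, number of CRS-R assessments, delay from
#' insult to last CRS-R, rehabilitation duration, discharge outcome, and
#' the return-home and walking secondary endpoints. `NA` is encoded as the
#' literal string `NA`. Lesion strings are kept verbatim; parse them with
#' [parse_lesions()].
#'
#' @param path Path to a delimited file, or `"-"` for standard input.
#' @return A tibble with typed columns in canonical order (plus any extra
#'   columns such as `etiology_raw`).
#' @seealso [doc_cohort()] for the packaged cohort.
#' @export
read_cohort <- function(path) {
  con_path <- if (identical(path, "-")) stdin() else path
  first <- tryCatch(readLines(con_path, n = 1L), error = function(e) character())
  if (length(first) == 0 || !nzchar(first)) {
    abort(sprintf(
      "Empty cohort file; expected a header with columns: %s.",
      paste(cohort_columns, collapse = ", ")
    ))
  }
  delim <- if (stringr::str_count(first, "\t") >
               stringr::str_count(first, ",")) "\t" else ","
  raw <- readr::read_delim(
    if (identical(path, "-")) I(paste(c(first, readLines(stdin())), collapse = "\n")) else path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = "NA", trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Cohort file is missing column(s): %s.\nExpected header: %s.",
      paste(missing_cols, collapse = ", "),
      paste(cohort_columns, collapse = ", ")
    ))
  }
  num_cols <- c("age", "delay_first_crsr", "n_crsr", "delay_last_crsr",
                "rehab_duration")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !is.na(raw[[cc]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric `%s` value at data line %s.", cc,
                    paste(bad, collapse = ", ")))
    }
    raw[[cc]] <- v
  }
  check_levels <- function(col, levels) {
    bad <- which(!is.na(raw[[col]]) & !raw[[col]] %in% levels)
    if (length(bad) > 0) {
      abort(sprintf(
        "Invalid `%s` value %s at data line %s (allowed: %s).",
        col, paste(unique(raw[[col]][bad]), collapse = ", "),
        paste(bad, collapse = ", "), paste(levels, collapse = ", ")
      ))
    }
  }
  check_levels("diagnosis", c("UWS", "MCS"))
  check_levels("outcome", c("Non DOC", "MCS", "UWS"))
  check_levels("return_home", c("Yes", "No"))
  check_levels("walk", c("Yes", "No"))
  raw |>
    relocate(dplyr::all_of(cohort_columns))
}

#' The packaged acute-DOC cohort
#'
#' The 33-patient acute neurorehabilitation cohort shipped with the
#' package: 20 patients initially in UWS and 13 in MCS, with demographics,
#' lesion localisation, aetiology, assessment-schedule summaries, discharge
#' outcome, and the walking/return-home secondary endpoints. One
#' aetiology entry with a garbled source value carries the normalised
#' label in `etiology` and the original string in `etiology_raw`.
#'
#' @return Cohort tibble (see [read_cohort()] for the schema).
#' @examples
#' doc_cohort()
#' @export
doc_cohort <- function() {
  read_cohort(system.file("extdata", "table3_cohort.csv",
                          package = "mbtcrsr", mustWork = TRUE))
}

lesion_regions <- c("F", "T", "P", "O", "BG", "Mes", "Pons", "DAI")

#' Parse lesion-localisation strings
#'
#' Lesion strings are comma-separated tokens; cortical/subcortical region
#' codes (F frontal, T temporal, P parietal, O occipital, BG basal
#' ganglia) carry a laterality prefix `r`/`l`/`b` (right/left/bilateral),
#' while `Mes` (mesencephalon), `Pons` and `DAI` (diffuse axonal injury)
#' appear unprefixed.
#'
#' @param x Character vector of lesion strings (`NA` or `""` give an empty
#'   set).
#' @return A list (one element per input) of tibbles with columns `region`
#'   and `laterality` (`"right"`, `"left"`, `"bilateral"` or `"none"`).
#' @examples
#' parse_lesions("bF, rT")
#' @export
parse_lesions <- function(x) {
  purrr::map(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      return(tibble(region = character(), laterality = character()))
    }
    tokens <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    rows <- purrr::map(tokens, function(tok) {
      if (tok %in% c("Mes", "Pons", "DAI")) {
        return(tibble(region = tok, laterality = "none"))
      }
      side <- substr(tok, 1, 1)
      region <- substr(tok, 2, nchar(tok))
      if (side %in% c("r", "l", "b") && region %in% c("F", "T", "P", "O", "BG")) {
        lat <- c(r = "right", l = "left", b = "bilateral")[[side]]
        return(tibble(region = region, laterality = lat))
      }
      abort(sprintf("Unknown lesion token `%s` in `%s`.", tok, s))
    })
    purrr::list_rbind(rows) |> distinct()
  })
}

# Long per-patient lesion-site table.
lesion_sites <- function(cohort) {
  parsed <- parse_lesions(cohort$lesions)
  purrr::map2(cohort$patient, parsed, function(id, df) {
    if (nrow(df) == 0) return(NULL)
    mutate(df, patient = id, .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Aetiology category lookup
#'
#' Editable mapping from the cohort's aetiology strings to the summary
#' categories used in the descriptive comparison (ischemic stroke,
#' haemorrhagic stroke, intraventricular haemorrhage, traumatic brain
#' injury, ruptured aneurysm, anoxia, infection). The convention: a
#' ruptured-aneurysm parenthetical overrides the stroke type, a combined
#' "IS, IVH" counts under intraventricular haemorrhage, and other combined
#' strings count under their first-listed aetiology. Strings absent from
#' the table fall back to the category `"Other"`.
#'
#' @return Tibble with columns `etiology` and `category`.
#' @export
etiology_categories <- function() {
  readr::read_csv(system.file("extdata", "etiology_categories.csv",
                              package = "mbtcrsr", mustWork = TRUE),
                  col_types = "cc", progress = FALSE)
}

map_etiology <- function(etiology, lookup = etiology_categories()) {
  idx <- match(etiology, lookup$etiology)
  ifelse(is.na(idx), "Other", lookup$category[idx])
}

#' Write a result table with deterministic formatting
#'
#' Writes any result tibble as CSV with a fixed column order (as given),
#' `NA` encoded as literal `NA`, and fixed decimal formatting: columns
#' whose names contain `p_` or end in `p` hold p-values and are written
#' with 3 decimals, other non-integer numeric columns with 2 decimals
#' (round-half-even). Repeated runs on the same input are byte-identical.
#'
#' @param x Data frame to write.
#' @param path Output path, or `"-"` for standard output.
#' @return Invisibly, the formatted data frame as written.
#' @export
write_result_table <- function(x, path) {
  is_p <- grepl("(^|_)p($|_)|p_value|pvalue", names(x))
  out <- x
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (is.numeric(v) && !is.integer(v)) {
      digits <- if (is_p[j]) 3L else 2L
      if (all(is.na(v) | v == round(v)) && !is_p[j]) next
      out[[j]] <- ifelse(is.na(v), NA_character_,
                         formatC(round(v, digits), format = "f", digits = digits))
    }
  }
  con <- if (identical(path, "-")) stdout() else path
  readr::write_csv(out, con, na = "NA", progress = FALSE)
  invisible(out)
}
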