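#' Orthonormal polynomial basis for trajectory modelling
#'
#' Builds the canonical regressor set for longitudinal CRS-R modelling:
#' monomials of degree 0..`degree` on the analysis day window, mapped to
#' the canonical interval \[-1, 1\] and orthonormalized over a uniform
#' reference grid (QR factorisation of the grid Vandermonde matrix, which
#' is numerically equivalent to Gram-Schmidt). Because the basis is fixed
#' by the window - not by any patient's visit days - coefficients are
#' comparable across patients; per-patient design matrices evaluate the
#' same canonical polynomials at the patient's own days.
#'
#' @param window Analysis day window, length-2 numeric (default
#'   `c(0, 100)` days).
#' @param degree Maximum polynomial degree (default 3: constant, linear,
#'   quadratic, cubic).
#' @param grid_n Reference grid size (default 101; must exceed `degree`).
#' @return An object of class `poly_basis` holding the monomial
#'   coefficients of each basis polynomial, the window, the reference
#'   grid, and `ortho_error`, the orthonormality certificate
#'   max |G'G - I| on the grid.
#' @examples
#' b <- poly_basis()
#' b$ortho_error < 1e-8
#' @export
poly_basis <- function(window = c(0, 100), degree = 3, grid_n = 101) {
  if (length(window) != 2 || diff(window) <= 0) {
    abort("`window` must be an increasing pair of days.")
  }
  if (grid_n < degree + 1) abort("`grid_n` must be at least degree + 1.")
  grid <- seq(window[1], window[2], length.out = grid_n)
  u <- 2 * (grid - window[1]) / diff(window) - 1
  v <- outer(u, 0:degree, `^`)
  qr_v <- qr(v)
  q <- qr.Q(qr_v)
  r <- qr.R(qr_v)
  # Fix signs so each basis polynomial has a positive leading coefficient.
  signs <- sign(diag(r))
  signs[signs == 0] <- 1
  coefs <- backsolve(r, diag(signs, nrow = length(signs)))
  g <- v %*% coefs
  structure(
    list(window = window, degree = degree, grid = grid, coefs = coefs,
         ortho_error = max(abs(crossprod(g) - diag(degree + 1)))),
    class = "poly_basis"
  )
}

#' Evaluate basis polynomials at given days
#'
#' @param basis A [poly_basis()] object.
#' @param days Numeric vector of days (within or near the window; the
#'   polynomials extrapolate smoothly).
#' @param degrees Degrees to evaluate (default all).
#' @return Matrix with one row per day and one column per degree.
#' @export
eval_basis <- function(basis, days, degrees = 0:basis$degree) {
  stopifnot(inherits(basis, "poly_basis"))
  if (!all(degrees %in% 0:basis$degree)) {
    abort("`degrees` outside the basis degree range.")
  }
  u <- 2 * (days - basis$window[1]) / diff(basis$window) - 1
  v <- outer(u, 0:basis$degree, `^`)
  (v %*% basis$coefs)[, degrees + 1, drop = FALSE]
}

#' Fit per-patient trajectory models on the polynomial basis
#'
#' Fits, by ordinary least squares, each patient's longitudinal score on
#' each CRS-R subscale against the basis polynomials of the chosen
#' degrees evaluated at the patient's assessment days (an identity-link
#' GLM; ordinal scores are treated as numeric). When the design is rank
#' deficient - e.g. more regressors than assessments - the minimum-norm
#' least-squares solution is returned and flagged.
#'
#' @param assessments Long tibble: `patient`, `day`, and the five
#'   subscale columns.
#' @param basis A [poly_basis()] object.
#' @param degrees Regressor subset, a subset of `0:basis$degree`
#'   (default all).
#' @param cap_by_n Drop the highest degrees for patients with few
#'   assessments so that at least one residual degree of freedom remains
#'   (at most `n_obs - 1` regressors); recommended when the fits are used
#'   for curve reconstruction, where interpolating fits extrapolate
#'   wildly. Default `FALSE` (the requested subset is used as-is, with a
#'   minimum-norm solution when rank deficient).
#' @return A `doc_fits` tibble: one row per (patient, subscale) with a
#'   `coefs` list column (named by degree), `rss`, `n_obs` and
#'   `rank_deficient`; the basis and degrees are carried as attributes.
#' @export
fit_trajectories <- function(assessments, basis, degrees = 0:basis$degree,
                             cap_by_n = FALSE) {
  # real-valued scores are allowed: MBT-weighted profiles are fractional
  validate_scores(assessments, integer = FALSE)
  if (!all(c("patient", "day") %in% names(assessments))) {
    abort("`assessments` must have `patient` and `day` columns.")
  }
  degrees <- sort(unique(as.integer(degrees)))
  subs <- crsr_subscales()
  idx <- split(seq_len(nrow(assessments)), assessments$patient)
  score_mat <- as.matrix(assessments[subs])
  fits <- purrr::map(idx, function(ii) {
    days <- assessments$day[ii]
    ord <- order(days)
    ii <- ii[ord]
    days <- days[ord]
    pid <- assessments$patient[ii[1]]
    if (anyDuplicated(days) > 0) {
      abort(sprintf("Duplicate assessment day for patient %s.", pid))
    }
    deg_i <- if (cap_by_n) {
      degrees[seq_len(min(length(degrees), max(1, length(days) - 1)))]
    } else {
      degrees
    }
    x <- eval_basis(basis, days, deg_i)
    y <- score_mat[ii, , drop = FALSE]
    # One SVD per patient solves all five subscales (minimum-norm when
    # rank deficient).
    sv <- svd(x)
    keep <- sv$d > 1e-10 * max(sv$d, 0)
    rank <- sum(keep)
    beta <- if (rank == 0) {
      matrix(0, ncol(x), ncol(y))
    } else {
      sv$v[, keep, drop = FALSE] %*%
        (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep])
    }
    rss <- colSums((y - x %*% beta)^2)
    tibble(
      patient = pid, subscale = subs,
      coefs = lapply(seq_along(subs), function(j) {
        setNames(beta[, j], paste0("d", deg_i))
      }),
      rss = unname(rss), n_obs = length(days),
      rank_deficient = rank < ncol(x)
    )
  }) |>
    purrr::list_rbind()
  structure(fits, class = c("doc_fits", class(fits)),
            basis = basis, degrees = degrees)
}

# Minimum-norm least squares via SVD; tolerance relative to largest
# singular value.
min_norm_lstsq <- function(x, y, tol = 1e-10) {
  sv <- svd(x)
  keep <- sv$d > tol * max(sv$d, 0)
  rank <- sum(keep)
  beta <- if (rank == 0) {
    rep(0, ncol(x))
  } else {
    sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
  }
  fitted <- x %*% beta
  list(beta = drop(beta), rss = sum((y - fitted)^2), rank = rank)
}

#' Tidy per-patient trajectory fits
#'
#' @param x A `doc_fits` object from [fit_trajectories()].
#' @param ... Unused.
#' @return Long tibble: `patient`, `subscale`, `degree`, `estimate`.
#' @export
tidy.doc_fits <- function(x, ...) {
  tibble(
    patient = rep(x$patient, lengths(x$coefs)),
    subscale = rep(x$subscale, lengths(x$coefs)),
    degree = as.integer(sub("^d", "", unlist(lapply(x$coefs, names)))),
    estimate = unlist(x$coefs, use.names = FALSE)
  )
}

#' One-line summary of a trajectory fit set
#'
#' @param x A `doc_fits` object.
#' @param ... Unused.
#' @return One-row tibble: number of patients, subscales, regressors,
#'   total residual sum of squares, and how many fits were rank
#'   deficient.
#' @export
glance.doc_fits <- function(x, ...) {
  tibble(
    n_patients = dplyr::n_distinct(x$patient),
    n_subscales = dplyr::n_distinct(x$subscale),
    n_regressors = length(attr(x, "degrees")),
    total_rss = sum(x$rss),
    n_rank_deficient = sum(x$rank_deficient)
  )
}

#' Generic tidy/glance (broom-style)
#'
#' @param x Object to tidy or summarise.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' All non-empty polynomial degree subsets
#'
#' The 15 non-empty subsets of degrees 0..3 (for the default cubic model)
#' used by the combinatorial regressor selection.
#'
#' @param max_degree Maximum degree (default 3).
#' @return List of integer vectors.
#' @export
all_degree_subsets <- function(max_degree = 3) {
  unlist(lapply(1:(max_degree + 1), function(k) {
    asplit(combn(0:max_degree, k), 2)
  }), recursive = FALSE)
}

#' Combinatorial regressor-subset tests on trajectory coefficients
#'
#' Implements the combinatorial modelling step: for every non-empty subset
#' of polynomial degrees, each patient's longitudinal subscale data are
#' refit on that subset, and the per-degree coefficients are compared
#' between the two groups of a comparison. For each (subset, subscale,
#' degree) the function reports a Lilliefors normality check on the pooled
#' coefficients, one-sample two-tailed t-tests of each group's
#' coefficients against zero, and a two-sample Welch t-test between
#' groups; Welch p-values are Holm-corrected across the five subscales
#' within a (comparison, subset, degree) family.
#'
#' @param assessments Long assessment tibble (see [fit_trajectories()]).
#' @param comparisons Comparison table from [doc_comparisons()], or a
#'   subset of its rows.
#' @param basis A [poly_basis()] object.
#' @param subsets List of degree subsets (default: all 15 non-empty
#'   subsets of 0:3).
#' @param lilliefors_nsim Monte-Carlo replicates for the normality check
#'   (default 2000); 0 skips the check.
#' @param seed Seed for the Lilliefors Monte-Carlo null.
#' @return Long tibble with one row per (comparison, subset, subscale,
#'   degree): group coefficient means, one-sample t p-values per group,
#'   Welch `p_raw`/`p_holm`, Lilliefors statistic and p-value, and flags
#'   for small groups or rank-deficient fits.
#' @export
coef_group_tests <- function(assessments, comparisons, basis,
                             subsets = all_degree_subsets(basis$degree),
                             lilliefors_nsim = 2000, seed = NULL) {
  rows <- purrr::map(seq_along(subsets), function(si) {
    degrees <- subsets[[si]]
    fits <- fit_trajectories(assessments, basis, degrees)
    td <- tidy(fits)
    flagged <- any(fits$rank_deficient)
    purrr::pmap(comparisons, function(comparison, lhs_ids, rhs_ids,
                                      n_lhs, n_rhs, degenerate, ...) {
      if (degenerate || n_lhs < 2 || n_rhs < 2) {
        return(tidyr::expand_grid(
          comparison = comparison,
          subset = paste(degrees, collapse = "+"),
          subscale = crsr_subscales(), degree = degrees,
          lhs_mean = NA_real_, rhs_mean = NA_real_,
          p_lhs_zero = NA_real_, p_rhs_zero = NA_real_,
          p_raw = NA_real_,
          lilliefors_stat = NA_real_, lilliefors_p = NA_real_,
          flagged = TRUE
        ))
      }
      purrr::map(crsr_subscales(), function(s) {
        purrr::map(degrees, function(d) {
          cl <- td$estimate[td$subscale == s & td$degree == d &
                              td$patient %in% lhs_ids]
          cr <- td$estimate[td$subscale == s & td$degree == d &
                              td$patient %in% rhs_ids]
          welch <- safe_t(cl, cr)
          lil <- if (lilliefors_nsim > 0 && length(c(cl, cr)) >= 4 &&
                     sd(c(cl, cr)) > 0) {
            lilliefors_test(c(cl, cr), nsim = lilliefors_nsim, seed = seed)
          } else {
            list(statistic = NA_real_, p_value = NA_real_)
          }
          tibble(
            comparison = comparison,
            subset = paste(degrees, collapse = "+"),
            subscale = s, degree = d,
            lhs_mean = mean(cl), rhs_mean = mean(cr),
            p_lhs_zero = safe_t(cl)$p.value,
            p_rhs_zero = safe_t(cr)$p.value,
            p_raw = welch$p.value,
            lilliefors_stat = lil$statistic, lilliefors_p = lil$p_value,
            flagged = flagged
          )
        }) |> purrr::list_rbind()
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(rows) |>
    group_by(.data$comparison, .data$subset, .data$degree) |>
    mutate(p_holm = holm_adjust(.data$p_raw)) |>
    ungroup() |>
    relocate("p_holm", .after = "p_raw")
}

# t.test that degrades to NA p-value for degenerate samples.
safe_t <- function(x, y = NULL) {
  res <- tryCatch(
    if (is.null(y)) t.test(x, mu = 0) else t.test(x, y),
    error = function(e) list(p.value = NA_real_)
  )
  res
}

#' Group mean trajectory curves with standard-error bands
#'
#' Reconstructs each patient's fitted trajectory on a regular day grid and
#' summarises each group and subscale by the across-patient mean curve
#' with its standard-error-of-the-mean band.
#'
#' @param fits A `doc_fits` object from [fit_trajectories()].
#' @param groups Named list of patient-identifier vectors, one per group
#'   (e.g. `list(emerged = ..., remaining = ...)`).
#' @param grid_step Day-grid resolution (default 1 day).
#' @param curve_window Day range over which curves are evaluated (default
#'   the basis window; in analyses this is usually restricted to the
#'   observed follow-up range, since polynomial fits extrapolate poorly).
#' @return A `doc_curves` tibble: `group`, `subscale`, `day`, `mean`,
#'   `sem`, `n`; the grid step is carried as an attribute.
#' @export
group_curves <- function(fits, groups, grid_step = 1, curve_window = NULL) {
  stopifnot(inherits(fits, "doc_fits"))
  basis <- attr(fits, "basis")
  curve_window <- curve_window %||% basis$window
  grid <- seq(curve_window[1], curve_window[2], by = grid_step)
  g_all <- eval_basis(basis, grid)
  colnames(g_all) <- paste0("d", 0:basis$degree)
  rows <- purrr::imap(groups, function(ids, gname) {
    purrr::map(crsr_subscales(), function(s) {
      sub <- fits[fits$subscale == s & fits$patient %in% ids, ]
      if (nrow(sub) == 0) {
        return(tibble(group = gname, subscale = s, day = grid,
                      mean = NA_real_, sem = NA_real_, n = 0L))
      }
      curves <- vapply(sub$coefs, function(b) {
        drop(g_all[, names(b), drop = FALSE] %*% b)
      }, numeric(length(grid)))
      curves <- matrix(curves, nrow = length(grid))
      # Polynomial fits can stray below zero where data are sparse (early
      # days before most first assessments); scores cannot, so the mean
      # curve is floored at zero.
      m <- pmax(rowMeans(curves), 0)
      sem <- if (ncol(curves) > 1) {
        apply(curves, 1, sd) / sqrt(ncol(curves))
      } else {
        rep(0, length(grid))
      }
      tibble(group = gname, subscale = s, day = grid, mean = m, sem = sem,
             n = ncol(curves))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(rows, class = c("doc_curves", class(rows)), grid_step = grid_step)
}

#' Earliest persistent separation of two group bands
#'
#' The discrimination time for a subscale is the earliest grid day from
#' which the two groups' mean +/- SEM bands are disjoint at every later
#' day (a persistence rule: a transient touch resets the clock). `NA`
#' when the bands never separate or still overlap at the end of the
#' window.
#'
#' @param curves A `doc_curves` object holding exactly two groups on a
#'   common grid.
#' @return Tibble with `subscale` and `day` (NA if never).
#' @export
discrimination_time <- function(curves) {
  stopifnot(inherits(curves, "doc_curves"))
  gs <- unique(curves$group)
  if (length(gs) != 2) abort("`curves` must hold exactly two groups.")
  purrr::map(unique(curves$subscale), function(s) {
    a <- curves[curves$group == gs[1] & curves$subscale == s, ]
    b <- curves[curves$group == gs[2] & curves$subscale == s, ]
    if (!identical(a$day, b$day)) abort("Group curves are on different grids.")
    if (nrow(a) == 0 || anyNA(a$mean) || anyNA(b$mean)) {
      return(tibble(subscale = s, day = NA_real_))
    }
    disjoint <- (a$mean - a$sem > b$mean + b$sem) |
      (b$mean - b$sem > a$mean + a$sem)
    day <- persistent_onset(a$day, disjoint)
    tibble(subscale = s, day = day)
  }) |> purrr::list_rbind()
}

# First day from which `flag` stays TRUE through the end; NA if none.
persistent_onset <- function(day, flag) {
  if (length(flag) == 0 || !flag[length(flag)]) return(NA_real_)
  last_false <- max(c(0L, which(!flag)))
  if (last_false == length(flag)) return(NA_real_)
  day[last_false + 1L]
}

#' Day at which a group mean curve attains a diagnostic cutoff
#'
#' Emergence from DOC is diagnosed at motor score 6 (functional object
#' use) or communication score 2 (functional communication). For a group
#' curve of one of those subscales, returns the earliest grid day at
#' which the mean curve reaches the cutoff, per group; `NA` when never
#' attained.
#'
#' @param curves A `doc_curves` object.
#' @param subscale `"motor"` (cutoff 6) or `"communication"` (cutoff 2).
#' @return Tibble with `group`, `subscale`, `day`.
#' @export
cutoff_attainment_time <- function(curves,
                                   subscale = c("motor", "communication")) {
  stopifnot(inherits(curves, "doc_curves"))
  subscale <- match.arg(subscale)
  cutoff <- c(motor = 6, communication = 2)[[subscale]]
  curves |>
    filter(.data$subscale == !!subscale) |>
    group_by(.data$group, .data$subscale) |>
    summarise(
      day = if (any(!is.na(.data$mean) & .data$mean >= cutoff)) {
        min(.data$day[.data$mean >= cutoff], na.rm = TRUE)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Plot group trajectory curves
#'
#' @param object A `doc_curves` object.
#' @param ... Unused.
#' @return A ggplot: mean curves (solid) with SEM bands (ribbon), one
#'   facet per subscale.
#' @export
autoplot.doc_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$day, y = .data$mean, colour = .data$group, fill = .data$group
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~subscale, scales = "free_y") +
    ggplot2::labs(x = "Days since insult", y = "CRS-R subscale score",
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
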