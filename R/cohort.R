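#' Pool per-subject parameters into a cohort summary table
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' every numeric parameter, per cohort; missing values are excluded
#' pairwise and the contributing n reported per cell. The SD of a
#' single-subject cell is reported as 0 (with n = 1 visible in the table).
#'
#' @param records Data.frame of subject records with a `cohort` column
#'   (e.g. `"HYA"` / `"OLD"`) and numeric parameter columns.
#' @param cohorts Cohorts to summarize (default: all present). An empty
#'   requested cohort is an error.
#' @param params Parameter columns (default: all numeric columns).
#' @return Long data.frame: `parameter`, `cohort`, `mean`, `sd`, `n`.
#' @export
summarize_cohorts <- function(records, cohorts = NULL, params = NULL) {
  stopifnot(is.data.frame(records), "cohort" %in% names(records))
  if (is.null(cohorts)) cohorts <- unique(as.character(records$cohort))
  if (is.null(params)) {
    params <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  out <- list()
  for (co in cohorts) {
    sub <- records[records$cohort == co, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop(sprintf("summarize_cohorts: cohort '%s' is empty", co),
           call. = FALSE)
    }
    for (p in params) {
      v <- sub[[p]]
      v <- v[!is.na(v)]
      n <- length(v)
      out[[length(out) + 1L]] <- data.frame(
        parameter = p, cohort = co,
        mean = if (n > 0) mean(v) else NA_real_,
        sd = if (n > 1) stats::sd(v) else if (n == 1) 0 else NA_real_,
        n = n
      )
    }
  }
  do.call(rbind, out)
}

#' Check recorded BMI against mass / height^2
#'
#' Consistency check on demographic records: BMI must equal
#' `mass_kg / height_m^2` within a relative tolerance.
#'
#' @param height_m,mass_kg,bmi Numeric vectors (recycled).
#' @param tol Relative tolerance (default 0.005, i.e. 0.5%).
#' @return Logical vector, TRUE where consistent.
#' @export
check_bmi <- function(height_m, mass_kg, bmi, tol = 0.005) {
  expected <- mass_kg / height_m^2
  abs(bmi - expected) / expected <= tol
}

#' Linear trend between hand-grip strength and MVIC torque
#'
#' Ordinary least-squares fit of `y` on `x` plus the Pearson correlation,
#' used to relate the hand-grip surrogate (kg) to the maximal extension
#' torque (Nm).
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs; `x` must vary).
#' @return List: `slope`, `intercept`, `r`, `n`.
#' @export
trend_line <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("trend_line: need at least 3 paired points", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("trend_line: x has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), n = length(x))
}
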