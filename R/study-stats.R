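#' Build paired crossover measurements
#'
#' Assembles matched per-subject measurements under two conditions (e.g. renal
#' clearance after oral vs iv dosing). Subjects with a missing side are
#' dropped before construction and the count reported.
#'
#' @param data Data frame with one row per subject and condition.
#' @param subject,condition,value Column names (strings) holding the subject
#'   label, the condition label and the measurement.
#' @param a,b The two condition labels to pair, in `a - b` order.
#' @param units Optional unit string carried into printing.
#' @return An object of class `paired_measurements`: a tibble with columns
#'   `subject_id`, `x` (condition `a`) and `y` (condition `b`).
#' @export
#' @examples
#' df <- tibble::tibble(
#'   subject_id = rep(1:4, each = 2),
#'   route = rep(c("oral", "iv_bolus"), 4),
#'   clr = c(21, 33, 18, 36, 25, 30, 20, 41)
#' )
#' paired_measurements(df, condition = "route", value = "clr",
#'                     a = "oral", b = "iv_bolus")
paired_measurements <- function(data, subject = "subject_id",
                                condition, value, a, b, units = NULL) {
  stopifnot(is.data.frame(data),
            all(c(subject, condition, value) %in% names(data)))
  wide <- data |>
    dplyr::filter(.data[[condition]] %in% c(a, b)) |>
    dplyr::select(subject_id = dplyr::all_of(subject),
                  cond = dplyr::all_of(condition),
                  val = dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "cond", values_from = "val",
                       values_fn = mean)
  complete <- stats::complete.cases(wide[, c(a, b)])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("Dropped ", n_dropped, " subject(s) with a missing side.")
  }
  wide <- wide[complete, ]
  if (nrow(wide) < 2) {
    stop("Need at least two complete pairs.", call. = FALSE)
  }
  out <- tibble::tibble(subject_id = wide$subject_id,
                        x = wide[[a]], y = wide[[b]])
  structure(out, class = c("paired_measurements", class(out)),
            conditions = c(a, b), units = units)
}

#' Paired t-test for crossover differences
#'
#' Two-sided paired t-test on `x - y`: `t = mean(d) / (sd(d) / sqrt(n))` with
#' `n - 1` degrees of freedom. When every difference is identical the sample
#' variance is zero: an all-zero difference gives a flagged degenerate result
#' with `p = 1`, and a constant nonzero difference is reported as the limit
#' `p = 0` with `zero_variance = TRUE` rather than an error.
#'
#' @param x,y Matched numeric vectors, or a `paired_measurements` object as
#'   `x` (then `y` is ignored).
#' @param alternative `"two.sided"` (default) or `"one.sided"`; the paired
#'   comparisons this package reports are two-sided.
#' @return An object of class `kirch_ttest` with fields `t`, `df`, `p`,
#'   `mean_difference`, `sd_difference`, `n`, `zero_variance`,
#'   `alternative`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' paired_t_test(c(2, 4, 6), c(1, 2, 3))
paired_t_test <- function(x, y = NULL, alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(x, "paired_measurements")) {
    y <- x$y
    x <- x$x
  }
  if (length(x) != length(y)) stop("`x` and `y` must match.", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("Need at least two complete pairs.", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  zero_var <- s == 0
  if (zero_var) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
    if (alternative == "one.sided") p <- p / 2
  }
  structure(list(t = t_stat, df = n - 1L, p = p, mean_difference = m,
                 sd_difference = s, n = n, zero_variance = zero_var,
                 alternative = alternative),
            class = "kirch_ttest")
}

#' @export
print.kirch_ttest <- function(x, ...) {
  cat("Paired t-test (", x$alternative, ")\n", sep = "")
  cat(sprintf("  mean difference = %.4g (sd %.4g, n = %d)\n",
              x$mean_difference, x$sd_difference, x$n))
  if (x$zero_variance) cat("  zero variance of differences (flagged)\n")
  cat(sprintf("  t = %.4f, df = %d, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired t-test result
#'
#' @param x A `kirch_ttest` object.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `statistic`, `p.value`,
#'   `parameter`, `method`, `alternative`.
#' @export
tidy.kirch_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$mean_difference, statistic = x$t,
                 p.value = x$p, parameter = x$df,
                 method = "paired t-test", alternative = x$alternative)
}

#' Glance at a paired t-test result
#'
#' @inheritParams tidy.kirch_ttest
#' @return A one-row tibble with `n`, `statistic`, `p.value`,
#'   `zero_variance`.
#' @export
glance.kirch_ttest <- function(x, ...) {
  tibble::tibble(n = x$n, statistic = x$t, p.value = x$p,
                 zero_variance = x$zero_variance)
}

#' Mean, sample SD and n of a measurement vector
#'
#' For rendering "mean +/- SD" study summaries. The SD uses the n - 1
#' denominator; a single value yields `sd = NA`.
#'
#' @param values Numeric vector; missing values dropped with a count message.
#' @return A one-row tibble with `mean`, `sd`, `n`.
#' @export
#' @examples
#' summarize_values(c(1, 2, 3))
summarize_values <- function(values) {
  if (anyNA(values)) {
    message("Dropped ", sum(is.na(values)), " missing value(s).")
    values <- values[!is.na(values)]
  }
  if (length(values) == 0) stop("No values to summarise.", call. = FALSE)
  tibble::tibble(mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else NA_real_,
                 n = length(values))
}
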