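#' Non-compartmental analysis of concentration-time profiles
#'
#' Standard model-independent exposure metrics on a tidy profile table:
#' trapezoidal AUC to the last sample, terminal log-linear slope, extrapolated
#' AUC and AUMC to infinity, mean residence time, and apparent clearance.
#' These feed the bioavailability and gut-clearance calculations.
#'
#' @name nca
NULL

validate_profile <- function(profile) {
  stopifnot(is.data.frame(profile))
  need <- c("time_h", "conc_mg_per_L")
  if (!all(need %in% names(profile))) {
    stop("Profile needs columns `time_h` and `conc_mg_per_L`.", call. = FALSE)
  }
  if (nrow(profile) < 2) {
    stop("Profile needs at least two samples.", call. = FALSE)
  }
  if (is.unsorted(profile$time_h, strictly = TRUE)) {
    stop("`time_h` must be strictly increasing.", call. = FALSE)
  }
  if (profile$time_h[1] < 0) stop("Times must be >= 0.", call. = FALSE)
  if (anyNA(profile$conc_mg_per_L) || any(profile$conc_mg_per_L < 0)) {
    stop("Concentrations must be non-negative and non-missing.", call. = FALSE)
  }
  invisible(profile)
}

# per-interval area; log trapezoid where concentration declines through
# positive values, linear otherwise
interval_areas <- function(t, c, method) {
  dt <- diff(t)
  c1 <- c[-length(c)]
  c2 <- c[-1]
  lin <- (c1 + c2) / 2 * dt
  if (method == "linear") return(lin)
  use_log <- c2 < c1 & c2 > 0 & c1 > 0
  logarea <- ifelse(use_log, (c1 - c2) / log(c1 / c2) * dt, lin)
  logarea
}

#' Trapezoidal AUC to the last sample
#'
#' @param profile Data frame with strictly increasing `time_h` and
#'   non-negative `conc_mg_per_L`.
#' @param method `"linear_up_log_down"` (default; logarithmic trapezoid on
#'   declining positive segments, linear elsewhere) or `"linear"`.
#' @param moment Exponent on time: 0 gives AUC, 1 gives AUMC (the first moment
#'   integral, computed by linear trapezoid on `t * C`).
#' @return AUC (mg·h/L) or AUMC (mg·h²/L) from the first to the last sample.
#' @export
#' @examples
#' tri <- tibble::tibble(time_h = c(0, 1, 2), conc_mg_per_L = c(0, 10, 0))
#' auc_trapezoid(tri, method = "linear")  # 10
auc_trapezoid <- function(profile, method = c("linear_up_log_down", "linear"),
                          moment = 0) {
  method <- match.arg(method)
  validate_profile(profile)
  t <- profile$time_h
  cc <- profile$conc_mg_per_L
  if (moment == 0) {
    sum(interval_areas(t, cc, method))
  } else {
    # moment integrals use the linear trapezoid: t*C is not log-linear even
    # on a mono-exponential tail
    sum(interval_areas(t, t^moment * cc, "linear"))
  }
}

#' Terminal log-linear slope (lambda_z)
#'
#' Ordinary least-squares fit of `log(C)` against time over the last
#' `n_points` samples, or over the post-peak window that maximises adjusted
#' R-squared when `n_points = "auto"` (minimum 3 points, ties broken toward
#' more points). Concentrations in the fitted window must be strictly
#' positive.
#'
#' @inheritParams auc_trapezoid
#' @param n_points Integer >= 3, or `"auto"`.
#' @return A one-row tibble: `lambda_z` (1/h), `intercept` (log mg/L),
#'   `n_points_used`, `adj_r_squared`.
#' @export
#' @examples
#' pr <- tibble::tibble(time_h = 1:6, conc_mg_per_L = 10 * exp(-0.5 * (1:6)))
#' terminal_slope(pr)$lambda_z  # 0.5
terminal_slope <- function(profile, n_points = "auto") {
  validate_profile(profile)
  t <- profile$time_h
  cc <- profile$conc_mg_per_L
  n <- length(t)

  fit_window <- function(idx) {
    if (any(cc[idx] <= 0)) return(NULL)
    fit <- stats::lm.fit(cbind(1, t[idx]), log(cc[idx]))
    slope <- fit$coefficients[2]
    k <- length(idx)
    rss <- sum(fit$residuals^2)
    tss <- sum((log(cc[idx]) - mean(log(cc[idx])))^2)
    adj <- if (tss > 0) 1 - (rss / (k - 2)) / (tss / (k - 1)) else 1
    list(lambda_z = -unname(slope), intercept = unname(fit$coefficients[1]),
         n_points_used = k, adj_r_squared = adj)
  }

  if (identical(n_points, "auto")) {
    i_max <- which.max(cc)
    first_ok <- i_max + 1L            # post-peak points only
    sizes <- seq.int(3L, max(3L, n - first_ok + 1L))
    sizes <- sizes[sizes <= n - first_ok + 1L]
    if (!length(sizes)) {
      stop("Too few post-peak samples for automatic lambda_z selection.",
           call. = FALSE)
    }
    fits <- purrr::map(sizes, function(k) fit_window(seq.int(n - k + 1L, n)))
    fits <- purrr::compact(fits)
    if (!length(fits)) {
      stop("No positive-concentration window available for lambda_z.",
           call. = FALSE)
    }
    adj <- purrr::map_dbl(fits, "adj_r_squared")
    # ties (within numerical dust) broken toward more points
    best <- max(which(adj >= max(adj) - 1e-10))
    out <- fits[[best]]
  } else {
    n_points <- as.integer(n_points)
    if (n_points < 3 || n_points > n) {
      stop("`n_points` must be between 3 and the number of samples.",
           call. = FALSE)
    }
    out <- fit_window(seq.int(n - n_points + 1L, n))
    if (is.null(out)) {
      stop("Non-positive concentration in the terminal window.", call. = FALSE)
    }
  }
  if (out$lambda_z <= 0) {
    stop("Terminal slope is non-negative; no disposition phase identified.",
         call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Extrapolate AUC to infinite time
#'
#' Adds the mono-exponential tail area `c_last / lambda_z` beyond the last
#' sample.
#'
#' @param auc_0_tlast AUC to the last sample, mg·h/L.
#' @param c_last Last observed concentration, mg/L.
#' @param lambda_z Terminal slope, 1/h.
#' @return AUC from 0 to infinity, mg·h/L.
#' @export
auc_extrapolate <- function(auc_0_tlast, c_last, lambda_z) {
  stopifnot(auc_0_tlast >= 0, c_last >= 0, lambda_z > 0)
  auc_0_tlast + c_last / lambda_z
}

#' Full non-compartmental analysis of one profile
#'
#' Computes AUC to the last sample, the terminal slope, extrapolated AUC and
#' AUMC, mean residence time (AUMC/AUC) and apparent clearance `dose / AUC`
#' (equal to CL/F for extravascular routes). Results with more than 20% of the
#' AUC extrapolated are flagged `extrapolation_unreliable` rather than
#' rejected.
#'
#' @inheritParams auc_trapezoid
#' @param dose Administered dose, mg; taken from a `dose_mg` column when
#'   missing.
#' @param u_infinity Optional amount excreted unchanged in urine over all
#'   time, mg; enables the `clr` (renal clearance) column.
#' @param n_points Terminal-slope window, passed to [terminal_slope()].
#' @return A one-row tibble: `auc_0_tlast`, `lambda_z`, `auc_0_inf`,
#'   `aumc_0_inf`, `mrt`, `cl_over_f`, `clr`, `extrap_fraction`,
#'   `extrapolation_unreliable`, plus `subject_id`/`route` when present in the
#'   input.
#' @export
#' @examples
#' p <- pk_params(ka = 1, kd = 0.5, v = 10, dose = 100)
#' pr <- simulate_profile(p, seq(0.25, 48, by = 0.25))
#' run_nca(pr)
run_nca <- function(profile, dose = NULL,
                    method = c("linear_up_log_down", "linear"),
                    n_points = "auto", u_infinity = NULL) {
  method <- match.arg(method)
  validate_profile(profile)
  if (is.null(dose)) {
    if (!"dose_mg" %in% names(profile)) {
      stop("Supply `dose` or a `dose_mg` column.", call. = FALSE)
    }
    dose <- profile$dose_mg[1]
  }

  auc_last <- auc_trapezoid(profile, method)
  aumc_last <- auc_trapezoid(profile, method, moment = 1)
  pos <- profile$conc_mg_per_L > 0
  if (!any(pos)) stop("All concentrations are zero.", call. = FALSE)

  if (profile$conc_mg_per_L[nrow(profile)] == 0) {
    # profile observed all the way down to zero: nothing to extrapolate
    lambda_z <- NA_real_
    auc_inf <- auc_last
    aumc_inf <- aumc_last
  } else {
    # drop trailing zero concentrations (below-quantification tail) for the
    # terminal fit but keep them in the trapezoid
    last_pos <- max(which(pos))
    ts <- terminal_slope(profile[seq_len(last_pos), ], n_points)
    lambda_z <- ts$lambda_z
    c_last <- profile$conc_mg_per_L[last_pos]
    t_last <- profile$time_h[last_pos]
    auc_inf <- auc_extrapolate(auc_last, c_last, lambda_z)
    aumc_inf <- aumc_last + c_last * t_last / lambda_z + c_last / lambda_z^2
  }
  extrap <- (auc_inf - auc_last) / auc_inf

  out <- tibble::tibble(
    auc_0_tlast = auc_last,
    lambda_z = lambda_z,
    auc_0_inf = auc_inf,
    aumc_0_inf = aumc_inf,
    mrt = aumc_inf / auc_inf,
    cl_over_f = dose / auc_inf,
    clr = if (is.null(u_infinity)) NA_real_ else
      renal_clearance(u_infinity, auc_inf),
    extrap_fraction = extrap,
    extrapolation_unreliable = extrap > 0.2
  )
  id_cols <- intersect(c("subject_id", "route"), names(profile))
  if (length(id_cols)) {
    out <- dplyr::bind_cols(profile[1, id_cols], out)
  }
  out
}

#' Mean residence and mean absorption time from paired NCA results
#'
#' Residence times add for in-series processes: the mean residence time after
#' extravascular dosing is the iv mean residence time plus the mean absorption
#' time, so `mat = mrt_oral - mrt_iv`. Sampling noise can make the difference
#' negative; that is reported with `mat_negative = TRUE`, not an error.
#'
#' @param nca_oral,nca_iv One-row tibbles from [run_nca()] for the
#'   extravascular and iv profiles.
#' @return A one-row tibble: `mrt_oral`, `mrt_iv`, `mat`, `mat_negative`.
#' @export
mrt_and_mat <- function(nca_oral, nca_iv) {
  stopifnot(is.data.frame(nca_oral), is.data.frame(nca_iv),
            "mrt" %in% names(nca_oral), "mrt" %in% names(nca_iv))
  mat <- nca_oral$mrt[1] - nca_iv$mrt[1]
  if (mat < 0) {
    warning("Negative mean absorption time; likely sampling noise.",
            call. = FALSE)
  }
  tibble::tibble(mrt_oral = nca_oral$mrt[1], mrt_iv = nca_iv$mrt[1],
                 mat = mat, mat_negative = mat < 0)
}

#' Renal clearance from urinary recovery and exposure
#'
#' The amount of drug excreted unchanged in urine over all time divided by the
#' systemic exposure that drove the excretion. The definition makes no
#' assumption about the input process, which is what makes it a diagnostic:
#' if slow absorption-site clearance inflates AUC, the renal clearance
#' measured for that route falls below the iv value.
#'
#' @param u_infinity Amount excreted unchanged over all time, mg.
#' @param auc_0_inf AUC from 0 to infinity, mg·h/L.
#' @return Renal clearance, L/h.
#' @export
#' @examples
#' renal_clearance(100, 10)  # 10 L/h
renal_clearance <- function(u_infinity, auc_0_inf) {
  if (any(u_infinity <= 0) || any(auc_0_inf <= 0)) {
    stop("`u_infinity` and `auc_0_inf` must be positive.", call. = FALSE)
  }
  u_infinity / auc_0_inf
}

#' Bioavailability from AUC ratios and urinary ratios
#'
#' Dose-corrected exposure ratio `f_auc = (AUC_x/dose_x) / (AUC_iv/dose_iv)`
#' and, when urinary recoveries are given, the dose-corrected urinary ratio
#' `f_urine`. Neither is clamped at 1: apparent values above 1 are data, and
#' the divergence `f_auc > f_urine` is the signature of absorption-limited
#' clearance.
#'
#' @param auc_x,dose_x AUC (mg·h/L) and dose (mg) for the test route.
#' @param auc_iv,dose_iv AUC and dose for the iv reference.
#' @param u_inf_x,u_inf_iv Optional amounts excreted unchanged (mg) for the
#'   two routes.
#' @return A one-row tibble with `f_auc` and `f_urine` (NA when urine data
#'   are absent).
#' @export
#' @examples
#' bioavailability(auc_x = 2.2, dose_x = 400, auc_iv = 0.5, dose_iv = 100)
bioavailability <- function(auc_x, dose_x, auc_iv, dose_iv,
                            u_inf_x = NULL, u_inf_iv = NULL) {
  stopifnot(auc_x > 0, dose_x > 0, auc_iv > 0, dose_iv > 0)
  f_auc <- (auc_x / dose_x) / (auc_iv / dose_iv)
  f_urine <- if (is.null(u_inf_x) || is.null(u_inf_iv)) NA_real_ else {
    stopifnot(u_inf_x > 0, u_inf_iv > 0)
    (u_inf_x / dose_x) / (u_inf_iv / dose_iv)
  }
  tibble::tibble(f_auc = f_auc, f_urine = f_urine)
}
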