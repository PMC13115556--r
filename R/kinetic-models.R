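#' Parameter set for the one-compartment extravascular model
#'
#' Bundles the parameters of a first-order absorption / first-order
#' elimination model: absorption rate constant `ka` (1/h), total gut-loss rate
#' constant `kgut` (1/h, the sum of `ka` and any other loss from the gut such
#' as degradation, so `kgut >= ka`), systemic elimination rate constant `kd`
#' (the iv-bolus disposition constant, 1/h), systemic volume of distribution
#' `v` (L), bioavailable fraction `f`, and `dose` (mg).
#'
#' `f` is ordinarily a fraction in (0, 1]. Crossover studies can produce
#' *apparent* bioavailabilities above 1 when absorption-site clearance limits
#' the measured clearance; set `apparent_f = TRUE` to permit `f > 1`.
#'
#' @param ka Absorption rate constant, 1/h.
#' @param kd Systemic (iv bolus) elimination rate constant, 1/h.
#' @param v Systemic volume of distribution, L.
#' @param dose Administered dose, mg.
#' @param f Bioavailable fraction (default 1).
#' @param kgut Total first-order loss rate from the gut, 1/h; defaults to `ka`
#'   (no gut loss other than absorption).
#' @param apparent_f Allow `f > 1` (apparent bioavailability)?
#' @return An object of class `pk_params`.
#' @export
#' @examples
#' pk_params(ka = 1, kd = 0.5, v = 10, dose = 100)
pk_params <- function(ka, kd, v, dose, f = 1, kgut = ka, apparent_f = FALSE) {
  for (nm in c("ka", "kd", "v", "dose", "f", "kgut")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
      stop("`", nm, "` must be a single positive finite number.", call. = FALSE)
    }
  }
  if (!apparent_f && f > 1) {
    stop("`f` > 1 requires `apparent_f = TRUE` (apparent bioavailability).",
         call. = FALSE)
  }
  if (kgut < ka * (1 - 1e-12)) {
    stop("`kgut` must be >= `ka`: total gut loss includes absorption.",
         call. = FALSE)
  }
  structure(list(ka = ka, kd = kd, v = v, dose = dose, f = f,
                 kgut = max(kgut, ka), apparent_f = apparent_f),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("One-compartment extravascular parameters\n")
  cat(sprintf("  ka = %g /h, kgut = %g /h, kd = %g /h\n", x$ka, x$kgut, x$kd))
  cat(sprintf("  V = %g L, F = %g%s, dose = %g mg\n",
              x$v, x$f, if (x$apparent_f) " (apparent)" else "", x$dose))
  invisible(x)
}

# Bateman difference term D/(k1 - k2) * (exp(-k2 t) - exp(-k1 t)) with the
# analytic limit t * exp(-k t) when the two constants coincide. The closed form
# is singular at k1 == k2 but the model is not; switch at 1e-8 relative.
bateman_term <- function(k1, k2, t) {
  if (abs(k1 - k2) / k2 < 1e-8) {
    k <- (k1 + k2) / 2
    t * exp(-k * t)
  } else {
    (exp(-k2 * t) - exp(-k1 * t)) / (k1 - k2)
  }
}

#' Amount of drug in the systemic circulation after an extravascular dose
#'
#' Closed-form solutions of the one-compartment model with first-order input
#' and elimination. The `"classic"` model assumes the available dose
#' (`f * dose`) leaves the gut at rate `ka`; the `"corrected"` model lets the
#' gut lose drug at the total rate `kgut >= ka` (absorption plus degradation
#' and other gut elimination), which steepens the input phase:
#' \deqn{A(t) = \frac{k_a F D}{k_{gut} - k_d}\left(e^{-k_d t} - e^{-k_{gut} t}\right)}
#' with `kgut` replaced by `ka` in the classic form. The degenerate case where
#' the two exponents coincide uses the analytic limit
#' \eqn{k_a F D\, t\, e^{-k t}}.
#'
#' @param p A [pk_params()] object.
#' @param t Time(s) since dosing, h; must be non-negative.
#' @param model `"classic"` or `"corrected"`.
#' @return Amount(s) in the systemic circulation, mg.
#' @export
#' @examples
#' p <- pk_params(ka = 1, kd = 0.5, v = 10, dose = 100)
#' amount_extravascular(p, c(0, 1, 2, 4))
amount_extravascular <- function(p, t, model = c("classic", "corrected")) {
  model <- match.arg(model)
  stopifnot(inherits(p, "pk_params"))
  if (any(t < 0)) stop("`t` must be non-negative.", call. = FALSE)
  k_in <- if (model == "classic") p$ka else p$kgut
  p$ka * p$f * p$dose * vapply(t, function(ti) bateman_term(k_in, p$kd, ti),
                               numeric(1))
}

#' @rdname amount_extravascular
#' @export
amount_classic <- function(p, t) amount_extravascular(p, t, "classic")

#' @rdname amount_extravascular
#' @export
amount_corrected <- function(p, t) amount_extravascular(p, t, "corrected")

#' Systemic concentration after an extravascular dose
#'
#' [amount_extravascular()] divided by the systemic volume of distribution.
#'
#' @inheritParams amount_extravascular
#' @return Concentration(s), mg/L.
#' @export
concentration_extravascular <- function(p, t, model = c("classic", "corrected")) {
  amount_extravascular(p, t, model) / p$v
}

#' Closed-form AUC of the one-compartment extravascular models
#'
#' Integrating the concentration curve over all time gives
#' `f * dose / (kd * v)` for the classic model and
#' `ka * f * dose / (v * kd * kgut)` for the gut-loss-corrected model: gut
#' loss beyond absorption reduces exposure by the factor `ka / kgut`.
#'
#' @inheritParams amount_extravascular
#' @return AUC from 0 to infinity, mg·h/L.
#' @export
#' @examples
#' p <- pk_params(ka = 1, kd = 0.5, v = 10, dose = 100)
#' auc_closed_form(p)                 # 20
#' auc_closed_form(pk_params(ka = 1, kgut = 2, kd = 0.5, v = 10, dose = 100),
#'                 model = "corrected")  # 10
auc_closed_form <- function(p, model = c("classic", "corrected")) {
  model <- match.arg(model)
  stopifnot(inherits(p, "pk_params"))
  if (model == "classic") {
    p$f * p$dose / (p$kd * p$v)
  } else {
    p$ka * p$f * p$dose / (p$v * p$kd * p$kgut)
  }
}

#' Clearance identities implied by a parameter set
#'
#' The iv-bolus clearance is `kd * v`. When a gut clearance is supplied
#' (directly, or as `kgut * v_gut` via a gut volume of distribution), the
#' clearance measured after oral dosing follows the series composition law:
#' it equals the iv clearance only in the limit of very large gut clearance.
#'
#' @param p A [pk_params()] object.
#' @param cl_gut Clearance from the gut into the systemic circulation, L/h.
#' @param v_gut Optional gut volume of distribution, L; used to derive
#'   `cl_gut = kgut * v_gut` when `cl_gut` is missing.
#' @return A one-row tibble with `cl_iv` and, when a gut clearance is
#'   available, `cl_gut` and `cl_after_oral_kirchhoff` (L/h).
#' @export
#' @examples
#' p <- pk_params(ka = 1, kd = 0.5, v = 10, dose = 100)
#' clearance_identities(p, cl_gut = 5)   # oral clearance = 2.5 L/h
clearance_identities <- function(p, cl_gut = NULL, v_gut = NULL) {
  stopifnot(inherits(p, "pk_params"))
  cl_iv <- p$kd * p$v
  if (is.null(cl_gut) && !is.null(v_gut)) cl_gut <- p$kgut * v_gut
  if (is.null(cl_gut)) {
    return(tibble::tibble(cl_iv = cl_iv))
  }
  check_positive(cl_gut, "cl_gut")
  tibble::tibble(
    cl_iv = cl_iv,
    cl_gut = cl_gut,
    cl_after_oral_kirchhoff = compose_series_clearance(cl_gut, cl_iv)
  )
}

#' Simulate a noiseless concentration-time profile
#'
#' Evaluates the selected model on a sampling grid and returns a tidy profile
#' table as used throughout the package (and written by the simulator's CSV
#' output). `route = "iv_bolus"` uses the mono-exponential
#' `dose / v * exp(-kd t)`; the extravascular routes use
#' [concentration_extravascular()].
#'
#' @inheritParams amount_extravascular
#' @param times Strictly increasing sampling times, h.
#' @param route One of `"iv_bolus"`, `"oral"`, `"subq"`, `"im"`.
#' @param subject_id Label for the subject column.
#' @return A tibble with columns `subject_id`, `route`, `time_h`,
#'   `conc_mg_per_L`, `dose_mg`.
#' @export
simulate_profile <- function(p, times, route = "oral",
                             model = c("classic", "corrected"),
                             subject_id = "S1") {
  model <- match.arg(model)
  route <- match.arg(route, c("iv_bolus", "oral", "subq", "im"))
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("`times` must be strictly increasing and non-negative.", call. = FALSE)
  }
  conc <- if (route == "iv_bolus") {
    p$dose / p$v * exp(-p$kd * times)
  } else {
    concentration_extravascular(p, times, model)
  }
  tibble::tibble(subject_id = subject_id, route = route, time_h = times,
                 conc_mg_per_L = conc, dose_mg = p$dose)
}
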