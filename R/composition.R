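#' Kirchhoff-style composition of rate-defining clearances and rate constants
#'
#' Pharmacokinetic elimination and absorption processes combine like electrical
#' conductances: rate-defining processes acting *in parallel* add directly,
#' while processes acting *in series* add reciprocally, so the overall value is
#' always smaller than any single series step. These helpers implement both
#' laws for clearances (canonical unit L/h) and first-order rate constants
#' (canonical unit 1/h).
#'
#' Only *rate-defining* processes may be composed: a process whose parameter
#' could, under some condition, equal the total observed clearance or rate
#' constant. The functions enforce this only as strict positivity; whether a
#' process is rate-defining is a modelling judgement the caller makes (a
#' reversible passive-permeability term, for example, is not admissible).
#'
#' @param values Numeric vector of positive, finite clearances (L/h) or rate
#'   constants (1/h).
#' @return A single numeric value in the same unit as the inputs.
#' @examples
#' compose_parallel_clearance(c(6, 4))        # renal: filtration + secretion
#' compose_series_clearance(78.6, 48.5)       # gut then systemic -> ~30 L/h
#' compose_series_rate(0.1, 1.0)              # slow absorption dominates
#' @name kirchhoff-composition
NULL

check_positive <- function(x, what) {
  if (length(x) == 0) {
    stop("`", what, "` must contain at least one value.", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("`", what, "` must be finite numeric, got non-finite or missing values.",
         call. = FALSE)
  }
  # reject values indistinguishable from zero: the composition laws apply only
  # to rate-defining (strictly positive) processes
  if (any(x <= .Machine$double.eps)) {
    stop("`", what, "` must be strictly positive; a non-positive clearance or ",
         "rate constant is not a rate-defining process.", call. = FALSE)
  }
  invisible(x)
}

#' @rdname kirchhoff-composition
#' @export
compose_parallel_clearance <- function(values) {
  check_positive(values, "values")
  sum(values)
}

#' @rdname kirchhoff-composition
#' @export
compose_parallel_rate <- function(values) {
  check_positive(values, "values")
  sum(values)
}

#' @rdname kirchhoff-composition
#' @param cl_entering,cl_leaving Clearance into and out of the systemic
#'   circulation (L/h), e.g. gut clearance and iv clearance. Vectorised.
#' @export
compose_series_clearance <- function(cl_entering, cl_leaving) {
  check_positive(cl_entering, "cl_entering")
  check_positive(cl_leaving, "cl_leaving")
  cl_entering * cl_leaving / (cl_entering + cl_leaving)
}

#' @rdname kirchhoff-composition
#' @param k_entering,k_leaving First-order rate constants (1/h) for the
#'   entering (absorption) and leaving (elimination) steps. Vectorised.
#' @export
compose_series_rate <- function(k_entering, k_leaving) {
  check_positive(k_entering, "k_entering")
  check_positive(k_leaving, "k_leaving")
  k_entering * k_leaving / (k_entering + k_leaving)
}

#' Describe a named kinetic process for tabular composition
#'
#' Builds a one-row tibble describing a rate-defining process, for use with
#' [compose_processes()]. `kind` distinguishes clearances (L/h) from rate
#' constants (1/h); the two kinds cannot be mixed in one composition.
#'
#' @param name Text label for the process.
#' @param value Positive finite clearance (L/h) or rate constant (1/h).
#' @param topology `"parallel"` or `"series"`.
#' @param kind `"clearance"` or `"rate"`.
#' @return A one-row tibble with columns `name`, `value`, `topology`, `kind`.
#' @export
#' @examples
#' kinetic_process("glomerular filtration", 7.2, "parallel")
kinetic_process <- function(name, value, topology = c("parallel", "series"),
                            kind = c("clearance", "rate")) {
  topology <- match.arg(topology)
  kind <- match.arg(kind)
  check_positive(value, "value")
  stopifnot(length(value) == 1L, length(name) == 1L)
  tibble::tibble(name = as.character(name), value = as.numeric(value),
                 topology = topology, kind = kind)
}

#' Compose a table of rate-defining processes
#'
#' Applies both composition laws to a tibble of processes (rows as produced by
#' [kinetic_process()]): parallel processes are first summed into a single
#' equivalent process, then combined reciprocally with each series process.
#' This sequential application is the natural compositional extension for
#' mixed topologies; see the package vignette for discussion.
#'
#' @param processes A data frame with columns `value` (positive numeric) and
#'   `topology` (`"parallel"`/`"series"`); an optional `kind` column must be
#'   constant.
#' @return The overall clearance or rate constant, a single numeric.
#' @export
#' @examples
#' dplyr::bind_rows(
#'   kinetic_process("filtration", 6, "parallel"),
#'   kinetic_process("secretion", 4, "parallel")
#' ) |> compose_processes()
compose_processes <- function(processes) {
  stopifnot(is.data.frame(processes))
  if (!all(c("value", "topology") %in% names(processes))) {
    stop("`processes` needs columns `value` and `topology`.", call. = FALSE)
  }
  if (nrow(processes) == 0) {
    stop("`processes` must contain at least one process.", call. = FALSE)
  }
  if ("kind" %in% names(processes) && dplyr::n_distinct(processes$kind) > 1) {
    stop("Cannot compose clearances with rate constants in one call.",
         call. = FALSE)
  }
  bad <- setdiff(unique(processes$topology), c("parallel", "series"))
  if (length(bad)) {
    stop("Unknown topology: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  check_positive(processes$value, "value")
  par_vals <- processes$value[processes$topology == "parallel"]
  ser_vals <- processes$value[processes$topology == "series"]
  terms <- c(if (length(par_vals)) sum(par_vals), ser_vals)
  1 / sum(1 / terms)
}

#' Convert a clearance from mL/min to L/h
#'
#' Some studies report renal clearance in mL/min; the package's canonical
#' clearance unit is L/h (1 mL/min = 0.06 L/h).
#'
#' @param x Numeric clearance(s) in mL/min.
#' @return Clearance(s) in L/h.
#' @export
#' @examples
#' ml_min_to_l_h(70.2)  # 4.212 L/h
ml_min_to_l_h <- function(x) x * 0.06
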