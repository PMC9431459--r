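#' Time-dependent nutrient forcing
#'
#' A forcing describes how the ammonium and nitrate concentrations seen by
#' the incubation model evolve over time. Each nutrient is either constant
#' or a quadratic in time `conc(t) = a t^2 + b t + c` (t in days), the form
#' fitted to measured drawdown curves. Evaluated concentrations are clipped
#' at zero from below, since a fitted quadratic can dip negative late in the
#' window.
#'
#' @param nh4,no3 Either a single non-negative number (constant forcing) or
#'   a numeric vector `c(a, b, c)` of quadratic coefficients.
#' @return An object of class `nutrient_forcing`.
#' @seealso [fit_nutrient_forcing()], [eval_forcing()]
#' @examples
#' f <- nutrient_forcing(nh4 = c(10, -45, 105), no3 = 15)
#' eval_forcing(f, c(0, 1, 3))
#' @export
nutrient_forcing <- function(nh4, no3) {
  comp <- function(x, what) {
    if (!is.numeric(x) || anyNA(x) || !all(is.finite(x)))
      stop(what, " must be finite numeric", call. = FALSE)
    if (length(x) == 1L) {
      if (x < 0) stop(what, " constant must be >= 0", call. = FALSE)
      list(kind = "constant", value = as.numeric(x))
    } else if (length(x) == 3L) {
      list(kind = "quadratic", coef = stats::setNames(as.numeric(x), c("a", "b", "c")))
    } else stop(what, " must be length 1 (constant) or 3 (quadratic)", call. = FALSE)
  }
  structure(list(nh4 = comp(nh4, "nh4"), no3 = comp(no3, "no3")),
            class = "nutrient_forcing")
}

#' @export
print.nutrient_forcing <- function(x, ...) {
  fmt <- function(cp) {
    if (cp$kind == "constant") sprintf("constant %.4g nmol/L", cp$value)
    else sprintf("quadratic %.4g t^2 + %.4g t + %.4g", cp$coef[["a"]],
                 cp$coef[["b"]], cp$coef[["c"]])
  }
  cat("<nutrient_forcing>\n  NH4: ", fmt(x$nh4), "\n  NO3: ", fmt(x$no3), "\n", sep = "")
  invisible(x)
}

#' Evaluate a nutrient forcing at given times
#'
#' @param forcing A [nutrient_forcing()].
#' @param t Times, days.
#' @return A tibble with columns `t`, `nh4`, `no3` (nmol L^-1, clipped at 0).
#' @export
eval_forcing <- function(forcing, t) {
  stopifnot(inherits(forcing, "nutrient_forcing"), is.numeric(t))
  ev <- function(cp) {
    v <- if (cp$kind == "constant") rep(cp$value, length(t))
    else cp$coef[["a"]] * t^2 + cp$coef[["b"]] * t + cp$coef[["c"]]
    pmax(v, 0)
  }
  tibble::tibble(t = as.numeric(t), nh4 = ev(forcing$nh4), no3 = ev(forcing$no3))
}

# internal: fast evaluation of a single component at scalar/vector t
.eval_component <- function(cp, t) {
  v <- if (cp$kind == "constant") rep.int(cp$value, length(t))
  else cp$coef[["a"]] * t * t + cp$coef[["b"]] * t + cp$coef[["c"]]
  pmax(v, 0)
}

#' Fit a quadratic nutrient forcing to measured concentrations
#'
#' Ordinary least-squares fit of `conc = a t^2 + b t + c` to a measured
#' drawdown series, the standard empirical stand-in for the (unmeasured)
#' continuous nutrient field driving an incubation. Observations censored at
#' the analytical detection limit are handled by a configurable
#' left-censoring heuristic before fitting.
#'
#' @param data A data frame with columns `day` and `conc_nmol_l`, and
#'   optionally a logical `below_detection` column.
#' @param detection_limit Detection limit, nmol L^-1. Used with
#'   `below_detection` (or, if that column is absent, with
#'   `conc_nmol_l < detection_limit`) to identify censored values.
#' @param censored How to treat censored values before fitting:
#'   `"half-limit"` (replace by detection_limit/2, the default), `"exclude"`
#'   (drop the rows), or `"zero"` (replace by 0).
#' @return A single-nutrient forcing component wrapped so it can be combined:
#'   a list with class `forcing_component` holding the quadratic
#'   coefficients, the fit object and the number of points used. Combine two
#'   with [as_forcing()].
#' @examples
#' d <- tibble::tibble(day = 0:3, conc_nmol_l = c(105, 52, 18, 5))
#' fit_nutrient_forcing(d, detection_limit = 6)
#' @export
fit_nutrient_forcing <- function(data, detection_limit = 0,
                                 censored = c("half-limit", "exclude", "zero")) {
  censored <- match.arg(censored)
  stopifnot(is.data.frame(data), all(c("day", "conc_nmol_l") %in% names(data)))
  d <- dplyr::as_tibble(data)
  if (any(d$conc_nmol_l < 0, na.rm = TRUE))
    stop("concentrations must be >= 0", call. = FALSE)
  cens <- if ("below_detection" %in% names(d)) as.logical(d$below_detection)
  else d$conc_nmol_l < detection_limit
  cens[is.na(cens)] <- FALSE
  d <- switch(censored,
    "half-limit" = dplyr::mutate(d, conc_nmol_l = ifelse(cens, detection_limit / 2,
                                                         .data$conc_nmol_l)),
    "exclude" = d[!cens, ],
    "zero" = dplyr::mutate(d, conc_nmol_l = ifelse(cens, 0, .data$conc_nmol_l))
  )
  if (length(unique(d$day)) < 3L)
    stop("need >= 3 distinct time points to fit a quadratic", call. = FALSE)
  fit <- stats::lm(conc_nmol_l ~ I(day^2) + day, data = d)
  co <- stats::coef(fit)
  structure(
    list(kind = "quadratic",
         coef = c(a = unname(co[["I(day^2)"]]), b = unname(co[["day"]]),
                  c = unname(co[["(Intercept)"]])),
         fit = fit, n = nrow(d)),
    class = "forcing_component"
  )
}

#' Combine fitted components into a forcing
#'
#' @param nh4,no3 Each a `forcing_component` from [fit_nutrient_forcing()],
#'   a single constant, or a length-3 coefficient vector.
#' @return A [nutrient_forcing()].
#' @export
as_forcing <- function(nh4, no3) {
  unwrap <- function(x) if (inherits(x, "forcing_component")) unname(x$coef) else x
  nutrient_forcing(unwrap(nh4), unwrap(no3))
}
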