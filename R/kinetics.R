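# Offset-exponential uptake/root-growth curves and the root-efficiency
# statistic RE(t) = (dU/dt) / RSA(t).

#' Days after transplanting corresponding to model time t = 0
#'
#' Zn uptake in the field trials this package models only starts about two
#' weeks after transplanting (seedlings first regrow the roots damaged at
#' transplanting from shoot Zn reserves), so the kinetic curves are fitted
#' on the 14--28 DAT window with model time `t = dat - 14`.
#'
#' @format Integer scalar, days after transplanting (DAT).
#' @export
ORIGIN_DAT <- 14L

#' Analysis window in model time (days)
#'
#' The curves are fitted on 14--28 DAT, i.e. model time 0--14 d; evaluation
#' outside this window is extrapolation.
#'
#' @format Numeric length-2 vector, days.
#' @export
ANALYSIS_WINDOW <- c(0, 14)

#' Convert days-after-transplanting to model time
#'
#' @param dat Days after transplanting.
#' @param origin_dat DAT corresponding to model time zero (default
#'   [ORIGIN_DAT]).
#' @return Model time in days (`dat - origin_dat`).
#' @export
dat_to_model_time <- function(dat, origin_dat = ORIGIN_DAT) {
  dat - as.numeric(origin_dat)
}

#' Offset-exponential curve
#'
#' The curve `value(t) = scale * exp(rate * t) - offset` used for both
#' cumulative Zn uptake per plant (`role = "uptake"`, ug plant^-1) and root
#' surface area per plant (`role = "rsa"`, cm2 plant^-1), with `t` in days
#' of model time.
#'
#' @param scale Positive multiplier, in trait units.
#' @param rate Positive exponential rate, d^-1.
#' @param offset Additive offset, in trait units.
#' @param role One of `"uptake"`, `"rsa"`.
#' @return An object of class `exp_curve`.
#' @examples
#' rsa <- exp_curve(110.2, 0.082, 22.2, role = "rsa")
#' eval_curve(rsa, 0) # 88.0 cm2 per plant at 14 DAT
#' @export
exp_curve <- function(scale, rate, offset, role = c("uptake", "rsa")) {
  role <- match.arg(role)
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(rate), length(rate) == 1L, is.finite(rate),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  if (scale <= 0) stop("'scale' must be > 0, got ", scale)
  if (rate <= 0) stop("'rate' must be > 0, got ", rate)
  # the curve is increasing, so its minimum on the window is at t = 0
  v0 <- scale - offset
  if (role == "rsa" && v0 <= 0) {
    stop("RSA curve must be strictly positive on the analysis window; ",
         "value at t = 0 is ", v0)
  }
  if (role == "uptake" && v0 < -1e-9 * scale) {
    stop("uptake curve is negative at t = 0 (", v0, ")")
  }
  structure(list(scale = scale, rate = rate, offset = offset, role = role),
            class = "exp_curve")
}

#' @export
print.exp_curve <- function(x, ...) {
  unit <- if (x$role == "uptake") "ug/plant" else "cm2/plant"
  cat(sprintf("<exp_curve %s> %.6g * exp(%.6g t) - %.6g  [%s, t in d]\n",
              x$role, x$scale, x$rate, x$offset, unit))
  invisible(x)
}

#' Evaluate an offset-exponential curve
#'
#' @param curve An [exp_curve()].
#' @param t Model time in days (vectorized).
#' @param warn_extrapolation Warn when `t` falls outside [ANALYSIS_WINDOW].
#' @return `scale * exp(rate * t) - offset`, in curve units.
#' @export
eval_curve <- function(curve, t, warn_extrapolation = FALSE) {
  stopifnot(inherits(curve, "exp_curve"), is.numeric(t), all(is.finite(t)))
  if (warn_extrapolation &&
      any(t < ANALYSIS_WINDOW[1] | t > ANALYSIS_WINDOW[2])) {
    warning("evaluating curve outside the fitted window [",
            ANALYSIS_WINDOW[1], ", ", ANALYSIS_WINDOW[2],
            "] d: extrapolation", call. = FALSE)
  }
  curve$scale * exp(curve$rate * t) - curve$offset
}

#' Instantaneous rate of change of an offset-exponential curve
#'
#' Analytic derivative `scale * rate * exp(rate * t)`; for an uptake curve
#' this is the Zn uptake rate dU/dt.
#'
#' @inheritParams eval_curve
#' @return Derivative in curve units per day; strictly positive.
#' @export
curve_rate <- function(curve, t) {
  stopifnot(inherits(curve, "exp_curve"), is.numeric(t), all(is.finite(t)))
  curve$scale * curve$rate * exp(curve$rate * t)
}

#' Paired uptake and root-surface-area curves for one genotype group
#'
#' @param uptake An [exp_curve()] with `role = "uptake"`.
#' @param rsa An [exp_curve()] with `role = "rsa"`.
#' @param group_id Group label, e.g. `"tolerant"`.
#' @return An object of class `efficiency_curve`.
#' @export
efficiency_curve <- function(uptake, rsa, group_id) {
  stopifnot(inherits(uptake, "exp_curve"), inherits(rsa, "exp_curve"),
            is.character(group_id), length(group_id) == 1L)
  if (uptake$role != "uptake") stop("'uptake' curve must have role 'uptake'")
  if (rsa$role != "rsa") stop("'rsa' curve must have role 'rsa'")
  structure(list(uptake = uptake, rsa = rsa, group_id = group_id),
            class = "efficiency_curve")
}

#' @export
print.efficiency_curve <- function(x, ...) {
  cat(sprintf("<efficiency_curve '%s'>\n  uptake: ", x$group_id))
  print(x$uptake)
  cat("  rsa:    ")
  print(x$rsa)
  cat(sprintf("  RE(0) = %.4g ug cm-2 d-1\n", root_efficiency(x, 0)))
  invisible(x)
}

#' Root efficiency: Zn uptake rate per unit root surface area
#'
#' `RE(t) = (dU/dt) / RSA(t)`, in ug cm^-2 d^-1.  This lumps together every
#' mechanism raising uptake per unit root, including root-induced changes in
#' the rhizosphere, so it is a phenomenological efficiency rather than a
#' transporter-kinetics parameter.
#'
#' @param ec An [efficiency_curve()].
#' @param t Model time in days (vectorized).
#' @return Root efficiency, ug cm^-2 d^-1.
#' @examples
#' gc <- default_group_curves()
#' root_efficiency(gc$tolerant, 0)
#' @export
root_efficiency <- function(ec, t) {
  stopifnot(inherits(ec, "efficiency_curve"))
  rsa <- eval_curve(ec$rsa, t)
  bad <- rsa <= 0
  if (any(bad)) {
    stop("RSA is non-positive at t = ",
         paste(signif(t[bad], 6), collapse = ", "),
         "; root efficiency undefined there")
  }
  curve_rate(ec$uptake, t) / rsa
}

#' Bundled group-level uptake and RSA curves
#'
#' Loads the packaged fitted coefficients for the Zn-deficiency tolerant and
#' sensitive genotype groups of the reference field trial (time origin
#' 14 DAT): uptake `U = a exp(bt) - c` and root surface area
#' `RSA = p exp(qt) - s`.
#'
#' @param path Optional path to an alternative curve JSON file.
#' @return Named list of [efficiency_curve()] objects
#'   (`tolerant`, `sensitive`).
#' @export
default_group_curves <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "group_curves.json", package = "rootzn",
                        mustWork = TRUE)
  }
  read_curves_json(path)
}
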