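# Least-squares fitting of offset-exponential curves to group-mean series.
#
# The model value(t) = a*exp(b*t) - c is linear in (a, c) given b, so the
# rate is profiled out: for each trial rate the scale and offset are solved
# by linear least squares, and the one-dimensional profiled RSS is minimized
# over a fixed multi-start grid with bounded quasi-Newton refinement.  This
# makes the fit deterministic and start-free.

#' Group-mean trait time-series
#'
#' @param group_id Group label.
#' @param times Model times (days), strictly increasing, at least 3.
#' @param values Trait values (ug plant^-1 for uptake, cm2 plant^-1 for RSA).
#' @param trait One of `"uptake"`, `"rsa"`.
#' @param se Optional standard errors of the group means.
#' @return An object of class `group_series`.
#' @export
group_series <- function(group_id, times, values, trait = c("uptake", "rsa"),
                         se = NULL) {
  trait <- match.arg(trait)
  stopifnot(is.character(group_id), length(group_id) == 1L,
            is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) < 3L) {
    stop("need at least 3 time points to fit a 3-parameter curve, got ",
         length(times))
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must all be finite")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!is.null(se)) stopifnot(length(se) == length(values), all(se >= 0))
  structure(list(group_id = group_id, times = as.numeric(times),
                 values = as.numeric(values), trait = trait, se = se),
            class = "group_series")
}

# Scale/offset solved by linear LS at fixed rate; returns list(a, c, rss,
# resid).  Model matrix [exp(bt), -1].
.profile_fit <- function(b, times, values) {
  x <- exp(b * times)
  X <- cbind(x, -1)
  coef <- tryCatch(qr.coef(qr(X), values), error = function(e) c(NA, NA))
  if (any(!is.finite(coef))) {
    return(list(a = NA_real_, c = NA_real_, rss = Inf, resid = NULL))
  }
  r <- values - X %*% coef
  list(a = coef[[1]], c = coef[[2]], rss = sum(r * r), resid = drop(r))
}

.profile_rss <- function(b, times, values) .profile_fit(b, times, values)$rss

# Envelope-theorem gradient of the profiled RSS wrt the rate.
.profile_grad <- function(b, times, values) {
  f <- .profile_fit(b, times, values)
  if (!is.finite(f$rss)) return(0)
  -2 * sum(f$resid * f$a * times * exp(b * times))
}

#' Fit an offset-exponential curve by least squares
#'
#' Fits `value = scale * exp(rate * t) - offset` to a [group_series()] by
#' bounded nonlinear least squares.  The rate is profiled (the model is
#' linear in scale and offset given the rate) and minimized from a fixed
#' multi-start grid, so the result is deterministic and needs no starting
#' guess.
#'
#' @param series A [group_series()].
#' @param rate_bounds Lower/upper bound on the rate, d^-1.
#' @param starts Multi-start rate grid (clipped to the bounds).
#' @return A `fit_result` list: `curve` ([exp_curve()]), `rss`, `converged`,
#'   `n_points`, `n_starts_used`.
#' @examples
#' s <- group_series("tolerant", c(0, 7, 14),
#'                   1.09 * exp(0.171 * c(0, 7, 14)) - 1.09, "uptake")
#' fit_exp(s)$curve
#' @export
fit_exp <- function(series, rate_bounds = c(1e-4, 1),
                    starts = c(0.02, 0.05, 0.1, 0.2, 0.4)) {
  stopifnot(inherits(series, "group_series"),
            length(rate_bounds) == 2L, rate_bounds[1] > 0,
            rate_bounds[2] > rate_bounds[1])
  times <- series$times
  values <- series$values
  if (length(unique(times)) < 3L) {
    stop("degenerate fit: fewer than 3 distinct time points")
  }
  if (diff(range(values)) <= 1e-12 * max(abs(values), 1)) {
    stop("degenerate fit: constant series, rate is unidentifiable")
  }
  starts <- pmin(pmax(starts, rate_bounds[1]), rate_bounds[2])
  fits <- lapply(starts, function(b0) {
    o <- stats::optim(b0, fn = .profile_rss, gr = .profile_grad,
                      times = times, values = values,
                      method = "L-BFGS-B",
                      lower = rate_bounds[1], upper = rate_bounds[2],
                      control = list(factr = 1e-2, pgtol = 0, maxit = 500))
    o
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  b <- best$par
  pf <- .profile_fit(b, times, values)
  if (!is.finite(pf$rss) || pf$a <= 0) {
    stop("degenerate fit: least-squares solution has non-positive scale ",
         "(series not of offset-exponential growth form)")
  }
  curve <- exp_curve(pf$a, b, pf$c, role = series$trait)
  structure(list(curve = curve, rss = pf$rss,
                 converged = best$convergence == 0L,
                 n_points = length(times),
                 n_starts_used = length(starts)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n = %d, rss = %.4g, converged = %s\n  ",
              x$n_points, x$rss, x$converged))
  print(x$curve)
  cat(sprintf("  display: %.2f exp(%.3ft) - %.2f\n",
              x$curve$scale, x$curve$rate, x$curve$offset))
  invisible(x)
}

#' Fit the uptake/RSA curve pair for one group
#'
#' @param uptake_series [group_series()] with `trait = "uptake"`.
#' @param rsa_series [group_series()] with `trait = "rsa"`, same group.
#' @param ... Passed to [fit_exp()].
#' @return An [efficiency_curve()] built from the two independent fits.
#' @export
fit_group_pair <- function(uptake_series, rsa_series, ...) {
  stopifnot(inherits(uptake_series, "group_series"),
            inherits(rsa_series, "group_series"))
  if (uptake_series$group_id != rsa_series$group_id) {
    stop("series belong to different groups: '", uptake_series$group_id,
         "' vs '", rsa_series$group_id, "'")
  }
  if (uptake_series$trait != "uptake" || rsa_series$trait != "rsa") {
    stop("expected an uptake series and an rsa series, got '",
         uptake_series$trait, "' and '", rsa_series$trait, "'")
  }
  efficiency_curve(fit_exp(uptake_series, ...)$curve,
                   fit_exp(rsa_series, ...)$curve,
                   group_id = uptake_series$group_id)
}
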