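#' Coefficient sets for the gamma shape/rate laws
#'
#' The invisible-length gamma parameters follow two empirical laws in
#' `r = mu/nu` and the sweep count `t`:
#' \deqn{1/\alpha - 1 = s(r)\,(t-1), \qquad 1/\beta = \mu\,
#'   \exp[b(r)\,(t-1)],}
#' where `s` and `b` are quadratics in `r`.  A `coefficient_set` holds the
#' two quadratics as `(a2, a1, a0)` triples (highest degree first).
#' `reference_coefficients()` returns the package's reference calibration,
#' `s(r) = -0.1725 r^2 + 0.5333 r - 0.039` and
#' `b(r) = -0.2458 r^2 + 0.9257 r - 0.0212`; [calibrate()] re-estimates the
#' triples from fresh simulations.
#'
#' @param shape_quad numeric triple `(a2, a1, a0)` for the shape law.
#' @param rate_quad numeric triple `(b2, b1, b0)` for the log-rate law.
#' @param provenance `"reference"` or `"recalibrated"`.
#' @param diagnostics optional list of fit diagnostics (kept by
#'   [calibrate()]).
#' @return An object of class `coefficient_set`.
#' @examples
#' reference_coefficients()
#' @export
coefficient_set <- function(shape_quad, rate_quad,
                            provenance = c("reference", "recalibrated"),
                            diagnostics = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(shape_quad), length(shape_quad) == 3L,
            is.numeric(rate_quad), length(rate_quad) == 3L)
  structure(list(shape_quad = as.numeric(shape_quad),
                 rate_quad = as.numeric(rate_quad),
                 provenance = provenance, diagnostics = diagnostics),
            class = "coefficient_set")
}

#' @rdname coefficient_set
#' @export
reference_coefficients <- function() {
  coefficient_set(shape_quad = c(-0.1725, 0.5333, -0.039),
                  rate_quad = c(-0.2458, 0.9257, -0.0212),
                  provenance = "reference")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("Coefficient set (%s):\n", x$provenance))
  cat(sprintf("  shape: 1/alpha - 1 = [%+.4g r^2 %+.4g r %+.4g] (t - 1)\n",
              x$shape_quad[1L], x$shape_quad[2L], x$shape_quad[3L]))
  cat(sprintf("  rate:  1/beta = mu exp{[%+.4g r^2 %+.4g r %+.4g] (t - 1)}\n",
              x$rate_quad[1L], x$rate_quad[2L], x$rate_quad[3L]))
  invisible(x)
}

quad_eval <- function(coefs, r) coefs[1L] * r^2 + coefs[2L] * r + coefs[3L]

#' Predicted gamma shape and rate of invisible lengths
#'
#' `shape_law()` returns `alpha = 1 / (1 + s(r) (t-1))`; `rate_law()`
#' returns `beta = 1 / (mu exp[b(r) (t-1)])`.  At `t = 1` these reduce to
#' `alpha = 1` and `beta = 1/mu` — after a single sweep the invisible
#' lengths are exactly the exponential deletion lengths.
#'
#' @param r positive real, the ratio `mu/nu` (vectors allowed).
#' @param t positive integer sweep count (vectors allowed).
#' @param mu positive real mean deletion length.
#' @param coeffs a [coefficient_set()].
#' @return Numeric `alpha` or `beta`.
#' @examples
#' shape_law(1/3, t = 2)   # about 0.893
#' rate_law(1, 1/3, t = 1) # 1
#' @export
shape_law <- function(r, t, coeffs = reference_coefficients()) {
  stopifnot(all(r > 0), all(t >= 1), all(t == floor(t)))
  denom <- 1 + quad_eval(coeffs$shape_quad, r) * (t - 1)
  if (any(denom <= 0))
    stop("shape law undefined: s(r) (t-1) <= -1", call. = FALSE)
  1 / denom
}

#' @rdname shape_law
#' @export
rate_law <- function(mu, r, t, coeffs = reference_coefficients()) {
  stopifnot(all(mu > 0), all(r > 0), all(t >= 1), all(t == floor(t)))
  1 / (mu * exp(quad_eval(coeffs$rate_quad, r) * (t - 1)))
}

#' Recalibrate the shape/rate laws from fresh simulations
#'
#' Reproduces the calibration pipeline behind the reference coefficients:
#' for each ratio `r` the simulator is run over the sweep range, a gamma is
#' fitted to the pooled invisible lengths of each sweep, and the per-ratio
#' slopes of `1/alpha - 1` and of `log(1/(beta mu))` against `t - 1` are
#' estimated by least squares (through the origin by default — both laws
#' are exact at `t = 1`).  The slopes are then regressed on `r` with a
#' quadratic, giving recalibrated coefficient triples.
#'
#' @param ratios numeric vector of at least 3 distinct `mu/nu` ratios.
#' @param sweeps integer vector of sweep counts (at least 3 values).
#' @param mu mean deletion length used in the runs (`nu = mu / r`).
#' @param genome_length,replicates simulation settings per run.
#' @param seed integer; run `i` uses `seed + i`.
#' @param pin_intercept logical; force the per-ratio lines through the
#'   origin (default) or fit a free intercept.
#' @return A `coefficient_set` with `provenance = "recalibrated"` and a
#'   `diagnostics` list (per-ratio slopes, quadratic-stage R squared, any
#'   dropped cells).
#' @export
calibrate <- function(ratios, sweeps, mu = 1, genome_length = 10000,
                      replicates = 5, seed = 1L, pin_intercept = TRUE) {
  stopifnot(length(unique(ratios)) >= 3L, all(ratios > 0),
            length(sweeps) >= 3L, all(sweeps >= 1))
  sweeps <- sort(unique(as.integer(sweeps)))
  slope_shape <- slope_rate <- rep(NA_real_, length(ratios))
  dropped <- character(0)
  for (i in seq_along(ratios)) {
    r <- ratios[i]
    run <- run_fractionation(
      sweep_params(nu = mu / r, mu = mu),
      sim_config(genome_length = genome_length, sweeps = max(sweeps),
                 replicates = replicates, seed = seed + i))
    ya <- yb <- rep(NA_real_, length(sweeps))
    for (k in seq_along(sweeps)) {
      t <- sweeps[k]
      gf <- tryCatch(
        fit_gamma(collect_lengths(run, sweep = t)$invisible),
        error = function(e) NULL)
      if (is.null(gf)) next
      ya[k] <- 1 / gf$alpha - 1
      yb[k] <- log(1 / (gf$beta * mu))
    }
    ok <- !is.na(ya)
    if (sum(ok) < 2L) {
      dropped <- c(dropped, sprintf("r = %g", r))
      warning("gamma fits failed for ratio ", r, "; cell dropped", call. = FALSE)
      next
    }
    x <- sweeps[ok] - 1
    slope_shape[i] <- fit_slope(x, ya[ok], pin_intercept)
    slope_rate[i] <- fit_slope(x, yb[ok], pin_intercept)
  }
  ok <- !is.na(slope_shape)
  if (sum(ok) < 3L)
    stop("calibration failed: fewer than 3 ratios survived", call. = FALSE)
  qs <- lm(slope_shape[ok] ~ I(ratios[ok]^2) + ratios[ok])
  qr <- lm(slope_rate[ok] ~ I(ratios[ok]^2) + ratios[ok])
  coefficient_set(
    shape_quad = unname(coef(qs)[c(2L, 3L, 1L)]),
    rate_quad = unname(coef(qr)[c(2L, 3L, 1L)]),
    provenance = "recalibrated",
    diagnostics = list(
      ratios = ratios, sweeps = sweeps,
      slope_shape = slope_shape, slope_rate = slope_rate,
      r_squared = c(shape = summary(qs)$r.squared,
                    rate = summary(qr)$r.squared),
      residuals = list(shape = unname(residuals(qs)),
                       rate = unname(residuals(qr))),
      dropped = dropped, seed = seed, pin_intercept = pin_intercept))
}

fit_slope <- function(x, y, pin_intercept) {
  if (pin_intercept) sum(x * y) / sum(x * x)
  else unname(coef(lm(y ~ x))[2L])
}
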