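#' Observed summary statistics for inference
#'
#' The three observables linking the data to the model: the exponential rate
#' `lambda^{-1}` of visible lengths, and the gamma shape `alpha` and rate
#' `beta` of invisible lengths.  Either pass the three numbers, or a
#' [fit_summary()] object.
#'
#' @param lambda_inv positive real, or a `fit_summary`.
#' @param alpha,beta positive reals (ignored when a `fit_summary` is given).
#' @return An object of class `observables`.
#' @examples
#' observables(1.665595, 0.6711252, 0.3504422)
#' @export
observables <- function(lambda_inv, alpha = NULL, beta = NULL) {
  if (inherits(lambda_inv, "fit_summary")) {
    fs <- lambda_inv
    lambda_inv <- fs$lambda_inv; alpha <- fs$alpha; beta <- fs$beta
  }
  vals <- c(lambda_inv = lambda_inv, alpha = alpha, beta = beta)
  if (length(vals) != 3L || !is.numeric(vals) || any(!is.finite(vals)) ||
      any(vals <= 0))
    stop("observables must be three positive numbers", call. = FALSE)
  structure(as.list(vals), class = "observables")
}

#' @export
print.observables <- function(x, ...) {
  cat(sprintf("Observables: lambda^-1 = %.6g, alpha = %.6g, beta = %.6g\n",
              x$lambda_inv, x$alpha, x$beta))
  invisible(x)
}

#' Invert the shape law for the ratio r = mu/nu
#'
#' Solves `s(r) = (1/alpha - 1)/(t - 1)` for `r`, where `s` is the shape-law
#' quadratic.  With the reference coefficients `s` is increasing on
#' `(0, ~1.55)` (its vertex), so the smaller quadratic root is the
#' admissible inverse; roots outside `(0, r_cap]` or a negative discriminant
#' mean no solution at this `t` — returned as `NA`, a signal rather than an
#' error.  At `t = 1` the law forces `alpha = 1` and `r` is unidentifiable.
#'
#' @param alpha positive observed gamma shape.
#' @param t candidate sweep count, `t >= 2`.
#' @param coeffs a [coefficient_set()].
#' @param r_cap admissible upper bound for `r` (default 1.5, near the
#'   vertex of the reference quadratic).
#' @return The ratio `r`, or `NA_real_` if no admissible solution exists.
#' @examples
#' invert_shape_law(0.6711252, t = 5)  # about 0.3403
#' invert_shape_law(0.6711252, t = 2)  # NA: no solution
#' @export
invert_shape_law <- function(alpha, t, coeffs = reference_coefficients(),
                             r_cap = 1.5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  stopifnot(length(t) == 1L, t == floor(t))
  if (t < 2) return(NA_real_)
  y <- (1 / alpha - 1) / (t - 1)
  a2 <- coeffs$shape_quad[1L]; a1 <- coeffs$shape_quad[2L]
  a0 <- coeffs$shape_quad[3L] - y
  disc <- a1^2 - 4 * a2 * a0
  if (disc < 0) return(NA_real_)
  roots <- sort((-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2))
  adm <- roots[roots > 0 & roots <= r_cap]
  if (!length(adm)) NA_real_ else adm[1L]
}

#' Candidate parameter values at a fixed sweep count
#'
#' For a candidate `t`, `nu_t = t / lambda^{-1}` (from the spacing law),
#' `r` comes from [invert_shape_law()], `mu_t = r nu_t`, `beta_t` from
#' [rate_law()], and the normalized rate discrepancy is
#' `delta = |beta - beta_t| / beta`.
#'
#' @param t positive integer candidate sweep count.
#' @param obs an [observables()] object.
#' @param coeffs a [coefficient_set()].
#' @param r_cap passed to [invert_shape_law()].
#' @return A one-row data frame with columns `t`, `nu_t`, `mu_t`, `beta_t`,
#'   `delta`, `status` (`"ok"` or `"no_solution"`).
#' @examples
#' obs <- observables(1.665595, 0.6711252, 0.3504422)
#' inference_candidate(5, obs)
#' @export
inference_candidate <- function(t, obs, coeffs = reference_coefficients(),
                                r_cap = 1.5) {
  stopifnot(inherits(obs, "observables"))
  nu_t <- t / obs$lambda_inv
  r <- invert_shape_law(obs$alpha, t, coeffs, r_cap)
  if (is.na(r))
    return(data.frame(t = as.integer(t), nu_t = nu_t, mu_t = NA_real_,
                      beta_t = NA_real_, delta = NA_real_,
                      status = "no_solution"))
  mu_t <- r * nu_t
  beta_t <- rate_law(mu_t, r, t, coeffs)
  data.frame(t = as.integer(t), nu_t = nu_t, mu_t = mu_t, beta_t = beta_t,
             delta = abs(obs$beta - beta_t) / obs$beta, status = "ok")
}

#' Infer (mu, nu, t) from observed length summaries
#'
#' Scans integer candidate sweep counts, computes `(nu_t, mu_t, beta_t)` for
#' each via [inference_candidate()], and selects
#' `t_hat = arg min |beta - beta_t| / beta` among candidates with a
#' solution (ties broken toward smaller `t`).
#'
#' @param obs an [observables()] object (or a `fit_summary`).
#' @param t_range integer vector of candidate sweep counts.
#' @param coeffs a [coefficient_set()].
#' @param r_cap passed to [invert_shape_law()].
#' @return An object of class `inference_result`: list with the candidate
#'   table `candidates`, the selected `t_hat`, and `mu_hat`, `nu_hat`.
#' @examples
#' infer(observables(1.665595, 0.6711252, 0.3504422), t_range = 3:7)
#' @export
infer <- function(obs, t_range = 1:30, coeffs = reference_coefficients(),
                  r_cap = 1.5) {
  if (inherits(obs, "fit_summary")) obs <- observables(obs)
  stopifnot(inherits(obs, "observables"), length(t_range) >= 1L)
  t_range <- sort(unique(as.integer(t_range)))
  cand <- do.call(rbind, lapply(t_range, inference_candidate,
                                obs = obs, coeffs = coeffs, r_cap = r_cap))
  ok <- cand$status == "ok"
  if (!any(ok)) {
    cond <- structure(
      class = c("inference_failed", "error", "condition"),
      list(message = "no candidate t admits a solution for mu",
           call = sys.call(), candidates = cand))
    stop(cond)
  }
  best <- which(ok)[which.min(cand$delta[ok])]
  structure(list(observables = obs, candidates = cand,
                 t_hat = cand$t[best], mu_hat = cand$mu_t[best],
                 nu_hat = cand$nu_t[best], coeffs = coeffs),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, digits = 6, ...) {
  cat("Fractionation inference\n")
  print(x$observables)
  tab <- x$candidates
  m <- rbind(mu = tab$mu_t, nu = tab$nu_t, beta_t = tab$beta_t,
             `100 delta` = 100 * tab$delta)
  colnames(m) <- paste0("t=", tab$t)
  print(round(m, digits))
  cat(sprintf("Estimate: t = %d, mu = %.6g, nu = %.6g\n",
              x$t_hat, x$mu_hat, x$nu_hat))
  invisible(x)
}
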