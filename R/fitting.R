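#' Fit an exponential rate to visible segment lengths
#'
#' Maximum-likelihood rate of an exponential sample: `1 / mean(x)`.  For
#' visible segment lengths after sweep `t` the model predicts rate
#' `lambda^{-1} = t / nu`.
#'
#' @param lengths positive numeric vector, `n >= 2`.
#' @return The fitted rate (single numeric), with attributes `n` and `se`
#'   (asymptotic standard error `rate / sqrt(n)`).
#' @examples
#' fit_exponential(c(2, 2, 2))  # 0.5
#' @export
fit_exponential <- function(lengths) {
  lengths <- check_lengths(lengths, min_n = 2L)
  rate <- 1 / mean(lengths)
  structure(rate, n = length(lengths), se = rate / sqrt(length(lengths)))
}

#' Fit a gamma distribution to invisible segment lengths
#'
#' Fits shape `alpha` and rate `beta` by maximum likelihood (via
#' \pkg{fitdistrplus}) or by the method of moments
#' (`alpha = mean^2/var`, `beta = mean/var`).  If the likelihood
#' optimization fails, the moment estimate is returned with a warning and
#' `method = "moments"`.
#'
#' @param lengths positive numeric vector, `n >= 10`.  Lengths below 1e-12
#'   (float dust from truncated splices) are dropped with a message.
#' @param method `"mle"` (default) or `"moments"`.
#' @return A list of class `gamma_fit` with elements `alpha`, `beta`,
#'   `method`, `n`, and (for MLE) `sd` — the estimated standard errors.
#' @examples
#' set.seed(1)
#' fit_gamma(rgamma(500, shape = 0.9, rate = 0.35))
#' @export
fit_gamma <- function(lengths, method = c("mle", "moments")) {
  method <- match.arg(method)
  lengths <- check_lengths(lengths, min_n = 10L)
  m <- mean(lengths); v <- var(lengths)
  if (v < 1e-12 * m^2)
    stop("degenerate sample: variance is (near) zero", call. = FALSE)
  mom <- c(alpha = m^2 / v, beta = m / v)
  if (method == "moments")
    return(structure(list(alpha = unname(mom[1L]), beta = unname(mom[2L]),
                          method = "moments", n = length(lengths), sd = NULL),
                     class = "gamma_fit"))
  fit <- tryCatch(
    fitdistrplus::fitdist(lengths, "gamma", method = "mle",
                          start = as.list(c(shape = unname(mom[1L]),
                                            rate = unname(mom[2L])))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$estimate)) {
    warning("gamma MLE did not converge; returning moment estimates",
            call. = FALSE)
    return(structure(list(alpha = unname(mom[1L]), beta = unname(mom[2L]),
                          method = "moments", n = length(lengths), sd = NULL),
                     class = "gamma_fit"))
  }
  structure(list(alpha = unname(fit$estimate["shape"]),
                 beta = unname(fit$estimate["rate"]),
                 method = "mle", n = length(lengths),
                 sd = unname(fit$sd)),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("Gamma fit (%s, n = %d): shape alpha = %.6g, rate beta = %.6g\n",
              x$method, x$n, x$alpha, x$beta))
  invisible(x)
}

check_lengths <- function(lengths, min_n) {
  if (!is.numeric(lengths) || !length(lengths))
    stop("'lengths' must be a non-empty numeric vector", call. = FALSE)
  if (any(lengths < 0)) stop("'lengths' must be positive", call. = FALSE)
  dust <- lengths < 1e-12   # float dust from truncated splices
  if (any(dust)) {
    message(sum(dust), " near-zero length(s) dropped")
    lengths <- lengths[!dust]
  }
  if (length(lengths) < min_n)
    stop("need at least ", min_n, " lengths", call. = FALSE)
  lengths
}

#' Cullen-Frey moment coordinates of a length sample
#'
#' Computes the squared sample skewness and the (Pearson, normal = 3) sample
#' kurtosis, the coordinates used in Cullen-Frey diagrams to identify a
#' candidate distribution family, together with a bootstrap cloud.  For an
#' exponential the point is (4, 9); for a gamma with shape `k` it is
#' `(4/k, 3 + 6/k)` — the gamma family is the line `kurtosis = 3 + 1.5 *
#' skewness^2`.
#'
#' @param lengths positive numeric vector, `n >= 10`.
#' @param n_boot number of bootstrap replicates for the cloud.
#' @return A list of class `cullen_frey` with `skewness_sq`, `kurtosis`,
#'   `n`, and a two-column matrix `boot`.
#' @examples
#' set.seed(1)
#' cullen_frey(rexp(2000), n_boot = 20)
#' @export
cullen_frey <- function(lengths, n_boot = 100L) {
  lengths <- check_lengths(lengths, min_n = 10L)
  pt <- moment_point(lengths)
  boot <- t(vapply(seq_len(n_boot), function(i)
    moment_point(sample(lengths, replace = TRUE)), numeric(2)))
  colnames(boot) <- c("skewness_sq", "kurtosis")
  structure(list(skewness_sq = pt[1L], kurtosis = pt[2L],
                 n = length(lengths), boot = boot),
            class = "cullen_frey")
}

moment_point <- function(x) {
  m <- mean(x); d <- x - m
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  c((m3 / m2^1.5)^2, m4 / m2^2)
}

#' @export
print.cullen_frey <- function(x, ...) {
  cat(sprintf(
    "Cullen-Frey point (n = %d): skewness^2 = %.4g, kurtosis = %.4g\n",
    x$n, x$skewness_sq, x$kurtosis))
  cat("  reference: exponential (4, 9); gamma line kurtosis = 3 + 1.5 skewness^2\n")
  invisible(x)
}

#' @export
plot.cullen_frey <- function(x, ...) {
  sk <- c(x$boot[, 1L], x$skewness_sq, 0, 4)
  ku <- c(x$boot[, 2L], x$kurtosis, 3, 9)
  plot(x$boot, pch = 16, col = "grey70",
       xlim = range(sk), ylim = rev(range(ku)),
       xlab = "square of skewness", ylab = "kurtosis", ...)
  curve(3 + 1.5 * x, add = TRUE, lty = 2)        # gamma family
  points(4, 9, pch = 8)                          # exponential
  points(0, 3, pch = 3)                          # normal
  points(x$skewness_sq, x$kurtosis, pch = 17, col = "red")
  invisible(x)
}

#' Observable summary of a length sample
#'
#' Computes the three observables the inference procedure needs: the
#' exponential rate `lambda^{-1}` of the visible lengths and the gamma
#' shape/rate `(alpha, beta)` of the invisible lengths.
#'
#' @param sample a `length_sample` (see [collect_lengths()]), or a list with
#'   numeric elements `visible` and `invisible`.
#' @param method gamma fitting method, `"mle"` or `"moments"`.
#' @return A list of class `fit_summary` with `lambda_inv`, `alpha`, `beta`,
#'   `n_visible`, `n_invisible`, `method`.
#' @examples
#' run <- run_fractionation(sweep_params(3, 1),
#'                          sim_config(2000, sweeps = 2, replicates = 2, seed = 1))
#' fit_summary(collect_lengths(run))
#' @export
fit_summary <- function(sample, method = c("mle", "moments")) {
  method <- match.arg(method)
  stopifnot(is.list(sample), !is.null(sample$visible), !is.null(sample$invisible))
  lam_inv <- fit_exponential(sample$visible)
  gf <- fit_gamma(sample$invisible, method = method)
  structure(list(lambda_inv = as.numeric(lam_inv), alpha = gf$alpha,
                 beta = gf$beta, n_visible = attr(lam_inv, "n"),
                 n_invisible = gf$n, method = gf$method),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf(
    "Fitted observables (%s): lambda^-1 = %.6g (n = %d), alpha = %.6g, beta = %.6g (n = %d)\n",
    x$method, x$lambda_inv, x$n_visible, x$alpha, x$beta, x$n_invisible))
  invisible(x)
}
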