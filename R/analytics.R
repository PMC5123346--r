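#' Mean visible spacing after t sweeps
#'
#' After sweep `t` the surviving deletion points along the visible genome
#' form a point process with mean spacing `lambda_t = nu / t`
#' (`lambda_exact()`).  `lambda_recursion()` obtains the same value by
#' iterating the one-step update `lambda_t = nu / (1 + nu / lambda_{t-1})`
#' from `lambda_1 = nu`; the recursion telescopes to `nu / t`.
#' `lambda_two_sweep_approx()` is an older first-order approximation for
#' `t = 2`, `nu / (1 + nu / (nu + mu))`; it is retained for reference only
#' and is inconsistent with the recursion (which gives `nu / 2`), so it is
#' never used downstream.
#'
#' @param nu positive real; mean deletion-point spacing.
#' @param mu positive real; mean deletion length.
#' @param t positive integer; sweep count.
#' @return Positive numeric spacing.
#' @examples
#' lambda_exact(3, 5)       # 0.6
#' lambda_recursion(3, 5)   # identical
#' @export
lambda_exact <- function(nu, t) {
  check_nu_t(nu, t)
  nu / t
}

#' @rdname lambda_exact
#' @export
lambda_recursion <- function(nu, t) {
  check_nu_t(nu, t)
  vapply(t, function(ti) {
    lam <- nu
    if (ti > 1L) for (s in 2:ti) lam <- nu / (1 + nu / lam)
    lam
  }, numeric(1))
}

#' @rdname lambda_exact
#' @export
lambda_two_sweep_approx <- function(nu, mu) {
  stopifnot(nu > 0, mu > 0)
  nu / (1 + nu / (nu + mu))
}

check_nu_t <- function(nu, t) {
  if (!is.numeric(nu) || any(nu <= 0)) stop("'nu' must be positive", call. = FALSE)
  if (!is.numeric(t) || any(t < 1) || any(t != floor(t)))
    stop("'t' must be a positive integer", call. = FALSE)
  invisible(NULL)
}

#' Distribution of the number of deletion points swallowed by a new event
#'
#' A new deletion event of exponential length (mean `mu`) dropped on a
#' visible genome whose deletion points have exponential spacing (mean
#' `lam`) swallows a geometrically distributed number `q` of pre-existing
#' points: `p_q = lam/(mu+lam) * (mu/(mu+lam))^q`, `q = 0, 1, 2, ...`.
#'
#' `overlap_pmf_integral()` evaluates the defining integrals for `q = 0`
#' (length-biased spacing containing the event, no point swallowed) and
#' `q = 1` (event reaching into exactly the next spacing) by numerical
#' quadrature; it exists as an independent cross-check of the closed form.
#'
#' @param q non-negative integer (vector allowed); for the quadrature
#'   version only 0 or 1.
#' @param mu positive real; mean deletion length.
#' @param lam positive real; mean spacing of the current visible deletion
#'   points.
#' @return Probability (vector for `overlap_pmf`).
#' @examples
#' overlap_pmf(0:3, mu = 1, lam = 3)
#' overlap_pmf_integral(1, mu = 1, lam = 3)  # 0.1875 by quadrature
#' @export
overlap_pmf <- function(q, mu, lam) {
  stopifnot(mu > 0, lam > 0)
  if (any(q < 0) || any(q != floor(q)))
    stop("'q' must be a non-negative integer", call. = FALSE)
  lam / (mu + lam) * (mu / (mu + lam))^q
}

#' @rdname overlap_pmf
#' @export
overlap_pmf_integral <- function(q, mu, lam) {
  stopifnot(length(q) == 1L, q %in% c(0, 1), mu > 0, lam > 0)
  Lam <- function(l) dexp(l, rate = 1 / lam)
  if (q == 0) {
    # P(event stays inside the spacing): length-biased spacing l, uniform
    # start x, deletion length shorter than l - x
    inner <- function(l) {
      vapply(l, function(li) {
        integrate(function(x) pexp(li - x, rate = 1 / mu), 0, li,
                  rel.tol = 1e-9)$value / li
      }, numeric(1))
    }
    out <- integrate(function(l) l * Lam(l) / lam * inner(l), 0, Inf,
                     rel.tol = 1e-8)
  } else {
    # event crosses the next deletion point but stops within the next
    # spacing z
    innerx <- function(l, z) {
      integrate(function(x) pexp(l - x + z, rate = 1 / mu) -
                             pexp(l - x, rate = 1 / mu),
                0, l, rel.tol = 1e-9)$value
    }
    innerz <- function(l) {
      vapply(l, function(li) {
        integrate(function(z) Lam(z) *
                    vapply(z, innerx, numeric(1), l = li),
                  0, Inf, rel.tol = 1e-8)$value
      }, numeric(1))
    }
    out <- integrate(function(l) Lam(l) * innerz(l) / lam, 0, Inf,
                     rel.tol = 1e-7)
  }
  if (out$message != "OK")
    stop("quadrature did not converge: ", out$message, call. = FALSE)
  out$value
}

#' Expected retained fraction of the genome
#'
#' Each sweep deletes on average a fraction `mu / (nu + mu)` of the visible
#' genome, so after `t` sweeps approximately `(1 - mu/(nu+mu))^t` of the
#' original genome is still visible.
#'
#' @param mu,nu positive reals; deletion length and spacing means.
#' @param t non-negative integer (vector allowed).
#' @return Fraction in (0, 1].
#' @examples
#' retained_proportion(1, 3, t = 0:5)
#' @export
retained_proportion <- function(mu, nu, t) {
  stopifnot(mu > 0, nu > 0, all(t >= 0), all(t == floor(t)))
  (1 - mu / (nu + mu))^t
}

#' Event-count distribution and its per-sweep update
#'
#' `pi_t(i)` is the proportion of event counters equal to `i` after sweep
#' `t`; after the first sweep it is a point mass at 1.  During a later sweep
#' each new deletion event creates one counter of value
#' `1 + C(z_1) + ... + C(z_q)` (swallowing `q` existing counters drawn, under
#' the model's independence approximation, from the current `pi`), so the
#' expected per-event change is
#' `Delta(i) = gain(i) - pi(i) * sum_q q p_q`, with
#' `gain(i) = p_0 1(i = 1) + sum_{q >= 1} p_q (pi^{*q})(i - 1)`,
#' where `pi^{*q}` is the q-fold convolution (equivalently a sum over ordered
#' compositions of `i - 1` into `q` positive parts) and `p_q` the geometric
#' overlap law ([overlap_pmf()]) at the pre-sweep spacing `lam`.
#'
#' Two update modes are available.  Mode `"event"` (the default) weights
#' `Delta` by the expected number of events per existing counter,
#' `w = lam / (nu + mu)`, and renormalizes by the net change in counter
#' count: `pi' = (pi + w Delta) / (1 + w (1 - mu/lam))`; this reproduces the
#' exact counter bookkeeping (up to the independence approximation).  Mode
#' `"renorm"` simply renormalizes `pi + Delta`.
#'
#' @param pi numeric vector; `pi[i]` is the probability of counter value
#'   `i`, summing to 1.
#' @param mu positive real; mean deletion length.
#' @param lam positive real; mean spacing of the pre-sweep deletion points.
#' @param mode `"event"` or `"renorm"`.
#' @param nu mean spacing parameter, used to derive the event weight in mode
#'   `"event"` (ignored if `weight` is given).
#' @param weight optional explicit events-per-counter weight.
#' @return Updated probability vector of the same length.
#' @examples
#' pi1 <- c(1, 0, 0, 0, 0, 0)
#' pi_update(pi1, mu = 1, lam = 3, nu = 3)
#' @export
pi_update <- function(pi, mu, lam, mode = c("event", "renorm"),
                      nu = NULL, weight = NULL) {
  mode <- match.arg(mode)
  stopifnot(mu > 0, lam > 0)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-6)
    stop("'pi' must be a normalized probability vector", call. = FALSE)
  delta <- pi_delta(pi, mu, lam)
  if (mode == "event") {
    if (is.null(weight)) {
      if (is.null(nu))
        stop("mode 'event' needs 'nu' (or an explicit 'weight')", call. = FALSE)
      weight <- lam / (nu + mu)
    }
    out <- (pi + weight * delta) / (1 + weight * (1 - mu / lam))
  } else {
    # plain renormalization can push entries negative when mu > lam (the
    # per-event loss exceeds the standing mass); floor at zero, as usual for
    # this approximate mode
    out <- pmax(pi + delta, 0)
  }
  out[out < 0 & out > -1e-9] <- 0
  if (any(out < 0))
    stop("update produced a negative probability; increase i_max or weight down",
         call. = FALSE)
  out / sum(out)
}

# expected per-event change Delta(i); gain via iterated convolution
pi_delta <- function(pi, mu, lam) {
  i_max <- length(pi)
  p <- overlap_pmf(0:(i_max - 1L), mu, lam)
  gain <- numeric(i_max)
  gain[1L] <- p[1L]                       # q = 0 creates a counter of 1
  cq <- pi                                # q-fold convolution of pi
  if (i_max > 1L) {
    for (q in 1:(i_max - 1L)) {
      if (q > 1L) {
        # truncated convolution: values above i_max - 1 can never feed gain
        cq <- convolve_trunc(cq, pi, i_max - 1L)
      }
      # new counter i = 1 + sum of q swallowed values
      idx <- seq_len(i_max - 1L)
      gain[idx + 1L] <- gain[idx + 1L] + p[q + 1L] * cq[idx]
      if (p[q + 1L] < 1e-14) break
    }
  }
  gain - pi * (mu / lam)                  # E q = mu/lam counters destroyed
}

convolve_trunc <- function(a, b, n) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq_len(i - 1L)
    if (length(j)) out[i] <- sum(a[j] * b[i - j])
  }
  out
}

#' @rdname pi_update
#' @param t positive integer; number of sweeps.
#' @param i_max truncation bound for counter values.
#' @return `pi_trajectory()` returns a list of length `t`; element `s` is
#'   the distribution after sweep `s` (element 1 is the point mass at 1).
#'   At sweep `s >= 2` the update uses the pre-sweep spacing
#'   `lam = nu / (s - 1)`.
#' @examples
#' traj <- pi_trajectory(mu = 1, nu = 3, t = 3)
#' sapply(traj, sum)
#' @export
pi_trajectory <- function(mu, nu, t, i_max = 50L, mode = c("event", "renorm")) {
  mode <- match.arg(mode)
  stopifnot(mu > 0, nu > 0, t >= 1, t == floor(t))
  pi <- c(1, numeric(i_max - 1L))
  out <- vector("list", t)
  out[[1L]] <- pi
  if (t > 1L) for (s in 2:t) {
    lam <- nu / (s - 1)
    pi <- pi_update(pi, mu, lam, mode = mode, nu = nu)
    out[[s]] <- pi
  }
  out
}
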