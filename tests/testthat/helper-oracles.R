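# Independent oracles and small builders used across the suite.

# All ordered compositions of n into q positive parts (matrix, one row each).
compositions <- function(n, q) {
  if (q == 1L) return(matrix(n, ncol = 1L))
  out <- NULL
  for (first in seq_len(n - q + 1L)) {
    rest <- compositions(n - first, q - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# Brute-force gain(i): p_0 1{i=1} + sum_q p_q sum_{compositions of i-1} prod pi
brute_gain <- function(pi, mu, lam, i) {
  g <- if (i == 1L) overlap_pmf(0, mu, lam) else 0
  if (i >= 2L) {
    for (q in seq_len(i - 1L)) {
      cm <- compositions(i - 1L, q)
      g <- g + overlap_pmf(q, mu, lam) *
        sum(apply(cm, 1L, function(cc) prod(pi[cc])))
    }
  }
  g
}

# hand-built alternating state (visible first), lengths given per segment
build_state <- function(lengths, visible_first = TRUE, counters = NULL,
                        sweep_index = 1L) {
  ends <- cumsum(lengths)
  starts <- c(0, ends[-length(ends)])
  vis <- rep(c(visible_first, !visible_first), length.out = length(lengths))
  cnt <- rep(NA_integer_, length(lengths))
  if (is.null(counters)) counters <- rep(1L, sum(!vis))
  cnt[!vis] <- as.integer(counters)
  st <- structure(list(start = starts, end = ends, visible = vis, counter = cnt),
                  sweep_index = as.integer(sweep_index),
                  target_length = sum(lengths[vis]),
                  class = "genome_state")
  validate_genome_state(st)
}

# pooled chi-square test of the swallowed-count histogram against the
# geometric overlap law, with sweep-specific spacing; the geometric tail is
# merged into one bin with expected count at least 5
overlap_chisq_p <- function(run, mu, nu, sweeps) {
  obs <- NULL
  expd <- NULL
  for (t in sweeps) {
    q <- unlist(lapply(run$sweeps[[t]]$events, `[[`, "q"))
    lam <- lambda_exact(nu, t - 1L)
    p <- overlap_pmf(0:40, mu, lam)
    n <- length(q)
    tailp <- rev(cumsum(rev(p)))            # P(q >= value), value = index - 1
    k <- max(which(n * tailp >= 5)) - 1L    # tail bin collects q >= k
    o <- tabulate(factor(pmin(q, k), levels = 0:k), nbins = k + 1L)
    obs <- c(obs, o)
    expd <- c(expd, n * p[seq_len(k)], n * tailp[k + 1L])
  }
  stat <- sum((obs - expd)^2 / expd)
  pchisq(stat, df = length(obs) - length(sweeps), lower.tail = FALSE)
}
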