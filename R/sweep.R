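#' Run one deletion sweep over the visible genome
#'
#' A sweep alternately samples a spacing `x' ~ Exp(mean nu)` and a deletion
#' length `a ~ Exp(mean mu)` along the concatenated visible coordinates; each
#' event deletes `[x, x + a)` and the cursor advances to the end of the
#' deletion before the next spacing is drawn.  Sampling stops when the next
#' deletion point falls beyond the current visible extent; a final deletion
#' overhanging the right edge is truncated there (its counter still merges
#' any swallowed deletion points).  Uses the current R random number stream.
#'
#' @param state a `genome_state` with positive visible length.
#' @param params a [sweep_params()] object.
#' @return A list with the updated `state` (its `sweep_index` incremented)
#'   and an `events` data frame (see [apply_deletion()]), with an extra
#'   logical column `truncated`.
#' @examples
#' set.seed(1)
#' s1 <- run_sweep(new_genome(1000), sweep_params(nu = 3, mu = 1))
#' nrow(s1$events)
#' @export
run_sweep <- function(state, params) {
  stopifnot(inherits(state, "genome_state"), inherits(params, "sweep_params"))
  V <- visible_length(state)
  if (V <= 0) stop("genome has no visible length left", call. = FALSE)
  nu <- params$nu; mu <- params$mu

  # strict alternation of spacing/length draws from one rate-1 stream
  n_guess <- max(16L, ceiling(1.15 * V / (nu + mu) + 6 * sqrt(V / (nu + mu))))
  sp <- numeric(0); aa <- numeric(0)
  repeat {
    u <- rexp(2L * n_guess)
    sp <- c(sp, u[c(TRUE, FALSE)] * nu)
    aa <- c(aa, u[c(FALSE, TRUE)] * mu)
    x <- cumsum(sp + c(0, aa[-length(aa)]))
    if (x[length(x)] >= V) break
    n_guess <- max(16L, ceiling(n_guess / 2))
  }
  keep <- x < V
  x <- x[keep]; aa <- aa[keep]

  res <- apply_events(state, x, pmin(aa, V - x))
  res$events$truncated <- x + aa > V
  attr(res$state, "sweep_index") <- attr(state, "sweep_index") + 1L
  res
}

#' Replenish the visible genome from a replicate trial
#'
#' After a sweep the visible length has shrunk below the target `G`.
#' Replenishment appends alternating segments copied (with their counters)
#' from a replicate trial at the same sweep index until the total visible
#' length equals `G` again; the last copied visible segment is truncated to
#' hit `G` exactly.  The splice preserves alternation: the first copied
#' segment has the opposite visibility of the recipient's last segment.
#'
#' @param state a `genome_state` to top up.
#' @param pool a `genome_state` or list of them (replicate trials at the same
#'   sweep index, generated with the same parameters), used cyclically.
#' @return The replenished `genome_state`.
#' @export
replenish <- function(state, pool) {
  stopifnot(inherits(state, "genome_state"))
  if (inherits(pool, "genome_state")) pool <- list(pool)
  G <- attr(state, "target_length")
  deficit <- G - visible_length(state)
  if (deficit <= 1e-9) return(state)
  if (!length(pool)) stop("replenishment needed but donor pool is empty", call. = FALSE)

  si <- attr(state, "sweep_index")
  for (donor in pool) {
    if (attr(donor, "sweep_index") != si)
      stop("donor and recipient are at different sweep indices", call. = FALSE)
  }

  di <- 0L
  guard <- 0L
  repeat {
    di <- di %% length(pool) + 1L
    donor <- pool[[di]]
    n <- length(state$start)
    ends_visible <- state$visible[n]
    # donor pointer: first segment of opposite visibility to the recipient end
    ptr <- which(donor$visible != ends_visible)[1L]
    if (is.na(ptr)) { guard <- guard + 1L; if (guard > length(pool)) break; next }
    idx <- ptr:length(donor$start)
    dvis <- donor$visible[idx]
    dlen <- donor$end[idx] - donor$start[idx]
    cumvis <- cumsum(ifelse(dvis, dlen, 0))
    cut <- which(dvis & cumvis >= deficit - 1e-12)[1L]
    if (is.na(cut)) cut <- length(idx)  # whole donor slice, continue with next
    take <- idx[seq_len(cut)]
    shift <- state$end[n] - donor$start[take[1L]]
    ts <- donor$start[take] + shift
    te <- donor$end[take] + shift
    tv <- donor$visible[take]
    tc <- donor$counter[take]
    added <- cumvis[cut]
    if (added >= deficit - 1e-12) {
      te[length(te)] <- te[length(te)] - (added - deficit)  # truncate to hit G
      done <- TRUE
    } else done <- FALSE
    keep <- te - ts > 1e-12
    state <- new_genome_state(c(state$start, ts[keep]), c(state$end, te[keep]),
                              c(state$visible, tv[keep]), c(state$counter, tc[keep]),
                              sweep_index = si, target_length = G)
    if (done) return(state)
    deficit <- G - visible_length(state)
    guard <- guard + 1L
    if (guard > 100L * length(pool))
      stop("replenishment failed: donor pool has too little visible length", call. = FALSE)
  }
  stop("replenishment failed: no donor segment of suitable visibility", call. = FALSE)
}

#' Simulate a full fractionation trajectory
#'
#' Runs `config$replicates` replicate genomes through `config$sweeps`
#' independent sweeps.  When replenishment is on, each replicate is topped up
#' to `G` after every sweep by copying segments from the next replicate (in
#' round-robin order), as in the standard experimental design.  All
#' randomness flows from `config$seed`; the trajectory is reproducible
#' bit-for-bit.
#'
#' @param params a [sweep_params()] object.
#' @param config a [sim_config()] object.
#' @return An object of class `fractionation_run`: a list with `params`,
#'   `config`, and `sweeps` — one element per sweep holding `states` (the
#'   post-replenishment `genome_state` of each replicate), `events` (one
#'   data frame per replicate), and `retained` (per-replicate ratio of
#'   visible length after the sweep, before replenishment, to visible length
#'   at the sweep start).
#' @examples
#' run <- run_fractionation(sweep_params(3, 1),
#'                          sim_config(genome_length = 2000, sweeps = 2,
#'                                     replicates = 2, seed = 7))
#' run$sweeps[[2]]$retained
#' @export
run_fractionation <- function(params, config) {
  stopifnot(inherits(params, "sweep_params"), inherits(config, "sim_config"))
  if (config$genome_length < 100 * params$mu)
    warning("genome_length is less than 100 * mu; edge effects may be large",
            call. = FALSE)
  set.seed(config$seed)
  R <- config$replicates
  states <- replicate(R, new_genome(config$genome_length), simplify = FALSE)
  sweeps <- vector("list", config$sweeps)
  for (s in seq_len(config$sweeps)) {
    v0 <- vapply(states, visible_length, numeric(1))
    res <- lapply(states, run_sweep, params = params)
    pre <- lapply(res, `[[`, "state")
    retained <- vapply(pre, visible_length, numeric(1)) / v0
    if (config$replenish) {
      states <- lapply(seq_len(R), function(r)
        replenish(pre[[r]], pre[[if (R > 1L) r %% R + 1L else 1L]]))
    } else states <- pre
    sweeps[[s]] <- list(states = states,
                        events = lapply(res, `[[`, "events"),
                        retained = retained)
  }
  structure(list(params = params, config = config, sweeps = sweeps),
            class = "fractionation_run")
}

#' @export
print.fractionation_run <- function(x, ...) {
  cat(sprintf("Fractionation run: nu = %g, mu = %g, %d sweeps x %d replicates, G = %g\n",
              x$params$nu, x$params$mu, x$config$sweeps, x$config$replicates,
              x$config$genome_length))
  for (s in seq_along(x$sweeps)) {
    sm <- collect_lengths(x$sweeps[[s]]$states)
    cat(sprintf(
      "  sweep %d: mean visible %.4g (n=%d), mean invisible %.4g (n=%d), retained %.4f\n",
      s, mean(sm$visible), length(sm$visible),
      mean(sm$invisible), length(sm$invisible),
      mean(x$sweeps[[s]]$retained)))
  }
  invisible(x)
}

#' Pool segment lengths from one or more genome states
#'
#' @param states a `genome_state`, a list of them at the same sweep index, or
#'   a `fractionation_run` (with `sweep` selecting which sweep; default the
#'   last).
#' @param sweep sweep index to extract when `states` is a run.
#' @return An object of class `length_sample`: a list with numeric vectors
#'   `visible` and `invisible` and the `sweep_index`.
#' @examples
#' collect_lengths(new_genome(100))
#' @export
collect_lengths <- function(states, sweep = NULL) {
  if (inherits(states, "fractionation_run")) {
    if (is.null(sweep)) sweep <- length(states$sweeps)
    states <- states$sweeps[[sweep]]$states
  }
  if (inherits(states, "genome_state")) states <- list(states)
  si <- unique(vapply(states, function(s) attr(s, "sweep_index"), integer(1)))
  if (length(si) != 1L)
    stop("states are at different sweep indices", call. = FALSE)
  vis <- unlist(lapply(states, function(s) (s$end - s$start)[s$visible]))
  inv <- unlist(lapply(states, function(s) (s$end - s$start)[!s$visible]))
  structure(list(visible = as.numeric(vis), invisible = as.numeric(inv),
                 sweep_index = si),
            class = "length_sample")
}

#' @export
print.length_sample <- function(x, ...) {
  cat(sprintf(
    "Length sample at sweep %d: %d visible (mean %.4g), %d invisible (mean %.4g)\n",
    x$sweep_index, length(x$visible), mean(x$visible),
    length(x$invisible), mean(x$invisible)))
  invisible(x)
}

#' Histogram of overlap counts q
#'
#' Tabulates, over the deletion events of one sweep (or several), how many
#' pre-existing deletion points each event swallowed.  Under the model this
#' count is geometric with parameter `mu / (mu + lambda)` (see
#' [overlap_pmf()]).
#'
#' @param events an events data frame as returned in a sweep, a list of them,
#'   or a `fractionation_run` with `sweep` selecting one sweep.
#' @param sweep sweep index when `events` is a run.
#' @return A data frame with columns `q` and `count` covering `0..max(q)`.
#' @export
overlap_histogram <- function(events, sweep = NULL) {
  if (inherits(events, "fractionation_run")) {
    if (is.null(sweep)) sweep <- length(events$sweeps)
    events <- events$sweeps[[sweep]]$events
  }
  if (is.data.frame(events)) events <- list(events)
  q <- unlist(lapply(events, `[[`, "q"))
  qmax <- if (length(q)) max(q) else 0L
  data.frame(q = 0:qmax,
             count = as.integer(tabulate(factor(q, levels = 0:qmax))))
}

#' Empirical distribution of event counters
#'
#' Census of the counters `C(x)` over all invisible runs: the empirical
#' version of the event-count distribution `pi_t(i)`.
#'
#' @param states a `genome_state`, list of states, or `fractionation_run`
#'   (`sweep` selects the sweep, default the last).
#' @param sweep sweep index when `states` is a run.
#' @return An object of class `counter_census`: data frame with columns `i`,
#'   `count`, `proportion` (proportions sum to 1), plus attribute `n_total`.
#'   A state with no invisible runs yields a zero-row census with
#'   `n_total = 0` (an empty census, not an error).
#' @export
counter_census <- function(states, sweep = NULL) {
  if (inherits(states, "fractionation_run")) {
    if (is.null(sweep)) sweep <- length(states$sweeps)
    states <- states$sweeps[[sweep]]$states
  }
  if (inherits(states, "genome_state")) states <- list(states)
  cts <- unlist(lapply(states, function(s) s$counter[!s$visible]))
  if (!length(cts)) {
    out <- data.frame(i = integer(0), count = integer(0), proportion = numeric(0))
  } else {
    imax <- max(cts)
    cnt <- tabulate(cts, nbins = imax)
    out <- data.frame(i = seq_len(imax), count = cnt, proportion = cnt / sum(cnt))
  }
  structure(out, n_total = length(cts), class = c("counter_census", "data.frame"))
}
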