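#' Genome state: alternating visible/invisible segments
#'
#' A `genome_state` records the fractionating genome copy in its original
#' (pre-deletion) coordinates as an ordered, contiguous list of half-open
#' segments `[start, end)` whose visibility strictly alternates.  Every
#' invisible run carries an event counter `C(x)`: the number of deletion
#' events merged into that run (a fresh deletion contributes 1 plus the
#' counters of any deletion points it swallows).
#'
#' `new_genome()` creates the state at time 0: a single visible segment of
#' length `G`.
#'
#' @param genome_length positive real; initial visible length `G`.
#' @return An object of class `genome_state`: a list with numeric vectors
#'   `start`, `end`, logical `visible`, integer `counter` (`NA` on visible
#'   rows), and attributes `sweep_index` and `target_length`.
#' @examples
#' g <- new_genome(100)
#' visible_length(g)
#' @export
new_genome <- function(genome_length = 10000) {
  if (!is.numeric(genome_length) || length(genome_length) != 1L || genome_length <= 0)
    stop("'genome_length' must be a single positive number", call. = FALSE)
  new_genome_state(start = 0, end = as.numeric(genome_length),
                   visible = TRUE, counter = NA_integer_,
                   sweep_index = 0L, target_length = as.numeric(genome_length))
}

# low-level constructor, no validation
new_genome_state <- function(start, end, visible, counter, sweep_index,
                             target_length) {
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 visible = as.logical(visible), counter = as.integer(counter)),
            sweep_index = as.integer(sweep_index),
            target_length = as.numeric(target_length),
            class = "genome_state")
}

#' Validate the invariants of a genome state
#'
#' Checks that segments are sorted, contiguous and non-overlapping, that
#' visibility strictly alternates, and that every invisible run (and only
#' invisible runs) carries a counter of at least 1.  Used after every
#' simulator operation in the test suite.
#'
#' @param state a `genome_state`.
#' @param tol absolute tolerance for contiguity of segment junctions.
#' @return `state`, invisibly; stops with an informative error on violation.
#' @export
validate_genome_state <- function(state, tol = 1e-8) {
  stopifnot(inherits(state, "genome_state"))
  n <- length(state$start)
  if (n == 0L) stop("genome state has no segments", call. = FALSE)
  if (any(state$end <= state$start))
    stop("segment with non-positive length", call. = FALSE)
  if (n > 1L) {
    if (any(diff(state$start) <= 0))
      stop("segments not sorted by start", call. = FALSE)
    gaps <- state$start[-1L] - state$end[-n]
    if (any(abs(gaps) > tol))
      stop("segments not contiguous", call. = FALSE)
    if (any(state$visible[-1L] == state$visible[-n]))
      stop("adjacent segments share a visibility state", call. = FALSE)
  }
  inv <- !state$visible
  if (any(is.na(state$counter[inv])) || any(state$counter[inv] < 1L, na.rm = TRUE))
    stop("invisible run with missing or non-positive counter", call. = FALSE)
  if (any(!is.na(state$counter[!inv])))
    stop("visible segment carries a counter", call. = FALSE)
  invisible(state)
}

#' @rdname new_genome
#' @param state a `genome_state`.
#' @export
visible_length <- function(state) {
  sum((state$end - state$start)[state$visible])
}

#' @rdname new_genome
#' @export
total_span <- function(state) {
  state$end[length(state$end)] - state$start[1L]
}

#' @rdname new_genome
#' @export
sweep_index <- function(state) attr(state, "sweep_index")

#' @export
as.data.frame.genome_state <- function(x, ...) {
  data.frame(start = x$start, end = x$end,
             state = ifelse(x$visible, "visible", "invisible"),
             counter = x$counter)
}

#' @export
print.genome_state <- function(x, ...) {
  n <- length(x$start)
  cat(sprintf(
    "Genome state after sweep %d: %d segments on [%g, %g), visible %g of %g\n",
    sweep_index(x), n, x$start[1L], x$end[n], visible_length(x), total_span(x)))
  inv <- !x$visible
  if (any(inv))
    cat(sprintf("  %d invisible runs, mean length %.4g, counters 1..%d\n",
                sum(inv), mean((x$end - x$start)[inv]), max(x$counter[inv])))
  invisible(x)
}

#' Map between concatenated-visible and original coordinates
#'
#' Deletion events are placed along the concatenation of the currently
#' visible segments.  `map_concat_to_original()` maps a concatenated
#' coordinate back to the original axis by skipping invisible runs;
#' `map_original_to_concat()` is its inverse on visible points.
#'
#' @param state a `genome_state`.
#' @param x_conc numeric vector of concatenated-visible coordinates in
#'   `[0, visible_length(state))`.
#' @param y numeric vector of original coordinates lying in visible segments.
#' @return Numeric vector of mapped coordinates.
#' @examples
#' g <- new_genome(100)
#' d <- apply_deletion(g, 10, 10)
#' map_concat_to_original(d$state, 15)  # 25: skips the invisible run
#' @export
map_concat_to_original <- function(state, x_conc) {
  vs <- state$start[state$visible]
  ve <- state$end[state$visible]
  vlen <- ve - vs
  b <- cumsum(vlen)
  bl <- c(0, b[-length(b)])
  if (any(x_conc < 0) || any(x_conc >= b[length(b)]))
    stop("'x_conc' outside [0, total visible length)", call. = FALSE)
  j <- findInterval(x_conc, bl)
  vs[j] + (x_conc - bl[j])
}

#' @rdname map_concat_to_original
#' @export
map_original_to_concat <- function(state, y) {
  vs <- state$start[state$visible]
  ve <- state$end[state$visible]
  vlen <- ve - vs
  bl <- c(0, head(cumsum(vlen), -1L))
  j <- findInterval(y, vs)
  if (any(j < 1L) || any(y >= ve[pmax(j, 1L)]))
    stop("'y' does not lie in a visible segment", call. = FALSE)
  bl[j] + (y - vs[j])
}

# Apply a batch of deletion intervals given in the *current* concatenated
# visible coordinates.  Intervals must be disjoint, sorted, and satisfy
# x + a <= visible length (within one sweep, events generated left to right
# are disjoint on the sweep-start concatenation, so the whole sweep can be
# applied at once).  Returns list(state, events) where events is a data frame
# with one row per deletion (x_conc, x_orig, a, q, counter) and a list column
# `swallowed` holding the counters of the swallowed deletion points.
apply_events <- function(state, x, a, tol = 1e-9) {
  stopifnot(inherits(state, "genome_state"))
  if (length(x) == 0L) {
    ev <- data.frame(x_conc = numeric(0), x_orig = numeric(0), a = numeric(0),
                     q = integer(0), counter = integer(0))
    ev$swallowed <- list()
    return(list(state = state, events = ev))
  }
  if (any(a <= 0)) stop("deletion length 'a' must be positive", call. = FALSE)
  vrow <- which(state$visible)
  vs <- state$start[vrow]
  ve <- state$end[vrow]
  vlen <- ve - vs
  m <- length(vlen)
  V <- sum(vlen)
  if (any(x < 0) || any(x >= V) || any(x + a > V + tol))
    stop("deletion interval outside [0, total visible length)", call. = FALSE)
  e <- pmin(x + a, V)
  if (length(x) > 1L && any(x[-1L] < e[-length(e)]))
    stop("deletion intervals must be sorted and disjoint", call. = FALSE)

  b <- cumsum(vlen)          # right concat boundary of visible segment j
  bl <- c(0, b[-m])          # left boundary
  j <- findInterval(x, bl)   # segment containing the deletion point
  k <- findInterval(e, bl, left.open = TRUE)  # segment containing the end
  ox <- vs[j] + (x - bl[j])
  oe <- vs[k] + (e - bl[k])

  # junction jun (1..m-1) = invisible run between visible segments jun, jun+1;
  # its concat coordinate is b[jun].  A junction is swallowed iff b[jun] lies
  # in [x, e).  Given disjoint sorted events that is jun in [jun_lo, k-1],
  # where jun_lo = j except in the measure-zero case x == bl[j] (the event
  # starts exactly at an existing deletion point, which it then swallows).
  jun_lo <- ifelse(x == bl[j] & j > 1L, j - 1L, j)
  q <- k - jun_lo
  jc <- if (m > 1L) state$counter[vrow[seq_len(m - 1L)] + 1L] else integer(0)
  S <- c(0, cumsum(as.numeric(jc)))
  swsum <- S[k] - S[jun_lo]
  counter <- as.integer(1 + swsum)

  swallowed <- vector("list", length(x))
  has <- q > 0L
  if (any(has)) {
    juns <- sequence(q[has], from = jun_lo[has])
    grp <- factor(rep(which(has), q[has]), levels = seq_along(x))
    swallowed <- split(jc[juns], grp)
  } else {
    swallowed[] <- list(integer(0))
  }

  # old invisible runs that survive
  inv_rows <- which(!state$visible)
  drop_rows <- integer(0)
  if (m > 1L && any(has)) {
    d <- tabulate(jun_lo[has], nbins = m) - tabulate(k[has], nbins = m)
    sw <- cumsum(d)[seq_len(m - 1L)] > 0L
    drop_rows <- (vrow[seq_len(m - 1L)] + 1L)[sw]
  }
  keep <- setdiff(inv_rows, drop_rows)

  rs <- c(state$start[keep], ox)
  re <- c(state$end[keep], oe)
  rc <- c(as.numeric(state$counter[keep]), as.numeric(counter))
  o <- order(rs)
  rs <- rs[o]; re <- re[o]; rc <- rc[o]

  # merge runs separated by a sub-tolerance gap (measure-zero adjacency)
  if (length(rs) > 1L) {
    grp <- cumsum(c(TRUE, rs[-1L] - re[-length(re)] >= tol))
    if (grp[length(grp)] < length(rs)) {
      rs <- as.numeric(tapply(rs, grp, min))
      re <- as.numeric(tapply(re, grp, max))
      rc <- as.numeric(tapply(rc, grp, sum))
    }
  }

  # rebuild alternating table: visible gaps between runs
  lo <- state$start[1L]
  hi <- state$end[length(state$end)]
  gs <- c(lo, re)
  ge <- c(rs, hi)
  gok <- (ge - gs) >= tol
  ps <- c(gs[gok], rs)
  pe <- c(ge[gok], re)
  pv <- c(rep(TRUE, sum(gok)), rep(FALSE, length(rs)))
  pc <- c(rep(NA_integer_, sum(gok)), as.integer(rc))
  o <- order(ps)
  # snap junctions exactly contiguous
  ps <- ps[o]; pe <- pe[o]
  if (length(ps) > 1L) ps[-1L] <- pe[-length(pe)]
  ps[1L] <- lo; pe[length(pe)] <- hi

  new_state <- new_genome_state(ps, pe, pv[o], pc[o],
                                sweep_index = attr(state, "sweep_index"),
                                target_length = attr(state, "target_length"))
  ev <- data.frame(x_conc = x, x_orig = ox, a = e - x, q = as.integer(q),
                   counter = counter)
  ev$swallowed <- swallowed
  list(state = new_state, events = ev)
}

#' Apply a single deletion event
#'
#' Deletes the visible mass in the concatenated-visible interval
#' `[x_conc, x_conc + a)`.  Any pre-existing deletion points inside the
#' interval are swallowed: their invisible runs merge with the new one, and
#' the merged run's counter is 1 plus the sum of the swallowed counters.
#'
#' @param state a `genome_state`.
#' @param x_conc deletion point, in concatenated-visible coordinates.
#' @param a positive deletion length; `x_conc + a` must not exceed the total
#'   visible length.
#' @return A list with the updated `state` and a one-row `events` data frame
#'   recording `x_conc`, `x_orig`, `a`, the number `q` of swallowed deletion
#'   points, the merged `counter`, and the swallowed counters.
#' @examples
#' g <- new_genome(100)
#' d <- apply_deletion(g, 10, 5)
#' as.data.frame(d$state)
#' @export
apply_deletion <- function(state, x_conc, a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number", call. = FALSE)
  if (!is.numeric(x_conc) || length(x_conc) != 1L || x_conc < 0)
    stop("'x_conc' must be a single non-negative number", call. = FALSE)
  apply_events(state, x_conc, a)
}
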