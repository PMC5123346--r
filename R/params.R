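#' Model parameters of the fractionation process
#'
#' `sweep_params()` bundles the two parameters of the deletion point process:
#' `nu`, the mean of the exponential spacing between successive deletion
#' points along visible coordinates, and `mu`, the mean of the exponential
#' length deleted by a single event.  Both are in genome-length units.
#' Typically `nu` is much larger than `mu`, but this is not required and is
#' not enforced.
#'
#' @param nu positive real; mean deletion-point spacing.
#' @param mu positive real; mean deletion length.
#' @return An object of class `sweep_params`.
#' @examples
#' sweep_params(nu = 3, mu = 1)
#' @export
sweep_params <- function(nu, mu) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0)
    stop("'nu' must be a single positive number", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single positive number", call. = FALSE)
  structure(list(nu = as.numeric(nu), mu = as.numeric(mu)),
            class = "sweep_params")
}

#' @export
print.sweep_params <- function(x, ...) {
  cat(sprintf("Fractionation parameters: nu = %g (spacing), mu = %g (deletion length)\n",
              x$nu, x$mu))
  invisible(x)
}

#' Simulation configuration
#'
#' Settings of a simulated fractionation experiment: the initial visible
#' genome length `G`, the number of sweeps, the number of replicate trials,
#' the random seed, and whether the visible genome is replenished back to `G`
#' after each sweep by copying segments from a replicate trial.
#'
#' @param genome_length positive real; initial visible length `G`.
#' @param sweeps positive integer; number of sweeps `t` to run.
#' @param replicates positive integer; number of replicate trials.
#' @param seed integer random seed.
#' @param replenish logical; restore visible length to `G` after each sweep.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(sweeps = 5, seed = 1)
#' @export
sim_config <- function(genome_length = 10000, sweeps = 1, replicates = 5,
                       seed = 1L, replenish = TRUE) {
  if (!is.numeric(genome_length) || length(genome_length) != 1L ||
      !is.finite(genome_length) || genome_length <= 0)
    stop("'genome_length' must be a single positive number", call. = FALSE)
  sweeps <- as.integer(sweeps)
  replicates <- as.integer(replicates)
  if (is.na(sweeps) || sweeps < 1L) stop("'sweeps' must be a positive integer", call. = FALSE)
  if (is.na(replicates) || replicates < 1L)
    stop("'replicates' must be a positive integer", call. = FALSE)
  structure(list(genome_length = as.numeric(genome_length), sweeps = sweeps,
                 replicates = replicates, seed = as.integer(seed),
                 replenish = isTRUE(replenish)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: G = %g, sweeps = %d, replicates = %d, seed = %d, replenish = %s\n",
    x$genome_length, x$sweeps, x$replicates, x$seed, x$replenish))
  invisible(x)
}
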