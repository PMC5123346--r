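#' Read and write genome states as TSV segment tables
#'
#' `write_segments()` serializes a `genome_state` to a tab-separated table
#' with columns `start`, `end`, `state`, `counter` (counter empty on visible
#' rows); coordinates are written with 9 significant digits, and the sweep
#' index and target length are kept in `#`-comment header lines.
#' `read_segments()` reads the table back, validating every genome-state
#' invariant and naming the offending line on failure.
#'
#' @param state a `genome_state`.
#' @param path file path.
#' @return `write_segments()` returns `path` invisibly; `read_segments()`
#'   returns a `genome_state`.
#' @export
write_segments <- function(state, path) {
  stopifnot(inherits(state, "genome_state"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sweep_index\t%d", attr(state, "sweep_index")),
               sprintf("# target_length\t%.9g", attr(state, "target_length")),
               "start\tend\tstate\tcounter"), con)
  writeLines(sprintf("%.9g\t%.9g\t%s\t%s", state$start, state$end,
                     ifelse(state$visible, "visible", "invisible"),
                     ifelse(state$visible, "", as.character(state$counter))),
             con)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE)
  if (!length(body) || length(body) < 2L)
    stop("empty segment file: ", path, call. = FALSE)
  hdr <- strsplit(lines[body[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr, c("start", "end", "state", "counter")))
    stop("line ", body[1L], ": expected header 'start end state counter'",
         call. = FALSE)
  rows <- body[-1L]
  if (!length(rows)) stop("segment file has a header but no rows", call. = FALSE)
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L | nf > 4L))
    stop("line ", rows[which(nf < 3L | nf > 4L)[1L]], ": malformed row",
         call. = FALSE)
  fields <- lapply(fields, function(f) c(f, rep("", 4L - length(f))))
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  st <- vapply(fields, `[[`, "", 3L)
  cf <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end) | !st %in% c("visible", "invisible"))
  if (length(bad))
    stop("line ", rows[bad[1L]], ": malformed row", call. = FALSE)
  visible <- st == "visible"
  counter <- suppressWarnings(as.integer(cf))
  bad <- which(!visible & (cf == "" | is.na(counter)))
  if (length(bad))
    stop("line ", rows[bad[1L]], ": invisible row without counter", call. = FALSE)
  counter[visible] <- NA_integer_

  getmeta <- function(key, default) {
    m <- grep(paste0("^# ", key, "\t"), meta, value = TRUE)
    if (length(m)) as.numeric(strsplit(m[1L], "\t", fixed = TRUE)[[1L]][2L])
    else default
  }
  state <- new_genome_state(start, end, visible, counter,
                            sweep_index = as.integer(getmeta("sweep_index", 0)),
                            target_length = getmeta("target_length",
                                                    end[length(end)] - start[1L]))
  tryCatch(validate_genome_state(state),
           error = function(e) stop("invalid segment table '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  state
}

#' Read and write length samples
#'
#' TSV with header `length  state`, one segment length per row.
#'
#' @param sample a `length_sample` (see [collect_lengths()]).
#' @param path file path.
#' @return `write_lengths()` returns `path` invisibly; `read_lengths()`
#'   returns a `length_sample` (with `sweep_index = NA`).
#' @export
write_lengths <- function(sample, path) {
  stopifnot(is.list(sample), !is.null(sample$visible), !is.null(sample$invisible))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("length\tstate", con)
  writeLines(c(sprintf("%.9g\tvisible", sample$visible),
               sprintf("%.9g\tinvisible", sample$invisible)), con)
  invisible(path)
}

#' @rdname write_lengths
#' @export
read_lengths <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("length", "state") %in% names(df)))
    stop("expected columns 'length' and 'state' in ", path, call. = FALSE)
  structure(list(visible = df$length[df$state == "visible"],
                 invisible = df$length[df$state == "invisible"],
                 sweep_index = NA_integer_),
            class = "length_sample")
}

#' Write a JSON run manifest
#'
#' Records the command, resolved parameters, seed and package version so
#' every output file is traceable to one invocation.
#'
#' @param path output file.
#' @param command character description of the invocation.
#' @param parameters named list of resolved parameters.
#' @param seed integer seed.
#' @param timestamps logical; include wall-clock timestamps (off by default
#'   so that fixture output is byte-reproducible).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, parameters, seed,
                               timestamps = FALSE) {
  manifest <- list(command = command, parameters = parameters,
                   seed = as.integer(seed),
                   software_version = as.character(packageVersion("fractionate")))
  if (timestamps) manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

fixture_presets <- list(
  mini = list(mu = 1, nu = 3, sweeps = 2L, genome_length = 500,
              replicates = 2L),
  table2 = list(mu = 1, nu = 3, sweeps = 5L, genome_length = 10000,
                replicates = 5L),
  table3 = list(mu = 6, nu = 12, sweeps = 2L, genome_length = 10000,
                replicates = 5L),
  table4 = list(mu = 1, nu = 3, sweeps = 3L, genome_length = 10000,
                replicates = 5L),
  table5 = list(mu = 5, nu = 15, sweeps = 8L, genome_length = 10000,
                replicates = 5L),
  `table1-grid` = list(mu = 1:10, nu = 3 * (1:10), sweeps = 2L,
                       genome_length = 10000, replicates = 5L))

#' Generate deterministic fixture files for a named scenario
#'
#' Runs the simulator under one of the standard configurations and writes,
#' per configuration: the final-sweep segment table of each replicate, the
#' pooled length sample, and a JSON summary (fitted observables and mean
#' retained fraction).  Identical seeds produce byte-identical files.
#'
#' Scenarios: `"mini"` (a small fast configuration for tests), `"table2"`
#' (mu = 1, nu = 3, t = 5), `"table3"` (6, 12, 2), `"table4"` (1, 3, 3),
#' `"table5"` (5, 15, 8), and `"table1-grid"` (mu = 1..10 with nu = 3 mu at
#' t = 2).
#'
#' @param scenario preset name.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
fixture_generator <- function(scenario, seed = 1L, dir = ".") {
  if (!scenario %in% names(fixture_presets))
    stop("unknown scenario '", scenario, "'; available: ",
         paste(names(fixture_presets), collapse = ", "), call. = FALSE)
  preset <- fixture_presets[[scenario]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in seq_along(preset$mu)) {
    mu <- preset$mu[g]; nu <- preset$nu[g]
    tag <- if (length(preset$mu) > 1L) sprintf("%s_mu%g", scenario, mu) else scenario
    run <- run_fractionation(
      sweep_params(nu = nu, mu = mu),
      sim_config(genome_length = preset$genome_length, sweeps = preset$sweeps,
                 replicates = preset$replicates, seed = seed + g - 1L))
    last <- run$sweeps[[preset$sweeps]]
    for (r in seq_along(last$states)) {
      f <- file.path(dir, sprintf("%s_rep%d_segments.tsv", tag, r))
      write_segments(last$states[[r]], f)
      files <- c(files, f)
    }
    sample <- collect_lengths(run)
    f <- file.path(dir, sprintf("%s_lengths.tsv", tag))
    write_lengths(sample, f)
    files <- c(files, f)
    fs <- fit_summary(sample)
    f <- file.path(dir, sprintf("%s_summary.json", tag))
    jsonlite::write_json(
      list(scenario = scenario, mu = mu, nu = nu, sweeps = preset$sweeps,
           genome_length = preset$genome_length,
           replicates = preset$replicates, seed = seed + g - 1L,
           lambda_inv = fs$lambda_inv, alpha = fs$alpha, beta = fs$beta,
           n_visible = fs$n_visible, n_invisible = fs$n_invisible,
           mean_retained_last_sweep = mean(last$retained)),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}
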