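#' Run independent seeded replicates of a pipeline
#'
#' Each replicate `r` runs [run_bo()] with a seed derived deterministically
#' from `(master_seed, r)`, so replicates use independent substreams:
#' re-running any subset reproduces exactly the same results.  A replicate
#' that errors is recorded as a failure and the others proceed.
#'
#' @inheritParams run_bo
#' @param n_replicates Number of replicates (convergence studies typically
#'   use 64).
#' @param master_seed Seed the replicate seeds derive from; defaults to
#'   `config$seed`.
#' @return List of `bo_result` objects (a failed replicate is a list with an
#'   `error` message instead).
#' @export
run_replicates <- function(objective, space, config, n_replicates,
                           master_seed = config$seed) {
  stopifnot(n_replicates >= 1L)
  lapply(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- derive_seed(master_seed, 1000L + r)
    tryCatch(run_bo(objective, space, cfg),
             error = function(e) list(error = conditionMessage(e),
                                      replicate = r))
  })
}

#' Extract the convergence trace of a run
#'
#' @param result A `bo_result`.
#' @return Data frame with `index`, the non-increasing `best_so_far` value,
#'   and `cum_wall_time`.
#' @export
convergence_trace <- function(result) {
  stopifnot(inherits(result, "bo_result"))
  result$history[, c("index", "best_so_far", "cum_wall_time")]
}

#' Aggregate convergence traces across replicates
#'
#' Per evaluation index, the median and first/third quartiles of the
#' best-so-far values across replicates.  Quartiles use the
#' linear-interpolation convention between order statistics (R quantile
#' type 7), recorded in the output's attributes.
#'
#' @param traces List of equal-length traces ([convergence_trace()] data
#'   frames, or bare numeric best-so-far vectors).
#' @return Data frame with `index`, `median`, `q1`, `q3`; attributes
#'   `quantile_convention` and `n_replicates`.
#' @export
aggregate_convergence <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  vals <- lapply(traces, function(tr) {
    if (is.data.frame(tr)) tr$best_so_far else as.numeric(tr)
  })
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L) {
    stop("all traces must have equal length (got ",
         paste(unique(lens), collapse = ", "), ")", call. = FALSE)
  }
  M <- do.call(cbind, vals)
  qs <- t(apply(M, 1, quantile, probs = c(0.25, 0.5, 0.75), type = 7,
                names = FALSE))
  out <- data.frame(index = seq_len(nrow(M)), median = qs[, 2],
                    q1 = qs[, 1], q3 = qs[, 3])
  attr(out, "quantile_convention") <- "linear interpolation (R type 7)"
  attr(out, "n_replicates") <- length(vals)
  out
}

#' Export replicate results to disk
#'
#' Writes, per replicate, a trace table
#' (`replicate_<r>_trace.csv`: index, phase, acquisition, parameters, y,
#' best-so-far, cumulative wall time) and a run summary
#' (`replicate_<r>_summary.json`: config echo, seed, incumbent parameters
#' and value, selected prior, coin-flip sequence), plus an aggregated
#' convergence table (`aggregated_convergence.csv`).
#'
#' @param results List of `bo_result` objects (failed replicates skipped).
#' @param out_dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
export_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  written <- character(0)
  ok_results <- Filter(function(r) inherits(r, "bo_result"), results)
  for (i in seq_along(ok_results)) {
    res <- ok_results[[i]]
    trace_path <- file.path(out_dir, sprintf("replicate_%03d_trace.csv", i))
    write.csv(res$history, trace_path, row.names = FALSE)
    summary_path <- file.path(out_dir,
                              sprintf("replicate_%03d_summary.json", i))
    cfg <- res$config
    summary <- list(
      config = list(acquisition = cfg$acquisition, prior_mode = cfg$prior,
                    budget = cfg$budget, seed = cfg$seed),
      seed = cfg$seed,
      incumbent = list(par = as.list(res$incumbent$par),
                       value = res$incumbent$value),
      selected_prior = res$prior,
      coin_flips = res$flips,
      quantile_convention = "linear interpolation (R type 7)")
    # I(17) significant digits: doubles survive the round trip bitwise
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = I(17), null = "null")
    written <- c(written, trace_path, summary_path)
  }
  if (length(ok_results) >= 1L) {
    agg <- aggregate_convergence(lapply(ok_results, convergence_trace))
    agg_path <- file.path(out_dir, "aggregated_convergence.csv")
    write.csv(agg, agg_path, row.names = FALSE)
    written <- c(written, agg_path)
  }
  invisible(written)
}

#' Read a flat YAML run configuration
#'
#' Expected keys: `space` (list of parameter entries with `name`, `lower`,
#' `upper`, and optional `scale`), `pipeline` (list with `acquisition` and
#' `prior`), `budget`, `seed`, and optional `out` (output directory) and
#' `replicates`.
#'
#' @param path Path to a YAML file.
#' @return List with a [search_space()] `space`, a [bo_config()] `config`,
#'   and any `out`/`replicates` entries.
#' @export
read_run_config <- function(path) {
  # keep YAML 1.1 boolean-like scalars (y/N/no/...) as literal strings:
  # they are perfectly good parameter names
  keep <- function(x) x
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                               "bool#no" = keep))
  if (is.null(cfg$space)) stop("config is missing 'space'", call. = FALSE)
  sp <- cfg$space
  space <- search_space(
    name = vapply(sp, function(p) as.character(p$name), ""),
    lower = vapply(sp, function(p) as.numeric(p$lower), 0),
    upper = vapply(sp, function(p) as.numeric(p$upper), 0),
    scale = vapply(sp, function(p) as.character(p$scale %||% "linear"), ""))
  pl <- cfg$pipeline %||% list()
  config <- bo_config(acquisition = pl$acquisition %||% "ensemble",
                      prior = pl$prior %||% "auto_restricted",
                      budget = cfg$budget %||% 100,
                      seed = cfg$seed %||% 1)
  list(space = space, config = config, out = cfg$out,
       replicates = cfg$replicates)
}
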