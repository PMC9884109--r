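#' Load and validate an experiment configuration file
#'
#' Reads a JSON (or YAML, if the `yaml` package is installed)
#' configuration with up to three blocks: `task`, `agent`, and
#' `experiment`. Unknown keys anywhere are rejected, as are invalid
#' values (e.g. a learning rate above 1, or a ratio/sum pair implying
#' one). An empty or absent agent block yields the defaults
#' (`alpha_sr = 0.05`, `beta = 5`, `gamma = 0.7`, and both systems'
#' rates from `sum_alpha = 1` with ratio 1).
#'
#' Agent keys: `rep1`, `rep2`, either explicit rates (`alpha1_pos`,
#' `alpha1_neg`, `alpha2_pos`, `alpha2_neg`) or `ratio1`/`ratio2` with
#' `sum_alpha`, plus `alpha_sr`, `beta`, `gamma`. Task keys: `kind`
#' (`"navigation"` or `"twostage"`) and `variant`. Experiment keys:
#' `n_sims`, `master_seed`.
#'
#' @param path Path to the configuration file.
#' @return A list with `task` (a `nav_task` or `twostage_task`), `agent`
#'   (an [agent_spec()]), and `experiment` (list of settings).
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  check_keys(raw, c("task", "agent", "experiment"), "top level")

  task_raw <- raw$task %||% list(kind = "navigation", variant = "original")
  check_keys(task_raw, c("kind", "variant"), "task")
  kind <- match.arg(task_raw$kind %||% "navigation",
    c("navigation", "twostage"))
  task <- if (kind == "navigation") {
    nav_task(task_raw$variant %||% "original")
  } else {
    twostage_task(task_raw$variant %||% "random_walk")
  }

  ag <- raw$agent %||% list()
  check_keys(ag, c(
    "rep1", "rep2", "alpha1_pos", "alpha1_neg", "alpha2_pos", "alpha2_neg",
    "ratio1", "ratio2", "sum_alpha", "alpha_sr", "beta", "gamma"
  ), "agent")
  sum_alpha <- ag$sum_alpha %||% 1
  rate_pair <- function(pos_key, neg_key, ratio_key) {
    if (!is.null(ag[[ratio_key]])) {
      if (!is.null(ag[[pos_key]]) || !is.null(ag[[neg_key]])) {
        stop("give either `", ratio_key, "` or explicit rates, not both",
          call. = FALSE
        )
      }
      r <- rates_from_ratio(sum_alpha, ag[[ratio_key]])
      if (any(r > 1)) {
        stop("`", ratio_key, "` = ", ag[[ratio_key]], " with sum_alpha = ",
          sum_alpha, " implies a learning rate above 1",
          call. = FALSE
        )
      }
      c(r[["pos"]], r[["neg"]])
    } else {
      c(
        ag[[pos_key]] %||% (sum_alpha / 2),
        ag[[neg_key]] %||% (sum_alpha / 2)
      )
    }
  }
  r1 <- rate_pair("alpha1_pos", "alpha1_neg", "ratio1")
  r2 <- rate_pair("alpha2_pos", "alpha2_neg", "ratio2")
  agent <- agent_spec(
    rep1 = ag$rep1 %||% "SR", rep2 = ag$rep2 %||% "IR",
    alpha1_pos = r1[1], alpha1_neg = r1[2],
    alpha2_pos = r2[1], alpha2_neg = r2[2],
    alpha_sr = ag$alpha_sr %||% 0.05,
    beta = ag$beta %||% 5,
    gamma = ag$gamma %||% if (kind == "twostage") 1 else 0.7
  )

  ex <- raw$experiment %||% list()
  check_keys(ex, c("n_sims", "master_seed"), "experiment")
  experiment <- list(
    n_sims = as.integer(ex$n_sims %||% 100L),
    master_seed = as.integer(ex$master_seed %||% 1L)
  )
  if (experiment$n_sims < 1L) {
    stop("`n_sims` must be a positive integer", call. = FALSE)
  }
  list(task = task, agent = agent, experiment = experiment)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop("unknown ", where, " key(s): ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(x)
}

#' Export a sweep result as delimited text
#'
#' Writes the long-format table (one row per condition with parameters,
#' mean, SD, SEM, and n) to `path`. For ratio-grid sweeps a companion
#' `<path minus extension>_matrix.csv` holds the mean-performance matrix
#' (rows: system-1 ratio, columns: system-2 ratio), the layout used for
#' heat maps.
#'
#' @param sweep A `sweep_result`.
#' @param path Output CSV path.
#' @return Invisibly, the path(s) written.
#' @export
export_sweep <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  written <- path
  if (all(c("ratio1", "ratio2") %in% names(sweep))) {
    r1 <- sort(unique(sweep$ratio1))
    r2 <- sort(unique(sweep$ratio2))
    if (nrow(sweep) == length(r1) * length(r2)) {
      m <- matrix(NA_real_, length(r1), length(r2),
        dimnames = list(signif(r1, 6), signif(r2, 6))
      )
      m[cbind(match(sweep$ratio1, r1), match(sweep$ratio2, r2))] <-
        sweep$mean
      mpath <- sub("(\\.[^.]+)?$", "_matrix.csv", path)
      utils::write.csv(m, mpath)
      written <- c(written, mpath)
    }
  }
  invisible(written)
}

#' Read back an exported sweep table
#'
#' @param path CSV written by [export_sweep()].
#' @return The long-format sweep data frame.
#' @export
read_sweep <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a machine-readable run manifest
#'
#' Records everything needed to re-execute a result exactly: the
#' configuration, the master seed and spawned child seeds, the package
#' version, and a timestamp.
#'
#' @param path Output JSON path.
#' @param config Configuration list (echoed verbatim).
#' @param master_seed Master seed.
#' @param n_child_seeds Number of child seeds to record (they are a pure
#'   function of the master seed via [child_seeds()]).
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, config, master_seed, n_child_seeds = 0) {
  manifest <- list(
    package = "opponentSR",
    version = as.character(utils::packageVersion("opponentSR")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = master_seed,
    child_seeds = if (n_child_seeds > 0) {
      child_seeds(master_seed, n_child_seeds)
    } else {
      NULL
    },
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Export a single-run environment/behaviour trace
#'
#' Writes one row per reward consumption: goal time, placement epoch and
#' placement state, for inspection or downstream plotting.
#'
#' @param run A `nav_run`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_run <- function(run, path) {
  utils::write.csv(
    data.frame(
      goal_time = run$goal_times,
      placement_epoch = run$placement_epochs,
      placement_state = run$placement_states
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}
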