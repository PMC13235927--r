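#' Run a replicate ensemble
#'
#' Runs `replicates` independent stochastic realizations of one
#' configuration. Replicate seeds are spawned deterministically from
#' `base_seed` (via `set.seed(base_seed)` followed by one `sample.int()`
#' draw per replicate), so rerunning with the same base seed reproduces
#' the ensemble exactly.
#'
#' @param I,P network pair.
#' @param params a [trait_params()].
#' @param initial_state abundance matrix; defaults to
#'   [make_initial_conditions()] for the pair.
#' @param t_max,record_interval passed to [simulation_config()].
#' @param replicates number of replicates.
#' @param base_seed integer seed governing the whole ensemble.
#' @param label experiment label attached to the ensemble.
#' @param stop_single_host,max_events passed to [run_simulation()].
#' @return a `replicate_ensemble`: list with `trajectories`, `label`,
#'   `base_seed`, `seeds`.
#' @export
run_ensemble <- function(I, P, params, initial_state = NULL,
                         t_max = 20000, record_interval = 5,
                         replicates = 300L, base_seed = 1L,
                         label = NULL, stop_single_host = FALSE,
                         max_events = Inf) {
  if (is.null(initial_state)) initial_state <- make_initial_conditions(I)
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  tables <- engine_tables(I, P, params)
  trajectories <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg <- simulation_config(I, P, params, initial_state,
                             t_max = t_max, record_interval = record_interval,
                             seed = seeds[r])
    trajectories[[r]] <- run_simulation(cfg, stop_single_host = stop_single_host,
                                        max_events = max_events, tables = tables)
  }
  new_replicate_ensemble(trajectories, label = label, base_seed = base_seed,
                         seeds = seeds)
}

new_replicate_ensemble <- function(trajectories, label = NULL,
                                   base_seed = NULL, seeds = NULL) {
  structure(list(trajectories = trajectories, label = label,
                 base_seed = base_seed, seeds = seeds),
            class = "replicate_ensemble")
}

#' @export
print.replicate_ensemble <- function(x, ...) {
  cat(sprintf("<replicate_ensemble%s: %d replicates>\n",
              if (!is.null(x$label)) paste0(" '", x$label, "'") else "",
              length(x$trajectories)))
  invisible(x)
}

#' @export
length.replicate_ensemble <- function(x) length(x$trajectories)

final_states <- function(ensemble) {
  lapply(ensemble$trajectories, function(tr) tr$final_state)
}
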