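#' Open or create a run store
#'
#' Persistent storage for simulation output: a directory holding two
#' plain-text relational tables, `runs.csv` (one row per run: run id,
#' experiment code, replicate index, seed, termination cause, end time,
#' and the serialized configuration) and `abundances.csv` (one row per
#' nonzero subpopulation per snapshot: run id, time in hours, host index,
#' profile bitstring, abundance). Zero-abundance rows are elided on write
#' and re-densified on read. Both tables are ordinary CSV readable by any
#' tabular tooling.
#'
#' @param path directory path.
#' @param create create the directory and empty tables if absent.
#' @return a `run_store` handle.
#' @export
run_store <- function(path, create = TRUE) {
  runs_f <- file.path(path, "runs.csv")
  ab_f <- file.path(path, "abundances.csv")
  if (!dir.exists(path)) {
    if (!create) stop("run store not found: ", path)
    dir.create(path, recursive = TRUE)
  }
  if (!file.exists(runs_f)) {
    data.table::fwrite(data.table::data.table(
      run_id = integer(0), experiment = character(0), replicate = integer(0),
      seed = integer(0), termination = character(0), t_end = numeric(0),
      n_plasmids = integer(0), n_hosts = integer(0), t_max = numeric(0),
      record_interval = numeric(0), config_json = character(0)), runs_f)
  }
  if (!file.exists(ab_f)) {
    data.table::fwrite(data.table::data.table(
      run_id = integer(0), time = numeric(0), host = integer(0),
      profile = character(0), abundance = integer(0)), ab_f)
  }
  structure(list(path = path, runs_file = runs_f, abundances_file = ab_f),
            class = "run_store")
}

serialize_config <- function(config) {
  jsonlite::toJSON(list(
    I = list(structure = config$I$structure, matrix = unname(config$I$matrix)),
    P = list(structure = config$P$structure, matrix = unname(config$P$matrix),
             hub_index = config$P$hub_index),
    params = config$params[c("n_hosts", "n_plasmids", "eta", "mu", "gamma",
                             "e", "cost", "K")],
    a = unname(config$params$a),
    t_max = config$t_max, record_interval = config$record_interval,
    seed = config$seed), auto_unbox = TRUE, digits = NA)
}

deserialize_config <- function(json, initial_state) {
  # CSV readers may leave RFC-4180 doubled quotes in place; undo them
  if (grepl('""', json, fixed = TRUE)) json <- gsub('""', '"', json, fixed = TRUE)
  x <- jsonlite::fromJSON(json)
  I <- build_infection_network("custom", matrix = x$I$matrix)
  I$structure <- x$I$structure
  P <- build_compatibility_network("custom", matrix = x$P$matrix)
  P$structure <- x$P$structure
  if (length(x$P$hub_index) > 0L) P$hub_index <- as.integer(x$P$hub_index)
  params <- trait_params(n_hosts = x$params$n_hosts, n_plasmids = x$params$n_plasmids,
                         eta = x$params$eta, mu = x$params$mu,
                         gamma = x$params$gamma, e = x$params$e,
                         cost = x$params$cost, K = x$params$K, a = as.matrix(x$a))
  simulation_config(I, P, params, initial_state, t_max = x$t_max,
                    record_interval = x$record_interval, seed = x$seed)
}

#' Persist a trajectory in a run store
#'
#' Appends all snapshots of a trajectory (nonzero rows only) and its
#' metadata; the run id is allocated as one more than the store's current
#' maximum.
#'
#' @param record a `plasmid_trajectory`.
#' @param store a [run_store()].
#' @param experiment experiment code/label stored with the run.
#' @param replicate replicate index within the experiment.
#' @return the allocated run id (invisibly).
#' @export
write_trajectory <- function(record, store, experiment = "1", replicate = 1L) {
  runs <- data.table::fread(store$runs_file)
  run_id <- if (nrow(runs) == 0L) 1L else max(runs$run_id) + 1L
  if (any(runs$experiment == as.character(experiment) & runs$replicate == replicate)) {
    stop(sprintf("run (experiment %s, replicate %d) already stored", experiment, replicate))
  }
  np <- record$config$params$n_plasmids
  s <- record$snapshots
  ab <- data.table::data.table(
    run_id = run_id, time = s$time, host = s$host,
    profile = vapply(s$profile, profile_string, character(1), n_plasmids = np),
    abundance = s$abundance)
  meta <- data.table::data.table(
    run_id = run_id, experiment = as.character(experiment),
    replicate = as.integer(replicate),
    seed = record$seed %||% NA_integer_, termination = record$termination,
    t_end = record$t_end, n_plasmids = np,
    n_hosts = record$config$params$n_hosts,
    t_max = record$config$t_max, record_interval = record$config$record_interval,
    config_json = as.character(serialize_config(record$config)))
  data.table::fwrite(meta, store$runs_file, append = TRUE)
  data.table::fwrite(ab, store$abundances_file, append = TRUE)
  invisible(run_id)
}

#' Persist a whole ensemble
#'
#' @param ensemble a `replicate_ensemble`.
#' @param store a [run_store()].
#' @param experiment experiment code for all members.
#' @return run ids (invisibly).
#' @export
write_ensemble <- function(ensemble, store, experiment = ensemble$label %||% "1") {
  ids <- integer(length(ensemble$trajectories))
  for (r in seq_along(ensemble$trajectories)) {
    ids[r] <- write_trajectory(ensemble$trajectories[[r]], store,
                               experiment = experiment, replicate = r)
  }
  invisible(ids)
}

#' Read an ensemble back from a run store
#'
#' Reconstructs the `replicate_ensemble` for one experiment code, ordered
#' by replicate index. Config echoes are checked for homogeneity (same
#' horizon, dimensions and recording grid under one code).
#'
#' @param store a [run_store()].
#' @param experiment experiment code.
#' @return a `replicate_ensemble`.
#' @export
read_ensemble <- function(store, experiment) {
  runs <- data.table::fread(store$runs_file)
  keep <- runs[["experiment"]] == as.character(experiment)
  sel <- runs[which(keep), ]
  if (nrow(sel) == 0L) stop("no runs stored under experiment code ", experiment)
  homo <- c("t_max", "record_interval", "n_plasmids", "n_hosts")
  for (f in homo) {
    if (length(unique(sel[[f]])) != 1L) {
      stop("heterogeneous configurations under experiment code ", experiment,
           ": field ", f)
    }
  }
  ab <- data.table::fread(store$abundances_file,
                          colClasses = list(character = "profile"))
  sel <- sel[order(sel$replicate), ]
  np <- sel$n_plasmids[1]
  trajectories <- vector("list", nrow(sel))
  for (j in seq_len(nrow(sel))) {
    rid <- sel$run_id[j]
    a <- ab[ab$run_id == rid, ]
    pidx <- vapply(strsplit(a$profile, ""), function(ch) {
      profile_index(as.integer(ch))
    }, integer(1))
    snaps <- data.table::data.table(time = a$time, host = a$host,
                                    profile = pidx, abundance = a$abundance)
    t_final <- sel$t_end[j]
    init <- matrix(0L, sel$n_hosts[j], 2L^np)
    s0 <- snaps[abs(snaps$time - min(snaps$time)) < 1e-9]
    init[cbind(s0$host, s0$profile)] <- s0$abundance
    config <- deserialize_config(sel$config_json[j], init)
    fin <- matrix(0L, sel$n_hosts[j], 2L^np,
                  dimnames = list(rownames(config$I$matrix),
                                  rownames(enumerate_profiles(np))))
    sf <- snaps[abs(snaps$time - max(snaps$time)) < 1e-9]
    fin[cbind(sf$host, sf$profile)] <- sf$abundance
    trajectories[[j]] <- structure(
      list(times = sort(unique(snaps$time)), snapshots = snaps,
           final_state = fin, t_end = t_final,
           termination = sel$termination[j], n_events = NA_real_,
           seed = sel$seed[j], config = config),
      class = "plasmid_trajectory")
  }
  new_replicate_ensemble(trajectories, label = as.character(experiment),
                         seeds = sel$seed)
}

#' Write / read a simulation configuration as YAML
#'
#' Human-editable round-trippable configuration files: networks are stored
#' either as structure labels or explicit 0/1 row lists, parameters and
#' initial abundances as plain scalars/lists.
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @return `read_config()` returns a `sim_config`.
#' @export
write_config <- function(config, path) {
  obj <- list(
    infection_network = list(structure = config$I$structure,
                             matrix = apply(unname(config$I$matrix), 1L, as.integer,
                                            simplify = FALSE)),
    compatibility_network = list(structure = config$P$structure,
                                 hub_index = config$P$hub_index,
                                 matrix = apply(unname(config$P$matrix), 1L, as.integer,
                                                simplify = FALSE)),
    params = list(n_hosts = config$params$n_hosts,
                  n_plasmids = config$params$n_plasmids,
                  eta = config$params$eta, mu = config$params$mu,
                  gamma = config$params$gamma, e = config$params$e,
                  cost = config$params$cost, K = config$params$K,
                  a = apply(unname(config$params$a), 1L, as.numeric,
                            simplify = FALSE)),
    initial_state = apply(unname(config$initial_state), 1L, as.integer,
                          simplify = FALSE),
    t_max = config$t_max, record_interval = config$record_interval,
    seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  im <- do.call(rbind, x$infection_network$matrix)
  I <- build_infection_network("custom", matrix = im)
  I$structure <- x$infection_network$structure %||% "custom"
  pm <- do.call(rbind, x$compatibility_network$matrix)
  P <- build_compatibility_network("custom", matrix = pm)
  P$structure <- x$compatibility_network$structure %||% "custom"
  if (!is.null(x$compatibility_network$hub_index)) {
    P$hub_index <- as.integer(x$compatibility_network$hub_index)
  }
  pr <- x$params
  params <- trait_params(n_hosts = pr$n_hosts, n_plasmids = pr$n_plasmids,
                         eta = pr$eta, mu = pr$mu, gamma = pr$gamma, e = pr$e,
                         cost = pr$cost, K = pr$K,
                         a = do.call(rbind, pr$a))
  simulation_config(I, P, params, do.call(rbind, x$initial_state),
                    t_max = x$t_max, record_interval = x$record_interval,
                    seed = x$seed)
}
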