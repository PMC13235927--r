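# Shared fixtures: canonical network motifs, parameter presets, and small
# hand-built systems used across test files.

canonical_I <- function(structure) build_infection_network(structure)
canonical_P <- function(structure, hub = 1L) {
  build_compatibility_network(structure,
                              hub_index = if (structure == "hub") hub else NULL)
}

# all 9 cells of the factorial design as (I, P) pairs
canonical_cells <- function() {
  out <- list()
  for (is in c("full", "nested", "modular")) {
    for (ps in c("full", "modular", "hub")) {
      out[[paste(is, ps, sep = "/")]] <- list(I = canonical_I(is), P = canonical_P(ps))
    }
  }
  out
}

# 1 host x 2 plasmids, fully permissive: the worked-example system
mini_system <- function() {
  I <- build_infection_network("custom", matrix = matrix(1L, 1L, 2L))
  P <- build_compatibility_network("custom", matrix = rbind(c(0L, 1L), c(1L, 0L)))
  list(I = I, P = P)
}

# 1 host x 1 plasmid system for demographic / mean-field comparisons
unihost_system <- function() {
  I <- build_infection_network("custom", matrix = matrix(1L, 1L, 1L))
  P <- build_compatibility_network("custom", matrix = matrix(0L, 1L, 1L))
  list(I = I, P = P)
}

scaled_params <- function(...) preset_params("scaled", ...)

scaled_init <- function(I) make_initial_conditions(I, plasmid_free = 200L,
                                                   monoplasmidic = 10L)

# minimal trajectory object for metric tests (bypasses the engine)
fake_trajectory <- function(states, times, t_max = max(times)) {
  nb <- nrow(states[[1]])
  M <- ncol(states[[1]])
  np <- as.integer(round(log2(M)))
  snaps <- do.call(rbind, lapply(seq_along(times), function(j) {
    st <- states[[j]]
    nz <- which(st > 0, arr.ind = TRUE)
    if (nrow(nz) == 0L) return(NULL)
    data.table::data.table(time = times[j], host = nz[, 1], profile = nz[, 2],
                           abundance = st[nz])
  }))
  if (is.null(snaps)) {
    snaps <- data.table::data.table(time = numeric(0), host = integer(0),
                                    profile = integer(0), abundance = integer(0))
  }
  params <- trait_params(n_hosts = nb, n_plasmids = np)
  structure(list(times = times, snapshots = snaps,
                 final_state = states[[length(states)]],
                 t_end = max(times), termination = "t_max", n_events = NA_real_,
                 seed = NA_integer_,
                 config = list(params = params, t_max = t_max,
                               I = list(matrix = matrix(1L, nb, np)))),
            class = "plasmid_trajectory")
}

fake_ensemble <- function(trajectories, label = "fake") {
  plasmidnets:::new_replicate_ensemble(trajectories, label = label)
}
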