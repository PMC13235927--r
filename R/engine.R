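#' Simulation configuration
#'
#' Bundles everything one stochastic replicate needs: the network pair, the
#' trait parameters, an initial abundance table, the horizon, the snapshot
#' grid and the RNG seed. Initial abundances must be feasible under the
#' network pair: any subpopulation with positive abundance must carry a
#' profile whose plasmids can all infect its host and pairwise co-reside.
#'
#' @param I an `infection_network`.
#' @param P a `compatibility_network`.
#' @param params a [trait_params()] object (dimensions must match the
#'   networks).
#' @param initial_state integer abundance matrix, hosts x profiles in
#'   canonical profile order (see [enumerate_profiles()]); typically from
#'   [make_initial_conditions()].
#' @param t_max simulation horizon in hours.
#' @param record_interval snapshot grid spacing in hours (default 5).
#' @param seed integer RNG seed for the replicate (`NULL` = use the current
#'   RNG state).
#' @return a `sim_config` object.
#' @export
simulation_config <- function(I, P, params, initial_state,
                              t_max = 20000, record_interval = 5,
                              seed = NULL) {
  viol <- validate_network_pair(I, P)
  if (length(viol) > 0L) stop("invalid network pair: ", paste(viol, collapse = "; "))
  nb <- nrow(I$matrix)
  np <- ncol(I$matrix)
  M <- 2L^np
  stopifnot(params$n_hosts == nb, params$n_plasmids == np)
  initial_state <- as.matrix(initial_state)
  storage.mode(initial_state) <- "integer"
  stopifnot(nrow(initial_state) == nb, ncol(initial_state) == M,
            all(initial_state >= 0L))
  if (t_max <= 0) stop("t_max must be positive")
  if (record_interval <= 0) stop("record_interval must be positive")
  feas <- feasibility_table(I, P)
  bad <- which(initial_state > 0L & !feas, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("infeasible initial state: host %d carries infeasible profile %s",
                 bad[1L, 1L], profile_string(bad[1L, 2L], np)))
  }
  structure(list(I = I, P = P, params = params, initial_state = initial_state,
                 t_max = t_max, record_interval = record_interval,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

# Flattened engine tables consumed by the C++ core (0-based indices).
engine_tables <- function(I, P, params, tensor = NULL) {
  np <- ncol(I$matrix)
  nb <- nrow(I$matrix)
  M <- 2L^np
  if (is.null(tensor)) tensor <- build_propensity_tensor(I, P)
  eta_ip <- eta_table(params)

  rec_ptr <- integer(M + 1L)
  rec_cells <- integer(0)
  tc_ptr <- integer(1L)
  tc_r <- integer(0)
  tc_w <- numeric(0)
  for (p in seq_len(M)) {
    rec_ptr[p] <- length(rec_cells)
    sel <- which(tensor$donor_profile == p)
    if (length(sel) > 0L) {
      key <- (tensor$rec_host[sel] - 1L) * M + (tensor$rec_profile[sel] - 1L)
      for (cell in unique(key)) {
        rec_cells <- c(rec_cells, cell)
        ent <- sel[key == cell]
        tc_r <- c(tc_r, tensor$tc_profile[ent] - 1L)
        tc_w <- c(tc_w, tensor$weight[ent])
        tc_ptr <- c(tc_ptr, length(tc_r))
      }
    }
  }
  rec_ptr[M + 1L] <- length(rec_cells)

  ncell <- nb * M
  rev_list <- vector("list", ncell)
  for (p in seq_len(M)) {
    cells <- rec_cells[(rec_ptr[p] + 1L):rec_ptr[p + 1L]]
    if (rec_ptr[p + 1L] == rec_ptr[p]) next
    for (cell in cells) rev_list[[cell + 1L]] <- c(rev_list[[cell + 1L]], p - 1L)
  }
  rev_ptr <- integer(ncell + 1L)
  rev_p <- integer(0)
  for (c in seq_len(ncell)) {
    rev_ptr[c] <- length(rev_p)
    rev_p <- c(rev_p, rev_list[[c]])
  }
  rev_ptr[ncell + 1L] <- length(rev_p)

  list(eta_ip = eta_ip, rec_ptr = rec_ptr, rec_cells = rec_cells,
       tc_ptr = tc_ptr, tc_r = tc_r, tc_w = tc_w,
       rev_ptr = rev_ptr, rev_p = rev_p, tensor = tensor)
}

#' Run one stochastic replicate
#'
#' Executes the exact stochastic simulation algorithm: draw an exponential
#' waiting time from the total event rate, pick a channel proportionally to
#' its total rate, pick the subpopulation(s) involved (for conjugation:
#' donor by infection rate, recipient by abundance within the donor's list,
#' transconjugant by the normalized propensity tensor column), execute the
#' event, and repeat. State is recorded on a fixed time grid (the state
#' after the first event reaching or passing each grid point) plus the
#' final state. The run terminates at `t_max`, at community collapse
#' (all abundances zero), or — optionally — once at most one host
#' population remains extant (host count can never recover, so stopping
#' there is exact for survival-frequency analyses).
#'
#' @param config a [simulation_config()].
#' @param stop_single_host stop as soon as <= 1 host is extant.
#' @param record_events also return the per-event log (channel, cells, dt,
#'   total rate); intended for short diagnostic runs.
#' @param max_events hard guard on the number of events.
#' @param tables precomputed [engine_tables] (internal reuse across
#'   replicates sharing networks and parameters).
#' @return a `plasmid_trajectory`: list with `times`, `snapshots` (a
#'   data.table `time`, `host`, `profile`, `abundance` of nonzero cells),
#'   `final_state`, `t_end`, `termination` (`"t_max"`, `"collapse"`,
#'   `"single_host"`), `n_events`, `seed`, `config`, and optionally
#'   `events`.
#' @export
run_simulation <- function(config, stop_single_host = FALSE,
                           record_events = FALSE, max_events = Inf,
                           tables = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tables)) tables <- engine_tables(config$I, config$P, config$params)
  if (!is.null(config$seed)) set.seed(config$seed)
  params <- config$params
  res <- cpp_gillespie(
    config$initial_state, tables$eta_ip, params$mu, params$e, params$gamma,
    params$b, params$K,
    tables$rec_ptr, tables$rec_cells, tables$tc_ptr, tables$tc_r, tables$tc_w,
    tables$rev_ptr, tables$rev_p,
    config$t_max, config$record_interval,
    stop_single_host, record_events,
    if (is.finite(max_events)) max_events else 1e18)
  np <- params$n_plasmids
  M <- 2L^np
  snap_time <- rep(res$snap_t, res$snap_len)
  snaps <- data.table::data.table(
    time = snap_time,
    host = res$snap_cell %/% M + 1L,
    profile = res$snap_cell %% M + 1L,
    abundance = res$snap_ab)
  final_state <- res$final_state
  dimnames(final_state) <- list(rownames(config$I$matrix),
                                rownames(enumerate_profiles(np)))
  out <- list(times = res$snap_t, snapshots = snaps, final_state = final_state,
              t_end = res$t_end, termination = res$termination,
              n_events = res$n_events, seed = config$seed, config = config)
  if (record_events) {
    out$events <- data.table::as.data.table(res$events)
  }
  structure(out, class = "plasmid_trajectory")
}

#' @export
print.plasmid_trajectory <- function(x, ...) {
  cat(sprintf("<plasmid_trajectory: t_end = %.1f h, %d snapshots, %.0f events, %s>\n",
              x$t_end, length(x$times), x$n_events, x$termination))
  invisible(x)
}

#' Reconstruct the dense state at a recorded time
#'
#' @param record a `plasmid_trajectory`.
#' @param time a recorded snapshot time; defaults to the last one.
#' @return integer abundance matrix hosts x profiles.
#' @export
state_at <- function(record, time = NULL) {
  if (is.null(time)) time <- max(record$times)
  if (!any(abs(record$times - time) < 1e-9)) {
    stop(sprintf("time %.3f is not on the recorded grid", time))
  }
  np <- record$config$params$n_plasmids
  nb <- record$config$params$n_hosts
  M <- 2L^np
  m <- matrix(0L, nb, M, dimnames = dimnames(record$final_state))
  sel <- abs(record$snapshots$time - time) < 1e-9
  s <- record$snapshots[sel]
  m[cbind(s$host, s$profile)] <- s$abundance
  m
}

#' Single Gillespie steps in R
#'
#' R-level counterparts of the engine's inner loop, exposed for inspection
#' and validation: `draw_time_step()` draws the exponential waiting time
#' `dt = X / R` with `X ~ Exp(mean 1)`; `sample_event()` draws one event
#' (channel proportional to channel totals, actors proportional to their
#' weights); `execute_event()` applies an event's bookkeeping to a state
#' matrix. The compiled engine must and does agree with these semantics
#' (see the package tests for the replay equivalence check).
#'
#' @param R total event rate; `R = 0` signals an absorbing state and
#'   returns `NA` (terminate).
#' @return `draw_time_step()`: waiting time in hours (NA if `R <= 0`).
#' @export
draw_time_step <- function(R) {
  if (R <= 0) return(NA_real_)
  rexp(1L, rate = 1) / R
}

#' @rdname draw_time_step
#' @param state integer abundance matrix (hosts x profiles).
#' @param params a [trait_params()].
#' @param tensor a [build_propensity_tensor()] result.
#' @param lists a [build_transfer_lists()] result.
#' @return `sample_event()`: a list with `channel` (one of `"death"`,
#'   `"growth"`, `"segregation"`, `"competition"`, `"infection"`), `actor`
#'   `c(host, profile)` and, for infection, `recipient` and
#'   `transconjugant`.
#' @export
sample_event <- function(state, params, tensor, lists) {
  totals <- total_rates(state, params, lists)
  R <- totals[["R"]]
  if (R <= 0) stop("no events possible: total rate is zero")
  channels <- c("death", "growth", "segregation", "competition", "infection")
  channel <- sample(channels, 1L, prob = totals[1:5] / R)
  nb <- nrow(state)
  M <- ncol(state)
  eta_ip <- eta_table(params)
  cellw <- switch(channel,
    death = params$mu * state,
    growth = eta_ip * state,
    segregation = {
      w <- params$e * eta_ip * state
      w[, 1L] <- 0
      w
    },
    competition = {
      press <- as.numeric(params$b %*% rowSums(state)) / params$K
      press * eta_ip * state
    },
    infection = {
      w <- matrix(0, nb, M)
      for (p in 2:M) {
        rec <- lists$recipients[[p]]
        Ls <- if (nrow(rec) == 0L) 0 else sum(state[cbind(rec$host, rec$profile)])
        w[, p] <- params$gamma * state[, p] * Ls
      }
      w
    })
  idx <- sample.int(nb * M, 1L, prob = as.numeric(cellw))
  actor <- c(host = (idx - 1L) %% nb + 1L, profile = (idx - 1L) %/% nb + 1L)
  ev <- list(channel = channel, actor = actor)
  if (channel == "infection") {
    p <- actor[["profile"]]
    rec <- lists$recipients[[p]]
    wrec <- state[cbind(rec$host, rec$profile)]
    j <- sample.int(nrow(rec), 1L, prob = wrec)
    recipient <- c(host = rec$host[j], profile = rec$profile[j])
    col <- tensor_column(tensor, p, recipient[["host"]], recipient[["profile"]])
    r <- col$tc_profile[sample.int(nrow(col), 1L, prob = col$weight)]
    ev$recipient <- recipient
    ev$transconjugant <- c(host = recipient[["host"]], profile = r)
  }
  ev
}

#' @rdname draw_time_step
#' @param ev an event as returned by `sample_event()`.
#' @return `execute_event()`: the updated state matrix. Death and
#'   competition remove one individual of the actor; growth adds one;
#'   segregation adds one plasmid-free individual of the actor's host
#'   (the actor itself is unchanged — the daughter cell lost all
#'   plasmids); infection moves one individual from the recipient to the
#'   transconjugant subpopulation while the donor is untouched.
#' @export
execute_event <- function(state, ev) {
  a <- ev$actor
  switch(ev$channel,
    death = ,
    competition = {
      stopifnot(state[a[["host"]], a[["profile"]]] >= 1L)
      state[a[["host"]], a[["profile"]]] <- state[a[["host"]], a[["profile"]]] - 1L
    },
    growth = {
      state[a[["host"]], a[["profile"]]] <- state[a[["host"]], a[["profile"]]] + 1L
    },
    segregation = {
      state[a[["host"]], 1L] <- state[a[["host"]], 1L] + 1L
    },
    infection = {
      rec <- ev$recipient
      tc <- ev$transconjugant
      stopifnot(state[rec[["host"]], rec[["profile"]]] >= 1L)
      state[rec[["host"]], rec[["profile"]]] <- state[rec[["host"]], rec[["profile"]]] - 1L
      state[tc[["host"]], tc[["profile"]]] <- state[tc[["host"]], tc[["profile"]]] + 1L
    },
    stop("unknown channel: ", ev$channel))
  state
}
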