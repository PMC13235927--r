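#' Mean-field derivatives of the stochastic model
#'
#' Deterministic expectation of the stochastic dynamics: each subpopulation's
#' time derivative is growth minus death, competition and conjugation
#' outflow, plus conjugation inflow and segregation routing,
#' with the same per-capita rates as the stochastic engine and conjugation
#' treated as mass action: a donor subpopulation (j, pd) converts
#' recipients (i, q) at rate `gamma_j * H[j,pd] * H[i,q]`, split over
#' transconjugant profiles by the normalized propensity tensor column.
#' Segregation adds `e_i * eta_{i,p} * H[i,p]` to the host's plasmid-free
#' subpopulation without removing the parent. This is validation machinery
#' for the stochastic engine, not a user-facing solver.
#'
#' @param state numeric abundance matrix (hosts x profiles; continuous).
#' @param params a [trait_params()].
#' @param tensor a [build_propensity_tensor()] result.
#' @param lists a [build_transfer_lists()] result.
#' @return numeric matrix of time derivatives, same shape as `state`.
#' @export
meanfield_derivatives <- function(state, params, tensor, lists) {
  nb <- nrow(state)
  M <- ncol(state)
  eta_ip <- eta_table(params)
  H_i <- rowSums(state)
  press <- as.numeric(params$b %*% H_i) / params$K
  d <- eta_ip * state - params$mu * state - (press * eta_ip) * state
  # segregation routing: plasmid-free daughter cells
  seg <- params$e * eta_ip * state
  seg[, 1L] <- 0
  d[, 1L] <- d[, 1L] + rowSums(seg)
  # conjugation flows
  for (pd in 2:M) {
    donors <- sum(params$gamma * state[, pd])
    if (donors <= 0) next
    sel <- which(tensor$donor_profile == pd)
    if (length(sel) == 0L) next
    k <- tensor$rec_host[sel]
    q <- tensor$rec_profile[sel]
    r <- tensor$tc_profile[sel]
    w <- tensor$weight[sel]
    flow <- donors * state[cbind(k, q)] * w
    for (j in seq_along(sel)) {
      d[k[j], q[j]] <- d[k[j], q[j]] - flow[j]
      d[k[j], r[j]] <- d[k[j], r[j]] + flow[j]
    }
  }
  d
}

#' Integrate the mean-field system
#'
#' Numerical integration (deSolve, `lsoda`) of [meanfield_derivatives()]
#' from a configuration's initial state. Trajectories are clipped at zero
#' (the clip magnitude is reported via the `clipped` attribute).
#'
#' @param config a [simulation_config()] (its seed is ignored).
#' @param times output time grid; defaults to the configuration's
#'   recording grid.
#' @param ... passed to [deSolve::ode()].
#' @return matrix of class `deSolve`: first column `time`, then one column
#'   per (host, profile) cell in column-major order named `"H<i>.<bits>"`.
#' @export
integrate_meanfield <- function(config, times = NULL, ...) {
  params <- config$params
  nb <- params$n_hosts
  M <- 2L^params$n_plasmids
  tensor <- build_propensity_tensor(config$I, config$P)
  lists <- build_transfer_lists(config$I, config$P, tensor)
  if (is.null(times)) times <- seq(0, config$t_max, by = config$record_interval)
  deriv <- function(t, y, parms) {
    st <- matrix(pmax(y, 0), nb, M)
    list(as.numeric(meanfield_derivatives(st, params, tensor, lists)))
  }
  y0 <- as.numeric(config$initial_state)
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL, ...)
  cat_ <- rownames(enumerate_profiles(params$n_plasmids))
  colnames(out) <- c("time", paste0("H", rep(seq_len(nb), times = M), ".",
                                    rep(cat_, each = nb)))
  clipped <- min(out[, -1L])
  attr(out, "clipped") <- if (clipped < 0) clipped else 0
  out
}

#' Brute-force propensity tensor
#'
#' Independent reference construction of the infection propensity tensor by
#' a naive triple loop over all (transconjugant r; donor p; recipient q)
#' profile combinations, checking the four infection conditions directly
#' from the network matrices: donor carries plasmids; the donor has at
#' least one plasmid the recipient lacks; the transferred set `r \\ q` is
#' non-empty, drawn from the donor, and can infect the recipient host; and
#' the transconjugant's plasmids are pairwise compatible (and host
#' feasible). Raw weight `1 / 2^(nu - 1)` with `nu = |r \\ q|`, column
#' normalized. Guarded to small systems; used to cross-check
#' [build_propensity_tensor()].
#'
#' @inheritParams build_propensity_tensor
#' @param max_slots guard on `n_hosts * 2^n_plasmids`.
#' @return a `propensity_tensor` (same layout as the primary constructor).
#' @export
brute_force_tensor <- function(I, P, max_slots = 64L) {
  nb <- nrow(I$matrix)
  np <- ncol(I$matrix)
  M <- 2L^np
  if (nb * M > max_slots) stop("system too large for the brute-force oracle")
  cat_ <- enumerate_profiles(np)
  feas <- feasibility_table(I, P)
  rows <- list()
  n <- 0L
  for (p in seq_len(M)) {
    pb <- cat_[p, ]
    if (sum(pb) == 0L) next                       # condition 1
    for (k in seq_len(nb)) {
      for (q in seq_len(M)) {
        if (!feas[k, q]) next
        qb <- cat_[q, ]
        if (!any(pb == 1L & qb == 0L)) next       # condition 2
        ent_r <- integer(0); ent_w <- numeric(0)
        for (r in seq_len(M)) {
          rb <- cat_[r, ]
          s <- which(rb == 1L & qb == 0L)         # transferred set
          if (length(s) == 0L) next
          if (any(rb == 0L & qb == 1L)) next      # recipient keeps its plasmids
          if (!all(pb[s] == 1L)) next             # transferred from the donor
          if (!all(I$matrix[k, s] == 1L)) next    # condition 3
          carried <- which(rb == 1L)
          if (!all(I$matrix[k, carried] == 1L)) next
          ok <- TRUE
          if (length(carried) >= 2L) {
            prs <- utils::combn(carried, 2L)
            for (j in seq_len(ncol(prs))) {
              if (P$matrix[prs[1L, j], prs[2L, j]] != 1L) { ok <- FALSE; break }
            }
          }
          if (!ok) next                           # condition 4
          ent_r <- c(ent_r, r)
          ent_w <- c(ent_w, 1 / 2^(length(s) - 1L))
        }
        if (length(ent_r) == 0L) next
        n <- n + 1L
        rows[[n]] <- data.frame(donor_profile = p, rec_host = k, rec_profile = q,
                                tc_profile = ent_r, raw = ent_w,
                                weight = ent_w / sum(ent_w))
      }
    }
  }
  entries <- if (n > 0L) do.call(rbind, rows) else
    data.frame(donor_profile = integer(0), rec_host = integer(0),
               rec_profile = integer(0), tc_profile = integer(0),
               raw = numeric(0), weight = numeric(0))
  structure(entries, class = c("propensity_tensor", "data.frame"),
            n_hosts = nb, n_plasmids = np)
}
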