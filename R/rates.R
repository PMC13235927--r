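#' Per-capita event rates
#'
#' The five event channels act on subpopulations `H[i, p]` (host `i`,
#' plasmid profile `p`) with per-capita rates:
#'
#' * death: `mu_i` (host-specific, profile-independent);
#' * growth: `eta_{i,p} = eta_i * prod(1 - c_a)` over carried plasmids
#'   (multiplicative costs, i.e. slight positive epistasis);
#' * segregation: `omega_{i,p} = e_i * eta_{i,p}` for plasmid-carrying
#'   profiles and 0 for the plasmid-free profile (the event would be a
#'   no-op there);
#' * competition: `xi_{i,p} = eta_{i,p} * sum_j(b_ij * H_j) / K` with
#'   `b_ij = 1 + a_ij` off-diagonal and `b_ii = 1`, under a community-wide
#'   carrying capacity `K`;
#' * infection: `phi_{i,p} = gamma_i * sum(H[k, q])` over the donor's
#'   recipient list, 0 for plasmid-free profiles.
#'
#' `growth_rate()` etc. take a binary profile vector (or 1-based profile
#' index) and return the per-capita rate of one subpopulation.
#'
#' @param host host index.
#' @param p binary profile vector or 1-based profile index.
#' @param params a [trait_params()] object.
#' @param state integer abundance matrix (hosts x profiles).
#' @param lists a `transfer_lists` object from [build_transfer_lists()].
#' @return per-capita rate (1/hour).
#' @name rates
NULL

as_bits <- function(p, n_plasmids) {
  if (length(p) == 1L && n_plasmids != 1L) profile_bits(p, n_plasmids) else as.integer(p)
}

#' @rdname rates
#' @export
growth_rate <- function(host, p, params) {
  bits <- as_bits(p, params$n_plasmids)
  params$eta[host] * prod(1 - params$cost[bits == 1L])
}

#' @rdname rates
#' @export
segregation_rate <- function(host, p, params) {
  bits <- as_bits(p, params$n_plasmids)
  if (all(bits == 0L)) return(0)
  params$e[host] * growth_rate(host, bits, params)
}

#' @rdname rates
#' @export
competition_rate <- function(host, p, state, params) {
  H_j <- rowSums(state)
  growth_rate(host, p, params) * sum(params$b[host, ] * H_j) / params$K
}

#' @rdname rates
#' @export
infection_rate <- function(host, p, state, lists, params) {
  bits <- as_bits(p, params$n_plasmids)
  if (all(bits == 0L)) return(0)
  rec <- lists$recipients[[profile_index(bits)]]
  if (is.null(rec) || nrow(rec) == 0L) return(0)
  params$gamma[host] * sum(state[cbind(rec$host, rec$profile)])
}

#' Total channel rates of a community state
#'
#' Sums per-capita rates times abundances over all subpopulations for each
#' of the five channels; the system's total event rate `R` is their sum.
#'
#' @param state integer abundance matrix (hosts x profiles, canonical
#'   profile order).
#' @param params a [trait_params()] object.
#' @param lists a `transfer_lists` object matching the networks in force.
#' @return named numeric vector `c(R_D, R_G, R_S, R_C, R_I, R)`.
#' @export
total_rates <- function(state, params, lists) {
  nb <- nrow(state)
  M <- ncol(state)
  eta_ip <- eta_table(params)
  H_i <- rowSums(state)
  R_D <- sum(params$mu * H_i)
  R_G <- sum(eta_ip * state)
  carrying <- matrix(rep(c(FALSE, rep(TRUE, M - 1L)), each = nb), nb, M)
  R_S <- sum((params$e * eta_ip * state)[carrying])
  press <- as.numeric(params$b %*% H_i) / params$K
  R_C <- sum(press * rowSums(eta_ip * state))
  R_I <- 0
  for (p in seq_len(M)) {
    if (p == 1L) next
    rec <- lists$recipients[[p]]
    Ls <- if (is.null(rec) || nrow(rec) == 0L) 0 else sum(state[cbind(rec$host, rec$profile)])
    R_I <- R_I + sum(params$gamma * state[, p]) * Ls
  }
  out <- c(R_D = R_D, R_G = R_G, R_S = R_S, R_C = R_C, R_I = R_I)
  c(out, R = sum(out))
}

# realized growth-rate table eta_{i,p}, hosts x profiles
eta_table <- function(params) {
  cat_ <- enumerate_profiles(params$n_plasmids)
  costfac <- apply(cat_, 1L, function(bits) prod(1 - params$cost[bits == 1L]))
  outer(params$eta, costfac)
}
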