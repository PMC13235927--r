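#' Host and plasmid trait parameters
#'
#' Container for the demographic and transfer traits driving the model.
#' Defaults are the uniform values of the theoretical analysis: growth rate
#' `eta = 1` per hour, death rate `mu = 0.12` per hour, conjugation
#' (infection) encounter rate `gamma = 1e-5` per cell per hour, segregation
#' error probability `e = 1e-8`, plasmid cost `cost = 0.3` (fraction of
#' growth rate lost per carried plasmid, applied multiplicatively),
#' community-wide carrying capacity `K = 20000` cells, and interspecific
#' competition coefficient `a_ij = 0.01` (the competition kernel used in
#' the density-pressure term is `b_ij = 1 + a_ij` off-diagonal, `b_ii = 1`).
#'
#' @param n_hosts,n_plasmids community dimensions.
#' @param eta per-capita growth rates (1/h), recycled to `n_hosts`.
#' @param mu per-capita death rates (1/h).
#' @param gamma donor-host-specific conjugation encounter rates
#'   (1/(cell h)); profile-independent.
#' @param e segregation error probabilities (dimensionless).
#' @param cost plasmid fitness costs in `[0, 1)`, recycled to `n_plasmids`.
#' @param K community-wide carrying capacity (cells).
#' @param a interspecific competition coefficients: a scalar applied to all
#'   off-diagonal pairs, or a full `n_hosts x n_hosts` matrix of `a_ij`
#'   (effect of host j on host i); the diagonal is ignored (`b_ii = 1`).
#' @return a `trait_params` object.
#' @examples
#' trait_params()                 # Table-scale theoretical defaults
#' trait_params(K = 2000)         # scaled-down preset capacity
#' @export
trait_params <- function(n_hosts = 3L, n_plasmids = 4L,
                         eta = 1, mu = 0.12, gamma = 1e-5, e = 1e-8,
                         cost = 0.3, K = 20000, a = 0.01) {
  n_hosts <- as.integer(n_hosts)
  n_plasmids <- as.integer(n_plasmids)
  eta <- rep_len(eta, n_hosts)
  mu <- rep_len(mu, n_hosts)
  gamma <- rep_len(gamma, n_hosts)
  e <- rep_len(e, n_hosts)
  cost <- rep_len(cost, n_plasmids)
  if (any(eta < 0) || any(mu < 0) || any(gamma < 0) || any(e < 0)) {
    stop("rates must be non-negative")
  }
  if (any(cost < 0) || any(cost >= 1)) stop("plasmid costs must lie in [0, 1)")
  if (K <= 0) stop("carrying capacity must be positive")
  if (is.matrix(a)) {
    stopifnot(nrow(a) == n_hosts, ncol(a) == n_hosts)
    amat <- a
  } else {
    amat <- matrix(a, n_hosts, n_hosts)
  }
  b <- amat + 1
  diag(b) <- 1
  structure(list(n_hosts = n_hosts, n_plasmids = n_plasmids,
                 eta = eta, mu = mu, gamma = gamma, e = e,
                 cost = cost, K = K, a = amat, b = b),
            class = "trait_params")
}

#' Named parameter presets
#'
#' `"table"` is the uniform theoretical parameterization (K = 20000,
#' `gamma` = 1e-5). `"scaled"` is the scaled-down desk preset at K = 2000
#' for moderate-size replicate ensembles whose outcomes are structural
#' (absorbing-state or symmetry driven): all unimolecular rates are
#' unchanged, while the bimolecular conjugation rate is scaled inversely
#' with system size (`gamma` = 1e-4, i.e. 1e-5 x 20000/2000) so the
#' per-capita infection force `gamma * N` — and with it the plasmid
#' invasion threshold — is preserved under the reduced capacity. Initial
#' conditions should be scaled alongside (see
#' [make_initial_conditions()]; 200 plasmid-free and 10 per mono-plasmidic
#' subpopulation at K = 2000).
#'
#' @param preset `"table"` or `"scaled"`.
#' @param ... overrides passed to [trait_params()].
#' @return a `trait_params` object.
#' @export
preset_params <- function(preset = c("table", "scaled"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     table = list(K = 20000, gamma = 1e-5),
                     scaled = list(K = 2000, gamma = 1e-4))
  do.call(trait_params, modifyList(defaults, list(...)))
}

#' @export
print.trait_params <- function(x, ...) {
  cat(sprintf("<trait_params: %d hosts, %d plasmids, K = %g>\n",
              x$n_hosts, x$n_plasmids, x$K))
  cat(" eta:", x$eta, "| mu:", x$mu, "| gamma:", x$gamma, "| e:", x$e, "\n")
  cat(" cost:", x$cost, "| a_ij:", unique(x$a[row(x$a) != col(x$a)]), "\n")
  invisible(x)
}
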