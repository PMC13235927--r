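#' Build the infection propensity tensor
#'
#' For every (donor profile `p`; recipient host `k`, profile `q`) column the
#' tensor holds the probability that a conjugation event turns the recipient
#' into each possible transconjugant `r`. A transfer set `s` is any
#' non-empty subset of the donor's plasmids absent from the recipient
#' (`s` within `p \\ q`) such that every plasmid of `s` can infect host `k`
#' and the union `r = q + s` is pairwise compatible and feasible for `k`.
#' Transferring `nu = |s|` plasmid strains gets raw weight `1 / 2^(nu - 1)`
#' (the more strains moved at once, the lower the propensity); each
#' non-empty column is then normalized to sum to 1 over transconjugants.
#'
#' Infection requires (1) a plasmid-carrying donor, (2) the donor to carry
#' at least one plasmid the recipient lacks, (3) the transferred plasmids to
#' be able to infect the recipient host, and (4) the transconjugant's
#' plasmids to be mutually compatible. Columns for which no transfer set
#' satisfies all conditions are absent (zero propensity).
#'
#' The tensor depends only on the donor's profile, not its host, because
#' all conditions involve the recipient's host.
#'
#' @param I an `infection_network`.
#' @param P a `compatibility_network`.
#' @return a `propensity_tensor`: a data frame of sparse entries
#'   (`donor_profile`, `rec_host`, `rec_profile`, `tc_profile`, `raw`,
#'   `weight`) with attributes `n_hosts`, `n_plasmids`. Profile columns are
#'   1-based catalog indices.
#' @examples
#' I1 <- build_infection_network("custom", matrix = matrix(1, 1, 2))
#' P1 <- build_compatibility_network("custom", matrix = matrix(c(0, 1, 1, 0), 2))
#' tensor_column(build_propensity_tensor(I1, P1),
#'               donor_profile = 4, rec_host = 1, rec_profile = 1)
#' @export
build_propensity_tensor <- function(I, P) {
  stopifnot(length(validate_network_pair(I, P)) == 0L)
  nb <- nrow(I$matrix)
  np <- ncol(I$matrix)
  M <- 2L^np
  cat_ <- enumerate_profiles(np)
  feas <- feasibility_table(I, P)
  rows <- list()
  n <- 0L
  for (p in 2:M) {
    pb <- cat_[p, ]
    for (k in seq_len(nb)) {
      for (q in seq_len(M)) {
        if (!feas[k, q]) next
        qb <- cat_[q, ]
        diffb <- pb & !qb
        if (!any(diffb)) next # condition 2
        transferable <- which(diffb & I$matrix[k, ] == 1L)
        if (length(transferable) == 0L) next # condition 3
        subs <- subsets_nonempty(transferable)
        ent_r <- integer(0); ent_w <- numeric(0)
        for (s in subs) {
          rb <- qb
          rb[s] <- 1L
          r <- profile_index(rb)
          if (!feas[k, r]) next # condition 4 (+ I-feasibility of r)
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

subsets_nonempty <- function(x) {
  n <- length(x)
  out <- vector("list", 2L^n - 1L)
  j <- 0L
  for (mask in seq_len(2L^n - 1L)) {
    j <- j + 1L
    out[[j]] <- x[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
  }
  out
}

#' Extract one column of a propensity tensor
#'
#' @param tensor a `propensity_tensor`.
#' @param donor_profile,rec_host,rec_profile column key (1-based profile
#'   indices).
#' @return data frame of the column's entries (possibly 0 rows), with
#'   normalized `weight` and unnormalized `raw` propensities.
#' @export
tensor_column <- function(tensor, donor_profile, rec_host, rec_profile) {
  sel <- tensor$donor_profile == donor_profile &
    tensor$rec_host == rec_host & tensor$rec_profile == rec_profile
  out <- tensor[sel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Build donor and recipient transfer lists
#'
#' Donors are all (host, non-empty feasible profile) subpopulation slots.
#' The recipient list of a donor is keyed by the donor's profile: all
#' (host, profile) slots with at least one feasible transconjugant in the
#' propensity tensor. Horizontal transfer occurs both within and between
#' hosts.
#'
#' @inheritParams build_propensity_tensor
#' @param tensor optionally, a precomputed [build_propensity_tensor()]
#'   result for the same pair.
#' @return a `transfer_lists` object: `donors` (data frame host, profile)
#'   and `recipients` (list indexed by donor profile; each element a data
#'   frame host, profile).
#' @export
build_transfer_lists <- function(I, P, tensor = NULL) {
  if (is.null(tensor)) tensor <- build_propensity_tensor(I, P)
  nb <- nrow(I$matrix)
  np <- ncol(I$matrix)
  M <- 2L^np
  feas <- feasibility_table(I, P)
  donors <- do.call(rbind, lapply(seq_len(nb), function(i) {
    ps <- which(feas[i, ])
    ps <- ps[ps != 1L]
    if (length(ps) == 0L) return(NULL)
    data.frame(host = i, profile = ps)
  }))
  if (is.null(donors)) donors <- data.frame(host = integer(0), profile = integer(0))
  recipients <- vector("list", M)
  for (p in seq_len(M)) {
    sel <- tensor$donor_profile == p
    if (!any(sel)) {
      recipients[[p]] <- data.frame(host = integer(0), profile = integer(0))
      next
    }
    cols <- unique(tensor[sel, c("rec_host", "rec_profile")])
    recipients[[p]] <- data.frame(host = cols$rec_host, profile = cols$rec_profile)
  }
  structure(list(donors = donors, recipients = recipients,
                 n_hosts = nb, n_plasmids = np),
            class = "transfer_lists")
}
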