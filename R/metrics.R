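#' Relative host abundance
#'
#' Fraction of the total community abundance belonging to each host
#' population. Undefined (all `NA`) for an empty community.
#'
#' @param state integer abundance matrix (hosts x profiles).
#' @return numeric vector, one fraction per host (sums to 1 when defined).
#' @export
relative_host_abundance <- function(state) {
  H_i <- rowSums(state)
  tot <- sum(H_i)
  if (tot <= 0) return(setNames(rep(NA_real_, nrow(state)), rownames(state)))
  H_i / tot
}

#' Plasmid prevalence
#'
#' For each plasmid, the fraction of host individuals across all
#' populations that carry it.
#'
#' @param state integer abundance matrix (hosts x profiles, canonical
#'   profile order).
#' @return numeric vector, one fraction in `[0, 1]` per plasmid (`NA` for
#'   an empty community).
#' @export
plasmid_prevalence <- function(state) {
  np <- as.integer(round(log2(ncol(state))))
  cat_ <- enumerate_profiles(np)
  tot <- sum(state)
  nm <- paste0("P", seq_len(np))
  if (tot <= 0) return(setNames(rep(NA_real_, np), nm))
  prev <- vapply(seq_len(np), function(a) sum(state[, cat_[, a] == 1L]) / tot,
                 numeric(1))
  setNames(prev, nm)
}

#' Prevalence summary across an ensemble
#'
#' Mean and standard error (sample SD over sqrt(n), across replicates with
#' a non-empty final community) of final plasmid prevalence.
#'
#' @param ensemble a `replicate_ensemble`.
#' @return data frame with `plasmid`, `mean`, `se`, `n`.
#' @export
summarize_prevalence <- function(ensemble) {
  fs <- final_states(ensemble)
  np <- as.integer(round(log2(ncol(fs[[1]]))))
  prevs <- t(vapply(fs, plasmid_prevalence, numeric(np)))
  ok <- stats::complete.cases(prevs)
  prevs <- prevs[ok, , drop = FALSE]
  data.frame(plasmid = colnames(prevs),
             mean = colMeans(prevs),
             se = apply(prevs, 2L, sd) / sqrt(nrow(prevs)),
             n = nrow(prevs), row.names = NULL)
}

#' Final host population composition
#'
#' For each host that survived (positive abundance at the final snapshot)
#' in strictly more than `min_surviving_replicates` replicates, the mean
#' across those replicates of the within-host proportion of each plasmid
#' profile. Averaging is over per-replicate proportions, not pooled counts.
#'
#' @param ensemble a `replicate_ensemble`.
#' @param min_surviving_replicates hosts surviving in at most this many
#'   replicates are omitted (strict `>` filter; default 5).
#' @return data frame with `host`, `profile` (bitstring), `proportion`;
#'   proportions sum to 1 within each reported host.
#' @export
host_composition <- function(ensemble, min_surviving_replicates = 5L) {
  fs <- final_states(ensemble)
  stopifnot(length(fs) > 0L)
  nb <- nrow(fs[[1]])
  out <- list()
  for (i in seq_len(nb)) {
    surv <- vapply(fs, function(m) sum(m[i, ]) > 0L, logical(1))
    if (sum(surv) <= min_surviving_replicates) next
    props <- vapply(fs[surv], function(m) m[i, ] / sum(m[i, ]),
                    numeric(ncol(fs[[1]])))
    mp <- rowMeans(props)
    out[[length(out) + 1L]] <- data.frame(
      host = rownames(fs[[1]])[i] %||% paste0("H", i),
      profile = colnames(fs[[1]]) %||% as.character(seq_along(mp)),
      proportion = unname(mp), row.names = NULL)
  }
  if (length(out) == 0L) {
    return(data.frame(host = character(0), profile = character(0),
                      proportion = numeric(0)))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Host coexistence probability over time
#'
#' At each recorded time, the fraction of replicates in which at least
#' (or, with `exact = TRUE`, exactly) `k` host populations are extant.
#' Host count can only decrease, so replicates that terminated early (at
#' collapse or at single-host absorption) are carried forward with their
#' terminal host count.
#'
#' @param ensemble a `replicate_ensemble` (shared recording grid).
#' @param k host count threshold (default 3, complete coexistence).
#' @param exact require exactly `k` extant hosts instead of at least `k`.
#' @return data frame with `time` and `probability`.
#' @export
coexistence_probability <- function(ensemble, k = 3L, exact = FALSE) {
  grid <- sort(unique(unlist(lapply(ensemble$trajectories, `[[`, "times"))))
  nrep <- length(ensemble$trajectories)
  counts <- matrix(NA_integer_, nrep, length(grid))
  for (r in seq_len(nrep)) {
    tr <- ensemble$trajectories[[r]]
    s <- tr$snapshots
    alive <- vapply(tr$times, function(tt) {
      length(unique(s$host[abs(s$time - tt) < 1e-9]))
    }, integer(1))
    idx <- findInterval(grid + 1e-9, tr$times)
    idx[idx == 0L] <- 1L
    counts[r, ] <- alive[idx]
  }
  prob <- if (exact) colMeans(counts == k) else colMeans(counts >= k)
  data.frame(time = grid, probability = prob)
}

#' Classify the coexistence outcome of one trajectory
#'
#' `"stable"`: at least two hosts extant at the final snapshot.
#' `"transient_only"`: at least two hosts coexisted at some snapshot but
#' not at the end. `"none"`: never more than one host.
#'
#' @param record a `plasmid_trajectory`.
#' @return one of `"none"`, `"transient_only"`, `"stable"`.
#' @export
classify_coexistence <- function(record) {
  s <- record$snapshots
  n_alive <- vapply(record$times, function(tt) {
    length(unique(s$host[abs(s$time - tt) < 1e-9]))
  }, integer(1))
  final <- n_alive[length(n_alive)]
  if (final >= 2L) return("stable")
  if (any(n_alive >= 2L)) return("transient_only")
  "none"
}

#' Tidy metric table for an ensemble
#'
#' Long-format export of final-state metrics across replicates:
#' one row per (replicate, metric, entity).
#'
#' @param ensemble a `replicate_ensemble`.
#' @return data frame with `experiment`, `replicate`, `time`, `metric`,
#'   `entity`, `value`.
#' @export
tidy_metrics <- function(ensemble) {
  fs <- final_states(ensemble)
  rows <- list()
  for (r in seq_along(fs)) {
    tr <- ensemble$trajectories[[r]]
    rel <- relative_host_abundance(fs[[r]])
    prev <- plasmid_prevalence(fs[[r]])
    rows[[r]] <- rbind(
      data.frame(experiment = ensemble$label %||% NA_character_, replicate = r,
                 time = tr$t_end, metric = "relative_host_abundance",
                 entity = names(rel), value = unname(rel)),
      data.frame(experiment = ensemble$label %||% NA_character_, replicate = r,
                 time = tr$t_end, metric = "plasmid_prevalence",
                 entity = names(prev), value = unname(prev)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
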