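#' Build a host-plasmid infection network
#'
#' The infection network `I` is a binary incidence matrix with hosts as rows
#' and plasmids as columns; `I[i, a] = 1` means plasmid `a` can conjugate
#' into host `i`. Three canonical 3-host x 4-plasmid motifs are provided:
#'
#' * `"full"`: every plasmid infects every host (control).
#' * `"nested"`: a stair-step hierarchy. H1 is susceptible to all four
#'   plasmids, H2 to \{P1, P2, P3\}, and the specialist host H3 only to the
#'   generalist plasmid P1.
#' * `"modular"`: two peripheral modules joined by a bridge. H1 hosts
#'   \{P1, P2\}, the bridge host H2 hosts the bridge plasmids \{P2, P3\}, and
#'   H3 hosts \{P3, P4\}.
#'
#' Arbitrary binary matrices can be wrapped with `structure = "custom"` and
#' an explicit `matrix` argument.
#'
#' @param structure one of `"full"`, `"nested"`, `"modular"`, `"custom"`.
#' @param n_hosts,n_plasmids dimensions; the named motifs require 3 x 4.
#' @param matrix explicit 0/1 matrix, required when `structure = "custom"`.
#' @return an `infection_network` object (list with `matrix` and
#'   `structure`).
#' @examples
#' build_infection_network("modular")$matrix
#' @export
build_infection_network <- function(structure = c("full", "nested", "modular", "custom"),
                                    n_hosts = 3L, n_plasmids = 4L,
                                    matrix = NULL) {
  structure <- match.arg(structure)
  if (structure == "custom") {
    if (is.null(matrix)) stop("custom infection networks need an explicit `matrix`")
    m <- as.matrix(matrix)
    check_binary(m, "infection network")
  } else {
    if (n_hosts != 3L || n_plasmids != 4L) {
      stop("the named infection motifs are defined for 3 hosts and 4 plasmids; ",
           "use structure = 'custom' for other dimensions")
    }
    m <- switch(structure,
      full = matrix(1L, 3L, 4L),
      nested = rbind(c(1L, 1L, 1L, 1L),
                     c(1L, 1L, 1L, 0L),
                     c(1L, 0L, 0L, 0L)),
      modular = rbind(c(1L, 1L, 0L, 0L),
                      c(0L, 1L, 1L, 0L),
                      c(0L, 0L, 1L, 1L)))
    if (any(colSums(m) == 0L)) stop("every plasmid must have at least one host")
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("H", seq_len(nrow(m))), paste0("P", seq_len(ncol(m))))
  new_infection_network(m, structure)
}

new_infection_network <- function(m, structure) {
  structure(list(matrix = m, structure = structure),
            class = "infection_network")
}

#' Build a plasmid-plasmid compatibility network
#'
#' The compatibility network `P` is a symmetric binary plasmid x plasmid
#' matrix with a zero diagonal (plasmids are self-incompatible);
#' `P[a, b] = 1` means plasmids `a` and `b` can co-reside in one host cell.
#' Canonical 4-plasmid motifs:
#'
#' * `"full"`: all plasmid pairs compatible (control).
#' * `"modular"`: modules \{P1, P2\} and \{P3, P4\}; compatible within a
#'   module, incompatible between modules.
#' * `"hub"`: one hub plasmid is compatible with every other plasmid while
#'   all non-hub pairs are incompatible.
#'
#' @param structure one of `"full"`, `"modular"`, `"hub"`, `"custom"`.
#' @param n_plasmids number of plasmids; named motifs require 4.
#' @param hub_index index of the hub plasmid (required iff
#'   `structure = "hub"`).
#' @param matrix explicit symmetric 0/1 matrix for `structure = "custom"`.
#' @return a `compatibility_network` object.
#' @examples
#' build_compatibility_network("hub", hub_index = 1)$matrix
#' @export
build_compatibility_network <- function(structure = c("full", "modular", "hub", "custom"),
                                        n_plasmids = 4L, hub_index = NULL,
                                        matrix = NULL) {
  structure <- match.arg(structure)
  if (structure == "custom") {
    if (is.null(matrix)) stop("custom compatibility networks need an explicit `matrix`")
    m <- as.matrix(matrix)
    check_binary(m, "compatibility network")
    if (!isTRUE(all(m == t(m)))) stop("compatibility matrix must be symmetric")
    if (any(diag(m) != 0L)) stop("plasmids are self-incompatible: diagonal must be 0")
  } else {
    if (n_plasmids != 4L) {
      stop("the named compatibility motifs are defined for 4 plasmids; ",
           "use structure = 'custom' for other dimensions")
    }
    m <- switch(structure,
      full = 1L - diag(1L, 4L),
      modular = {
        x <- matrix(0L, 4L, 4L)
        x[1L, 2L] <- x[2L, 1L] <- 1L
        x[3L, 4L] <- x[4L, 3L] <- 1L
        x
      },
      hub = {
        if (is.null(hub_index)) stop("hub structure requires `hub_index`")
        hub_index <- as.integer(hub_index)
        if (hub_index < 1L || hub_index > 4L) stop("`hub_index` out of range")
        x <- matrix(0L, 4L, 4L)
        x[hub_index, ] <- 1L
        x[, hub_index] <- 1L
        diag(x) <- 0L
        x
      })
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("P", seq_len(nrow(m))), paste0("P", seq_len(ncol(m))))
  structure(list(matrix = m, structure = structure,
                 hub_index = if (structure == "hub") as.integer(hub_index) else NULL),
            class = "compatibility_network")
}

check_binary <- function(m, what) {
  if (!all(m %in% c(0L, 1L))) stop(what, " entries must be 0 or 1")
  invisible(m)
}

#' Validate an infection / compatibility network pair
#'
#' Report-based validation: returns a character vector of violations (empty
#' when the pair is consistent). Checked: matching plasmid dimension,
#' binary entries, symmetry and zero diagonal of the compatibility matrix.
#'
#' @param I an `infection_network`.
#' @param P a `compatibility_network`.
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validate_network_pair <- function(I, P) {
  report <- character(0)
  im <- I$matrix
  pm <- P$matrix
  if (ncol(im) != ncol(pm)) {
    report <- c(report, sprintf(
      "dimension mismatch: infection network has %d plasmids, compatibility network has %d",
      ncol(im), ncol(pm)))
  }
  if (!all(im %in% c(0L, 1L))) report <- c(report, "infection network entries are not all 0/1")
  if (!all(pm %in% c(0L, 1L))) report <- c(report, "compatibility network entries are not all 0/1")
  if (nrow(pm) != ncol(pm)) {
    report <- c(report, "compatibility matrix is not square")
  } else {
    if (!isTRUE(all(pm == t(pm)))) report <- c(report, "compatibility matrix is not symmetric")
    if (any(diag(pm) != 0L)) report <- c(report, "compatibility matrix diagonal is not all zero")
  }
  report
}

#' Summarize the structure of a network pair
#'
#' Lightweight structural summary: node degrees, connectance of each
#' network, and the number of feasible plasmid profiles per host (profiles
#' whose plasmids can all infect the host and pairwise co-reside).
#'
#' @inheritParams validate_network_pair
#' @return a list with `host_degree`, `plasmid_degree` (in `I`),
#'   `compat_degree` (in `P`), `connectance_I`, `connectance_P`, and
#'   `feasible_profiles` (count per host).
#' @export
summarize_structure <- function(I, P) {
  stopifnot(length(validate_network_pair(I, P)) == 0L)
  im <- I$matrix
  pm <- P$matrix
  np <- ncol(im)
  cat_ <- enumerate_profiles(np)
  feas <- vapply(seq_len(nrow(im)), function(i) {
    sum(vapply(seq_len(nrow(cat_)), function(r) profile_feasible(cat_[r, ], i, I, P),
               logical(1)))
  }, integer(1))
  list(
    host_degree = rowSums(im),
    plasmid_degree = colSums(im),
    compat_degree = rowSums(pm),
    connectance_I = mean(im),
    connectance_P = if (np > 1L) sum(pm) / (np * (np - 1L)) else NA_real_,
    feasible_profiles = setNames(feas, rownames(im))
  )
}

#' @export
print.infection_network <- function(x, ...) {
  cat(sprintf("<infection network '%s': %d hosts x %d plasmids>\n",
              x$structure, nrow(x$matrix), ncol(x$matrix)))
  print(x$matrix)
  invisible(x)
}

#' @export
print.compatibility_network <- function(x, ...) {
  cat(sprintf("<compatibility network '%s': %d plasmids%s>\n",
              x$structure, nrow(x$matrix),
              if (!is.null(x$hub_index)) paste0(", hub = P", x$hub_index) else ""))
  print(x$matrix)
  invisible(x)
}
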