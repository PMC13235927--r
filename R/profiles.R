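#' Enumerate plasmid profiles
#'
#' A plasmid profile is a binary vector of length `n_plasmids` whose element
#' `a` is 1 iff plasmid `a` is present; the leftmost element corresponds to
#' P1, so with four plasmids the bitstring `"0011"` carries P3 and P4. Each
#' plasmid has a single copy per cell. Profiles are returned in canonical
#' integer-ascending order (P1 is the least-significant bit), so index 1 is
#' always the plasmid-free profile; with two plasmids the order is
#' `00, 10, 01, 11`.
#'
#' @param n_plasmids number of plasmid types (>= 0).
#' @return integer matrix with `2^n_plasmids` rows (profiles) and
#'   `n_plasmids` columns; row names are the profile bitstrings.
#' @examples
#' rownames(enumerate_profiles(2)) # "00" "10" "01" "11"
#' @export
enumerate_profiles <- function(n_plasmids) {
  n_plasmids <- as.integer(n_plasmids)
  stopifnot(n_plasmids >= 0L)
  n <- 2L^n_plasmids
  idx <- 0L:(n - 1L)
  m <- matrix(0L, nrow = n, ncol = n_plasmids)
  for (a in seq_len(n_plasmids)) {
    m[, a] <- bitwAnd(idx, bitwShiftL(1L, a - 1L)) > 0L
  }
  storage.mode(m) <- "integer"
  rownames(m) <- apply(m, 1L, paste0, collapse = "")
  if (n_plasmids == 0L) rownames(m) <- ""
  if (n_plasmids > 0L) colnames(m) <- paste0("P", seq_len(n_plasmids))
  m
}

#' Profile bitstring / index conversions
#'
#' Profiles are indexed 1-based in the canonical catalog order of
#' [enumerate_profiles()] (index 1 = plasmid-free). The bitstring reads
#' left to right from P1, so `"1100"` carries P1 and P2.
#'
#' @param bits binary vector (one profile).
#' @param index 1-based profile index.
#' @param n_plasmids profile length.
#' @return `profile_index()` returns the integer index; `profile_bits()`
#'   the binary vector; `profile_string()` the bitstring.
#' @export
profile_index <- function(bits) {
  as.integer(sum(bits * 2L^(seq_along(bits) - 1L))) + 1L
}

#' @rdname profile_index
#' @export
profile_bits <- function(index, n_plasmids) {
  idx <- as.integer(index) - 1L
  stopifnot(idx >= 0L, idx < 2L^n_plasmids)
  as.integer(bitwAnd(idx, bitwShiftL(1L, seq_len(n_plasmids) - 1L)) > 0L)
}

#' @rdname profile_index
#' @export
profile_string <- function(index, n_plasmids) {
  paste0(profile_bits(index, n_plasmids), collapse = "")
}

#' Can a plasmid profile reside in a host?
#'
#' A profile is feasible for a host iff every carried plasmid can infect the
#' host (infection network) and every carried pair of plasmids can co-reside
#' (compatibility network). The plasmid-free profile is always feasible.
#'
#' @param p binary profile vector (or 1-based profile index).
#' @param host host index.
#' @param I an `infection_network`.
#' @param P a `compatibility_network`.
#' @return logical scalar.
#' @export
profile_feasible <- function(p, host, I, P) {
  np <- ncol(I$matrix)
  if (length(p) == 1L && np != 1L) p <- profile_bits(p, np)
  carried <- which(p == 1L)
  if (length(carried) == 0L) return(TRUE)
  if (!all(I$matrix[host, carried] == 1L)) return(FALSE)
  if (length(carried) >= 2L) {
    pairs <- utils::combn(carried, 2L)
    for (j in seq_len(ncol(pairs))) {
      if (P$matrix[pairs[1L, j], pairs[2L, j]] != 1L) return(FALSE)
    }
  }
  TRUE
}

# logical n_b x n_profiles feasibility table
feasibility_table <- function(I, P) {
  nb <- nrow(I$matrix)
  cat_ <- enumerate_profiles(ncol(I$matrix))
  m <- matrix(FALSE, nb, nrow(cat_), dimnames = list(rownames(I$matrix), rownames(cat_)))
  for (i in seq_len(nb)) {
    for (r in seq_len(nrow(cat_))) m[i, r] <- profile_feasible(cat_[r, ], i, I, P)
  }
  m
}
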