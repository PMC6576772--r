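# Exhaustive enumeration oracle. Independent of the DP engine: structures are
# generated combinatorially and scored by explicit loop decomposition in R,
# using only the shared parameter tables. Intended for sequences up to 20 nt.

#' Enumerate every nested secondary structure of a short sequence
#'
#' All structures obeying canonical pairing (AU, UA, GC, CG, GU, UG), the
#' minimum hairpin loop, and nestedness, each exactly once.
#'
#' @param seq RNA sequence of length at most 20.
#' @param params [fold_params()] (for the minimum hairpin loop).
#' @return list of pair matrices (two columns `i`, `j`); the first element is
#'   always the empty structure.
#' @export
enumerate_structures <- function(seq, params = fold_params()) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  if (n > 20) stop("refusing to enumerate structures for length > 20")
  si <- encode_seq(seq)
  mh <- params$min_hairpin
  can <- function(i, j) {
    j - i - 1 >= mh && !is.na(pair_type(substr(seq, i, i), substr(seq, j, j)))
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i + 1 < mh + 2) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)  # i unpaired
    for (k in (i + mh + 1):j) {
      if (!can(i, k)) next
      left <- rec(i + 1, k - 1)
      right <- if (k < j) rec(k + 1, j) else list(matrix(integer(0), 0, 2))
      for (L in left) for (R in right)
        out[[length(out) + 1L]] <- rbind(matrix(c(i, k), 1, 2), L, R)
    }
    memo[[key]] <- out
    out
  }
  res <- rec(1, n)
  lapply(res, function(m) {
    colnames(m) <- c("i", "j")
    m[order(m[, 1]), , drop = FALSE]
  })
}

#' Count nested structures by an independent recursion
#'
#' Counts without constructing the structures; cross-checks
#' [enumerate_structures()].
#'
#' @inheritParams enumerate_structures
#' @return integer count (includes the empty structure).
#' @export
count_structures <- function(seq, params = fold_params()) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  mh <- params$min_hairpin
  can <- function(i, j) {
    j - i - 1 >= mh && !is.na(pair_type(substr(seq, i, i), substr(seq, j, j)))
  }
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (j - i + 1 < mh + 2) return(1)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    total <- cnt(i + 1, j)
    for (k in (i + mh + 1):j)
      if (can(i, k)) total <- total + cnt(i + 1, k - 1) * (if (k < j) cnt(k + 1, j) else 1)
    memo[[key]] <- total
    total
  }
  cnt(1, n)
}

#' Free energy of a given structure by explicit loop decomposition
#'
#' Decomposes the structure into hairpin, stack, bulge, internal and
#' multibranch loops and sums their contributions; interior loops larger than
#' `params$max_interior` unpaired nt make the structure inadmissible (`Inf`).
#' Exterior bases contribute nothing. This is the oracle's scoring path; it
#' shares only the parameter tables with the DP engine.
#'
#' @param seq RNA sequence.
#' @param pairs two-column pair matrix.
#' @param params [fold_params()].
#' @return energy in kcal/mol (0 for the empty structure; `Inf` if
#'   inadmissible).
#' @export
structure_energy <- function(seq, pairs, params = fold_params()) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) return(0)
  validate_structure(pairs, n, params$min_hairpin)
  tabs <- loop_tables(params, n)
  partner <- integer(n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  base_at <- strsplit(seq, "")[[1]]
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # children of (i, j): pairs directly enclosed
    children <- list(); unpaired <- 0L; p <- i + 1L
    while (p < j) {
      if (partner[p] > p) {
        children[[length(children) + 1L]] <- c(p, partner[p])
        p <- partner[p] + 1L
      } else {
        unpaired <- unpaired + 1L
        p <- p + 1L
      }
    }
    nb <- length(children)
    if (nb == 0L) {
      e <- e + hairpin_energy(j - i - 1L, params, tabs)
    } else if (nb == 1L) {
      k <- children[[1]][1]; l <- children[[1]][2]
      l1 <- k - i - 1L; l2 <- j - l - 1L
      if (l1 == 0L && l2 == 0L) {
        e <- e + params$stack[pair_type(base_at[i], base_at[j]),
                              pair_type(base_at[k], base_at[l])]
      } else if (l1 + l2 > params$max_interior) {
        return(Inf)
      } else if (l1 == 0L || l2 == 0L) {
        e <- e + tabs$bulge[l1 + l2]
      } else {
        e <- e + tabs$internal[l1 + l2]
      }
    } else {
      e <- e + params$ml_closing + params$ml_branch * nb +
        params$ml_unpaired * unpaired
    }
    if (!is.finite(e)) return(Inf)
  }
  unname(e)
}

# Exhaustive reference quantities over all enumerated structures: MFE energy,
# Boltzmann pair probabilities, fMFE. Used to check the DP engine.
brute_force_ensemble <- function(seq, params = fold_params()) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  structs <- enumerate_structures(seq, params)
  energies <- vapply(structs, function(s) structure_energy(seq, s, params),
                     numeric(1))
  keep <- is.finite(energies)
  structs <- structs[keep]; energies <- energies[keep]
  w <- exp(-energies / params$rt)
  Z <- sum(w)
  bpp <- matrix(0, n, n)
  for (t in seq_along(structs)) {
    s <- structs[[t]]
    if (nrow(s)) bpp[s] <- bpp[s] + w[t]
  }
  bpp <- bpp / Z
  mfe <- min(energies)
  list(mfe = mfe, bpp = bpp, fmfe = max(w[energies <= mfe + 1e-12]) / Z,
       Z = Z, n_structures = length(structs),
       mfe_pairs = structs[[which.min(energies)]])
}
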