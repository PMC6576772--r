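#' Folding constraints
#'
#' @param forced_pairs two-column matrix of pairs that must form (1-based).
#' @param forced_unpaired integer vector of positions that must stay unpaired.
#' @param max_span maximum allowed pair distance `j - i`, or `NULL`.
#' @return an object of class `fold_constraints`.
#' @export
fold_constraints <- function(forced_pairs = NULL, forced_unpaired = integer(0),
                             max_span = NULL) {
  if (!is.null(forced_pairs)) {
    forced_pairs <- as.matrix(forced_pairs)
    storage.mode(forced_pairs) <- "integer"
    if (ncol(forced_pairs) != 2) stop("forced_pairs must have two columns")
    if (nrow(forced_pairs)) {
      if (any(forced_pairs[, 1] >= forced_pairs[, 2]))
        stop("inconsistent constraints: forced pairs must satisfy i < j")
      idx <- as.vector(forced_pairs)
      if (anyDuplicated(idx))
        stop("inconsistent constraints: an index has more than one forced partner")
      if (pairs_cross(forced_pairs))
        stop("inconsistent constraints: forced pairs cross")
      if (length(intersect(idx, forced_unpaired)))
        stop("inconsistent constraints: an index is both forced paired and unpaired")
    }
  }
  forced_unpaired <- as.integer(forced_unpaired)
  if (!is.null(max_span)) {
    max_span <- as.integer(max_span)
    if (max_span < 4) stop("max_span must be at least 4")
  }
  structure(list(forced_pairs = forced_pairs, forced_unpaired = forced_unpaired,
                 max_span = max_span), class = "fold_constraints")
}

# shared plumbing: integer sequence, forced vector, loop tables
.fold_setup <- function(seq, constraints, params) {
  seq <- as_rna(seq)
  n <- nchar(seq)
  forced <- integer(n)
  max_span <- 0L
  if (!is.null(constraints)) {
    if (!inherits(constraints, "fold_constraints"))
      stop("constraints must be built with fold_constraints()")
    fp <- constraints$forced_pairs
    if (!is.null(fp) && nrow(fp)) {
      if (any(fp > n)) stop("inconsistent constraints: pair index beyond sequence end")
      forced[fp[, 1]] <- fp[, 2]
      forced[fp[, 2]] <- fp[, 1]
    }
    fu <- constraints$forced_unpaired
    if (length(fu)) {
      if (any(fu < 1 | fu > n)) stop("forced_unpaired index out of range")
      forced[fu] <- -1L
    }
    if (!is.null(constraints$max_span)) max_span <- constraints$max_span
  }
  tabs <- loop_tables(params, n)
  list(seq = seq, n = n, si = encode_seq(seq), forced = forced,
       max_span = max_span, tabs = tabs)
}

#' Minimum free energy fold
#'
#' Nested secondary structure of minimum free energy under the bundled
#' nearest-neighbor model at the parameter temperature, honoring hard
#' constraints. The traceback is deterministic: on energy ties it prefers the
#' maximally stacked, 5'-most decomposition.
#'
#' @param seq RNA sequence (character; T is normalized to U).
#' @param constraints optional [fold_constraints()].
#' @param params [fold_params()].
#' @param backend `"bundled"` (default) or `"vienna"` to delegate to an
#'   installed `RNAfold` binary for fidelity runs.
#' @return list with `pairs` (matrix), `db` (dot-bracket), `delta_g`
#'   (kcal/mol) and `n`.
#' @export
mfe_fold <- function(seq, constraints = NULL, params = fold_params(),
                     backend = getOption("foldscan.backend", "bundled")) {
  if (identical(backend, "vienna"))
    return(vienna_mfe_fold(seq, constraints, params))
  s <- .fold_setup(seq, constraints, params)
  res <- c_mfe_fold(s$si, s$max_span, s$forced, params$stack,
                    s$tabs$hairpin, s$tabs$bulge, s$tabs$internal,
                    params$ml_closing, params$ml_branch, params$ml_unpaired,
                    params$min_hairpin, params$max_interior, TRUE)
  if (!res$forced_ok)
    stop("constraint error: forced pair(s) cannot be satisfied")
  pairs <- res$pairs
  colnames(pairs) <- c("i", "j")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  list(pairs = pairs, db = pairs_to_db(pairs, s$n),
       delta_g = round(res$energy, 10), n = s$n)
}

# MFE energy only (no traceback); used for shuffle nulls.
mfe_energy <- function(seq, params = fold_params(), max_span = 0L) {
  s <- .fold_setup(seq, NULL, params)
  res <- c_mfe_fold(s$si, as.integer(max_span), s$forced, params$stack,
                    s$tabs$hairpin, s$tabs$bulge, s$tabs$internal,
                    params$ml_closing, params$ml_branch, params$ml_unpaired,
                    params$min_hairpin, params$max_interior, FALSE)
  res$energy
}

#' Boltzmann ensemble metrics
#'
#' McCaskill partition function over the same grammar and parameters as
#' [mfe_fold()]: base-pair probabilities, ensemble diversity
#' ED = sum 2 p (1 - p) (the expected base-pair distance between two
#' independent draws from the ensemble), the MFE frequency
#' fMFE = exp(-dG_MFE/RT)/Z, the centroid (all pairs with p > 0.5), and the
#' ensemble free energy G = -RT log Z.
#'
#' Forced pairs in `constraints` restrict those positions to their given
#' partner (they may still be unpaired in part of the ensemble); forced
#' unpaired positions and `max_span` are hard.
#'
#' @inheritParams mfe_fold
#' @return list with `bpp` (matrix), `ed`, `fmfe`, `centroid_pairs`,
#'   `centroid_db`, `g_ensemble`, `mfe`, `temperature`.
#' @export
ensemble_metrics <- function(seq, constraints = NULL, params = fold_params()) {
  s <- .fold_setup(seq, constraints, params)
  pf <- c_partfn(s$si, s$max_span, s$forced, params$stack,
                 s$tabs$hairpin, s$tabs$bulge, s$tabs$internal,
                 params$ml_closing, params$ml_branch, params$ml_unpaired,
                 params$min_hairpin, params$max_interior, params$rt)
  # MFE under the same (soft) pairing restrictions: drop mandatory-pair bonuses
  # by treating forced pairs as allowed-only
  mfe <- mfe_fold(seq, constraints, params)
  bpp <- pf$bpp
  p <- bpp[upper.tri(bpp)]
  ed <- sum(2 * p * (1 - p))
  fmfe <- exp(-mfe$delta_g / params$rt - pf$lnZ)
  cen <- which(bpp > 0.5, arr.ind = TRUE)
  cen <- cen[cen[, 1] < cen[, 2], , drop = FALSE]
  colnames(cen) <- c("i", "j")
  cen <- cen[order(cen[, 1]), , drop = FALSE]
  list(bpp = bpp, ed = ed, fmfe = fmfe,
       centroid_pairs = cen, centroid_db = pairs_to_db(cen, s$n),
       g_ensemble = -params$rt * pf$lnZ, mfe = mfe,
       temperature = params$temperature)
}

#' Ensemble free energy of a region, optionally with positions held open
#'
#' Convenience for accessibility scoring: returns G = -RT log Z.
#'
#' @param seq RNA sequence.
#' @param forced_unpaired positions forced single-stranded.
#' @param params [fold_params()].
#' @export
ensemble_free_energy <- function(seq, forced_unpaired = integer(0),
                                 params = fold_params()) {
  cons <- if (length(forced_unpaired))
    fold_constraints(forced_unpaired = forced_unpaired) else NULL
  s <- .fold_setup(seq, cons, params)
  pf <- c_partfn(s$si, s$max_span, s$forced, params$stack,
                 s$tabs$hairpin, s$tabs$bulge, s$tabs$internal,
                 params$ml_closing, params$ml_branch, params$ml_unpaired,
                 params$min_hairpin, params$max_interior, params$rt)
  -params$rt * pf$lnZ
}

#' Minimum hybridization energy of two strands
#'
#' Intermolecular pairing only (no intramolecular structure), with
#' bulge/internal loops of up to `params$duplex_max_gap` unpaired nt per
#' strand between consecutive pairs; 0 when no canonical pair can form.
#'
#' @param mirna,target_site RNA sequences, both 5' to 3'.
#' @param params [fold_params()].
#' @return energy in kcal/mol (<= 0).
#' @export
duplex_energy <- function(mirna, target_site, params = fold_params()) {
  s1 <- encode_seq(as_rna(mirna))
  s2 <- encode_seq(as_rna(target_site))
  tabs <- loop_tables(params, 2L * params$duplex_max_gap + 2L)
  c_duplex(s1, s2, params$stack, tabs$bulge, tabs$internal,
           params$duplex_max_gap)
}
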