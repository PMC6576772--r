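# Weighted consensus base-pair calling: per-window MFE pairs are tallied per
# nucleotide with their window z-scores; the most negative z-sum candidate
# wins per nucleotide; mutual winners form pairs; crossing conflicts are
# resolved greedily by z-sum. Partner 0 encodes "unpaired".

#' Tally base-pairing partners across scan windows
#'
#' For every window, each MFE pair (i, j) in transcript coordinates
#' increments the tallies of i with partner j and of j with partner i, adding
#' the window's z-score to the running z-sum; unpaired positions tally
#' partner 0 the same way.
#'
#' @param scan a [scan_sequence()] table (windows share one coordinate
#'   system).
#' @return data.frame of class `partner_tally` with columns `nt`, `partner`,
#'   `count`, `z_sum`; attribute `length` holds the transcript length
#'   covered.
#' @export
tally_partners <- function(scan) {
  nt_all <- integer(0); pa_all <- integer(0); z_all <- numeric(0)
  for (w in seq_len(nrow(scan))) {
    db <- scan$mfe_db[w]
    pairs <- tryCatch(db_to_pairs(db), error = function(e)
      stop("window ", w, " (i=", scan$i[w], "): ", conditionMessage(e)))
    off <- scan$i[w] - 1L
    wlen <- scan$j[w] - scan$i[w] + 1L
    partner <- integer(wlen)
    if (nrow(pairs)) {
      partner[pairs[, 1]] <- pairs[, 2] + off
      partner[pairs[, 2]] <- pairs[, 1] + off
    }
    nt_all <- c(nt_all, seq_len(wlen) + off)
    pa_all <- c(pa_all, partner)
    z_all <- c(z_all, rep(scan$zscore[w], wlen))
  }
  key <- paste(nt_all, pa_all)
  agg_count <- tapply(z_all, key, length)
  agg_sum <- tapply(z_all, key, sum)
  uk <- !duplicated(key)
  tal <- data.frame(nt = nt_all[uk], partner = pa_all[uk], row.names = NULL)
  tal$count <- as.integer(agg_count[key[uk]])
  tal$z_sum <- as.numeric(agg_sum[key[uk]])
  tal <- tal[order(tal$nt, tal$partner), ]
  rownames(tal) <- NULL
  attr(tal, "length") <- max(scan$j)
  class(tal) <- c("partner_tally", "data.frame")
  tal
}

#' Call the winning z-score-weighted base pairs
#'
#' Per nucleotide, the candidate partner (or unpaired) with the most negative
#' z-sum wins (ties prefer unpaired, then the smaller partner index). A pair
#' is emitted only when both nucleotides select each other. Crossing
#' conflicts among mutual pairs are resolved greedily by the more negative
#' z-sum; losers are demoted to unpaired. The result is a valid nested
#' structure.
#'
#' @param tally a [tally_partners()] result.
#' @return data.frame of weighted pairs: `i`, `j`, `z_sum`, `n_windows`,
#'   `z_avg`, `provenance` (= "consensus").
#' @export
call_winning_pairs <- function(tally) {
  if (!nrow(tally)) stop("empty tally")
  pick <- function(d) {
    o <- order(d$z_sum, d$partner != 0L, d$partner)
    d[o[1], ]
  }
  winners <- do.call(rbind, lapply(split(tally, tally$nt), pick))
  wp <- setNames(winners$partner, winners$nt)
  cand <- winners[winners$partner != 0L, , drop = FALSE]
  cand <- cand[cand$nt < cand$partner, , drop = FALSE]
  mutual <- cand[!is.na(wp[as.character(cand$partner)]) &
                   wp[as.character(cand$partner)] == cand$nt, , drop = FALSE]
  if (!nrow(mutual)) {
    return(data.frame(i = integer(0), j = integer(0), z_sum = numeric(0),
                      n_windows = integer(0), z_avg = numeric(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  mutual <- mutual[order(mutual$z_sum, mutual$nt), , drop = FALSE]
  kept <- matrix(integer(0), 0, 2)
  keep_row <- logical(nrow(mutual))
  for (r in seq_len(nrow(mutual))) {
    i <- mutual$nt[r]; j <- mutual$partner[r]
    crosses <- nrow(kept) && any((kept[, 1] < i & i < kept[, 2] & kept[, 2] < j) |
                                   (i < kept[, 1] & kept[, 1] < j & j < kept[, 2]))
    if (!crosses) {
      kept <- rbind(kept, c(i, j))
      keep_row[r] <- TRUE
    }
  }
  res <- mutual[keep_row, , drop = FALSE]
  res <- data.frame(i = res$nt, j = res$partner, z_sum = res$z_sum,
                    n_windows = res$count, z_avg = res$z_sum / res$count,
                    provenance = "consensus", stringsAsFactors = FALSE)
  res <- res[order(res$i), ]
  rownames(res) <- NULL
  validate_structure(res[, c("i", "j")], max(res$j))
  res
}

#' Filter weighted pairs at an average-z cutoff (strict)
#'
#' @param pairs weighted-pair data.frame.
#' @param cutoff keep pairs with `z_avg < cutoff`.
#' @export
filter_by_zavg <- function(pairs, cutoff) {
  stopifnot(is.finite(cutoff))
  pairs[!is.na(pairs$z_avg) & pairs$z_avg < cutoff, , drop = FALSE]
}

#' Constrained refold and helix fill-in
#'
#' Folds the full sequence with the consensus pairs as hard constraints and a
#' maximum pair span, then keeps only new pairs that either stack
#' contiguously onto a constrained helix or fall within an existing motif
#' span (extending helices or closing unpaired bases); all other new pairs
#' are discarded. Fill-in never removes a consensus pair.
#'
#' @param seq full-length RNA sequence.
#' @param constraint_pairs weighted-pair data.frame (or 2-column matrix) of
#'   consensus pairs.
#' @param max_span maximum base-pair distance for the refold (nt).
#' @param merge_gap motif-boundary gap used to derive the constraint motif
#'   spans (see [extract_motifs()]).
#' @param params [fold_params()].
#' @return data.frame of added pairs with `provenance = "fill_in"` and `NA`
#'   z-score fields.
#' @export
refold_fill_in <- function(seq, constraint_pairs, max_span = 300L,
                           merge_gap = 10L, params = fold_params()) {
  cp <- as.matrix(constraint_pairs[, c("i", "j")])
  storage.mode(cp) <- "integer"
  if (nrow(cp)) {
    bad <- cp[, 2] - cp[, 1] > max_span
    if (any(bad))
      stop("constraint pair(s) exceed max_span: ",
           paste(sprintf("(%d,%d)", cp[bad, 1], cp[bad, 2]), collapse = " "))
  }
  fold <- mfe_fold(seq, fold_constraints(forced_pairs = cp, max_span = max_span),
                   params = params)
  key <- function(m) paste(m[, 1], m[, 2])
  new <- fold$pairs[!key(fold$pairs) %in% key(cp), , drop = FALSE]
  if (!nrow(new)) {
    return(data.frame(i = integer(0), j = integer(0), z_sum = numeric(0),
                      n_windows = integer(0), z_avg = numeric(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  spans <- if (nrow(cp)) {
    m <- extract_motifs(data.frame(i = cp[, 1], j = cp[, 2], z_avg = NA_real_),
                        merge_gap = merge_gap)
    cbind(vapply(m, `[[`, integer(1), "start"), vapply(m, `[[`, integer(1), "end"))
  } else matrix(integer(0), 0, 2)
  in_span <- function(i, j) any(spans[, 1] <= i & j <= spans[, 2])
  accepted <- cp
  keep <- rep(FALSE, nrow(new))
  repeat {
    progressed <- FALSE
    for (r in which(!keep)) {
      i <- new[r, 1]; j <- new[r, 2]
      stacks <- any((accepted[, 1] == i - 1L & accepted[, 2] == j + 1L) |
                      (accepted[, 1] == i + 1L & accepted[, 2] == j - 1L))
      if (stacks || (nrow(spans) && in_span(i, j))) {
        keep[r] <- TRUE
        accepted <- rbind(accepted, c(i, j))
        progressed <- TRUE
      }
    }
    if (!progressed) break
  }
  add <- new[keep, , drop = FALSE]
  data.frame(i = as.integer(add[, 1]), j = as.integer(add[, 2]),
             z_sum = rep(NA_real_, nrow(add)),
             n_windows = rep(NA_integer_, nrow(add)),
             z_avg = rep(NA_real_, nrow(add)),
             provenance = rep("fill_in", nrow(add)), stringsAsFactors = FALSE)
}

#' Group base pairs into motifs
#'
#' Pairs are grouped into connected components by span overlap/nesting (a
#' nested pair set makes spans either nested or disjoint); components whose
#' spans are separated by at most `merge_gap` unpaired nt are merged. Motifs
#' are numbered 5' to 3'.
#'
#' @param pairs weighted-pair data.frame (needs `i`, `j`; `z_avg` used for
#'   the motif mean when present).
#' @param merge_gap gap tolerance in nt.
#' @return list of motifs: each a list with `index`, `start`, `end`, `pairs`
#'   (data.frame) and `mean_zavg`.
#' @export
extract_motifs <- function(pairs, merge_gap = 10L) {
  if (!nrow(pairs)) return(list())
  validate_structure(as.matrix(pairs[, c("i", "j")]), max(pairs$j))
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  motifs <- list()
  cur <- pairs[1, , drop = FALSE]
  cur_end <- pairs$j[1]
  for (r in seq_len(nrow(pairs))[-1]) {
    if (pairs$i[r] <= cur_end + merge_gap + 1L) {
      cur <- rbind(cur, pairs[r, ])
      cur_end <- max(cur_end, pairs$j[r])
    } else {
      motifs[[length(motifs) + 1L]] <- cur
      cur <- pairs[r, , drop = FALSE]
      cur_end <- pairs$j[r]
    }
  }
  motifs[[length(motifs) + 1L]] <- cur
  lapply(seq_along(motifs), function(k) {
    m <- motifs[[k]]
    rownames(m) <- NULL
    list(index = k, start = as.integer(min(m$i)), end = as.integer(max(m$j)),
         pairs = m,
         mean_zavg = if ("z_avg" %in% names(m) && any(!is.na(m$z_avg)))
           mean(m$z_avg, na.rm = TRUE) else NA_real_)
  })
}

#' Overlap of motif pairs with an unconstrained global structure
#'
#' @param motifs [extract_motifs()] result.
#' @param global_fold an [mfe_fold()] result for the same sequence (typically
#'   unconstrained, no span limit).
#' @return list with `per_motif` (data.frame: motif, n_pairs, n_shared,
#'   fraction) and `overall` fraction.
#' @export
global_overlap <- function(motifs, global_fold) {
  gk <- paste(global_fold$pairs[, 1], global_fold$pairs[, 2])
  per <- do.call(rbind, lapply(motifs, function(m) {
    k <- paste(m$pairs$i, m$pairs$j)
    data.frame(motif = m$index, n_pairs = length(k),
               n_shared = sum(k %in% gk))
  }))
  if (is.null(per)) return(list(per_motif = NULL, overall = NA_real_))
  per$fraction <- per$n_shared / per$n_pairs
  list(per_motif = per, overall = sum(per$n_shared) / sum(per$n_pairs))
}

#' Annotate tetraloops in motifs
#'
#' Hairpin loops of exactly 4 nt, classified into degenerate families with
#' precedence UNCG > GNRA > RNYA > other (R = A/G, Y = C/U, N = any).
#'
#' @param motifs [extract_motifs()] result.
#' @param seq the transcript sequence the motif coordinates refer to.
#' @return data.frame: `motif`, `loop_start`, `loop_end`, `loop_seq`,
#'   `family`.
#' @export
annotate_tetraloops <- function(motifs, seq) {
  seq <- as_rna(seq)
  rows <- list()
  for (m in motifs) {
    p <- m$pairs
    for (r in seq_len(nrow(p))) {
      i <- p$i[r]; j <- p$j[r]
      if (j - i - 1L != 4L) next
      inside <- p$i > i & p$j < j
      if (any(inside)) next
      loop <- substr(seq, i + 1L, j - 1L)
      family <- if (grepl("^U.CG$", loop)) "UNCG"
        else if (grepl("^G.[AG]A$", loop)) "GNRA"
        else if (grepl("^[AG].[CU]A$", loop)) "RNYA"
        else "other"
      rows[[length(rows) + 1L]] <- data.frame(
        motif = m$index, loop_start = i + 1L, loop_end = j - 1L,
        loop_seq = loop, family = family, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = integer(0), loop_start = integer(0),
                      loop_end = integer(0), loop_seq = character(0),
                      family = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
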