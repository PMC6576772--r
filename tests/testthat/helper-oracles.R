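# Independent brute-force oracles used across test files. These share only
# the parameter tables with the implementation; all composition logic is
# re-derived here.

pair_key <- function(d) paste(d[, 1], d[, 2])

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# exhaustive intermolecular duplex search over monotone pair chains,
# honoring the per-strand gap cap
duplex_oracle <- function(s1, s2, p = fold_params()) {
  a <- strsplit(as_rna(s1), "")[[1]]
  b <- strsplit(as_rna(s2), "")[[1]]
  n1 <- length(a); n2 <- length(b)
  tabs <- foldscan:::loop_tables(p, 2L * p$duplex_max_gap + 2L)
  best <- 0
  extend <- function(i, k, e) {
    if (e < best) best <<- e
    for (ii in seq(i + 1, n1)) {
      if (ii > n1) break
      l1 <- ii - i - 1
      if (l1 > p$duplex_max_gap) break
      for (kk in seq(k - 1, 1)) {
        if (kk < 1) break
        l2 <- k - kk - 1
        if (l2 > p$duplex_max_gap) break
        if (is.na(pair_type(a[ii], b[kk]))) next
        de <- if (l1 == 0 && l2 == 0)
          p$stack[pair_type(a[i], b[k]), pair_type(a[ii], b[kk])]
        else if (l1 == 0 || l2 == 0) tabs$bulge[l1 + l2]
        else tabs$internal[l1 + l2]
        extend(ii, kk, e + de)
      }
    }
  }
  for (i in seq_len(n1)) for (k in rev(seq_len(n2)))
    if (!is.na(pair_type(a[i], b[k]))) extend(i, k, 0)
  best
}

# exhaustive maximum-|z_sum| nested subset of candidate pairs
best_nested_subset <- function(cand) {
  m <- nrow(cand)
  best_score <- 0; best_idx <- integer(0)
  for (mask in 0:(2^m - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (!length(idx)) next
    sub <- cand[idx, , drop = FALSE]
    if (anyDuplicated(c(sub$i, sub$j))) next
    if (foldscan:::pairs_cross(as.matrix(sub[, c("i", "j")]))) next
    sc <- sum(abs(sub$z_sum))
    if (sc > best_score) { best_score <- sc; best_idx <- idx }
  }
  cand[best_idx, , drop = FALSE]
}

# minimal scan-like table for consensus tests
fake_scan <- function(i, j, zscore, mfe_db) {
  data.frame(i = i, j = j, zscore = zscore, mfe_db = mfe_db,
             stringsAsFactors = FALSE)
}
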