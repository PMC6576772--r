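test_that("partner tallies accumulate counts and z-sums additively", {
  # one 7-nt window, structure ((...))
  sc1 <- fake_scan(i = 1, j = 7, zscore = -2, mfe_db = "((...))")
  t1 <- tally_partners(sc1)
  r <- t1[t1$nt == 1, ]
  expect_equal(r$partner, 7)
  expect_equal(r$count, 1)
  expect_equal(r$z_sum, -2)

  # two identical windows with z = -2 and -4: additivity
  sc2 <- fake_scan(i = c(1, 1), j = c(7, 7), zscore = c(-2, -4),
                   mfe_db = c("((...))", "((...))"))
  t2 <- tally_partners(sc2)
  expect_equal(t2$z_sum[t2$nt == 1 & t2$partner == 7], -6)
  expect_equal(t2$count[t2$nt == 2 & t2$partner == 6], 2)
  expect_equal(t2$z_sum[t2$nt == 4 & t2$partner == 0], -6)  # loop nt unpaired

  # offset windows tallied in transcript coordinates; by-hand check
  sc3 <- fake_scan(i = c(1, 3), j = c(7, 9), zscore = c(-1, -3),
                   mfe_db = c("((...))", "((...))"))
  t3 <- tally_partners(sc3)
  expect_equal(t3$z_sum[t3$nt == 3 & t3$partner == 9], -3)
  # nt 3: unpaired in window 1 (z -1), paired to 9 in window 2 (z -3)
  expect_equal(t3$z_sum[t3$nt == 3 & t3$partner == 0], -1)
  expect_equal(sum(t3$count[t3$nt == 3]), 2)

  expect_error(tally_partners(fake_scan(1, 7, -1, "((...)")), "window 1")
})

test_that("winning pairs need mutual selection; losers are demoted to unpaired", {
  # nt 5 prefers 20 (z_sum -8), but nt 20 prefers 30 (z_sum -9, mutual)
  tal <- data.frame(
    nt      = c(5L, 20L, 20L, 30L),
    partner = c(20L, 5L, 30L, 20L),
    count   = c(2L, 2L, 3L, 3L),
    z_sum   = c(-8, -8, -9, -9))
  class(tal) <- c("partner_tally", "data.frame")
  res <- call_winning_pairs(tal)
  expect_equal(pair_key(res), "20 30")
  expect_equal(res$z_avg, -3)
})

test_that("crossing resolution matches exhaustive search on a constructed conflict set", {
  # candidate mutual pairs with crossings; greedy-by-z-sum equals the
  # maximum-|z_sum| nested subset here
  cand <- data.frame(i = c(1L, 5L, 10L, 22L, 30L),
                     j = c(20L, 26L, 15L, 40L, 36L),
                     z_sum = c(-10, -4, -6, -8, -3))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    rows[[length(rows) + 1L]] <- data.frame(nt = cand$i[r], partner = cand$j[r],
                                            count = 2L, z_sum = cand$z_sum[r])
    rows[[length(rows) + 1L]] <- data.frame(nt = cand$j[r], partner = cand$i[r],
                                            count = 2L, z_sum = cand$z_sum[r])
  }
  tal <- do.call(rbind, rows)
  class(tal) <- c("partner_tally", "data.frame")
  res <- call_winning_pairs(tal)
  expect_false(foldscan:::pairs_cross(as.matrix(res[, c("i", "j")])))
  oracle <- best_nested_subset(cand)
  expect_setequal(pair_key(res), pair_key(oracle))
})

test_that("z-avg filtering is strict and nested across cutoffs", {
  pairs <- data.frame(i = 1:5, j = 11:15,
                      z_avg = c(-0.5, -1.0, -1.5, -2.0, -2.5))
  f1 <- filter_by_zavg(pairs, -1)
  f2 <- filter_by_zavg(pairs, -2)
  expect_equal(f1$z_avg, c(-1.5, -2.0, -2.5))  # exactly -1.0 excluded
  expect_equal(f2$z_avg, -2.5)                 # exactly -2.0 excluded
  expect_true(all(pair_key(f2) %in% pair_key(f1)))
})

test_that("fill-in recovers exactly the stacked extensions of a constrained helix", {
  # designed 6-bp stem in an unpairable poly-A background
  stem <- "GCGCGC"
  seqv <- paste0(strrep("A", 30), stem, "AAAA", revcomp_rna(stem), strrep("A", 30))
  full <- data.frame(i = 31:36, j = 46:41)
  # constrain the middle 4 bp; the outermost and innermost stacked pairs
  # are the only admissible additions
  inner <- full[2:5, ]
  add <- refold_fill_in(seqv, inner, max_span = 300)
  expect_setequal(pair_key(add), pair_key(full[c(1, 6), ]))
  expect_true(all(add$provenance == "fill_in"))

  # constraints equal to the full MFE structure: nothing to add
  mfe <- mfe_fold(seqv)
  none <- refold_fill_in(seqv, data.frame(i = mfe$pairs[, 1], j = mfe$pairs[, 2]),
                         max_span = 300)
  expect_equal(nrow(none), 0)

  expect_error(refold_fill_in(seqv, data.frame(i = 1, j = 50), max_span = 40),
               "max_span")
})

test_that("motif extraction groups by span and merges across small gaps", {
  expect_equal(extract_motifs(data.frame(i = integer(0), j = integer(0),
                                         z_avg = numeric(0))), list())

  two <- data.frame(i = c(10, 11, 600, 601), j = c(30, 29, 630, 629),
                    z_avg = -2)
  m2 <- extract_motifs(two, merge_gap = 10)
  expect_length(m2, 2)

  # hairpins ending/starting with gaps of 5 and 50 nt: first two merge
  three <- data.frame(i = c(10, 40, 120), j = c(34, 70, 150), z_avg = -2)
  m3 <- extract_motifs(three, merge_gap = 10)
  expect_length(m3, 2)
  expect_equal(m3[[1]]$start, 10)
  expect_equal(m3[[1]]$end, 70)
  expect_equal(vapply(m3, `[[`, integer(1), "index"), 1:2)
})

test_that("global overlap fractions span the identical and disjoint extremes", {
  pairs <- data.frame(i = c(10, 11, 12), j = c(30, 29, 28), z_avg = -2)
  motifs <- extract_motifs(pairs)
  same <- list(pairs = as.matrix(pairs[, c("i", "j")]))
  ov1 <- global_overlap(motifs, same)
  expect_equal(ov1$overall, 1)
  other <- list(pairs = cbind(i = c(100, 101), j = c(140, 139)))
  ov0 <- global_overlap(motifs, other)
  expect_equal(ov0$overall, 0)
})

test_that("tetraloop annotation matches family patterns with documented precedence", {
  mk <- function(loop) {
    seqv <- paste0("AAA", "GGCC", loop, "GGCC", "AAA")
    # stem pairs (4,15)(5,14)(6,13)(7,12) close a 4-nt loop at 8..11
    pairs <- data.frame(i = 4:7, j = 15:12, z_avg = -2)
    annotate_tetraloops(extract_motifs(pairs), chartr("T", "U", seqv))
  }
  expect_equal(mk("UUCG")$family, "UNCG")
  expect_equal(mk("GAAA")$family, "GNRA")  # GNRA beats RNYA when both match
  expect_equal(mk("AGUA")$family, "RNYA")
  expect_equal(mk("CCCC")$family, "other")
  # 5-nt loops are not tetraloops
  seqv <- paste0("AAA", "GG", "GAAAA", "CC", "AAA")
  pairs <- data.frame(i = 4:5, j = 12:11, z_avg = -2)
  expect_equal(nrow(annotate_tetraloops(extract_motifs(pairs), seqv)), 0)
})

test_that("consensus plus fill-in always forms a valid nested structure", {
  em <- embed_motif(synthetic_motif_spec(length = 150,
                                         inserts = list(list(position = 60,
                                                             stem = 10,
                                                             loop = "UUCG")),
                                         seed = 77))
  sc <- scan_sequence(em$seq, scan_params(window = 40, n_randomizations = 20,
                                          rng_seed = 78, ensemble = FALSE))
  winners <- call_winning_pairs(tally_partners(sc))
  f1 <- filter_by_zavg(winners, -1)
  fill <- refold_fill_in(em$seq, f1, max_span = 300)
  all_pairs <- rbind(f1, fill)
  expect_silent(validate_structure(as.matrix(all_pairs[, c("i", "j")]),
                                   nchar(em$seq)))
  # fill-in conservatism: no consensus pair removed, none crossed
  expect_true(all(pair_key(f1) %in% pair_key(all_pairs)))
  # motif nesting across cutoffs: every -2 motif lies inside a -1 motif
  m1 <- extract_motifs(f1)
  f2 <- filter_by_zavg(winners, -2)
  if (nrow(f2)) {
    m2 <- extract_motifs(f2)
    for (m in m2) {
      expect_true(any(vapply(m1, function(x)
        x$start <= m$start && m$end <= x$end, logical(1))))
    }
  }
})
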