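p <- fold_params()

test_that("trivial folds: no complementarity and forced-open give the empty structure", {
  r <- mfe_fold("AAAAAAAAAA", params = p)
  expect_equal(nrow(r$pairs), 0)
  expect_equal(r$delta_g, 0)
  expect_equal(r$db, strrep(".", 10))

  s <- "GGGGAAAACCCC"
  r2 <- mfe_fold(s, fold_constraints(forced_unpaired = seq_len(nchar(s))),
                 params = p)
  expect_equal(nrow(r2$pairs), 0)
  expect_equal(r2$delta_g, 0)
})

test_that("a simple stem-loop folds into the expected 3-pair stem at the enumerated minimum", {
  r <- mfe_fold("GGGAAACCC", params = p)
  expect_equal(r$db, "(((...)))")
  expect_lt(r$delta_g, 0)
  bf <- foldscan:::brute_force_ensemble("GGGAAACCC", p)
  expect_equal(r$delta_g, bf$mfe, tolerance = 1e-9)
})

test_that("enumeration basics: counts, refusal, and the independent counter agree", {
  e1 <- enumerate_structures("AAAA", p)
  expect_length(e1, 1)
  expect_equal(nrow(e1[[1]]), 0)

  e2 <- enumerate_structures("GAAAC", p)
  expect_length(e2, 2)
  expect_equal(e2[[2]], matrix(c(1L, 5L), 1, 2, dimnames = list(NULL, c("i", "j"))))

  expect_equal(length(enumerate_structures("GGAAAACC", p)),
               count_structures("GGAAAACC", p))
  set.seed(31)
  for (k in 1:10) {
    s <- random_rna(sample(6:12, 1))
    expect_equal(length(enumerate_structures(s, p)), count_structures(s, p))
  }
  expect_error(enumerate_structures(strrep("A", 21), p), "length > 20")
})

test_that("DP engine matches the enumeration oracle on random short sequences", {
  set.seed(101)
  for (t in 1:80) {
    s <- random_rna(sample(5:14, 1))
    bf <- foldscan:::brute_force_ensemble(s, p)
    dp <- mfe_fold(s, params = p)
    em <- ensemble_metrics(s, params = p)
    expect_equal(dp$delta_g, min(bf$mfe, 0), tolerance = 1e-9)
    expect_lt(max(abs(bf$bpp - em$bpp)), 1e-9)
    expect_equal(em$fmfe, bf$fmfe, tolerance = 1e-9)
    # the traceback structure reproduces its reported energy under the
    # independent loop-decomposition scorer
    if (nrow(dp$pairs))
      expect_equal(structure_energy(s, dp$pairs, p), dp$delta_g,
                   tolerance = 1e-9)
  }
})

test_that("constraints never stabilize, max_span is respected, inconsistencies error", {
  set.seed(55)
  for (t in 1:15) {
    s <- random_rna(40)
    un <- mfe_fold(s, params = p)
    con <- mfe_fold(s, fold_constraints(forced_unpaired = sample(40, 5)),
                    params = p)
    expect_gte(con$delta_g, un$delta_g - 1e-9)
    ms <- mfe_fold(s, fold_constraints(max_span = 12), params = p)
    if (nrow(ms$pairs)) expect_true(all(ms$pairs[, 2] - ms$pairs[, 1] <= 12))
    expect_gte(ms$delta_g, un$delta_g - 1e-9)
  }
  expect_error(fold_constraints(forced_pairs = rbind(c(1, 10), c(5, 15))),
               "cross")
  expect_error(fold_constraints(forced_pairs = rbind(c(1, 10)),
                                forced_unpaired = 10), "both")
  expect_error(mfe_fold("AAAAAAAAAA", fold_constraints(forced_pairs = rbind(c(1, 10))),
                        params = p), "constraint")
  expect_error(mfe_fold("", params = p), "empty")
})

test_that("ensemble metrics: singleton ensemble, centroid/probability consistency, dominant stem", {
  em <- ensemble_metrics("AAAAA", params = p)
  expect_equal(em$fmfe, 1)
  expect_equal(em$ed, 0)
  expect_true(all(em$bpp == 0))

  set.seed(77)
  for (t in 1:10) {
    s <- random_rna(16)
    em <- ensemble_metrics(s, params = p)
    expect_true(all(em$bpp >= 0 & em$bpp <= 1))
    expect_true(all(rowSums(em$bpp + t(em$bpp)) <= 1 + 1e-9))
    want <- which(em$bpp > 0.5, arr.ind = TRUE)
    want <- want[want[, 1] < want[, 2], , drop = FALSE]
    expect_equal(nrow(em$centroid_pairs), nrow(want))
    expect_gte(em$ed, 0)
  }

  em <- ensemble_metrics("GGGGAAAACCCC", params = p)
  expect_gt(em$fmfe, 0.5)
  expect_equal(pair_key(em$centroid_pairs), pair_key(em$mfe$pairs))
})

test_that("duplex energy: trivial zero, seed-mismatch penalty, brute-force agreement", {
  expect_equal(duplex_energy("AAAA", "AAAA", p), 0)

  m8 <- "GGCAUGCA"
  t_perfect <- revcomp_rna(m8)
  t_mismatch <- paste0(substr(t_perfect, 1, 3), "C", substr(t_perfect, 5, 8))
  expect_lt(duplex_energy(m8, t_perfect, p), duplex_energy(m8, t_mismatch, p))

  set.seed(13)
  for (t in 1:10) {
    s1 <- random_rna(10); s2 <- random_rna(10)
    expect_equal(duplex_energy(s1, s2, p), duplex_oracle(s1, s2, p),
                 tolerance = 1e-9)
  }
})

test_that("dot-bracket round-trips exactly and rejects malformed input", {
  set.seed(3)
  for (t in 1:10) {
    s <- random_rna(25)
    r <- mfe_fold(s, params = p)
    expect_equal(db_to_pairs(r$db), r$pairs)
    expect_equal(pairs_to_db(db_to_pairs(r$db), 25), r$db)
  }
  expect_error(db_to_pairs("(()"), "unmatched")
  expect_error(db_to_pairs("*)("), "unexpected character")
  expect_error(validate_structure(rbind(c(1, 10), c(5, 15)), 20), "crossing")
  expect_error(validate_structure(rbind(c(1, 3)), 10), "hairpin")
})

test_that("the vienna backend delegates to RNAfold and returns a valid fold", {
  expect_true(vienna_available())
  r <- vienna_mfe_fold("GGGGAAAACCCC")
  expect_lt(r$delta_g, 0)
  expect_equal(nchar(r$db), 12)
  validate_structure(r$pairs, 12)
})
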