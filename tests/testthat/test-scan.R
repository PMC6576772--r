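test_that("window accounting: full windows only, attributed to the first nt", {
  w <- iter_windows(strrep("A", 100), 70, 1)
  expect_equal(nrow(w), 31)
  expect_equal(c(w$i[1], w$j[1]), c(1, 70))
  expect_equal(c(w$i[31], w$j[31]), c(31, 100))

  w1 <- iter_windows(strrep("A", 70), 70, 1)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$i, w1$j), c(1, 70))

  expect_error(iter_windows(strrep("A", 50), 70), "shorter than the window")
  w3 <- iter_windows(strrep("A", 101), 70, 10)
  expect_equal(w3$i, c(1, 11, 21, 31))
})

test_that("mononucleotide shuffle conserves composition and is uniform over permutations", {
  expect_equal(foldscan:::with_seed(1, shuffle_mononucleotide("AAAA")), "AAAA")
  set.seed(9)
  for (t in 1:20) {
    s <- random_rna(sample(10:60, 1))
    sh <- shuffle_mononucleotide(s)
    expect_equal(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
  # all 24 permutations of ACGU appear at frequencies consistent with uniformity
  set.seed(4)
  perms <- replicate(10000, shuffle_mononucleotide("ACGU"))
  tab <- table(perms)
  expect_equal(length(tab), 24)
  chi <- suppressWarnings(chisq.test(as.vector(tab)))
  expect_gt(chi$p.value, 0.001)
})

test_that("z-score and P-value arithmetic follow the stated conventions", {
  # zero numerator
  null0 <- null_summary(-30, c(-28, -32))
  expect_equal(as.numeric(compute_zscore(-30, null0)), 0)

  # worked example: native -33, randoms {-29, -31}; sigma is the population
  # SD over all three energies = sqrt(8/3); z = -3 / 1.63299 = -1.83712
  null <- null_summary(-33, c(-29, -31), sigma_mode = "all")
  expect_equal(null$mean_random, -30)
  expect_equal(null$sigma, sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(as.numeric(compute_zscore(-33, null)), -3 / sqrt(8 / 3),
               tolerance = 1e-12)

  # randoms-only sigma mode
  nr <- null_summary(-33, c(-29, -31), sigma_mode = "randoms")
  expect_equal(nr$sigma, 1)

  # sigma = 0 flagged
  nz <- null_summary(-5, c(-5, -5))
  z <- compute_zscore(-5, nz)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "flagged"))

  # P-values: strict "more stable" counting
  expect_equal(compute_pvalue(-40, null_summary(-40, c(-30, -35, -20))), 0)
  expect_equal(compute_pvalue(-10, null_summary(-10, c(-30, -35, -20))), 1)
  expect_equal(compute_pvalue(-33, null_summary(-33, c(-35, -29, -31))), 1 / 3)
  expect_equal(compute_pvalue(-30, null_summary(-30, c(-30, -30))), 0)
})

test_that("homopolymer scans give zero-energy flagged windows with singleton ensembles", {
  sc <- scan_sequence(strrep("A", 40),
                      scan_params(window = 20, n_randomizations = 5,
                                  rng_seed = 1))
  expect_equal(nrow(sc), 21)
  expect_true(all(sc$delta_g == 0))
  expect_true(all(sc$ed == 0))
  expect_true(all(sc$fmfe == 1))
  expect_true(all(sc$zscore == 0))
  expect_true(all(sc$z_flagged))
  expect_true(all(sc$mfe_db == strrep(".", 20)))
})

test_that("scans are deterministic per seed and respond to seed changes", {
  s <- random_background(120, seed = 8)
  sp <- scan_params(window = 40, n_randomizations = 20, rng_seed = 5,
                    ensemble = FALSE)
  a <- scan_sequence(s, sp)
  b <- scan_sequence(s, sp)
  expect_identical(a, b)
  d <- scan_sequence(s, scan_params(window = 40, n_randomizations = 20,
                                    rng_seed = 6, ensemble = FALSE))
  expect_false(identical(a$zscore, d$zscore))
  expect_identical(a$delta_g, d$delta_g)  # native folds are seed-independent
})

test_that("an embedded stable hairpin owns the minimum z-score of the scan", {
  em <- embed_motif(synthetic_motif_spec(length = 160,
                                         inserts = list(list(position = 70,
                                                             stem = 12,
                                                             loop = "GAAA")),
                                         seed = 21))
  sc <- scan_sequence(em$seq, scan_params(window = 40, n_randomizations = 30,
                                          rng_seed = 22, ensemble = FALSE))
  wmin <- which.min(sc$zscore)
  ins_start <- 70; ins_end <- 70 + 2 * 12 + 4 - 1
  expect_true(sc$i[wmin] <= ins_end && sc$j[wmin] >= ins_start)
  expect_lt(min(sc$zscore), -2)
})

test_that("region summaries: means, Welch tests against the textbook formula, correlations", {
  set.seed(66)
  n <- 40
  scan <- data.frame(
    i = seq_len(2 * n), j = seq_len(2 * n) + 39,
    delta_g = c(rnorm(n, -20, 2), rnorm(n, -10, 2)),
    zscore = c(rnorm(n, -1, 0.5), rnorm(n, 0, 0.5)),
    pvalue = runif(2 * n), ed = c(rnorm(n, 5, 1), rnorm(n, 8, 1)),
    fmfe = runif(2 * n), gc_pct = runif(2 * n, 30, 70))
  regions <- region_spec(c("left", "right"), c(1, n + 1), c(n, 2 * n))
  sm <- summarize_regions(scan, regions)
  expect_equal(sm$means$delta_g, c(mean(scan$delta_g[1:n]),
                                   mean(scan$delta_g[(n + 1):(2 * n)])))
  # Welch statistic recomputed from first principles
  xa <- scan$zscore[1:n]; xb <- scan$zscore[(n + 1):(2 * n)]
  tt <- welch_t_test(xa, xb)
  se <- sqrt(var(xa) / n + var(xb) / n)
  t_hand <- (mean(xa) - mean(xb)) / se
  df_hand <- se^4 / ((var(xa) / n)^2 / (n - 1) + (var(xb) / n)^2 / (n - 1))
  expect_equal(tt$t, t_hand, tolerance = 1e-10)
  expect_equal(tt$df, df_hand, tolerance = 1e-10)
  expect_equal(sm$ttests$zscore["left", "right"], tt$p)
  # self-correlation is 1
  expect_equal(unname(diag(sm$correlations)), rep(1, ncol(sm$correlations)))

  # degenerate: all windows identical -> flagged, not an error
  flat <- scan; flat[] <- lapply(scan, function(x) rep(x[1], length(x)))
  flat$i <- seq_len(2 * n); flat$j <- flat$i + 39
  sm2 <- summarize_regions(flat, regions)
  expect_true(any(grepl("constant", sm2$flags)))
  expect_true(any(grepl("zero variance", sm2$flags)))

  expect_error(region_spec(c("a", "b"), c(1, 5), c(6, 10)), "overlap")
})
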