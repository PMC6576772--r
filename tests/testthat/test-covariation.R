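test_that("reference-to-alignment maps are gap-aware and invertible", {
  aln <- c(ref = "ACGU", hom = "ACGU")
  m <- map_reference_to_alignment(aln, "ref")
  expect_equal(m$pos_to_col, 1:4)

  m2 <- map_reference_to_alignment(c(ref = "A-CG", hom = "AUCG"), "ref")
  expect_equal(m2$pos_to_col[2], 3)
  expect_equal(m2$col_to_pos, c(1L, NA, 2L, 3L))

  # random gappy rows: col_to_pos inverts pos_to_col on ungapped sites
  set.seed(12)
  for (t in 1:10) {
    ch <- sample(c("A", "C", "G", "U", "-"), 40, TRUE)
    aln <- c(ref = paste(ch, collapse = ""),
             hom = paste(sample(c("A", "C", "G", "U", "-"), 40, TRUE),
                         collapse = ""))
    m <- map_reference_to_alignment(aln, "ref")
    expect_equal(m$col_to_pos[m$pos_to_col], seq_along(m$pos_to_col))
  }

  expect_error(map_reference_to_alignment(aln, "nope"), "not found")
  expect_error(map_reference_to_alignment(c(a = "ACG", b = "AC"), "a"), "ragged")
})

test_that("pair categories follow the mutation definitions exactly", {
  #              12345            pair (1,5) = G..C
  mk <- function(hom) map_reference_to_alignment(c(ref = "GAAAC", hom = hom), "ref")
  cat1 <- function(hom) classify_pair(c(1, 5), mk(hom))$categories[["hom"]]
  expect_equal(cat1("GAAAC"), "conserved")
  expect_equal(cat1("GAAAU"), "consistent")    # GC -> GU, one side changed
  expect_equal(cat1("CAAAG"), "compensatory")  # GC -> CG, both changed
  expect_equal(cat1("GAAAG"), "disruptive")    # GG non-canonical
  expect_equal(cat1("-AAAC"), "gapped")

  ref_au <- function(hom) classify_pair(c(1, 5),
    map_reference_to_alignment(c(ref = "AAAAU", hom = hom), "ref"))$categories[["hom"]]
  expect_equal(ref_au("GAAAC"), "compensatory")
  expect_equal(ref_au("AAAAC"), "disruptive")

  # gapped homologs are excluded from the conservation denominator
  aln <- c(ref = "GAAAC", h1 = "GAAAC", h2 = "-AAAC", h3 = "GAAAG")
  cl <- classify_pair(c(1, 5), map_reference_to_alignment(aln, "ref"))
  expect_equal(cl$conservation_fraction, 1 / 2)
  expect_equal(cl$n_gapped, 1)

  # non-canonical reference pair is flagged but still classified
  cl2 <- classify_pair(c(1, 5), map_reference_to_alignment(
    c(ref = "GAAAG", hom = "GAAAG"), "ref"))
  expect_true(cl2$ref_noncanonical)
})

test_that("classifier output equals the synthetic generator's truth table", {
  em <- embed_motif(synthetic_motif_spec(length = 120,
                                         inserts = list(list(position = 30,
                                                             stem = 10,
                                                             loop = "GAAA")),
                                         seed = 41))
  spec <- synthetic_alignment_spec(em$seq, em$truth_pairs, n_homologs = 50,
                                   rates = c(consistent = 0.2,
                                             compensatory = 0.1,
                                             disruptive = 0.1),
                                   background_rate = 0.1, seed = 42)
  sa <- synth_alignment(spec)
  m <- map_reference_to_alignment(sa$aln, "ref")
  mismatches <- 0L
  for (r in seq_len(nrow(em$truth_pairs))) {
    cl <- classify_pair(c(em$truth_pairs$i[r], em$truth_pairs$j[r]), m)
    truth_r <- sa$truth[sa$truth$i == em$truth_pairs$i[r] &
                          sa$truth$j == em$truth_pairs$j[r], ]
    got <- cl$categories[truth_r$homolog]
    mismatches <- mismatches + sum(got != truth_r$category)
  }
  expect_equal(mismatches, 0L)

  # every homolog/pair receives exactly one category
  cl <- classify_pair(c(em$truth_pairs$i[1], em$truth_pairs$j[1]), m)
  expect_length(cl$categories, 50)
  expect_true(all(cl$categories %in%
                    c("conserved", "consistent", "compensatory",
                      "disruptive", "gapped")))
})

test_that("motif conservation percent recovers a programmed disruption rate", {
  em <- embed_motif(synthetic_motif_spec(length = 100,
                                         inserts = list(list(position = 20,
                                                             stem = 12,
                                                             loop = "UUCG")),
                                         seed = 51))
  spec <- synthetic_alignment_spec(em$seq, em$truth_pairs, n_homologs = 60,
                                   rates = c(consistent = 0,
                                             compensatory = 0,
                                             disruptive = 0.10),
                                   background_rate = 0, seed = 52)
  sa <- synth_alignment(spec)
  m <- map_reference_to_alignment(sa$aln, "ref")
  cls <- lapply(seq_len(nrow(em$truth_pairs)), function(r)
    classify_pair(c(em$truth_pairs$i[r], em$truth_pairs$j[r]), m))
  sm <- summarize_motif_conservation(cls)
  # 12 pairs x 60 homologs = 720 Bernoulli(0.9) draws; 4 sigma ~ 4.5 pct
  expect_gt(sm$percent_canonical, 85.5)
  expect_lt(sm$percent_canonical, 94.5)
  expect_equal(sm$n_pairs, 12)
  expect_equal(sm$n_consistent, 0)

  # all-identical homologs give 100%
  flat <- synth_alignment(synthetic_alignment_spec(em$seq, em$truth_pairs,
                                                   n_homologs = 5,
                                                   rates = c(consistent = 0,
                                                             compensatory = 0,
                                                             disruptive = 0),
                                                   background_rate = 0, seed = 1))
  mf <- map_reference_to_alignment(flat$aln, "ref")
  cf <- lapply(seq_len(nrow(em$truth_pairs)), function(r)
    classify_pair(c(em$truth_pairs$i[r], em$truth_pairs$j[r]), mf))
  expect_equal(summarize_motif_conservation(cf)$percent_canonical, 100)
})

test_that("probing consistency counts WC-paired modified nucleotides", {
  # hairpin: GGGC AAAA GCCC -> pairs (1,12)(2,11)(3,10)(4,9); loop 5..8
  seqv <- "GGGCAAAAGCCC"
  pairs <- cbind(i = 1:4, j = 12:9)
  loops_only <- data.frame(pos = 5:7, reactivity = "strong")
  r0 <- probing_consistency(pairs, seqv, loops_only)
  expect_equal(r0$n_inconsistent, 0)

  all_paired <- data.frame(pos = c(1, 2, 3), reactivity = c("strong", "weak", "strong"))
  r1 <- probing_consistency(pairs, seqv, all_paired)
  expect_equal(r1$n_inconsistent, 3)

  mix <- data.frame(pos = c(5, 6, 7, 2), reactivity = "strong")
  r2 <- probing_consistency(pairs, seqv, mix)
  expect_equal(c(r2$n_modified, r2$n_inconsistent), c(4, 1))

  # a GU wobble is not Watson-Crick: not counted as inconsistent
  squ <- "GAAAU"
  r3 <- probing_consistency(cbind(1, 5), squ,
                            data.frame(pos = 1, reactivity = "strong"))
  expect_equal(r3$n_inconsistent, 0)

  expect_error(probing_consistency(pairs, seqv,
                                   data.frame(pos = 99, reactivity = "strong")),
               "outside")
})
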