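#!/usr/bin/env Rscript
# Structural conservation of motif base pairs against a programmed alignment.
#
# A 50-homolog ungapped alignment is generated with known per-pair rates of
# consistent (20%), compensatory (10%) and disruptive (10%) mutations plus
# 10% background substitutions; the classifier is then scored against the
# generator truth and summarized the way motif conservation is reported.
# Writes results/covariation_pairs.tsv.

suppressPackageStartupMessages(library(foldscan))
dir.create("results", showWarnings = FALSE)

em <- embed_motif(synthetic_motif_spec(
  length = 200, inserts = list(list(position = 60, stem = 14, loop = "GAAA")),
  seed = 11))
sa <- synth_alignment(synthetic_alignment_spec(
  em$seq, em$truth_pairs, n_homologs = 50,
  rates = c(consistent = 0.2, compensatory = 0.1, disruptive = 0.1),
  background_rate = 0.1, seed = 12))
m <- map_reference_to_alignment(sa$aln, "ref")

cls <- lapply(seq_len(nrow(em$truth_pairs)), function(r)
  classify_pair(c(em$truth_pairs$i[r], em$truth_pairs$j[r]), m))
tab <- do.call(rbind, lapply(cls, function(cl) {
  data.frame(i = cl$i, j = cl$j, ref_pair = cl$ref_pair,
             conservation_pct = 100 * cl$conservation_fraction,
             n_consistent = sum(cl$categories == "consistent"),
             n_compensatory = sum(cl$categories == "compensatory"),
             n_disruptive = sum(cl$categories == "disruptive"))
}))
write.table(tab, "results/covariation_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

mismatch <- 0L
for (r in seq_len(nrow(em$truth_pairs))) {
  tr <- sa$truth[sa$truth$i == em$truth_pairs$i[r] &
                   sa$truth$j == em$truth_pairs$j[r], ]
  mismatch <- mismatch + sum(cls[[r]]$categories[tr$homolog] != tr$category)
}
sm <- summarize_motif_conservation(cls)
cat(sprintf("classifier vs generator truth: %d mismatches over %d homolog-pair calls\n",
            mismatch, nrow(sa$truth)))
cat(sprintf("motif conservation: %.1f%% canonical pairing; %d pairs with consistent,\n",
            sm$percent_canonical, sm$n_consistent))
cat(sprintf("%d with compensatory, %d with disruptive mutations (of %d pairs)\n",
            sm$n_compensatory, sm$n_disruptive, sm$n_pairs))
cat("With the programmed 30% mutation load the expected canonical fraction is\n")
cat("~90% (consistent and compensatory mutations preserve pairing).\n")
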