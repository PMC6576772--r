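#!/usr/bin/env Rscript
# Dual-luciferase translational efficiency on a synthetic assay table.
#
# Four constructs with programmed TE effects (control 1.00, a strong
# repressor at 0.42 emulating a ~58% decrease, a rescued variant at 0.95,
# and an intermediate at 0.62) are generated with realistic noise and pushed
# through the RRR -> ddCt -> TE chain with Welch t-tests between construct
# groups. Writes results/reporter_te.tsv and results/reporter_tests.tsv.

suppressPackageStartupMessages(library(foldscan))
dir.create("results", showWarnings = FALSE)

assay <- synth_reporter(
  n_per_construct = 6,
  fold_effects = c(pIS2 = 1, M17 = 0.42, LS1 = 0.95, AS1 = 0.62),
  noise_sd = 0.12, seed = 20190617 %% 2^31)
te <- compute_te(assay, "pIS2")
write.table(te$samples, "results/reporter_te.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- attr(assay, "truth")
cat("construct  programmed  recovered (mean +/- SD)\n")
for (r in seq_len(nrow(te$constructs))) {
  cn <- te$constructs$construct[r]
  cat(sprintf("%-9s  %10.2f  %.3f +/- %.3f\n", cn, truth[[cn]],
              te$constructs$te_norm_mean[r], te$constructs$te_norm_sd[r]))
}

cmp <- te_comparisons(te)
write.table(cmp, "results/reporter_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nWelch t-tests (two-tailed; * p<0.05, ** p<0.005):\n")
for (r in seq_len(nrow(cmp)))
  cat(sprintf("%-9s vs %-9s t = %6.2f, df = %4.1f, p = %.4f %s\n",
              cmp$group_a[r], cmp$group_b[r], cmp$t[r], cmp$df[r], cmp$p[r],
              cmp$stars[r]))
cat("\nThe strong repressor separates from control; the rescued construct\n")
cat("does not - mirroring how reporter assays distinguish structural effects.\n")
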