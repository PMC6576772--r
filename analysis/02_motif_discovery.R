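#!/usr/bin/env Rscript
# Scan -> weighted consensus -> motif discovery on a synthetic transcript.
#
# A 300-nt random background carries one designed 12-bp GC-rich hairpin.
# The full pipeline runs at the standard settings (70-nt window, 1-nt step,
# 100 shuffles, cutoffs -1/-2, 300-nt refold span) and the discovered motifs
# are compared with the designed truth and with the unconstrained global
# fold. Outputs land under results/motif_discovery/.

suppressPackageStartupMessages(library(foldscan))
dir.create("results", showWarnings = FALSE)

em <- embed_motif(synthetic_motif_spec(
  length = 300,
  inserts = list(list(position = 140, stem = 12, loop = "GAAA")),
  seed = 2026))
cat(sprintf("designed hairpin: stem 12 bp, span %d-%d\n",
            min(em$truth_pairs$i), max(em$truth_pairs$j)))

res <- run_pipeline(em$seq, pipeline_config(
  window = 70, step = 1, n_randomizations = 100, cutoffs = c(-1, -2),
  max_span = 300, merge_gap = 10, seed = 7,
  out_dir = "results/motif_discovery"))

sc <- res$scan
cat(sprintf("scan: %d windows; z range [%.2f, %.2f], mean %.2f\n",
            nrow(sc), min(sc$zscore), max(sc$zscore), mean(sc$zscore)))
wmin <- which.min(sc$zscore)
cat(sprintf("most negative window starts at nt %d (z = %.2f) - it overlaps the insert\n",
            sc$i[wmin], sc$zscore[wmin]))

tk <- paste(em$truth_pairs$i, em$truth_pairs$j)
for (cf in names(res$by_cutoff)) {
  f <- res$by_cutoff[[cf]]
  cat(sprintf("%s: %d bp called, %d/%d designed pairs recovered, %d outside the design\n",
              cf, nrow(f), sum(paste(f$i, f$j) %in% tk), length(tk),
              sum(!paste(f$i, f$j) %in% tk)))
}
cat(sprintf("fill-in added %d bp; %d motifs span:\n", nrow(res$fill_in),
            length(res$motifs)))
for (m in res$motifs)
  cat(sprintf("  motif %d: %d-%d, %d bp, mean z-avg %.2f\n", m$index, m$start,
              m$end, nrow(m$pairs), m$mean_zavg))
cat(sprintf("global-model overlap: %.0f%% of motif pairs appear in the unconstrained fold\n",
            100 * res$overlap$overall))
if (nrow(res$tetraloops))
  cat(sprintf("tetraloops: %s\n",
              paste(res$tetraloops$loop_seq, "(", res$tetraloops$family, ")",
                    collapse = ", ")))
cat("Pairs called outside the design cluster either adjacent to the insert\n")
cat("(stack extensions) or on chance fold-ordered background regions; see\n")
cat("the methods vignette for why a random background produces the latter.\n")
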