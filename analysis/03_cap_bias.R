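#!/usr/bin/env Rscript
# Capped-5'-end validation. Reverse transcription of the 5' cap adds a
# template-mismatched G at tag 5' ends, so genuinely capped tags show a G
# excess among first-base mismatches. Two alignment fixtures anchored at
# high-signal STR 3' ends: a "capped" set with a planted cap-G rate and an
# uncapped control whose first-base mismatches are uniform.

library(strinit)

oriented <- strinit:::.read_signal_table("results/world/signal.tsv")
top <- head(oriented[order(-oriented$signal), ], 300)
anchors <- gintervals(top$chrom, top$three_prime_end - 1,
                      top$three_prime_end, strand = top$strand)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

capped <- generate_alignments(anchors, n_per_anchor = 20, cap_g_rate = 0.45,
                              seed = 31)
control <- generate_alignments(anchors, n_per_anchor = 20,
                               uniform_mismatch_rate = 0.45, seed = 32)
write_alignments(capped, "results/world/capped.sam")
write_alignments(control, "results/world/uncapped_control.sam")

report <- NULL
for (nm in c("capped", "uncapped_control")) {
  al <- read_alignments(sprintf("results/world/%s.sam", nm))
  tal <- first_base_tally(al, anchors)
  r <- g_bias_report(tal)
  r$set <- nm
  report <- rbind(report, r)
  cat(sprintf("\n%s: %d intersecting tags, %.1f%% with mismatched first base\n",
              nm, tal$total, 100 * r$mismatch_fraction[1]))
  cat("  first-base composition among mismatches:",
      paste(sprintf("%s=%.2f", r$base, r$share_of_mismatched), collapse = " "),
      "\n")
}
write.table(report, "results/tables/g_bias.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nThe capped set is G-dominated; the control is near-uniform.\n")
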