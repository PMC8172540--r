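#!/usr/bin/env Rscript
# Variant analyses: (i) STRs carrying variants vs variant-free STRs
# (signal contrast with one-sided rank tests under BH adjustment);
# (ii) positional distribution of variants around the 3' end against a
# uniform mutation map (two-sample KS); (iii) eQTL sign concordance —
# does sign(predict(alt) - predict(ref)) agree with the eQTL slope, within
# the -15/+30 window around 3' ends of promoter STRs, stratified by the
# model's reference-genome prediction error at 0.2?

library(strinit)

store <- read_sequence_store("results/world/genome.fa")
oriented <- strinit:::.read_signal_table("results/world/signal.tsv")
model <- load_model("results/world/model.json")
truth <- read.table("results/world/truth.tsv", header = TRUE, sep = "\t")
world <- list(store = store,
              catalog = read_str_catalog("results/world/catalog.bed"),
              truth = truth, model = signal_model())
class(world) <- "synthetic_world"

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

gv <- generate_variants(world, n = 400, seed = 41)
v <- gv$variants
write.table(v, "results/tables/variants.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# (i) signal at variant-bearing vs variant-free STRs
mp <- map_variants_to_strs(v, world$catalog, w = 50)
sense <- oriented[oriented$strand == "+", ]
with_v <- unique(mp$pairs$str_idx)
groups <- list(with_variant = sense$signal[with_v],
               without_variant = sense$signal[mp$unpaired_strs])
gc <- signal_group_comparison(groups)
cat(sprintf("Signal, STRs with (n=%d) vs without (n=%d) variants:\n",
            length(groups$with_variant), length(groups$without_variant)))
cat(sprintf("  ANOVA p = %.3g\n", gc$anova_p))
for (k in seq_len(nrow(gc$pairwise)))
  cat(sprintf("  one-sided rank test (%s > %s): BH p = %.3g\n",
              gc$pairwise$greater[k], gc$pairwise$lesser[k],
              gc$pairwise$p_adj[k]))
cat("  (variants preferentially hit carriers of the repressive downstream\n",
    "  motif, so the variant-bearing set runs lower here)\n")

# (ii) variant positions vs a uniform mutation map
t0 <- world$catalog$end[match(v$str_name, world$catalog$name)] - 1
off <- (v$pos - 1) - t0
set.seed(42)
unif <- sample(-50:50, 4000, replace = TRUE)
ks <- compare_positional(off, unif)
cat(sprintf("Variant offsets vs uniform map: KS D = %.3f, p = %.3g\n",
            ks$statistic, ks$p_value))

# (iii) eQTL sign concordance, stratified by prediction error at 0.2
res <- eqtl_sign_concordance(model, store, v, oriented, gv$gene_starts)
write.table(res$strata, "results/tables/eqtl_concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\neQTL sign concordance by prediction-error stratum:\n")
print(res$strata, row.names = FALSE)

# (iv) label enrichment machinery on the variant-bearing STR classes
cls <- world$catalog$motif
enr <- set_enrichment(cls[with_v], cls)
write.table(enr, "results/tables/class_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nClass enrichment among variant-bearing STRs (Fisher, BH-adjusted):\n")
print(enr[, c("label", "odds_ratio", "p", "p_adj")], row.names = FALSE)
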