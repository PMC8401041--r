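#!/usr/bin/env Rscript
# Validate the fragment-ANIb engine against a direct position-wise (Hamming)
# oracle on indel-free 51-kb genome pairs across substitution rates, and
# check that ANI decreases strictly with divergence.

suppressMessages(library(pseudotax))
dir.create("results", showWarnings = FALSE)

rates <- c(0.005, 0.01, 0.02, 0.04)
rows <- list()
for (seed in 1:3) {
  anc <- simulate_ancestor(51000, 0.60, seed = seed)
  g0 <- genome_record("anc", anc$sequence)
  for (r in rates) {
    ev <- evolve_genome(anc, r, 0, seed = 100 + seed, id = "mut")
    ani <- anib_pairwise(g0, ev$genome)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = seed, subst_rate = r,
      hamming_identity = 100 * (1 - ev$divergence),
      anib = ani$ani, aligned_fraction = ani$aligned_fraction
    )
  }
}
tab <- do.call(rbind, rows)
tab$abs_error <- abs(tab$anib - tab$hamming_identity)
write.table(format(tab, digits = 6), "results/ani_validation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("ANIb vs Hamming on", nrow(tab), "indel-free pairs\n")
cat(sprintf("max |ANIb - Hamming|: %.3f percentage points\n",
            max(tab$abs_error)))
mono <- all(tapply(tab$anib, tab$seed, function(v) all(diff(v) < 0)))
cat("ANI strictly decreasing in substitution rate:", mono, "\n")
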