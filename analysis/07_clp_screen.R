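#!/usr/bin/env Rscript
# Screen a synthetic panel of NRPS architectures for CLP hallmarks (tandem
# TE domains, no epimerization domains) and assign families by synteny.

suppressMessages(library(pseudotax))
dir.create("results", showWarnings = FALSE)

families <- c("Viscosin/WLIP", "Putisolvin", "Entolysin", "Xantholysin",
              "LP-13", "novel", "none")
archs <- c(
  lapply(families, generate_bgc),
  list(generate_bgc("Putisolvin", fragmented = TRUE, seed = 2))
)
tsv <- "results/clp_panel.tsv"
write_bgc_tsv(archs, tsv)
parsed <- parse_bgc(tsv) # round trip through the exchange format

calls <- lapply(parsed, function(a) {
  call <- detect_clp(a)
  if (call$status == "positive") call <- assign_family(call)
  call
})
write_clp_report_tsv(calls, "results/clp_report.tsv")

for (cl in calls) {
  cat(sprintf("%-28s %-9s %2d modules (%s)  family: %s %s\n",
              cl$cluster_id, cl$status, cl$total_modules,
              paste(cl$per_gene_modules, collapse = "+"), cl$family,
              cl$family_note))
}
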