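#!/usr/bin/env Rscript
# Apply the species-assignment decision tree (ANI >= 96.5 assigned; 95-96.5
# resolved by dDDH; < 95 new species) to every strain of the packaged
# reassignment table, and number the putative new species.

suppressMessages(library(pseudotax))
dir.create("results", showWarnings = FALSE)

fixture <- parse_fixture(fixture_path("table3"), "table3")
res <- classify_reassignments(fixture)
write.table(res$table, "results/reassignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")

cat("Strains classified:", nrow(res$table), "\n")
cat("Assigned to known/new species:", res$counts[["assigned"]], "\n")
cat("Representing new species:", res$counts[["new_strains"]],
    "strains in", res$counts[["new_species"]], "putative species\n")
print(table(res$table$decision))
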