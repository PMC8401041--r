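#!/usr/bin/env Rscript
# Census of the packaged group/subgroup table: group counts, orphan groups,
# and the P. putida group summary (subgroups, species, newly described).

suppressMessages(library(pseudotax))
dir.create("results", showWarnings = FALSE)

fixture <- parse_fixture(fixture_path("table1"), "table1")
cz <- census(fixture)
jsonlite::write_json(cz, "results/census.json", auto_unbox = TRUE,
                     digits = NA)

cat("Non-orphan groups:", cz$n_non_orphan_groups, "\n")
cat("Orphan groups:", cz$n_orphan_groups,
    "holding", cz$n_orphan_species, "species\n")
cat("P. putida group:", cz$n_focal_species, "species in",
    cz$n_focal_subgroups, "subgroups;",
    cz$n_focal_new_species, "newly described\n")
for (w in cz$warnings) cat("warning:", w, "\n")
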