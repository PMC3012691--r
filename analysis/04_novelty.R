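#!/usr/bin/env Rscript

# Stage 4: the four-stage novelty screen, under both overlap criteria.
#
# Screens one pseudo-algorithm's filtered calls against the merged
# normals database, restricts survivors to case-only events, and screens
# those against the disease-literature records not already present in
# normals. The two criteria produce two parallel result sets; the looser
# "40% either" rule eliminates fewer calls at the database screens, so
# its survivor counts are at least as large.

suppressPackageStartupMessages(library(cnvrpipe))

sim <- "results/sim"
out <- "results"
normals <- preprocess_ref_table(read_ref_db(file.path(sim, "refdb_normals.tsv")))
scz <- preprocess_ref_table(read_ref_db(file.path(sim, "refdb_scz.tsv")))
filtered <- read_calls(file.path(out, "filtered_callsets.tsv"))
study <- filtered[filtered$source == sort(unique(filtered$source))[1], ]

counts <- NULL
for (crit in list(overlap_criterion("any"),
                  overlap_criterion("pct_either", 0.40))) {
  rep <- run_novelty_flow(study, normals, scz, crit)
  cat(sprintf("criterion %s:\n", crit$mode))
  print(rep)
  sc <- rep$stage_counts
  sc$criterion <- crit$mode
  counts <- rbind(counts, sc)
  write.table(rep$fates,
              file.path(out, sprintf("novelty_fates_%s.tsv", crit$mode)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(counts, file.path(out, "novelty_stage_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

final <- counts[counts$stage == "not_in_normals_or_scz", ]
cat(sprintf("\nnovel case CNVs: %d (any) vs %d (40%% either)\n",
            final$total[1], final$total[2]))
stopifnot(final$total[2] >= final$total[1])
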