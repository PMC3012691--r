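#!/usr/bin/env Rscript

# Stage 3: CNVR merging under both overlap criteria, and multi-algorithm
# consensus.
#
# Merges the normals reference table into unique CNV regions under the
# "any" and "40% either" criteria (the looser 40% rule always leaves at
# least as many regions), then intersects the filtered study call sets,
# requiring one, two or all four pseudo-algorithms to report each event
# — consensus counts can only fall as the requirement grows.

suppressPackageStartupMessages(library(cnvrpipe))

sim <- "results/sim"
out <- "results"
normals <- preprocess_ref_table(read_ref_db(file.path(sim, "refdb_normals.tsv")))
filtered <- read_calls(file.path(out, "filtered_callsets.tsv"))

tally <- NULL
for (crit in list(any = overlap_criterion("any"),
                  pct_either = overlap_criterion("pct_either", 0.40))) {
  regions <- build_merged_db(normals, crit)
  tally <- rbind(tally, data.frame(criterion = crit$mode,
                                   t(count_by_type(regions))))
  write_regions(regions,
                file.path(out, sprintf("merged_normals_%s.tsv", crit$mode)))
}
cat("merged normals regions by criterion:\n")
print(tally, row.names = FALSE)

srcs <- sort(unique(filtered$source))
cons_rows <- NULL
for (req in list(srcs[1], srcs[1:2], srcs)) {
  cc <- consensus_calls(filtered, req, overlap_criterion("any"))
  cons_rows <- rbind(cons_rows,
                     data.frame(required = paste(req, collapse = "+"),
                                n_sources = length(req), calls = nrow(cc)))
  if (length(req) == length(srcs))
    write_calls(cc, file.path(out, "consensus_fourway.tsv"))
}
cat("\nconsensus calls by required-source set:\n")
print(cons_rows, row.names = FALSE)
stopifnot(all(diff(cons_rows$calls) <= 0))

write.table(tally, file.path(out, "merged_normals_tally.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cons_rows, file.path(out, "consensus_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
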