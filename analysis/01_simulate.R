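#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs.
#
# Emulates a CNV-enriched autosomal SNP array for a two-cohort study
# (cases and matched controls) at a reduced scale — 12 + 12 subjects on
# chromosomes 1-4 with ~14,900 markers, preserving the full array's
# ~59 kb mean inter-marker spacing — so the whole workflow reruns in
# seconds. Writes the
# probe tracks, implanted truth, pseudo-algorithm call sets, reference
# databases and roster under results/sim/.

suppressPackageStartupMessages(library(cnvrpipe))

seed <- 20260930
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_cases = 12, n_controls = 12,
                  chroms = c("1", "2", "3", "4"),
                  n_markers = 14900, cnv_rate = 6)
arr <- simulate_array(cfg, seed = seed)
calls <- simulate_callsets(arr$truth, arr$map, cfg, seed = seed + 1)
db <- simulate_ref_db(arr$truth, cfg, seed = seed + 2)

write.table(arr$signals, file.path(out, "probe_signals.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(arr$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(arr$roster, file.path(out, "roster.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_calls(calls, file.path(out, "callsets.tsv"))
write_calls(db$normals, file.path(out, "refdb_normals.tsv"))
write_calls(db$scz, file.path(out, "refdb_scz.tsv"))
write.table(default_centromeres(cfg$chrom_lengths),
            file.path(out, "centromeres_synthetic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("markers: %d (mean gap %.1f kb)\n", nrow(arr$map),
            mean(unlist(lapply(split(arr$map$pos, arr$map$chrom),
                               diff))) / 1000))
cat(sprintf("implanted CNVs: %d across %d subjects (%d loss, %d gain)\n",
            nrow(arr$truth), length(unique(arr$truth$subject_id)),
            sum(arr$truth$type == "loss"), sum(arr$truth$type == "gain")))
cat(sprintf("pseudo-algorithm calls: %d from %d algorithms\n",
            nrow(calls), length(unique(calls$source))))
cat(sprintf("reference records: %d normals, %d scz\n",
            nrow(db$normals), nrow(db$scz)))
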