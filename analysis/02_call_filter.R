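#!/usr/bin/env Rscript

# Stage 2: rule-based calling on the probe tracks, and post-call filters
# on the pseudo-algorithm call sets.
#
# Runs the HMM-smoothed event classifier (homozygous deletion,
# hemizygous deletion, amplification rules) on every subject's LRR/BAF
# track, splits any centromere-spanning calls, and reports its agreement
# with the implanted truth. Then applies the standard post-call filters
# (>= 10 bp, Log Bayes Factor >= 30, varying probe minima) to the
# simulated multi-algorithm call sets, the same filters applied to
# PennCNV/QuantiSNP/cnvPartition-style output.

suppressPackageStartupMessages(library(cnvrpipe))

sim <- "results/sim"
out <- "results"
signals <- read_probe_track(file.path(sim, "probe_signals.tsv"))
truth <- read.delim(file.path(sim, "truth.tsv"))
callsets <- read_calls(file.path(sim, "callsets.tsv"))
cens <- read_centromeres(file.path(sim, "centromeres_synthetic.tsv"))

hmm_calls <- call_cnvs(signals, source = "hmmcaller")
hmm_calls <- split_at_centromere(hmm_calls, cens, track = signals)

matched <- vapply(seq_len(nrow(truth)), function(k)
  any(hmm_calls$subject_id == truth$subject_id[k] &
        hmm_calls$chrom == as.character(truth$chrom[k]) &
        hmm_calls$type == truth$type[k] &
        hmm_calls$start <= truth$end[k] & hmm_calls$end >= truth$start[k]),
  logical(1))
# events below the rules' probe/span minima are undetectable by design
eligible <- truth$n_probes >= 10 |
  (truth$copy_state == "homo_del" & truth$n_probes >= 3)
cat(sprintf("HMM caller: %d calls; recall %.2f overall, %.2f on rule-eligible implants\n",
            nrow(hmm_calls), mean(matched), mean(matched[eligible])))

filtered <- filter_confidence(filter_min_size(callsets, 10), 30)
cat(sprintf("call-set filters: %d -> %d after >=10 bp, %d after LBF >= 30\n",
            nrow(callsets), nrow(filter_min_size(callsets, 10)),
            nrow(filtered)))
for (k in c(3, 5, 10)) {
  cat(sprintf("  minimum %2d probes: %d calls\n", k,
              nrow(filter_min_probes(filtered, k))))
}

write_calls(hmm_calls, file.path(out, "hmm_calls.tsv"))
write_calls(filtered, file.path(out, "filtered_callsets.tsv"))
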