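# Fixture builders and independent oracle implementations used across the
# suite. Oracles are deliberately naive (sorted sweeps, all-pairs scans,
# scalar loops) and share no code with the package internals they check.

mk_calls <- function(chrom, start, end, type, subject_id = "s1",
                     cohort = "case", n_probes = 10L, confidence = 50,
                     source = "algX") {
  data.frame(subject_id = subject_id, cohort = cohort,
             chrom = as.character(chrom), start = start, end = end,
             type = type, n_probes = n_probes, confidence = confidence,
             source = source, stringsAsFactors = FALSE)
}

mk_refs <- function(chrom, start, end, type, cohort = "normal",
                    study = "litA", gain_count = NA, loss_count = NA) {
  data.frame(chrom = as.character(chrom), start = start, end = end,
             type = type, cohort = cohort, study = study,
             gain_count = gain_count, loss_count = loss_count,
             stringsAsFactors = FALSE)
}

# random loss/gain records on a few chromosomes, possibly clustered so
# overlaps actually occur
fuzz_records <- function(n, max_chrom = 3, max_pos = 5000,
                         max_len = 400, types = c("loss", "gain")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = as.character(sample.int(max_chrom, n, replace = TRUE)),
             start = start, end = start + len - 1,
             type = sample(types, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# --- oracle: sweep-line union of type-compatible intervals (any overlap)
# Valid for loss/gain-only inputs, where type compatibility is equality.
oracle_sweep_union <- function(records) {
  out <- list()
  for (ty in unique(records$type)) {
    for (ch in unique(records$chrom)) {
      sub <- records[records$type == ty & records$chrom == ch, , drop = FALSE]
      if (!nrow(sub)) next
      sub <- sub[order(sub$start, sub$end), , drop = FALSE]
      cur_s <- sub$start[1]; cur_e <- sub$end[1]; cur_n <- 1L
      for (i in seq_len(nrow(sub))[-1]) {
        if (sub$start[i] <= cur_e) {   # closed intervals: touching bp merges
          cur_e <- max(cur_e, sub$end[i]); cur_n <- cur_n + 1L
        } else {
          out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                                end = cur_e, type = ty,
                                                n_members = cur_n)
          cur_s <- sub$start[i]; cur_e <- sub$end[i]; cur_n <- 1L
        }
      }
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                            end = cur_e, type = ty,
                                            n_members = cur_n)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(as.integer(res$chrom), res$start, res$end, res$type), ]
  rownames(res) <- NULL
  res
}

# --- oracle: the documented pct_either schedule, coded as a plain list-
# of-groups loop with scalar meets_criterion() calls
oracle_schedule_merge <- function(records, criterion) {
  ord <- order(as.integer(records$chrom), records$start, records$end,
               records$type)
  items <- lapply(ord, function(i) list(chrom = records$chrom[i],
                                        start = records$start[i],
                                        end = records$end[i],
                                        type = records$type[i],
                                        members = i))
  repeat {
    groups <- list()
    for (it in items) {
      placed <- FALSE
      for (g in seq_along(groups)) {
        gr <- groups[[g]]
        if (meets_criterion(it, gr, criterion)) {
          gr$start <- min(gr$start, it$start)
          gr$end <- max(gr$end, it$end)
          if (it$type != gr$type) gr$type <- "both"
          gr$members <- c(gr$members, it$members)
          groups[[g]] <- gr
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1L]] <- it
    }
    if (length(groups) == length(items)) break
    o <- order(vapply(groups, function(g) as.integer(g$chrom), integer(1)),
               vapply(groups, function(g) g$start, numeric(1)),
               vapply(groups, function(g) g$end, numeric(1)),
               vapply(groups, function(g) g$type, character(1)))
    items <- groups[o]
  }
  res <- do.call(rbind, lapply(items, function(g) {
    ty <- records$type[g$members]
    data.frame(chrom = g$chrom, start = min(records$start[g$members]),
               end = max(records$end[g$members]),
               type = if (any(ty == "both")) "both" else unique(ty),
               n_members = length(g$members),
               member_ids = paste(sort(g$members), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(as.integer(res$chrom), res$start, res$end, res$type), ]
  rownames(res) <- NULL
  res
}

# --- track/truth builders on the package simulator --------------------
# config + map for a single-chromosome array of n probes
small_array_cfg <- function(n_markers = 400, n_cases = 1, n_controls = 0,
                            lrr_sd = 0, baf_sd = 0, ...) {
  sim_config(n_cases = n_cases, n_controls = n_controls, chroms = "1",
             n_markers = n_markers, lrr_sd = lrr_sd, baf_sd = baf_sd, ...)
}

# truth rows at explicit probe-index runs on a map
truth_at <- function(map, runs, subject_id = "case001", cohort = "case") {
  do.call(rbind, lapply(runs, function(r) {
    data.frame(subject_id = subject_id, cohort = cohort,
               chrom = map$chrom[r$first],
               start = map$pos[r$first], end = map$pos[r$last],
               type = if (r$state == "gain") "gain" else "loss",
               copy_state = r$state,
               probe_first = r$first, probe_last = r$last,
               n_probes = r$last - r$first + 1L,
               stringsAsFactors = FALSE)
  }))
}

# recall / FDR of calls against truth (same subject, same type, any overlap)
match_truth <- function(calls, truth) {
  hit_truth <- vapply(seq_len(NROW(truth)), function(k) {
    any(calls$subject_id == truth$subject_id[k] &
          calls$chrom == truth$chrom[k] &
          calls$type == truth$type[k] &
          calls$start <= truth$end[k] & calls$end >= truth$start[k])
  }, logical(1))
  call_true <- vapply(seq_len(NROW(calls)), function(k) {
    any(truth$subject_id == calls$subject_id[k] &
          truth$chrom == calls$chrom[k] &
          truth$type == calls$type[k] &
          truth$start <= calls$end[k] & truth$end >= calls$start[k])
  }, logical(1))
  list(recall = mean(hit_truth),
       fdr = if (NROW(calls)) mean(!call_true) else 0)
}
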