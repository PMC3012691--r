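# Rule-based CNV event detection on LRR/BAF probe tracks, plus the
# post-call filters applied to external callers' output.
#
# Segmentation is a small Gaussian hidden-Markov smoother over the LRR
# track (Viterbi decoding); the scientific contract is the event
# classification rules applied to candidate runs:
#   homozygous deletion : >= 3 probes, >= 1 kb, mean LRR < -1
#   hemizygous deletion : >= 10 probes, >= 1 kb, mean LRR < -0.25,
#                         heterozygous proportion < 10%
#   amplification (gain): >= 10 probes, >= 1 kb, mean LRR > 0.25,
#                         mean |BAF - 0.5| at het SNPs > 0.05

#' Caller configuration
#'
#' Parameters of the Gaussian HMM used to smooth the LRR track before
#' event classification. The default uses four states centred at the
#' copy-state LRR means (homozygous deletion, hemizygous deletion,
#' neutral, gain) with a shared emission SD and a sticky self-transition;
#' states below the neutral mean are "low", above it "high". Candidate
#' segments are maximal runs of probes decoded into the same direction.
#'
#' @param state_means named numeric vector of state LRR means; exactly one
#'   must be 0 (the neutral state).
#' @param state_sd shared emission standard deviation.
#' @param self_prob self-transition probability (remaining mass split
#'   evenly over the other states).
#' @param neutral_prior prior probability of starting in the neutral state.
#' @return list of class `caller_config`.
#' @export
caller_config <- function(state_means = c(homo_del = -2.0, hemi_del = -0.5,
                                          neutral = 0, gain = 0.35),
                          state_sd = 0.2,
                          self_prob = 0.999,
                          neutral_prior = 0.99) {
  stopifnot(sum(state_means == 0) == 1, state_sd > 0,
            self_prob > 0, self_prob < 1,
            neutral_prior > 0, neutral_prior < 1)
  structure(list(state_means = state_means, state_sd = state_sd,
                 self_prob = self_prob, neutral_prior = neutral_prior),
            class = "caller_config")
}

#' Event classification rules
#'
#' The three rule instances applied to candidate segments, in precedence
#' order homozygous deletion, hemizygous deletion, amplification (first
#' match wins). Span is evaluated on the probe-span interval
#' (last position - first position + 1). The heterozygous proportion
#' denominator is the number of called polymorphic genotypes (AA/AB/BB);
#' a segment with none fails the het-proportion and BAF-deviation
#' conditions (fail closed).
#'
#' @param homo_min_probes,homo_min_bp,homo_lrr_max homozygous-deletion
#'   rule: minimum probes, minimum span, upper bound on mean LRR
#'   (strict `<`).
#' @param hemi_min_probes,hemi_min_bp,hemi_lrr_max,hemi_het_max
#'   hemizygous-deletion rule: minimum probes, minimum span, upper bound
#'   on mean LRR, upper bound on heterozygous proportion (strict `<`).
#' @param gain_min_probes,gain_min_bp,gain_lrr_min,gain_bafdev_min gain
#'   rule: minimum probes, minimum span, lower bound on mean LRR and on
#'   mean |BAF - 0.5| at heterozygous SNPs (both strict `>`).
#' @return list of class `segment_rules`.
#' @export
segment_rules <- function(homo_min_probes = 3, homo_min_bp = 1000,
                          homo_lrr_max = -1,
                          hemi_min_probes = 10, hemi_min_bp = 1000,
                          hemi_lrr_max = -0.25, hemi_het_max = 0.10,
                          gain_min_probes = 10, gain_min_bp = 1000,
                          gain_lrr_min = 0.25, gain_bafdev_min = 0.05) {
  structure(as.list(environment()), class = "segment_rules")
}

# Viterbi decoding of a Gaussian HMM over one LRR vector.
# Returns the integer state path. Hand-rolled: small, log-space, K states.
#' @keywords internal
viterbi_lrr <- function(lrr, config) {
  mu <- config$state_means
  K <- length(mu)
  n <- length(lrr)
  neutral <- which(mu == 0)
  log_trans <- matrix(log((1 - config$self_prob) / (K - 1)), K, K)
  diag(log_trans) <- log(config$self_prob)
  prior <- rep((1 - config$neutral_prior) / (K - 1), K)
  prior[neutral] <- config$neutral_prior
  # emission log-likelihoods, n x K
  em <- vapply(mu, function(m) stats::dnorm(lrr, m, config$state_sd, log = TRUE),
               numeric(n))
  em <- matrix(em, nrow = n)
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1, ] <- log(prior) + em[1, ]
  if (n > 1) {
    for (t in 2:n) {
      cand <- delta[t - 1, ] + log_trans       # K x K: from (row) to (col)
      psi[t, ] <- max.col(t(cand), ties.method = "first")
      delta[t, ] <- cand[cbind(psi[t, ], seq_len(K))] + em[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Find candidate CNV segments on a probe track
#'
#' Decodes the LRR track of one subject with the configured Gaussian HMM
#' and returns maximal runs of consecutive probes decoded below (low) or
#' above (high) the neutral state, per chromosome. Each run carries its
#' probe-index range (row indices into `track`), its base-pair span
#' (first to last probe position) and its direction.
#'
#' @param track probe-signal data frame for one subject: columns
#'   `marker_id`, `chrom`, `pos`, `lrr`, `baf`, `genotype`, positions
#'   strictly increasing within chromosome.
#' @param config a [caller_config()].
#' @return data frame with columns `chrom`, `first`, `last` (row indices),
#'   `start`, `end`, `n_probes`, `direction` (`"low"`/`"high"`).
#' @export
segment_candidates <- function(track, config = caller_config()) {
  if (NROW(track) == 0) stop("empty probe track")
  track$chrom <- strip_chr(track$chrom)
  out <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    pos <- track$pos[idx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("probe positions not strictly increasing on chromosome ", ch)
    path <- viterbi_lrr(track$lrr[idx], config)
    dir <- ifelse(config$state_means[path] < 0, "low",
                  ifelse(config$state_means[path] > 0, "high", "neutral"))
    r <- rle(dir)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != "neutral"
    if (!any(keep)) next
    out[[ch]] <- data.frame(
      chrom = ch,
      first = idx[starts[keep]],
      last = idx[ends[keep]],
      start = pos[starts[keep]],
      end = pos[ends[keep]],
      n_probes = r$lengths[keep],
      direction = r$values[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), first = integer(),
                      last = integer(), start = numeric(), end = numeric(),
                      n_probes = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(chrom_rank(res$chrom), res$start), , drop = FALSE]
}

#' Classify a candidate segment into a CNV call
#'
#' Applies the event rules in precedence order (homozygous deletion,
#' hemizygous deletion, amplification); the first rule whose conditions
#' all hold determines the call. Returns `NULL` when no rule matches.
#'
#' @param run one row of [segment_candidates()] output (list or one-row
#'   data frame with `first`, `last`, `chrom`, `start`, `end`,
#'   `n_probes`).
#' @param track the probe-signal data frame the run indexes into.
#' @param rules a [segment_rules()].
#' @param subject_id,cohort,source metadata copied onto the emitted call.
#' @return a one-row call data frame, or `NULL`.
#' @export
classify_segment <- function(run, track, rules = segment_rules(),
                             subject_id = NA_character_,
                             cohort = NA_character_,
                             source = "hmmcaller") {
  i <- seq(run$first, run$last)
  n <- length(i)
  span <- run$end - run$start + 1
  mean_lrr <- mean(track$lrr[i])
  geno <- track$genotype[i]
  called <- geno %in% c("AA", "AB", "BB")
  het_prop <- if (any(called)) sum(geno == "AB") / sum(called) else NA_real_
  het <- which(geno == "AB")
  baf_dev <- if (length(het)) mean(abs(track$baf[i][het] - 0.5)) else NA_real_

  type <- NULL
  if (n >= rules$homo_min_probes && span >= rules$homo_min_bp &&
      mean_lrr < rules$homo_lrr_max) {
    type <- "loss"
  } else if (n >= rules$hemi_min_probes && span >= rules$hemi_min_bp &&
             mean_lrr < rules$hemi_lrr_max &&
             !is.na(het_prop) && het_prop < rules$hemi_het_max) {
    type <- "loss"
  } else if (n >= rules$gain_min_probes && span >= rules$gain_min_bp &&
             mean_lrr > rules$gain_lrr_min &&
             !is.na(baf_dev) && baf_dev > rules$gain_bafdev_min) {
    type <- "gain"
  }
  if (is.null(type)) return(NULL)
  data.frame(subject_id = subject_id, cohort = cohort,
             chrom = strip_chr(run$chrom), start = run$start, end = run$end,
             type = type, n_probes = as.integer(n), confidence = NA_real_,
             source = source, stringsAsFactors = FALSE)
}

#' Call CNVs on probe tracks
#'
#' Segments and classifies each subject's track. `signals` may contain
#' several subjects (column `subject_id`); candidate runs are generated
#' per subject and chromosome, so emitted calls never overlap one another
#' within a subject.
#'
#' @param signals probe-signal data frame with columns `subject_id`,
#'   `chrom`, `pos`, `lrr`, `baf`, `genotype` (and optionally `cohort`).
#' @param config a [caller_config()].
#' @param rules a [segment_rules()].
#' @param source algorithm label stamped on the calls.
#' @return a CNV call data frame (possibly empty).
#' @export
call_cnvs <- function(signals, config = caller_config(),
                      rules = segment_rules(), source = "hmmcaller") {
  if (is.null(signals$subject_id)) signals$subject_id <- "subject1"
  out <- list()
  for (sid in unique(signals$subject_id)) {
    track <- signals[signals$subject_id == sid, , drop = FALSE]
    cohort <- if (!is.null(track$cohort)) track$cohort[1] else NA_character_
    cand <- segment_candidates(track, config)
    for (k in seq_len(nrow(cand))) {
      call <- classify_segment(cand[k, ], track, rules,
                               subject_id = sid, cohort = cohort,
                               source = source)
      if (!is.null(call)) out[[length(out) + 1L]] <- call
    }
  }
  if (!length(out)) return(empty_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject_id, chrom_rank(res$chrom), res$start), , drop = FALSE]
}

#' Filter calls by minimum probe count
#'
#' Keeps calls supported by at least `k` probes. Every call must carry a
#' known (positive) probe count.
#'
#' @param calls call data frame.
#' @param k minimum number of probes (inclusive), `k >= 1`.
#' @return the filtered calls, order preserved.
#' @export
filter_min_probes <- function(calls, k) {
  stopifnot(k >= 1)
  if (nrow(calls) && (any(is.na(calls$n_probes)) || any(calls$n_probes < 1)))
    stop("filter_min_probes requires a known probe count on every call")
  calls[calls$n_probes >= k, , drop = FALSE]
}

#' Filter calls by minimum size
#'
#' Keeps calls whose closed-interval size is at least `min_bp` (a 10-bp
#' call survives `min_bp = 10`; a 9-bp call does not).
#'
#' @param calls call data frame.
#' @param min_bp minimum size in base pairs (inclusive), `>= 1`.
#' @return the filtered calls, order preserved.
#' @export
filter_min_size <- function(calls, min_bp) {
  stopifnot(min_bp >= 1)
  if (!nrow(calls)) return(calls)
  calls[size_bp(calls$start, calls$end) >= min_bp, , drop = FALSE]
}

#' Filter calls by confidence (Log Bayes Factor)
#'
#' Drops calls whose confidence is strictly below `lbf_min`; a call at
#' exactly the bound is kept ("less than 30 omitted" keeps 30).
#'
#' @param calls call data frame; every call must carry a confidence.
#' @param lbf_min minimum confidence (inclusive), default 30.
#' @return the filtered calls, order preserved.
#' @export
filter_confidence <- function(calls, lbf_min = 30) {
  if (!nrow(calls)) return(calls)
  if (any(is.na(calls$confidence)))
    stop("filter_confidence requires a confidence value on every call")
  calls[calls$confidence >= lbf_min, , drop = FALSE]
}

#' Split calls spanning the centromere
#'
#' A call whose interval strictly contains part of both centromere flanks
#' is replaced by two calls, `[start, cen_start - 1]` and
#' `[cen_end + 1, end]`, with the same subject/type/source. Calls not
#' spanning the centromere pass through unchanged; a call entirely inside
#' the centromere interval is dropped. Probe counts of split pieces are
#' recomputed from `track` when supplied, otherwise set to `NA` with a
#' warning (such calls are exempt from probe-count filters until
#' recounted).
#'
#' @param calls call data frame.
#' @param centromeres data frame with columns `chrom`, `cen_start`,
#'   `cen_end` (1-based closed); must cover every chromosome in `calls`.
#' @param track optional probe-signal data frame used to recount probes
#'   (matched by `subject_id` when present).
#' @return call data frame with spanning calls split.
#' @export
split_at_centromere <- function(calls, centromeres, track = NULL) {
  if (!nrow(calls)) return(calls)
  centromeres$chrom <- strip_chr(centromeres$chrom)
  miss <- setdiff(unique(strip_chr(calls$chrom)), centromeres$chrom)
  if (length(miss)) stop("no centromere entry for chromosome(s): ",
                         paste(miss, collapse = ", "))
  cs <- centromeres$cen_start[match(strip_chr(calls$chrom), centromeres$chrom)]
  ce <- centromeres$cen_end[match(strip_chr(calls$chrom), centromeres$chrom)]

  count_probes <- function(row) {
    if (is.null(track)) return(NA_integer_)
    tr <- track
    if (!is.null(tr$subject_id) && !is.na(row$subject_id))
      tr <- tr[tr$subject_id == row$subject_id, , drop = FALSE]
    sum(strip_chr(tr$chrom) == row$chrom &
          tr$pos >= row$start & tr$pos <= row$end)
  }

  out <- list()
  warned <- FALSE
  for (k in seq_len(nrow(calls))) {
    row <- calls[k, ]
    spans <- row$start < cs[k] && row$end > ce[k]
    inside <- row$start >= cs[k] && row$end <= ce[k]
    if (inside) next
    if (!spans) {
      out[[length(out) + 1L]] <- row
      next
    }
    left <- row; left$end <- cs[k] - 1
    right <- row; right$start <- ce[k] + 1
    for (piece in list(left, right)) {
      piece$n_probes <- count_probes(piece)
      if (is.na(piece$n_probes) && !warned && is.null(track)) {
        warning("probe counts of split calls set to NA (no track supplied)")
        warned <- TRUE
      }
      out[[length(out) + 1L]] <- piece
    }
  }
  if (!length(out)) return(calls[0, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
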