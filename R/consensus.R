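# Multi-algorithm consensus calling: keep only CNVs identified, with
# qualifying overlap, by every algorithm in a required set, per subject
# and chromosome. The consensus span is the union (minimum start, maximum
# end) of the contributing calls.

# connected components over n nodes given an edge test function(i, j)
#' @keywords internal
components_by_test <- function(n, edge_test) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (n > 1) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (edge_test(a, b)) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

#' Intersect call sets from multiple algorithms
#'
#' Within each subject / chromosome / type cell, builds the overlap graph
#' over calls from the required sources (edge iff the criterion holds)
#' and emits one consensus call per connected component that contains at
#' least one call from *every* required source. The consensus interval is
#' the union span of the component, its probe count the maximum member
#' probe count, and its source label the required sources joined with
#' `"+"`. Components missing any required source emit nothing; calls from
#' sources outside the required set are ignored.
#'
#' With `matching = "clique"`, a component additionally qualifies only if
#' every pair of its calls satisfies the criterion directly.
#'
#' @param calls call data frame across sources (column `source` set).
#' @param required_sources character vector of algorithm labels; every
#'   label must occur somewhere in `calls$source` (a completely absent
#'   source signals mislabelled input). A single label is allowed as the
#'   degenerate case (the source's own calls pass through).
#' @param criterion an [overlap_criterion()].
#' @param matching `"component"` (default) or `"clique"`.
#' @return consensus call data frame.
#' @export
consensus_calls <- function(calls, required_sources,
                            criterion = overlap_criterion("any"),
                            matching = c("component", "clique")) {
  matching <- match.arg(matching)
  stopifnot(length(required_sources) >= 1)
  calls <- as_cnv_calls(calls)
  absent <- setdiff(required_sources, unique(calls$source))
  if (length(absent))
    stop("required source(s) absent from the call collection: ",
         paste(absent, collapse = ", "))
  calls <- calls[calls$source %in% required_sources, , drop = FALSE]
  if (!nrow(calls)) return(empty_calls())

  key <- paste(calls$subject_id, calls$chrom, calls$type, sep = "\r")
  out <- list()
  for (cell in split(seq_len(nrow(calls)), key)) {
    sub <- calls[cell, , drop = FALSE]
    edge <- function(a, b) {
      ov <- overlap_len(sub$start[a], sub$end[a], sub$start[b], sub$end[b])
      ov >= 1 && criterion_holds(ov, size_bp(sub$start[a], sub$end[a]),
                                 size_bp(sub$start[b], sub$end[b]), criterion)
    }
    comps <- components_by_test(nrow(sub), edge)
    for (m in comps) {
      if (!all(required_sources %in% sub$source[m])) next
      if (matching == "clique" && length(m) > 1) {
        pairs <- utils::combn(m, 2)
        if (!all(apply(pairs, 2, function(p) edge(p[1], p[2])))) next
      }
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sub$subject_id[m[1]],
        cohort = sub$cohort[m[1]],
        chrom = sub$chrom[m[1]],
        start = min(sub$start[m]),
        end = max(sub$end[m]),
        type = sub$type[m[1]],
        n_probes = as.integer(max(sub$n_probes[m])),
        confidence = NA_real_,
        source = paste(sort(required_sources), collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject_id, chrom_rank(res$chrom), res$start, res$type), ,
      drop = FALSE]
}

#' Concordance between two call sets
#'
#' Jaccard-style agreement: the overlap graph is built over the pooled
#' calls of both sets (edge iff the criterion holds between two
#' type-comparable calls), and the score is the fraction of connected
#' components containing calls from both sets — matched events over all
#' distinct events, with multiply-matched calls collapsed into one event.
#'
#' @param calls_a,calls_b call data frames for the same subjects.
#' @param criterion an [overlap_criterion()].
#' @param by_subject when `TRUE` (default) calls only match within the
#'   same subject.
#' @return a fraction in `[0, 1]` (1 for identical sets, 0 for disjoint
#'   ones; `NA` when both sets are empty).
#' @export
jaccard_concordance <- function(calls_a, calls_b,
                                criterion = overlap_criterion("any"),
                                by_subject = TRUE) {
  calls_a <- as_cnv_calls(calls_a)
  calls_b <- as_cnv_calls(calls_b)
  pool <- rbind(calls_a, calls_b)
  if (!nrow(pool)) return(NA_real_)
  set <- rep(c("a", "b"), c(nrow(calls_a), nrow(calls_b)))
  edge <- function(i, j) {
    if (by_subject && !identical(pool$subject_id[i], pool$subject_id[j]))
      return(FALSE)
    if (pool$chrom[i] != pool$chrom[j]) return(FALSE)
    if (pool$type[i] != pool$type[j]) return(FALSE)
    ov <- overlap_len(pool$start[i], pool$end[i], pool$start[j], pool$end[j])
    ov >= 1 && criterion_holds(ov, size_bp(pool$start[i], pool$end[i]),
                               size_bp(pool$start[j], pool$end[j]), criterion)
  }
  comps <- components_by_test(nrow(pool), edge)
  matched <- vapply(comps, function(m) {
    any(set[m] == "a") && any(set[m] == "b")
  }, logical(1))
  sum(matched) / length(comps)
}
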