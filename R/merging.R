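# Collapsing CNV records into merged CNV regions (CNVRs).
#
# Under the "any" criterion the result is the classic union of
# type-compatible overlapping intervals. Under "pct_either" (40% of the
# smaller event) merging is not confluent — the grown union span can newly
# satisfy or fail the threshold against later records — so a deterministic
# schedule is fixed: records sorted by (chrom, start, end, type, id,
# source), single-linkage agglomeration left to right testing each record
# against the spans of groups already formed, whole passes repeated until
# the grouping stops changing (the group count is non-increasing, so a
# fixed point is reached).

# stable sort order used by the schedule
#' @keywords internal
record_order <- function(df) {
  id <- if (!is.null(df$subject_id)) df$subject_id
        else if (!is.null(df$study)) df$study
        else rep("", nrow(df))
  src <- if (!is.null(df$source)) df$source else rep("", nrow(df))
  order(chrom_rank(df$chrom), df$start, df$end, df$type, id, src)
}

#' Merge CNV records into CNV regions
#'
#' Groups records (subject calls or reference-database records) whose
#' typed intervals satisfy the overlap criterion, and emits one region
#' per group with the union span (minimum start, maximum end of the
#' members). Losses merge with losses or "both", gains with gains or
#' "both"; a "both" record can bridge losses and gains into a single
#' region, which is then typed "both". A region is typed "both" iff at
#' least one member is; otherwise it carries the members' common type.
#'
#' Two linkage variants are provided. `"span"` (default) follows the
#' deterministic agglomeration schedule described above, testing each
#' record against the current union span of each group. `"member"`
#' computes the transitive closure of the criterion over the original
#' records (connected components of the pairwise overlap graph).
#' Under the `"any"` criterion the two coincide.
#'
#' @param records data frame with columns `chrom`, `start`, `end`, `type`
#'   (plus any others, carried into member bookkeeping).
#' @param criterion an [overlap_criterion()].
#' @param linkage `"span"` or `"member"`.
#' @return region data frame with columns `chrom`, `start`, `end`,
#'   `type`, `n_members`, `member_ids` (comma-separated indices into the
#'   input row order), sorted by (chrom, start, end).
#' @examples
#' recs <- data.frame(chrom = "1", start = c(1, 90, 180),
#'                    end = c(100, 190, 280), type = "loss")
#' merge_records(recs, overlap_criterion("any"))        # one region [1, 280]
#' merge_records(recs, overlap_criterion("pct_either")) # three regions
#' @export
merge_records <- function(records, criterion,
                          linkage = c("span", "member")) {
  linkage <- match.arg(linkage)
  if (NROW(records) == 0) return(empty_regions())
  records <- as.data.frame(records)
  records$chrom <- strip_chr(records$chrom)
  stopifnot(all(records$type %in% CNV_TYPES),
            all(records$start >= 1 & records$end >= records$start))
  ord <- record_order(records)

  groups <- if (linkage == "member") {
    merge_member_linkage(records, ord, criterion)
  } else {
    merge_span_linkage(records, ord, criterion)
  }

  res <- do.call(rbind, lapply(groups, function(m) {
    ty <- records$type[m]
    type <- if (any(ty == "both")) "both" else unique(ty)
    stopifnot(length(type) == 1)
    data.frame(chrom = records$chrom[m[1]],
               start = min(records$start[m]),
               end = max(records$end[m]),
               type = type,
               n_members = length(m),
               member_ids = paste(sort(m), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res[order(chrom_rank(res$chrom), res$start, res$end, res$type), ,
      drop = FALSE]
}

# single-linkage left-to-right agglomeration against group spans,
# repeated to a fixed point; vectorised over open groups
#' @keywords internal
merge_span_linkage <- function(records, ord, criterion) {
  # current items: spans + the original-record members they carry
  it_chrom <- records$chrom[ord]
  it_start <- records$start[ord]
  it_end <- records$end[ord]
  it_type <- records$type[ord]
  it_members <- as.list(ord)

  repeat {
    n <- length(it_start)
    g_chrom <- character(0); g_start <- numeric(0); g_end <- numeric(0)
    g_type <- character(0); g_members <- list()
    for (i in seq_len(n)) {
      hit <- 0L
      if (length(g_start)) {
        ok <- g_chrom == it_chrom[i] &
          types_mergeable(it_type[i], g_type)
        if (any(ok)) {
          ov <- overlap_len(it_start[i], it_end[i], g_start, g_end)
          ok <- ok & criterion_holds(
            ov, size_bp(it_start[i], it_end[i]), size_bp(g_start, g_end),
            criterion)
          if (any(ok)) hit <- which(ok)[1]
        }
      }
      if (hit > 0L) {
        g_start[hit] <- min(g_start[hit], it_start[i])
        g_end[hit] <- max(g_end[hit], it_end[i])
        if (it_type[i] == "both" || g_type[hit] == "both" ||
            it_type[i] != g_type[hit]) g_type[hit] <- "both"
        # (differing non-both types cannot pass types_mergeable, so the
        # last disjunct is defensive)
        g_members[[hit]] <- c(g_members[[hit]], it_members[[i]])
      } else {
        g_chrom <- c(g_chrom, it_chrom[i])
        g_start <- c(g_start, it_start[i])
        g_end <- c(g_end, it_end[i])
        g_type <- c(g_type, it_type[i])
        g_members[[length(g_start)]] <- it_members[[i]]
      }
    }
    if (length(g_start) == n) return(g_members)
    # re-sort groups into schedule order for the next pass
    o <- order(chrom_rank(g_chrom), g_start, g_end, g_type)
    it_chrom <- g_chrom[o]; it_start <- g_start[o]; it_end <- g_end[o]
    it_type <- g_type[o]; it_members <- g_members[o]
  }
}

# transitive closure over original records (connected components)
#' @keywords internal
merge_member_linkage <- function(records, ord, criterion) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (a in seq_len(n)) {
    sz_a <- size_bp(records$start[a], records$end[a])
    for (b in seq_len(n)) {
      if (b <= a) next
      if (records$chrom[a] != records$chrom[b]) next
      if (!types_mergeable(records$type[a], records$type[b])) next
      ov <- overlap_len(records$start[a], records$end[a],
                        records$start[b], records$end[b])
      if (ov >= 1 && criterion_holds(ov, sz_a,
                                     size_bp(records$start[b], records$end[b]),
                                     criterion)) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

#' Count merged regions by type
#'
#' Tallies a region set into loss / gain / both / total, the row shape of
#' a merged-database summary.
#'
#' @param regions region data frame from [merge_records()].
#' @return named numeric vector `c(loss, gain, both, total)`.
#' @export
count_by_type <- function(regions) {
  c(loss = sum(regions$type == "loss"),
    gain = sum(regions$type == "gain"),
    both = sum(regions$type == "both"),
    total = nrow(regions))
}
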