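# Core interval algebra and domain conventions.
#
# All coordinates are 1-based and fully closed: a single base is
# [p, p], size = end - start + 1, and adjacent intervals (end + 1 == start)
# do NOT overlap. BED-style 0-based half-open input is converted at I/O.
# Only autosomes ("1".."22") are handled; sex chromosomes are dropped on
# read, matching how CNV studies on mixed-sex cohorts report autosomal
# events only.

CNV_TYPES <- c("loss", "gain", "both")

#' Normalise chromosome labels
#'
#' Strips a leading `"chr"` prefix and returns the bare label
#' (`"chr8"` -> `"8"`).
#'
#' @param x character vector of chromosome labels.
#' @return character vector of bare labels.
#' @export
strip_chr <- function(x) sub("^chr", "", as.character(x))

#' @keywords internal
is_autosome <- function(chrom) strip_chr(chrom) %in% as.character(1:22)

# numeric rank for sorting "1".."22"
#' @keywords internal
chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.integer(strip_chr(chrom)))
  r[is.na(r)] <- 999L
  r
}

#' Size of a genomic interval in base pairs
#'
#' Closed-interval size: `end - start + 1`. A single-base interval has
#' size 1.
#'
#' @param start,end 1-based inclusive coordinates (vectorised).
#' @return integer-valued numeric vector of sizes.
#' @examples
#' size_bp(100, 100)          # 1
#' size_bp(25046920, 25130278) # 83359
#' @export
size_bp <- function(start, end) {
  stopifnot(all(end >= start), all(start >= 1))
  end - start + 1
}

#' Length of overlap between two closed intervals
#'
#' Returns 0 for disjoint intervals or intervals on different chromosomes.
#' Adjacent closed intervals (`end1 + 1 == start2`) share no base and
#' return 0.
#'
#' @param start1,end1,start2,end2 1-based inclusive coordinates
#'   (vectorised).
#' @param chrom1,chrom2 optional chromosome labels; when supplied, pairs on
#'   different chromosomes get overlap 0.
#' @return numeric vector of shared base-pair counts.
#' @export
overlap_len <- function(start1, end1, start2, end2,
                        chrom1 = NULL, chrom2 = NULL) {
  ov <- pmax(0, pmin(end1, end2) - pmax(start1, start2) + 1)
  if (!is.null(chrom1) || !is.null(chrom2)) {
    ov[strip_chr(chrom1) != strip_chr(chrom2)] <- 0
  }
  ov
}

#' Type comparability for screening a subject call against a reference
#'
#' Gains are compared only to gains or "both"; losses only to losses or
#' "both". Subject-level calls are never typed "both", so a `"both"` query
#' is an error.
#'
#' @param query type of the query call, `"loss"` or `"gain"` (vectorised).
#' @param reference type of the reference record, `"loss"`, `"gain"` or
#'   `"both"` (vectorised).
#' @return logical vector.
#' @export
types_comparable <- function(query, reference) {
  if (any(query == "both")) {
    stop("subject-level calls are never typed 'both'")
  }
  stopifnot(all(query %in% c("loss", "gain")), all(reference %in% CNV_TYPES))
  reference == query | reference == "both"
}

# symmetric variant used during merging, where either side may be "both"
#' @keywords internal
types_mergeable <- function(a, b) {
  a == b | a == "both" | b == "both"
}

#' Construct an overlap criterion
#'
#' The rule deciding whether two typed intervals "overlap" for merging,
#' consensus and novelty screening:
#' \describe{
#'   \item{`any`}{at least one shared base pair.}
#'   \item{`pct_either`}{the shared length is at least `threshold` times
#'     the size of at least one of the two intervals — equivalently, of the
#'     smaller one ("40% either" at the default threshold).}
#'   \item{`pct_both`}{reciprocal rule: the shared length is at least
#'     `threshold` times the size of *each* interval. Provided for
#'     completeness; not part of the replication pipelines.}
#' }
#' The threshold comparison is inclusive (`>=`).
#'
#' @param mode one of `"any"`, `"pct_either"`, `"pct_both"`.
#' @param threshold overlap fraction in (0, 1]; used by the `pct_*` modes.
#' @return an object of class `overlap_criterion`.
#' @examples
#' overlap_criterion("any")
#' overlap_criterion("pct_either", 0.40)
#' @export
overlap_criterion <- function(mode = c("any", "pct_either", "pct_both"),
                              threshold = 0.40) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold <= 1)
  structure(list(mode = mode, threshold = threshold),
            class = "overlap_criterion")
}

#' @export
print.overlap_criterion <- function(x, ...) {
  if (x$mode == "any") {
    cat("overlap criterion: any (>= 1 shared bp)\n")
  } else {
    cat(sprintf("overlap criterion: %s (threshold %.2f)\n", x$mode,
                x$threshold))
  }
  invisible(x)
}

# vectorised criterion test given precomputed overlaps and sizes
#' @keywords internal
criterion_holds <- function(ov, size_a, size_b, criterion) {
  switch(criterion$mode,
    any = ov >= 1,
    pct_either = ov >= 1 & ov >= criterion$threshold * pmin(size_a, size_b),
    pct_both = ov >= 1 & ov >= criterion$threshold * size_a &
      ov >= criterion$threshold * size_b,
    stop("unknown criterion mode: ", criterion$mode)
  )
}

#' Test whether two typed intervals satisfy an overlap criterion
#'
#' Returns `FALSE` when the types are not comparable (losses pair with
#' losses or "both", gains with gains or "both") or when the intervals
#' share no base pair. The test is symmetric in its two arguments.
#'
#' @param a,b lists or one-row data frames with fields `chrom`, `start`,
#'   `end`, `type`.
#' @param criterion an [overlap_criterion()].
#' @return single logical.
#' @examples
#' crit <- overlap_criterion("pct_either", 0.40)
#' a <- list(chrom = "1", start = 1, end = 100, type = "loss")
#' b <- list(chrom = "1", start = 61, end = 260, type = "loss")
#' meets_criterion(a, b, crit)  # TRUE: 40 shared bp = 40% of a
#' @export
meets_criterion <- function(a, b, criterion) {
  if (strip_chr(a$chrom) != strip_chr(b$chrom)) return(FALSE)
  if (!types_mergeable(a$type, b$type)) return(FALSE)
  ov <- overlap_len(a$start, a$end, b$start, b$end)
  if (ov == 0) return(FALSE)
  criterion_holds(ov, size_bp(a$start, a$end), size_bp(b$start, b$end),
                  criterion)
}

#' Union span of a set of intervals on one chromosome
#'
#' The merged-region span rule: start is the minimum start among members,
#' end is the maximum end.
#'
#' @param records data frame with columns `chrom`, `start`, `end` (one or
#'   more rows, all on the same chromosome).
#' @return list with fields `chrom`, `start`, `end`.
#' @export
span_union <- function(records) {
  if (NROW(records) == 0) stop("span_union of an empty record set")
  ch <- unique(strip_chr(records$chrom))
  if (length(ch) != 1) stop("span_union across mixed chromosomes: ",
                            paste(ch, collapse = ", "))
  list(chrom = ch, start = min(records$start), end = max(records$end))
}

#' Validate a CNV call table
#'
#' Checks the column contract for subject-level calls: `chrom`, `start`,
#' `end`, `type` required; `subject_id`, `cohort`, `n_probes`,
#' `confidence`, `source` filled with defaults when absent. Subject calls
#' must be typed `loss` or `gain` (never `both`), lie on autosomes, and
#' have `1 <= start <= end`.
#'
#' @param calls data frame of calls.
#' @return the calls with defaulted columns, invisibly validated.
#' @export
as_cnv_calls <- function(calls) {
  calls <- as.data.frame(calls)
  req <- c("chrom", "start", "end", "type")
  miss <- setdiff(req, names(calls))
  if (length(miss)) stop("missing call columns: ", paste(miss, collapse = ", "))
  calls$chrom <- strip_chr(calls$chrom)
  if (nrow(calls)) {
    if (!all(is_autosome(calls$chrom)))
      stop("non-autosomal chromosome in calls (sex chromosomes are dropped at I/O)")
    if (!all(calls$type %in% c("loss", "gain")))
      stop("subject-level call types must be 'loss' or 'gain'")
    if (!all(calls$start >= 1 & calls$end >= calls$start))
      stop("invalid call coordinates (need 1 <= start <= end)")
  }
  n <- nrow(calls)
  if (is.null(calls$subject_id)) calls$subject_id <- rep(NA_character_, n)
  if (is.null(calls$cohort)) calls$cohort <- rep(NA_character_, n)
  if (is.null(calls$n_probes)) calls$n_probes <- rep(0L, n)
  if (is.null(calls$confidence)) calls$confidence <- rep(NA_real_, n)
  if (is.null(calls$source)) calls$source <- rep("unknown", n)
  calls
}

#' Validate a reference CNV database table
#'
#' Reference records (`RefCnv`) may be typed `loss`, `gain` or `both`, and
#' carry a cohort tag (`normal` or `scz`), a study label, and optional
#' per-record `gain_count` / `loss_count` columns used only by database
#' preprocessing.
#'
#' @param db data frame of reference records.
#' @return the records with defaulted columns.
#' @export
as_ref_db <- function(db) {
  db <- as.data.frame(db)
  req <- c("chrom", "start", "end", "type")
  miss <- setdiff(req, names(db))
  if (length(miss)) stop("missing reference columns: ",
                         paste(miss, collapse = ", "))
  db$chrom <- strip_chr(db$chrom)
  if (nrow(db)) {
    if (!all(db$type %in% CNV_TYPES))
      stop("reference types must be loss/gain/both")
    if (!all(db$start >= 1 & db$end >= db$start))
      stop("invalid reference coordinates")
  }
  n <- nrow(db)
  if (is.null(db$cohort)) db$cohort <- rep("normal", n)
  if (is.null(db$study)) db$study <- rep("unknown", n)
  if (is.null(db$gain_count)) db$gain_count <- rep(NA_real_, n)
  if (is.null(db$loss_count)) db$loss_count <- rep(NA_real_, n)
  db
}

# empty schemas shared by several modules
#' @keywords internal
empty_calls <- function() {
  data.frame(subject_id = character(), cohort = character(),
             chrom = character(), start = numeric(), end = numeric(),
             type = character(), n_probes = integer(),
             confidence = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

#' @keywords internal
empty_regions <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             type = character(), n_members = integer(),
             member_ids = character(), stringsAsFactors = FALSE)
}
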