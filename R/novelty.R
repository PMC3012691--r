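# The four-stage novelty-screening flow: preprocess literature CNV
# tables, merge the normals database, screen study calls against it,
# restrict survivors to case-only events, and screen what remains against
# the merged disease-literature records not already present in normals.
#
# Screens are all-or-nothing: one qualifying, type-comparable overlap
# eliminates a call outright (no interval trimming), and every eliminated
# call is blamed on the first eliminating record in deterministic
# (chrom, start, end) scan order.

#' Preprocess a literature CNV table
#'
#' Standard clean-up applied to downloaded reference tables before
#' merging: drops sex-chromosome records; drops records smaller than
#' `min_size_bp`; for records carrying observation counts, drops those
#' with both `gain_count` and `loss_count` absent or zero and re-derives
#' the type from the counts (gain only, loss only, or both); drops
#' records from excluded studies.
#'
#' @param db reference data frame (see [as_ref_db()]).
#' @param min_size_bp minimum record size in bp (inclusive), default 10.
#' @param exclude_studies study tags to drop entirely, default `"hgdp"`.
#' @return the cleaned reference table.
#' @export
preprocess_ref_table <- function(db, min_size_bp = 10,
                                 exclude_studies = "hgdp") {
  db <- as_ref_db(db)
  if (!nrow(db)) return(db)
  db <- db[is_autosome(db$chrom), , drop = FALSE]
  if (nrow(db)) db <- db[size_bp(db$start, db$end) >= min_size_bp, , drop = FALSE]
  db <- db[!(db$study %in% exclude_studies), , drop = FALSE]
  has_counts <- !is.na(db$gain_count) | !is.na(db$loss_count)
  if (any(has_counts)) {
    g <- ifelse(is.na(db$gain_count), 0, db$gain_count)
    l <- ifelse(is.na(db$loss_count), 0, db$loss_count)
    drop <- has_counts & g == 0 & l == 0
    db$type[has_counts & g > 0 & l == 0] <- "gain"
    db$type[has_counts & g == 0 & l > 0] <- "loss"
    db$type[has_counts & g > 0 & l > 0] <- "both"
    db <- db[!drop, , drop = FALSE]
  }
  rownames(db) <- NULL
  db
}

#' Merge a preprocessed reference table into unique regions
#'
#' Delegates to [merge_records()] and tags the result with the records'
#' cohort.
#'
#' @param db preprocessed reference table.
#' @param criterion an [overlap_criterion()].
#' @param linkage passed to [merge_records()].
#' @return region data frame with a `cohort` column.
#' @export
build_merged_db <- function(db, criterion, linkage = "span") {
  db <- as_ref_db(db)
  regions <- merge_records(db, criterion, linkage = linkage)
  regions$cohort <- rep(if (nrow(db)) unique(db$cohort)[1] else NA_character_,
                        nrow(regions))
  regions
}

# first qualifying region index (in scan order) per call, or 0
#' @keywords internal
first_hit <- function(calls, db, criterion) {
  if (!nrow(db)) return(integer(nrow(calls)))
  scan <- order(chrom_rank(db$chrom), db$start, db$end)
  db <- db[scan, , drop = FALSE]
  db_size <- size_bp(db$start, db$end)
  vapply(seq_len(NROW(calls)), function(i) {
    ok <- db$chrom == calls$chrom[i] &
      types_mergeable(calls$type[i], db$type)
    if (!any(ok)) return(0L)
    ov <- overlap_len(calls$start[i], calls$end[i], db$start, db$end)
    ok <- ok & criterion_holds(ov, size_bp(calls$start[i], calls$end[i]),
                               db_size, criterion)
    if (!any(ok)) return(0L)
    scan[which(ok)[1]]
  }, integer(1))
}

#' Screen calls against a merged reference database
#'
#' A call is eliminated iff the criterion holds against at least one
#' type-comparable database region (gains against gains or "both",
#' losses against losses or "both"); surviving calls are returned
#' unmodified. Eliminated calls carry the blame region as
#' `"chrom:start-end"`. The query side may itself be a reference table
#' (e.g. disease-literature records, possibly typed "both") — a "both"
#' query matches either region type.
#'
#' @param calls call or reference data frame (columns `chrom`, `start`,
#'   `end`, `type`).
#' @param db_regions merged reference regions (same criterion as the
#'   screen).
#' @param criterion an [overlap_criterion()].
#' @return list with elements `kept` (calls) and `eliminated` (calls plus
#'   a `blame` column).
#' @export
screen_vs_db <- function(calls, db_regions, criterion) {
  calls <- as.data.frame(calls)
  calls$chrom <- strip_chr(calls$chrom)
  stopifnot(all(calls$type %in% CNV_TYPES))
  hit <- first_hit(calls, db_regions, criterion)
  kept <- calls[hit == 0L, , drop = FALSE]
  elim <- calls[hit != 0L, , drop = FALSE]
  if (nrow(elim)) {
    h <- hit[hit != 0L]
    elim$blame <- sprintf("%s:%d-%d", db_regions$chrom[h],
                          as.integer(db_regions$start[h]),
                          as.integer(db_regions$end[h]))
  } else {
    elim$blame <- character(0)
  }
  list(kept = kept, eliminated = elim)
}

#' Restrict calls to case-only events
#'
#' A case call is eliminated iff it satisfies the criterion against any
#' type-comparable control call (raw control calls, not merged regions).
#'
#' @param calls_case,calls_control call data frames.
#' @param criterion an [overlap_criterion()].
#' @return list with elements `kept` and `eliminated` (blamed on the
#'   first matching control call).
#' @export
case_only <- function(calls_case, calls_control, criterion) {
  calls_case <- as_cnv_calls(calls_case)
  calls_control <- as_cnv_calls(calls_control)
  screen_vs_db(calls_case, calls_control, criterion)
}

#' @keywords internal
type_counts <- function(calls) {
  c(loss = sum(calls$type == "loss"),
    gain = sum(calls$type == "gain"),
    total = nrow(calls))
}

#' Run the four-stage novelty flow
#'
#' Executes, under one overlap criterion throughout:
#' \enumerate{
#'   \item screen all study calls (both cohorts) against the merged
#'     normals literature database;
#'   \item restrict the surviving case calls to those not present in the
#'     control subjects (screened against all control calls of the input
#'     set);
#'   \item screen the disease-literature records against the merged
#'     normals database and merge the survivors into regions;
#'   \item screen the stage-2 survivors against those regions.
#' }
#'
#' @param calls study call data frame (column `cohort` set to `"case"` /
#'   `"control"`).
#' @param normals_db preprocessed normals literature table.
#' @param scz_db preprocessed disease (schizophrenia) literature table.
#' @param criterion an [overlap_criterion()] shared by every stage.
#' @param linkage linkage passed to the database merges.
#' @return a `novelty_report`: list with `stage_counts` (data frame of
#'   loss/gain/total per stage), `fates` (per-call stage of elimination
#'   and blame), `survivors` (final call data frame), `merged_normals`
#'   and `scz_lit_regions` (the intermediate databases), and
#'   `survivor_regions` (the survivors merged under the same criterion,
#'   for merged-database tallies).
#' @export
run_novelty_flow <- function(calls, normals_db, scz_db, criterion,
                             linkage = "span") {
  calls <- as_cnv_calls(calls)
  calls$.call_id <- seq_len(nrow(calls)) + 0L
  merged_normals <- build_merged_db(normals_db, criterion, linkage)

  s1 <- screen_vs_db(calls, merged_normals, criterion)
  s1_case <- s1$kept[s1$kept$cohort %in% "case", , drop = FALSE]
  controls <- calls[calls$cohort %in% "control", , drop = FALSE]

  s2 <- case_only(s1_case, controls, criterion)

  scz_clean <- as_ref_db(scz_db)
  scz_surv <- screen_vs_db(scz_clean, merged_normals, criterion)$kept
  scz_regions <- merge_records(scz_surv, criterion, linkage = linkage)

  s3 <- screen_vs_db(s2$kept, scz_regions, criterion)

  fates <- data.frame(call_id = calls$.call_id,
                      subject_id = calls$subject_id,
                      cohort = calls$cohort,
                      chrom = calls$chrom, start = calls$start,
                      end = calls$end, type = calls$type,
                      fate = rep("survived", nrow(calls)),
                      blame = rep(NA_character_, nrow(calls)),
                      stringsAsFactors = FALSE)
  mark <- function(elim, label) {
    if (!nrow(elim)) return(invisible())
    i <- match(elim$.call_id, fates$call_id)
    fates$fate[i] <<- label
    fates$blame[i] <<- elim$blame
  }
  mark(s1$eliminated, "in_normals_db")
  fates$fate[fates$cohort %in% "control" &
               fates$fate == "survived"] <- "control_subject"
  mark(s2$eliminated, "in_study_controls")
  mark(s3$eliminated, "in_scz_lit")

  stage_counts <- rbind(
    input = type_counts(calls),
    not_in_normals = type_counts(s1$kept),
    case_only = type_counts(s2$kept),
    not_in_normals_or_scz = type_counts(s3$kept))
  stage_counts <- data.frame(stage = rownames(stage_counts),
                             stage_counts, row.names = NULL,
                             stringsAsFactors = FALSE)

  survivors <- s3$kept
  survivors$.call_id <- NULL
  structure(list(stage_counts = stage_counts,
                 fates = fates,
                 survivors = survivors,
                 merged_normals = merged_normals,
                 scz_lit_regions = scz_regions,
                 survivor_regions = merge_records(survivors, criterion,
                                                  linkage = linkage)),
            class = "novelty_report")
}

#' @export
print.novelty_report <- function(x, ...) {
  cat("novelty flow stage counts (loss / gain / total):\n")
  print(x$stage_counts, row.names = FALSE)
  invisible(x)
}
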