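# Summary tables over a call set: counts by type and size class, size
# statistics, and per-subject burden statistics including subjects with
# zero calls. The size classes split at 100 kb, with the boundary
# assigned to the ">=100 kb" class. Display rounding is one decimal,
# half away from zero; underlying values are kept at full precision.

#' Round half away from zero
#'
#' One-decimal-style display rounding (39.25 -> 39.3, -1.15 -> -1.2),
#' as opposed to R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @keywords internal
size_class <- function(calls, boundary = 1e5) {
  sz <- size_bp(calls$start, calls$end)
  ifelse(sz >= boundary, "ge100kb", "lt100kb")
}

#' Count calls by type and size class
#'
#' Tabulates loss / gain / total over all calls and over the `<100 kb`
#' and `>=100 kb` size classes (a call of exactly 100,000 bp falls in
#' the `>=100 kb` class). The two classes partition the full set.
#'
#' @param calls call data frame.
#' @param boundary size-class boundary in bp (default 100,000).
#' @return data frame with rows loss/gain/total and columns `all`,
#'   `lt100kb`, `ge100kb`.
#' @export
count_table <- function(calls, boundary = 1e5) {
  cls <- size_class(calls, boundary)
  cell <- function(keep) c(loss = sum(calls$type[keep] == "loss"),
                           gain = sum(calls$type[keep] == "gain"),
                           total = sum(keep))
  n <- NROW(calls)
  data.frame(all = cell(rep(TRUE, n)),
             lt100kb = cell(cls == "lt100kb"),
             ge100kb = cell(cls == "ge100kb"))
}

#' Size statistics of a call set, in kb
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and
#' maximum of call sizes in kilobases (size_bp / 1000), for all calls
#' and per size class. An empty class yields an all-`NA` row with
#' `n = 0`; a single-call class has `SD = NA`.
#'
#' @param calls call data frame.
#' @param boundary size-class boundary in bp.
#' @return data frame with rows `all`, `lt100kb`, `ge100kb` and columns
#'   `n`, `mean`, `sd`, `min`, `max`.
#' @export
size_stats <- function(calls, boundary = 1e5) {
  cls <- size_class(calls, boundary)
  kb <- size_bp(calls$start, calls$end) / 1000
  one <- function(x) {
    if (!length(x)) return(c(n = 0, mean = NA, sd = NA, min = NA, max = NA))
    c(n = length(x), mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else NA,
      min = min(x), max = max(x))
  }
  out <- rbind(all = one(kb),
               lt100kb = one(kb[cls == "lt100kb"]),
               ge100kb = one(kb[cls == "ge100kb"]))
  as.data.frame(out)
}

#' Per-subject burden statistics
#'
#' Mean, sample SD, minimum and maximum of the number of calls per
#' subject, over all calls and per size class. The roster is supplied
#' independently of the calls so that subjects with zero calls enter the
#' denominator: mean = total calls / roster size, exactly. `mean_1dp`
#' gives the one-decimal display value (half away from zero). Also
#' reports the number of zero-call subjects per cohort.
#'
#' @param calls call data frame (column `subject_id` set; every subject
#'   must appear in the roster).
#' @param roster data frame with columns `subject_id` and `cohort`.
#' @param boundary size-class boundary in bp.
#' @return list with `stats` (data frame, rows `all`/`lt100kb`/`ge100kb`,
#'   columns `n_subjects`, `total`, `mean`, `mean_1dp`, `sd`, `min`,
#'   `max`) and `zero_by_cohort` (named integer vector of zero-call
#'   subjects per cohort).
#' @export
per_subject_stats <- function(calls, roster, boundary = 1e5) {
  stopifnot(!anyDuplicated(roster$subject_id))
  stray <- setdiff(unique(calls$subject_id), roster$subject_id)
  if (length(stray))
    stop("call subject(s) missing from roster: ", paste(stray, collapse = ", "))
  cls <- size_class(calls, boundary)
  counts_for <- function(keep) {
    tab <- table(factor(calls$subject_id[keep], levels = roster$subject_id))
    as.vector(tab)
  }
  n_all <- counts_for(rep(TRUE, NROW(calls)))
  one <- function(cnt) {
    c(n_subjects = length(cnt), total = sum(cnt), mean = mean(cnt),
      mean_1dp = round_half_out(mean(cnt), 1),
      sd = if (length(cnt) > 1) stats::sd(cnt) else NA,
      min = min(cnt), max = max(cnt))
  }
  stats <- rbind(all = one(n_all),
                 lt100kb = one(counts_for(cls == "lt100kb")),
                 ge100kb = one(counts_for(cls == "ge100kb")))
  zero <- tapply(n_all == 0, roster$cohort, sum)
  list(stats = as.data.frame(stats),
       zero_by_cohort = vapply(zero, as.integer, integer(1)))
}
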