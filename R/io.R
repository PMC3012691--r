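# Readers/writers for the pipeline's TSV formats, plus the end-to-end
# pipeline driver with its JSON run manifest.
#
# The canonical on-disk dialect is 1-based fully-closed TSV with an
# explicit header. BED-style input (0-based half-open) is converted on
# read (start + 1). Chromosome labels are normalised by stripping a
# "chr" prefix; sex-chromosome rows are dropped with a logged count.

#' @keywords internal
read_tsv_checked <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(basename(path), ": missing required column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' @keywords internal
normalize_coords <- function(df, path, dialect) {
  if (dialect == "bed") df$start <- df$start + 1
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start > df$end | df$start < 1)
  if (length(bad))
    stop(basename(path), ": malformed coordinates on data line(s) ",
         paste(bad, collapse = ", "))
  df$chrom <- strip_chr(df$chrom)
  sex <- !is_autosome(df$chrom)
  if (any(sex)) {
    message("dropping ", sum(sex), " sex-chromosome row(s) from ",
            basename(path))
    df <- df[!sex, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read a CNV call table
#'
#' TSV with header; required columns `chrom`, `start`, `end`, `type`.
#' Coordinates are normalised to 1-based closed (`dialect = "bed"`
#' converts 0-based half-open starts); rows with malformed coordinates
#' abort with their line numbers; sex-chromosome rows are dropped with a
#' logged count.
#'
#' @param path TSV file path.
#' @param dialect `"tsv1"` (1-based closed, default) or `"bed"`.
#' @return call data frame (see [as_cnv_calls()]).
#' @export
read_calls <- function(path, dialect = c("tsv1", "bed")) {
  dialect <- match.arg(dialect)
  df <- read_tsv_checked(path, c("chrom", "start", "end", "type"))
  as_cnv_calls(normalize_coords(df, path, dialect))
}

#' Write a CNV call table
#'
#' @param calls call data frame.
#' @param path output TSV path (1-based closed dialect).
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a reference CNV database table
#'
#' Required columns `chrom`, `start`, `end`, `type`; optional `cohort`,
#' `study`, `gain_count`, `loss_count`. Same coordinate handling as
#' [read_calls()].
#'
#' @inheritParams read_calls
#' @return reference data frame (see [as_ref_db()]).
#' @export
read_ref_db <- function(path, dialect = c("tsv1", "bed")) {
  dialect <- match.arg(dialect)
  df <- read_tsv_checked(path, c("chrom", "start", "end", "type"))
  as_ref_db(normalize_coords(df, path, dialect))
}

#' Read a probe-signal track
#'
#' TSV with columns `marker_id`, `chrom`, `pos`, `lrr`, `baf`,
#' `genotype` (and optionally `subject_id`, `cohort`). Sex-chromosome
#' probes are dropped.
#'
#' @param path TSV file path.
#' @return probe-signal data frame.
#' @export
read_probe_track <- function(path) {
  df <- read_tsv_checked(path, c("marker_id", "chrom", "pos", "lrr",
                                 "baf", "genotype"))
  df$chrom <- strip_chr(df$chrom)
  sex <- !is_autosome(df$chrom)
  if (any(sex)) {
    message("dropping ", sum(sex), " sex-chromosome probe(s) from ",
            basename(path))
    df <- df[!sex, , drop = FALSE]
  }
  df
}

#' Read a centromere coordinate table
#'
#' TSV with columns `chrom`, `cen_start`, `cen_end` (1-based closed).
#'
#' @param path TSV file path.
#' @return centromere data frame.
#' @export
read_centromeres <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "cen_start", "cen_end"))
  df$chrom <- strip_chr(df$chrom)
  df
}

#' Write a merged-region table
#'
#' @param regions region data frame from [merge_records()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Assembles and validates the settings of one replication run: a single
#' overlap criterion shared by merging, consensus and every novelty
#' screen; the post-call filters; and an optional consensus requirement.
#'
#' @param criterion an [overlap_criterion()].
#' @param min_size_bp,min_probes,lbf_min optional filter settings
#'   (`NULL` disables a filter).
#' @param consensus_sources optional character vector of required
#'   algorithm labels; `NULL` skips consensus.
#' @param linkage merging linkage, `"span"` or `"member"`.
#' @param seed integer seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(criterion = overlap_criterion("any"),
                            min_size_bp = NULL, min_probes = NULL,
                            lbf_min = NULL, consensus_sources = NULL,
                            linkage = "span", seed = 1L) {
  stopifnot(inherits(criterion, "overlap_criterion"))
  structure(list(criterion = criterion, min_size_bp = min_size_bp,
                 min_probes = min_probes, lbf_min = lbf_min,
                 consensus_sources = consensus_sources, linkage = linkage,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys: `criterion` (`any` / `pct_either` / `pct_both`),
#' `threshold`, `min_size_bp`, `min_probes`, `lbf_min`,
#' `consensus_sources` (list), `linkage`, `seed`.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    criterion = overlap_criterion(y$criterion %||% "any",
                                  y$threshold %||% 0.40),
    min_size_bp = y$min_size_bp, min_probes = y$min_probes,
    lbf_min = y$lbf_min,
    consensus_sources = unlist(y$consensus_sources),
    linkage = y$linkage %||% "span",
    seed = y$seed %||% 1L)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one replication pipeline end to end
#'
#' Applies the configured post-call filters, optionally intersects the
#' required sources into consensus calls, runs the four-stage novelty
#' flow, and writes summary tables, per-call fates and a JSON run
#' manifest (config hash, seed, per-stage counts, output checksums) into
#' `out_dir`. Rerunning with identical inputs and config reproduces
#' byte-identical outputs.
#'
#' @param calls study call data frame (or TSV path).
#' @param normals_db,scz_db preprocessed reference tables (or TSV paths;
#'   preprocessing via [preprocess_ref_table()] is applied when
#'   `preprocess = TRUE`).
#' @param roster subject roster data frame (or TSV path with columns
#'   `subject_id`, `cohort`).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param centromeres optional centromere table; spanning calls are split
#'   before filtering.
#' @param preprocess apply [preprocess_ref_table()] to the reference
#'   tables.
#' @return the run manifest (list), invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(calls, normals_db, scz_db, roster, config,
                         out_dir, centromeres = NULL, preprocess = TRUE) {
  if (is.character(calls)) calls <- read_calls(calls)
  if (is.character(normals_db)) normals_db <- read_ref_db(normals_db)
  if (is.character(scz_db)) scz_db <- read_ref_db(scz_db)
  if (is.character(roster))
    roster <- read_tsv_checked(roster, c("subject_id", "cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- as_cnv_calls(calls)
  log_n <- function(stage, n) message(sprintf("[%s] %d calls", stage, n))
  counts <- list(input = nrow(calls))
  log_n("input", nrow(calls))

  if (!is.null(centromeres)) {
    calls <- split_at_centromere(calls, centromeres)
    counts$centromere_split <- nrow(calls)
    log_n("centromere_split", nrow(calls))
  }
  if (!is.null(config$min_size_bp)) {
    calls <- filter_min_size(calls, config$min_size_bp)
    counts$min_size <- nrow(calls)
    log_n("min_size", nrow(calls))
  }
  if (!is.null(config$min_probes)) {
    calls <- filter_min_probes(calls, config$min_probes)
    counts$min_probes <- nrow(calls)
    log_n("min_probes", nrow(calls))
  }
  if (!is.null(config$lbf_min)) {
    calls <- filter_confidence(calls, config$lbf_min)
    counts$confidence <- nrow(calls)
    log_n("confidence", nrow(calls))
  }
  if (!is.null(config$consensus_sources)) {
    calls <- consensus_calls(calls, config$consensus_sources,
                             config$criterion)
    counts$consensus <- nrow(calls)
    log_n("consensus", nrow(calls))
  }

  if (preprocess) {
    normals_db <- preprocess_ref_table(normals_db)
    scz_db <- preprocess_ref_table(scz_db)
  }
  report <- run_novelty_flow(calls, normals_db, scz_db, config$criterion,
                             linkage = config$linkage)

  tab2 <- count_table(calls)
  tab3 <- size_stats(calls)
  tab4 <- per_subject_stats(calls, roster)

  paths <- c(filtered_calls = "filtered_calls.tsv",
             merged_normals = "merged_normals.tsv",
             novelty_fates = "novelty_fates.tsv",
             counts_by_class = "counts_by_class.tsv",
             size_stats_kb = "size_stats_kb.tsv",
             per_subject = "per_subject.tsv")
  paths <- vapply(paths, function(p) file.path(out_dir, p), character(1))
  write_calls(calls, paths["filtered_calls"])
  write_regions(report$merged_normals, paths["merged_normals"])
  utils::write.table(report$fates, paths["novelty_fates"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(row = rownames(tab2), tab2),
                     paths["counts_by_class"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cbind(row = rownames(tab3), tab3),
                     paths["size_stats_kb"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cbind(row = rownames(tab4$stats), tab4$stats),
                     paths["per_subject"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cfg_plain <- unclass(config)
  cfg_plain$criterion <- unclass(cfg_plain$criterion)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE,
                               null = "null", digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    config = jsonlite::fromJSON(cfg_json),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed,
    filter_counts = counts,
    novelty_stage_counts = report$stage_counts,
    zero_cnv_subjects = as.list(tab4$zero_by_cohort),
    output_md5 = as.list(tools::md5sum(unname(paths))))
  unlink(tmp)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
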