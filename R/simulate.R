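# Seed-deterministic synthetic data: a CNV-enriched autosomal SNP-array
# marker map, per-subject LRR/BAF tracks with implanted loss/gain events,
# discordant pseudo-algorithm call sets, literature-style reference
# databases and a subject roster. Every generator is a pure function of
# (config, seed): the caller's RNG state is saved and restored.

# run code under a fixed seed without disturbing the session RNG
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# hg18 autosome lengths (bp) - public reference constants
#' @keywords internal
HG18_AUTOSOMES <- c(
  `1` = 247249719, `2` = 242951149, `3` = 199501827, `4` = 191273063,
  `5` = 180857866, `6` = 170899992, `7` = 158821424, `8` = 146274826,
  `9` = 140273252, `10` = 135374737, `11` = 134452384, `12` = 132349534,
  `13` = 114142980, `14` = 106368585, `15` = 100338915, `16` = 88827254,
  `17` = 78774742, `18` = 76117153, `19` = 63811651, `20` = 62435964,
  `21` = 46944323, `22` = 49691432)

#' Synthetic centromere table
#'
#' A synthetic stand-in for a genome-browser centromere table: each
#' chromosome gets a centromere interval of `width` bp centred at
#' `frac` of its length. For real analyses, read actual coordinates with
#' [read_centromeres()].
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param frac position of the centromere midpoint as a fraction of the
#'   chromosome length.
#' @param width centromere width in bp.
#' @return data frame with columns `chrom`, `cen_start`, `cen_end`.
#' @export
default_centromeres <- function(chrom_lengths = HG18_AUTOSOMES,
                                frac = 0.4, width = 3e6) {
  mid <- round(chrom_lengths * frac)
  data.frame(chrom = names(chrom_lengths),
             cen_start = pmax(1, mid - round(width / 2)),
             cen_end = mid + round(width / 2),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The study conditions the generator emulates: a ~47K-marker autosomal
#' array (46,875 markers at the default, ~59 kb mean spacing, 69%
#' polymorphic), 48 cases and 48 controls, implanted CNVs with a
#' log-uniform size distribution, a copy-state LRR/BAF signal model, a
#' panel of discordant pseudo-algorithms, and literature-style reference
#' databases. All values are overridable; tests and examples typically
#' restrict `chroms` and subject counts to keep problem sizes small.
#'
#' @param n_cases,n_controls subjects per cohort.
#' @param chroms chromosomes to simulate (subset of `"1".."22"`).
#' @param n_markers total markers across the selected chromosomes
#'   (allocated proportionally to length; the default over all 22
#'   autosomes reproduces the ~59 kb mean spacing).
#' @param frac_polymorphic fraction of markers that are polymorphic SNPs
#'   (the rest are intensity-only, genotype `"NP"`).
#' @param cnv_rate expected implanted CNVs per subject (Poisson).
#' @param size_range_kb CNV size range in kb; sizes are log-uniform.
#' @param p_gain probability an implanted event is a gain (losses are
#'   twice as common at the default, matching the loss-skew of array
#'   call sets).
#' @param p_homo_loss probability a loss is a homozygous (two-copy)
#'   deletion rather than hemizygous.
#' @param min_event_probes implanted events must cover at least this many
#'   markers (redrawn otherwise).
#' @param lrr_means named vector of LRR state means (neutral, hemizygous
#'   deletion, homozygous deletion, gain).
#' @param lrr_sd,baf_sd Gaussian noise SDs for LRR and BAF.
#' @param panel data frame describing the pseudo-algorithm panel:
#'   columns `source`, `sensitivity`, `fp_rate` (expected false calls per
#'   subject), `jitter_sd` (boundary jitter in probes).
#' @param refdb list of reference-database settings: `n_normal_bg` /
#'   `n_scz_bg` background records, `overlap_frac_normal` /
#'   `overlap_frac_scz` fractions of truth events covered by records,
#'   `p_both` fraction of records typed `"both"`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 48, n_controls = 48,
                       chroms = names(HG18_AUTOSOMES),
                       n_markers = 46875,
                       frac_polymorphic = 0.69,
                       cnv_rate = 10,
                       size_range_kb = c(5, 500),
                       p_gain = 1 / 3,
                       p_homo_loss = 0.5,
                       min_event_probes = 3,
                       lrr_means = c(neutral = 0, hemi_del = -0.5,
                                     homo_del = -2.0, gain = 0.35),
                       lrr_sd = 0.2,
                       baf_sd = 0.03,
                       panel = data.frame(
                         source = c("alphahmm", "betapart", "gammacnv",
                                    "deltasnp"),
                         sensitivity = c(0.95, 0.90, 0.85, 0.80),
                         fp_rate = c(2, 1, 1, 0.5),
                         jitter_sd = c(0, 1, 1, 2),
                         stringsAsFactors = FALSE),
                       refdb = list(n_normal_bg = 300, n_scz_bg = 50,
                                    overlap_frac_normal = 0.5,
                                    overlap_frac_scz = 0.3,
                                    p_both = 0.1)) {
  stopifnot(all(chroms %in% names(HG18_AUTOSOMES)),
            frac_polymorphic >= 0, frac_polymorphic <= 1,
            p_gain >= 0, p_gain <= 1,
            all(panel$sensitivity >= 0 & panel$sensitivity <= 1))
  cfg <- as.list(environment())
  cfg$chrom_lengths <- HG18_AUTOSOMES[chroms]
  structure(cfg, class = "sim_config")
}

# shared marker map: uniform positions per chromosome (spacings are then
# exponential with mean length / (n + 1), ~59 kb at the default scale)
#' @keywords internal
make_marker_map <- function(config) {
  lens <- config$chrom_lengths
  n_per <- round(config$n_markers * lens / sum(lens))
  out <- lapply(names(lens), function(ch) {
    n <- max(n_per[[ch]], 2L)
    pos <- sort(sample.int(lens[[ch]], n))
    data.frame(chrom = ch, pos = pos,
               polymorphic = stats::runif(n) < config$frac_polymorphic,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, out)
  map$marker_id <- sprintf("m%06d", seq_len(nrow(map)))
  rownames(map) <- NULL
  map[, c("marker_id", "chrom", "pos", "polymorphic")]
}

#' @keywords internal
roster_ids <- function(config) {
  data.frame(
    subject_id = c(sprintf("case%03d", seq_len(config$n_cases)),
                   sprintf("ctrl%03d", seq_len(config$n_controls))),
    cohort = rep(c("case", "control"),
                 c(config$n_cases, config$n_controls)),
    stringsAsFactors = FALSE)
}

#' Subject roster for a simulation
#'
#' @param config a [sim_config()].
#' @return data frame with columns `subject_id`, `cohort`.
#' @export
simulate_roster <- function(config = sim_config()) roster_ids(config)

# random truth events for one subject, non-overlapping, >= min probes
#' @keywords internal
draw_truth_subject <- function(sid, cohort, config, map) {
  n_ev <- stats::rpois(1, config$cnv_rate)
  if (n_ev == 0) return(NULL)
  lens <- config$chrom_lengths
  rows <- list()
  tries <- 0
  while (length(rows) < n_ev && tries < 50 * n_ev) {
    tries <- tries + 1
    ch <- sample(names(lens), 1, prob = lens / sum(lens))
    size <- round(exp(stats::runif(1, log(config$size_range_kb[1] * 1000),
                                   log(config$size_range_kb[2] * 1000))))
    if (size > lens[[ch]]) stop("CNV size exceeds chromosome length")
    start <- sample.int(lens[[ch]] - size + 1, 1)
    end <- start + size - 1
    probes <- which(map$chrom == ch & map$pos >= start & map$pos <= end)
    if (length(probes) < config$min_event_probes) next
    clash <- any(vapply(rows, function(r)
      r$chrom == ch && overlap_len(r$start, r$end, start, end) > 0,
      logical(1)))
    if (clash) next
    is_gain <- stats::runif(1) < config$p_gain
    state <- if (is_gain) "gain" else if (stats::runif(1) < config$p_homo_loss)
      "homo_del" else "hemi_del"
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sid, cohort = cohort, chrom = ch,
      start = start, end = end,
      type = if (is_gain) "gain" else "loss",
      copy_state = state,
      probe_first = probes[1], probe_last = probes[length(probes)],
      n_probes = length(probes), stringsAsFactors = FALSE)
  }
  if (!length(rows)) NULL else do.call(rbind, rows)
}

#' Draw implanted-CNV truth for a cohort
#'
#' Implants per-subject CNVs (count Poisson at `cnv_rate`, sizes
#' log-uniform, loss:gain per `p_gain`, losses split homozygous /
#' hemizygous), non-overlapping within subject, each covering at least
#' `min_event_probes` markers of `map`. Probe indices refer to rows of
#' `map`.
#'
#' @param config a [sim_config()].
#' @param map marker map (from [simulate_array()]; pass the same map the
#'   signals were built on).
#' @param seed integer seed.
#' @return truth data frame (possibly zero rows).
#' @export
simulate_truth <- function(config, map, seed) {
  if (config$size_range_kb[1] * 1000 > max(config$chrom_lengths))
    stop("configured CNV size exceeds every chromosome length")
  with_seed(seed, {
    roster <- roster_ids(config)
    out <- mapply(draw_truth_subject, roster$subject_id, roster$cohort,
                  MoreArgs = list(config = config, map = map),
                  SIMPLIFY = FALSE)
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) {
      return(data.frame(subject_id = character(), cohort = character(),
                        chrom = character(), start = numeric(),
                        end = numeric(), type = character(),
                        copy_state = character(), probe_first = integer(),
                        probe_last = integer(), n_probes = integer(),
                        stringsAsFactors = FALSE))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

# per-probe copy state labels for one subject given its truth rows
#' @keywords internal
probe_states <- function(map, truth_sub) {
  st <- rep("neutral", nrow(map))
  for (k in seq_len(NROW(truth_sub)))
    st[truth_sub$probe_first[k]:truth_sub$probe_last[k]] <-
      truth_sub$copy_state[k]
  st
}

#' Simulate a probe-signal array for a cohort
#'
#' Builds a shared marker map (uniform marker placement per chromosome,
#' giving near-exponential inter-marker gaps at the configured density)
#' and per-subject LRR/BAF/genotype tracks with implanted CNVs. LRR is
#' Gaussian around the copy-state mean. BAF for polymorphic markers
#' follows the state: heterozygotes at 0.5 (neutral), lost to homozygous
#' bands (hemizygous deletion), uniform noise (homozygous deletion,
#' genotype `"NC"`), or split to 1/3 and 2/3 (gain). Intensity-only
#' markers have genotype `"NP"` and `NA` BAF. Identical `(config, seed)`
#' give bit-identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param truth optional truth data frame to implant (as from
#'   [simulate_truth()], probe indices into this config's map); when
#'   `NULL`, truth is drawn from the config.
#' @return list with `map` (marker map), `truth`, `signals` (long data
#'   frame: `subject_id`, `cohort`, `marker_id`, `chrom`, `pos`, `lrr`,
#'   `baf`, `genotype`) and `roster`.
#' @export
simulate_array <- function(config = sim_config(), seed, truth = NULL) {
  stopifnot(!missing(seed))
  map <- with_seed(seed, make_marker_map(config))
  if (is.null(truth)) truth <- simulate_truth(config, map, seed + 1)
  roster <- roster_ids(config)

  signals <- with_seed(seed + 2, {
    per_subject <- lapply(seq_len(nrow(roster)), function(i) {
      sid <- roster$subject_id[i]
      st <- probe_states(map, truth[truth$subject_id == sid, , drop = FALSE])
      n <- nrow(map)
      lrr <- stats::rnorm(n, config$lrr_means[st], config$lrr_sd)
      geno <- rep("NP", n)
      baf <- rep(NA_real_, n)
      poly <- map$polymorphic
      # underlying diploid genotype at polymorphic markers
      g0 <- sample(c("AA", "AB", "BB"), n, replace = TRUE,
                   prob = c(0.25, 0.5, 0.25))
      noise <- stats::rnorm(n, 0, config$baf_sd)
      for (j in which(poly)) {
        s <- st[j]
        if (s == "homo_del") {
          geno[j] <- "NC"
          baf[j] <- stats::runif(1)
        } else if (s == "hemi_del") {
          g <- if (g0[j] == "AB") sample(c("AA", "BB"), 1) else g0[j]
          geno[j] <- g
          baf[j] <- (if (g == "AA") 0 else 1) + noise[j]
        } else if (s == "gain" && g0[j] == "AB") {
          geno[j] <- "AB"
          baf[j] <- sample(c(1 / 3, 2 / 3), 1) + noise[j]
        } else {
          geno[j] <- g0[j]
          baf[j] <- switch(g0[j], AA = 0, AB = 0.5, BB = 1) + noise[j]
        }
      }
      baf[poly] <- pmin(1, pmax(0, baf[poly]))
      data.frame(subject_id = sid, cohort = roster$cohort[i],
                 marker_id = map$marker_id, chrom = map$chrom,
                 pos = map$pos, lrr = lrr, baf = baf, genotype = geno,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_subject)
  })
  rownames(signals) <- NULL
  list(map = map, truth = truth, signals = signals, roster = roster)
}

#' Simulate discordant pseudo-algorithm call sets
#'
#' Each panel algorithm reports each truth event with its sensitivity,
#' with boundaries jittered by a per-algorithm SD in probes (clamped to
#' the chromosome's marker range), plus Poisson false-positive calls at
#' random probe runs. Types are preserved for true detections;
#' confidences are uniform on [5, 100] so a Log-Bayes-Factor filter at 30
#' bites.
#'
#' @param truth truth data frame (probe indices into `map`).
#' @param map marker map the truth was drawn on.
#' @param config a [sim_config()] (panel settings).
#' @param seed integer seed.
#' @return call data frame labelled by pseudo-algorithm `source`.
#' @export
simulate_callsets <- function(truth, map, config = sim_config(), seed) {
  stopifnot(!missing(seed))
  chrom_idx <- split(seq_len(nrow(map)), map$chrom)
  with_seed(seed, {
    out <- list()
    for (p in seq_len(nrow(config$panel))) {
      alg <- config$panel[p, ]
      # true detections
      for (k in seq_len(NROW(truth))) {
        if (stats::runif(1) > alg$sensitivity) next
        rng <- range(chrom_idx[[truth$chrom[k]]])
        f <- truth$probe_first[k] + round(stats::rnorm(1, 0, alg$jitter_sd))
        l <- truth$probe_last[k] + round(stats::rnorm(1, 0, alg$jitter_sd))
        f <- min(max(f, rng[1]), rng[2])
        l <- min(max(l, rng[1]), rng[2])
        if (f > l) { tmp <- f; f <- l; l <- tmp }
        out[[length(out) + 1L]] <- data.frame(
          subject_id = truth$subject_id[k], cohort = truth$cohort[k],
          chrom = truth$chrom[k], start = map$pos[f], end = map$pos[l],
          type = truth$type[k], n_probes = l - f + 1L,
          confidence = stats::runif(1, 5, 100), source = alg$source,
          stringsAsFactors = FALSE)
      }
      # false positives per subject
      roster <- roster_ids(config)
      for (i in seq_len(nrow(roster))) {
        n_fp <- stats::rpois(1, alg$fp_rate)
        for (fp in seq_len(n_fp)) {
          ch <- sample(names(chrom_idx), 1)
          idx <- chrom_idx[[ch]]
          f <- sample(idx, 1)
          l <- min(f + 2L + stats::rpois(1, 3), max(idx))
          out[[length(out) + 1L]] <- data.frame(
            subject_id = roster$subject_id[i], cohort = roster$cohort[i],
            chrom = ch, start = map$pos[f], end = map$pos[l],
            type = sample(c("loss", "gain"), 1), n_probes = l - f + 1L,
            confidence = stats::runif(1, 5, 100), source = alg$source,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(out)) return(empty_calls())
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res[order(res$source, res$subject_id, chrom_rank(res$chrom), res$start), ,
        drop = FALSE]
  })
}

# random background reference records
#' @keywords internal
draw_bg_records <- function(n, config, cohort, study, types) {
  if (n == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), type = character(),
                      cohort = character(), study = character(),
                      stringsAsFactors = FALSE))
  }
  lens <- config$chrom_lengths
  ch <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  size <- round(exp(stats::runif(n, log(config$size_range_kb[1] * 1000),
                                 log(config$size_range_kb[2] * 1000))))
  start <- vapply(seq_len(n),
                  function(i) sample.int(lens[[ch[i]]] - size[i] + 1, 1),
                  numeric(1))
  data.frame(chrom = ch, start = start, end = start + size - 1,
             type = sample(types, n, replace = TRUE),
             cohort = cohort, study = study, stringsAsFactors = FALSE)
}

#' Simulate literature-style reference databases
#'
#' Emits a "normals" and a disease ("scz") reference table. A configured
#' fraction of truth events is covered by a record with the event's exact
#' span (typed `"both"` with probability `p_both`, else the event's
#' type), so each covered event's fate in the novelty flow is known a
#' priori; the rest of each table is random background records. The scz
#' table covers only case-subject truth events.
#'
#' @param truth truth data frame.
#' @param config a [sim_config()] (refdb settings).
#' @param seed integer seed.
#' @return list with `normals` and `scz` reference data frames and
#'   `covered_normal` / `covered_scz` (row indices of `truth` covered by
#'   each table).
#' @export
simulate_ref_db <- function(truth, config = sim_config(), seed) {
  stopifnot(!missing(seed))
  rd <- config$refdb
  with_seed(seed, {
    cover <- function(rows, frac, cohort, study) {
      take <- rows[stats::runif(length(rows)) < frac]
      rec <- if (length(take)) data.frame(
        chrom = truth$chrom[take], start = truth$start[take],
        end = truth$end[take],
        type = ifelse(stats::runif(length(take)) < rd$p_both, "both",
                      truth$type[take]),
        cohort = cohort, study = study, stringsAsFactors = FALSE)
      else draw_bg_records(0, config, cohort, study, CNV_TYPES)
      list(rec = rec, idx = take)
    }
    cn <- cover(seq_len(NROW(truth)), rd$overlap_frac_normal, "normal",
                "litnorm")
    case_rows <- which(truth$cohort == "case")
    cs <- cover(case_rows, rd$overlap_frac_scz, "scz", "litscz")
    normals <- rbind(cn$rec,
                     draw_bg_records(rd$n_normal_bg, config, "normal",
                                     "litbg", CNV_TYPES))
    scz <- rbind(cs$rec,
                 draw_bg_records(rd$n_scz_bg, config, "scz", "litbgscz",
                                 c("loss", "gain")))
    normals$gain_count <- rep(NA_real_, nrow(normals))
    normals$loss_count <- rep(NA_real_, nrow(normals))
    scz$gain_count <- rep(NA_real_, nrow(scz))
    scz$loss_count <- rep(NA_real_, nrow(scz))
    rownames(normals) <- NULL; rownames(scz) <- NULL
    list(normals = normals, scz = scz,
         covered_normal = cn$idx, covered_scz = cs$idx)
  })
}
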