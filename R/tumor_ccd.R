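# Chromatin-compartment-dependent pathway activity in tumor genomes.
#
# Signature deletions: >5 bp deletions with >= 2 bp junctional microhomology
# are MMEJ-generated (MMEJ_sig); >5 bp deletions without microhomology are
# NHEJ-generated (NHEJ_sig); everything else (including 1 bp microhomology)
# is unclassified and never enters the counts. Deletions fully contained in a
# constitutive LAD (cLAD) are heterochromatic (Het), in a constitutive
# inter-LAD (ciLAD) euchromatic (Eu). Per gene of interest (GOI) and cancer
# subtype, case counts are compared with a bootstrap distribution of the
# control statistic; subtype z-scores are combined by Stouffer's method and
# BH-corrected across GOIs.

COMPARTMENT_CLASSES <- c("MMEJ_Het", "NHEJ_Het", "MMEJ_Eu", "NHEJ_Eu")

#' Junctional microhomology length of a deletion
#'
#' The microhomology is the longer of (a) the longest common prefix of the
#' deleted sequence and the downstream flank and (b) the longest common
#' suffix of the deleted sequence and the upstream flank, capped at the
#' deletion length. Coordinates are 0-based half-open.
#'
#' @param ref Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param chrom Chromosome name(s).
#' @param start,end Integer vectors, 0-based half-open deleted segment.
#' @return Integer vector of microhomology lengths.
#' @export
compute_microhomology <- function(ref, chrom, start, end) {
  if (methods::is(ref, "DNAStringSet")) {
    ref <- stats::setNames(as.character(ref), names(ref))
  }
  common_prefix <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    if (n == 0L) return(0L)
    ai <- utf8ToInt(substr(a, 1, n)); bi <- utf8ToInt(substr(b, 1, n))
    d <- which(ai != bi)
    if (length(d) == 0L) n else d[1] - 1L
  }
  mapply(function(ch, s, e) {
    if (!ch %in% names(ref)) {
      stop(sprintf("chromosome '%s' absent from reference", ch))
    }
    seqs <- ref[[ch]]
    len <- nchar(seqs)
    if (s < 0 || e > len || e <= s) {
      stop(sprintf("deletion [%d,%d) outside reference %s (length %d)", s, e, ch, len))
    }
    L <- e - s
    del <- substr(seqs, s + 1L, e)
    down <- substr(seqs, e + 1L, min(e + L, len))
    up <- substr(seqs, max(s - L, 0L) + 1L, s)
    m_right <- common_prefix(del, down)
    # suffix match = prefix match of the reversed strings
    rev1 <- function(x) intToUtf8(rev(utf8ToInt(x)))
    m_left <- common_prefix(rev1(del), rev1(up))
    min(max(m_right, m_left), L)
  }, chrom, start, end, USE.NAMES = FALSE)
}

#' Classify deletions into MMEJ/NHEJ signature classes
#'
#' @param length Deletion length(s) in bp (>= 1).
#' @param mh_len Junctional microhomology length(s) (>= 0).
#' @return Character vector: `MMEJ_sig` (length > 5 and mh >= 2), `NHEJ_sig`
#'   (length > 5 and mh = 0), otherwise `unclassified` (includes length <= 5
#'   and the 1 bp-microhomology case).
#' @export
classify_deletion <- function(length, mh_len) {
  stopifnot(all(length >= 1), all(mh_len >= 0))
  ifelse(length > 5 & mh_len >= 2, "MMEJ_sig",
         ifelse(length > 5 & mh_len == 0, "NHEJ_sig", "unclassified"))
}

#' Assign deletions to chromatin compartments
#'
#' `Het` when the deleted segment is fully contained in a cLAD, `Eu` when
#' fully contained in a ciLAD, `neither` otherwise (a deletion spanning a
#' compartment boundary is excluded from all counts).
#'
#' @param dels Deletion table (sample_id, chrom, start, end; 0-based
#'   half-open).
#' @param lads `GRanges` from [read_lads()], or a data.frame with chrom,
#'   start, end (0-based half-open) and lad_class.
#' @return Character vector (`Het`, `Eu`, `neither`) parallel to `dels` rows.
#' @export
assign_compartment <- function(dels, lads) {
  if (is.data.frame(lads)) {
    lads <- GenomicRanges::GRanges(lads$chrom,
                                   IRanges::IRanges(lads$start + 1L, lads$end),
                                   lad_class = lads$lad_class)
  }
  dgr <- GenomicRanges::GRanges(dels$chrom,
                                IRanges::IRanges(dels$start + 1L, dels$end))
  ov <- GenomicRanges::findOverlaps(dgr, lads, type = "within")
  comp <- rep("neither", nrow(dels))
  lab <- lads$lad_class[S4Vectors::subjectHits(ov)]
  comp[S4Vectors::queryHits(ov)] <- ifelse(lab == "cLAD", "Het", "Eu")
  comp
}

#' Annotate a deletion table with length, microhomology, class, compartment
#'
#' @param dels Deletion table (sample_id, chrom, start, end, optional mh_len).
#' @param lads LAD intervals (see [assign_compartment()]).
#' @param ref Reference sequences, required only when `mh_len` is absent.
#' @return The table with columns del_length, mh_len, class, compartment.
#' @export
annotate_deletions <- function(dels, lads, ref = NULL) {
  check_columns(dels, c("sample_id", "chrom", "start", "end"), "deletion table")
  dels$del_length <- dels$end - dels$start
  if (is.null(dels$mh_len)) {
    if (is.null(ref)) stop("mh_len absent: a reference sequence is required")
    dels$mh_len <- compute_microhomology(ref, dels$chrom, dels$start, dels$end)
  }
  dels$class <- classify_deletion(dels$del_length, dels$mh_len)
  dels$compartment <- assign_compartment(dels, lads)
  dels
}

#' Assign case/control roles for one gene of interest
#'
#' A sample is a case for `goi` when (I) it carries a LOF driver mutation in
#' exactly one of the genes of interest, namely `goi`; (II) it has no marker
#' of another DNA repair deficiency; (III) it shows no mutational signature of
#' previous mutagenic treatment; and (IV) it has at least `min_substitutions`
#' substitutions genome-wide. Controls satisfy II-IV and carry no driver in
#' any gene of interest.
#'
#' @param meta Sample metadata (see [read_tumor_meta()]).
#' @param goi Gene of interest.
#' @param min_substitutions Substitution floor (default 500).
#' @return `meta` with a `role` column (`case`, `control`, `excluded`).
#' @export
filter_samples <- function(meta, goi, min_substitutions = 500) {
  check_columns(meta, c("sample_id", "cancer_subtype", "dataset", "goi_drivers",
                        "other_repair_deficiency", "mutagenic_signature",
                        "n_substitutions"), "sample metadata")
  drv <- strsplit(ifelse(is.na(meta$goi_drivers), "", meta$goi_drivers), ",")
  drv <- lapply(drv, function(x) x[nzchar(x)])
  qc <- !meta$other_repair_deficiency & !meta$mutagenic_signature &
    meta$n_substitutions >= min_substitutions
  is_case <- qc & lengths(drv) == 1L &
    vapply(drv, function(x) length(x) == 1L && x == goi, logical(1))
  is_ctrl <- qc & lengths(drv) == 0L
  meta$role <- ifelse(is_case, "case", ifelse(is_ctrl, "control", "excluded"))
  meta
}

#' Genes of interest with enough mutant samples to analyze
#'
#' A gene is analyzed only with at least `min_cases` case samples overall of
#' which at least `min_subtype_cases` belong to the same cancer subtype.
#'
#' @param meta Sample metadata.
#' @param gois Character vector of candidate genes.
#' @param min_cases,min_subtype_cases Selection thresholds (defaults 5 and 3).
#' @return Character vector of selected genes.
#' @export
select_gois <- function(meta, gois, min_cases = 5, min_subtype_cases = 3) {
  keep <- vapply(gois, function(g) {
    m <- filter_samples(meta, g)
    cs <- m[m$role == "case", , drop = FALSE]
    nrow(cs) >= min_cases &&
      any(table(cs$cancer_subtype) >= min_subtype_cases)
  }, logical(1))
  gois[keep]
}

#' Per-sample signature-deletion counts by compartment
#'
#' @param dels Annotated deletion table ([annotate_deletions()]).
#' @param sample_ids Samples to include (rows are emitted even for samples
#'   without any classified deletion).
#' @return Integer matrix, rows = samples, columns `MMEJ_Het`, `NHEJ_Het`,
#'   `MMEJ_Eu`, `NHEJ_Eu`.
#' @export
sample_compartment_counts <- function(dels, sample_ids) {
  m <- matrix(0L, length(sample_ids), 4,
              dimnames = list(sample_ids, COMPARTMENT_CLASSES))
  d <- dels[dels$sample_id %in% sample_ids &
              dels$class %in% c("MMEJ_sig", "NHEJ_sig") &
              dels$compartment %in% c("Het", "Eu"), , drop = FALSE]
  if (nrow(d) > 0L) {
    col <- paste(sub("_sig", "", d$class), d$compartment, sep = "_")
    t <- table(factor(d$sample_id, levels = sample_ids),
               factor(col, levels = COMPARTMENT_CLASSES))
    m[] <- as.integer(t)
  }
  m
}

#' Aggregate compartment counts over a sample group
#'
#' Sums classified deletion counts over the member samples (the group sum of
#' per-sample counts), yielding the four totals MMEJ_Het, NHEJ_Het, MMEJ_Eu,
#' NHEJ_Eu.
#'
#' @param dels Annotated deletion table.
#' @param sample_ids Member samples of the group (cases or controls).
#' @return Named numeric vector of the four counts.
#' @export
aggregate_counts <- function(dels, sample_ids) {
  colSums(sample_compartment_counts(dels, sample_ids))
}

#' Het/Eu pathway-balance statistic
#'
#' log2(MMEJ_Het / NHEJ_Het) - log2(MMEJ_Eu / NHEJ_Eu). When any of the four
#' counts is zero, 0.5 is added to all four (continuity correction) and the
#' result is flagged via the `corrected` attribute.
#'
#' @param counts Named numeric vector with MMEJ_Het, NHEJ_Het, MMEJ_Eu,
#'   NHEJ_Eu.
#' @return The statistic (numeric scalar) with attribute `corrected`.
#' @export
het_eu_stat <- function(counts) {
  counts <- counts[COMPARTMENT_CLASSES]
  if (anyNA(counts)) stop("counts must contain MMEJ_Het, NHEJ_Het, MMEJ_Eu, NHEJ_Eu")
  if (all(counts == 0)) stop("all four compartment counts are zero; statistic undefined")
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  out <- log2(counts[["MMEJ_Het"]] / counts[["NHEJ_Het"]]) -
    log2(counts[["MMEJ_Eu"]] / counts[["NHEJ_Eu"]])
  attr(out, "corrected") <- corrected
  out
}

#' Bootstrap z-score of the case Het/Eu statistic against controls
#'
#' Each of the `n_boot` bootstrap draws resamples, with replacement from the
#' control set, the same number of samples as there are cases, and recomputes
#' the group-summed Het/Eu statistic. This emulates the sampling distribution
#' of a case-sized cohort under the control process, so the case statistic's
#' z-score against the mean and standard deviation of that distribution is
#' approximately standard normal under the null whenever the control set is
#' large relative to the case set.
#'
#' @param case_counts Per-sample count matrix of the cases
#'   ([sample_compartment_counts()]).
#' @param control_counts Per-sample count matrix of the controls (>= 5 rows).
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @return list with `delta_het_eu` (case statistic), `bootstrap_mean`,
#'   `bootstrap_sd`, `z_case`, `n_boot`, `seed`, `corrected` (continuity
#'   correction used for the case statistic).
#' @export
bootstrap_z <- function(case_counts, control_counts, n_boot = 1000, seed) {
  if (nrow(control_counts) < 5L) stop("at least 5 control samples are required")
  case_stat <- het_eu_stat(colSums(case_counts))
  n <- nrow(control_counts)
  n_draw <- nrow(case_counts)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n_draw, replace = TRUE)
      as.numeric(het_eu_stat(colSums(control_counts[idx, , drop = FALSE])))
    }, numeric(1))
  })
  s <- stats::sd(boot)
  if (!is.finite(s) || s == 0) stop("degenerate controls: bootstrap sd is 0")
  list(delta_het_eu = as.numeric(case_stat),
       bootstrap_mean = mean(boot), bootstrap_sd = s,
       z_case = (as.numeric(case_stat) - mean(boot)) / s,
       n_boot = n_boot, seed = seed,
       corrected = isTRUE(attr(case_stat, "corrected")))
}

#' Combine subtype z-scores with Stouffer's method
#'
#' Z = sum(z) / sqrt(k) over the k cancer subtypes, with a two-sided normal
#' p-value.
#'
#' @param z Numeric vector of per-subtype z-scores (k >= 1).
#' @return list with `Z`, `k`, `p`.
#' @export
stouffer <- function(z) {
  if (length(z) == 0L) stop("empty z-score list")
  Z <- sum(z) / sqrt(length(z))
  list(Z = Z, k = length(z), p = clamp_p(2 * stats::pnorm(-abs(Z))))
}

#' Full tumor CCD analysis across genes of interest
#'
#' For each selected gene of interest, assigns case/control roles, analyzes
#' each cancer-subtype/dataset stratum with enough cases and controls via
#' [bootstrap_z()], combines stratum z-scores per gene with [stouffer()], and
#' BH-corrects the combined p-values across genes. Datasets of the same
#' subtype are kept as separate strata.
#'
#' @param dels Annotated deletion table ([annotate_deletions()]).
#' @param meta Sample metadata.
#' @param gois Candidate genes of interest.
#' @param n_boot Bootstrap draws per stratum (default 1000).
#' @param seed Integer seed (stratum seeds are derived deterministically).
#' @param min_stratum_cases Minimum cases per analyzed stratum (default 3).
#' @param p_adj_threshold Significance threshold on the adjusted p (0.05).
#' @return list with `strata` (per-stratum data.frame: goi, stratum,
#'   delta_het_eu, bootstrap_mean, bootstrap_sd, z_case, corrected) and
#'   `gois` (per-gene data.frame: goi, k, Z, p, p_adj, significant).
#' @export
tumor_ccd_analysis <- function(dels, meta, gois, n_boot = 1000, seed,
                               min_stratum_cases = 3, p_adj_threshold = 0.05) {
  selected <- select_gois(meta, gois)
  strata_rows <- list()
  goi_rows <- list()
  seed_i <- 0L
  for (g in selected) {
    m <- filter_samples(meta, g)
    m$stratum <- paste(m$cancer_subtype, m$dataset, sep = "/")
    zs <- c()
    for (st in sort(unique(m$stratum[m$role == "case"]))) {
      cases <- m$sample_id[m$role == "case" & m$stratum == st]
      ctrls <- m$sample_id[m$role == "control" & m$stratum == st]
      if (length(cases) < min_stratum_cases || length(ctrls) < 5L) next
      cc <- sample_compartment_counts(dels, cases)
      kc <- sample_compartment_counts(dels, ctrls)
      seed_i <- seed_i + 1L
      bz <- bootstrap_z(cc, kc, n_boot = n_boot,
                        seed = (seed + seed_i) %% .Machine$integer.max)
      strata_rows[[length(strata_rows) + 1L]] <-
        data.frame(goi = g, stratum = st, n_cases = length(cases),
                   n_controls = length(ctrls),
                   delta_het_eu = bz$delta_het_eu,
                   bootstrap_mean = bz$bootstrap_mean,
                   bootstrap_sd = bz$bootstrap_sd, z_case = bz$z_case,
                   corrected = bz$corrected, stringsAsFactors = FALSE)
      zs <- c(zs, bz$z_case)
    }
    if (length(zs) > 0L) {
      st <- stouffer(zs)
      goi_rows[[length(goi_rows) + 1L]] <-
        data.frame(goi = g, k = st$k, Z = st$Z, p = st$p,
                   stringsAsFactors = FALSE)
    }
  }
  strata <- do.call(rbind, strata_rows) %||%
    data.frame(goi = character(0), stratum = character(0))
  gdf <- do.call(rbind, goi_rows)
  if (is.null(gdf)) {
    gdf <- data.frame(goi = character(0), k = integer(0), Z = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0))
  } else {
    gdf$p_adj <- benjamini_hochberg(gdf$p)
    gdf$significant <- gdf$p_adj < p_adj_threshold
  }
  list(strata = strata, gois = gdf)
}

#' Long microhomology-assisted deletions by compartment
#'
#' Counts deletions with >= 2 bp microhomology and size within
#' `[size_lo, size_hi]` (defaults 1.4 kb and 272.9 kb, the 95% size interval
#' of microhomology-assisted structural-variant deletions) that are fully
#' contained in a labeled compartment, per cohort, and compares the case
#' cohort's Het:Eu log2 count ratio with a bootstrap of the control cohort's
#' samples.
#'
#' @param svs Deletion/SV table with sample_id, chrom, start, end, mh_len and
#'   a `cohort` column naming each sample's cohort.
#' @param lads LAD intervals.
#' @param case_cohort,control_cohort Cohort labels to compare.
#' @param size_lo,size_hi Size window in bp.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @return list with `counts` (cohort x compartment), `log2_het_eu` per
#'   cohort, `z_case`, `bootstrap_mean`, `bootstrap_sd`.
#' @export
long_mh_deletions <- function(svs, lads, case_cohort, control_cohort,
                              size_lo = 1400, size_hi = 272900,
                              n_boot = 1000, seed) {
  check_columns(svs, c("sample_id", "chrom", "start", "end", "mh_len", "cohort"),
                "SV table")
  svs$del_length <- svs$end - svs$start
  keep <- svs$mh_len >= 2 & svs$del_length >= size_lo & svs$del_length <= size_hi
  svs <- svs[keep, , drop = FALSE]
  svs$compartment <- assign_compartment(svs, lads)
  svs <- svs[svs$compartment %in% c("Het", "Eu"), , drop = FALSE]

  per_sample <- function(cohort) {
    ids <- unique(svs$sample_id[svs$cohort == cohort])
    t <- table(factor(svs$sample_id[svs$cohort == cohort], levels = ids),
               factor(svs$compartment[svs$cohort == cohort],
                      levels = c("Het", "Eu")))
    matrix(as.integer(t), ncol = 2, dimnames = list(ids, c("Het", "Eu")))
  }
  log_ratio <- function(v) {
    if (all(v == 0)) stop("no long microhomology deletions in cohort")
    if (any(v == 0)) v <- v + 0.5
    log2(v[["Het"]] / v[["Eu"]])
  }
  case_m <- per_sample(case_cohort)
  ctrl_m <- per_sample(control_cohort)
  case_stat <- log_ratio(colSums(case_m))
  n <- nrow(ctrl_m)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      log_ratio(colSums(ctrl_m[sample.int(n, n, replace = TRUE), , drop = FALSE]))
    }, numeric(1))
  })
  s <- stats::sd(boot)
  if (!is.finite(s) || s == 0) stop("degenerate controls: bootstrap sd is 0")
  counts <- rbind(colSums(case_m), colSums(ctrl_m))
  rownames(counts) <- c(case_cohort, control_cohort)
  list(counts = counts,
       log2_het_eu = c(case = case_stat,
                       control = log_ratio(colSums(ctrl_m))),
       z_case = (case_stat - mean(boot)) / s,
       bootstrap_mean = mean(boot), bootstrap_sd = s)
}
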