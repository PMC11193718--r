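# Synthetic screens and tumor cohorts with planted ground truth.
#
# The screen generator emulates the study design: 19 barcoded reporters (IPRs)
# spread over four chromatin states, 25 correlated chromatin features, 519
# targeted proteins plus 33 mock controls, 3 replicates, overdispersed
# amplicon read depth, and per-IPR indel-class probabilities modulated by a
# planted global effect (gamma, log2 units) and planted per-feature synergies
# (beta, log2 units per feature sd). The tumor generator emulates an
# alternating cLAD/ciLAD genome with per-compartment MMEJ/NHEJ deletion rates
# and a multiplicative case effect.

# synthetic stand-in for the K562 chromatin feature panel: 25 features in the
# four major state blocks (euchromatin; H3K9me2/3 + late replication + LMNB1
# "triple" heterochromatin; H3K27me3 heterochromatin; other)
default_feature_panel <- function() {
  list(euchromatin = c("H3K4me1", "H3K4me2", "H3K4me3", "H3K27ac", "H3K9ac",
                       "H4K5acK8ac", "H2AFZ", "DNase_I", "TT_seq", "POL2",
                       "POL2AS2", "H3K36me3", "H3K79me2"),
       triple_heterochromatin = c("H3K9me2", "H3K9me3", "LMNB1",
                                  "late_replication"),
       H3K27me3_heterochromatin = c("H3K27me3", "EZH2"),
       other = c("CTCF", "SMC3", "HDAC1", "HDAC2", "HDAC3", "m5C"))
}

#' Simulate a chromatin feature matrix with state structure
#'
#' Each IPR is assigned one of four chromatin states; features belonging to a
#' state's defining block are positively correlated with each other (in-block
#' correlation about 0.8) and elevated on IPRs of that state. Columns are
#' standardized (population sd).
#'
#' @param n_ipr Number of IPRs (>= 6; default 19, the screen's reporter count).
#' @param seed Integer seed.
#' @param panel Named list of feature names per state block (default: a
#'   synthetic 25-feature panel).
#' @param block_cor In-block feature correlation (default 0.8).
#' @param state_shift Latent elevation of a block on IPRs of its state
#'   (default 1.5 latent sd).
#' @return list with `features` (standardized IPR x feature matrix),
#'   `ipr_states` (named character), `feature_states` (named character).
#' @export
sim_chromatin <- function(n_ipr = 19, seed, panel = default_feature_panel(),
                          block_cor = 0.8, state_shift = 1.5) {
  states <- names(panel)
  if (n_ipr < 6L) stop("n_ipr too small to populate all four chromatin states")
  with_seed(seed, {
    # deterministic near-even state assignment mirroring the design's spread
    ipr_states <- rep(states, length.out = n_ipr)
    ipr_states <- sample(ipr_states)      # shuffle which IPR gets which state
    barcodes <- sprintf("IPR%02d", seq_len(n_ipr))
    names(ipr_states) <- barcodes
    feats <- unlist(panel, use.names = FALSE)
    m <- matrix(NA_real_, n_ipr, length(feats),
                dimnames = list(barcodes, feats))
    for (b in states) {
      latent <- state_shift * (ipr_states == b) + stats::rnorm(n_ipr)
      for (f in panel[[b]]) {
        m[, f] <- sqrt(block_cor) * latent +
          sqrt(1 - block_cor) * stats::rnorm(n_ipr)
      }
    }
    features <- standardize_features(m)
    feature_states <- stats::setNames(
      rep(states, lengths(panel)), unlist(panel, use.names = FALSE))
    list(features = features, ipr_states = ipr_states,
         feature_states = feature_states)
  })
}

#' Simulate a knockout reporter screen with planted effects
#'
#' For each (protein, IPR, replicate) the total read count is negative
#' binomial (overdispersed amplicon depth); the MMEJ fraction among the two
#' signature classes is `plogis(baseline_logit + gamma + beta . features)`;
#' reads are split multinomially over the classes {-7, +1, other, intact}
#' with fixed other/intact fractions. Mock conditions have gamma = 0 and
#' beta = 0 by construction. The truth record stores, besides gamma and beta,
#' the implied marginal synergy vector `beta %*% C` (C = feature correlation
#' matrix of the simulated chromatin), which is what per-feature linear fits
#' estimate when features are correlated.
#'
#' @param chromatin Output of [sim_chromatin()].
#' @param n_proteins Number of targeted (non-mock) conditions (default 519).
#' @param n_mock Number of mock controls (default 33).
#' @param n_replicates Replicates (default 3).
#' @param reads_per_ipr Mean reads per (sample, IPR) (default 3000).
#' @param dispersion Negative-binomial dispersion (default 0.2; variance
#'   mu + dispersion * mu^2).
#' @param gamma Named numeric vector of planted global effects (log2 units);
#'   names must be protein ids (`KO001`, ...). Unnamed proteins get 0.
#' @param beta Named list of planted synergy coefficients per protein: each
#'   element a named numeric vector over features (log2 units per feature sd).
#' @param baseline_logit Baseline log2-odds of the MMEJ fraction in
#'   euchromatin (default -0.5), so gamma and beta act in log2 units.
#' @param het_shift Additive log2-odds shift on heterochromatic IPRs (default
#'   0.5; the MMEJ:NHEJ ratio runs higher in heterochromatin).
#' @param frac_other,frac_intact Fixed fractions of other indels and intact
#'   reads (defaults 0.2 and 0.3).
#' @param seed Integer seed.
#' @return list with `counts` (count table), `samples` (sample sheet),
#'   `truth` (gamma, beta matrix, synergy_truth matrix, baseline logits,
#'   parameters, seed).
#' @export
sim_screen <- function(chromatin, n_proteins = 519, n_mock = 33,
                       n_replicates = 3, reads_per_ipr = 3000,
                       dispersion = 0.2, gamma = NULL, beta = NULL,
                       baseline_logit = -0.5, het_shift = 0.5,
                       frac_other = 0.2, frac_intact = 0.3, seed) {
  stopifnot(frac_other >= 0, frac_intact >= 0, frac_other + frac_intact < 1)
  cfm <- chromatin$features
  n_ipr <- nrow(cfm)
  barcodes <- rownames(cfm)
  prots <- sprintf("KO%03d", seq_len(n_proteins))
  mocks <- sprintf("mock%02d", seq_len(n_mock))
  conds <- c(prots, mocks)

  gvec <- stats::setNames(rep(0, length(conds)), conds)
  if (!is.null(gamma)) {
    bad <- setdiff(names(gamma), prots)
    if (length(bad) > 0L) stop("gamma names must be targeted protein ids")
    gvec[names(gamma)] <- gamma
  }
  bmat <- matrix(0, length(conds), ncol(cfm),
                 dimnames = list(conds, colnames(cfm)))
  if (!is.null(beta)) {
    for (p in names(beta)) {
      if (!p %in% prots) stop("beta names must be targeted protein ids")
      b <- beta[[p]]
      if (is.null(names(b)) || !all(names(b) %in% colnames(cfm))) {
        stop("each beta element must be named by features")
      }
      bmat[p, names(b)] <- b
    }
  }
  het <- chromatin$ipr_states %in% c("triple_heterochromatin",
                                     "H3K27me3_heterochromatin")
  logit0 <- stats::setNames(baseline_logit + het_shift * het, barcodes)

  # marginal synergy truth: slope of delta on feature j is sum_k beta_k C_jk
  C <- stats::cor(cfm)
  synergy_truth <- bmat %*% C

  sig_frac <- 1 - frac_other - frac_intact
  with_seed(seed, {
    grid <- expand.grid(condition = conds, ipr_barcode = barcodes,
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    total <- stats::rnbinom(nrow(grid), mu = reads_per_ipr,
                            size = 1 / dispersion)
    lin <- logit0[grid$ipr_barcode] + gvec[grid$condition] +
      rowSums(bmat[grid$condition, , drop = FALSE] *
                cfm[grid$ipr_barcode, , drop = FALSE])
    # lin is on the log2-odds scale (gamma/beta in log2 units); plogis is
    # parameterized in natural log-odds
    p_mmej <- stats::plogis(as.numeric(lin) * log(2))
    probs <- cbind(`-7` = sig_frac * p_mmej, `1` = sig_frac * (1 - p_mmej),
                   `3` = frac_other, `0` = frac_intact)
    cls <- c(-7L, 1L, 3L, 0L)   # "other" indels rendered as +3
    counts_mat <- matrix(0L, nrow(grid), 4)
    for (i in seq_len(nrow(grid))) {
      if (total[i] > 0) {
        counts_mat[i, ] <- stats::rmultinom(1, total[i], probs[i, ])
      }
    }
    sample_id <- paste(grid$condition, grid$replicate, sep = "_R")
    counts <- data.frame(sample_id = rep(sample_id, 4),
                         ipr_barcode = rep(grid$ipr_barcode, 4),
                         indel_size = rep(cls, each = nrow(grid)),
                         count = as.integer(counts_mat),
                         stringsAsFactors = FALSE)
    counts <- counts[counts$count > 0, , drop = FALSE]
    counts <- counts[order(counts$sample_id, counts$ipr_barcode,
                           counts$indel_size), , drop = FALSE]
    rownames(counts) <- NULL
    skey <- !duplicated(sample_id)
    samples <- data.frame(sample_id = sample_id[skey],
                          condition = grid$condition[skey],
                          replicate = grid$replicate[skey],
                          stringsAsFactors = FALSE)
    list(counts = counts, samples = samples,
         truth = list(gamma = gvec, beta = bmat,
                      synergy_truth = synergy_truth,
                      baseline_logit = logit0, mock_ids = mocks,
                      n_replicates = n_replicates,
                      reads_per_ipr = reads_per_ipr,
                      dispersion = dispersion, seed = seed))
  })
}

#' Render an indel spectrum as error-free FASTQ reads
#'
#' Each counted indel class is rendered as the corresponding edit of the
#' reporter's break-site window (insertions add `A` bases at the window
#' center; deletions remove bases from the center), so [call_indels()]
#' recovers the spectrum exactly.
#'
#' @param counts Count table (sample_id, ipr_barcode, indel_size, count); the
#'   barcodes are used verbatim as reporter barcodes.
#' @param ref A [reporter_reference()] with a `gap_sequence`.
#' @param path Optional FASTQ output path (written when given).
#' @param seed Optional seed used to shuffle read order.
#' @return Character vector of read sequences (named), invisibly when `path`
#'   is given.
#' @export
sim_reads <- function(counts, ref, path = NULL, seed = NULL) {
  stopifnot(inherits(ref, "reporter_reference"))
  if (is.null(ref$gap_sequence)) stop("reporter_reference needs a gap_sequence")
  gap <- ref$gap_sequence
  eg <- nchar(gap)
  render <- function(size) {
    if (size < 0 && -size > eg) {
      stop(sprintf("deletion of %d nt exceeds the %d nt break-site window",
                   -size, eg))
    }
    mid <- eg %/% 2L
    if (size == 0) gap
    else if (size > 0) paste0(substr(gap, 1, mid), strrep("A", size),
                              substr(gap, mid + 1, eg))
    else paste0(substr(gap, 1, mid - (-size) %/% 2),
                substr(gap, mid - (-size) %/% 2 + (-size) + 1, eg))
  }
  if (nrow(counts) == 0L) {
    reads <- character(0)
  } else {
    reads <- rep(paste0(ref$upstream_anchor, counts$ipr_barcode,
                        ref$left_anchor,
                        vapply(counts$indel_size, render, character(1)),
                        ref$right_anchor),
                 counts$count)
  }
  if (!is.null(seed) && length(reads) > 1L) {
    reads <- with_seed(seed, sample(reads))
  }
  if (length(reads) > 0L) {
    names(reads) <- sprintf("read%06d", seq_along(reads))
  }
  if (!is.null(path)) {
    dss <- Biostrings::DNAStringSet(reads)
    Biostrings::writeXStringSet(dss, path, format = "fastq")
    return(invisible(reads))
  }
  reads
}

#' Simulate a tumor cohort with planted compartment effects
#'
#' The genome model is a single synthetic chromosome of alternating cLAD and
#' ciLAD intervals. Per sample and compartment, MMEJ- and NHEJ-signature
#' deletion counts are Poisson with the stated control rates; case samples
#' multiply selected rates by `case_effect`. MMEJ-class deletions get
#' microhomology >= 2 and length > 5; NHEJ-class deletions microhomology 0
#' and length > 5; a background of short unclassifiable deletions is added.
#' Metadata satisfies the case/control filters by construction.
#'
#' @param n_cases,n_controls Cohort sizes (defaults 10 and 50, mirroring the
#'   typical design of few mutant samples against a far larger control set;
#'   the bootstrap z-score is calibrated when controls outnumber cases, see
#'   the methods vignette).
#' @param rates Named numeric vector of expected per-sample counts per
#'   compartment/class: MMEJ_Het, NHEJ_Het, MMEJ_Eu, NHEJ_Eu (defaults
#'   20, 10, 10, 20: the MMEJ:NHEJ ratio runs higher in heterochromatin).
#' @param case_effect Named numeric vector of multiplicative rate changes for
#'   cases, e.g. `c(MMEJ_Het = 0.5)`; default none.
#' @param goi Gene of interest carried by the cases (default "ATM").
#' @param n_subtypes Number of cancer subtypes to split the cohort into
#'   (default 2).
#' @param n_lad,lad_length Number and length (bp) of intervals per
#'   compartment class (defaults 10 and 1e6).
#' @param background_rate Expected short unclassifiable deletions per sample
#'   per compartment (default 5).
#' @param seed Integer seed.
#' @return list with `deletions` (table incl. mh_len), `meta`, `lads`
#'   (data.frame chrom/start/end/lad_class, 0-based half-open) and `truth`.
#' @export
sim_tumors <- function(n_cases = 10, n_controls = 50,
                       rates = c(MMEJ_Het = 20, NHEJ_Het = 10,
                                 MMEJ_Eu = 10, NHEJ_Eu = 20),
                       case_effect = NULL, goi = "ATM", n_subtypes = 2,
                       n_lad = 10, lad_length = 1e6,
                       background_rate = 5, seed) {
  if (lad_length <= 0 || n_lad < 1) stop("compartment intervals must have positive length")
  rates <- rates[COMPARTMENT_CLASSES]
  if (anyNA(rates)) stop("rates must name MMEJ_Het, NHEJ_Het, MMEJ_Eu, NHEJ_Eu")
  eff <- stats::setNames(rep(1, 4), COMPARTMENT_CLASSES)
  if (!is.null(case_effect)) eff[names(case_effect)] <- case_effect

  # alternating cLAD/ciLAD with a gap between consecutive intervals
  starts <- (seq_len(2 * n_lad) - 1) * (lad_length + 1000)
  lads <- data.frame(chrom = "chrS", start = starts,
                     end = starts + lad_length,
                     lad_class = rep(c("cLAD", "ciLAD"), n_lad),
                     stringsAsFactors = FALSE)

  ids <- c(sprintf("case%03d", seq_len(n_cases)),
           sprintf("ctrl%03d", seq_len(n_controls)))
  role <- rep(c("case", "control"), c(n_cases, n_controls))
  subtype <- paste0("subtype", rep_len(LETTERS[seq_len(n_subtypes)],
                                       n_cases + n_controls))
  meta <- data.frame(sample_id = ids, cancer_subtype = subtype,
                     dataset = "D1",
                     goi_drivers = ifelse(role == "case", goi, ""),
                     other_repair_deficiency = FALSE,
                     mutagenic_signature = FALSE,
                     n_substitutions = 1000L, stringsAsFactors = FALSE)

  with_seed(seed, {
    rows <- list()
    for (si in seq_along(ids)) {
      mult <- if (role[si] == "case") eff else stats::setNames(rep(1, 4),
                                                               COMPARTMENT_CLASSES)
      for (cls in COMPARTMENT_CLASSES) {
        comp <- if (grepl("Het", cls)) "cLAD" else "ciLAD"
        n_ev <- stats::rpois(1, rates[[cls]] * mult[[cls]])
        if (n_ev == 0) next
        iv <- lads[lads$lad_class == comp, , drop = FALSE]
        pick <- sample.int(nrow(iv), n_ev, replace = TRUE)
        len <- sample(6:30, n_ev, replace = TRUE)
        pos <- floor(stats::runif(n_ev) * (lad_length - max(len) - 1))
        mh <- if (startsWith(cls, "MMEJ")) sample(2:6, n_ev, replace = TRUE)
              else rep(0L, n_ev)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = ids[si], chrom = "chrS",
          start = iv$start[pick] + pos, end = iv$start[pick] + pos + len,
          mh_len = mh, stringsAsFactors = FALSE)
      }
      # short unclassifiable background
      for (comp in c("cLAD", "ciLAD")) {
        n_bg <- stats::rpois(1, background_rate)
        if (n_bg == 0) next
        iv <- lads[lads$lad_class == comp, , drop = FALSE]
        pick <- sample.int(nrow(iv), n_bg, replace = TRUE)
        len <- sample(1:5, n_bg, replace = TRUE)
        pos <- floor(stats::runif(n_bg) * (lad_length - 10))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = ids[si], chrom = "chrS",
          start = iv$start[pick] + pos, end = iv$start[pick] + pos + len,
          mh_len = sample(0:1, n_bg, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    dels <- do.call(rbind, rows)
    rownames(dels) <- NULL
    list(deletions = dels, meta = meta, lads = lads,
         truth = list(rates = rates, case_effect = eff, goi = goi,
                      n_cases = n_cases, n_controls = n_controls,
                      seed = seed))
  })
}
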