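# Chromatin context-dependency (CCD) detection.
#
# Three-step linear modeling per protein:
#   1. omnibus pre-filter: does the protein's delta vector deviate from the
#      per-IPR mock null at all? (sum of squared mock z-scores, chi-square
#      reference, lenient BH FDR <= 0.25)
#   2. principal component regression of the delta vector on the top
#      principal components of the chromatin feature matrix; the overall
#      model F-test p-value is the CCD p-value, BH-corrected across proteins
#      (significant CCD at FDR < 0.05)
#   3. for significant proteins, simple per-feature linear fits; the slope is
#      the synergy score (positive = N-synergy, negative = M-synergy) and
#      slopes with p >= 0.05 are stored as exact zeros.

#' Standardize a chromatin feature matrix across IPRs
#'
#' Each feature column is z-scored across IPRs, so a feature with values
#' (1, 2, 3) maps to (-1, 0, 1).
#'
#' @param raw Numeric matrix or data.frame, rows = IPRs (row names =
#'   barcodes), columns = features.
#' @return Standardized numeric matrix (each column mean 0, sd 1).
#' @export
standardize_features <- function(raw) {
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (nrow(m) < 3L) stop("at least 3 IPRs are required")
  if (anyNA(m)) stop("feature matrix contains missing values")
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (stats::sd(v) == 0) {
      stop(sprintf("feature '%s' has zero variance", colnames(m)[j] %||% j))
    }
    m[, j] <- zscore(v)
  }
  m
}

# number of PCs: smallest k explaining >= var_explained of variance,
# capped at n_ipr - 3 (prevents saturated fits) and at the matrix rank
choose_k <- function(pca, n_ipr, var_explained) {
  v <- pca$sdev^2
  v <- v[v > 1e-10]
  k <- which(cumsum(v) / sum(v) >= var_explained)[1]
  max(1L, min(k, n_ipr - 3L, length(v)))
}

#' Detect chromatin context-dependencies of screen proteins
#'
#' Runs the three-step linear modeling approach on a delta matrix and a
#' standardized chromatin feature matrix. Mock conditions are run through the
#' identical pipeline as negative controls and reported separately; they do
#' not enter the BH corrections for real proteins.
#'
#' @param dm A `bb_delta` from [delta_scores()].
#' @param cfm Standardized chromatin feature matrix
#'   ([standardize_features()]); row names must match IPR barcodes.
#' @param step1_fdr Lenient pre-filter FDR (default 0.25).
#' @param ccd_fdr_threshold CCD significance threshold on the step-2 FDR
#'   (default 0.05; 0.25 is used for low-power pooled reporter lines).
#' @param slope_p Per-feature significance cutoff in step 3 (default 0.05);
#'   non-significant synergy scores are stored as exact zeros.
#' @param var_explained Cumulative variance the principal components must
#'   reach (default 0.9).
#' @param min_shared_iprs Minimum IPRs shared between delta vector and
#'   feature matrix for a protein to be testable (default 6).
#' @return An object of class `bb_ccd`: list with
#'   \describe{
#'     \item{results}{per-protein data.frame: n_ipr, step1_p, step1_fdr,
#'       retained, ccd_p, ccd_fdr, significant, synergy_class.}
#'     \item{synergy}{matrix (significant proteins x features) of synergy
#'       scores with non-significant cells zeroed.}
#'     \item{slopes, intercepts, slope_p}{raw per-feature fits for all
#'       significant proteins (used by [estimate_feature_delta()]).}
#'     \item{mock_results}{the same statistics for mock conditions.}
#'     \item{k}{number of principal components used.}
#'   }
#' @export
ccd_test <- function(dm, cfm, step1_fdr = 0.25, ccd_fdr_threshold = 0.05,
                     slope_p = 0.05, var_explained = 0.9,
                     min_shared_iprs = 6) {
  stopifnot(inherits(dm, "bb_delta"))
  iprs <- intersect(colnames(dm$delta), rownames(cfm))
  if (length(iprs) < min_shared_iprs) {
    stop("too few IPRs shared between delta matrix and feature matrix")
  }
  delta <- dm$delta[, iprs, drop = FALSE]
  cfm <- cfm[iprs, , drop = FALSE]
  mock_rows <- rownames(delta) %in% dm$mock_ids
  if (sum(mock_rows) < 2L) stop("need >= 2 mock conditions")

  # per-IPR mock null
  mock_mean <- colMeans(delta[mock_rows, , drop = FALSE], na.rm = TRUE)
  mock_sd <- apply(delta[mock_rows, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(mock_sd)) || any(mock_sd == 0)) {
    stop("degenerate per-IPR mock null (zero or undefined sd)")
  }

  pca <- stats::prcomp(cfm, center = TRUE, scale. = FALSE)
  k <- choose_k(pca, length(iprs), var_explained)
  scores <- pca$x[, seq_len(k), drop = FALSE]

  one_protein <- function(p) {
    y <- delta[p, ]
    avail <- which(!is.na(y))
    out <- list(n_ipr = length(avail), step1_p = NA_real_, ccd_p = NA_real_,
                slopes = rep(NA_real_, ncol(cfm)),
                intercepts = rep(NA_real_, ncol(cfm)),
                slope_pv = rep(NA_real_, ncol(cfm)), skipped = FALSE)
    if (length(avail) < min_shared_iprs) {
      message(sprintf("protein %s: only %d IPRs shared, skipped", p, length(avail)))
      out$skipped <- TRUE
      return(out)
    }
    z <- (y[avail] - mock_mean[avail]) / mock_sd[avail]
    out$step1_p <- clamp_p(stats::pchisq(sum(z^2), df = length(avail),
                                         lower.tail = FALSE))
    fit <- stats::lm(y[avail] ~ scores[avail, , drop = FALSE])
    # summary.lm warns on essentially perfect fits; those are legitimate
    # degenerate inputs here (constant or noiseless delta vectors)
    fs <- suppressWarnings(summary(fit))$fstatistic
    out$ccd_p <- if (is.null(fs)) 1 else
      clamp_p(as.numeric(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)))
    for (j in seq_len(ncol(cfm))) {
      sfit <- stats::lm(y[avail] ~ cfm[avail, j])
      co <- suppressWarnings(summary(sfit))$coefficients
      out$intercepts[j] <- co[1, 1]
      if (nrow(co) > 1) {
        out$slopes[j] <- co[2, 1]
        out$slope_pv[j] <- co[2, 4]
      } else {             # constant feature over available IPRs
        out$slopes[j] <- 0
        out$slope_pv[j] <- 1
      }
    }
    out
  }

  prots <- rownames(delta)
  fits <- lapply(prots, one_protein)
  names(fits) <- prots

  build <- function(sel) {
    f <- fits[sel]
    res <- data.frame(protein = names(f),
                      n_ipr = vapply(f, `[[`, 0L, "n_ipr"),
                      step1_p = vapply(f, `[[`, 0, "step1_p"),
                      stringsAsFactors = FALSE)
    testable <- !vapply(f, `[[`, TRUE, "skipped")
    res$step1_fdr <- NA_real_
    if (any(testable)) {
      res$step1_fdr[testable] <- benjamini_hochberg(res$step1_p[testable])
    }
    res$retained <- testable & res$step1_fdr <= step1_fdr
    res$ccd_p <- NA_real_
    res$ccd_p[res$retained] <- vapply(f[res$retained], `[[`, 0, "ccd_p")
    res$ccd_fdr <- NA_real_
    if (any(res$retained)) {
      res$ccd_fdr[res$retained] <- benjamini_hochberg(res$ccd_p[res$retained])
    }
    res$significant <- !is.na(res$ccd_fdr) & res$ccd_fdr < ccd_fdr_threshold
    rownames(res) <- NULL
    res
  }

  res <- build(prots[!mock_rows])
  mock_res <- build(prots[mock_rows])

  sig <- res$protein[res$significant]
  nf <- ncol(cfm)
  synergy <- matrix(0, length(sig), nf, dimnames = list(sig, colnames(cfm)))
  slopes <- intercepts <- pv <- matrix(NA_real_, length(sig), nf,
                                       dimnames = list(sig, colnames(cfm)))
  for (p in sig) {
    f <- fits[[p]]
    slopes[p, ] <- f$slopes
    intercepts[p, ] <- f$intercepts
    pv[p, ] <- f$slope_pv
    keep <- f$slope_pv < slope_p
    synergy[p, keep] <- f$slopes[keep]
  }
  res$synergy_class <- NA_character_
  for (i in seq_len(nrow(res))) {
    if (res$significant[i]) {
      res$synergy_class[i] <- classify_synergy(synergy[res$protein[i], ])
    }
  }
  structure(list(results = res, mock_results = mock_res, synergy = synergy,
                 slopes = slopes, intercepts = intercepts, slope_p = pv,
                 k = k, features = colnames(cfm)),
            class = "bb_ccd")
}

#' @method print bb_ccd
#' @export
print.bb_ccd <- function(x, ...) {
  cat(sprintf("CCD analysis: %d proteins tested, %d significant (%d PCs); %d mock controls, %d significant\n",
              nrow(x$results), sum(x$results$significant), x$k,
              nrow(x$mock_results), sum(x$mock_results$significant)))
  invisible(x)
}

#' Classify a synergy-score vector as M-, N- or mixed synergy
#'
#' All significant (nonzero) scores negative is M-synergy (the protein favors
#' MMEJ where the features are high), all positive is N-synergy, both signs
#' is mixed, and no nonzero score is none.
#'
#' @param scores Numeric vector of (sparsified) synergy scores.
#' @return One of `"M"`, `"N"`, `"mixed"`, `"none"`.
#' @export
classify_synergy <- function(scores) {
  neg <- any(scores < 0)
  pos <- any(scores > 0)
  if (neg && pos) "mixed" else if (neg) "M" else if (pos) "N" else "none"
}

#' Cross-classify CCD and global-effect significance
#'
#' @param ccd A `bb_ccd` from [ccd_test()].
#' @param glob Global-effect results from [global_effect_test()].
#' @return data.frame with protein and `global_link` among
#'   `global_and_ccd`, `ccd_only`, `global_only`, `none`.
#' @export
ccd_vs_global <- function(ccd, glob) {
  stopifnot(inherits(ccd, "bb_ccd"))
  glob <- glob[!glob$is_mock, , drop = FALSE]
  prots <- union(ccd$results$protein, glob$protein)
  only <- setdiff(prots, intersect(ccd$results$protein, glob$protein))
  if (length(only) > 0L) {
    message(sprintf("%d protein(s) present in only one result set; labeled from available evidence",
                    length(only)))
  }
  ccd_sig <- stats::setNames(ccd$results$significant, ccd$results$protein)
  glob_sig <- stats::setNames(glob$direction != "none", glob$protein)
  cs <- ifelse(is.na(ccd_sig[prots]), FALSE, ccd_sig[prots])
  gs <- ifelse(is.na(glob_sig[prots]), FALSE, glob_sig[prots])
  lab <- ifelse(cs & gs, "global_and_ccd",
                ifelse(cs, "ccd_only", ifelse(gs, "global_only", "none")))
  data.frame(protein = prots, global_link = as.character(lab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimated delta log2 MMEJ:NHEJ at a given chromatin feature level
#'
#' Evaluates the step-3 per-feature linear fit, intercept + slope x level,
#' at `level_z` standard deviations above the mean feature level (default +1).
#'
#' @param ccd A `bb_ccd` from [ccd_test()].
#' @param protein Protein id (must be CCD-significant).
#' @param feature Feature name.
#' @param level_z Feature level in z-score units (default 1).
#' @return Estimated delta log2 MMEJ:NHEJ (numeric).
#' @export
estimate_feature_delta <- function(ccd, protein, feature, level_z = 1) {
  stopifnot(inherits(ccd, "bb_ccd"))
  if (!protein %in% rownames(ccd$slopes)) {
    stop(sprintf("no stored fits for protein '%s' (not CCD-significant?)", protein))
  }
  if (!feature %in% colnames(ccd$slopes)) {
    stop(sprintf("unknown feature '%s'", feature))
  }
  ccd$intercepts[protein, feature] + ccd$slopes[protein, feature] * level_z
}

#' Hierarchical clustering of protein synergy vectors
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the rows
#' of a synergy matrix; rows are pre-sorted by protein name so the leaf order
#' is deterministic.
#'
#' @param sm Synergy matrix (proteins x features).
#' @param k Optional number of clusters to cut into.
#' @return list with `hclust`, `order` (protein names in leaf order) and
#'   `clusters` (named integer vector when `k` is given).
#' @export
cluster_synergies <- function(sm, k = NULL) {
  if (nrow(sm) < 2L) stop("at least 2 proteins are required")
  sm <- sm[order(rownames(sm)), , drop = FALSE]
  h <- stats::hclust(stats::dist(sm, method = "euclidean"), method = "average")
  out <- list(hclust = h, order = rownames(sm)[h$order], clusters = NULL)
  if (!is.null(k)) out$clusters <- stats::cutree(h, k = k)
  out
}
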