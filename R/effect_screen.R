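# Screen-level effect statistics: delta log2 MMEJ:NHEJ scores relative to
# mock knockout controls, a z-test for per-protein global effects against the
# empirical mock null, a t-test variant for inhibitor experiments, and
# Benjamini-Hochberg correction.

#' Compute delta log2 MMEJ:NHEJ scores relative to mock controls
#'
#' For every replicate and IPR, the mock mean of log2 MMEJ:NHEJ is taken over
#' the mock control samples of that replicate; each sample's deviation from
#' this mean is the per-replicate delta, and the reported value is the
#' unweighted mean over replicates. Mock conditions are retained (their delta
#' is computed against the same mock mean, so per IPR the mock deltas
#' average to zero).
#'
#' @param balance Balance table from [compute_balance()] (rows with `NA`
#'   balance are ignored), or the output of [filter_iprs()].
#' @param samples Sample sheet (sample_id, condition, replicate).
#' @param mock_ids Character vector of mock condition ids (>= 2).
#' @return An object of class `bb_delta`: list with `delta` (condition x IPR
#'   matrix, `NA` for missing cells), `support` (replicates contributing per
#'   cell) and `mock_ids`.
#' @export
delta_scores <- function(balance, samples, mock_ids) {
  check_columns(samples, c("sample_id", "condition", "replicate"),
                "sample sheet")
  if (length(mock_ids) < 2L) stop("at least 2 mock conditions are required")
  b <- balance[!is.na(balance$log2_mmej_nhej), , drop = FALSE]
  idx <- match(b$sample_id, samples$sample_id)
  if (anyNA(idx)) stop("balance table contains samples absent from the sample sheet")
  b$condition <- samples$condition[idx]
  b$replicate <- samples$replicate[idx]
  if (!any(b$condition %in% mock_ids)) stop("no mock samples found in balance data")

  conds <- sort(unique(b$condition))
  iprs <- sort(unique(b$ipr_barcode))
  reps <- sort(unique(b$replicate))

  delta_sum <- matrix(0, length(conds), length(iprs),
                      dimnames = list(conds, iprs))
  support <- matrix(0L, length(conds), length(iprs),
                    dimnames = list(conds, iprs))
  for (r in reps) {
    br <- b[b$replicate == r, , drop = FALSE]
    mock <- br[br$condition %in% mock_ids, , drop = FALSE]
    mock_mean <- tapply(mock$log2_mmej_nhej, mock$ipr_barcode, mean)
    mm <- mock_mean[br$ipr_barcode]
    ok <- !is.na(mm)
    if (any(!ok)) {
      message(sprintf("replicate %s: %d cell(s) lack mock coverage and are skipped",
                      as.character(r), sum(!ok)))
    }
    br <- br[ok, , drop = FALSE]
    d <- br$log2_mmej_nhej - as.numeric(mm[ok])
    ij <- cbind(match(br$condition, conds), match(br$ipr_barcode, iprs))
    delta_sum[ij] <- delta_sum[ij] + d
    support[ij] <- support[ij] + 1L
  }
  delta <- delta_sum / support
  delta[support == 0L] <- NA_real_
  structure(list(delta = delta, support = support,
                 mock_ids = intersect(mock_ids, conds)),
            class = "bb_delta")
}

#' @method print bb_delta
#' @export
print.bb_delta <- function(x, ...) {
  cat(sprintf("delta log2 MMEJ:NHEJ matrix: %d conditions (%d mock) x %d IPRs; %d missing cells\n",
              nrow(x$delta), length(x$mock_ids), ncol(x$delta),
              sum(is.na(x$delta))))
  invisible(x)
}

#' Test per-protein global effects on pathway balance (z-test)
#'
#' The global score of a condition is the mean delta over its available IPRs.
#' Each non-mock condition is z-scored against the empirical mean and sample
#' standard deviation of the mock global scores, converted to a two-sided
#' normal p-value, and corrected by Benjamini-Hochberg across non-mock
#' conditions. A knockout that lowers the MMEJ:NHEJ ratio (negative score)
#' marks a protein that favors MMEJ.
#'
#' @param dm A `bb_delta` from [delta_scores()].
#' @param fdr_threshold FDR below which a direction is assigned (default
#'   0.001, the screen's global-effect cutoff).
#' @return data.frame with columns protein, global_score, z, p, fdr,
#'   direction (`favors_MMEJ`, `favors_NHEJ`, `none`) and is_mock; mock rows
#'   carry z/p but no fdr or direction.
#' @export
global_effect_test <- function(dm, fdr_threshold = 0.001) {
  stopifnot(inherits(dm, "bb_delta"))
  g <- rowMeans(dm$delta, na.rm = TRUE)
  mock_g <- g[rownames(dm$delta) %in% dm$mock_ids]
  if (length(mock_g) < 2L) stop("need >= 2 mock conditions with global scores")
  m0 <- mean(mock_g)
  s0 <- stats::sd(mock_g)
  if (!is.finite(s0) || s0 == 0) stop("degenerate mock null: sd of mock global scores is 0")
  res <- data.frame(protein = names(g), global_score = as.numeric(g),
                    stringsAsFactors = FALSE)
  res$is_mock <- res$protein %in% dm$mock_ids
  res$z <- (res$global_score - m0) / s0
  res$p <- clamp_p(2 * stats::pnorm(-abs(res$z)))
  res$fdr <- NA_real_
  nm <- !res$is_mock
  res$fdr[nm] <- benjamini_hochberg(res$p[nm])
  res$direction <- "none"
  sig <- nm & !is.na(res$fdr) & res$fdr < fdr_threshold
  res$direction[sig & res$global_score < 0] <- "favors_MMEJ"
  res$direction[sig & res$global_score > 0] <- "favors_NHEJ"
  rownames(res) <- NULL
  res
}

#' Two-sample t-test for global effects (inhibitor design)
#'
#' Inhibitor experiments carry a single control sample per replicate, so the
#' mock-based z-test is replaced by a two-sided two-sample Student's t-test
#' (pooled variance) of per-replicate global scores.
#'
#' @param condition Numeric vector of per-replicate global scores (treated).
#' @param control Numeric vector of per-replicate control global scores.
#' @return list with `effect` (mean difference), `t`, `df`, `p` and
#'   `degenerate` (TRUE when both groups have zero variance; then p is 1 for
#'   a zero difference and 0 otherwise, flagged rather than crashing).
#' @export
global_effect_ttest <- function(condition, control) {
  if (length(condition) < 2L || length(control) < 2L) {
    stop("at least 2 replicates per group are required")
  }
  n1 <- length(condition); n2 <- length(control)
  d <- mean(condition) - mean(control)
  sp2 <- ((n1 - 1) * stats::var(condition) + (n2 - 1) * stats::var(control)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  if (se == 0) {
    tt <- if (d == 0) 0 else sign(d) * Inf
    return(list(effect = d, t = tt, df = df,
                p = if (d == 0) 1 else 0, degenerate = TRUE))
  }
  tt <- d / se
  list(effect = d, t = tt, df = df,
       p = 2 * stats::pt(-abs(tt), df), degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validating wrapper around the standard step-up procedure: adjusted values
#' are order-preserving and never smaller than the raw p-values.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
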