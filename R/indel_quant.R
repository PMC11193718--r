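# Indel quantification: turn amplicon reads (or pre-tabulated counts) into
# per-IPR indel spectra and log2 MMEJ:NHEJ balance values.
#
# Reads of a barcoded integrated pathway reporter (IPR) have the layout
#   [upstream_anchor][barcode][left_anchor][break-site window][right_anchor]...
# The indel size at the Cas9 break site is the observed spacing between the
# two break-site anchors minus the reference spacing. The +1 insertion is the
# NHEJ signature (NHEJ_ins) and the -7 deletion the MMEJ signature (MMEJ_del).

#' Describe a barcoded reporter amplicon
#'
#' @param upstream_anchor Constant sequence preceding the barcode (ACGT).
#' @param barcode_length Barcode length in nt (> 0).
#' @param left_anchor Constant sequence immediately 5' of the break-site window.
#' @param right_anchor Constant sequence immediately 3' of it.
#' @param reference_gap Reference distance (nt) between the two anchors.
#' @param dialect `"original"` or `"v2"`; the v2 reporter carries 8 extra nt
#'   of constant sequence, shifting reference coordinates by exactly 8.
#' @param gap_sequence Optional reference sequence of the break-site window
#'   (needed to simulate reads); its length must equal the effective gap.
#' @return An object of class `reporter_reference`.
#' @export
reporter_reference <- function(upstream_anchor, barcode_length, left_anchor,
                               right_anchor, reference_gap,
                               dialect = c("original", "v2"),
                               gap_sequence = NULL) {
  dialect <- match.arg(dialect)
  for (a in list(upstream_anchor, left_anchor, right_anchor)) {
    if (!is.character(a) || nchar(a) == 0L || grepl("[^ACGT]", a)) {
      stop("anchors must be nonempty uppercase ACGT strings")
    }
  }
  if (barcode_length <= 0) stop("barcode_length must be > 0")
  if (reference_gap < 0) stop("reference_gap must be >= 0")
  ref <- structure(list(upstream_anchor = upstream_anchor,
                        barcode_length = as.integer(barcode_length),
                        left_anchor = left_anchor,
                        right_anchor = right_anchor,
                        reference_gap = as.integer(reference_gap),
                        dialect = dialect,
                        gap_sequence = gap_sequence),
                   class = "reporter_reference")
  eg <- effective_gap(ref)
  if (!is.null(gap_sequence) && nchar(gap_sequence) != eg) {
    stop(sprintf("gap_sequence length (%d) must equal the effective gap (%d)",
                 nchar(gap_sequence), eg))
  }
  ref
}

# v2 reporters add 8 nt of constant region between the anchors
effective_gap <- function(ref) {
  ref$reference_gap + if (identical(ref$dialect, "v2")) 8L else 0L
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# match one barcode against the whitelist: exact, else unique <=1 mismatch;
# returns the matched barcode or NA (ambiguous or no match)
match_barcode <- function(bc, whitelist) {
  if (bc %in% whitelist) return(bc)
  if (nchar(bc) != nchar(whitelist[1])) return(NA_character_)
  d <- vapply(whitelist, hamming, integer(1), a = bc)
  hit <- which(d <= 1L)
  if (length(hit) == 1L) whitelist[hit] else NA_character_
}

#' Call indels from amplicon reads
#'
#' Assigns each read to a whitelisted barcode (exact match, or a unique match
#' with at most one mismatch) and scores the indel size as the observed
#' anchor spacing minus the reference spacing. Reads with an unmatched or
#' ambiguous barcode, a missing anchor, or anchors out of order are counted
#' as unassigned, never dropped silently.
#'
#' @param reads A FASTQ file path (plain or gzip) or a character vector of
#'   read sequences.
#' @param ref A [reporter_reference()].
#' @param barcode_whitelist Nonempty character vector of IPR barcodes.
#' @param sample_id Sample identifier for the output table.
#' @return A list with `counts` (count table: sample_id, ipr_barcode,
#'   indel_size, count) and `unassigned` (integer).
#' @export
call_indels <- function(reads, ref, barcode_whitelist, sample_id = "sample") {
  if (length(barcode_whitelist) == 0L) stop("barcode whitelist must be nonempty")
  stopifnot(inherits(ref, "reporter_reference"))
  if (length(reads) == 1L && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  eg <- effective_gap(ref)
  up <- ref$upstream_anchor
  bl <- ref$barcode_length
  score_read <- function(rd) {
    upos <- regexpr(up, rd, fixed = TRUE)[1]
    if (upos < 0L) return(NA_character_)
    bstart <- upos + nchar(up)
    bc <- substr(rd, bstart, bstart + bl - 1L)
    if (nchar(bc) < bl) return(NA_character_)
    bc <- match_barcode(bc, barcode_whitelist)
    if (is.na(bc)) return(NA_character_)
    rest <- substr(rd, bstart + bl, nchar(rd))
    lpos <- regexpr(ref$left_anchor, rest, fixed = TRUE)[1]
    if (lpos < 0L) return(NA_character_)
    after_left <- lpos + nchar(ref$left_anchor)
    rpos <- regexpr(ref$right_anchor, substr(rest, after_left, nchar(rest)),
                    fixed = TRUE)[1]
    if (rpos < 0L) return(NA_character_)
    observed <- rpos - 1L                       # bases between the anchors
    paste(bc, observed - eg, sep = "\r")
  }
  keys <- vapply(reads, score_read, character(1), USE.NAMES = FALSE)
  n_un <- sum(is.na(keys))
  keys <- keys[!is.na(keys)]
  if (length(keys) > 0L) {
    tab <- table(keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    counts <- data.frame(sample_id = sample_id,
                         ipr_barcode = vapply(parts, `[`, "", 1L),
                         indel_size = as.integer(vapply(parts, `[`, "", 2L)),
                         count = as.integer(tab),
                         stringsAsFactors = FALSE)
    counts <- validate_count_table(counts)
  } else {
    counts <- data.frame(sample_id = character(0), ipr_barcode = character(0),
                         indel_size = integer(0), count = integer(0))
  }
  list(counts = counts, unassigned = n_un)
}

#' Compute the log2 MMEJ:NHEJ balance per (sample, IPR)
#'
#' The balance is log2 of the ratio of the MMEJ signature deletion count
#' (indel size -7) to the NHEJ signature insertion count (+1). The balance
#' is only defined when both signature counts reach `min_reads_per_class`;
#' otherwise the IPR is excluded for that sample (balance `NA`). The default
#' threshold is 1; inhibitor experiments in pooled reporter lines use 40.
#'
#' @param counts Count table (sample_id, ipr_barcode, indel_size, count).
#' @param min_reads_per_class Minimum reads in each signature class (>= 1).
#' @return data.frame with one row per (sample, IPR): `mmej_reads`,
#'   `nhej_reads`, `total_reads`, `ipr_frequency` (fraction of the sample's
#'   assigned reads carried by the IPR) and `log2_mmej_nhej` (NA when
#'   undefined).
#' @export
compute_balance <- function(counts, min_reads_per_class = 1) {
  if (min_reads_per_class < 1) stop("min_reads_per_class must be >= 1")
  counts <- validate_count_table(counts)
  key <- paste(counts$sample_id, counts$ipr_barcode, sep = "\r")
  lv <- unique(key)
  total <- tapply(counts$count, key, sum)
  pick <- function(size) {
    out <- stats::setNames(rep(0, length(lv)), lv)
    x <- counts[counts$indel_size == size, , drop = FALSE]
    if (nrow(x) > 0) {
      out[paste(x$sample_id, x$ipr_barcode, sep = "\r")] <- x$count
    }
    out
  }
  first <- match(lv, key)
  res <- data.frame(sample_id = counts$sample_id[first],
                    ipr_barcode = counts$ipr_barcode[first],
                    stringsAsFactors = FALSE)
  res$mmej_reads <- as.numeric(pick(-7L)[lv])
  res$nhej_reads <- as.numeric(pick(1L)[lv])
  res$total_reads <- as.numeric(total[lv])
  sample_totals <- tapply(res$total_reads, res$sample_id, sum)
  res$ipr_frequency <- res$total_reads / as.numeric(sample_totals[res$sample_id])
  ok <- res$mmej_reads >= min_reads_per_class &
    res$nhej_reads >= min_reads_per_class
  res$log2_mmej_nhej <- ifelse(ok, log2(res$mmej_reads / res$nhej_reads), NA_real_)
  res <- res[order(res$sample_id, res$ipr_barcode), ]
  rownames(res) <- NULL
  res
}

#' Filter IPRs by within-sample frequency and replicate support
#'
#' IPRs with `ipr_frequency` below `freq_threshold` are dropped from that
#' sample; IPRs with a defined balance in fewer than `min_replicates`
#' replicates of a condition are dropped from that condition entirely.
#' Pooled reporter lines use frequency thresholds of 0.0025 (p53-null) and
#' 0.0075 (p53/BRCA1-null) with a three-replicate requirement.
#'
#' @param balance Balance table from [compute_balance()].
#' @param samples Sample sheet (sample_id, condition, replicate).
#' @param freq_threshold Frequency threshold in `[0, 1]`.
#' @param min_replicates Minimum replicates per (condition, IPR).
#' @return Filtered balance table (rows with undefined balance removed).
#' @export
filter_iprs <- function(balance, samples, freq_threshold = 0,
                        min_replicates = 1) {
  if (freq_threshold < 0 || freq_threshold > 1) {
    stop("freq_threshold must lie in [0, 1]")
  }
  check_columns(samples, c("sample_id", "condition", "replicate"),
                "sample sheet")
  b <- balance[!is.na(balance$log2_mmej_nhej) &
                 balance$ipr_frequency >= freq_threshold, , drop = FALSE]
  idx <- match(b$sample_id, samples$sample_id)
  if (anyNA(idx)) stop("balance table contains samples absent from the sample sheet")
  b$condition <- samples$condition[idx]
  b$replicate <- samples$replicate[idx]
  ck <- paste(b$condition, b$ipr_barcode, sep = "\r")
  nrep <- tapply(b$replicate, ck, function(r) length(unique(r)))
  keep <- as.numeric(nrep[ck]) >= min_replicates
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
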