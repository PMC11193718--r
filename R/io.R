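# Readers and writers for the plain-text formats the pipeline consumes:
# indel count tables, balance tables, sample sheets, chromatin feature
# matrices, delta matrices, interaction edge lists, LAD BED files and
# deletion tables (TSV or VCF).

#' Read an indel count table
#'
#' Reads a tab-delimited table with columns `sample_id`, `ipr_barcode`,
#' `indel_size`, `count`. Duplicate (sample, barcode, size) rows are summed.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` with columns `sample_id`, `ipr_barcode`,
#'   `indel_size` (signed integer; 0 = intact) and `count`.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "ipr_barcode", "indel_size", "count"),
                "count table")
  validate_count_table(df)
}

#' Validate (and normalize) an in-memory indel count table
#'
#' @param df A data.frame with the count-table columns.
#' @return The validated table with duplicate keys summed.
#' @export
validate_count_table <- function(df) {
  check_columns(df, c("sample_id", "ipr_barcode", "indel_size", "count"),
                "count table")
  bad_size <- which(df$indel_size != round(df$indel_size))
  if (length(bad_size) > 0L) {
    stop(sprintf("non-integer indel_size in row %d", bad_size[1]))
  }
  bad_count <- which(df$count < 0 | df$count != round(df$count))
  if (length(bad_count) > 0L) {
    stop(sprintf("negative or non-integer count in row %d", bad_count[1]))
  }
  agg <- stats::aggregate(count ~ sample_id + ipr_barcode + indel_size,
                          data = df, FUN = sum)
  agg <- agg[order(agg$sample_id, agg$ipr_barcode, agg$indel_size), ]
  rownames(agg) <- NULL
  agg[, c("sample_id", "ipr_barcode", "indel_size", "count")]
}

#' Write an indel count table
#'
#' @param df Count table as returned by [read_count_table()] or [call_indels()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(df, path) {
  check_columns(df, c("sample_id", "ipr_barcode", "indel_size", "count"),
                "count table")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `condition` (gene symbol, inhibitor or mock label),
#' `replicate`; optional `cell_line`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "condition", "replicate"), "sample sheet")
  df
}

#' Read a chromatin feature matrix (IPR x feature)
#'
#' First column (or row names) holds IPR barcodes; remaining columns are
#' numeric feature levels.
#'
#' @param path TSV path.
#' @return Numeric matrix, rows = IPR barcodes, columns = features.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  if (anyNA(m)) stop("feature matrix contains missing values")
  m
}

#' Read a delta matrix (condition x IPR) from TSV
#'
#' @param path TSV path; first column = condition id, header = IPR barcodes.
#' @return Numeric matrix.
#' @export
read_delta_matrix <- function(path) {
  read_feature_matrix(path)
}

#' Write a named numeric matrix as TSV with an id column
#' @param m Matrix with row names.
#' @param path Output path.
#' @param id_name Name for the row-name column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' BioGRID-style physical interaction pairs: columns `protein_a`,
#' `protein_b` and optionally `method` (detection system).
#'
#' @param path TSV path.
#' @param methods Optional character vector; keep only edges whose `method`
#'   is listed (e.g. the physical detection systems used for screen pairs).
#' @return data.frame with columns protein_a, protein_b, method.
#' @export
read_edge_list <- function(path, methods = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("protein_a", "protein_b"), "edge list")
  if (is.null(df$method)) df$method <- NA_character_
  if (!is.null(methods)) df <- df[df$method %in% methods, , drop = FALSE]
  df
}

#' Read cLAD/ciLAD intervals from a BED file
#'
#' The 4th BED column must label each interval `cLAD` (constitutive
#' lamina-associated domain, heterochromatin proxy) or `ciLAD` (constitutive
#' inter-LAD, euchromatin proxy).
#'
#' @param path BED path (0-based half-open, as standard).
#' @return A `GRanges` with a `lad_class` metadata column.
#' @export
read_lads <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file: ", conditionMessage(e)))
  labs <- gr$name
  bad <- which(!labs %in% c("cLAD", "ciLAD"))
  if (length(bad) > 0L) {
    stop(sprintf("BED line %d: label '%s' is not cLAD/ciLAD", bad[1], labs[bad[1]]))
  }
  gr$lad_class <- labs
  gr
}

#' Read a deletion table from TSV
#'
#' Columns: `sample_id`, `chrom`, `start`, `end` (0-based half-open genome
#' coordinates of the deleted segment); optional `mh_len` (junctional
#' microhomology, computed from a reference when absent).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_deletions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "chrom", "start", "end"), "deletion table")
  if (any(df$end <= df$start)) stop("deletion with end <= start")
  df
}

#' Read deletions from a VCF file
#'
#' Extracts deletion records (REF longer than ALT with a shared anchor base)
#' and converts the 1-based anchor convention to 0-based half-open
#' coordinates of the deleted segment.
#'
#' @param path VCF path (plain or gzip).
#' @param sample_id Sample identifier to assign to all records.
#' @return data.frame with sample_id, chrom, start, end.
#' @export
read_deletions_vcf <- function(path, sample_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  keep <- !is.na(alt) & nchar(ref) > nchar(alt) & nchar(alt) >= 1 &
    substr(ref, 1, nchar(alt)) == alt
  fix <- fix[keep, , drop = FALSE]
  pos <- as.integer(fix$POS)
  len <- nchar(fix$REF[seq_len(nrow(fix))]) - nchar(fix$ALT[seq_len(nrow(fix))])
  # deleted bases occupy [POS+1, POS+len] in 1-based -> [POS, POS+len) 0-based
  data.frame(sample_id = sample_id,
             chrom = fix$CHROM,
             start = pos,
             end = pos + len,
             stringsAsFactors = FALSE)
}

#' Read tumor sample metadata
#'
#' Columns: `sample_id`, `cancer_subtype`, `dataset`, `goi_drivers`
#' (comma-separated LOF driver genes among the genes of interest, empty when
#' none), `other_repair_deficiency` (logical), `mutagenic_signature`
#' (logical), `n_substitutions` (integer).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tumor_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "cancer_subtype", "dataset", "goi_drivers",
                      "other_repair_deficiency", "mutagenic_signature",
                      "n_substitutions"), "sample metadata")
  df$goi_drivers[is.na(df$goi_drivers)] <- ""
  df$other_repair_deficiency <- as.logical(df$other_repair_deficiency)
  df$mutagenic_signature <- as.logical(df$mutagenic_signature)
  df
}
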