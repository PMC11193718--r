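# Shared fixtures: a small reporter layout, barcode sets, and independent
# brute-force oracles used to cross-check the package implementations.

test_reference <- function(dialect = "original") {
  gap <- "TTGACCGGTTAACCAGGCATTCAGGTCAAT"        # 30 nt break-site window
  if (dialect == "v2") gap <- paste0(gap, "ACGTTGCA")  # +8 nt constant
  reporter_reference(
    upstream_anchor = "ACGTACGTAA",
    barcode_length = 8,
    left_anchor = "GGATCCGAGCTCGAAT",
    right_anchor = "CTCGAGTCTAGAGGAT",
    reference_gap = 30,
    dialect = dialect,
    gap_sequence = gap)
}

test_barcodes <- function(n = 4) {
  c("AAAACCCC", "GGGGTTTT", "ACACGTGT", "TGTGCACA",
    "AATTGGCC", "CCGGAATT", "AGAGTCTC", "TCTCAGAG")[seq_len(n)]
}

# brute-force maximal clique enumeration over all vertex subsets (<= 12 nodes)
brute_force_cliques <- function(edges, min_size = 4) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    if (a != b) adj[a, b] <- adj[b, a] <- TRUE
  }
  is_clique <- function(v) all(adj[v, v][upper.tri(matrix(0, length(v), length(v)))])
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    v <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(v) >= 2 && is_clique(v)) cliques[[length(cliques) + 1]] <- v
  }
  # maximal = not a subset of a larger clique
  maximal <- Filter(function(v) {
    !any(vapply(cliques, function(w) length(w) > length(v) && all(v %in% w),
                logical(1)))
  }, cliques)
  maximal <- Filter(function(v) length(v) >= min_size, maximal)
  maximal <- lapply(maximal, sort)
  key <- vapply(maximal, paste, "", collapse = "|")
  maximal[order(-lengths(maximal), key)]
}

# brute-force per-sample compartment count aggregation (oracle for Eq-style
# group sums)
brute_force_counts <- function(dels, sample_ids) {
  out <- c(MMEJ_Het = 0, NHEJ_Het = 0, MMEJ_Eu = 0, NHEJ_Eu = 0)
  for (s in sample_ids) {
    d <- dels[dels$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      if (d$class[i] == "unclassified" || d$compartment[i] == "neither") next
      key <- paste(sub("_sig", "", d$class[i]), d$compartment[i], sep = "_")
      out[key] <- out[key] + 1
    }
  }
  out
}

# small annotated deletion table with known classes/compartments
tiny_lads <- function() {
  data.frame(chrom = "chr1",
             start = c(0, 2000, 4000, 6000),
             end = c(1000, 3000, 5000, 7000),
             lad_class = c("cLAD", "ciLAD", "cLAD", "ciLAD"),
             stringsAsFactors = FALSE)
}
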