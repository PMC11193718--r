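# Similarity of CCD patterns: cosine similarity of synergy-score vectors,
# enrichment of similarity among physically interacting protein pairs against
# a random-pair null, maximal cliques in the interaction graph, and
# cross-cell-type pattern similarity with a feature-sampling eligibility rule.

#' Cosine similarity of two synergy-score vectors
#'
#' sum(A_i B_i) / (||A|| ||B||). Cosine is used because sparsified synergy
#' vectors contain many exact zeros.
#'
#' @param a,b Numeric vectors of equal length, each with at least one nonzero
#'   entry.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine is undefined for an all-zero vector")
  sum(a * b) / (na * nb)
}

# full cosine matrix of the rows of m (rows must be nonzero)
cosine_matrix <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("all-zero synergy vector encountered")
  (m %*% t(m)) / outer(nrm, nrm)
}

# drop all-zero rows of a synergy matrix with a warning
drop_zero_rows <- function(sm) {
  zero <- rowSums(sm != 0) == 0
  if (any(zero)) {
    warning(sprintf("dropping %d protein(s) with all-zero synergy vectors: %s",
                    sum(zero), paste(rownames(sm)[zero], collapse = ", ")))
    sm <- sm[!zero, , drop = FALSE]
  }
  sm
}

#' Test whether interacting protein pairs have more similar CCD patterns
#'
#' Compares the mean cosine similarity over physically interacting pairs with
#' the distribution of mean similarities of `n_draws` random sets of the same
#' number of distinct protein pairs (sampled without replacement within a
#' draw, self-pairs excluded). The two-sided p-value comes from a Gaussian
#' fit to the null means, since the empirical granularity of 1000 draws
#' cannot resolve small tail probabilities.
#'
#' @param sm Synergy matrix (proteins x features); all-zero rows are dropped
#'   with a warning.
#' @param edges data.frame with columns protein_a, protein_b (and optionally
#'   method); edges whose endpoints lack synergy vectors are ignored.
#' @param n_draws Number of random draws (default 1000).
#' @param seed Integer seed.
#' @param methods Optional filter on the edge `method` column.
#' @return list with `pairs` (edge table with cosine scores),
#'   `observed_mean`, `null_means`, `z_vs_null`, `p_two_sided`, `n_pairs`,
#'   `n_draws`, `seed`.
#' @export
interacting_pair_test <- function(sm, edges, n_draws = 1000, seed,
                                  methods = NULL) {
  check_columns(edges, c("protein_a", "protein_b"), "edge list")
  if (!is.null(methods)) edges <- edges[edges$method %in% methods, , drop = FALSE]
  sm <- drop_zero_rows(as.matrix(sm))
  prots <- rownames(sm)
  keep <- edges$protein_a %in% prots & edges$protein_b %in% prots &
    edges$protein_a != edges$protein_b
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) stop("no usable interaction edges")
  m <- length(prots)
  n_pairs <- nrow(edges)
  if (choose(m, 2) < n_pairs) {
    stop("not enough proteins to draw the required number of distinct pairs")
  }
  cm <- cosine_matrix(sm)
  edges$cosine <- cm[cbind(match(edges$protein_a, prots),
                           match(edges$protein_b, prots))]
  observed <- mean(edges$cosine)
  null_means <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      idx <- sample.int(choose(m, 2), n_pairs)
      ij <- unrank_pair(idx, m)
      mean(cm[ij])
    }, numeric(1))
  })
  z <- (observed - mean(null_means)) / stats::sd(null_means)
  list(pairs = edges, observed_mean = observed, null_means = null_means,
       z_vs_null = z, p_two_sided = clamp_p(2 * stats::pnorm(-abs(z))),
       n_pairs = n_pairs, n_draws = n_draws, seed = seed)
}

#' Find maximal cliques of interacting proteins
#'
#' All maximal cliques of at least `min_size` proteins in the physical
#' interaction graph, each sorted by protein name, in a deterministic order.
#'
#' @param edges data.frame with columns protein_a, protein_b.
#' @param min_size Minimum clique size (default 4).
#' @return list of character vectors (possibly empty).
#' @export
find_cliques <- function(edges, min_size = 4) {
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(edges[, c("protein_a", "protein_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(names(v)))
  key <- vapply(cl, function(v) paste(v, collapse = "|"), character(1))
  cl[order(-lengths(cl), key)]
}

#' Compare CCD patterns between two cell types
#'
#' Features of cell type B are only compared when sufficiently sampled there:
#' at least `min_iprs` IPRs embedded in the feature (feature z-score >
#' `z_cut`). Cosine similarity is then computed on the retained shared
#' features for each protein present in both synergy matrices, and compared
#' with a null built by pairing each matched protein of B with random
#' proteins of A (one random partner per matched protein per draw).
#'
#' @param sm_a Synergy matrix of the reference cell type (e.g. the full
#'   screen), proteins x features.
#' @param sm_b Synergy matrix of the second cell type.
#' @param cfm_b Standardized chromatin feature matrix of the second cell type
#'   (IPRs x features), used for the sampling-eligibility rule.
#' @param min_iprs Minimum embedded IPRs per feature (default 2).
#' @param z_cut Embedding cutoff on the feature z-score (default 0.5).
#' @param n_draws Random draws for the null (default 1000).
#' @param seed Integer seed.
#' @return list with `scores` (per matched protein), `features_used`,
#'   `observed_mean`, `null_means`, `null_ci95`, `z_vs_null`, `p_two_sided`.
#' @export
cross_celltype_similarity <- function(sm_a, sm_b, cfm_b, min_iprs = 2,
                                      z_cut = 0.5, n_draws = 1000, seed) {
  sm_a <- as.matrix(sm_a); sm_b <- as.matrix(sm_b)
  eligible <- colnames(cfm_b)[colSums(cfm_b > z_cut) >= min_iprs]
  feats <- intersect(intersect(colnames(sm_a), colnames(sm_b)), eligible)
  if (length(feats) == 0L) stop("no eligible shared chromatin features")
  a <- sm_a[, feats, drop = FALSE]
  b <- sm_b[, feats, drop = FALSE]
  a_ok <- rownames(a)[rowSums(a != 0) > 0]
  matched <- intersect(a_ok, rownames(b)[rowSums(b != 0) > 0])
  if (length(matched) == 0L) stop("no proteins with nonzero synergy vectors in both cell types")
  scores <- vapply(matched, function(p) cosine(a[p, ], b[p, ]), numeric(1))
  observed <- mean(scores)
  null_means <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      partners <- sample(a_ok, length(matched), replace = TRUE)
      mean(vapply(seq_along(matched), function(j) {
        cosine(a[partners[j], ], b[matched[j], ])
      }, numeric(1)))
    }, numeric(1))
  })
  z <- (observed - mean(null_means)) / stats::sd(null_means)
  list(scores = data.frame(protein = matched, cosine = as.numeric(scores),
                           stringsAsFactors = FALSE),
       features_used = feats, observed_mean = observed,
       null_means = null_means,
       null_ci95 = stats::quantile(null_means, c(0.025, 0.975), names = FALSE),
       z_vs_null = z, p_two_sided = clamp_p(2 * stats::pnorm(-abs(z))))
}
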