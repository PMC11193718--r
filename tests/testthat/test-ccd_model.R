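# Feature standardization, the three-step CCD model, synergy classification
# and clustering.

# delta matrix with given rows planted on a chromatin matrix; mocks get
# N(0, noise_sd) rows so the per-IPR mock null is well-defined
make_dm <- function(cfm, planted, n_mock = 10, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  mocks <- matrix(rnorm(n_mock * nrow(cfm), sd = noise_sd), n_mock,
                  dimnames = list(sprintf("mock%02d", 1:n_mock),
                                  rownames(cfm)))
  delta <- rbind(do.call(rbind, planted), mocks)
  structure(list(delta = delta,
                 support = matrix(3L, nrow(delta), ncol(delta),
                                  dimnames = dimnames(delta)),
                 mock_ids = rownames(mocks)),
            class = "bb_delta")
}

test_that("standardize_features z-scores each feature across IPRs", {
  m <- cbind(f1 = c(1, 2, 3), f2 = c(10, 20, 60))
  rownames(m) <- paste0("ipr", 1:3)
  z <- standardize_features(m)
  expect_equal(unname(z[, "f1"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(f1 = 0, f2 = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(f1 = 1, f2 = 1), tolerance = 1e-12)
  expect_equal(standardize_features(z), z, tolerance = 1e-12)  # idempotent
  expect_error(standardize_features(cbind(m, f3 = c(5, 5, 5))), "f3")
})

test_that("a noiseless planted slope is recovered exactly in step 3", {
  chrom <- sim_chromatin(19, seed = 31)
  cfm <- chrom$features
  f <- cfm[, "LMNB1"]
  dm <- make_dm(cfm, list(P1 = 0.5 * f), noise_sd = 0.02, seed = 2)
  res <- ccd_test(dm, cfm)
  expect_true(res$results$significant[res$results$protein == "P1"])
  expect_equal(res$synergy["P1", "LMNB1"], 0.5, tolerance = 1e-9)
  expect_lt(res$results$ccd_p[res$results$protein == "P1"], 1e-6)
})

test_that("a constant delta vector yields no significant CCD and zero slopes", {
  chrom <- sim_chromatin(19, seed = 32)
  cfm <- chrom$features
  dm <- make_dm(cfm, list(P1 = rep(0.01, 19)), seed = 3)
  res <- ccd_test(dm, cfm)
  expect_false(res$results$significant[res$results$protein == "P1"])
})

test_that("regression on all PCs reproduces the raw-feature fitted values", {
  # with few features and no PC cap binding, the PC rotation is invertible
  chrom <- sim_chromatin(19, seed = 33)
  cfm <- chrom$features[, c("LMNB1", "H3K4me3", "H3K27me3")]
  set.seed(4)
  y <- 0.3 * cfm[, 1] - 0.2 * cfm[, 2] + rnorm(19, sd = 0.1)
  pca <- prcomp(cfm, center = TRUE, scale. = FALSE)
  fit_pc <- lm(y ~ pca$x)
  fit_raw <- lm(y ~ cfm)
  expect_equal(unname(fitted(fit_pc)), unname(fitted(fit_raw)),
               tolerance = 1e-10)
})

test_that("planted M-synergy on LMNB1 recovers a negative slope there", {
  chrom <- sim_chromatin(19, seed = 34)
  scr <- sim_screen(chrom, n_proteins = 8, n_mock = 20, seed = 35,
                    beta = list(KO001 = c(LMNB1 = -0.5)))
  bal <- compute_balance(scr$counts)
  dm <- delta_scores(bal, scr$samples, scr$truth$mock_ids)
  res <- ccd_test(dm, chrom$features)
  expect_true(res$results$significant[res$results$protein == "KO001"])
  expect_lt(res$synergy["KO001", "LMNB1"], 0)
  expect_equal(res$results$synergy_class[res$results$protein == "KO001"], "M")
  # slopes off the correlated heterochromatin block stay near zero
  eu_truth <- scr$truth$synergy_truth["KO001", "H3K4me3"]
  expect_equal(res$slopes["KO001", "H3K4me3"], eu_truth, tolerance = 0.15)
})

test_that("adding a constant to a protein's delta vector leaves slopes unchanged", {
  chrom <- sim_chromatin(19, seed = 36)
  cfm <- chrom$features
  f <- cfm[, "H3K27me3"]
  dm1 <- make_dm(cfm, list(P1 = -0.4 * f), noise_sd = 0.02, seed = 5)
  dm2 <- dm1
  dm2$delta["P1", ] <- dm2$delta["P1", ] + 2
  r1 <- ccd_test(dm1, cfm)
  r2 <- ccd_test(dm2, cfm)
  expect_equal(r1$slopes["P1", ], r2$slopes["P1", ], tolerance = 1e-9)
})

test_that("every non-significant synergy cell is stored as exact zero", {
  chrom <- sim_chromatin(19, seed = 37)
  scr <- sim_screen(chrom, n_proteins = 6, n_mock = 20, seed = 38,
                    beta = list(KO001 = c(LMNB1 = -0.8)))
  bal <- compute_balance(scr$counts)
  dm <- delta_scores(bal, scr$samples, scr$truth$mock_ids)
  res <- ccd_test(dm, chrom$features)
  ns <- res$slope_p >= 0.05
  expect_true(all(res$synergy[ns] == 0))
  sig <- res$slope_p < 0.05
  expect_true(all(res$synergy[sig] == res$slopes[sig]))
})

test_that("synergy classification follows the sign rule", {
  expect_equal(classify_synergy(c(-0.2, -0.1, 0, 0)), "M")
  expect_equal(classify_synergy(c(0.3, 0)), "N")
  expect_equal(classify_synergy(c(0.3, -0.2)), "mixed")
  expect_equal(classify_synergy(c(0, 0)), "none")
})

test_that("ccd_vs_global cross-classifies significance", {
  chrom <- sim_chromatin(19, seed = 39)
  scr <- sim_screen(chrom, n_proteins = 6, n_mock = 20, seed = 40,
                    gamma = c(KO001 = -0.8, KO002 = -0.8),
                    beta = list(KO002 = c(LMNB1 = -0.6),
                                KO003 = c(H3K4me3 = 0.6)))
  bal <- compute_balance(scr$counts)
  dm <- delta_scores(bal, scr$samples, scr$truth$mock_ids)
  glob <- global_effect_test(dm, fdr_threshold = 0.001)
  ccd <- ccd_test(dm, chrom$features)
  link <- ccd_vs_global(ccd, glob)
  lab <- setNames(link$global_link, link$protein)
  expect_equal(unname(lab["KO002"]), "global_and_ccd")
  expect_equal(unname(lab["KO003"]), "ccd_only")
  expect_equal(unname(lab["KO001"]), "global_only")
  expect_equal(unname(lab["KO004"]), "none")
})

test_that("estimate_feature_delta evaluates the stored linear fit", {
  chrom <- sim_chromatin(19, seed = 41)
  cfm <- chrom$features
  f <- cfm[, "LMNB1"]
  dm <- make_dm(cfm, list(P1 = -0.4 * f), noise_sd = 0.01, seed = 6)
  res <- ccd_test(dm, cfm)
  est1 <- estimate_feature_delta(res, "P1", "LMNB1", level_z = 1)
  est0 <- estimate_feature_delta(res, "P1", "LMNB1", level_z = 0)
  expect_equal(est0, res$intercepts["P1", "LMNB1"])
  expect_equal(est1 - est0, res$slopes["P1", "LMNB1"])
  expect_equal(est1, -0.4, tolerance = 0.02)
  expect_error(estimate_feature_delta(res, "P1", "NOFEAT"), "unknown feature")
  expect_error(estimate_feature_delta(res, "NOPROT", "LMNB1"))
})

test_that("hierarchical clustering recovers planted synergy archetypes", {
  arch <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1), c = c(-1, 0, 0, -1))
  set.seed(8)
  sm <- arch[rep(1:3, each = 4), ] + matrix(rnorm(48, sd = 0.05), 12)
  rownames(sm) <- sprintf("p%02d", 1:12)
  truth <- rep(1:3, each = 4)
  cl <- cluster_synergies(sm, k = 3)
  # exact recovery: planted grouping and cut agree up to label permutation
  expect_equal(length(unique(table(cl$clusters, truth)[table(cl$clusters, truth) > 0])), 1)
  expect_true(all(apply(table(cl$clusters, truth) > 0, 1, sum) == 1))
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(mclust::adjustedRandIndex(cl$clusters, truth), 1)
  }
  # identical rows merge at height 0 and sit adjacent in the leaf order
  sm2 <- rbind(x = c(1, 2), y = c(1, 2), z = c(9, 9))
  cl2 <- cluster_synergies(sm2)
  expect_equal(min(cl2$hclust$height), 0)
  expect_equal(abs(diff(match(c("x", "y"), cl2$order))), 1)
})

test_that("mock conditions rarely reach CCD significance on null screens", {
  sig <- tot <- 0
  for (s in 1:4) {
    chrom <- sim_chromatin(19, seed = 300 + s)
    scr <- sim_screen(chrom, n_proteins = 20, n_mock = 33,
                      reads_per_ipr = 1000, seed = 400 + s)
    bal <- compute_balance(scr$counts)
    dm <- delta_scores(bal, scr$samples, scr$truth$mock_ids)
    res <- ccd_test(dm, chrom$features)
    sig <- sig + sum(res$mock_results$significant)
    tot <- tot + nrow(res$mock_results)
  }
  expect_lte(sig / tot, 0.05 + 3 * sqrt(0.05 * 0.95 / tot))
})
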