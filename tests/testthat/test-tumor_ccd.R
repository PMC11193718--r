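# Microhomology computation, deletion classification, compartment
# stratification, case/control filtering, Eq-style aggregation, bootstrap
# z-scores and Stouffer combination.

test_that("microhomology follows the flank-matching definition", {
  ref <- c(chr1 = "TAGCAGCTT")
  # deletion [1,4) removes "AGC"; downstream "AGCTT" shares prefix AGC
  expect_equal(compute_microhomology(ref, "chr1", 1, 4), 3)
  # deleted sequence sharing nothing with either flank
  ref2 <- c(chr1 = "AAAATTTTGGGG")
  expect_equal(compute_microhomology(ref2, "chr1", 4, 8), 0)
  # perfect tandem copy: microhomology equals the deletion length
  ref3 <- c(chr1 = "GGACGTACGTCC")
  expect_equal(compute_microhomology(ref3, "chr1", 2, 6), 4)
  # left-flank homology counts too
  ref4 <- c(chr1 = "TTAGCAGCAA")   # delete second AGC: suffix of upstream = AGC
  expect_equal(compute_microhomology(ref4, "chr1", 5, 8), 3)
  expect_error(compute_microhomology(ref, "chr1", 5, 20), "outside")
  expect_error(compute_microhomology(ref, "chr2", 1, 4), "absent")
})

test_that("microhomology accepts a DNAStringSet reference", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "TAGCAGCTT"))
  expect_equal(compute_microhomology(ref, "chr1", 1, 4), 3)
})

test_that("deletion classification applies the >5 bp and >=2 bp rules", {
  expect_equal(classify_deletion(7, 3), "MMEJ_sig")
  expect_equal(classify_deletion(6, 0), "NHEJ_sig")
  expect_equal(classify_deletion(5, 2), "unclassified")   # not > 5 bp
  expect_equal(classify_deletion(8, 1), "unclassified")   # 1 bp microhomology
  expect_equal(classify_deletion(c(7, 6, 5, 8), c(3, 0, 2, 1)),
               c("MMEJ_sig", "NHEJ_sig", "unclassified", "unclassified"))
})

test_that("compartment assignment requires full containment", {
  lads <- tiny_lads()
  dels <- data.frame(sample_id = "s",
                     chrom = "chr1",
                     start = c(100, 950, 2100, 1200),
                     end = c(150, 1050, 2200, 1300))
  comp <- assign_compartment(dels, lads)
  expect_equal(comp, c("Het", "neither", "Eu", "neither"))
  # boundary-exact containment counts
  dels2 <- data.frame(sample_id = "s", chrom = "chr1", start = 0, end = 1000)
  expect_equal(assign_compartment(dels2, lads), "Het")
})

test_that("LAD BED round trip through read_lads", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000\tcLAD", "chr1\t2000\t3000\tciLAD"), bed)
  gr <- read_lads(bed)
  expect_equal(gr$lad_class, c("cLAD", "ciLAD"))
  expect_equal(GenomicRanges::start(gr), c(1, 2001))  # GRanges is 1-based
  dels <- data.frame(sample_id = "s", chrom = "chr1",
                     start = c(10, 2010), end = c(20, 2020))
  expect_equal(assign_compartment(dels, data.frame(
    chrom = "chr1", start = c(0, 2000), end = c(1000, 3000),
    lad_class = c("cLAD", "ciLAD"))), c("Het", "Eu"))
  writeLines(c("chr1\t0\t1000\tLAD"), bed)
  expect_error(read_lads(bed), "cLAD/ciLAD")
  unlink(bed)
})

test_that("VCF deletions convert to 0-based half-open coordinates", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tATTTTTTT\tA\t.\tPASS\t.",   # 7 bp deletion
               "chr1\t200\t.\tA\tATT\t.\tPASS\t.",        # insertion: skipped
               "chr1\t300\t.\tC\tG\t.\tPASS\t."), vcf)    # SNV: skipped
  d <- read_deletions_vcf(vcf, "s1")
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 100)       # deleted bases are POS+1..POS+7 (1-based)
  expect_equal(d$end, 107)
  expect_equal(d$end - d$start, 7)
  unlink(vcf)
})

test_that("case/control filters I-IV are enforced", {
  meta <- data.frame(
    sample_id = paste0("s", 1:6),
    cancer_subtype = "st1", dataset = "D1",
    goi_drivers = c("ATM", "", "ATM,BRCA2", "ATM", "ATM", ""),
    other_repair_deficiency = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    mutagenic_signature = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    n_substitutions = c(600L, 800L, 700L, 900L, 400L, 450L),
    stringsAsFactors = FALSE)
  m <- filter_samples(meta, "ATM")
  expect_equal(m$role,
               c("case",       # LOF driver in exactly ATM, QC ok
                 "control",    # no driver, QC ok
                 "excluded",   # drivers in two GOIs
                 "excluded",   # other repair deficiency
                 "excluded",   # < 500 substitutions
                 "excluded"))  # control candidate but < 500 substitutions
  # a BRCA2 carrier is not a control for ATM either
  meta2 <- meta[1:2, ]; meta2$goi_drivers[2] <- "BRCA2"
  expect_equal(filter_samples(meta2, "ATM")$role[2], "excluded")
})

test_that("gene selection needs >= 5 cases with >= 3 in one subtype", {
  mk <- function(subtypes) data.frame(
    sample_id = paste0("s", seq_along(subtypes)),
    cancer_subtype = subtypes, dataset = "D1", goi_drivers = "ATM",
    other_repair_deficiency = FALSE, mutagenic_signature = FALSE,
    n_substitutions = 1000L, stringsAsFactors = FALSE)
  expect_equal(select_gois(mk(c("a", "a", "a", "b", "b")), "ATM"), "ATM")
  expect_equal(select_gois(mk(c("a", "a", "b", "b")), "ATM"), character(0))
  expect_equal(select_gois(mk(c("a", "a", "b", "b", "c")), "ATM"), character(0))
})

test_that("aggregation equals brute-force per-sample summation", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    dels <- data.frame(
      sample_id = sample(paste0("s", 1:n), 60, replace = TRUE),
      class = sample(c("MMEJ_sig", "NHEJ_sig", "unclassified"), 60, TRUE),
      compartment = sample(c("Het", "Eu", "neither"), 60, TRUE),
      stringsAsFactors = FALSE)
    ids <- paste0("s", 1:n)
    expect_equal(aggregate_counts(dels, ids), brute_force_counts(dels, ids))
    # additivity over a partition of the samples
    expect_equal(aggregate_counts(dels, ids),
                 aggregate_counts(dels, ids[1:2]) +
                   aggregate_counts(dels, ids[-(1:2)]))
  }
})

test_that("het_eu_stat arithmetic, invariances and continuity correction", {
  v <- c(MMEJ_Het = 40, NHEJ_Het = 10, MMEJ_Eu = 20, NHEJ_Eu = 40)
  expect_equal(as.numeric(het_eu_stat(v)), 3)
  expect_equal(as.numeric(het_eu_stat(v * 10)), 3)           # scale-invariant
  eq <- c(MMEJ_Het = 30, NHEJ_Het = 10, MMEJ_Eu = 60, NHEJ_Eu = 20)
  expect_equal(as.numeric(het_eu_stat(eq)), 0)               # equal ratios
  sw <- c(MMEJ_Het = 20, NHEJ_Het = 40, MMEJ_Eu = 40, NHEJ_Eu = 10)
  expect_equal(as.numeric(het_eu_stat(sw)), -3)              # antisymmetric
  z <- c(MMEJ_Het = 0, NHEJ_Het = 10, MMEJ_Eu = 20, NHEJ_Eu = 40)
  expect_true(attr(het_eu_stat(z), "corrected"))
  expect_equal(as.numeric(het_eu_stat(z)),
               log2(0.5 / 10.5) - log2(20.5 / 40.5))
  expect_error(het_eu_stat(c(MMEJ_Het = 0, NHEJ_Het = 0,
                             MMEJ_Eu = 0, NHEJ_Eu = 0)), "undefined")
})

test_that("bootstrap z is seed-reproducible and rejects degenerate controls", {
  set.seed(17)
  ctrl <- matrix(rpois(80, 20), 20, 4,
                 dimnames = list(NULL, c("MMEJ_Het", "NHEJ_Het",
                                         "MMEJ_Eu", "NHEJ_Eu")))
  cases <- matrix(rpois(20, 20), 5, 4, dimnames = dimnames(ctrl))
  b1 <- bootstrap_z(cases, ctrl, n_boot = 200, seed = 3)
  b2 <- bootstrap_z(cases, ctrl, n_boot = 200, seed = 3)
  expect_equal(b1$z_case, b2$z_case)
  same <- matrix(rep(c(10L, 10L, 10L, 10L), each = 6), 6,
                 dimnames = dimnames(ctrl))
  expect_error(bootstrap_z(cases, same, n_boot = 50, seed = 1), "degenerate")
  expect_error(bootstrap_z(cases, ctrl[1:4, ], n_boot = 50, seed = 1),
               "at least 5")
})

test_that("Stouffer combination closed forms", {
  expect_equal(stouffer(1.7)$Z, 1.7)                         # k = 1 identity
  expect_equal(stouffer(c(1.2, -0.4, 2.0))$Z, 2.8 / sqrt(3), tolerance = 1e-12)
  expect_equal(stouffer(rep(0.9, 4))$Z, 0.9 * sqrt(4), tolerance = 1e-12)
  s <- stouffer(c(2, 2))
  expect_equal(s$p, 2 * pnorm(-2 * sqrt(2)), tolerance = 1e-12)
  expect_error(stouffer(numeric(0)), "empty")
})

test_that("planted Het-specific MMEJ loss is detected with the right sign", {
  tum <- sim_tumors(case_effect = c(MMEJ_Het = 0.5), seed = 61)
  ann <- annotate_deletions(tum$deletions, tum$lads)
  res <- tumor_ccd_analysis(ann, tum$meta, gois = "ATM", n_boot = 500, seed = 62)
  expect_true(all(res$strata$z_case < 0))
  expect_true(res$gois$significant)
  expect_lt(res$gois$Z, -3)
})

test_that("long microhomology-assisted deletions obey the size window", {
  lads <- data.frame(chrom = "chr1", start = c(0, 4e5),
                     end = c(3e5, 7e5), lad_class = c("cLAD", "ciLAD"))
  svs <- data.frame(
    sample_id = rep(c("a", "b", "c", "d", "e", "f"), each = 2),
    cohort = rep(c("case", "ctrl"), c(2, 10)),
    chrom = "chr1",
    start = rep(c(1000, 401000), 6),
    end = rep(c(1000, 401000), 6) + c(2000, 1399, 2000, 2000, rep(2000, 8)),
    mh_len = c(3, 3, 3, 1, rep(3, 8)),
    stringsAsFactors = FALSE)
  res <- long_mh_deletions(svs, lads, "case", "ctrl", n_boot = 100, seed = 4)
  # case's ciLAD deletion is 1399 bp, below the 1.4 kb floor -> excluded;
  # control sample b's ciLAD deletion has mh 1 -> excluded
  expect_equal(unname(res$counts["case", ]), c(1, 0))
  expect_equal(unname(res$counts["ctrl", ]), c(5, 4))
})

test_that("null cohorts give calibrated tumor z-scores (small run)", {
  zs <- vapply(1:25, function(s) {
    tum <- sim_tumors(n_subtypes = 1, seed = 5000 + s)
    ann <- annotate_deletions(tum$deletions, tum$lads)
    cases <- tum$meta$sample_id[grepl("case", tum$meta$sample_id)]
    ctrls <- tum$meta$sample_id[grepl("ctrl", tum$meta$sample_id)]
    bootstrap_z(sample_compartment_counts(ann, cases),
                sample_compartment_counts(ann, ctrls),
                n_boot = 300, seed = 6000 + s)$z_case
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.75)
  expect_true(sd(zs) > 0.5 && sd(zs) < 1.7)
})
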