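# breakbalance

Quantify the balance between the two mutagenic DNA double-strand-break
repair pathways — microhomology-mediated end-joining (MMEJ) and
non-homologous end-joining (NHEJ) — from multiplexed barcoded reporter
screens, detect **chromatin context-dependencies (CCDs)** of DNA repair
proteins, compare CCD patterns within and across cell types, and test
whether loss of a repair gene shifts MMEJ/NHEJ signature mutations between
heterochromatin and euchromatin in tumor genomes.

The package is aimed at groups running integrated-pathway-reporter (IPR)
knockout or inhibitor screens, and at cancer-genomics analysts stratifying
indel calls by chromatin compartment.

## What it computes

At one barcoded reporter, NHEJ leaves a +1 insertion and MMEJ a −7
deletion, so the local pathway balance is `log2(n[−7] / n[+1])`. For a
knockout, the score is the change relative to mock controls, per replicate
and reporter:

    Δlog2 MMEJ:NHEJ = log2 MMEJ:NHEJ (KO) − mean log2 MMEJ:NHEJ (mocks)

- **Global effects** — mean Δ over reporters, z-scored against the empirical
  mock null (33 mocks), BH-corrected (FDR 0.001); a t-test variant serves
  inhibitor designs with a single control per replicate.
- **CCDs** — a three-step linear model: omnibus mock-based pre-filter,
  principal-component regression of Δ on the chromatin feature matrix
  (CCD FDR 0.05), then per-feature slopes = **synergy scores** (positive:
  the protein favors NHEJ where the feature is high; negative: favors MMEJ).
- **Pattern similarity** — cosine similarity of synergy vectors
  (`cos(A,B) = ΣAᵢBᵢ / (‖A‖‖B‖)`), tested against 1000 random-pair draws;
  maximal cliques of physically interacting proteins; cross-cell-type
  comparison restricted to sufficiently sampled features (≥ 2 reporters
  with feature z > 0.5).
- **Tumor compartment shifts** — deletions > 5 bp with ≥ 2 bp junctional
  microhomology (MMEJ signature) or none (NHEJ signature), assigned to
  constitutive LADs (heterochromatin) or inter-LADs (euchromatin) by full
  containment; per gene of interest and cancer subtype,
  `Δlog2 MMEJ:NHEJ (Het/Eu)` of cases is z-scored against a case-sized
  bootstrap of the controls, combined across subtypes by Stouffer's
  `Z = Σz/√k`, BH-corrected across genes.

A synthetic-data module (`sim_chromatin`, `sim_screen`, `sim_reads`,
`sim_tumors`) generates screens and tumor cohorts with planted ground truth
in exactly the formats the pipeline reads, so every stage is testable
without external downloads.

## Worked example

```r
library(breakbalance)

chrom <- sim_chromatin(n_ipr = 19, seed = 11)
scr <- sim_screen(chrom, n_proteins = 67, n_mock = 33, seed = 12,
                  gamma = c(KO001 = -1),                 # global MMEJ loss
                  beta = list(KO002 = c(LMNB1 = -0.5)))  # lamina M-synergy

bal  <- compute_balance(scr$counts)
dm   <- delta_scores(bal, scr$samples, scr$truth$mock_ids)
glob <- global_effect_test(dm)
glob[glob$protein == "KO001", c("global_score", "fdr", "direction")]
#>   global_score fdr      direction
#>        -1.0013   0    favors_MMEJ

ccd <- ccd_test(dm, chrom$features)
ccd
#> CCD analysis: 67 proteins tested, 2 significant (5 PCs); 33 mock controls, 0 significant
ccd$synergy["KO002", "LMNB1"]
#> [1] -0.5065
```

The planted global effect (−1 log₂ unit) is recovered as −1.00 and called
`favors_MMEJ`; the planted lamina synergy (−0.5) is recovered as −0.51 with
M-synergy classification, while no mock control reaches significance.

For tumor cohorts:

```r
tum <- sim_tumors(case_effect = c(MMEJ_Het = 0.5), seed = 6)   # 50% MMEJ loss in heterochromatin
ann <- annotate_deletions(tum$deletions, tum$lads)
res <- tumor_ccd_analysis(ann, tum$meta, gois = "ATM", n_boot = 1000, seed = 10)
res$gois
#>   goi k         Z            p        p_adj significant
#> 1 ATM 2 -9.435687 3.884421e-21 3.884421e-21        TRUE
```

`run_pipeline()` orchestrates the stages from a single YAML/list
configuration and writes result tables plus a reproducibility manifest.

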