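# Pipeline orchestration: run the stages (quantify -> screen -> ccd ->
# similarity; tumor independent) from a single configuration list or YAML
# file, writing TSV result tables and a reproducibility manifest.

#' Run the analysis pipeline from a configuration
#'
#' The configuration is a named list (or path to a YAML file) with an `out`
#' directory and any of the stage blocks below; stages execute in dependency
#' order and every stochastic stage must carry a `seed`.
#'
#' \describe{
#'   \item{simulate_screen}{`seed`, optional `n_ipr`, `n_proteins`, `n_mock`,
#'     `n_replicates`, `reads_per_ipr`: generates a synthetic screen (counts,
#'     sample sheet, chromatin features) used by later stages when no real
#'     inputs are given.}
#'   \item{screen}{optional `counts`, `samples` (TSV paths), `mock_ids`,
#'     `min_reads` (default 1), `freq_threshold`, `min_replicates`,
#'     `global_fdr` (default 0.001): balance, delta and global-effect tables.}
#'   \item{ccd}{optional `features` (TSV path), `ccd_fdr` (default 0.05),
#'     `step1_fdr` (0.25), `slope_p` (0.05): CCD results and synergy matrix.}
#'   \item{similarity}{`edges` (TSV path), `n_draws` (default 1000), `seed`:
#'     interacting-pair test and cliques.}
#'   \item{simulate_tumor}{`seed` plus [sim_tumors()] parameters.}
#'   \item{tumor}{optional `deletions`, `meta`, `lads` (paths), `gois`,
#'     `n_boot` (default 1000), `seed`: per-stratum and per-GOI tables.}
#' }
#'
#' @param config Named list or YAML file path.
#' @return Invisibly, a list of in-memory stage results; tables and a
#'   `manifest.yaml` (config hash, seeds, package version) are written under
#'   `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out)) stop("config$out (output directory) is required")
  for (stage in c("simulate_screen", "similarity", "simulate_tumor", "tumor")) {
    if (!is.null(config[[stage]]) && is.null(config[[stage]]$seed)) {
      stop(sprintf("stage '%s' is stochastic and requires a seed", stage))
    }
  }
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  counts <- samples <- cfm <- NULL
  if (!is.null(config$simulate_screen)) {
    sc <- config$simulate_screen
    chrom <- sim_chromatin(n_ipr = sc$n_ipr %||% 19, seed = sc$seed)
    scr <- sim_screen(chrom,
                      n_proteins = sc$n_proteins %||% 519,
                      n_mock = sc$n_mock %||% 33,
                      n_replicates = sc$n_replicates %||% 3,
                      reads_per_ipr = sc$reads_per_ipr %||% 3000,
                      seed = sc$seed + 1)
    counts <- scr$counts; samples <- scr$samples; cfm <- chrom$features
    write_count_table(counts, file.path(out, "sim_counts.tsv"))
    utils::write.table(samples, file.path(out, "sim_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(cfm, file.path(out, "sim_chromatin.tsv"), "ipr_barcode")
    results$simulate_screen <- scr
    log_stage("simulate_screen", sprintf("%d samples simulated", nrow(samples)))
  }

  dm <- glob <- NULL
  if (!is.null(config$screen)) {
    sc <- config$screen
    if (!is.null(sc$counts)) counts <- read_count_table(sc$counts)
    if (!is.null(sc$samples)) samples <- read_sample_sheet(sc$samples)
    if (is.null(counts)) stop("screen stage: no count table available")
    mock_ids <- sc$mock_ids %||% grep("^mock", unique(samples$condition),
                                      value = TRUE)
    bal <- compute_balance(counts, min_reads_per_class = sc$min_reads %||% 1)
    bal <- filter_iprs(bal, samples,
                       freq_threshold = sc$freq_threshold %||% 0,
                       min_replicates = sc$min_replicates %||% 1)
    dm <- delta_scores(bal, samples, mock_ids)
    glob <- global_effect_test(dm, fdr_threshold = sc$global_fdr %||% 0.001)
    utils::write.table(bal, file.path(out, "balance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_matrix_tsv(dm$delta, file.path(out, "delta.tsv"), "condition")
    utils::write.table(glob, file.path(out, "global_effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$screen <- list(balance = bal, delta = dm, global = glob)
    log_stage("screen", sprintf("%d conditions, %d with a global direction",
                                nrow(glob), sum(glob$direction != "none")))
  }

  ccd <- NULL
  if (!is.null(config$ccd)) {
    cc <- config$ccd
    if (!is.null(cc$features)) cfm <- standardize_features(read_feature_matrix(cc$features))
    if (is.null(dm) || is.null(cfm)) stop("ccd stage needs the screen stage and a feature matrix")
    ccd <- ccd_test(dm, cfm,
                    step1_fdr = cc$step1_fdr %||% 0.25,
                    ccd_fdr_threshold = cc$ccd_fdr %||% 0.05,
                    slope_p = cc$slope_p %||% 0.05)
    res <- ccd$results
    if (!is.null(glob)) {
      link <- ccd_vs_global(ccd, glob)
      res$global_link <- link$global_link[match(res$protein, link$protein)]
    }
    utils::write.table(res, file.path(out, "ccd_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_matrix_tsv(ccd$synergy, file.path(out, "synergy.tsv"), "protein")
    results$ccd <- ccd
    log_stage("ccd", sprintf("%d significant CCDs", sum(res$significant)))
  }

  if (!is.null(config$similarity)) {
    si <- config$similarity
    if (is.null(ccd)) stop("similarity stage needs the ccd stage")
    edges <- read_edge_list(si$edges, methods = si$methods)
    sim <- interacting_pair_test(ccd$synergy, edges,
                                 n_draws = si$n_draws %||% 1000,
                                 seed = si$seed)
    cliques <- find_cliques(edges, min_size = si$min_clique %||% 4)
    utils::write.table(sim$pairs, file.path(out, "pair_similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(vapply(cliques, paste, "", collapse = "\t"),
               file.path(out, "cliques.txt"))
    results$similarity <- list(pairs = sim, cliques = cliques)
    log_stage("similarity", sprintf("observed mean %.3f, p = %.2g",
                                    sim$observed_mean, sim$p_two_sided))
  }

  tum_in <- NULL
  if (!is.null(config$simulate_tumor)) {
    st <- config$simulate_tumor
    tum_in <- sim_tumors(n_cases = st$n_cases %||% 20,
                         n_controls = st$n_controls %||% 20,
                         seed = st$seed)
    utils::write.table(tum_in$deletions, file.path(out, "sim_deletions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tum_in$meta, file.path(out, "sim_tumor_meta.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$simulate_tumor <- tum_in
    log_stage("simulate_tumor", sprintf("%d deletions", nrow(tum_in$deletions)))
  }

  if (!is.null(config$tumor)) {
    tu <- config$tumor
    if (!is.null(tu$deletions)) {
      dels <- read_deletions_tsv(tu$deletions)
      meta <- read_tumor_meta(tu$meta)
      lads <- read_lads(tu$lads)
      lads <- data.frame(chrom = as.character(GenomicRanges::seqnames(lads)),
                         start = GenomicRanges::start(lads) - 1L,
                         end = GenomicRanges::end(lads),
                         lad_class = lads$lad_class, stringsAsFactors = FALSE)
    } else if (!is.null(tum_in)) {
      dels <- tum_in$deletions; meta <- tum_in$meta; lads <- tum_in$lads
    } else stop("tumor stage: no deletion table available")
    ann <- annotate_deletions(dels, lads)
    res <- tumor_ccd_analysis(ann, meta,
                              gois = tu$gois %||% unique(
                                unlist(strsplit(meta$goi_drivers[nzchar(meta$goi_drivers)], ","))),
                              n_boot = tu$n_boot %||% 1000, seed = tu$seed)
    utils::write.table(res$strata, file.path(out, "tumor_strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$gois, file.path(out, "tumor_gois.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$tumor <- res
    log_stage("tumor", sprintf("%d GOI(s) analyzed", nrow(res$gois)))
  }

  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("breakbalance")),
                   seeds = lapply(Filter(is.list, config),
                                  function(x) x$seed),
                   stages = names(results))
  writeLines(yaml::as.yaml(manifest), file.path(out, "manifest.yaml"))
  invisible(results)
}
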