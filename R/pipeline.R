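#' Default pipeline run configuration
#'
#' Collects the thresholds and sizes of every pipeline stage. Every value
#' that affects results is echoed into the JSON run report. Problem sizes
#' default to a quick demonstration scale; the simulation defaults of
#' [sim_config()] can be overridden through `sim`.
#'
#' @param seed integer seed (mandatory; also forwarded to the simulator).
#' @param outdir output directory.
#' @param sim named list of [sim_config()] overrides.
#' @param ... named overrides of the fields listed below.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, outdir = tempfile("regulomer_run_"),
                       sim = list(), ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed), outdir = outdir, sim = sim,
    min_support = 2L, min_frac = 0,
    max_distance = 1e5, tss_cutoff = 1000, proximal_cutoff = 10000,
    enrich_bins = 10L, groups_alpha = 0.05,
    tau = 1, pseudocount = 0.5, ranked_bins = 11L,
    padj_pair = 0.1, padj_lrt = 0.05,
    gsea_weight = 1, gsea_nperm = 500L,
    concordance_alpha = 0.1,
    p53_cutoff = 17L, p53_bin_width = 5L, ci_level = 0.90,
    som_grid = c(8L, 8L), som_epochs = 10L, metacluster_k = 10L,
    cofactor = 5, mid_band = 0.18
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' The YAML file holds `seed` plus any [run_config()] fields; a nested `sim`
#' block overrides [sim_config()] defaults.
#'
#' @param path YAML file.
#' @param ... further overrides taking precedence over the file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config file must set a seed")
  args <- utils::modifyList(y, list(...))
  do.call(run_config, args)
}

log_msg <- function(...) {
  message("[regulomer] ", ...)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the stage chain simulate -> consensus -> annotate -> enrich ->
#' classify -> core -> metascore -> cytof on synthetic inputs with planted
#' ground truth, writing stage outputs (narrowPeak / BED / TSV / CSV) and a
#' JSON run report to `config$outdir`. The report echoes every parameter
#' and seed, records an md5 checksum per output file, and collects headline
#' statistics per stage (consensus recall against the planted truth,
#' enrichment extremes, classification accuracy, core-set sizes, phase
#' chi-squared results). Reports contain no timestamps, so identical
#' configurations produce identical reports.
#'
#' @param config a [run_config()].
#' @return the report, invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  report <- list(parameters = config[setdiff(names(config), "outdir")],
                 stages = list())

  ## simulate
  log_msg("simulate: regulome, DE tables, peak signal, meta scores, CyTOF")
  reg <- sim_regulome(scfg)
  for (sid in names(reg$chip_sets)) {
    write_peaks(reg$chip_sets[[sid]], out(paste0(sid, ".narrowPeak")),
                format = "narrowPeak")
  }
  write_peaks(reg$dnase, out("dnase.bed"), format = "bed")
  write_gene_models(reg$genes, out("genes.tsv"))
  write_tsv(reg$truth, out("truth_peaks.tsv"))
  write_tsv(reg$site_genes, out("truth_site_genes.tsv"))
  bound_truth <- reg$genes$gene_id %in% reg$site_genes$gene_id
  names(bound_truth) <- reg$genes$gene_id
  de <- sim_de_tables(scfg, bound_truth)
  for (ln in names(de$lines)) write_tsv(de$lines[[ln]], out(paste0(ln, ".tsv")))
  write_tsv(de$lrt, out("lrt.tsv"))
  write_tsv(de$truth, out("truth_de.tsv"))
  sig <- sim_peak_signals(scfg)
  write_tsv(sig$signal, out("peak_signal.tsv"))
  write_tsv(sig$acetylation, out("acetylation.tsv"))
  write_tsv(sig$truth, out("truth_classes.tsv"))
  meta <- sim_metascores(scfg)
  write_tsv(meta, out("metascores.tsv"))
  cy <- sim_cytof(scfg)
  write_events(cy$events, out("cytof_events.csv"))
  write_tsv(cy$truth, out("truth_cytof.tsv"))
  report$stages$simulate <- list(
    n_genes = nrow(reg$genes), n_true_sites = nrow(reg$true_sites),
    n_chip_sets = length(reg$chip_sets), n_events = nrow(cy$events))

  ## consensus
  log_msg("consensus: merge + support filter + open-chromatin filter")
  merged <- merge_intervals(do.call(rbind_peak_sets, reg$chip_sets))
  supported <- support_filter(merged, reg$chip_sets,
                              min_support = config$min_support,
                              min_frac = config$min_frac)
  consensus <- support_filter(supported, list(reg$dnase), min_support = 1L)
  consensus$support <- NULL
  write_peaks(consensus, out("consensus.narrowPeak"), format = "narrowPeak")
  hits <- support_filter(reg$true_sites, list(consensus), min_support = 0L)
  recall <- mean(hits$support > 0)
  true_cov <- support_filter(consensus, list(reg$true_sites),
                             min_support = 0L)
  fdr <- mean(true_cov$support == 0)
  report$stages$consensus <- list(
    n_merged = nrow(merged), n_consensus = nrow(consensus),
    recall_true_sites = recall, false_discovery_rate = fdr)

  ## annotate
  log_msg("annotate: nearest-gene assignment")
  ann <- nearest_gene(consensus, reg$genes,
                      max_distance = config$max_distance,
                      tss_cutoff = config$tss_cutoff,
                      proximal_cutoff = config$proximal_cutoff)
  write_tsv(ann, out("annotation.tsv"))
  report$stages$annotate <- list(
    n_annotated = sum(!is.na(ann$gene_id)),
    category_counts = as.list(table(ann$category)))

  ## enrich
  log_msg("enrich: binding-by-expression bins")
  flags <- flag_bound_genes(ann, reg$genes)
  de1 <- de$lines[[1]]
  enr <- binned_binding_enrichment(de1, flags, rank_bins = config$enrich_bins)
  write_tsv(as.data.frame(enr), out("enrichment_bins.tsv"))
  grp <- binned_binding_enrichment(de1, flags, groups = TRUE,
                                   alpha = config$groups_alpha)
  write_tsv(as.data.frame(grp), out("enrichment_groups.tsv"))
  report$stages$enrich <- list(
    n_bound_genes = sum(flags$bound),
    min_padj_bin = enr$bin_label[which.min(enr$padj)],
    min_padj = min(enr$padj))

  ## classify
  log_msg("classify: dual-factor CPM classes + ranked bins")
  cls <- classify_peaks(sig$signal, tau = config$tau,
                        pseudocount = config$pseudocount)
  write_classified_peaks(cls, out("peak_classes.tsv"))
  acc <- mean(cls$class_label == sig$truth$class_label)
  rstat <- sign(sig$acetylation$log2fc) * -log10(sig$acetylation$pvalue)
  rbp <- ranked_bin_proportions(rstat, cls$class_label,
                                k = config$ranked_bins,
                                peak_ids = cls$peak_id)
  write_tsv(as.data.frame(rbp), out("ranked_bins.tsv"))
  fusion_prop <- rbp$prop_ER + rbp$prop_R1_ER
  report$stages$classify <- list(
    class_counts = as.list(table(cls$class_label)),
    class_accuracy = acc,
    fusion_prop_spearman = cor(seq_len(nrow(rbp)), fusion_prop,
                               method = "spearman"))

  ## core
  log_msg("core: cross-line consensus + GSEA + concordance")
  core <- core_consensus_filter(de$lines, de$lrt,
                                padj_pair = config$padj_pair,
                                padj_lrt = config$padj_lrt)
  write_gmt(list(core_up = core$core_up, core_down = core$core_down),
            out("core_sets.gmt"))
  ranked <- rank_metric(de$lrt, mode = "signed_logp")
  write_tsv(ranked, out("ranked_list.tsv"))
  bound_set <- reg$genes$gene_id[bound_truth]
  gsea <- gsea_preranked(ranked, bound_set, weight = config$gsea_weight,
                         n_perm = config$gsea_nperm, seed = config$seed)
  conc <- quadrant_concordance(de$lines[[1]], de$lines[[2]],
                               alpha = config$concordance_alpha)
  report$stages$core <- list(
    n_core_up = length(core$core_up), n_core_down = length(core$core_down),
    gsea_es = gsea$es, gsea_nes = gsea$nes, gsea_pvalue = gsea$pvalue,
    concordant_fraction = conc$concordant_fraction, concordance_n = conc$n)

  ## metascore
  log_msg("metascore: score bins + group tests")
  cc_bins <- bin_by_score(meta, "cc_count",
                          edges = c(0, 1, 2, 4, 6, 9, Inf))
  cc_sum <- binned_mean_ci(cc_bins$bins, meta$lfc_kd,
                           level = config$ci_level, bound = meta$bound)
  write_tsv(as.data.frame(cc_sum), out("metascore_cc_bins.tsv"))
  p53_edges <- seq(-40, 40 + config$p53_bin_width, by = config$p53_bin_width)
  p53_bins <- bin_by_score(meta, "p53_score", edges = p53_edges)
  p53_sum <- binned_mean_ci(p53_bins$bins, meta$lfc_kd,
                            level = config$ci_level)
  write_tsv(as.data.frame(p53_sum), out("metascore_p53_bins.tsv"))
  gt <- score_group_tests(meta, meta$lfc_kd, cutoff = config$p53_cutoff)
  write_tsv(gt$tests, out("metascore_group_tests.tsv"))
  report$stages$metascore <- list(
    group_sizes = as.list(table(gt$groups)),
    group_stars = setNames(as.list(gt$tests$stars), gt$tests$group))

  ## cytof
  log_msg("cytof: transform + SOM + annotation + phase tests")
  sp <- split_events(cy$events)
  scaled <- arcsinh_scale(sp$markers, cofactor = config$cofactor)
  roles <- marker_roles()
  phase_markers <- c(roles$cycle, roles$death)
  som_phase <- train_som(scaled[, phase_markers], grid = config$som_grid,
                         epochs = config$som_epochs, seed = config$seed)
  phase_ann <- metacluster_annotate(scaled, som_phase,
                                    k = config$metacluster_k,
                                    rules = default_phase_rules(),
                                    mid_band = config$mid_band,
                                    seed = config$seed)
  som_pop <- train_som(scaled[, roles$surface], grid = config$som_grid,
                       epochs = config$som_epochs, seed = config$seed)
  pop_ann <- metacluster_annotate(scaled, som_pop, k = 5L,
                                  rules = default_population_rules(),
                                  mid_band = config$mid_band,
                                  seed = config$seed)
  labels_df <- data.frame(condition = sp$meta$condition,
                          population = pop_ann$labels,
                          phase = phase_ann$labels,
                          stringsAsFactors = FALSE)
  write_tsv(labels_df, out("cytof_labels.tsv"))
  tests <- phase_distribution_test(phase_ann$labels, sp$meta$condition)
  phase_acc <- mean(phase_ann$labels == cy$truth$phase)
  pop_acc <- mean(pop_ann$labels == cy$truth$population)
  report$stages$cytof <- list(
    phase_accuracy = phase_acc, population_accuracy = pop_acc,
    chisq_statistic = tests$all$test$statistic,
    chisq_df = tests$all$test$df,
    phase_counts = as.list(table(phase_ann$labels)))

  files <- setdiff(list.files(config$outdir), "report.json")
  report$checksums <- as.list(tools::md5sum(file.path(config$outdir, files)))
  names(report$checksums) <- files
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_msg("done: ", config$outdir)
  invisible(report)
}

#' Row-bind several peak sets into one
#'
#' Peak ids are prefixed with their set id to stay unique.
#'
#' @param ... [peak_set()] objects (or a single list of them).
#' @return a [peak_set()] with set id `"combined"`.
#' @export
rbind_peak_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "peak_set")) sets <- sets[[1]]
  dfs <- lapply(sets, function(s) {
    s$peak_id <- paste0(set_id(s), ":", s$peak_id)
    as.data.frame(s)
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  attr(out, "set_id") <- "combined"
  class(out) <- c("peak_set", "data.frame")
  out
}
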