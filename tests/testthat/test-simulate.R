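test_that("sim_config validates and freezes parameters", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(1, nonsense = 2), "unknown")
  expect_error(sim_config(1, sensitivity = 1.5), "0, 1")
  cfg <- sim_config(7, n_genes = 100L)
  expect_equal(cfg$n_genes, 100L)
  expect_s3_class(cfg, "sim_config")
})

test_that("regulome simulation respects sensitivity limits", {
  base <- list(n_genes = 120L, n_true_sites = 80L, n_dnase_background = 100L)
  perfect <- do.call(sim_config, c(list(seed = 2, sensitivity = 1,
                                        false_rate = 0), base))
  reg <- sim_regulome(perfect)
  for (ps in reg$chip_sets) {
    expect_equal(nrow(ps), 80L)
  }
  blind <- do.call(sim_config, c(list(seed = 2, sensitivity = 0,
                                      false_rate = 0), base))
  reg0 <- sim_regulome(blind)
  expect_true(all(vapply(reg0$chip_sets, nrow, 1L) == 0L))
  dense <- sim_config(2, chrom_length = 10000L, n_true_sites = 500L)
  expect_error(sim_regulome(dense), "density")
})

test_that("consensus filtering recovers planted sites from default regulome", {
  cfg <- sim_config(101, n_genes = 400L, n_true_sites = 300L,
                    n_dnase_background = 500L)
  reg <- sim_regulome(cfg)
  merged <- merge_intervals(do.call(rbind_peak_sets, reg$chip_sets))
  supported <- support_filter(merged, reg$chip_sets, min_support = 2)
  consensus <- support_filter(supported, list(reg$dnase), min_support = 1)
  hits <- support_filter(reg$true_sites, list(consensus), min_support = 0)
  recall <- mean(hits$support > 0)
  cov <- support_filter(consensus, list(reg$true_sites), min_support = 0)
  fdr <- mean(cov$support == 0)
  expect_gte(recall, 0.90)
  expect_lte(fdr, 0.05)
})

test_that("DE simulation is calibrated under the null and coupled by default", {
  genes <- sprintf("g%04d", 1:800)
  bound <- setNames(rep(c(TRUE, FALSE), each = 400), genes)
  null_cfg <- sim_config(11, de_delta = 0)
  de0 <- sim_de_tables(null_cfg, bound)
  ks <- ks.test(de0$lines[[1]]$pvalue[bound], de0$lines[[1]]$pvalue[!bound])
  expect_gt(ks$p.value, 0.01)
  strong <- sim_config(11, de_delta = 5, de_sd = 0.1)
  deS <- sim_de_tables(strong, bound)
  core <- core_consensus_filter(deS$lines, deS$lrt)
  expect_setequal(core$core_down, genes[bound])
  expect_length(core$core_up, 0)
})

test_that("planted repression shows up in the most-down bins only", {
  genes <- sprintf("g%04d", 1:1500)
  set.seed(1)
  bound <- setNames(runif(1500) < 0.3, genes)
  de <- sim_de_tables(sim_config(13), bound)
  res <- binned_binding_enrichment(de$lines[[1]], unname(bound),
                                   rank_bins = 10)
  expect_lt(res$padj[1], 0.05)
  expect_gt(min(res$padj[9:10]), 0.5)
})

test_that("peak-signal simulation supports classification recovery", {
  sig <- sim_peak_signals(sim_config(17))
  cl <- classify_peaks(sig$signal)
  expect_gte(mean(cl$class_label == sig$truth$class_label), 0.90)
  # degenerate: no ratio separation means chance-level accuracy
  flat <- sim_peak_signals(sim_config(17, ratio_means = c(R1 = 0, R1_ER = 0,
                                                          ER = 0)))
  clf <- classify_peaks(flat$signal)
  expect_lt(mean(clf$class_label == flat$truth$class_label), 0.6)
})

test_that("acetylation coupling drives the ranked-bin trend; off = flat", {
  sig <- sim_peak_signals(sim_config(19))
  cl <- classify_peaks(sig$signal)
  rs <- sign(sig$acetylation$log2fc) * -log10(sig$acetylation$pvalue)
  rb <- ranked_bin_proportions(rs, cl$class_label, k = 11)
  fusion <- rb$prop_ER + rb$prop_R1_ER
  expect_lt(cor(seq_len(11), fusion, method = "spearman"), -0.8)
  rhos <- vapply(19:23, function(s) {
    off <- sim_peak_signals(sim_config(s, ac_means = c(R1 = 0, R1_ER = 0,
                                                       ER = 0)))
    clo <- classify_peaks(off$signal)
    rso <- sign(off$acetylation$log2fc) * -log10(off$acetylation$pvalue)
    rbo <- ranked_bin_proportions(rso, clo$class_label, k = 11)
    cor(seq_len(11), rbo$prop_ER + rbo$prop_R1_ER, method = "spearman")
  }, numeric(1))
  expect_lt(median(abs(rhos)), 0.5)
  expect_lt(max(abs(rhos)), 0.8)
})

test_that("meta-score simulation plants the asymmetric couplings", {
  meta <- sim_metascores(sim_config(23, n_genes_meta = 8000L))
  expect_true(all(meta$p53_score >= -40 & meta$p53_score <= 40))
  expect_true(all(meta$cc_count >= 0 & meta$cc_count <= 12))
  edges <- seq(-40, 45, by = 5)
  b <- bin_by_score(meta, "p53_score", edges = edges)
  s <- binned_mean_ci(b$bins, meta$lfc_kd)
  ok <- !is.na(s$mean_lfc)
  expect_gt(cor(seq_len(nrow(s))[ok], s$mean_lfc[ok], method = "spearman"),
            0.8)
  # fusion-like column couples only on the negative-score side
  neg <- meta$p53_score < 0
  expect_lt(cor(meta$p53_score[neg], meta$lfc_fusion[neg]), -0.3)
  expect_lt(abs(cor(meta$p53_score[!neg], meta$lfc_fusion[!neg])), 0.1)
  # group sizes match a brute-force count
  gr <- score_group_tests(meta, meta$lfc_kd)
  expect_equal(unname(table(gr$groups)["cell_cycle"]),
               sum(meta$p53_score <= -17), ignore_attr = TRUE)
  # decoupled scores give a flat trend
  flat <- sim_metascores(sim_config(23, kd_slope = 0, n_genes_meta = 8000L))
  bf <- bin_by_score(flat, "p53_score", edges = edges)
  sf <- binned_mean_ci(bf$bins, flat$lfc_kd)
  okf <- !is.na(sf$mean_lfc) & sf$n > 30
  fit <- summary(lm(sf$mean_lfc[okf] ~ seq_len(nrow(sf))[okf]))
  expect_gt(fit$coefficients[2, 4], 0.05)   # slope not significant
})

test_that("simulators are byte-deterministic and seed-sensitive", {
  cfg <- sim_config(29, n_genes = 150L, n_true_sites = 100L,
                    n_events = 500L, n_genes_meta = 1000L)
  cfg2 <- sim_config(30, n_genes = 150L, n_true_sites = 100L,
                     n_events = 500L, n_genes_meta = 1000L)
  expect_identical(sim_regulome(cfg), sim_regulome(cfg))
  expect_identical(sim_cytof(cfg), sim_cytof(cfg))
  expect_identical(sim_metascores(cfg), sim_metascores(cfg))
  expect_false(identical(sim_regulome(cfg)$chip_sets,
                         sim_regulome(cfg2)$chip_sets))
  bound <- setNames(rep(c(TRUE, FALSE), 75), sprintf("g%03d", 1:150))
  expect_identical(sim_de_tables(cfg, bound), sim_de_tables(cfg, bound))
})

test_that("truth stays in sidecar structures, not analysis-facing tables", {
  cfg <- sim_config(31, n_genes = 150L, n_true_sites = 100L,
                    n_events = 400L, n_genes_meta = 500L)
  reg <- sim_regulome(cfg)
  expect_false(any(grepl("site_id|true", names(reg$chip_sets[[1]]))))
  sig <- sim_peak_signals(cfg)
  expect_false("class_label" %in% names(sig$signal))
  cy <- sim_cytof(cfg)
  expect_false(any(c("phase", "population") %in% names(cy$events)))
})
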