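#' Simulation configuration with planted ground truth
#'
#' Collects every parameter of the synthetic-data generators in one list.
#' The defaults describe the study conditions the analysis modules are
#' designed for: a toy genome with ~1500 genes and 1000 true binding sites
#' detected by three replicate ChIP peak sets (90% sensitivity, 15% false
#' peaks) inside an open-chromatin superset; five cell-line knockdown DE
#' tables with a planted repressive coupling of binding to expression
#' (effect 0.5 noise-sd units); dual-factor CPM signal with three planted
#' binding classes and acetylation loss coupled to fusion binding; meta-score
#' tables with a positive knockdown coupling and a negative fusion coupling
#' restricted to the cell-cycle (negative-score) arm; and two-condition
#' CyTOF mixtures with a planted S-phase excess in the fusion condition.
#' Identical configs give byte-identical outputs; the seed is mandatory.
#'
#' @param seed integer seed (mandatory).
#' @param ... named overrides of any default listed below.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    # genome / regulome
    chrom = "chrS", chrom_length = 3e7L, n_genes = 1500L,
    gene_length_range = c(2000L, 20000L),
    n_true_sites = 1000L, site_halfwidth = 150L,
    site_category_probs = c(tss = 0.3, intragenic = 0.4, upstream = 0.3),
    n_chip_sets = 3L, sensitivity = 0.9, false_rate = 0.15,
    jitter_sd = 20, signal_meanlog = log(20), signal_sdlog = 0.5,
    n_dnase_background = 2000L,
    # differential expression
    n_lines = 5L, de_delta = 0.5, de_sd = 1, de_direction = -1,
    # dual-factor peak signal
    n_signal_peaks = 2000L,
    class_probs = c(R1 = 0.35, R1_ER = 0.40, ER = 0.25),
    ratio_means = c(R1 = -2, R1_ER = 0, ER = 2), ratio_sd = 0.4,
    log2cpm_mean = 5, log2cpm_sd = 1, measurement_sd = 0.2,
    library_size = 2e7,
    ac_means = c(R1 = 0, R1_ER = -1, ER = -1.5), ac_sd = 1, ac_se = 0.3,
    # meta scores
    n_genes_meta = 19148L, p53_score_sd = 10, p53_score_range = c(-40L, 40L),
    cc_count_max = 12L, cc_base_rate = 0.3, cc_score_slope = 8,
    kd_slope = 0.02, fusion_slope = -0.03, meta_lfc_sd = 0.15,
    bound_intercept = -1.5, bound_cc_slope = 0.35,
    # CyTOF
    n_events = 10000L, conditions = c("wildtype", "fusion"),
    cofactor = 5,
    surface_sd = 0.5, cycle_sd = 0.8,
    marker_low = 1, marker_mid = 3, marker_high = 5,
    phase_mix = list(
      wildtype = c(G0 = 0.12, G1 = 0.38, S = 0.20, G2 = 0.12, M = 0.05,
                   apoptotic = 0.07, dead = 0.06),
      fusion = c(G0 = 0.08, G1 = 0.32, S = 0.30, G2 = 0.12, M = 0.05,
                 apoptotic = 0.07, dead = 0.06)),
    population_mix = list(
      wildtype = c(HSPC = 0.12, preB = 0.28, CD19low = 0.12, CD45RA = 0.16,
                   CD45 = 0.32),
      fusion = c(HSPC = 0.22, preB = 0.12, CD19low = 0.22, CD45RA = 0.14,
                 CD45 = 0.30))
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  for (p in c("sensitivity", "false_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  stopifnot(abs(sum(cfg$class_probs) - 1) < 1e-8,
            all(vapply(cfg$phase_mix, function(x) abs(sum(x) - 1) < 1e-8, TRUE)),
            all(vapply(cfg$population_mix, function(x) abs(sum(x) - 1) < 1e-8, TRUE)))
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Simulate a regulome: genes, true binding sites, ChIP and DNaseI peak sets
#'
#' Places true binding sites near gene TSSs with a configurable mix of
#' tss-proximal, intragenic and upstream positions. Each observed ChIP set
#' detects each true site with probability `sensitivity`, adds Gaussian
#' boundary jitter, and contributes `false_rate * n_true_sites` false peaks
#' at random positions. The DNaseI set is a superset: all true sites plus
#' random background open regions.
#'
#' @param config a [sim_config()].
#' @return list: `genes` ([gene_model()]), `chip_sets` (list of
#'   [peak_set()]), `dnase` ([peak_set()]), `true_sites` ([peak_set()]),
#'   `truth` (data.frame mapping each observed peak to its true site, `NA`
#'   for false peaks) and `site_genes` (data.frame site_id, gene_id).
#' @export
sim_regulome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$chrom_length
  ng <- config$n_genes
  if (config$n_true_sites > L / 200) {
    stop("infeasible site density: ", config$n_true_sites,
         " sites on a ", L, " bp genome")
  }
  glen <- round(runif(ng, config$gene_length_range[1],
                      config$gene_length_range[2]))
  gstart <- sort(sample.int(L - max(glen) - 1L, ng))
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  genes <- gene_model(sprintf("gene_%04d", seq_len(ng)), config$chrom,
                      strand, gstart, gstart + glen)
  ns <- config$n_true_sites
  gi <- sample.int(ng, ns, replace = TRUE)
  cat_ <- sample(names(config$site_category_probs), ns, replace = TRUE,
                 prob = config$site_category_probs)
  tss <- genes$tss[gi]
  summit <- integer(ns)
  for (i in seq_len(ns)) {
    if (cat_[i] == "tss") {
      summit[i] <- tss[i] + round(max(-900, min(900, rnorm(1, 0, 400))))
    } else if (cat_[i] == "intragenic") {
      lo <- genes$body_start[gi[i]] + 1100L
      hi <- genes$body_end[gi[i]] - 100L
      summit[i] <- if (lo < hi) round(runif(1, lo, hi)) else
        (genes$body_start[gi[i]] + genes$body_end[gi[i]]) %/% 2L
    } else {
      d <- round(runif(1, 1100, 20000))
      summit[i] <- if (genes$strand[gi[i]] == "+") tss[i] - d else tss[i] + d
    }
  }
  hw <- config$site_halfwidth
  summit <- pmax(hw + 1L, pmin(L - hw - 1L, summit))
  true_sites <- peak_set(config$chrom, summit - hw, summit + hw + 1L,
                         peak_id = sprintf("site_%04d", seq_len(ns)),
                         signal = round(rlnorm(ns, config$signal_meanlog,
                                               config$signal_sdlog), 4),
                         summit_offset = hw, set_id = "true_sites")
  # the planted target is the nearest-TSS gene of the final summit (the
  # sampled gene unless a neighbour's TSS ends up closer), so the truth is
  # consistent with summit-anchored annotation
  target <- vapply(summit, function(s) which.min(abs(s - genes$tss)),
                   integer(1))
  site_genes <- data.frame(site_id = true_sites$peak_id,
                           gene_id = genes$gene_id[target],
                           category = cat_, stringsAsFactors = FALSE)
  n_false <- round(config$false_rate * ns)
  chip_sets <- list()
  truth <- list()
  for (s in seq_len(config$n_chip_sets)) {
    det <- runif(ns) < config$sensitivity
    idx <- which(det)
    js <- round(rnorm(length(idx), 0, config$jitter_sd))
    je <- round(rnorm(length(idx), 0, config$jitter_sd))
    st <- pmax(0L, true_sites$start[idx] + js)
    en <- pmax(st + 50L, true_sites$end[idx] + je)
    fsummit <- round(runif(n_false, hw + 1, L - hw - 1))
    all_st <- c(st, fsummit - hw)
    all_en <- c(en, fsummit + hw + 1L)
    soff <- pmin(pmax(0L, c(summit[idx], fsummit) - all_st),
                 all_en - all_st - 1L)
    sid <- sprintf("chip%d", s)
    ps <- peak_set(config$chrom, all_st, all_en,
                   peak_id = sprintf("%s_p%05d", sid,
                                     seq_len(length(idx) + n_false)),
                   signal = round(rlnorm(length(idx) + n_false,
                                         config$signal_meanlog,
                                         config$signal_sdlog), 4),
                   summit_offset = soff, set_id = sid)
    chip_sets[[sid]] <- ps
    truth[[sid]] <- data.frame(
      set_id = rep(sid, nrow(ps)), peak_id = ps$peak_id,
      site_id = c(true_sites$peak_id[idx], rep(NA_character_, n_false)),
      stringsAsFactors = FALSE)
  }
  nb <- config$n_dnase_background
  bsummit <- round(runif(nb, hw + 1, L - hw - 1))
  dnase <- merge_intervals(peak_set(
    config$chrom,
    c(true_sites$start, bsummit - hw),
    c(true_sites$end, bsummit + hw + 1L),
    peak_id = sprintf("dnase_p%05d", seq_len(ns + nb)),
    signal = 1, set_id = "dnase"))
  list(genes = genes, chip_sets = chip_sets, dnase = dnase,
       true_sites = true_sites, truth = do.call(rbind, truth),
       site_genes = site_genes)
}

#' Simulate multi-cell-line differential-expression tables
#'
#' For each of `n_lines` cell lines, the per-gene effect is
#' `delta * bound * direction + N(0, sd)`; p-values come from the matching
#' z-test and are BH-adjusted. A joint LRT-style table is derived from the
#' pooled z statistic across lines, with the mean fold change as the
#' representative sign.
#'
#' @param config a [sim_config()].
#' @param bound logical per-gene bound flags (named by gene id, e.g. from
#'   the [sim_regulome()] truth via [flag_bound_genes()]).
#' @return list: `lines` (list of DE data.frames with `gene_id`, `log2fc`,
#'   `pvalue`, `padj`, `stat`), `lrt` (joint table), `truth` (data.frame
#'   with the planted per-gene effect).
#' @export
sim_de_tables <- function(config, bound) {
  stopifnot(inherits(config, "sim_config"), is.logical(bound),
            !is.null(names(bound)))
  set.seed(config$seed + 1L)
  n <- length(bound)
  effect <- config$de_delta * config$de_direction * as.numeric(bound)
  zmat <- matrix(0, n, config$n_lines)
  lines <- list()
  for (l in seq_len(config$n_lines)) {
    lfc <- effect + rnorm(n, 0, config$de_sd)
    z <- lfc / config$de_sd
    p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
    lines[[paste0("line_", l)]] <- data.frame(
      gene_id = names(bound), log2fc = lfc, pvalue = p,
      padj = bh_adjust(p), stat = z, stringsAsFactors = FALSE)
    zmat[, l] <- z
  }
  zpool <- rowSums(zmat) / sqrt(config$n_lines)
  p_lrt <- pmax(2 * pnorm(-abs(zpool)), .Machine$double.xmin)
  lrt <- data.frame(
    gene_id = names(bound),
    log2fc = rowMeans(vapply(lines, `[[`, numeric(n), "log2fc")),
    pvalue = p_lrt, padj = bh_adjust(p_lrt), stringsAsFactors = FALSE)
  list(lines = lines, lrt = lrt,
       truth = data.frame(gene_id = names(bound), bound = bound,
                          true_effect = effect, stringsAsFactors = FALSE))
}

#' Simulate dual-factor CPM signal and differential acetylation
#'
#' Draws a binding class for each peak from the configured mixture, then CPM
#' pairs on a lognormal scale with class-dependent log-ratio means (R1
#' negative, R1_ER zero, ER positive) and a differential-acetylation table
#' whose fold change is coupled to class (fusion-dominated classes lose
#' acetylation).
#'
#' @param config a [sim_config()].
#' @return list: `signal` (data.frame `peak_id`, `raw_count_a/b`,
#'   `cpm_a/b`), `acetylation` (data.frame `peak_id`, `log2fc`, `pvalue`,
#'   `padj`), `truth` (planted class per peak).
#' @export
sim_peak_signals <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_signal_peaks
  cls <- sample(names(config$class_probs), n, replace = TRUE,
                prob = config$class_probs)
  base <- rnorm(n, config$log2cpm_mean, config$log2cpm_sd)
  ratio <- rnorm(n, config$ratio_means[cls], config$ratio_sd)
  l2a <- base - ratio / 2 + rnorm(n, 0, config$measurement_sd)
  l2b <- base + ratio / 2 + rnorm(n, 0, config$measurement_sd)
  raw_a <- as.integer(round(2^l2a * config$library_size / 1e6))
  raw_b <- as.integer(round(2^l2b * config$library_size / 1e6))
  ids <- sprintf("speak_%05d", seq_len(n))
  signal <- data.frame(
    peak_id = ids, raw_count_a = raw_a, raw_count_b = raw_b,
    cpm_a = cpm_normalize(raw_a, config$library_size),
    cpm_b = cpm_normalize(raw_b, config$library_size),
    stringsAsFactors = FALSE)
  ac_lfc <- rnorm(n, config$ac_means[cls], config$ac_sd)
  ac_p <- 2 * pnorm(-abs(ac_lfc / config$ac_se))
  list(signal = signal,
       acetylation = data.frame(peak_id = ids, log2fc = ac_lfc,
                                pvalue = ac_p, padj = bh_adjust(ac_p),
                                stringsAsFactors = FALSE),
       truth = data.frame(peak_id = ids, class_label = cls,
                          stringsAsFactors = FALSE))
}

#' Simulate per-gene meta-analysis scores with coupled fold changes
#'
#' Generates an integer p53 score (negative = cell-cycle arm, positive =
#' apoptosis / DNA-damage arm) and a cell-cycle study count whose rate grows
#' on the negative-score side. Two fold-change columns are planted:
#' `lfc_kd` (native-factor knockdown) is positively coupled to the p53 score
#' across its whole range; `lfc_fusion` (fusion knockdown) is negatively
#' coupled on the negative-score side only, reproducing the asymmetry in
#' which the fusion opposes its native counterpart on cell-cycle genes but
#' not on the apoptosis arm. Binding flags are more probable at high
#' cell-cycle study counts.
#'
#' @param config a [sim_config()].
#' @return data.frame: `gene_id`, `p53_score`, `cc_count`, `lfc_kd`,
#'   `lfc_fusion`, `bound`.
#' @export
sim_metascores <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- config$n_genes_meta
  rng <- config$p53_score_range
  score <- pmax(rng[1], pmin(rng[2], round(rnorm(n, 0, config$p53_score_sd))))
  lambda <- config$cc_base_rate +
    config$cc_score_slope * pmax(-score, 0) / abs(rng[1])
  cc <- pmin(config$cc_count_max, rpois(n, lambda))
  lfc_kd <- config$kd_slope * score + rnorm(n, 0, config$meta_lfc_sd)
  lfc_fusion <- config$fusion_slope * pmin(score, 0) +
    rnorm(n, 0, config$meta_lfc_sd)
  pb <- stats::plogis(config$bound_intercept + config$bound_cc_slope * cc)
  data.frame(
    gene_id = sprintf("mgene_%05d", seq_len(n)),
    p53_score = as.integer(score), cc_count = as.integer(cc),
    lfc_kd = lfc_kd, lfc_fusion = lfc_fusion,
    bound = runif(n) < pb, stringsAsFactors = FALSE)
}

sim_marker_tables <- function(config) {
  lo <- config$marker_low; mi <- config$marker_mid; hi <- config$marker_high
  surface <- rbind(
    HSPC    = c(CD45 = hi, CD45RA = lo, CD34 = hi, CD19 = lo),
    preB    = c(CD45 = hi, CD45RA = lo, CD34 = lo, CD19 = hi),
    CD19low = c(CD45 = hi, CD45RA = lo, CD34 = mi, CD19 = mi),
    CD45RA  = c(CD45 = hi, CD45RA = hi, CD34 = lo, CD19 = lo),
    CD45    = c(CD45 = hi, CD45RA = lo, CD34 = lo, CD19 = lo))
  cycle <- rbind(
    G0        = c(pRb = lo, IdU = lo, CycB1 = lo, pHisH3 = lo,
                  cisplatin = lo, cCaspase3 = lo),
    G1        = c(pRb = hi, IdU = lo, CycB1 = lo, pHisH3 = lo,
                  cisplatin = lo, cCaspase3 = lo),
    S         = c(pRb = hi, IdU = hi, CycB1 = mi, pHisH3 = lo,
                  cisplatin = lo, cCaspase3 = lo),
    G2        = c(pRb = hi, IdU = lo, CycB1 = hi, pHisH3 = lo,
                  cisplatin = lo, cCaspase3 = lo),
    M         = c(pRb = hi, IdU = lo, CycB1 = hi, pHisH3 = hi,
                  cisplatin = lo, cCaspase3 = lo),
    # apoptotic cells are membrane-intact and exclude the viability stain
    apoptotic = c(pRb = lo, IdU = lo, CycB1 = lo, pHisH3 = lo,
                  cisplatin = lo, cCaspase3 = hi),
    dead      = c(pRb = lo, IdU = lo, CycB1 = lo, pHisH3 = lo,
                  cisplatin = hi, cCaspase3 = hi))
  list(surface = surface, cycle = cycle)
}

#' Simulate a mass-cytometry event matrix with planted truth
#'
#' Events are drawn from condition-specific population and phase mixtures.
#' Marker means come from built-in tables in arcsinh space (e.g. IdU high in
#' S phase, pHisH3 high in M, cisplatin high in dead cells; graded
#' intermediate levels where biology dictates, such as cyclin B1 rising
#' through S to G2/M). Gaussian noise is added in transformed space and the
#' values are mapped back to the raw ion-count scale with
#' `cofactor * sinh(x)` (clipped at 0).
#'
#' @param config a [sim_config()].
#' @return list: `events` (data.frame with marker columns and
#'   `meta_condition`), `truth` (data.frame `condition`, `population`,
#'   `phase` per event), `marker_tables` (the mean tables used).
#' @export
sim_cytof <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  tabs <- sim_marker_tables(config)
  rows <- list(); truths <- list()
  for (cond in config$conditions) {
    n <- config$n_events
    pops <- sample(rownames(tabs$surface), n, replace = TRUE,
                   prob = config$population_mix[[cond]])
    phases <- sample(rownames(tabs$cycle), n, replace = TRUE,
                     prob = config$phase_mix[[cond]])
    smeans <- tabs$surface[pops, , drop = FALSE]
    cmeans <- tabs$cycle[phases, , drop = FALSE]
    svals <- smeans + matrix(rnorm(length(smeans), 0, config$surface_sd),
                             nrow = n)
    cvals <- cmeans + matrix(rnorm(length(cmeans), 0, config$cycle_sd),
                             nrow = n)
    tr <- cbind(svals, cvals)
    raw <- config$cofactor * sinh(tr)
    raw[raw < 0] <- 0
    df <- as.data.frame(raw)
    df$meta_condition <- cond
    rows[[cond]] <- df
    truths[[cond]] <- data.frame(condition = cond, population = pops,
                                 phase = phases, stringsAsFactors = FALSE)
  }
  list(events = do.call(rbind, rows), truth = do.call(rbind, truths),
       marker_tables = tabs)
}
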