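#' Cross-cell-line core target consensus filter
#'
#' Defines "core" target genes of a knocked-down factor across several cell
#' lines: a gene is in the core up (down) set when its pairwise adjusted
#' p-value is below `padj_pair` with positive (negative) log2 fold change in
#' every line, and the joint likelihood-ratio-test adjusted p-value is below
#' `padj_lrt`. The two sets are disjoint by construction.
#'
#' @param lines list (>= 2) of per-line DE data.frames with `gene_id`,
#'   `log2fc`, `padj`.
#' @param lrt joint data.frame with `gene_id`, `padj`.
#' @param padj_pair per-line adjusted-p cutoff (default 0.1).
#' @param padj_lrt joint LRT adjusted-p cutoff (default 0.05).
#' @return list with character vectors `core_up`, `core_down`, and
#'   `n_excluded` (genes missing from at least one table).
#' @export
core_consensus_filter <- function(lines, lrt, padj_pair = 0.1,
                                  padj_lrt = 0.05) {
  if (length(lines) < 2L) stop("need at least 2 cell lines")
  universe <- Reduce(intersect, c(lapply(lines, `[[`, "gene_id"),
                                  list(lrt$gene_id)))
  all_genes <- unique(c(unlist(lapply(lines, `[[`, "gene_id")), lrt$gene_id))
  n_excluded <- length(setdiff(all_genes, universe))
  if (n_excluded > 0) {
    message(n_excluded, " gene(s) missing from at least one table were excluded")
  }
  up <- rep(TRUE, length(universe))
  down <- rep(TRUE, length(universe))
  for (ln in lines) {
    ix <- match(universe, ln$gene_id)
    ok <- !is.na(ln$padj[ix]) & ln$padj[ix] < padj_pair
    up <- up & ok & ln$log2fc[ix] > 0
    down <- down & ok & ln$log2fc[ix] < 0
  }
  lx <- match(universe, lrt$gene_id)
  lrt_ok <- !is.na(lrt$padj[lx]) & lrt$padj[lx] < padj_lrt
  list(core_up = universe[up & lrt_ok],
       core_down = universe[down & lrt_ok],
       n_excluded = n_excluded)
}

#' Rank metric for preranked GSEA
#'
#' Builds a strictly ordered ranked gene list from a DE table, either from a
#' supplied test-statistic column (`mode = "stat"`) or as
#' `sign(log2fc) * -log10(pvalue)` (`mode = "signed_logp"`, the convention
#' for LRT-derived tables whose statistic carries no sign). Genes are ordered
#' by descending score with ties broken by gene id; zero p-values are clamped
#' to the smallest positive double.
#'
#' @param de data.frame with `gene_id`, `log2fc`, `pvalue` and, for
#'   `mode = "stat"`, the column named by `stat_col`.
#' @param mode `"signed_logp"` or `"stat"`.
#' @param stat_col name of the statistic column used when `mode = "stat"`.
#' @return data.frame with `gene_id`, `score`, ordered descending by score.
#' @export
rank_metric <- function(de, mode = c("signed_logp", "stat"),
                        stat_col = "stat") {
  mode <- match.arg(mode)
  if (anyDuplicated(de$gene_id)) stop("duplicate gene_ids in DE table")
  if (mode == "signed_logp") {
    p <- de$pvalue
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    n0 <- sum(p == 0, na.rm = TRUE)
    if (n0 > 0) {
      message(n0, " zero p-value(s) clamped to the smallest positive double")
      p[p == 0] <- .Machine$double.xmin
    }
    score <- sign(de$log2fc) * -log10(p)
  } else {
    if (!stat_col %in% names(de)) stop("no column '", stat_col, "' in DE table")
    score <- de[[stat_col]]
  }
  out <- data.frame(gene_id = de$gene_id, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# running-sum extremum from sorted hit positions; O(k) per evaluation
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  wsum <- cumsum(w) / sum(w)
  miss_step <- 1 / (N - k)
  at_hit <- wsum - (pos - seq_len(k)) * miss_step
  before_hit <- c(0, wsum[-k]) - (pos - seq_len(k)) * miss_step
  hi <- max(at_hit)
  lo <- min(before_hit)
  if (hi >= -lo) {
    list(es = hi, idx = which.max(at_hit), positive = TRUE)
  } else {
    list(es = lo, idx = which.min(before_hit), positive = FALSE)
  }
}

#' Preranked gene-set enrichment analysis
#'
#' Classic running-sum GSEA on a preranked list: walking down the ranking,
#' the sum is incremented at gene-set members (hits) in proportion to
#' `|score|^weight` (normalized to total 1) and decremented by `1/(N - k)` at
#' non-members. The enrichment score ES is the extremum of the running sum.
#' The null is gene-label permutation: set membership is reassigned to random
#' positions. The p-value is the fraction of same-sign null ES at least as
#' extreme; NES divides ES by the mean absolute same-sign null ES. The
#' leading edge contains the set members at or before the extremum (at or
#' after it, for negative ES).
#'
#' @param ranked data.frame from [rank_metric()] (`gene_id`, `score`,
#'   descending).
#' @param gene_set character vector of member gene ids.
#' @param weight 0 (unweighted, Kolmogorov-Smirnov-like) or 1 (classic
#'   weighted GSEA; default).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation null.
#' @return list of class `gsea_result`: `es`, `nes`, `pvalue`,
#'   `leading_edge`, `n_hits`, `n_perm`.
#' @export
gsea_preranked <- function(ranked, gene_set, weight = 1, n_perm = 1000,
                           seed = 1) {
  stopifnot(weight %in% c(0, 1))
  if (n_perm < 100) stop("n_perm must be >= 100")
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  k <- sum(hit)
  if (k == 0L) stop("gene_set does not intersect the ranked list")
  if (k == N) stop("gene_set covers the whole ranked list")
  absw <- abs(ranked$score)^weight
  # guard against an all-zero weight vector (all scores 0 with weight 1)
  if (all(absw[hit] == 0)) absw <- rep(1, N)
  pos <- which(hit)
  obs <- es_from_positions(pos, absw[pos], N)
  members <- ranked$gene_id[pos]
  leading <- if (obs$positive) members[seq_len(obs$idx)] else
    members[obs$idx:k]
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    p <- sort(sample.int(N, k))
    es_from_positions(p, absw[p], N)$es
  }, numeric(1))
  same <- null_es[sign(null_es) == sign(obs$es)]
  if (length(same) == 0L) {
    pvalue <- 1 / n_perm
    nes <- obs$es / mean(abs(null_es))
  } else {
    pvalue <- sum(abs(same) >= abs(obs$es)) / length(same)
    nes <- obs$es / mean(abs(same))
  }
  structure(list(es = obs$es, nes = nes, pvalue = pvalue,
                 leading_edge = leading, n_hits = k, n_perm = n_perm),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p = %.4g (%d hits, %d perms)\n",
              x$es, x$nes, x$pvalue, x$n_hits, x$n_perm))
  cat("leading edge:", length(x$leading_edge), "genes\n")
  invisible(x)
}

#' Sign concordance of two differential-expression tables
#'
#' Restricts to genes significant in both tables (`padj < alpha`, nonzero
#' fold change), cross-tabulates the fold-change signs and tests association
#' with a two-sided Fisher test. Reports the concordant (same-sign) and
#' discordant fractions.
#'
#' @param deA,deB data.frames with `gene_id`, `log2fc`, `padj`.
#' @param alpha adjusted-p cutoff applied to both tables (default 0.1).
#' @return list: `table` (2x2 sign table), `odds_ratio`, `pvalue`,
#'   `concordant_fraction`, `discordant_fraction`, `n`.
#' @export
quadrant_concordance <- function(deA, deB, alpha = 0.1) {
  m <- merge(deA[, c("gene_id", "log2fc", "padj")],
             deB[, c("gene_id", "log2fc", "padj")],
             by = "gene_id", suffixes = c("_a", "_b"))
  keep <- !is.na(m$padj_a) & !is.na(m$padj_b) &
    m$padj_a < alpha & m$padj_b < alpha &
    m$log2fc_a != 0 & m$log2fc_b != 0
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) {
    warning("no genes pass padj < ", alpha, " in both tables")
    return(list(table = matrix(0L, 2, 2), odds_ratio = NA_real_,
                pvalue = NA_real_, concordant_fraction = NA_real_,
                discordant_fraction = NA_real_, n = 0L))
  }
  sa <- factor(sign(m$log2fc_a), levels = c(-1, 1), labels = c("dn", "up"))
  sb <- factor(sign(m$log2fc_b), levels = c(-1, 1), labels = c("dn", "up"))
  tab <- table(A = sa, B = sb)
  ft <- fisher_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                   alternative = "two_sided")
  conc <- (tab["dn", "dn"] + tab["up", "up"]) / sum(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, pvalue = ft$pvalue,
       concordant_fraction = as.numeric(conc),
       discordant_fraction = 1 - as.numeric(conc), n = nrow(m))
}

#' Principal components of samples restricted to a gene signature
#'
#' Restricts an expression matrix to a gene signature, centers each gene
#' across samples, and computes sample scores on the first two principal
#' components by singular value decomposition. Constant genes are dropped
#' with a warning. The sign of each component is fixed by requiring the
#' largest-magnitude gene loading to be positive.
#'
#' @param expr numeric matrix, samples x genes, with dimnames.
#' @param signature character vector of signature gene ids.
#' @return list: `scores` (samples x 2), `loadings` (genes x 2), `sdev`,
#'   `genes_used`.
#' @export
signature_pca <- function(expr, signature) {
  stopifnot(is.matrix(expr), !is.null(colnames(expr)))
  if (nrow(expr) < 2) stop("need at least 2 samples")
  keep <- intersect(colnames(expr), signature)
  if (length(keep) < 2) stop("fewer than 2 signature genes present")
  x <- expr[, keep, drop = FALSE]
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped from the signature")
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 non-constant signature genes")
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  npc <- min(2L, length(sv$d))
  u <- sv$u[, seq_len(npc), drop = FALSE]
  v <- sv$v[, seq_len(npc), drop = FALSE]
  for (j in seq_len(npc)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(sv$d[seq_len(npc)], npc)
  dimnames(scores) <- list(rownames(expr), paste0("PC", seq_len(npc)))
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(npc)))
  list(scores = scores, loadings = v,
       sdev = sv$d / sqrt(max(1, nrow(xc) - 1)), genes_used = colnames(x))
}
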