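random_multiline <- function(n_genes = 150, n_lines = 5) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  lines <- lapply(seq_len(n_lines), function(i) {
    data.frame(gene_id = genes, log2fc = rnorm(n_genes),
               padj = runif(n_genes), stringsAsFactors = FALSE)
  })
  lrt <- data.frame(gene_id = genes, padj = runif(n_genes),
                    stringsAsFactors = FALSE)
  list(lines = lines, lrt = lrt)
}

test_that("core filter applies the pairwise and joint thresholds", {
  genes <- c("hit", "flip", "weak")
  lines <- lapply(list(
    c(0.09, 0.02, 0.09), c(0.05, 0.03, 0.05), c(0.01, 0.01, 0.01),
    c(0.08, 0.04, 0.08), c(0.099, 0.02, 0.15)), function(p) {
      data.frame(gene_id = genes, log2fc = c(1, 1, 1), padj = p)
    })
  lines[[3]]$log2fc <- c(1, -1, 1)   # "flip" changes direction in one line
  lrt <- data.frame(gene_id = genes, padj = c(0.049, 0.001, 0.001))
  core <- core_consensus_filter(lines, lrt)
  expect_equal(core$core_up, "hit")
  expect_equal(core$core_down, character(0))
})

test_that("core filter equals the set-algebra oracle and is monotone in both alphas", {
  set.seed(31)
  for (rep in 1:30) {
    m <- random_multiline()
    got <- core_consensus_filter(m$lines, m$lrt, 0.4, 0.4)
    # row-wise boolean oracle
    padj_ok <- Reduce(`&`, lapply(m$lines, function(l) l$padj < 0.4))
    up_ok <- Reduce(`&`, lapply(m$lines, function(l) l$log2fc > 0))
    dn_ok <- Reduce(`&`, lapply(m$lines, function(l) l$log2fc < 0))
    lrt_ok <- m$lrt$padj < 0.4
    expect_equal(got$core_up, m$lrt$gene_id[padj_ok & up_ok & lrt_ok])
    expect_equal(got$core_down, m$lrt$gene_id[padj_ok & dn_ok & lrt_ok])
    expect_length(intersect(got$core_up, got$core_down), 0)
    loose <- core_consensus_filter(m$lines, m$lrt, 0.6, 0.6)
    expect_true(all(got$core_up %in% loose$core_up))
    expect_true(all(got$core_down %in% loose$core_down))
  }
})

test_that("rank metric computes signed log p and orders deterministically", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   log2fc = c(2, -1, 0.5),
                   pvalue = c(0.01, 0.1, 1))
  r <- rank_metric(de, "signed_logp")
  expect_equal(r$score[r$gene_id == "a"], 2)
  expect_equal(r$score[r$gene_id == "b"], -1)
  expect_equal(r$score[r$gene_id == "c"], 0)
  expect_equal(r$gene_id, c("a", "c", "b"))   # descending score
  de0 <- data.frame(gene_id = c("a", "b"), log2fc = c(1, -1),
                    pvalue = c(0, 0.5))
  expect_message(r0 <- rank_metric(de0), "clamped")
  expect_true(is.finite(r0$score[1]))
  ds <- data.frame(gene_id = c("a", "b"), log2fc = c(1, 1),
                   pvalue = c(0.5, 0.5), stat = c(-3, 5))
  expect_equal(rank_metric(ds, "stat")$gene_id, c("b", "a"))
})

test_that("GSEA hits-at-extremes reach |ES| = 1 and survive bottom padding", {
  ranked <- data.frame(gene_id = sprintf("g%02d", 1:10),
                       score = seq(5, -4, length.out = 10))
  top <- gsea_preranked(ranked, c("g01", "g02"), weight = 0,
                        n_perm = 100, seed = 1)
  expect_equal(top$es, 1)
  expect_setequal(top$leading_edge, c("g01", "g02"))
  bottom <- gsea_preranked(ranked, c("g09", "g10"), weight = 0,
                           n_perm = 100, seed = 1)
  expect_equal(bottom$es, -1)
  expect_setequal(bottom$leading_edge, c("g09", "g10"))
  # appending genes below every member keeps ES at 1
  padded <- rbind(ranked, data.frame(gene_id = sprintf("x%02d", 1:15),
                                     score = seq(-5, -8, length.out = 15)))
  expect_equal(gsea_preranked(padded, c("g01", "g02"), weight = 0,
                              n_perm = 100, seed = 1)$es, 1)
  expect_error(gsea_preranked(ranked, c("zz"), n_perm = 100), "intersect")
})

test_that("GSEA running sum matches fgsea on random inputs", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  for (rep in 1:10) {
    n <- 200
    ranked <- data.frame(gene_id = sprintf("g%03d", 1:n),
                         score = sort(rnorm(n), decreasing = TRUE))
    gs <- sample(ranked$gene_id, 20)
    mine <- gsea_preranked(ranked, gs, weight = 1, n_perm = 100, seed = rep)
    stats <- setNames(ranked$score, ranked$gene_id)
    ref <- fgsea::calcGseaStat(stats, selectedStats = which(names(stats) %in% gs),
                               gseaParam = 1)
    expect_equal(mine$es, ref, tolerance = 1e-8)
  }
})

test_that("quadrant concordance identifies planted correlation structure", {
  set.seed(23)
  n <- 400
  base <- rnorm(n, 0, 2)
  # realistic coupling: significance tracks effect size
  deA <- data.frame(gene_id = sprintf("g%03d", 1:n), log2fc = base,
                    padj = 2 * pnorm(-abs(base) / 1.5))
  deB_same <- deA
  self <- quadrant_concordance(deA, deB_same, alpha = 0.1)
  expect_equal(self$concordant_fraction, 1)
  deB_anti <- transform(deA, log2fc = -base)
  anti <- quadrant_concordance(deA, deB_anti, alpha = 0.1)
  expect_equal(anti$discordant_fraction, 1)
  # planted anticorrelation rho = -0.7
  lfc_b <- -0.7 * base + sqrt(1 - 0.49) * rnorm(n, 0, 2)
  deB_noise <- data.frame(gene_id = deA$gene_id, log2fc = lfc_b,
                          padj = 2 * pnorm(-abs(lfc_b) / 1.5))
  noisy <- quadrant_concordance(deA, deB_noise, alpha = 0.1)
  expect_gt(noisy$discordant_fraction, 0.8)
  expect_warning(quadrant_concordance(deA, transform(deA, padj = 1), 0.1),
                 "no genes")
})

test_that("signature PCA matches a covariance eigen-decomposition oracle", {
  set.seed(29)
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:10)))
  sig <- paste0("g", 1:10)
  got <- signature_pca(x, sig)
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc))
  # |scores| along PC1/PC2 match the eigenvector projections
  for (j in 1:2) {
    proj <- xc %*% ev$vectors[, j]
    expect_equal(unname(abs(got$scores[, j])), abs(as.vector(proj)),
                 tolerance = 1e-8)
  }
  # two identical samples score identically on PC1
  x2 <- rbind(x, x[1, , drop = FALSE])
  rownames(x2)[5] <- "s1b"
  got2 <- signature_pca(x2, sig)
  expect_equal(got2$scores["s1", "PC1"], got2$scores["s1b", "PC1"])
  # invariant to gene order (sign convention fixes orientation)
  got3 <- signature_pca(x[, sample(10)], sig)
  expect_equal(got3$scores, got$scores, tolerance = 1e-8)
  # constant genes dropped with warning
  xconst <- cbind(x, gC = rep(1, 4))
  expect_warning(signature_pca(xconst, c(sig, "gC")), "constant")
  # rank-2 reconstruction error equals the SVD oracle
  sv <- svd(xc)
  rank2 <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  recon <- got$scores %*% t(got$loadings)
  expect_equal(sum((xc - recon)^2), sum((xc - rank2)^2), tolerance = 1e-8)
})
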