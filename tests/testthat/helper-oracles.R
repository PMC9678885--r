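# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (GenomicRanges, dhyper, p.adjust)
# that the package itself uses.

# per-base boolean-mask union of intervals on a small toy chromosome
oracle_merge_mask <- function(starts, ends, chrom_len = 10000L) {
  mask <- logical(chrom_len)
  for (i in seq_along(starts)) {
    mask[(starts[i] + 1L):ends[i]] <- TRUE
  }
  r <- rle(mask)
  pos <- cumsum(c(0L, r$lengths))
  keep <- which(r$values)
  data.frame(start = pos[keep], end = pos[keep + 1L])
}

# per-peak overlap enumeration: does peak i overlap any interval in `other`?
oracle_overlaps_any <- function(starts, ends, o_starts, o_ends) {
  vapply(seq_along(starts), function(i) {
    any(starts[i] < o_ends & o_starts < ends[i])
  }, logical(1))
}

# exhaustive nearest-gene search over all genes
oracle_nearest <- function(summit, chrom, genes, max_distance) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  dd <- abs(summit - g$tss)
  g <- g[order(dd, g$gene_id), , drop = FALSE]
  if (min(dd) > max_distance) return(NULL)
  g[1, , drop = FALSE]
}

# hand-coded BH step-up, independent of p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q[i] <- min(q[i], q[i + 1])
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# full hypergeometric enumeration via choose(), independent of dhyper
oracle_fisher <- function(a, b, c, d, alternative) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  lo <- max(0, c1 - (N - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(c1, xs) * choose(N - c1, r1 - xs) / choose(N, r1)
  if (alternative == "greater") {
    sum(probs[xs >= a])
  } else {
    p_obs <- probs[xs == a]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

# random peak set on a toy chromosome
random_peak_set <- function(n, chrom_len = 10000L, set_id = "rnd",
                            min_w = 20L, max_w = 400L) {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sample.int(chrom_len - max_w - 1L, n, replace = TRUE)
  peak_set(rep("chrT", n), s, s + w,
           peak_id = sprintf("%s_%03d", set_id, seq_len(n)),
           signal = round(runif(n, 1, 100), 4), set_id = set_id)
}

# random gene models on a toy chromosome
random_genes <- function(n, chrom_len = 100000L) {
  len <- sample(500:5000, n, replace = TRUE)
  s <- sample.int(chrom_len - 6000L, n, replace = TRUE)
  gene_model(sprintf("g%03d", seq_len(n)), "chrT",
             sample(c("+", "-"), n, replace = TRUE), s, s + len)
}
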