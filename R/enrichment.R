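#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric exact test on the table
#' \preformatted{ a  b
#'  c  d }
#' with fixed margins. `"greater"` (overrepresentation of `a`, the one-way
#' test used for enrichment bars) sums the upper tail; `"two_sided"` sums all
#' tables at most as probable as the observed one. The odds ratio is the
#' unconditional sample estimate `(a*d)/(b*c)`, with `Inf` allowed.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return list with `odds_ratio` and `pvalue`.
#' @examples
#' fisher_2x2(9, 1, 1, 9, "greater")
#' @export
fisher_2x2 <- function(a, b, c, d, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative")
  }
  if (sum(counts) == 0) stop("all margins are zero")
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  lo <- max(0, c1 - (N - r1))
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- dhyper(xs, c1, N - c1, r1)
  if (alternative == "greater") {
    p <- sum(probs[xs >= a])
  } else {
    p_obs <- probs[xs == a]
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  list(odds_ratio = (a * d) / (b * c), pvalue = min(1, p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control: input order is preserved, output is
#' elementwise >= input and capped at 1. Errors on values outside (0, 1].
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return vector of adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Flag genes with at least one annotated binding event
#'
#' Converts a peak-to-gene annotation (from [nearest_gene()]) into per-gene
#' bound flags and peak counts over a gene universe.
#'
#' @param annotations data.frame with `peak_id`, `gene_id` (NA rows, i.e.
#'   unannotated peaks, are ignored).
#' @param genes a [gene_model()] table or character vector defining the gene
#'   universe.
#' @return data.frame with `gene_id`, `bound` (logical), `n_peaks`.
#' @export
flag_bound_genes <- function(annotations, genes) {
  universe <- if (is.character(genes)) genes else genes$gene_id
  ann <- annotations[!is.na(annotations$gene_id), , drop = FALSE]
  unknown <- setdiff(ann$gene_id, universe)
  if (length(unknown)) {
    stop("annotation references unknown gene(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  counts <- table(factor(ann$gene_id, levels = universe))
  data.frame(
    gene_id = universe,
    bound = as.vector(counts) > 0L,
    n_peaks = as.vector(counts),
    stringsAsFactors = FALSE
  )
}

#' Binding enrichment across expression bins
#'
#' Tests whether bound genes are overrepresented in bins of a
#' differential-expression table. Two binning modes:
#' \itemize{
#'   \item `rank_bins = k`: genes are ordered by `log2fc` (ties by gene id)
#'     and split into `k` bins of equal size (+/- 1), bin 1 = most
#'     down-regulated;
#'   \item `groups = TRUE`: genes are grouped into `up` (`padj < alpha`,
#'     `log2fc > 0`), `dn` (`padj < alpha`, `log2fc < 0`) and `ns`
#'     (raw `pvalue > 0.05`).
#' }
#' Each bin is tested against all genes outside the bin with a one-sided
#' Fisher test (`greater`, overrepresentation), and p-values are BH-adjusted
#' across the bins of the analysis.
#'
#' @param de data.frame with `gene_id`, `log2fc`, `pvalue` and (for groups
#'   mode) `padj`.
#' @param bound logical vector of bound flags aligned with `de`, or a
#'   data.frame from [flag_bound_genes()].
#' @param rank_bins number of equal-size bins (>= 2), or `NULL`.
#' @param groups if `TRUE`, use the up/dn/ns grouping instead of rank bins.
#' @param alpha adjusted-p cutoff for the up/dn groups (default 0.05).
#' @param alternative Fisher alternative per bin.
#' @return data.frame of class `enrichment_result` with one row per bin:
#'   `bin_label`, `n_genes`, `n_bound`, `background_n`, `background_bound`,
#'   `odds_ratio`, `pvalue`, `padj`.
#' @export
binned_binding_enrichment <- function(de, bound, rank_bins = NULL,
                                      groups = FALSE, alpha = 0.05,
                                      alternative = "greater") {
  if (is.data.frame(bound)) {
    bound <- bound$bound[match(de$gene_id, bound$gene_id)]
  }
  stopifnot(length(bound) == nrow(de), is.logical(bound))
  if (groups) {
    lab <- rep(NA_character_, nrow(de))
    lab[!is.na(de$padj) & de$padj < alpha & de$log2fc > 0] <- "up"
    lab[!is.na(de$padj) & de$padj < alpha & de$log2fc < 0] <- "dn"
    lab[is.na(lab) & de$pvalue > 0.05] <- "ns"
    bins <- factor(lab, levels = c("dn", "ns", "up"))
  } else {
    if (is.null(rank_bins) || rank_bins < 2) {
      stop("supply rank_bins >= 2 or groups = TRUE")
    }
    k <- as.integer(rank_bins)
    ord <- order(de$log2fc, de$gene_id)
    n <- nrow(de)
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    idx <- rep(seq_len(k), sizes)
    lab <- character(n)
    lab[ord] <- sprintf("bin_%02d", idx)
    bins <- factor(lab, levels = sprintf("bin_%02d", seq_len(k)))
  }
  total_bound <- sum(bound, na.rm = TRUE)
  res <- lapply(levels(bins), function(bl) {
    inb <- !is.na(bins) & bins == bl
    ng <- sum(inb)
    nb <- sum(bound[inb])
    bg_n <- nrow(de) - ng
    bg_b <- total_bound - nb
    if (ng == 0L) {
      warning("empty bin: ", bl)
      or <- NA_real_; p <- 1
    } else {
      ft <- fisher_2x2(nb, ng - nb, bg_b, bg_n - bg_b,
                       alternative = alternative)
      or <- ft$odds_ratio; p <- ft$pvalue
    }
    data.frame(bin_label = bl, n_genes = ng, n_bound = nb,
               background_n = bg_n, background_bound = bg_b,
               odds_ratio = or, pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$pvalue)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Chi-squared test of homogeneity with adjusted standardized residuals
#'
#' Pearson chi-squared test of an R x K contingency table against
#' independence of rows and columns, with `df = (R-1)(K-1)` (e.g. 6
#' cell-cycle categories against 2 conditions give df = 5; 5 populations give
#' df = 4). Residuals are the adjusted standardized residuals
#' `(O - E) / sqrt(E (1 - rowfrac) (1 - colfrac))`, whose magnitudes show the
#' relative contribution of each cell.
#'
#' @param counts nonnegative matrix; every row and column margin must be > 0.
#' @return list of class `contingency_result`: `statistic`, `df`, `pvalue`,
#'   `std_residuals`, `expected`.
#' @export
chisq_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0)) stop("zero row margin at row ", which(rs == 0)[1])
  if (any(cs == 0)) stop("zero column margin at column ", which(cs == 0)[1])
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  out <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
              pvalue = ct$p.value, std_residuals = ct$stdres,
              expected = ct$expected)
  class(out) <- "contingency_result"
  out
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Chi-squared = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$pvalue))
  cat("adjusted standardized residuals:\n")
  print(round(x$std_residuals, 2))
  invisible(x)
}

#' Co-occurrence of two binding flags over a shared gene universe
#'
#' Cross-tabulates two per-gene boolean flags (e.g. bound by the fusion,
#' bound by another factor) and applies Fisher's exact test.
#'
#' @param flagsA,flagsB logical vectors over the same gene universe; if
#'   named, names must agree.
#' @param alternative Fisher alternative (default two-sided).
#' @return list with `odds_ratio`, `pvalue` and the 2x2 `table`.
#' @export
gene_set_cooccurrence <- function(flagsA, flagsB, alternative = "two_sided") {
  if (length(flagsA) != length(flagsB)) stop("gene universes differ in size")
  if (!is.null(names(flagsA)) && !is.null(names(flagsB)) &&
      !identical(names(flagsA), names(flagsB))) {
    stop("gene universes differ (names mismatch)")
  }
  a <- sum(flagsA & flagsB); b <- sum(flagsA & !flagsB)
  c_ <- sum(!flagsA & flagsB); d <- sum(!flagsA & !flagsB)
  ft <- fisher_2x2(a, b, c_, d, alternative = alternative)
  list(odds_ratio = ft$odds_ratio, pvalue = ft$pvalue,
       table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                      dimnames = list(A = c("TRUE", "FALSE"),
                                      B = c("TRUE", "FALSE"))))
}
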