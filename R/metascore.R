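#' Bin genes by a meta-analysis score
#'
#' Assigns each gene to a half-open bin `[e_i, e_{i+1})` of the chosen score
#' column. Use `-Inf`/`Inf` edges for open-ended first/last bins; genes
#' outside the edge range are reported and left unassigned (`NA`).
#'
#' @param table data.frame with `gene_id` and the score column.
#' @param score column name, typically `"cc_count"` (number of studies
#'   calling the gene a cell-cycle gene) or `"p53_score"`.
#' @param edges strictly increasing numeric vector of bin edges.
#' @return list: `bins` (factor aligned with `table`, labelled
#'   `[e_i,e_{i+1})`), `n_out_of_range`.
#' @export
bin_by_score <- function(table, score = c("cc_count", "p53_score"),
                         edges) {
  score <- if (length(score) == 1L) score else match.arg(score)
  if (!score %in% names(table)) stop("no column '", score, "' in table")
  if (length(edges) < 2L || any(diff(edges) <= 0)) {
    stop("edges must be strictly increasing with length >= 2")
  }
  x <- table[[score]]
  idx <- findInterval(x, edges)           # 0 below, length(edges) at/above top
  idx[x >= edges[length(edges)]] <- 0L    # top edge exclusive
  out_of_range <- sum(idx == 0L | is.na(idx))
  if (out_of_range > 0) {
    message(out_of_range, " gene(s) outside the bin range")
  }
  labs <- sprintf("[%g,%g)", edges[-length(edges)], edges[-1])
  bins <- factor(ifelse(idx >= 1L & idx < length(edges), labs[idx], NA),
                 levels = labs)
  list(bins = bins, n_out_of_range = out_of_range)
}

#' Per-bin mean fold change with t confidence intervals
#'
#' For each bin, the mean log2 fold change with a symmetric t interval
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)` (default 90% confidence,
#' matching mean +/- 90% CI summaries), plus the bound-gene fraction when
#' binding flags are supplied. Singleton bins report the mean with an `NA`
#' interval.
#'
#' @param bins factor of bin assignments (NA = unassigned).
#' @param lfc per-gene log2 fold change aligned with `bins`.
#' @param level confidence level (default 0.90).
#' @param bound optional logical bound flags aligned with `bins`.
#' @return data.frame of class `bin_summary`: `bin_label`, `n`, `mean_lfc`,
#'   `ci_low`, `ci_high`, and `bound_fraction` when flags are given.
#' @export
binned_mean_ci <- function(bins, lfc, level = 0.90, bound = NULL) {
  stopifnot(length(bins) == length(lfc))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  res <- lapply(levels(bins), function(bl) {
    x <- lfc[!is.na(bins) & bins == bl]
    n <- length(x)
    if (n == 0L) {
      row <- data.frame(bin_label = bl, n = 0L, mean_lfc = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_)
    } else if (n == 1L) {
      row <- data.frame(bin_label = bl, n = 1L, mean_lfc = x,
                        ci_low = NA_real_, ci_high = NA_real_)
    } else {
      hw <- qt((1 + level) / 2, df = n - 1) * sd(x) / sqrt(n)
      row <- data.frame(bin_label = bl, n = n, mean_lfc = mean(x),
                        ci_low = mean(x) - hw, ci_high = mean(x) + hw)
    }
    if (!is.null(bound)) {
      b <- bound[!is.na(bins) & bins == bl]
      row$bound_fraction <- if (n > 0) mean(b) else NA_real_
    }
    row
  })
  out <- do.call(rbind, res)
  class(out) <- c("bin_summary", "data.frame")
  out
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 0.01, "**",
  ifelse(p < 0.05, "*", "ns"))))
}

#' Group genes by p53 score and test fold-change shifts
#'
#' Partitions genes into three exhaustive groups by the signed p53
#' meta-analysis score -- `cell_cycle` (score <= -cutoff; p53-downregulated
#' cell-cycle genes), `apoptosis_dd` (score >= cutoff; p53-induced
#' apoptosis / DNA-damage genes) and `control` (in between) -- and compares
#' the fold-change distribution of each non-control group against control
#' with a two-sided unpaired Welch t-test. Significance bands: `*` p < 0.05,
#' `**` < 0.01, `***` < 0.001, `****` < 0.0001.
#'
#' @param table data.frame with `gene_id` and `p53_score`.
#' @param lfc per-gene log2 fold change aligned with `table`.
#' @param cutoff score magnitude defining the outer groups (default 17).
#' @return list: `groups` (factor aligned with `table`) and `tests`
#'   (data.frame: group, n, mean_lfc, t, df, pvalue, stars).
#' @export
score_group_tests <- function(table, lfc, cutoff = 17) {
  stopifnot("p53_score" %in% names(table), length(lfc) == nrow(table))
  s <- table$p53_score
  groups <- factor(ifelse(s <= -cutoff, "cell_cycle",
                   ifelse(s >= cutoff, "apoptosis_dd", "control")),
                   levels = c("cell_cycle", "control", "apoptosis_dd"))
  ctl <- lfc[groups == "control"]
  res <- lapply(c("cell_cycle", "apoptosis_dd"), function(g) {
    x <- lfc[groups == g]
    if (length(x) < 2L || length(ctl) < 2L) {
      warning("group '", g, "' or control too small; test skipped")
      return(data.frame(group = g, n = length(x), mean_lfc = mean(x),
                        t = NA_real_, df = NA_real_, pvalue = NA_real_,
                        stars = NA_character_))
    }
    tt <- t.test(x, ctl, alternative = "two.sided", var.equal = FALSE)
    data.frame(group = g, n = length(x), mean_lfc = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               pvalue = tt$p.value, stars = significance_stars(tt$p.value),
               stringsAsFactors = FALSE)
  })
  list(groups = groups, tests = do.call(rbind, res))
}
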