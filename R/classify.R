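#' Counts-per-million normalization
#'
#' @param counts nonnegative per-feature read counts.
#' @param library_size total mapped reads (> 0).
#' @return `counts * 1e6 / library_size`.
#' @export
cpm_normalize <- function(counts, library_size) {
  if (length(library_size) != 1L || !is.finite(library_size) ||
      library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  counts * 1e6 / library_size
}

#' Classify dual-factor binding sites from CPM signal
#'
#' For each peak with CPM signal for the native factor (`cpm_a`, RUNX1-like)
#' and the fusion (`cpm_b`), computes the pseudocounted log ratio
#' `r = log2((cpm_b + pseudocount) / (cpm_a + pseudocount))` and assigns
#' \itemize{
#'   \item `ER`    if `r >= tau` (more highly bound by the fusion),
#'   \item `R1`    if `r <= -tau` (more highly bound by the native factor),
#'   \item `R1_ER` otherwise (similarly bound by both).
#' }
#'
#' @param table data.frame with `peak_id`, `cpm_a`, `cpm_b`.
#' @param tau log2-ratio threshold (> 0; default 1, i.e. 2-fold).
#' @param pseudocount added to both CPM values (> 0; default 0.5).
#' @return the input with added `log2_ratio` and `class_label` columns;
#'   `tau` and `pseudocount` are recorded as attributes.
#' @export
classify_peaks <- function(table, tau = 1, pseudocount = 0.5) {
  stopifnot(all(c("peak_id", "cpm_a", "cpm_b") %in% names(table)))
  if (tau <= 0) stop("tau must be > 0")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  r <- log2((table$cpm_b + pseudocount) / (table$cpm_a + pseudocount))
  table$log2_ratio <- r
  table$class_label <- ifelse(r >= tau, "ER", ifelse(r <= -tau, "R1", "R1_ER"))
  attr(table, "tau") <- tau
  attr(table, "pseudocount") <- pseudocount
  table
}

#' Sweep the classification threshold
#'
#' Class counts as a function of the log-ratio threshold `tau`, for assessing
#' sensitivity of the three-way classification to the cutoff.
#'
#' @param table as for [classify_peaks()].
#' @param taus numeric vector of thresholds.
#' @param pseudocount see [classify_peaks()].
#' @return data.frame with one row per `tau`: counts of R1, ER, R1_ER.
#' @export
classify_tau_sweep <- function(table, taus = seq(0.25, 2, by = 0.25),
                               pseudocount = 0.5) {
  do.call(rbind, lapply(taus, function(tt) {
    cl <- classify_peaks(table, tau = tt, pseudocount = pseudocount)$class_label
    data.frame(tau = tt,
               n_R1 = sum(cl == "R1"),
               n_ER = sum(cl == "ER"),
               n_R1_ER = sum(cl == "R1_ER"))
  }))
}

#' Per-peak signal change between conditions
#'
#' Log2 change of CPM signal for the same peaks under two conditions (e.g. an
#' IP in the presence versus absence of a competing factor), summarised per
#' binding class.
#'
#' @param control,treated data.frames with `peak_id` and `cpm` columns over
#'   the identical peak universe.
#' @param classes optional per-peak class labels aligned with `control`
#'   (e.g. from [classify_peaks()]).
#' @param pseudocount added to both CPM values.
#' @return list with `delta` (per-peak data.frame) and `summary` (mean delta
#'   and count per class; single class "all" when no classes given).
#' @export
condition_delta <- function(control, treated, classes = NULL,
                            pseudocount = 0.5) {
  stopifnot(all(c("peak_id", "cpm") %in% names(control)),
            all(c("peak_id", "cpm") %in% names(treated)))
  if (!setequal(control$peak_id, treated$peak_id) ||
      nrow(control) != nrow(treated)) {
    stop("control and treated must cover the identical peak universe")
  }
  tr <- treated[match(control$peak_id, treated$peak_id), , drop = FALSE]
  delta <- log2((tr$cpm + pseudocount) / (control$cpm + pseudocount))
  cls <- if (is.null(classes)) rep("all", nrow(control)) else as.character(classes)
  per_peak <- data.frame(peak_id = control$peak_id, class_label = cls,
                         delta = delta, stringsAsFactors = FALSE)
  agg <- aggregate(delta ~ class_label, data = per_peak,
                   FUN = function(x) c(mean = mean(x), n = length(x)))
  summary <- data.frame(class_label = agg$class_label,
                        mean_delta = agg$delta[, "mean"],
                        n = as.integer(agg$delta[, "n"]),
                        stringsAsFactors = FALSE)
  list(delta = per_peak, summary = summary)
}

#' Class proportions across ranked bins
#'
#' Orders peaks by a signed significance statistic (most significantly
#' down-regulated first, i.e. ascending `sign(log2fc) * -log10(p)`), splits
#' them into `k` bins of equal size (+/- 1, ties broken by peak id) and
#' tabulates per-bin class proportions.
#'
#' @param rank_stat finite numeric per-peak statistic.
#' @param classes per-peak class labels.
#' @param k number of bins (default 11).
#' @param peak_ids optional ids used for deterministic tie-breaking.
#' @return data.frame of class `ranked_bin_table`: `bin_index`,
#'   `n`, `mean_rank_stat`, one count and one proportion column per class.
#' @export
ranked_bin_proportions <- function(rank_stat, classes, k = 11,
                                   peak_ids = NULL) {
  n <- length(rank_stat)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of peaks (", n, ")")
  if (any(!is.finite(rank_stat))) stop("rank_stat must be finite")
  stopifnot(length(classes) == n)
  if (is.null(peak_ids)) peak_ids <- sprintf("peak_%06d", seq_len(n))
  ord <- order(rank_stat, peak_ids)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  bin <- integer(n)
  bin[ord] <- rep(seq_len(k), sizes)
  lv <- sort(unique(as.character(classes)))
  tab <- table(factor(bin, levels = seq_len(k)),
               factor(classes, levels = lv))
  props <- tab / rowSums(tab)
  out <- data.frame(bin_index = seq_len(k),
                    n = as.integer(rowSums(tab)),
                    mean_rank_stat = as.vector(tapply(rank_stat, bin, mean)))
  for (cl in lv) {
    out[[paste0("n_", cl)]] <- as.integer(tab[, cl])
    out[[paste0("prop_", cl)]] <- as.numeric(props[, cl])
  }
  class(out) <- c("ranked_bin_table", "data.frame")
  out
}

#' Write classified peaks with the parameters embedded as header comments
#'
#' @param table output of [classify_peaks()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_classified_peaks <- function(table, path) {
  write_tsv(as.data.frame(table), path,
            comments = c(paste0("tau=", attr(table, "tau")),
                         paste0("pseudocount=", attr(table, "pseudocount"))))
}
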