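#' Construct a peak set
#'
#' A peak set is a data frame of genomic intervals in 0-based half-open (BED)
#' coordinates with one row per peak, plus a set identifier (typically the
#' sample or antibody the peaks were called from). Summits are stored as
#' offsets from the interval start, following the narrowPeak convention;
#' `NA` means the summit is unknown and the interval midpoint is used
#' wherever a summit is required.
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer vectors; 0-based inclusive start, exclusive end.
#' @param peak_id peak labels, unique within the set. Generated
#'   (`<set_id>_peak_<i>`) when omitted.
#' @param signal nonnegative per-peak signal (pileup or CPM units).
#' @param summit_offset integer offset of the summit from `start`, or `NA`.
#' @param set_id label for the whole set.
#' @return A `data.frame` of class `peak_set` with columns `chrom`, `start`,
#'   `end`, `peak_id`, `signal`, `summit_offset` and attribute `set_id`.
#' @examples
#' peak_set("chr1", 100, 200, signal = 5, summit_offset = 50)
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL, signal = 0,
                     summit_offset = NA_integer_, set_id = "peaks") {
  n <- length(start)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(end) != n) stop("start and end lengths differ")
  if (is.null(peak_id)) peak_id <- sprintf("%s_peak_%d", set_id, seq_len(n))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n), start = start, end = end,
    peak_id = as.character(peak_id),
    signal = rep_len(as.numeric(signal), n),
    summit_offset = rep_len(as.integer(summit_offset), n),
    stringsAsFactors = FALSE
  )
  validate_peak_set(df)
  attr(df, "set_id") <- set_id
  class(df) <- c("peak_set", "data.frame")
  df
}

validate_peak_set <- function(df) {
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    stop("malformed interval (start >= end) for peak_id: ",
         paste(df$peak_id[bad], collapse = ", "))
  }
  if (anyDuplicated(df$peak_id)) {
    stop("peak_ids are not unique within the set")
  }
  off <- df$summit_offset
  ok <- is.na(off) | (off >= 0L & off < (df$end - df$start))
  if (!all(ok)) {
    stop("summit_offset outside interval for peak_id: ",
         paste(df$peak_id[!ok], collapse = ", "))
  }
  invisible(df)
}

set_id <- function(x) attr(x, "set_id")

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    peak_id = x$peak_id
  )
}

#' Summit position of each peak
#'
#' Returns the absolute 0-based summit coordinate: `start + summit_offset`
#' when a summit is recorded, otherwise the interval midpoint
#' `floor((start + end) / 2)`.
#'
#' @param peaks a [peak_set()].
#' @return integer vector of summit positions.
#' @export
summit_position <- function(peaks) {
  mid <- (peaks$start + peaks$end) %/% 2L
  ifelse(is.na(peaks$summit_offset), mid,
         peaks$start + peaks$summit_offset)
}

#' Merge overlapping intervals within a peak set
#'
#' Collapses a peak set to disjoint, sorted intervals covering exactly the
#' union of the input bases. The merged signal is the maximum over the merged
#' constituents; the summit (and peak id) are taken from the highest-signal
#' constituent.
#'
#' @param peaks a [peak_set()].
#' @return a disjoint, sorted [peak_set()].
#' @examples
#' ps <- peak_set("chr1", c(100, 150), c(200, 250), signal = c(1, 2))
#' merge_intervals(ps)
#' @export
merge_intervals <- function(peaks) {
  validate_peak_set(peaks)
  if (nrow(peaks) == 0L) return(peaks)
  gr <- as_granges(peaks)
  red <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(red, gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # per merged interval, index of the highest-signal constituent
  ord <- order(qh, -peaks$signal[sh], peaks$peak_id[sh])
  top <- sh[ord][!duplicated(qh[ord])]
  sig <- tapply(peaks$signal[sh], qh, max)
  new_start <- GenomicRanges::start(red) - 1L
  summit <- summit_position(peaks)[top]
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = new_start,
    end = GenomicRanges::end(red),
    peak_id = peaks$peak_id[top],
    signal = as.numeric(sig),
    summit_offset = ifelse(is.na(peaks$summit_offset[top]),
                           NA_integer_, as.integer(summit - new_start)),
    stringsAsFactors = FALSE
  )
  ord2 <- order(out$chrom, out$start)
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "set_id") <- set_id(peaks)
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Filter reference peaks by support in other peak sets
#'
#' Retains reference peaks overlapped by at least `min_support` of the other
#' peak sets, the operation behind high-confidence consensus sites (e.g.
#' peaks supported by independent antibodies and open chromatin). Overlap is
#' any shared base by default; `min_frac` optionally requires the overlap to
#' cover at least that fraction of the reference peak.
#'
#' @param reference a [peak_set()].
#' @param others list of [peak_set()] objects.
#' @param min_support minimum number of supporting sets (<= length(others)).
#' @param min_frac minimum overlap fraction of the reference peak width
#'   required for a set to count as supporting (default 0 = any overlap).
#' @return the retained subset of `reference` with an added `support` column.
#' @export
support_filter <- function(reference, others, min_support, min_frac = 0) {
  validate_peak_set(reference)
  if (!is.list(others) || length(others) == 0L)
    stop("'others' must be a non-empty list of peak sets")
  if (min_support > length(others))
    stop("min_support (", min_support, ") exceeds number of other sets (",
         length(others), ")")
  if (nrow(reference) == 0L) {
    warning("empty reference peak set")
    out <- reference
    out$support <- integer(0)
    return(out)
  }
  ref_gr <- as_granges(reference)
  w <- reference$end - reference$start
  support <- integer(nrow(reference))
  for (other in others) {
    validate_peak_set(other)
    if (nrow(other) == 0L) next
    ogr <- as_granges(other)
    hits <- GenomicRanges::findOverlaps(ref_gr, ogr)
    if (min_frac > 0) {
      ov <- GenomicRanges::width(GenomicRanges::pintersect(
        ref_gr[S4Vectors::queryHits(hits)], ogr[S4Vectors::subjectHits(hits)]))
      keep <- ov >= min_frac * w[S4Vectors::queryHits(hits)]
      hit_idx <- unique(S4Vectors::queryHits(hits)[keep])
    } else {
      hit_idx <- unique(S4Vectors::queryHits(hits))
    }
    support[hit_idx] <- support[hit_idx] + 1L
  }
  out <- reference[support >= min_support, , drop = FALSE]
  out$support <- support[support >= min_support]
  rownames(out) <- NULL
  attr(out, "set_id") <- set_id(reference)
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Fixed-width windows centered on peak summits
#'
#' Returns windows of odd width `width` centered on each peak summit
#' (midpoint when no summit is recorded), clipped at position 0. Used e.g.
#' for motif scans in 501 bp windows or signal heatmaps in 3 kb windows.
#'
#' @param peaks a [peak_set()].
#' @param width odd window width in bases.
#' @return a [peak_set()] of windows (same peak ids and signal).
#' @examples
#' summit_window(peak_set("chr1", 100, 200, summit_offset = 50), width = 501)
#' @export
summit_window <- function(peaks, width) {
  validate_peak_set(peaks)
  if (width < 1 || width %% 2L == 0L) stop("width must be a positive odd integer")
  half <- (width - 1L) %/% 2L
  s <- summit_position(peaks)
  new_start <- pmax(0L, s - half)
  new_end <- s + half + 1L
  out <- peaks
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_end)
  out$summit_offset <- as.integer(s - new_start)
  out
}

#' Construct a gene model table
#'
#' Strand-aware gene bodies in 0-based half-open coordinates. The TSS is
#' derived from the strand: `body_start` for `+` genes, `body_end - 1` for
#' `-` genes.
#'
#' @param gene_id gene labels (unique).
#' @param chrom chromosome labels.
#' @param strand `"+"` or `"-"`.
#' @param body_start,body_end 0-based inclusive start, exclusive end.
#' @return data.frame of class `gene_model` with a derived `tss` column.
#' @export
gene_model <- function(gene_id, chrom, strand, body_start, body_end) {
  body_start <- as.integer(body_start)
  body_end <- as.integer(body_end)
  if (any(!(body_start < body_end))) stop("body_start must be < body_end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(gene_id)) stop("gene_ids must be unique")
  df <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    strand = as.character(strand),
    body_start = body_start, body_end = body_end,
    tss = ifelse(strand == "+", body_start, body_end - 1L),
    stringsAsFactors = FALSE
  )
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Annotate peaks to their nearest gene
#'
#' Maps each peak summit to the gene with the smallest absolute summit-to-TSS
#' distance within `max_distance`, with ties broken by smaller distance then
#' lexicographic gene id. The signed distance is negative when the summit
#' lies 5' (upstream) of the TSS relative to the gene's strand. Each peak is
#' then categorised:
#' \itemize{
#'   \item `tss` if `|d| <= tss_cutoff` (default 1 kb);
#'   \item `intragenic` if the summit falls inside the gene body (and not tss);
#'   \item `upstream_proximal` if `-proximal_cutoff <= d < -tss_cutoff`;
#'   \item `upstream_distal` if `d < -proximal_cutoff` (default 10 kb);
#'   \item `downstream` otherwise.
#' }
#' Peaks with no gene within `max_distance` get an `NA` annotation; their
#' count is reported via a message.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_model()] table.
#' @param max_distance maximum summit-to-TSS distance considered (default 100 kb).
#' @param tss_cutoff,proximal_cutoff category boundaries in bases.
#' @return data.frame with columns `peak_id`, `gene_id`, `signed_distance`,
#'   `category`.
#' @export
nearest_gene <- function(peaks, genes, max_distance = 1e5,
                         tss_cutoff = 1000, proximal_cutoff = 10000) {
  validate_peak_set(peaks)
  stopifnot(inherits(genes, "gene_model") || all(
    c("gene_id", "chrom", "strand", "body_start", "body_end", "tss") %in%
      names(genes)))
  summit <- summit_position(peaks)
  n <- nrow(peaks)
  gidx <- rep(NA_integer_, n)
  for (ch in unique(peaks$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    pi <- which(peaks$chrom == ch)
    if (nrow(g) == 0L) next
    # collapse genes sharing a TSS to the lexicographically smallest gene_id
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    first <- !duplicated(g$tss)
    gu <- g[first, , drop = FALSE]
    gpos <- which(genes$chrom == ch)[order(genes$tss[genes$chrom == ch],
                                           genes$gene_id[genes$chrom == ch])][first]
    s <- summit[pi]
    left <- findInterval(s, gu$tss)          # last tss <= s (0 if none)
    right <- left + 1L
    dl <- ifelse(left >= 1L, abs(s - gu$tss[pmax(left, 1L)]), Inf)
    dr <- ifelse(right <= nrow(gu), abs(gu$tss[pmin(right, nrow(gu))] - s), Inf)
    pick_left <- dl < dr |
      (dl == dr & left >= 1L & right <= nrow(gu) &
         gu$gene_id[pmax(left, 1L)] < gu$gene_id[pmin(right, nrow(gu))])
    best <- ifelse(pick_left, pmax(left, 1L), pmin(right, nrow(gu)))
    bestd <- pmin(dl, dr)
    ok <- is.finite(bestd) & bestd <= max_distance
    gidx[pi[ok]] <- gpos[best[ok]]
  }
  miss <- sum(is.na(gidx))
  if (miss > 0) message(miss, " peak(s) had no gene within ", max_distance, " bases")
  d <- rep(NA_real_, n)
  cat_ <- rep(NA_character_, n)
  ok <- !is.na(gidx)
  if (any(ok)) {
    g <- genes[gidx[ok], , drop = FALSE]
    s <- summit[ok]
    dd <- ifelse(g$strand == "+", s - g$tss, g$tss - s)
    inside <- s >= g$body_start & s < g$body_end
    cc <- ifelse(abs(dd) <= tss_cutoff, "tss",
          ifelse(inside, "intragenic",
          ifelse(dd < -proximal_cutoff, "upstream_distal",
          ifelse(dd < -tss_cutoff, "upstream_proximal", "downstream"))))
    d[ok] <- dd
    cat_[ok] <- cc
  }
  data.frame(
    peak_id = peaks$peak_id,
    gene_id = ifelse(is.na(gidx), NA_character_, genes$gene_id[gidx]),
    signed_distance = d,
    category = cat_,
    stringsAsFactors = FALSE
  )
}
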