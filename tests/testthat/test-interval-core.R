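test_that("peak_set validates intervals and summits", {
  expect_error(peak_set("chr1", 200, 100, peak_id = "bad1"), "bad1")
  expect_error(peak_set("chr1", 100, 200, summit_offset = 150), "summit_offset")
  expect_error(peak_set("chr1", c(1, 1), c(10, 10), peak_id = c("a", "a")),
               "unique")
  ps <- peak_set("chr1", 100, 200, summit_offset = 50)
  expect_s3_class(ps, "peak_set")
  expect_equal(summit_position(ps), 150)
  expect_equal(summit_position(peak_set("chr1", 100, 201)), 150)
})

test_that("merge_intervals merges an overlapping pair and is idempotent", {
  ps <- peak_set("chr1", c(100, 150), c(200, 250), signal = c(3, 7),
                 summit_offset = c(10, 60))
  m <- merge_intervals(ps)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100, 250))
  expect_equal(m$signal, 7)                 # max of constituents
  expect_equal(summit_position(m), 210)     # summit of the stronger peak
  disjoint <- peak_set("chr1", c(0, 500), c(100, 600))
  expect_equal(as.data.frame(merge_intervals(disjoint))[, 1:3],
               as.data.frame(disjoint)[, 1:3])
  expect_equal(merge_intervals(m), m)
})

test_that("merge_intervals equals the per-base mask oracle on random sets", {
  set.seed(42)
  for (rep in 1:40) {
    ps <- random_peak_set(50)
    m <- merge_intervals(ps)
    o <- oracle_merge_mask(ps$start, ps$end)
    expect_equal(m$start, o$start)
    expect_equal(m$end, o$end)
  }
})

test_that("support_filter matches pairwise overlap enumeration and is monotone", {
  set.seed(7)
  for (rep in 1:20) {
    ref <- random_peak_set(30, set_id = "ref")
    others <- lapply(1:3, function(i) random_peak_set(25, set_id = paste0("o", i)))
    got <- support_filter(ref, others, min_support = 2)
    sup <- rowSums(vapply(others, function(o) {
      oracle_overlaps_any(ref$start, ref$end, o$start, o$end)
    }, logical(nrow(ref))))
    expect_equal(got$peak_id, ref$peak_id[sup >= 2])
    expect_equal(got$support, unname(sup[sup >= 2]))
    n_by_support <- vapply(0:3, function(k) {
      nrow(support_filter(ref, others, min_support = k))
    }, numeric(1))
    expect_true(all(diff(n_by_support) <= 0))
  }
})

test_that("support_filter edge cases", {
  ref <- peak_set("chr1", c(100, 300), c(200, 400), set_id = "r")
  other_hit <- peak_set("chr1", c(150, 350), c(160, 360), set_id = "h")
  other_miss <- peak_set("chr1", c(5000, 6000), c(5100, 6100), set_id = "m")
  expect_equal(nrow(support_filter(ref, list(other_hit, other_hit), 2)), 2L)
  expect_equal(nrow(support_filter(ref, list(other_miss), 1)), 0L)
  expect_error(support_filter(ref, list(other_hit), min_support = 2),
               "exceeds")
  empty <- peak_set(character(0), integer(0), integer(0), set_id = "e")
  expect_warning(res <- support_filter(empty, list(other_hit), 1), "empty")
  expect_equal(nrow(res), 0L)
})

test_that("summit_window arithmetic, clipping and width-1 identity", {
  p <- peak_set("chr1", 100, 200, summit_offset = 50)
  w <- summit_window(p, 501)
  expect_equal(c(w$start, w$end), c(0, 401))   # clipped at chromosome start
  p2 <- peak_set("chr1", 4000, 6000, summit_offset = 1000)  # summit 5000
  w2 <- summit_window(p2, 3001)
  expect_equal(c(w2$start, w2$end), c(3500, 6501))
  w3 <- summit_window(p2, 1)
  expect_equal(c(w3$start, w3$end), c(5000, 5001))
  expect_error(summit_window(p, 500), "odd")
})

test_that("nearest_gene handles strand, categories and the null annotation", {
  genes <- gene_model(c("gPlus", "gMinus"), "chr1", c("+", "-"),
                      c(10000, 1000), c(12000, 2000))
  # summit exactly at the + strand TSS
  at_tss <- nearest_gene(peak_set("chr1", 9900, 10101, summit_offset = 100),
                         genes)
  expect_equal(at_tss$gene_id, "gPlus")
  expect_equal(at_tss$signed_distance, 0)
  expect_equal(at_tss$category, "tss")
  # - strand gene body [1000,2000): tss 1999; summit 2500 is 501 bp upstream,
  # within the 1 kb promoter band
  near <- nearest_gene(peak_set("chr1", 2400, 2601, summit_offset = 100),
                       genes)
  expect_equal(near$gene_id, "gMinus")
  expect_equal(near$signed_distance, -501)
  expect_equal(near$category, "tss")
  # summit 3500 is 1501 bp upstream of the - strand TSS
  up <- nearest_gene(peak_set("chr1", 3400, 3601, summit_offset = 100), genes)
  expect_equal(up$signed_distance, -1501)
  expect_equal(up$category, "upstream_proximal")
  # summit mid-body of the + gene, > 1 kb from its TSS
  mid <- nearest_gene(peak_set("chr1", 11400, 11601, summit_offset = 100),
                      genes)
  expect_equal(mid$category, "intragenic")
  # no gene within range
  expect_message(
    far <- nearest_gene(peak_set("chr1", 900000, 900201), genes,
                        max_distance = 1000),
    "no gene")
  expect_true(is.na(far$gene_id))
})

test_that("nearest_gene agrees with exhaustive search on random instances", {
  set.seed(13)
  for (rep in 1:25) {
    genes <- random_genes(50)
    peaks <- random_peak_set(200, chrom_len = 100000L)
    peaks$chrom <- "chrT"
    ann <- nearest_gene(peaks, genes, max_distance = 20000)
    summit <- summit_position(peaks)
    for (i in seq_len(nrow(peaks))) {
      o <- oracle_nearest(summit[i], "chrT", genes, 20000)
      if (is.null(o)) {
        expect_true(is.na(ann$gene_id[i]))
      } else {
        expect_equal(ann$gene_id[i], o$gene_id)
      }
    }
  }
})

test_that("annotation is strand-symmetric under coordinate reflection", {
  set.seed(99)
  L <- 100000L
  genes <- random_genes(30, chrom_len = L)
  peaks <- random_peak_set(100, chrom_len = L)
  ann <- nearest_gene(peaks, genes, max_distance = 30000)
  # reflect all coordinates and flip strands
  rgenes <- gene_model(genes$gene_id, genes$chrom,
                       ifelse(genes$strand == "+", "-", "+"),
                       L - genes$body_end, L - genes$body_start)
  rpeaks <- peak_set(peaks$chrom, L - peaks$end, L - peaks$start,
                     peak_id = peaks$peak_id, signal = peaks$signal,
                     set_id = "refl")
  # mirror the summit: original midpoint reflects to L - mid; widths odd/even
  # differences cancel because both use floor((start+end)/2) on reflected
  # intervals of the same width when width is odd; use odd widths only
  w <- peaks$end - peaks$start
  odd <- w %% 2L == 1L
  rann <- nearest_gene(rpeaks, rgenes, max_distance = 30000)
  expect_equal(rann$signed_distance[odd], ann$signed_distance[odd])
  expect_equal(rann$category[odd], ann$category[odd])
})
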