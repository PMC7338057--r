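test_that("qualifying-base rule boundaries behave as specified", {
  # 9/10 libraries non-zero (exactly 90%), mean 2.7 > 2 -> one peak
  m <- matrix(c(rep(3L, 9), 0L), nrow = 1)
  r <- call_peaks_matrix(m, positions = 100L)
  expect_equal(nrow(r$peaks), 1L)
  expect_equal(r$peaks$pas_pos, 100L)
  # mean exactly 2 fails the strict inequality
  m2 <- matrix(rep(2L, 10), nrow = 1)
  expect_equal(nrow(call_peaks_matrix(m2, 100L)$peaks), 0L)
  # 8/10 non-zero fails the 90% rule even with a high mean
  m3 <- matrix(c(rep(30L, 8), 0L, 0L), nrow = 1)
  expect_equal(nrow(call_peaks_matrix(m3, 100L)$peaks), 0L)
})

test_that("runs of qualifying bases merge and gaps split peaks", {
  # bases 10,11 qualify; 12 does not; 13 qualifies -> 2 peaks
  cnt <- rbind(rep(5L, 4), rep(5L, 4), rep(0L, 4), rep(5L, 4))
  r <- call_peaks_matrix(cnt, positions = 10:13)
  expect_equal(r$peaks$start, c(10L, 13L))
  expect_equal(r$peaks$end, c(12L, 14L))
  expect_equal(r$peaks$pas_pos, c(11L, 13L))
  # minus strand: PAS is the 5'-most genomic base of the run
  r2 <- call_peaks_matrix(cnt, positions = 10:13, strand = "-")
  expect_equal(r2$peaks$pas_pos, c(10L, 13L))
  # a coordinate gap splits runs even when all bases qualify
  r3 <- call_peaks_matrix(rbind(rep(5L, 4), rep(5L, 4)),
                          positions = c(20L, 22L))
  expect_equal(nrow(r3$peaks), 2L)
})

test_that("call_peaks matches the brute-force per-base oracle on random coverage", {
  set.seed(99)
  for (i in 1:60) {
    n_pos <- sample(5:60, 1)
    L <- sample(2:12, 1)
    pos <- sort(sample(1:200, n_pos))
    cnt <- matrix(rpois(n_pos * L, lambda = sample(c(0.5, 2, 4), 1)),
                  n_pos, L)
    got <- call_peaks_matrix(cnt, pos)
    want <- brute_force_peaks(cnt, pos)
    expect_equal(got$peaks$start, want$peaks$start)
    expect_equal(got$peaks$end, want$peaks$end)
    expect_equal(got$peaks$pas_pos, want$peaks$pas_pos)
    expect_equal(unname(got$counts), unname(want$counts))
  }
})

test_that("call_peaks pools libraries and sums per-library counts over peak spans", {
  reads <- rbind(
    data.frame(chrom = "chr1", pos = c(100L, 101L), strand = "+",
               library_id = "a", count = c(4L, 2L)),
    data.frame(chrom = "chr1", pos = c(100L, 101L), strand = "+",
               library_id = "b", count = c(3L, 5L)))
  pk <- call_peaks(reads, libraries = c("a", "b"))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 102L)
  cnt <- attr(pk, "counts")
  expect_equal(unname(cnt[1, ]), c(6, 8))
  # empty input
  empty <- call_peaks(reads[0, ], libraries = c("a", "b"))
  expect_equal(nrow(empty), 0L)
  expect_error(call_peaks(reads, libraries = "a"), ">= 2")
})

test_that("gene assignment follows the annotation hierarchy with overlap tie-breaks", {
  ann <- list(
    genes = data.frame(
      gene_id = c("geneA", "geneB", "geneC", "geneD"), chrom = "chr1",
      strand = "+", start = c(0L, 0L, 15000L, 30000L),
      end = c(1000L, 2000L, 16000L, 31000L), stringsAsFactors = FALSE),
    features = data.frame(
      gene_id = c("geneA", "geneB", "geneC", "geneD", "geneD"),
      chrom = "chr1", strand = "+",
      category = c("utr3", "intron", "intron", "exon", "utr5"),
      start = c(500L, 400L, 15000L, 30100L, 30100L),
      end = c(1000L, 1500L, 16000L, 30400L, 30400L), stringsAsFactors = FALSE))
  peaks <- data.frame(
    chrom = "chr1", strand = "+",
    start = c(600L, 15100L, 30150L), end = c(610L, 15110L, 30160L),
    pas_pos = c(609L, 15109L, 30159L), stringsAsFactors = FALSE)
  got <- assign_gene(peaks, ann)
  # 3'UTR of geneA outranks intron of geneB
  expect_equal(got$gene_id, c("geneA", "geneC", "geneD"))
  expect_equal(got$category, c("utr3", "intron", "exon"))
  # downstream-5kb beats exon but loses to 3'UTR
  pk2 <- data.frame(chrom = "chr1", strand = "+", start = 1100L, end = 1110L,
                    pas_pos = 1109L, stringsAsFactors = FALSE)
  got2 <- assign_gene(pk2, ann)   # inside geneB intron and geneA downstream
  expect_equal(got2$category, "downstream5kb")
  expect_equal(got2$gene_id, "geneA")
  # unassigned peaks stay NA
  pk3 <- data.frame(chrom = "chr1", strand = "+", start = 180000L,
                    end = 180010L, pas_pos = 180009L, stringsAsFactors = FALSE)
  expect_true(is.na(assign_gene(pk3, ann)$gene_id))
  # strand mismatch prevents assignment
  pk4 <- peaks[1, ]; pk4$strand <- "-"
  expect_true(is.na(assign_gene(pk4, ann)$gene_id))
  # invariance to annotation row order
  ann_shuffled <- ann
  set.seed(4)
  ann_shuffled$features <- ann$features[sample(nrow(ann$features)), ]
  expect_equal(assign_gene(peaks, ann_shuffled)$gene_id, got$gene_id)
})

test_that("the PAS-level mispriming filter applies the 6-run / 11-of-15 rule", {
  # the 11-of-15 window: 11 A, max run 5 (73% A, no 6-run)
  w11 <- "AAAAAGAAAAAGACC"
  stopifnot(nchar(w11) == 15,
            sum(strsplit(w11, "")[[1]] == "A") == 11,
            !grepl("AAAAAA", w11))
  seq <- paste0(strrep("C", 20), "AAAAAACGTACGTAC",
                strrep("C", 5), w11,
                strrep("C", 5), "ACGTACGTACGTACG", strrep("C", 20))
  genome <- make_genome(seq)
  pas <- data.frame(chrom = "chrT", strand = "+",
                    pas_pos = c(19L, 39L, 59L),
                    stringsAsFactors = FALSE)
  out <- filter_misprimed_pas(pas, genome)
  expect_equal(out$pas_pos, 59L)
  expect_equal(attr(out, "n_removed"), 2L)
  # exactly 10 of 15 A (66.7%) is below the 70% threshold -> retained
  w10 <- "AAAAAGAAAAAGCCC"
  genome2 <- make_genome(paste0(strrep("C", 20), w10, strrep("C", 20)))
  out2 <- filter_misprimed_pas(
    data.frame(chrom = "chrT", strand = "+", pas_pos = 19L), genome2)
  expect_equal(nrow(out2), 1L)
})

test_that("usage quantification normalizes within gene and preserves missingness", {
  cnt <- rbind(c(30L, 0L), c(70L, 0L), c(10L, 5L))
  u <- make_usage(cnt, gene_ids = c("g1", "g1", "g2"),
                  fractions = c("nuclear", "total"))
  expect_equal(unname(u$usage[1:2, 1]), c(0.3, 0.7))
  expect_equal(unname(u$usage[3, ]), c(1, 1))  # single-PAS gene
  expect_true(all(is.na(u$usage[1:2, 2])))      # zero gene total -> missing

  # quantify_usage itself: reads overlapping two peaks count in both
  pas <- data.frame(chrom = "chr1", strand = "+",
                    start = c(100L, 105L), end = c(110L, 115L),
                    pas_pos = c(109L, 114L), gene_id = "g1",
                    category = "utr3", stringsAsFactors = FALSE)
  reads <- data.frame(chrom = "chr1", pos = c(107L, 112L), strand = "+",
                      library_id = "lib1", count = c(2L, 3L),
                      stringsAsFactors = FALSE)
  samples <- data.frame(library_id = "lib1", individual = "i1",
                        fraction = "nuclear", batch = "b1",
                        stringsAsFactors = FALSE)
  q <- quantify_usage(pas, reads, samples)
  expect_equal(unname(q$counts[, 1]), c(2, 5))  # read at 107 in both peaks
  expect_error(quantify_usage(pas, transform(reads, library_id = "libX"),
                              samples), "sample sheet")
})

test_that("per-gene usage columns sum to one wherever defined", {
  u <- shared_quantified()
  for (g in unique(u$pas$gene_id)) {
    rows <- u$pas$gene_id == g
    cs <- colSums(u$usage[rows, , drop = FALSE])
    ok <- !is.na(cs)
    expect_true(all(abs(cs[ok] - 1) < 1e-9))
  }
})

test_that("low-usage filter removes only PAS below threshold in both fractions", {
  cnt <- rbind(c(6L, 94L, 1L, 99L),
               c(94L, 6L, 99L, 1L),
               c(2L, 98L, 3L, 97L),
               c(98L, 2L, 97L, 3L))
  u <- make_usage(cnt, gene_ids = c("g1", "g1", "g2", "g2"),
                  fractions = c("nuclear", "nuclear", "total", "total"))
  # PAS1: nuclear mean (0.06+0.94)/2 = 0.5 ... construct precise cases instead
  u$usage <- matrix(c(0.06, 0.06, 0.01, 0.01,    # nuclear 0.06 | total 0.01 -> keep
                      0.02, 0.02, 0.03, 0.03,    # 0.02 | 0.03 -> drop
                      0.05, 0.05, 0.05, 0.05,    # exactly 0.05 -> keep (strict "<")
                      0.87, 0.87, 0.91, 0.91),
                    nrow = 4, byrow = TRUE, dimnames = dimnames(u$usage))
  u$samples$fraction <- c("nuclear", "nuclear", "total", "total")
  out <- filter_low_usage(u)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(unname(out$usage[, 1]), c(0.06, 0.05, 0.87))
})

test_that("PAS formed at planted traps are removed even without the read filter", {
  s <- shared_study()
  pk <- call_peaks(s$reads, s$samples$library_id)   # read filter bypassed
  pk <- assign_gene(pk, truth_annotation(s$truth))
  trap_pos <- s$truth$artifacts$pos
  at_trap <- vapply(seq_len(nrow(pk)), function(i) {
    any(pk$chrom[i] == s$truth$artifacts$chrom &
          abs(pk$pas_pos[i] - trap_pos) <= 3)
  }, logical(1))
  expect_gt(sum(at_trap), 0)   # traps do form peaks without the read filter
  kept <- filter_misprimed_pas(pk, s$truth$genome)
  still <- vapply(seq_len(nrow(kept)), function(i) {
    any(kept$chrom[i] == s$truth$artifacts$chrom &
          abs(kept$pas_pos[i] - trap_pos) <= 3)
  }, logical(1))
  expect_equal(sum(still), 0L)
})
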