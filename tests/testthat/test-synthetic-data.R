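test_that("truth generation honors degenerate configs and is deterministic", {
  cfg0 <- synth_config(n_individuals = 4, n_genes = 6, qtl_fraction = 0,
                       artifact_rate = 0, seed = 11)
  tr <- generate_truth(cfg0)
  expect_equal(nrow(tr$qtl_effects), 0L)
  expect_equal(nrow(tr$artifacts), 0L)

  # no A-rich stretch downstream of any true PAS (generator constraint)
  win <- apaqtl:::.window_downstream(tr$genome, tr$pas$chrom, tr$pas$pos,
                                     tr$pas$strand, 15L)
  expect_false(any(grepl("AAAAAA", win, fixed = TRUE)))

  tr2 <- generate_truth(cfg0)
  expect_identical(tr, tr2)
  tr3 <- generate_truth(synth_config(n_individuals = 4, n_genes = 6,
                                     qtl_fraction = 0, artifact_rate = 0,
                                     seed = 12))
  expect_false(identical(tr$genome, tr3$genome))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(n_individuals = 1), "n_individuals")
  expect_error(synth_config(pas_per_gene = 1:5), "pas_per_gene")
  expect_error(synth_config(maf_range = c(0.01, 0.5)), "maf_range")
  expect_error(synth_config(intron_survival = 0), "intron_survival")
})

test_that("true PAS lie within gene spans, carry planted signal motifs and traps are A-rich", {
  tr <- shared_study()$truth
  g <- tr$genes[match(tr$pas$gene_id, tr$genes$gene_id), ]
  expect_true(all(tr$pas$pos >= g$start & tr$pas$pos < g$end + 5000L))
  expect_true(all(tr$pas$motif %in% PAS_SIGNAL_MOTIFS))
  # planted hexamer is present at the recorded upstream offset
  up <- apaqtl:::.window_upstream(tr$genome, tr$pas$chrom, tr$pas$pos,
                                  tr$pas$strand, 100L)
  starts <- nchar(up) - tr$pas$signal_offset + 1L
  planted <- substr(up, starts, starts + 5L)
  expect_identical(planted, tr$pas$motif)
  # artifact traps: >= 6 consecutive A immediately downstream
  win <- apaqtl:::.window_downstream(tr$genome, tr$artifacts$chrom,
                                     tr$artifacts$pos, tr$artifacts$strand, 10L)
  expect_true(all(grepl("AAAAAA", win, fixed = TRUE)))
  # planted QTL SNPs within the 25 kb cis window of their target PAS
  qt <- tr$qtl_effects
  tpos <- tr$pas$pos[match(qt$pas_id, tr$pas$pas_id)]
  expect_true(all(abs(qt$snp_pos - tpos) <= 25000L))
})

test_that("genotype dosages match their allele frequency and respect the MAF floor", {
  cfg <- synth_config(n_individuals = 10000, n_genes = 2,
                      maf_range = c(0.5, 0.5), n_background_snps = 2,
                      qtl_fraction = 0, seed = 3)
  tr <- generate_truth(cfg)
  gt <- generate_genotypes(tr, cfg)
  # binomial expectation: mean dosage 2f = 1 at f = 0.5
  expect_true(all(abs(rowMeans(gt$dosage) - 1) < 0.03))

  cfg2 <- synth_config(n_individuals = 20, n_genes = 10,
                       maf_range = c(0.08, 0.15), seed = 5)
  tr2 <- generate_truth(cfg2)
  gt2 <- generate_genotypes(tr2, cfg2)
  af <- rowMeans(gt2$dosage) / 2
  expect_true(all(pmin(af, 1 - af) >= 0.05))
  expect_true(all(gt2$dosage %in% 0:2))
})

test_that("with no background SNPs the genotype matrix is exactly the planted set", {
  cfg <- synth_config(n_individuals = 8, n_genes = 12, qtl_fraction = 1,
                      n_background_snps = 0, seed = 9)
  tr <- generate_truth(cfg)
  gt <- generate_genotypes(tr, cfg)
  expect_equal(nrow(gt$dosage), nrow(tr$qtl_effects))
  expect_setequal(rownames(gt$dosage), tr$qtl_effects$snp_id)
})

test_that("expected PAS proportions follow the softmax / survival model", {
  p <- apaqtl:::.expected_props(c(0, 0), c(1, 1), "nuclear")
  expect_equal(p, c(0.5, 0.5))
  # planted effect beta = 1, dosage 2 on PAS 2
  p2 <- apaqtl:::.expected_props(c(0, 0 + 1 * 2), c(1, 1), "nuclear")
  expect_equal(p2[2], exp(2) / (1 + exp(2)), tolerance = 1e-12)
  # survival 1: nuclear and total identical
  expect_equal(apaqtl:::.expected_props(c(0.4, -0.2), c(1, 1), "total"),
               apaqtl:::.expected_props(c(0.4, -0.2), c(1, 1), "nuclear"))
  # survival < 1 depresses the intronic term monotonically
  base <- apaqtl:::.expected_props(c(0, 0), c(0.3, 1), "nuclear")
  tot <- apaqtl:::.expected_props(c(0, 0), c(0.3, 1), "total")
  expect_lt(tot[1], base[1])
  # beta monotonicity at fixed dosage > 0
  u <- vapply(c(0, 0.5, 1, 2), function(b) {
    apaqtl:::.expected_props(c(0, b * 1), c(1, 1), "nuclear")[2]
  }, numeric(1))
  expect_true(all(diff(u) > 0))
})

test_that("simulated usage matches softmax expectations at high depth", {
  cfg <- synth_config(n_individuals = 2, n_genes = 1, pas_per_gene = 2,
                      read_depth_per_gene = 1e5, qtl_fraction = 0,
                      artifact_rate = 0, peak_width = 0, seed = 17)
  tr <- generate_truth(cfg)
  tr$pas$logit <- c(0, 0)
  tr$pas$survival <- c(1, 1)
  gt <- generate_genotypes(tr, cfg)
  for (fr in c("nuclear", "total")) {
    lib <- simulate_library(tr, gt, "ind001", fr, cfg)
    cnt <- vapply(tr$pas$pos, function(p) sum(lib$count[lib$pos == p]),
                  numeric(1))
    expect_equal(cnt[1] / sum(cnt), 0.5, tolerance = 0.01)
  }
  # planted beta = 1, dosage 2: expected usage exp(2)/(1+exp(2)) ~ 0.881
  tr$qtl_effects <- data.frame(
    gene_id = tr$pas$gene_id[1], pas_id = tr$pas$pas_id[2], chrom = tr$pas$chrom[1],
    snp_pos = tr$pas$pos[1] - 1000L, snp_id = "snp_forced", beta = 1,
    stringsAsFactors = FALSE)
  gt2 <- gt
  gt2$dosage <- rbind(gt$dosage, snp_forced = c(2L, 0L))
  lib <- simulate_library(tr, gt2, "ind001", "nuclear", cfg)
  cnt <- vapply(tr$pas$pos, function(p) sum(lib$count[lib$pos == p]),
                numeric(1))
  expect_equal(cnt[2] / sum(cnt), exp(2) / (1 + exp(2)), tolerance = 0.01)
})

test_that("simulate_library validates individual and fraction and scatters reads locally", {
  s <- shared_study()
  cfg <- s$truth$config
  expect_error(simulate_library(s$truth, s$genotypes, "nobody", "nuclear", cfg),
               "unknown individual")
  expect_error(simulate_library(s$truth, s$genotypes, "ind001", "cytoplasm", cfg),
               "fraction")
  lib <- simulate_library(s$truth, s$genotypes, "ind001", "nuclear", cfg)
  # every read within peak_width/2 of a true PAS or at a trap
  anchors <- c(s$truth$pas$pos, s$truth$artifacts$pos)
  d <- vapply(lib$pos, function(p) min(abs(anchors - p)), numeric(1))
  expect_true(all(d <= cfg$peak_width / 2))
  # same seed reproduces the library exactly
  expect_identical(lib, simulate_library(s$truth, s$genotypes, "ind001",
                                         "nuclear", cfg))
})

test_that("intronic decay depresses total-fraction usage of intronic PAS", {
  s <- shared_study()   # intron_survival = 0.5 default
  u <- shared_usage()
  nuc <- u$samples$library_id[u$samples$fraction == "nuclear"]
  tot <- u$samples$library_id[u$samples$fraction == "total"]
  intr <- u$pas$category == "intron"
  m_nuc <- rowMeans(u$usage[intr, nuc], na.rm = TRUE)
  m_tot <- rowMeans(u$usage[intr, tot], na.rm = TRUE)
  # Monte-Carlo tolerance: the vast majority must move in the decay direction
  expect_gt(mean(m_tot < m_nuc), 0.95)
})
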