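test_that("phenotype normalization applies the rank inverse-normal transform", {
  cnt <- rbind(c(1L, 3L, 5L, 7L, 9L), c(9L, 7L, 5L, 3L, 1L))
  u <- make_usage(cnt, gene_ids = c("g1", "g1"),
                  fractions = rep("nuclear", 5))
  ph <- normalize_phenotypes(u, "nuclear")
  # increasing row: ranks 1..5 -> qnorm((rank - 0.5)/5), rescaled to unit
  # sd; symmetric about zero and monotone in the input
  q <- qnorm((1:5 - 0.5) / 5)
  want <- (q - mean(q)) / sd(q)
  expect_equal(unname(ph$mat[1, ]), want, tolerance = 1e-12)
  expect_equal(unname(rowMeans(ph$mat)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(ph$mat, 1, sd)), c(1, 1), tolerance = 1e-9)
  # rank invariance: any monotone transform of a row yields identical output
  u2 <- u
  u2$usage[1, ] <- u$usage[1, ]^3 + 2
  ph2 <- normalize_phenotypes(u2, "nuclear")
  expect_equal(ph2$mat[1, ], ph$mat[1, ])
})

test_that("constant and under-observed phenotype rows are dropped", {
  u <- make_usage(matrix(5L, 2, 6), gene_ids = c("g1", "g1"),
                  fractions = rep("nuclear", 6))
  # constant usage row (0.5 everywhere)
  expect_warning(ph <- normalize_phenotypes(u, "nuclear"), "dropped")
  expect_equal(nrow(ph$mat), 0L)
  # fewer than 5 non-missing individuals
  u2 <- make_usage(rbind(c(1L, 5L, 9L), c(9L, 5L, 1L)),
                   gene_ids = c("g1", "g1"), fractions = rep("nuclear", 3))
  expect_warning(ph2 <- normalize_phenotypes(u2, "nuclear"), "dropped")
  expect_equal(nrow(ph2$mat), 0L)
})

test_that("covariates combine phenotype PCs and batch indicators", {
  set.seed(3)
  n <- 20
  base <- matrix(rnorm(10 * n), 10, n,
                 dimnames = list(NULL, sprintf("i%02d", 1:n)))
  batch <- setNames(rep(c("A", "B"), each = n / 2), colnames(base))
  shifted <- base + rep(ifelse(batch == "B", 3, 0), each = 10)
  ph <- structure(list(mat = shifted, raw = shifted,
                       pas = data.frame(pas_id = sprintf("p%d", 1:10)),
                       individuals = colnames(base), fraction = "nuclear"),
                  class = "apa_phenotypes")
  cv <- build_covariates(ph, n_pcs = 4, batch = batch)
  expect_equal(colnames(cv), c("PC1", "PC2", "PC3", "PC4", "batch_B"))
  # PCs mutually orthogonal
  cp <- crossprod(cv[, 1:4])
  expect_true(all(abs(cp[upper.tri(cp)]) < 1e-8))
  # the planted batch shift dominates PC1
  expect_gt(abs(cor(cv[, "PC1"], as.numeric(batch == "B"))), 0.5)
  # intercept-only configuration
  cv0 <- build_covariates(ph, n_pcs = 0, batch = NULL)
  expect_equal(ncol(cv0), 0L)
  expect_error(build_covariates(ph, n_pcs = 20), "smaller")
})

test_that("cis_scan matches a hand-coded normal-equations solver", {
  set.seed(11)
  n <- 6
  inds <- sprintf("i%d", 1:n)
  dos <- matrix(c(0, 1, 2, 0, 1, 2, 2, 2, 0, 1, 0, 1), 2, n, byrow = TRUE,
                dimnames = list(c("v1", "v2"), inds))
  gt <- structure(list(
    dosage = dos,
    map = data.frame(snp_id = c("v1", "v2"), chrom = "chr1",
                     pos = c(1000L, 2000L), af = c(0.5, 0.5),
                     planted = FALSE, row.names = c("v1", "v2"),
                     stringsAsFactors = FALSE)), class = "apa_genotypes")
  C <- matrix(rnorm(n), n, 1, dimnames = list(inds, "cov1"))
  y <- setNames(rnorm(n), inds)
  got <- cis_scan(y, gt, "chr1", 1500L, covariates = C, window = 25000L)
  for (i in 1:2) {
    X <- cbind(1, dos[i, ], C)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    resid <- y - X %*% beta
    s2 <- sum(resid^2) / (n - ncol(X))
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    tstat <- beta[2] / se
    expect_equal(got$slope[i], unname(beta[2]), tolerance = 1e-10)
    expect_equal(got$se[i], unname(se), tolerance = 1e-10)
    expect_equal(got$p_value[i],
                 unname(2 * pt(-abs(tstat), n - 3)), tolerance = 1e-10)
  }
  # perfect fit: phenotype equal to dosage
  y2 <- setNames(as.numeric(dos[1, ]), inds)
  got2 <- cis_scan(y2, gt, "chr1", 1000L, window = 100L)
  expect_equal(got2$slope[got2$snp_id == "v1"], 1, tolerance = 1e-9)
  expect_lt(got2$p_value[got2$snp_id == "v1"], 1e-12)
})

test_that("the cis window bound is inclusive at exactly 25 kb", {
  inds <- sprintf("i%d", 1:8)
  dos <- matrix(rep(c(0, 1, 2, 1), 6), 3, 8,
                dimnames = list(c("a", "b", "c"), inds))
  gt <- structure(list(
    dosage = dos,
    map = data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                     pos = c(75000L, 125000L, 125001L), af = 0.5,
                     planted = FALSE, row.names = c("a", "b", "c"),
                     stringsAsFactors = FALSE)), class = "apa_genotypes")
  y <- setNames(rnorm(8), inds)
  got <- cis_scan(y, gt, "chr1", 100000L)
  expect_setequal(got$snp_id, c("a", "b"))   # +/-25000 inclusive, 25001 out
})

test_that("permutation p-values respect their support and reproduce under a seed", {
  set.seed(21)
  n <- 20
  inds <- sprintf("i%02d", 1:n)
  dos <- matrix(rbinom(5 * n, 2, 0.4), 5, n,
                dimnames = list(sprintf("v%d", 1:5), inds))
  gt <- structure(list(
    dosage = dos,
    map = data.frame(snp_id = rownames(dos), chrom = "chr1",
                     pos = seq(1000L, 5000L, by = 1000L), af = 0.4,
                     planted = FALSE, row.names = rownames(dos),
                     stringsAsFactors = FALSE)), class = "apa_genotypes")
  y <- setNames(rnorm(n), inds)
  pp <- permutation_pass(y, gt, "chr1", 3000L, B = 100L, seed = 9L)
  expect_gte(pp$permutation_p, 1 / 101)
  expect_lte(pp$permutation_p, 1)
  pp2 <- permutation_pass(y, gt, "chr1", 3000L, B = 100L, seed = 9L)
  expect_identical(pp, pp2)

  # single-variant window: permutation p consistent with the nominal p's
  # rank among the permuted nominal p-values, recomputed by brute force
  gt1 <- structure(list(dosage = dos[1, , drop = FALSE],
                        map = gt$map[1, , drop = FALSE]),
                   class = "apa_genotypes")
  pp1 <- permutation_pass(y, gt1, "chr1", 1000L, B = 100L, seed = 13L)
  obs <- cis_scan(y, gt1, "chr1", 1000L)$p_value
  perm_p <- apaqtl:::.with_seed(13L, {
    vapply(1:100, function(b) {
      cis_scan(setNames(y[sample.int(n)], inds), gt1, "chr1", 1000L)$p_value
    }, numeric(1))
  })
  expect_equal(pp1$permutation_p, (1 + sum(perm_p <= obs)) / 101)
})

test_that("BH over permutation p-values matches hand computation and brute force", {
  rec <- data.frame(permutation_p = c(0.001, 0.02, 0.04, 0.8))
  out <- call_qtls(rec, fdr = 0.1)
  expect_equal(out$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$q_value, p.adjust(rec$permutation_p, "BH"))
  out1 <- call_qtls(data.frame(permutation_p = rep(1, 5)), fdr = 0.1)
  expect_false(any(out1$significant))
  # duplicating every entry leaves the significant fraction unchanged
  set.seed(31)
  for (i in 1:25) {
    p <- runif(40)^sample(c(1, 3), 1)
    a <- call_qtls(data.frame(permutation_p = p), fdr = 0.1)
    b <- call_qtls(data.frame(permutation_p = rep(p, 2)), fdr = 0.1)
    expect_equal(mean(a$significant), mean(b$significant))
    expect_equal(a$significant, brute_force_bh(p, 0.1))
  }
})

test_that("raw effect sizes are interpretable slopes per alternate allele", {
  usage_row <- setNames(c(0.2, 0.2, 0.4, 0.4, 0.6, 0.6), sprintf("i%d", 1:6))
  dosage <- setNames(c(0, 0, 1, 1, 2, 2), sprintf("i%d", 1:6))
  expect_equal(effect_size_raw(usage_row, dosage), 0.2, tolerance = 1e-12)
  expect_equal(effect_size_raw(usage_row, 2 - dosage), -0.2, tolerance = 1e-12)
  expect_true(is.na(effect_size_raw(usage_row, dosage * 0)))
})
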