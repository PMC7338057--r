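# Cross-dataset statistics: Storey pi1 sharing, effect-size concordance,
# gene-category enrichment, per-gene Bonferroni overlap with external
# QTLs, and bootstrap annotation overlap.

#' Storey pi1 estimate of sharing
#'
#' Estimates the fraction of true associations (pi1 = 1 - pi0) in a set of
#' p-values, typically the replication p-values of QTLs ascertained in
#' another dataset or fraction. pi0(lambda) = #{p > lambda} / (n (1 -
#' lambda)) is evaluated on a lambda grid; the final pi0 is a cubic
#' smoothing-spline fit of pi0(lambda) evaluated at the largest lambda
#' (method "smooth"), falling back to the mean of the three largest-lambda
#' estimates when the fit is degenerate, or that mean directly (method
#' "mean_top3").
#'
#' @param pvalues numeric vector of p-values in [0, 1]; at least 20.
#' @param lambda evaluation grid (default 0.05 to 0.95 by 0.05).
#' @param method `"smooth"` (default) or `"mean_top3"`.
#' @return object of class `apa_pi1`: list with `pi0`, `pi1`, `lambda`,
#'   `pi0_lambda`, `n`.
#' @export
pi1_estimate <- function(pvalues, lambda = seq(0.05, 0.95, by = 0.05),
                         method = c("smooth", "mean_top3")) {
  method <- match.arg(method)
  pvalues <- pvalues[!is.na(pvalues)]
  if (length(pvalues) < 20L) {
    stop("pi1 estimation needs at least 20 p-values")
  }
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  n <- length(pvalues)
  pi0_l <- vapply(lambda, function(l) sum(pvalues > l) / (n * (1 - l)),
                  numeric(1))
  pi0 <- NA_real_
  if (method == "smooth") {
    fit <- tryCatch(smooth.spline(lambda, pi0_l, df = 3),
                    error = function(e) NULL)
    if (!is.null(fit)) pi0 <- predict(fit, x = max(lambda))$y
  }
  if (!is.finite(pi0)) {
    top <- order(lambda, decreasing = TRUE)[1:3]
    pi0 <- mean(pi0_l[top])
  }
  pi0 <- min(max(pi0, 0), 1)
  out <- list(pi0 = pi0, pi1 = 1 - pi0, lambda = lambda,
              pi0_lambda = pi0_l, n = n, method = method)
  class(out) <- "apa_pi1"
  out
}

#' @export
print.apa_pi1 <- function(x, ...) {
  cat(sprintf("Storey sharing estimate: pi1 = %.3f (pi0 = %.3f, n = %d)\n",
              x$pi1, x$pi0, x$n))
  invisible(x)
}

#' Concordance of paired effect sizes
#'
#' Pearson correlation and OLS regression of one set of effect sizes on
#' another, for pairs matched by PAS/variant — e.g. lead-SNP slopes in the
#' nuclear vs total fraction.
#'
#' @param slopes_a,slopes_b paired numeric vectors (length >= 3).
#' @return list with `r` (Pearson), `r_squared`, `slope` (of b on a),
#'   `p_value` (two-sided, of the regression slope), `n`.
#' @export
effect_concordance <- function(slopes_a, slopes_b) {
  ok <- is.finite(slopes_a) & is.finite(slopes_b)
  a <- slopes_a[ok]; b <- slopes_b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (sd(a) == 0 || sd(b) == 0) stop("zero-variance input")
  fit <- lm(b ~ a)
  sm <- summary(fit)
  r <- cor(a, b)
  list(r = r, r_squared = r^2, slope = unname(coef(fit)[2]),
       p_value = sm$coefficients[2, 4], n = length(a))
}

#' Category enrichment of small association p-values
#'
#' One-sided Wilcoxon rank-sum tests that the association p-values of each
#' gene category are stochastically smaller than those of the background
#' category (exact for small samples without ties, normal approximation
#' with tie correction otherwise, as implemented by `wilcox.test`).
#'
#' @param pvalues numeric vector of association p-values (one per gene).
#' @param categories character/factor vector of gene categories.
#' @param background the category label serving as reference.
#' @return data frame (category, n, n_background, w_statistic, p_value),
#'   one row per non-background category.
#' @export
category_enrichment <- function(pvalues, categories, background) {
  stopifnot(length(pvalues) == length(categories))
  categories <- as.character(categories)
  if (!background %in% categories) stop("background category is empty")
  bg <- pvalues[categories == background]
  cats <- setdiff(unique(categories), background)
  rows <- lapply(cats, function(cc) {
    x <- pvalues[categories == cc]
    if (length(x) == 0L) stop("empty category: ", cc)
    wt <- wilcox.test(x, bg, alternative = "less", exact = NULL)
    data.frame(category = cc, n = length(x), n_background = length(bg),
               w_statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-gene overlap of external QTLs with nominal APA associations
#'
#' For each external gene-variant pair (e.g. an eQTL), looks up the
#' nominal APA association p-values of that variant across the gene's
#' PAS, takes the most significant one, applies a Bonferroni correction
#' for the number of PAS tested in the gene, and flags the gene as
#' overlapping when the corrected p-value is below `alpha`.
#'
#' @param pairs data frame with `gene_id` and `snp_id` columns (one
#'   external QTL per row).
#' @param nominal data frame of nominal associations with `gene_id`,
#'   `pas_id`, `snp_id`, `p_value` columns (e.g. the `nominal` element of
#'   an `apa_qtl`, with `p_value` renamed from `p_value`/`p`).
#' @param alpha significance level after correction (default 0.05).
#' @return `pairs` with `n_pas`, `min_p`, `p_adj`, `overlapping` (NA
#'   when the gene-variant pair has no tested PAS).
#' @export
gene_overlap_test <- function(pairs, nominal, alpha = 0.05) {
  .stopifnot_cols(pairs, c("gene_id", "snp_id"), "pairs")
  .stopifnot_cols(nominal, c("gene_id", "pas_id", "snp_id", "p_value"),
                  "nominal")
  key_nom <- paste(nominal$gene_id, nominal$snp_id)
  pairs$n_pas <- NA_integer_
  pairs$min_p <- NA_real_
  pairs$p_adj <- NA_real_
  pairs$overlapping <- NA
  for (i in seq_len(nrow(pairs))) {
    sel <- key_nom == paste(pairs$gene_id[i], pairs$snp_id[i])
    if (!any(sel)) next
    k <- length(unique(nominal$pas_id[sel]))
    mp <- min(nominal$p_value[sel], na.rm = TRUE)
    pairs$n_pas[i] <- k
    pairs$min_p[i] <- mp
    pairs$p_adj[i] <- min(1, k * mp)
    pairs$overlapping[i] <- pairs$p_adj[i] < alpha
  }
  pairs
}

#' Bootstrap confidence intervals for annotation-class overlap
#'
#' Assigns each variant to the annotation class of the interval containing
#' it (first match in input order; `"none"` when uncovered), reports the
#' observed proportion per class, and percentile 95% confidence intervals
#' from resampling the variant set with replacement.
#'
#' @param variants data frame with `chrom` and `pos` (0-based) columns.
#' @param annotation data frame of labeled intervals (chrom, start, end
#'   0-based half-open, class).
#' @param B bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return data frame (class, proportion, ci_lo, ci_hi).
#' @export
annotation_overlap_bootstrap <- function(variants, annotation, B = 1000L,
                                         seed = 1L) {
  .stopifnot_cols(variants, c("chrom", "pos"), "variants")
  .stopifnot_cols(annotation, c("chrom", "start", "end", "class"),
                  "annotation")
  gr_v <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos + 1L, width = 1L))
  gr_a <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end))
  hits <- GenomicRanges::findOverlaps(gr_v, gr_a, select = "first")
  cls <- ifelse(is.na(hits), "none", annotation$class[hits])
  classes <- sort(unique(cls))
  n <- length(cls)
  prop_of <- function(v) {
    tab <- table(factor(v, levels = classes))
    as.numeric(tab) / length(v)
  }
  obs <- prop_of(cls)
  boot <- .with_seed(seed, {
    vapply(seq_len(B),
           function(b) prop_of(cls[sample.int(n, n, replace = TRUE)]),
           numeric(length(classes)))
  })
  boot <- matrix(boot, nrow = length(classes))
  data.frame(
    class = classes, proportion = obs,
    ci_lo = apply(boot, 1, quantile, 0.025),
    ci_hi = apply(boot, 1, quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
}
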