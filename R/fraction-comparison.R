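# Differential PAS usage between nuclear and total mRNA fractions:
# per-gene Dirichlet-multinomial likelihood-ratio test with shared
# concentration, delta-PAU effect sizes, and nuclear-enriched PAS calls.

#' Dirichlet-multinomial log likelihood
#'
#' Log probability mass of a count vector under the Dirichlet-multinomial
#' with mean proportions `p` and concentration `alpha0` (so alpha =
#' `alpha0 * p`), including the multinomial coefficient. At
#' `alpha0 = Inf` the distribution reduces to the multinomial. A category
#' with zero probability but positive count yields `-Inf`.
#'
#' @param x non-negative integer count vector.
#' @param p probability simplex of the same length.
#' @param alpha0 positive concentration (may be `Inf`).
#' @return log likelihood (scalar).
#' @export
dm_loglik <- function(x, p, alpha0) {
  stopifnot(length(x) == length(p), all(x >= 0), alpha0 > 0)
  n <- sum(x)
  coef <- lgamma(n + 1) - sum(lgamma(x + 1))
  if (any(p <= 0 & x > 0)) return(-Inf)
  if (!is.finite(alpha0)) {
    return(coef + sum(ifelse(x > 0, x * log(p), 0)))
  }
  a <- alpha0 * p
  pos <- a > 0
  coef + lgamma(alpha0) - lgamma(alpha0 + n) +
    sum(lgamma(a[pos] + x[pos]) - lgamma(a[pos]))
}

# Sum of DM log likelihoods of the rows of a count matrix.
.dm_loglik_rows <- function(counts, p, alpha0) {
  n <- rowSums(counts)
  coef <- lgamma(n + 1) - rowSums(lgamma(counts + 1))
  if (any(p <= 0 & colSums(counts) > 0)) return(-Inf)
  if (!is.finite(alpha0)) {
    lp <- log(p)
    return(sum(coef) + sum(counts %*% ifelse(is.finite(lp), lp, 0)))
  }
  a <- alpha0 * p
  sum(coef) + length(n) * lgamma(alpha0) - sum(lgamma(alpha0 + n)) +
    sum(lgamma(sweep(counts, 2, a, "+"))) - nrow(counts) * sum(lgamma(a))
}

# Moment-based starting value for log(alpha0) from per-sample proportions.
.alpha0_init <- function(counts) {
  n <- rowSums(counts)
  ok <- n > 0
  if (sum(ok) < 2L) return(log(50))
  pr <- counts[ok, , drop = FALSE] / n[ok]
  ph <- colMeans(pr)
  v <- apply(pr, 2, var)
  use <- ph > 0 & ph < 1 & v > 0
  if (!any(use)) return(log(1e4))
  a0 <- mean(ph[use] * (1 - ph[use]) / v[use]) - 1
  log(min(max(a0, 0.5), 1e6))
}

# Maximize the DM likelihood with one proportion vector per group and a
# concentration shared across groups, by profiling: for fixed alpha0 the
# groups decouple and each group's logits are optimized by BFGS; the
# profile likelihood is then maximized over log(alpha0) by bounded 1-D
# search (the likelihood is flat in alpha0 near the multinomial limit,
# which a joint quasi-Newton handles poorly). Warm starts are carried
# across outer evaluations. Returns list(p per group, alpha0, ll).
.dm_fit <- function(counts, groups) {
  K <- ncol(counts)
  glev <- unique(groups)
  grp_counts <- lapply(glev, function(g) counts[groups == g, , drop = FALSE])
  warm <- lapply(grp_counts, function(cc) {
    cs <- colSums(cc) + 0.5
    lg <- log(cs / sum(cs))
    (lg - lg[K])[-K]
  })
  state <- new.env(parent = emptyenv())
  state$warm <- warm
  fit_group <- function(gi, log_a0) {
    cc <- grp_counts[[gi]]
    nll <- function(lg) {
      v <- .dm_loglik_rows(cc, .softmax(c(lg, 0)), exp(log_a0))
      if (!is.finite(v)) 1e10 else -v
    }
    f <- optim(state$warm[[gi]], nll, method = "BFGS",
               control = list(reltol = 1e-10, maxit = 200))
    state$warm[[gi]] <- f$par
    list(ll = -f$value, p = .softmax(c(f$par, 0)))
  }
  profile_ll <- function(log_a0) {
    sum(vapply(seq_along(glev), function(gi) fit_group(gi, log_a0)$ll,
               numeric(1)))
  }
  out <- tryCatch({
    o <- stats::optimize(profile_ll, interval = c(log(1e-2), log(1e8)),
                         maximum = TRUE, tol = 1e-8)
    fits <- lapply(seq_along(glev), function(gi) fit_group(gi, o$maximum))
    ps <- lapply(fits, `[[`, "p")
    names(ps) <- glev
    list(p = ps, alpha0 = exp(o$maximum),
         ll = sum(vapply(fits, `[[`, numeric(1), "ll")), converged = TRUE)
  }, error = function(e) NULL)
  if (is.null(out)) {
    return(list(p = NULL, alpha0 = NA_real_, ll = NA_real_, converged = FALSE))
  }
  out
}

#' Dirichlet-multinomial differential usage test for one gene
#'
#' Likelihood-ratio test of whether PAS proportions differ between the
#' nuclear and total fractions. The null model shares one proportion
#' vector across fractions; the alternative fits one per fraction; the
#' concentration is shared across fractions under both models. The LRT
#' statistic is referred to a chi-square with K - 1 degrees of freedom.
#' Per-PAS delta-PAU is the mean raw usage in the total fraction minus the
#' mean in the nuclear fraction (positive = higher in total).
#'
#' @param counts samples x K PAS count matrix for one gene.
#' @param fractions character vector per sample, `"nuclear"` or `"total"`.
#' @return list with `lrt`, `df`, `p_value`, `dpau` (length K), fitted
#'   proportions `p_null`/`p_alt`, `alpha0` estimates and a `converged`
#'   flag.
#' @export
differential_usage_test <- function(counts, fractions) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(fractions))
  if (!all(fractions %in% c("nuclear", "total"))) {
    stop("fractions must be 'nuclear' or 'total'")
  }
  K <- ncol(counts)
  if (K < 2L) stop("the test requires at least 2 PAS")
  if (min(table(factor(fractions, c("nuclear", "total")))) < 2L) {
    stop("at least 2 samples per fraction are required")
  }
  fit0 <- .dm_fit(counts, rep("all", nrow(counts)))
  fit1 <- .dm_fit(counts, fractions)
  conv <- isTRUE(fit0$converged) && isTRUE(fit1$converged)
  lrt <- if (conv) max(2 * (fit1$ll - fit0$ll), 0) else NA_real_
  n <- rowSums(counts)
  usage <- counts[n > 0, , drop = FALSE] / n[n > 0]
  fr <- fractions[n > 0]
  mean_tot <- colMeans(usage[fr == "total", , drop = FALSE])
  mean_nuc <- colMeans(usage[fr == "nuclear", , drop = FALSE])
  list(lrt = lrt, df = K - 1L,
       p_value = if (conv) pchisq(lrt, K - 1L, lower.tail = FALSE) else NA_real_,
       dpau = mean_tot - mean_nuc,
       mean_usage_total = mean_tot, mean_usage_nuclear = mean_nuc,
       p_null = fit0$p[["all"]], p_alt = fit1$p,
       alpha0_null = fit0$alpha0, alpha0_alt = fit1$alpha0,
       converged = conv)
}

#' Test all genes for nuclear-vs-total differential usage
#'
#' Runs [differential_usage_test()] per gene on an [quantify_usage()]
#' object; libraries are the samples, grouped by their fraction label.
#' Genes with fewer than 2 PAS are skipped.
#'
#' @param usage `apa_usage` object.
#' @return object of class `apa_fraction_test`: list with `genes` (gene_id,
#'   lrt, df, p_value), `pas` (pas_id, gene_id, category, dpau,
#'   mean_usage_nuclear, mean_usage_total) and the input dimensions.
#' @export
test_fraction_usage <- function(usage) {
  stopifnot(inherits(usage, "apa_usage"))
  frac <- usage$samples$fraction[match(colnames(usage$counts),
                                       usage$samples$library_id)]
  genes <- unique(usage$pas$gene_id)
  g_rows <- list()
  p_rows <- list()
  for (g in genes) {
    idx <- which(usage$pas$gene_id == g)
    if (length(idx) < 2L) next
    cnt <- t(usage$counts[idx, , drop = FALSE])
    res <- differential_usage_test(cnt, frac)
    g_rows[[g]] <- data.frame(gene_id = g, lrt = res$lrt, df = res$df,
                              p_value = res$p_value,
                              converged = res$converged,
                              stringsAsFactors = FALSE)
    p_rows[[g]] <- data.frame(
      pas_id = usage$pas$pas_id[idx], gene_id = g,
      category = usage$pas$category[idx], dpau = res$dpau,
      mean_usage_nuclear = res$mean_usage_nuclear,
      mean_usage_total = res$mean_usage_total, stringsAsFactors = FALSE)
  }
  out <- list(genes = do.call(rbind, c(g_rows, list(make.row.names = FALSE))),
              pas = do.call(rbind, c(p_rows, list(make.row.names = FALSE))),
              n_genes_tested = length(g_rows))
  class(out) <- "apa_fraction_test"
  out
}

#' @export
print.apa_fraction_test <- function(x, ...) {
  cat(sprintf("apa_fraction_test: %d genes tested (%d PAS)\n",
              x$n_genes_tested, nrow(x$pas)))
  if (!is.null(x$genes$q_value)) {
    cat(sprintf("  significant at FDR %.0f%%: %d genes, %d labeled PAS\n",
                100 * attr(x, "fdr"), sum(x$genes$q_value <= attr(x, "fdr"),
                                          na.rm = TRUE),
                sum(x$pas$label != "none", na.rm = TRUE)))
  }
  invisible(x)
}

#' Label differentially used PAS
#'
#' Benjamini-Hochberg correction over gene-level p-values; within genes
#' significant at the given FDR, PAS with |delta-PAU| above the cutoff are
#' labeled by direction: positive delta-PAU = enriched in the total
#' fraction, negative = enriched in the nuclear fraction.
#'
#' @param x `apa_fraction_test` result.
#' @param fdr gene-level FDR (default 0.1).
#' @param dpau_cut |delta-PAU| cutoff (default 0.2, strict inequality).
#' @return `x` with `q_value` added to `genes` and a `label` column
#'   (`"total_enriched"`, `"nuclear_enriched"`, `"none"`) added to `pas`.
#' @export
classify_differential <- function(x, fdr = 0.1, dpau_cut = 0.2) {
  stopifnot(inherits(x, "apa_fraction_test"))
  x$genes$q_value <- p.adjust(x$genes$p_value, method = "BH")
  sig <- x$genes$gene_id[!is.na(x$genes$q_value) & x$genes$q_value <= fdr]
  lab <- rep("none", nrow(x$pas))
  in_sig <- x$pas$gene_id %in% sig
  lab[in_sig & x$pas$dpau > dpau_cut] <- "total_enriched"
  lab[in_sig & x$pas$dpau < -dpau_cut] <- "nuclear_enriched"
  x$pas$label <- lab
  attr(x, "fdr") <- fdr
  x
}

#' Nuclear-enriched PAS
#'
#' Among genes significant at the FDR used in [classify_differential()],
#' returns PAS used at least `dpau_cut` more in the nuclear than in the
#' total fraction (delta-PAU at or below `-dpau_cut`), flagging those with
#' mean total usage at or below `absent_cut` as near-absent from the
#' total mRNA pool (candidates for isoforms lost to decay or retained in
#' the nucleus).
#'
#' @param x classified `apa_fraction_test` (after [classify_differential()]).
#' @param dpau_cut nuclear-enrichment threshold on -delta-PAU (default 0.2).
#' @param absent_cut mean total usage at or below which a PAS is flagged
#'   (default 0.01).
#' @return data frame of nuclear-enriched PAS with
#'   `near_absent_from_total` flag.
#' @export
nuclear_enriched_pas <- function(x, dpau_cut = 0.2, absent_cut = 0.01) {
  stopifnot(inherits(x, "apa_fraction_test"))
  if (is.null(x$genes$q_value)) {
    stop("run classify_differential() first")
  }
  fdr <- attr(x, "fdr")
  sig <- x$genes$gene_id[!is.na(x$genes$q_value) & x$genes$q_value <= fdr]
  sel <- x$pas$gene_id %in% sig & x$pas$dpau <= -dpau_cut
  out <- x$pas[sel, , drop = FALSE]
  out$near_absent_from_total <- out$mean_usage_total <= absent_cut
  rownames(out) <- NULL
  out
}
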