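# cis-apaQTL mapping: per-fraction phenotype normalization, PC + batch
# covariates, OLS nominal scan in a 25-kb window, permutation pass for the
# lead SNP, and Benjamini-Hochberg FDR over PAS-level permutation p-values.

#' Normalize usage ratios into QTL phenotypes
#'
#' For one fraction, collapses libraries to individuals (one library per
#' individual per fraction), imputes missing usage entries to the row
#' mean, centers and scales each PAS row, applies a rank-based inverse
#' normal transform with offset (rank - 0.5)/n (ties by average rank), and
#' rescales to exactly zero mean and unit variance. Rows with zero
#' variance or fewer than 5 non-missing individuals are dropped with a
#' warning.
#'
#' @param usage `apa_usage` object.
#' @param fraction `"nuclear"` or `"total"`.
#' @return object of class `apa_phenotypes`: list with `mat` (PAS x
#'   individuals, normalized), `raw` (pre-normalization usage, missing
#'   imputed to the row mean), `pas` metadata and `individuals`.
#' @export
normalize_phenotypes <- function(usage, fraction) {
  stopifnot(inherits(usage, "apa_usage"))
  if (!fraction %in% c("nuclear", "total")) {
    stop("fraction must be 'nuclear' or 'total'")
  }
  ss <- usage$samples[usage$samples$fraction == fraction, , drop = FALSE]
  if (any(duplicated(ss$individual))) {
    stop("multiple libraries per individual in fraction '", fraction,
         "'; collapse libraries first")
  }
  m <- usage$usage[, ss$library_id, drop = FALSE]
  colnames(m) <- ss$individual
  n_obs <- rowSums(!is.na(m))
  too_few <- n_obs < 5L
  rmean <- rowMeans(m, na.rm = TRUE)
  imp <- m
  for (i in which(rowSums(is.na(m)) > 0L & !too_few)) {
    imp[i, is.na(imp[i, ])] <- rmean[i]
  }
  rsd <- apply(imp, 1, sd)
  constant <- is.na(rsd) | rsd == 0
  drop <- too_few | constant
  if (any(drop)) {
    warning(sum(drop), " PAS row(s) dropped (constant or < 5 non-missing ",
            "individuals)")
  }
  imp <- imp[!drop, , drop = FALSE]
  n <- ncol(imp)
  if (nrow(imp) == 0L) {
    z <- imp
  } else {
    z <- t(apply(imp, 1, function(r) {
      r <- (r - mean(r)) / sd(r)
      q <- qnorm((rank(r, ties.method = "average") - 0.5) / n)
      (q - mean(q)) / sd(q)
    }))
    dimnames(z) <- dimnames(imp)
  }
  out <- list(mat = z, raw = imp, pas = usage$pas[!drop, , drop = FALSE],
              individuals = colnames(z), fraction = fraction)
  class(out) <- "apa_phenotypes"
  out
}

#' Build QTL covariates: phenotype PCs plus batch
#'
#' Principal components are computed from the normalized phenotype matrix
#' with individuals as observations; batch labels are one-hot encoded
#' against a reference level. The intercept is added by the association
#' model itself.
#'
#' @param phenotypes `apa_phenotypes` object.
#' @param n_pcs number of phenotype PCs (default 4; 0 allowed).
#' @param batch named character vector or factor of batch labels per
#'   individual (names matching `phenotypes$individuals`), or NULL for a
#'   single batch.
#' @return numeric matrix individuals x covariates (0 columns when
#'   `n_pcs = 0` and a single batch).
#' @export
build_covariates <- function(phenotypes, n_pcs = 4L, batch = NULL) {
  stopifnot(inherits(phenotypes, "apa_phenotypes"))
  inds <- phenotypes$individuals
  if (n_pcs >= length(inds)) stop("n_pcs must be smaller than the number of individuals")
  cov <- matrix(0, length(inds), 0, dimnames = list(inds, NULL))
  if (n_pcs > 0L) {
    pc <- prcomp(t(phenotypes$mat), center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x))
    cov <- pc$x[, seq_len(k), drop = FALSE]
    colnames(cov) <- paste0("PC", seq_len(k))
  }
  if (!is.null(batch)) {
    b <- factor(batch[inds])
    if (nlevels(b) > 1L) {
      mm <- model.matrix(~b)[, -1L, drop = FALSE]
      colnames(mm) <- paste0("batch_", levels(b)[-1L])
      cov <- cbind(cov, mm)
    }
  }
  rownames(cov) <- inds
  cov
}

# Residual-maker application: residualize columns of X on [1, C].
.residualize <- function(X, C) {
  D <- cbind(`(Intercept)` = 1, C)
  qr_d <- qr(D)
  X - D %*% qr.coef(qr_d, X)
}

#' Nominal cis association scan for one phenotype
#'
#' Tests every variant within `window` bases of the PAS position by OLS of
#' the phenotype on dosage adjusting for covariates (via
#' Frisch-Waugh residualization of both phenotype and dosage on the
#' covariates, which reproduces the multiple-regression t-test exactly).
#' The window bound is inclusive on both sides.
#'
#' @param y numeric phenotype vector (one value per individual).
#' @param genotypes `apa_genotypes` object (columns must cover the
#'   phenotype's individuals).
#' @param pas_chrom,pas_pos PAS location anchoring the cis window.
#' @param covariates individuals x covariates matrix (may have 0 columns).
#' @param window cis half-width in bases (default 25000).
#' @return data frame (snp_id, pos, slope, se, statistic, p_value); zero
#'   rows when no variant falls in the window.
#' @export
cis_scan <- function(y, genotypes, pas_chrom, pas_pos, covariates = NULL,
                     window = 25000L) {
  inds <- names(y)
  if (is.null(inds)) stop("y must be named by individual")
  map <- genotypes$map
  sel <- map$chrom == pas_chrom & abs(map$pos - pas_pos) <= window
  out0 <- data.frame(snp_id = character(), pos = integer(), slope = numeric(),
                     se = numeric(), statistic = numeric(),
                     p_value = numeric(), stringsAsFactors = FALSE)
  if (!any(sel)) return(out0)
  G <- t(genotypes$dosage[sel, inds, drop = FALSE])  # individuals x variants
  if (is.null(covariates)) covariates <- matrix(0, length(y), 0, dimnames = list(inds, NULL))
  res <- .cis_assoc(y, G, covariates[inds, , drop = FALSE])
  data.frame(snp_id = colnames(G), pos = map$pos[sel], slope = res$slope,
             se = res$se, statistic = res$statistic, p_value = res$p,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized covariate-adjusted OLS of y on each column of G.
.cis_assoc <- function(y, G, C) {
  n <- length(y)
  k <- ncol(C)
  yr <- drop(.residualize(matrix(y, ncol = 1), C))
  Gr <- .residualize(G, C)
  gss <- colSums(Gr^2)
  ok <- gss > 1e-12
  slope <- se <- stat <- p <- rep(NA_real_, ncol(G))
  df <- n - k - 2L
  if (any(ok) && df > 0) {
    b <- colSums(Gr[, ok, drop = FALSE] * yr) / gss[ok]
    rss <- sum(yr^2) - b^2 * gss[ok]
    rss <- pmax(rss, 0)
    s2 <- rss / df
    sei <- sqrt(s2 / gss[ok])
    ti <- ifelse(sei > 0, b / sei, sign(b) * Inf)
    slope[ok] <- b
    se[ok] <- sei
    stat[ok] <- ti
    p[ok] <- 2 * pt(-abs(ti), df)
  }
  list(slope = slope, se = se, statistic = stat, p = p)
}

#' Permutation pass for a phenotype's cis window
#'
#' The observed statistic is the minimum nominal p over the window. The
#' phenotype values are permuted across individuals B times (the
#' genotype-covariate configuration stays fixed) and the minimum nominal p
#' recomputed each time; the permutation p-value is
#' `(1 + #{permuted min-p <= observed}) / (B + 1)`.
#'
#' @param y named phenotype vector.
#' @param genotypes `apa_genotypes` object.
#' @param pas_chrom,pas_pos cis-window anchor.
#' @param covariates covariate matrix.
#' @param window cis half-width.
#' @param B number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `lead` (snp_id), `lead_pos`, `nominal_p` (lead's),
#'   `slope` (lead's, on the normalized phenotype), `permutation_p`,
#'   `n_cis`; NULL when the window is empty.
#' @export
permutation_pass <- function(y, genotypes, pas_chrom, pas_pos,
                             covariates = NULL, window = 25000L,
                             B = 1000L, seed = 1L) {
  inds <- names(y)
  map <- genotypes$map
  sel <- map$chrom == pas_chrom & abs(map$pos - pas_pos) <= window
  if (!any(sel)) return(NULL)
  G <- t(genotypes$dosage[sel, inds, drop = FALSE])
  if (is.null(covariates)) covariates <- matrix(0, length(y), 0, dimnames = list(inds, NULL))
  C <- covariates[inds, , drop = FALSE]
  n <- length(y)
  k <- ncol(C)
  df <- n - k - 2L
  Gr <- .residualize(G, C)
  gss <- colSums(Gr^2)
  ok <- gss > 1e-12
  if (!any(ok) || df <= 0) return(NULL)
  Gok <- Gr[, ok, drop = FALSE]
  gss_ok <- gss[ok]
  minp_of <- function(yv) {
    yr <- drop(.residualize(matrix(yv, ncol = 1), C))
    b <- colSums(Gok * yr) / gss_ok
    rss <- pmax(sum(yr^2) - b^2 * gss_ok, 0)
    ti <- b / sqrt(rss / df / gss_ok)
    pv <- 2 * pt(-abs(ti), df)
    list(p = pv, min = min(pv))
  }
  obs <- minp_of(y)
  lead_i <- which.min(obs$p)
  perm_min <- .with_seed(seed, {
    vapply(seq_len(B), function(b) minp_of(y[sample.int(n)])$min, numeric(1))
  })
  snp_ids <- colnames(G)[ok]
  pos_ok <- map$pos[sel][ok]
  yr <- drop(.residualize(matrix(y, ncol = 1), C))
  slope_lead <- sum(Gok[, lead_i] * yr) / gss_ok[lead_i]
  list(lead = snp_ids[lead_i], lead_pos = pos_ok[lead_i],
       nominal_p = obs$min, slope = slope_lead,
       permutation_p = (1 + sum(perm_min <= obs$min)) / (B + 1),
       n_cis = sum(ok))
}

#' Effect size on the raw usage scale
#'
#' Covariate-adjusted OLS slope of the pre-normalized usage ratio on the
#' lead variant's dosage: the change in usage per alternate allele.
#'
#' @param usage_row numeric raw usage vector named by individual.
#' @param dosage dosage vector named by individual.
#' @param covariates covariate matrix (may be NULL).
#' @return slope (NA when the dosage is constant).
#' @export
effect_size_raw <- function(usage_row, dosage, covariates = NULL) {
  inds <- names(usage_row)
  d <- dosage[inds]
  if (is.null(covariates)) covariates <- matrix(0, length(d), 0, dimnames = list(inds, NULL))
  res <- .cis_assoc(usage_row, matrix(d, ncol = 1),
                    covariates[inds, , drop = FALSE])
  res$slope[1]
}

#' Map cis apaQTLs in one fraction
#'
#' End-to-end mapping: normalization ([normalize_phenotypes()]),
#' covariates ([build_covariates()]), per-PAS nominal scan and
#' permutation pass within the cis window, raw-scale effect sizes for the
#' lead variants, and BH FDR over PAS-level permutation p-values.
#' Only variants with sample MAF above `maf_min` are tested.
#'
#' @param usage `apa_usage` object.
#' @param genotypes `apa_genotypes` object.
#' @param fraction `"nuclear"` or `"total"`.
#' @param window cis half-width (default 25000).
#' @param n_pcs phenotype PCs used as covariates (default 4).
#' @param batch per-individual batch labels (default taken from the sample
#'   sheet).
#' @param B permutations (default 1000).
#' @param fdr BH FDR level for calling apaQTLs (default 0.1).
#' @param maf_min sample minor-allele-frequency floor (default 0.05,
#'   exclusive bound: MAF must exceed it).
#' @param seed RNG seed (each PAS derives its own stream).
#' @return object of class `apa_qtl`: list with `records` (one row per
#'   tested PAS: pas_id, gene_id, lead, lead_pos, n_cis, nominal_p,
#'   slope_raw, permutation_p, q_value, significant), `nominal` (all
#'   nominal PAS x variant associations) and run metadata.
#' @export
map_apaqtls <- function(usage, genotypes, fraction, window = 25000L,
                        n_pcs = 4L, batch = NULL, B = 1000L, fdr = 0.1,
                        maf_min = 0.05, seed = 1L) {
  phen <- normalize_phenotypes(usage, fraction)
  if (is.null(batch)) {
    ss <- usage$samples[usage$samples$fraction == fraction, ]
    batch <- setNames(ss$batch, ss$individual)
  }
  covs <- build_covariates(phen, n_pcs = n_pcs, batch = batch)
  maf <- pmin(genotypes$map$af, 1 - genotypes$map$af)
  gt <- list(dosage = genotypes$dosage[maf > maf_min, , drop = FALSE],
             map = genotypes$map[maf > maf_min, , drop = FALSE])
  class(gt) <- "apa_genotypes"
  rec_rows <- vector("list", nrow(phen$mat))
  nom_rows <- vector("list", nrow(phen$mat))
  for (i in seq_len(nrow(phen$mat))) {
    pid <- phen$pas$pas_id[i]
    y <- phen$mat[i, ]
    nom <- cis_scan(y, gt, phen$pas$chrom[i], phen$pas$pas_pos[i],
                    covariates = covs, window = window)
    if (nrow(nom) == 0L) next
    nom$pas_id <- pid
    nom$gene_id <- phen$pas$gene_id[i]
    nom_rows[[i]] <- nom
    pp <- permutation_pass(y, gt, phen$pas$chrom[i], phen$pas$pas_pos[i],
                           covariates = covs, window = window, B = B,
                           seed = .derive_seed(seed, paste("perm", pid)))
    if (is.null(pp)) next
    slope_raw <- effect_size_raw(phen$raw[i, ], gt$dosage[pp$lead, ],
                                 covariates = covs)
    rec_rows[[i]] <- data.frame(
      pas_id = pid, gene_id = phen$pas$gene_id[i],
      category = phen$pas$category[i], pas_pos = phen$pas$pas_pos[i],
      lead = pp$lead, lead_pos = pp$lead_pos, n_cis = pp$n_cis,
      nominal_p = pp$nominal_p, slope_norm = pp$slope,
      slope_raw = slope_raw, permutation_p = pp$permutation_p,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, c(rec_rows, list(make.row.names = FALSE)))
  if (is.null(records) || nrow(records) == 0L) {
    stop("no PAS had any cis variant to test")
  }
  records <- call_qtls(records, fdr = fdr)
  out <- list(records = records,
              nominal = do.call(rbind, c(nom_rows, list(make.row.names = FALSE))),
              fraction = fraction, window = window, B = B, fdr = fdr,
              n_pcs = n_pcs)
  class(out) <- "apa_qtl"
  out
}

#' Benjamini-Hochberg FDR over permutation p-values
#'
#' @param records data frame with a `permutation_p` column (one row per
#'   tested PAS).
#' @param fdr FDR level (default 0.1).
#' @return `records` with `q_value` and `significant` columns.
#' @export
call_qtls <- function(records, fdr = 0.1) {
  records$q_value <- p.adjust(records$permutation_p, method = "BH")
  records$significant <- records$q_value <= fdr
  records
}

#' @export
print.apa_qtl <- function(x, ...) {
  cat(sprintf(
    "apa_qtl (%s fraction): %d PAS tested, %d apaQTLs at %.0f%% FDR (B = %d)\n",
    x$fraction, nrow(x$records), sum(x$records$significant), 100 * x$fdr, x$B))
  invisible(x)
}

#' @export
summary.apa_qtl <- function(object, ...) {
  sig <- object$records[object$records$significant, , drop = FALSE]
  cat(sprintf("%d significant PAS in %d genes\n", nrow(sig),
              length(unique(sig$gene_id))))
  if (nrow(sig)) print(head(sig[order(sig$permutation_p),
                                c("pas_id", "lead", "nominal_p", "slope_raw",
                                  "permutation_p", "q_value")], 10))
  invisible(object)
}

#' Replicate QTLs in the other fraction
#'
#' For each significant (or all) PAS-lead-SNP pairs mapped in one
#' fraction, computes the nominal association p-value and the raw-scale
#' slope for the same pair in the other fraction — the inputs to
#' Storey-pi1 sharing and effect-size concordance analyses.
#'
#' @param qtl an `apa_qtl` from [map_apaqtls()].
#' @param usage the `apa_usage` object both fractions were quantified from.
#' @param genotypes `apa_genotypes` object.
#' @param fraction the replication fraction.
#' @param n_pcs,batch covariate settings for the replication fraction
#'   (defaults mirror [map_apaqtls()]).
#' @param significant_only restrict to the discovery fraction's
#'   significant records (default TRUE).
#' @return data frame (pas_id, snp_id, slope_raw_discovery,
#'   slope_raw_replication, p_replication); rows limited to PAS present
#'   in the replication fraction's phenotype matrix.
#' @export
replicate_qtls <- function(qtl, usage, genotypes, fraction, n_pcs = 4L,
                           batch = NULL, significant_only = TRUE) {
  stopifnot(inherits(qtl, "apa_qtl"))
  rec <- qtl$records
  if (significant_only) rec <- rec[rec$significant, , drop = FALSE]
  phen <- normalize_phenotypes(usage, fraction)
  if (is.null(batch)) {
    ss <- usage$samples[usage$samples$fraction == fraction, ]
    batch <- setNames(ss$batch, ss$individual)
  }
  covs <- build_covariates(phen, n_pcs = n_pcs, batch = batch)
  rows <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    j <- match(rec$pas_id[i], phen$pas$pas_id)
    if (is.na(j) || !rec$lead[i] %in% rownames(genotypes$dosage)) next
    d <- genotypes$dosage[rec$lead[i], phen$individuals]
    a <- .cis_assoc(phen$mat[j, ], matrix(d, ncol = 1),
                    covs[phen$individuals, , drop = FALSE])
    rows[[i]] <- data.frame(
      pas_id = rec$pas_id[i], snp_id = rec$lead[i],
      slope_raw_discovery = rec$slope_raw[i],
      slope_raw_replication = effect_size_raw(phen$raw[j, ], d, covs),
      p_replication = a$p[1], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(pas_id = character(), snp_id = character(),
                      slope_raw_discovery = numeric(),
                      slope_raw_replication = numeric(),
                      p_replication = numeric(), stringsAsFactors = FALSE)
  }
  out
}
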