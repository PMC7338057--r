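# Synthetic 3'-Seq study generator: genome, gene models, planted PAS with
# signal motifs, internal-priming traps, genotypes with planted apaQTL
# effects, and two-fraction (nuclear/total) read sets with known truth.

# Fixed gene architecture (transcript coordinates, lengths in bp).
# Genes are laid out non-overlapping with a gap wide enough that the
# 5-kb-downstream annotation class of one gene never reaches the next gene.
.GENE_TEMPLATE <- list(
  utr5 = 200L, exon1 = 500L, intron = 1500L, exon2 = 500L, utr3 = 1000L,
  gene_len = 3700L, gap = 5800L, stride = 9500L, genes_per_chrom = 50L,
  margin = 1000L
)

#' Configuration for a synthetic APA study
#'
#' Defines the generative conditions of a self-contained two-fraction
#' (nuclear and total mRNA) 3'-Seq study with planted ground truth:
#' per-gene PAS with polyadenylation signal motifs, internal-priming
#' A-rich traps, genotypes, and cis genetic effects on PAS choice.
#'
#' @param n_individuals number of individuals (each yields one nuclear and
#'   one total library). Default 52, the panel size the design emulates.
#' @param n_genes number of genes.
#' @param pas_per_gene integer vector of admissible PAS counts per gene;
#'   each gene draws uniformly from it. Values must lie in 1..4 (a gene has
#'   four structural PAS slots: 3'UTR end, intron, mid-3'UTR, exon).
#' @param read_depth_per_gene mean 3'-Seq read depth per gene per library
#'   (Poisson).
#' @param maf_range length-2 numeric, allele-frequency range in (0.05, 0.5].
#' @param qtl_fraction fraction of genes given a planted cis effect on one
#'   of their PAS.
#' @param effect_size_beta absolute logit-scale effect per alternate allele
#'   of a planted QTL (sign randomized per QTL).
#' @param intron_survival total-fraction retention factor in (0, 1] applied
#'   to isoforms terminating at intronic PAS (decay of prematurely
#'   polyadenylated transcripts); 1 means no decay.
#' @param artifact_rate fraction of genes carrying a planted A-rich
#'   internal-priming trap that emits artifact reads.
#' @param artifact_read_rate mean artifact reads at a trap, as a fraction
#'   of `read_depth_per_gene`.
#' @param overdispersion Dirichlet-multinomial concentration of per-library
#'   PAS proportions; `Inf` (default) draws plain multinomial counts.
#' @param peak_width read 3'-end jitter span: reads scatter within
#'   `peak_width/2` bases of the true cleavage site (truncated discrete
#'   Gaussian, sd `peak_width/4`).
#' @param n_background_snps non-causal SNPs drawn per gene within the cis
#'   window.
#' @param n_batches number of library-preparation batches individuals are
#'   assigned to (round robin).
#' @param mixed_strands if TRUE genes are placed on both strands; default
#'   all plus strand.
#' @param seed master seed; all randomness derives from it.
#' @return an object of class `apa_config` (a validated list).
#' @export
synth_config <- function(n_individuals = 52L,
                         n_genes = 200L,
                         pas_per_gene = 2:3,
                         read_depth_per_gene = 300,
                         maf_range = c(0.1, 0.5),
                         qtl_fraction = 0.1,
                         effect_size_beta = 1.5,
                         intron_survival = 0.5,
                         artifact_rate = 0.1,
                         artifact_read_rate = 0.3,
                         overdispersion = Inf,
                         peak_width = 6L,
                         n_background_snps = 8L,
                         n_batches = 2L,
                         mixed_strands = FALSE,
                         seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_genes = as.integer(n_genes),
    pas_per_gene = as.integer(pas_per_gene),
    read_depth_per_gene = read_depth_per_gene,
    maf_range = as.numeric(maf_range), qtl_fraction = qtl_fraction,
    effect_size_beta = effect_size_beta, intron_survival = intron_survival,
    artifact_rate = artifact_rate, artifact_read_rate = artifact_read_rate,
    overdispersion = overdispersion, peak_width = as.integer(peak_width),
    n_background_snps = as.integer(n_background_snps),
    n_batches = as.integer(n_batches), mixed_strands = isTRUE(mixed_strands),
    seed = as.integer(seed)
  )
  if (cfg$n_individuals < 2L) stop("n_individuals must be >= 2")
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (any(cfg$pas_per_gene < 1L) || any(cfg$pas_per_gene > 4L)) {
    stop("pas_per_gene values must lie in 1..4: a gene has four PAS slots ",
         "and more sites would not fit inside the gene model")
  }
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0.05 || cfg$maf_range[2] > 0.5) {
    stop("maf_range must be within (0.05, 0.5]")
  }
  for (f in c("qtl_fraction", "artifact_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (cfg$intron_survival <= 0 || cfg$intron_survival > 1) {
    stop("intron_survival must be in (0, 1]")
  }
  if (cfg$overdispersion <= 0) stop("overdispersion must be positive")
  if (cfg$peak_width < 0L || cfg$peak_width > 20L) {
    stop("peak_width must be in 0..20")
  }
  class(cfg) <- "apa_config"
  cfg
}

# The 12 polyadenylation signal hexamers (canonical AATAAA plus variants);
# sampling weights put most mass on the canonical site.
.MOTIF_WEIGHTS <- c(
  AATAAA = 0.55, AATTAA = 0.16, AAAAAA = 0.029, AAAAAG = 0.029,
  AATACA = 0.029, AATAGA = 0.029, AATATA = 0.029, ACTAAA = 0.029,
  AGTAAA = 0.029, CATAAA = 0.029, GATAAA = 0.029, TATAAA = 0.029
)

# Rejection-sample a genomic window free of internal-priming signatures:
# no 6-A run, < 7 A in any 10-base subwindow, < 11 A in any 15-base
# subwindow. Keeps planted cleavage sites from tripping the mispriming
# filters regardless of peak jitter.
.safe_window <- function(len) {
  repeat {
    v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    a <- as.integer(v == "A")
    s <- paste(v, collapse = "")
    if (grepl("AAAAAA", s, fixed = TRUE)) next
    cs <- cumsum(c(0L, a))
    bad <- FALSE
    if (len >= 10L) {
      w10 <- cs[(10L + 1L):(len + 1L)] - cs[1L:(len - 10L + 1L)]
      if (any(w10 >= 7L)) bad <- TRUE
    } else if (sum(a) >= 7L) bad <- TRUE
    if (!bad && len >= 15L) {
      w15 <- cs[(15L + 1L):(len + 1L)] - cs[1L:(len - 15L + 1L)]
      if (any(w15 >= 11L)) bad <- TRUE
    }
    if (!bad) return(s)
  }
}

# Transcript coordinate -> 0-based genomic position (strand recycled).
.tx2gen <- function(gene_start, strand, tx_pos, gene_len = .GENE_TEMPLATE$gene_len) {
  strand <- rep_len(strand, length(tx_pos))
  ifelse(strand == "+", gene_start + tx_pos, gene_start + gene_len - 1L - tx_pos)
}

# Transcript-sense interval [c1, c2) -> genomic half-open interval.
.txint2gen <- function(gene_start, strand, c1, c2, gene_len = .GENE_TEMPLATE$gene_len) {
  if (strand == "+") c(gene_start + c1, gene_start + c2)
  else c(gene_start + gene_len - c2, gene_start + gene_len - c1)
}

#' Generate the ground truth of a synthetic APA study
#'
#' Builds a uniform-composition genome, non-overlapping gene models
#' (5'UTR/exon/intron/exon/3'UTR), true PAS with a polyadenylation signal
#' hexamer planted 15-45 bases upstream of each cleavage site, A-rich
#' internal-priming traps in a configurable fraction of genes, and planted
#' cis QTL effects on PAS choice. Sequence immediately around each true
#' cleavage site is constrained to be A-poor so that genuine sites never
#' trip the mispriming filters by construction.
#'
#' @param config an [synth_config()] object.
#' @return object of class `apa_truth`: list with `genome` (named character
#'   vector of chromosome sequences), `genes`, `features`, `pas`,
#'   `qtl_effects`, `artifacts` data frames and the `config`. All
#'   coordinates 0-based; intervals half-open.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "apa_config"))
  tmpl <- .GENE_TEMPLATE
  .with_seed(.derive_seed(config$seed, "truth"), {
    n <- config$n_genes
    chrom_of <- (seq_len(n) - 1L) %/% tmpl$genes_per_chrom + 1L
    idx_on <- (seq_len(n) - 1L) %% tmpl$genes_per_chrom
    chroms <- sprintf("chr%d", sort(unique(chrom_of)))
    gene_start <- tmpl$margin + idx_on * tmpl$stride
    strand <- if (config$mixed_strands) {
      sample(c("+", "-"), n, replace = TRUE)
    } else rep("+", n)
    gene_id <- sprintf("gene%04d", seq_len(n))
    genes <- data.frame(
      gene_id = gene_id, chrom = sprintf("chr%d", chrom_of), strand = strand,
      start = gene_start, end = gene_start + tmpl$gene_len,
      stringsAsFactors = FALSE
    )
    chrom_len <- vapply(chroms, function(ch) {
      k <- sum(genes$chrom == ch)
      tmpl$margin + k * tmpl$stride + tmpl$margin
    }, numeric(1))

    # structural feature intervals in transcript coordinates
    tx_feats <- list(
      utr5  = c(0L, 200L),
      exon  = c(200L, 700L),
      intron = c(700L, 2200L),
      exon2 = c(2200L, 2700L),
      utr3  = c(2700L, 3700L)
    )
    feat_rows <- vector("list", n)
    pas_rows <- vector("list", n)
    patches <- list()  # list of (chrom, start0, seq)
    qtl_rows <- list()
    art_rows <- list()

    has_qtl <- runif(n) < config$qtl_fraction
    has_trap <- runif(n) < config$artifact_rate

    for (i in seq_len(n)) {
      g0 <- genes$start[i]; st <- genes$strand[i]; ch <- genes$chrom[i]
      fr <- do.call(rbind, lapply(names(tx_feats), function(nm) {
        iv <- .txint2gen(g0, st, tx_feats[[nm]][1], tx_feats[[nm]][2])
        data.frame(gene_id = gene_id[i], chrom = ch, strand = st,
                   category = sub("2$", "", nm), start = iv[1], end = iv[2],
                   stringsAsFactors = FALSE)
      }))
      feat_rows[[i]] <- fr

      # PAS slots: transcript coordinates of the cleavage site
      k <- if (length(config$pas_per_gene) == 1L) config$pas_per_gene else
        sample(config$pas_per_gene, 1L)
      slots <- c("utr3_end")
      if (k > 1L) {
        extra <- sample(c("intron", "utr3_mid", "exon"), k - 1L,
                        prob = c(0.6, 0.3, 0.1))
        slots <- c(slots, extra)
      }
      tx_pos <- vapply(slots, function(sl) {
        switch(sl,
               utr3_end = 3600L + sample(0:70, 1L),
               intron   = 1100L + sample(0:700, 1L),
               utr3_mid = 2800L + sample(0:500, 1L),
               exon     = 300L + sample(0:300, 1L))
      }, integer(1))
      o <- order(tx_pos)
      slots <- slots[o]; tx_pos <- tx_pos[o]
      cat_of <- c(utr3_end = "utr3", utr3_mid = "utr3",
                  intron = "intron", exon = "exon")[slots]
      # 3'UTR sites dominate; intronic/exonic baselines are drawn relative
      # to the pooled 3'UTR mass (log(k-1) offset) so their expected usage
      # centers near 17% regardless of how many sites the gene has.
      logit <- rnorm(k,
                     mean = ifelse(cat_of == "utr3", 0.8,
                                   -0.55 + log(max(k - 1L, 1L))),
                     sd = ifelse(cat_of == "utr3", 0.4, 0.45))
      logit <- logit - mean(logit)
      motif <- sample(names(.MOTIF_WEIGHTS), k, replace = TRUE,
                      prob = .MOTIF_WEIGHTS)
      offset <- sample(15:45, k, replace = TRUE)
      gpos <- .tx2gen(g0, st, tx_pos)

      for (j in seq_len(k)) {
        # A-poor collar: 9 bases upstream through 19 bases downstream
        iv <- .txint2gen(g0, st, tx_pos[j] - 9L, tx_pos[j] + 20L)
        s <- .safe_window(29L)
        patches[[length(patches) + 1L]] <-
          list(ch, iv[1], if (st == "+") s else revcomp(s))
        # signal hexamer starting `offset` bases upstream of the site
        iv <- .txint2gen(g0, st, tx_pos[j] - offset[j], tx_pos[j] - offset[j] + 6L)
        patches[[length(patches) + 1L]] <-
          list(ch, iv[1], if (st == "+") motif[j] else revcomp(motif[j]))
      }

      pas_rows[[i]] <- data.frame(
        pas_id = sprintf("%s:pas%d", gene_id[i], seq_len(k)),
        gene_id = gene_id[i], chrom = ch, strand = st, pos = gpos,
        category = unname(cat_of), logit = logit, motif = motif,
        signal_offset = offset,
        survival = ifelse(cat_of == "intron", config$intron_survival, 1),
        stringsAsFactors = FALSE
      )

      if (has_trap[i]) {
        t_tx <- 2250L + sample(0:300, 1L)
        t_g <- .tx2gen(g0, st, t_tx)
        iv <- .txint2gen(g0, st, t_tx + 1L, t_tx + 21L)
        patches[[length(patches) + 1L]] <-
          list(ch, iv[1], if (st == "+") strrep("A", 20L) else strrep("T", 20L))
        art_rows[[length(art_rows) + 1L]] <- data.frame(
          gene_id = gene_id[i], chrom = ch, strand = st, pos = t_g,
          stringsAsFactors = FALSE
        )
      }

      if (has_qtl[i]) {
        tgt <- sample.int(k, 1L)
        off <- sample(200:8000, 1L) * sample(c(-1L, 1L), 1L)
        spos <- min(max(gpos[tgt] + off, 100L),
                    as.integer(chrom_len[[ch]]) - 100L)
        qtl_rows[[length(qtl_rows) + 1L]] <- data.frame(
          gene_id = gene_id[i], pas_id = sprintf("%s:pas%d", gene_id[i], tgt),
          chrom = ch, snp_pos = spos,
          snp_id = sprintf("snp_%s_%d", ch, spos),
          beta = config$effect_size_beta * sample(c(-1, 1), 1L),
          stringsAsFactors = FALSE
        )
      }
    }

    genome <- vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), chrom_len[[ch]], replace = TRUE),
            collapse = "")
    }, character(1))
    for (p in patches) {
      substr(genome[[p[[1]]]], p[[2]] + 1L, p[[2]] + nchar(p[[3]])) <- p[[3]]
    }

    truth <- list(
      genome = genome,
      chrom_len = chrom_len,
      genes = genes,
      features = do.call(rbind, feat_rows),
      pas = do.call(rbind, pas_rows),
      qtl_effects = if (length(qtl_rows)) do.call(rbind, qtl_rows) else
        data.frame(gene_id = character(), pas_id = character(),
                   chrom = character(), snp_pos = integer(),
                   snp_id = character(), beta = numeric(),
                   stringsAsFactors = FALSE),
      artifacts = if (length(art_rows)) do.call(rbind, art_rows) else
        data.frame(gene_id = character(), chrom = character(),
                   strand = character(), pos = integer(),
                   stringsAsFactors = FALSE),
      config = config
    )
    rownames(truth$pas) <- truth$pas$pas_id
    class(truth) <- "apa_truth"
    truth
  })
}

#' @export
print.apa_truth <- function(x, ...) {
  cat(sprintf(
    "apa_truth: %d genes on %d chromosome(s), %d PAS (%d intronic), %d planted QTLs, %d traps\n",
    nrow(x$genes), length(x$genome), nrow(x$pas),
    sum(x$pas$category == "intron"), nrow(x$qtl_effects), nrow(x$artifacts)))
  invisible(x)
}

#' Gene annotation of a synthetic truth
#'
#' @param truth an `apa_truth` object.
#' @return list with `genes` and `features` data frames (0-based half-open),
#'   the annotation format consumed by [assign_gene()].
#' @export
truth_annotation <- function(truth) {
  stopifnot(inherits(truth, "apa_truth"))
  list(genes = truth$genes, features = truth$features)
}

.individual_ids <- function(n) sprintf("ind%03d", seq_len(n))

#' Draw genotypes for a synthetic study
#'
#' Planted QTL SNPs (at the positions fixed in the truth) plus background
#' SNPs around every gene. Allele frequencies are drawn from
#' `config$maf_range` and dosages binomially; draws are repeated until the
#' sample minor-allele frequency is at least 5%, the floor applied by the
#' QTL mapper.
#'
#' @param truth an `apa_truth` object.
#' @param config the same [synth_config()] used for the truth.
#' @return object of class `apa_genotypes`: list with `dosage` (variants x
#'   individuals integer matrix in 0..2) and `map` (snp_id, chrom, pos, af,
#'   planted).
#' @export
generate_genotypes <- function(truth, config) {
  stopifnot(inherits(truth, "apa_truth"), inherits(config, "apa_config"))
  .with_seed(.derive_seed(config$seed, "genotypes"), {
    inds <- .individual_ids(config$n_individuals)
    rows <- list()
    planted <- truth$qtl_effects
    for (i in seq_len(nrow(truth$genes))) {
      g <- truth$genes[i, ]
      pl <- planted[planted$gene_id == g$gene_id, , drop = FALSE]
      pos <- integer(0)
      if (config$n_background_snps > 0L) {
        lo <- max(g$start - 15000L, 100L)
        hi <- min(g$end + 15000L, as.integer(truth$chrom_len[[g$chrom]]) - 100L)
        pos <- sort(sample(lo:hi, config$n_background_snps))
        pos <- setdiff(pos, pl$snp_pos)
      }
      if (length(pos)) {
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = sprintf("snp_%s_%d", g$chrom, pos), chrom = g$chrom,
          pos = pos, planted = FALSE, stringsAsFactors = FALSE)
      }
      if (nrow(pl)) {
        rows[[length(rows) + 1L]] <- data.frame(
          snp_id = pl$snp_id, chrom = pl$chrom, pos = pl$snp_pos,
          planted = TRUE, stringsAsFactors = FALSE)
      }
    }
    map <- do.call(rbind, rows)
    map <- map[!duplicated(map$snp_id), , drop = FALSE]
    map <- map[order(map$chrom, map$pos), , drop = FALSE]
    n <- config$n_individuals
    dosage <- matrix(0L, nrow(map), n, dimnames = list(map$snp_id, inds))
    af <- numeric(nrow(map))
    for (v in seq_len(nrow(map))) {
      repeat {
        f <- runif(1, config$maf_range[1], config$maf_range[2])
        d <- rbinom(n, 2L, f)
        fhat <- mean(d) / 2
        if (min(fhat, 1 - fhat) >= 0.05) break
      }
      dosage[v, ] <- d
      af[v] <- fhat
    }
    map$af <- af
    rownames(map) <- map$snp_id
    out <- list(dosage = dosage, map = map)
    class(out) <- "apa_genotypes"
    out
  })
}

#' @export
print.apa_genotypes <- function(x, ...) {
  cat(sprintf("apa_genotypes: %d variants x %d individuals (%d planted)\n",
              nrow(x$dosage), ncol(x$dosage), sum(x$map$planted)))
  invisible(x)
}

# Truncated discrete Gaussian jitter weights for read 3'-ends around the
# true cleavage site: offsets -peak_width/2 .. +peak_width/2, sd peak_width/4.
.jitter_weights <- function(peak_width) {
  if (peak_width == 0L) return(c(`0` = 1))
  half <- peak_width %/% 2L
  off <- -half:half
  w <- dnorm(off, 0, peak_width / 4)
  w <- w / sum(w)
  names(w) <- off
  w
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) return(rep(1 / length(alpha), length(alpha)))
  g / sum(g)
}

# Expected PAS proportions for one gene, one individual, one fraction.
.expected_props <- function(logits, survival, fraction) {
  p <- .softmax(logits)
  if (fraction == "total") {
    p <- p * survival
    p <- p / sum(p)
  }
  p
}

#' Simulate one 3'-Seq library
#'
#' Draws per-gene read depth (Poisson), allocates reads to PAS by a
#' multinomial (optionally Dirichlet-multinomial) with proportions
#' `softmax(baseline logit + beta * dosage)`; in the total fraction the
#' intronic-PAS terms are first multiplied by their survival factor and
#' renormalized (isoform-specific decay). Read 3'-ends jitter around the
#' true cleavage site; internal-priming traps emit artifact reads at the
#' trap position.
#'
#' @param truth an `apa_truth` object.
#' @param genotypes an `apa_genotypes` object.
#' @param individual individual id (a column of `genotypes$dosage`).
#' @param fraction `"nuclear"` or `"total"`.
#' @param config the study [synth_config()].
#' @return data frame of aggregated read 3'-end positions: chrom, pos
#'   (0-based cleavage site), strand (transcript sense), library_id, count.
#' @export
simulate_library <- function(truth, genotypes, individual, fraction, config) {
  stopifnot(inherits(truth, "apa_truth"))
  if (!fraction %in% c("nuclear", "total")) {
    stop("fraction must be 'nuclear' or 'total'")
  }
  if (!individual %in% colnames(genotypes$dosage)) {
    stop("unknown individual: ", individual)
  }
  lib_id <- paste(individual, fraction, sep = "_")
  .with_seed(.derive_seed(config$seed, paste("lib", individual, fraction)), {
    jw <- .jitter_weights(config$peak_width)
    joff <- as.integer(names(jw))
    pas <- truth$pas
    qtl <- truth$qtl_effects
    dos <- genotypes$dosage[, individual]
    out <- vector("list", nrow(truth$genes) + nrow(truth$artifacts))
    oi <- 0L
    for (i in seq_len(nrow(truth$genes))) {
      gid <- truth$genes$gene_id[i]
      gp <- pas[pas$gene_id == gid, , drop = FALSE]
      logits <- gp$logit
      ql <- qtl[qtl$gene_id == gid, , drop = FALSE]
      if (nrow(ql)) {
        for (r in seq_len(nrow(ql))) {
          j <- match(ql$pas_id[r], gp$pas_id)
          logits[j] <- logits[j] + ql$beta[r] * dos[[ql$snp_id[r]]]
        }
      }
      p <- .expected_props(logits, gp$survival, fraction)
      depth <- rpois(1L, config$read_depth_per_gene)
      if (depth == 0L) next
      if (is.finite(config$overdispersion)) {
        p <- .rdirichlet1(config$overdispersion * p)
      }
      cnt <- rmultinom(1L, depth, p)[, 1L]
      for (j in seq_len(nrow(gp))) {
        if (cnt[j] == 0L) next
        spread <- rmultinom(1L, cnt[j], jw)[, 1L]
        keep <- spread > 0L
        if (!any(keep)) next
        oi <- oi + 1L
        out[[oi]] <- data.frame(
          chrom = gp$chrom[j], pos = gp$pos[j] + joff[keep],
          strand = gp$strand[j], library_id = lib_id,
          count = spread[keep], stringsAsFactors = FALSE)
      }
    }
    if (nrow(truth$artifacts)) {
      for (a in seq_len(nrow(truth$artifacts))) {
        nreads <- rpois(1L, config$artifact_read_rate * config$read_depth_per_gene)
        if (nreads == 0L) next
        oi <- oi + 1L
        out[[oi]] <- data.frame(
          chrom = truth$artifacts$chrom[a], pos = truth$artifacts$pos[a],
          strand = truth$artifacts$strand[a], library_id = lib_id,
          count = nreads, stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, out[seq_len(oi)])
    if (is.null(res)) {
      res <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), library_id = character(),
                        count = integer(), stringsAsFactors = FALSE)
    }
    rownames(res) <- NULL
    res
  })
}

#' Simulate the full two-fraction study
#'
#' Ground truth, genotypes, sample sheet (one nuclear and one total library
#' per individual, batches assigned round robin) and all read sets.
#'
#' @param config a [synth_config()].
#' @return object of class `apa_study`: list with `truth`, `genotypes`,
#'   `samples` (library_id, individual, fraction, batch) and `reads`
#'   (aggregated read 3'-end data frame across libraries).
#' @export
simulate_apa_study <- function(config) {
  truth <- generate_truth(config)
  genotypes <- generate_genotypes(truth, config)
  inds <- colnames(genotypes$dosage)
  samples <- expand.grid(individual = inds, fraction = c("nuclear", "total"),
                         stringsAsFactors = FALSE)
  samples$library_id <- paste(samples$individual, samples$fraction, sep = "_")
  samples$batch <- sprintf("b%d",
    (match(samples$individual, inds) - 1L) %% config$n_batches + 1L)
  samples <- samples[, c("library_id", "individual", "fraction", "batch")]
  reads <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    reads[[i]] <- simulate_library(truth, genotypes, samples$individual[i],
                                   samples$fraction[i], config)
  }
  out <- list(truth = truth, genotypes = genotypes, samples = samples,
              reads = do.call(rbind, reads))
  class(out) <- "apa_study"
  out
}

#' @export
print.apa_study <- function(x, ...) {
  cat(sprintf("apa_study: %d libraries (%d individuals x 2 fractions), %s reads\n",
              nrow(x$samples), length(unique(x$samples$individual)),
              format(sum(x$reads$count), big.mark = ",")))
  print(x$truth)
  invisible(x)
}
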