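# Coverage-based PAS peak calling across libraries, hierarchical gene
# assignment, site-level mispriming filter, and usage quantification.

#' Call PAS peaks from a per-base coverage matrix
#'
#' Low-level peak caller used by [call_peaks()] and directly testable
#' against a brute-force scan. A base qualifies when it has a non-zero
#' count in at least `ceiling(min_nonzero_frac * L)` of the `L` libraries
#' AND a cross-library mean count strictly greater than `min_mean_count`.
#' Maximal runs of consecutive qualifying bases become peaks.
#'
#' @param counts integer matrix, rows = genomic bases (consecutive
#'   coordinates given by `positions`), columns = libraries.
#' @param positions 0-based genomic coordinates of the rows (sorted,
#'   not necessarily contiguous; a coordinate gap always splits peaks).
#' @param strand single strand of this coverage slice ("+" or "-"); the
#'   peak's PAS position is its transcript-sense 3'-most qualifying base.
#' @param min_nonzero_frac fraction of libraries that must be non-zero.
#' @param min_mean_count strict lower bound on the cross-library mean.
#' @return list with `peaks` (data frame: start, end 0-based half-open,
#'   pas_pos) and `counts` (peak x library sums over the peak span).
#' @export
call_peaks_matrix <- function(counts, positions, strand = "+",
                              min_nonzero_frac = 0.9, min_mean_count = 2) {
  stopifnot(is.matrix(counts), length(positions) == nrow(counts))
  L <- ncol(counts)
  if (nrow(counts) == 0L) {
    return(list(peaks = data.frame(start = integer(), end = integer(),
                                   pas_pos = integer()),
                counts = matrix(0L, 0L, L, dimnames = list(NULL, colnames(counts)))))
  }
  o <- order(positions)
  counts <- counts[o, , drop = FALSE]
  positions <- positions[o]
  qual <- rowSums(counts > 0) >= ceiling(min_nonzero_frac * L) &
    rowSums(counts) / L > min_mean_count
  if (!any(qual)) {
    return(list(peaks = data.frame(start = integer(), end = integer(),
                                   pas_pos = integer()),
                counts = matrix(0L, 0L, L, dimnames = list(NULL, colnames(counts)))))
  }
  qp <- positions[qual]
  brk <- c(TRUE, diff(qp) != 1L)
  run <- cumsum(brk)
  start <- tapply(qp, run, min)
  end <- tapply(qp, run, max) + 1L
  pas_pos <- if (strand == "+") end - 1L else start
  pk_counts <- rowsum(counts[qual, , drop = FALSE], run)
  storage.mode(pk_counts) <- "integer"
  rownames(pk_counts) <- NULL
  list(peaks = data.frame(start = as.integer(start), end = as.integer(end),
                          pas_pos = as.integer(pas_pos), row.names = NULL),
       counts = pk_counts)
}

#' Call PAS peaks from pooled library read sets
#'
#' Applies the qualifying-base rule (non-zero in at least 90% of libraries
#' and cross-library mean count above 2, by default) per chromosome and
#' strand over all libraries pooled, and merges maximal runs of qualifying
#' bases into peaks. The PAS position of a peak is its transcript-sense
#' 3'-most qualifying base.
#'
#' @param reads aggregated read data frame (chrom, pos, strand, library_id,
#'   count).
#' @param libraries character vector of all library ids in the experiment
#'   (libraries without reads at a base count as zero).
#' @param min_nonzero_frac,min_mean_count see [call_peaks_matrix()].
#' @return data frame of peaks (chrom, strand, start, end, pas_pos) with a
#'   peak x library count matrix in attribute `counts`.
#' @export
call_peaks <- function(reads, libraries, min_nonzero_frac = 0.9,
                       min_mean_count = 2) {
  .stopifnot_cols(reads, c("chrom", "pos", "strand", "library_id", "count"),
                  "reads")
  libraries <- as.character(libraries)
  if (length(libraries) < 2L) stop("peak calling requires >= 2 libraries")
  if (!all(reads$library_id %in% libraries)) {
    stop("reads contain library ids absent from `libraries`")
  }
  empty <- list(
    peaks = data.frame(chrom = character(), strand = character(),
                       start = integer(), end = integer(),
                       pas_pos = integer(), stringsAsFactors = FALSE),
    counts = matrix(0L, 0L, length(libraries),
                    dimnames = list(NULL, libraries)))
  if (nrow(reads) == 0L) {
    out <- empty$peaks
    attr(out, "counts") <- empty$counts
    return(out)
  }
  key <- split(seq_len(nrow(reads)), paste(reads$chrom, reads$strand))
  pk_list <- list()
  ct_list <- list()
  for (k in names(key)) {
    sub <- reads[key[[k]], , drop = FALSE]
    pos_f <- factor(sub$pos, levels = sort(unique(sub$pos)))
    lib_f <- factor(sub$library_id, levels = libraries)
    m <- matrix(0L, nlevels(pos_f), length(libraries),
                dimnames = list(levels(pos_f), libraries))
    m[cbind(as.integer(pos_f), as.integer(lib_f))] <- 0L  # init
    # accumulate counts (duplicated (pos, lib) pairs summed)
    acc <- rowsum(sub$count, paste(as.integer(pos_f), as.integer(lib_f)))
    ij <- do.call(rbind, strsplit(rownames(acc), " "))
    m[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <- acc[, 1]
    res <- call_peaks_matrix(m, as.integer(levels(pos_f)),
                             strand = sub$strand[1],
                             min_nonzero_frac = min_nonzero_frac,
                             min_mean_count = min_mean_count)
    if (nrow(res$peaks)) {
      res$peaks$chrom <- sub$chrom[1]
      res$peaks$strand <- sub$strand[1]
      pk_list[[k]] <- res$peaks
      ct_list[[k]] <- res$counts
    }
  }
  if (!length(pk_list)) {
    out <- empty$peaks
    attr(out, "counts") <- empty$counts
    return(out)
  }
  peaks <- do.call(rbind, pk_list)
  counts <- do.call(rbind, ct_list)
  o <- order(peaks$chrom, peaks$start)
  peaks <- peaks[o, c("chrom", "strand", "start", "end", "pas_pos")]
  rownames(peaks) <- NULL
  counts <- counts[o, , drop = FALSE]
  attr(peaks, "counts") <- counts
  peaks
}

.CATEGORY_PRIORITY <- c(utr3 = 1L, downstream5kb = 2L, exon = 3L,
                        utr5 = 4L, intron = 5L)

#' Assign peaks to genes by annotation hierarchy
#'
#' Among same-strand features overlapping a peak, the highest-priority
#' class wins, in the order 3' UTR, 5 kb downstream of the gene, exon,
#' 5' UTR, intron. Ties within a class are broken by larger overlap, then
#' lexicographically smaller gene id. The 5-kb-downstream class is derived
#' from the gene spans.
#'
#' @param peaks data frame from [call_peaks()] (chrom, strand, start, end).
#' @param annotation list with `genes` (gene_id, chrom, strand, start, end)
#'   and `features` (gene_id, chrom, strand, category in
#'   utr5/exon/intron/utr3, start, end), 0-based half-open, e.g. from
#'   [truth_annotation()] or [read_annotation_gff3()].
#' @return `peaks` with `gene_id` and `category` columns (NA when no
#'   feature overlaps).
#' @export
assign_gene <- function(peaks, annotation) {
  g <- annotation$genes
  down <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    category = "downstream5kb",
    start = ifelse(g$strand == "+", g$end, pmax(g$start - 5000L, 0L)),
    end = ifelse(g$strand == "+", g$end + 5000L, g$start),
    stringsAsFactors = FALSE)
  feats <- rbind(annotation$features[, c("gene_id", "chrom", "strand",
                                         "category", "start", "end")], down)
  feats <- feats[order(feats$gene_id, feats$category, feats$start), ]
  gr_f <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand)
  gr_p <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = peaks$strand)
  hits <- GenomicRanges::findOverlaps(gr_p, gr_f, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_p)[qh], IRanges::ranges(gr_f)[sh]))
  cand <- data.frame(
    peak = qh, gene_id = feats$gene_id[sh], category = feats$category[sh],
    prio = .CATEGORY_PRIORITY[feats$category[sh]], overlap = ov,
    stringsAsFactors = FALSE)
  cand <- cand[order(cand$peak, cand$prio, -cand$overlap, cand$gene_id), ]
  best <- cand[!duplicated(cand$peak), ]
  peaks$gene_id <- NA_character_
  peaks$category <- NA_character_
  peaks$gene_id[best$peak] <- best$gene_id
  peaks$category[best$peak] <- best$category
  peaks
}

#' Remove internally primed PAS
#'
#' A PAS is removed when the 15 bases immediately downstream (transcript
#' sense) of its position contain at least 6 consecutive A or at least
#' 11 A in total (the smallest count at or above 70% of 15). Windows
#' truncated at a chromosome end are evaluated with the proportional count
#' threshold on the available bases, with a warning.
#'
#' @param pas data frame with chrom, strand and `pas_pos` columns (e.g.
#'   assigned peaks).
#' @param genome named character vector of chromosome sequences.
#' @return the retained rows of `pas`; attribute `n_removed` counts the
#'   removed sites.
#' @export
filter_misprimed_pas <- function(pas, genome) {
  .stopifnot_cols(pas, c("chrom", "strand", "pas_pos"), "pas")
  if (nrow(pas) == 0L) {
    attr(pas, "n_removed") <- 0L
    return(pas)
  }
  win <- .window_downstream(genome, pas$chrom, pas$pas_pos, pas$strand, 15L)
  wlen <- nchar(win)
  if (any(wlen < 15L)) {
    warning(sum(wlen < 15L), " PAS window(s) truncated at a chromosome end; ",
            "evaluated with a proportional A-count threshold")
  }
  thr <- floor(0.7 * wlen) + 1L
  bad <- grepl("AAAAAA", win, fixed = TRUE) | .count_A(win) >= thr
  counts <- attr(pas, "counts")
  out <- pas[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(counts)) attr(out, "counts") <- counts[!bad, , drop = FALSE]
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Quantify PAS usage ratios
#'
#' Counts, per library, the reads whose cleavage position falls inside a
#' peak span (a read overlapping several peaks is counted in each) and
#' divides by the per-library total over all PAS of the same gene. A
#' library where the gene has zero reads yields missing usage, not zero.
#'
#' @param pas assigned, filtered peak data frame with columns chrom,
#'   strand, start, end, pas_pos, gene_id, category (rows with missing
#'   gene_id are dropped).
#' @param reads aggregated read data frame.
#' @param samples sample sheet (library_id, individual, fraction, batch).
#' @return an object of class `apa_usage`: list with `pas` (metadata,
#'   pas_id = chrom:pas_pos:strand:gene), `counts` and `usage` (PAS x
#'   library matrices; usage rows sum to 1 per gene per library where the
#'   gene total is non-zero) and `samples`.
#' @export
quantify_usage <- function(pas, reads, samples) {
  .stopifnot_cols(samples, c("library_id", "individual", "fraction"), "samples")
  if (!all(reads$library_id %in% samples$library_id)) {
    stop("reads contain library ids absent from the sample sheet")
  }
  pas <- pas[!is.na(pas$gene_id), , drop = FALSE]
  if (nrow(pas) == 0L) stop("no PAS with an assigned gene")
  pas$pas_id <- sprintf("%s:%d:%s:%s", pas$chrom, pas$pas_pos, pas$strand,
                        pas$gene_id)
  libs <- samples$library_id
  gr_p <- GenomicRanges::GRanges(
    seqnames = pas$chrom,
    ranges = IRanges::IRanges(start = pas$start + 1L, end = pas$end),
    strand = pas$strand)
  gr_r <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$pos + 1L, width = 1L),
    strand = reads$strand)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_p, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  counts <- matrix(0, nrow(pas), length(libs),
                   dimnames = list(pas$pas_id, libs))
  if (length(qh)) {
    acc <- rowsum(reads$count[qh],
                  paste(sh, match(reads$library_id[qh], libs)))
    ij <- do.call(rbind, strsplit(rownames(acc), " "))
    counts[cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))] <- acc[, 1]
  }
  gene_tot <- rowsum(counts, pas$gene_id)
  tot_per_pas <- gene_tot[pas$gene_id, , drop = FALSE]
  usage <- counts / tot_per_pas
  usage[tot_per_pas == 0] <- NA_real_
  rownames(pas) <- pas$pas_id
  out <- list(pas = pas[, c("pas_id", "gene_id", "category", "chrom",
                            "strand", "start", "end", "pas_pos")],
              counts = counts, usage = usage, samples = samples)
  class(out) <- "apa_usage"
  out
}

#' @export
print.apa_usage <- function(x, ...) {
  cat(sprintf("apa_usage: %d PAS in %d genes x %d libraries\n",
              nrow(x$pas), length(unique(x$pas$gene_id)), ncol(x$usage)))
  tab <- table(x$pas$category)
  cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subset an apa_usage object by PAS
#' @param x `apa_usage` object.
#' @param keep logical or index vector over PAS rows.
#' @return subsetted `apa_usage`.
#' @export
subset_usage <- function(x, keep) {
  stopifnot(inherits(x, "apa_usage"))
  x$pas <- x$pas[keep, , drop = FALSE]
  x$counts <- x$counts[keep, , drop = FALSE]
  x$usage <- x$usage[keep, , drop = FALSE]
  x
}

#' Drop PAS with low mean usage in both fractions
#'
#' A PAS is removed only when its mean usage (over non-missing libraries)
#' is below `min_mean` in the nuclear libraries AND in the total
#' libraries; a site above the threshold in either fraction is kept.
#' The boundary is inclusive: a mean exactly at `min_mean` retains.
#'
#' @param x `apa_usage` object.
#' @param min_mean usage threshold (default 0.05).
#' @return filtered `apa_usage`; attribute `n_removed` counts dropped PAS.
#' @export
filter_low_usage <- function(x, min_mean = 0.05) {
  stopifnot(inherits(x, "apa_usage"))
  nuc <- x$samples$library_id[x$samples$fraction == "nuclear"]
  tot <- x$samples$library_id[x$samples$fraction == "total"]
  mean_nuc <- rowMeans(x$usage[, nuc, drop = FALSE], na.rm = TRUE)
  mean_tot <- rowMeans(x$usage[, tot, drop = FALSE], na.rm = TRUE)
  keep <- (!is.nan(mean_nuc) & mean_nuc >= min_mean) |
    (!is.nan(mean_tot) & mean_tot >= min_mean)
  out <- subset_usage(x, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Run the full PAS discovery pipeline on a read set
#'
#' Mispriming read filter, pooled peak calling, hierarchical gene
#' assignment, PAS-level mispriming filter, usage quantification and the
#' low-usage filter, in the standard order.
#'
#' @param reads aggregated read data frame.
#' @param genome named character vector of chromosome sequences.
#' @param annotation annotation list (see [assign_gene()]).
#' @param samples sample sheet.
#' @param min_nonzero_frac,min_mean_count peak-calling parameters.
#' @param min_mean_usage low-usage filter threshold.
#' @return `apa_usage` object.
#' @export
discover_pas <- function(reads, genome, annotation, samples,
                         min_nonzero_frac = 0.9, min_mean_count = 2,
                         min_mean_usage = 0.05) {
  reads <- filter_misprimed_reads(reads, genome)
  peaks <- call_peaks(reads, samples$library_id,
                      min_nonzero_frac = min_nonzero_frac,
                      min_mean_count = min_mean_count)
  peaks <- assign_gene(peaks, annotation)
  peaks <- filter_misprimed_pas(peaks, genome)
  usage <- quantify_usage(peaks, reads, samples)
  filter_low_usage(usage, min_mean = min_mean_usage)
}
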