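# On-disk representation of a synthetic study, in standard text formats:
# FASTA genome, GFF3 (+ per-feature BED) annotation, VCF 4.2 genotypes,
# BED6 per-library read 3'-ends, TSV sample sheet and truth tables.

.features_granges <- function(truth_or_ann) {
  f <- truth_or_ann$features
  GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand, gene_id = f$gene_id, category = f$category)
}

#' Write a synthetic study to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, per-feature BED files
#' (`utr5.bed`, `exon.bed`, `intron.bed`, `utr3.bed`), `genotypes.vcf`
#' (VCF 4.2, GT field), one `reads_<library>.bed` BED6 per library (one
#' length-1 interval per read, score 1, name = library id), `samples.tsv`,
#' and truth tables `truth_pas.tsv` / `truth_qtl.tsv`.
#'
#' @param study an `apa_study` object.
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, the vector of paths written.
#' @export
write_dataset <- function(study, out_dir, force = FALSE) {
  stopifnot(inherits(study, "apa_study"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory exists and is non-empty; use force = TRUE")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- study$truth
  paths <- character(0)

  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(truth$genome), fa)
  paths <- c(paths, fa)

  # GFF3: gene rows plus feature rows (1-based inclusive at the boundary)
  g <- truth$genes
  gr_gene <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand, type = "gene", ID = g$gene_id, gene_id = g$gene_id)
  f <- truth$features
  type_map <- c(utr5 = "five_prime_UTR", exon = "exon", intron = "intron",
                utr3 = "three_prime_UTR")
  gr_feat <- GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand, type = type_map[f$category],
    ID = sprintf("%s_%s_%d", f$gene_id, f$category, seq_len(nrow(f))),
    gene_id = f$gene_id)
  gff <- file.path(out_dir, "annotation.gff3")
  rtracklayer::export(c(gr_gene, gr_feat), gff, format = "gff3")
  paths <- c(paths, gff)

  for (cat in unique(f$category)) {
    sub <- f[f$category == cat, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = sub$chrom,
      ranges = IRanges::IRanges(start = sub$start + 1L, end = sub$end),
      strand = sub$strand, name = sub$gene_id)
    p <- file.path(out_dir, paste0(cat, ".bed"))
    rtracklayer::export(gr, p, format = "bed")
    paths <- c(paths, p)
  }

  vcf <- file.path(out_dir, "genotypes.vcf")
  .write_vcf(study$genotypes, truth$genome, vcf)
  paths <- c(paths, vcf)

  for (lib in study$samples$library_id) {
    rd <- study$reads[study$reads$library_id == lib, , drop = FALSE]
    rd <- rd[rep(seq_len(nrow(rd)), rd$count), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = rd$chrom,
      ranges = IRanges::IRanges(start = rd$pos + 1L, width = 1L),
      strand = rd$strand, name = lib, score = 1L)
    p <- file.path(out_dir, sprintf("reads_%s.bed", lib))
    rtracklayer::export(gr, p, format = "bed")
    paths <- c(paths, p)
  }

  ss <- file.path(out_dir, "samples.tsv")
  write.table(study$samples, ss, sep = "\t", quote = FALSE, row.names = FALSE)
  tp <- file.path(out_dir, "truth_pas.tsv")
  write.table(truth$pas, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  tq <- file.path(out_dir, "truth_qtl.tsv")
  write.table(truth$qtl_effects, tq, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, ss, tp, tq)
  invisible(paths)
}

# Plain-text VCF 4.2 with GT genotypes; REF taken from the genome, ALT an
# arbitrary different base.
.write_vcf <- function(genotypes, genome, path) {
  map <- genotypes$map
  dos <- genotypes$dosage
  ref <- toupper(substr(genome[map$chrom], map$pos + 1L, map$pos + 1L))
  alt <- c(A = "G", C = "T", G = "A", T = "C", N = "A")[ref]
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow = nrow(dos),
               dimnames = dimnames(dos))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dos)), collapse = "\t"))
  body <- paste(map$chrom, map$pos + 1L, map$snp_id, ref, alt, ".", "PASS",
                sprintf("AF=%.4f", map$af), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genotype VCF into a dosage matrix
#'
#' @param path a VCF file with GT genotypes.
#' @return `apa_genotypes` object (dosage = alternate-allele count 0..2).
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  map <- data.frame(
    snp_id = fix[, "ID"], chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    planted = NA, af = rowMeans(dos) / 2, stringsAsFactors = FALSE)
  rownames(map) <- map$snp_id
  rownames(dos) <- map$snp_id
  out <- list(dosage = dos, map = map)
  class(out) <- "apa_genotypes"
  out
}

#' Read a BED6 file of read 3'-end positions
#'
#' @param path BED6 file; name column is the library id; each interval is
#'   one read 3'-end (length-1).
#' @return aggregated read data frame (chrom, pos, strand, library_id, count).
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    library_id = gr$name, stringsAsFactors = FALSE)
  agg <- aggregate(list(count = rep(1L, nrow(df))),
                   df[, c("chrom", "pos", "strand", "library_id")], sum)
  agg[order(agg$chrom, agg$pos, agg$library_id), , drop = FALSE]
}

#' Read a GFF3 annotation
#'
#' @param path GFF3 with `gene`, `five_prime_UTR`, `exon`, `intron`,
#'   `three_prime_UTR` records carrying a `gene_id` attribute.
#' @return annotation list (`genes`, `features`; 0-based half-open) usable
#'   by [assign_gene()].
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type), gene_id = gr$gene_id,
    stringsAsFactors = FALSE)
  genes <- df[df$type == "gene", c("gene_id", "chrom", "strand", "start", "end")]
  cat_map <- c(five_prime_UTR = "utr5", exon = "exon", intron = "intron",
               three_prime_UTR = "utr3")
  feats <- df[df$type %in% names(cat_map), , drop = FALSE]
  feats$category <- cat_map[feats$type]
  features <- feats[, c("gene_id", "chrom", "strand", "category", "start", "end")]
  rownames(genes) <- rownames(features) <- NULL
  list(genes = genes, features = features)
}

#' Read a genome FASTA as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}
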