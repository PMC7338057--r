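# From mapped 3'-Seq alignments to cleavage-site positions, and removal of
# internally primed (oligo-dT mispriming) reads.

#' Infer cleavage sites from alignments
#'
#' Converts mapped read intervals into single-base cleavage positions on
#' the transcript-sense strand. Under the reverse 3'-Seq protocol (e.g.
#' Lexogen QuantSeq REV) reads map antisense to the transcript and the
#' read's 5' mapping end marks the transcript 3' terminus: a read mapped to
#' the minus strand over `[start, end)` yields a plus-strand transcript
#' cleavage site at `start`. Under a forward protocol the read maps sense
#' and its 3' end is taken.
#'
#' @param alignments data frame with columns chrom, start, end (0-based
#'   half-open mapped interval), strand (mapping orientation) and
#'   library_id; e.g. from [read_alignments_sam()].
#' @param protocol `"reverse"` (default) or `"forward"`.
#' @return aggregated read data frame: chrom, pos (0-based cleavage site),
#'   strand (transcript sense), library_id, count.
#' @export
extract_cleavage_sites <- function(alignments, protocol = c("reverse", "forward")) {
  protocol <- match.arg(protocol)
  .stopifnot_cols(alignments, c("chrom", "start", "end", "strand", "library_id"),
                  "alignments")
  if (nrow(alignments) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), library_id = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  map_plus <- alignments$strand == "+"
  if (protocol == "reverse") {
    tx_strand <- ifelse(map_plus, "-", "+")
    # read 5' mapping end = transcript 3' end
    pos <- ifelse(map_plus, alignments$end - 1L, alignments$start)
  } else {
    tx_strand <- alignments$strand
    pos <- ifelse(map_plus, alignments$end - 1L, alignments$start)
  }
  df <- data.frame(chrom = alignments$chrom, pos = as.integer(pos),
                   strand = tx_strand, library_id = alignments$library_id,
                   stringsAsFactors = FALSE)
  agg <- aggregate(list(count = rep(1L, nrow(df))),
                   df[, c("chrom", "pos", "strand", "library_id")], sum)
  agg[order(agg$chrom, agg$pos, agg$library_id), , drop = FALSE]
}

#' Read alignments from a SAM or BAM file
#'
#' Loads mapped reads with Rsamtools (SAM input is converted to BAM in a
#' temporary file first). Reference-space alignment width is computed from
#' the CIGAR (M/D/N/=/X operations).
#'
#' @param path SAM or BAM file.
#' @param library_id library label for these reads; defaults to the file
#'   name without extension.
#' @return data frame chrom, start, end (0-based half-open), strand
#'   (mapping orientation), library_id.
#' @export
read_alignments_sam <- function(path, library_id = NULL) {
  if (is.null(library_id)) {
    library_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "cigar"),
                               flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(x$pos) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), library_id = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = as.character(x$rname), start = x$pos - 1L,
    end = x$pos - 1L + .cigar_ref_width(x$cigar),
    strand = as.character(x$strand), library_id = library_id,
    stringsAsFactors = FALSE)
}

# Reference-consumed width of CIGAR strings (sum of M, D, N, =, X lengths).
.cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' Remove internally primed reads
#'
#' A 3'-Seq read is treated as an oligo-dT mispriming artifact when the
#' genomic sequence immediately downstream (transcript sense) of its
#' cleavage site is A-rich: at least 6 consecutive A, or at least 7 A in
#' the 10 bases directly adjacent (exclusive of the cleavage base). In
#' read-mapping orientation this is the classical "6 Ts in a row or 7 of
#' 10 Ts upstream of the mapping position" rule; stating it on the
#' transcript sense makes it strand symmetric. Reads whose downstream
#' window is truncated by the chromosome end cannot be assessed and are
#' dropped with a warning.
#'
#' @param reads aggregated read data frame (chrom, pos, strand, library_id,
#'   count).
#' @param genome named character vector of chromosome sequences.
#' @return the retained reads, same structure; attribute `n_removed` gives
#'   the number of reads removed as misprimed.
#' @export
filter_misprimed_reads <- function(reads, genome) {
  .stopifnot_cols(reads, c("chrom", "pos", "strand", "count"), "reads")
  if (nrow(reads) == 0L) {
    attr(reads, "n_removed") <- 0L
    return(reads)
  }
  if (!all(reads$chrom %in% names(genome))) {
    stop("genome does not cover all read chromosomes")
  }
  len <- nchar(genome)[reads$chrom]
  truncated <- ifelse(reads$strand == "+", reads$pos + 10L >= len,
                      reads$pos - 10L < 0L)
  if (any(truncated)) {
    warning(sum(reads$count[truncated]),
            " read(s) within 10 bp of a chromosome end dropped ",
            "(mispriming status not assessable)")
  }
  keep <- reads[!truncated, , drop = FALSE]
  win <- .window_downstream(genome, keep$chrom, keep$pos, keep$strand, 10L)
  bad <- .a_rich(win, run_len = 6L, min_count = 7L)
  out <- keep[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(keep$count[bad]) + sum(reads$count[truncated])
  out
}
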