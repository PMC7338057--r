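#' @importFrom stats rbinom rpois rmultinom rnorm runif rgamma dnorm pnorm qnorm
#'   pchisq pt optim prcomp p.adjust wilcox.test ks.test smooth.spline predict
#'   lm coef quantile sd var cor setNames aggregate model.matrix
#' @importFrom utils write.table read.table head
NULL

# All genomic coordinates inside the package are 0-based; intervals are
# half-open [start, end); single positions (cleavage sites, PAS, SNPs) are
# 0-based. 1-based formats (GFF3, VCF) are converted at the IO boundary.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Extract genome subsequences, 0-based half-open, clipped to [0, chrom
# length). Returns plus-strand sequences. Works per chromosome so the long
# chromosome strings are never replicated.
.fetch_seq <- function(genome, chrom, start, end) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    len <- nchar(genome[[ch]])
    s <- pmax(start[i], 0L)
    e <- pmin(end[i], len)
    res <- substring(genome[[ch]], s + 1L, e)
    res[e <= s] <- ""
    out[i] <- res
  }
  out
}

# Transcript-sense window of `w` bases immediately 3' of position `pos`
# (exclusive of pos itself). Vectorized over pos/chrom/strand.
.window_downstream <- function(genome, chrom, pos, strand, w) {
  plus <- strand == "+"
  out <- character(length(pos))
  if (any(plus)) {
    out[plus] <- .fetch_seq(genome, chrom[plus], pos[plus] + 1L, pos[plus] + 1L + w)
  }
  if (any(!plus)) {
    out[!plus] <- revcomp(.fetch_seq(genome, chrom[!plus], pos[!plus] - w, pos[!plus]))
  }
  out
}

# Transcript-sense window of `w` bases immediately 5' of position `pos`
# (exclusive). The base adjacent to pos is the last character.
.window_upstream <- function(genome, chrom, pos, strand, w) {
  plus <- strand == "+"
  out <- character(length(pos))
  if (any(plus)) {
    out[plus] <- .fetch_seq(genome, chrom[plus], pos[plus] - w, pos[plus])
  }
  if (any(!plus)) {
    out[!plus] <- revcomp(.fetch_seq(genome, chrom[!plus], pos[!plus] + 1L, pos[!plus] + 1L + w))
  }
  out
}

# Count of 'A' characters per string.
.count_A <- function(x) nchar(x) - nchar(gsub("A", "", x, fixed = TRUE))

# TRUE where the window is A-rich under the internal-priming rule:
# >= run_len consecutive A, or >= min_count A in total.
.a_rich <- function(win, run_len, min_count) {
  run <- strrep("A", run_len)
  grepl(run, win, fixed = TRUE) | .count_A(win) >= min_count
}

# Deterministic sub-seed derived from a master seed and a string tag.
# Stays within 32-bit integer range.
.derive_seed <- function(seed, tag) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480009)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Softmax of a numeric vector.
.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

.stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
}
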