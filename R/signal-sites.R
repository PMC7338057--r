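# Polyadenylation signal-site scanning: exact matching of the 12 signal
# hexamer variants upstream of each PAS, positional summaries, and a
# presence comparison against random intronic background windows.

#' The 12 polyadenylation signal hexamers
#'
#' Canonical AATAAA and AATTAA plus ten single-base variants, matched
#' exactly (no mismatches) on the transcript-sense strand.
#' @export
PAS_SIGNAL_MOTIFS <- c("AATAAA", "AATTAA", "AAAAAA", "AAAAAG", "AATACA",
                       "AATAGA", "AATATA", "ACTAAA", "AGTAAA", "CATAAA",
                       "GATAAA", "TATAAA")

#' Scan upstream sequence of PAS for signal hexamers
#'
#' Extracts the `window_up` transcript-sense bases immediately upstream of
#' each PAS position and reports every exact hit of the 12 signal-site
#' hexamers. A hit's offset is the distance from the motif start to the
#' cleavage site (the base adjacent to the PAS has offset 1). The
#' per-PAS flag `has_signal_10_50` is TRUE when any hit starts 10 to 50
#' bases upstream, inclusive — the positional band in which functional
#' signal sites concentrate.
#'
#' @param pas data frame with pas_id, chrom, strand and `pas_pos`.
#' @param genome named character vector of chromosome sequences.
#' @param window_up upstream window length (default 100; truncated at
#'   chromosome start).
#' @return list with `hits` (pas_id, motif, offset) and `pas` (the input
#'   with `has_signal_10_50` added).
#' @export
scan_signals <- function(pas, genome, window_up = 100L) {
  .stopifnot_cols(pas, c("pas_id", "chrom", "strand", "pas_pos"), "pas")
  up <- .window_upstream(genome, pas$chrom, pas$pas_pos, pas$strand, window_up)
  wlen <- nchar(up)
  seqs <- Biostrings::DNAStringSet(up)
  hit_list <- list()
  for (m in PAS_SIGNAL_MOTIFS) {
    mh <- Biostrings::vmatchPattern(m, seqs)
    st <- Biostrings::startIndex(mh)
    idx <- which(lengths(st) > 0)
    for (i in idx) {
      # string index s (1-based) -> offset = window length - s + 1
      hit_list[[length(hit_list) + 1L]] <- data.frame(
        pas_id = pas$pas_id[i], motif = m,
        offset = wlen[i] - st[[i]] + 1L, stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    data.frame(pas_id = character(), motif = character(),
               offset = integer(), stringsAsFactors = FALSE)
  hits <- hits[order(match(hits$pas_id, pas$pas_id), hits$offset), ,
               drop = FALSE]
  rownames(hits) <- NULL
  in_band <- hits$pas_id[hits$offset >= 10L & hits$offset <= 50L]
  pas$has_signal_10_50 <- pas$pas_id %in% in_band
  list(hits = hits, pas = pas)
}

#' Signal-site rate in random intronic windows
#'
#' Draws random fixed-width windows from intronic intervals and returns
#' the fraction containing at least one of the 12 signal hexamers on the
#' interval's sense strand — the background presence rate against which
#' PAS-proximal enrichment is judged.
#'
#' @param introns data frame of intronic intervals (chrom, strand, start,
#'   end; 0-based half-open). Introns shorter than `width` are skipped.
#' @param genome named character vector of chromosome sequences.
#' @param width window width (default 40).
#' @param n_draws number of random windows.
#' @param seed RNG seed.
#' @return list with `rate`, `n_draws`, `n_hit`.
#' @export
background_signal_rate <- function(introns, genome, width = 40L,
                                   n_draws = 1000L, seed = 1L) {
  .stopifnot_cols(introns, c("chrom", "strand", "start", "end"), "introns")
  introns <- introns[introns$end - introns$start >= width, , drop = FALSE]
  if (nrow(introns) == 0L) stop("no intron of at least `width` bases")
  .with_seed(seed, {
    pick <- sample.int(nrow(introns), n_draws, replace = TRUE)
    off <- floor(runif(n_draws) * (introns$end[pick] - introns$start[pick] -
                                     width + 1L))
    s0 <- introns$start[pick] + off
    win <- .fetch_seq(genome, introns$chrom[pick], s0, s0 + width)
    minus <- introns$strand[pick] == "-"
    if (any(minus)) win[minus] <- revcomp(win[minus])
    pat <- paste(PAS_SIGNAL_MOTIFS, collapse = "|")
    hit <- grepl(pat, win)
    list(rate = mean(hit), n_draws = n_draws, n_hit = sum(hit))
  })
}

#' Two-sample proportion test (pooled z)
#'
#' Two-sided z-test for a difference of proportions with pooled variance,
#' as used to compare signal-site presence between PAS classes and against
#' the intronic background.
#'
#' @param k1,n1 successes and size of group 1.
#' @param k2,n2 successes and size of group 2.
#' @return list with `statistic` (z), `p.value`, `estimate` (p1, p2).
#' @export
proportion_diff_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (k1 > n1 || k2 > n2) stop("successes cannot exceed group size")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(statistic = z, p.value = 2 * pnorm(-abs(z)),
       estimate = c(p1 = p1, p2 = p2))
}
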