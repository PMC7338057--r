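# Independent brute-force oracles used to pin expected values.

# Per-base scan + run merge peak caller, written as directly as possible.
brute_force_peaks <- function(counts, positions, strand = "+",
                              min_nonzero_frac = 0.9, min_mean_count = 2) {
  L <- ncol(counts)
  o <- order(positions)
  counts <- counts[o, , drop = FALSE]
  positions <- positions[o]
  qual <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    qual[i] <- sum(counts[i, ] > 0) >= ceiling(min_nonzero_frac * L) &&
      mean(counts[i, ]) > min_mean_count
  }
  peaks <- list()
  cur <- NULL
  for (i in seq_len(nrow(counts))) {
    if (!qual[i]) next
    if (!is.null(cur) && positions[i] == cur$end) {
      cur$end <- positions[i] + 1L
      cur$rows <- c(cur$rows, i)
    } else {
      if (!is.null(cur)) peaks[[length(peaks) + 1L]] <- cur
      cur <- list(start = positions[i], end = positions[i] + 1L, rows = i)
    }
  }
  if (!is.null(cur)) peaks[[length(peaks) + 1L]] <- cur
  if (!length(peaks)) {
    return(list(peaks = data.frame(start = integer(), end = integer(),
                                   pas_pos = integer()),
                counts = matrix(0L, 0L, L)))
  }
  df <- data.frame(
    start = vapply(peaks, `[[`, integer(1), "start"),
    end = vapply(peaks, `[[`, integer(1), "end"))
  df$pas_pos <- if (strand == "+") df$end - 1L else df$start
  cnt <- t(vapply(peaks, function(p) {
    colSums(counts[p$rows, , drop = FALSE])
  }, numeric(L)))
  list(peaks = df, counts = cnt)
}

# Dirichlet-multinomial pmf by explicit Polya-urn enumeration: sum the
# sequential draw probabilities over every ordering of the count vector.
polya_urn_pmf <- function(x, p, alpha0) {
  a <- alpha0 * p
  K <- length(x)
  total <- 0
  rec <- function(remaining, drawn, prob) {
    if (sum(remaining) == 0L) {
      total <<- total + prob
      return(invisible())
    }
    t <- sum(drawn)
    for (k in seq_len(K)) {
      if (remaining[k] == 0L) next
      pk <- (a[k] + drawn[k]) / (alpha0 + t)
      r2 <- remaining; r2[k] <- r2[k] - 1L
      d2 <- drawn; d2[k] <- d2[k] + 1L
      rec(r2, d2, prob * pk)
    }
  }
  rec(as.integer(x), integer(K), 1)
  total
}

# Naive sliding-window motif scan of an upstream sequence; returns offsets
# (motif start to cleavage site) for one motif.
naive_motif_offsets <- function(upstream_seq, motif) {
  w <- nchar(upstream_seq)
  m <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(max(w - m + 1L, 0L))) {
    if (substr(upstream_seq, i, i + m - 1L) == motif) {
      hits <- c(hits, w - i + 1L)
    }
  }
  hits
}

# Textbook Benjamini-Hochberg decision rule.
brute_force_bh <- function(p, fdr) {
  n <- length(p)
  o <- order(p)
  ok <- which(p[o] <= fdr * seq_len(n) / n)
  sig <- logical(n)
  if (length(ok)) sig[o[seq_len(max(ok))]] <- TRUE
  sig
}
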