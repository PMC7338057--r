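# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small two-fraction study used by module-level property tests.
shared_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- synth_config(n_individuals = 12, n_genes = 40, seed = 421)
    .fixture_env$study <- simulate_apa_study(cfg)
  }
  .fixture_env$study
}

# Quantified usage before the low-usage filter (usage columns still sum
# to 1 per gene) and after it (the pipeline's final catalog).
shared_quantified <- function() {
  if (is.null(.fixture_env$quantified)) {
    s <- shared_study()
    reads <- filter_misprimed_reads(s$reads, s$truth$genome)
    pk <- call_peaks(reads, s$samples$library_id)
    pk <- assign_gene(pk, truth_annotation(s$truth))
    pk <- filter_misprimed_pas(pk, s$truth$genome)
    .fixture_env$quantified <- quantify_usage(pk, reads, s$samples)
  }
  .fixture_env$quantified
}

shared_usage <- function() {
  if (is.null(.fixture_env$usage)) {
    .fixture_env$usage <- filter_low_usage(shared_quantified())
  }
  .fixture_env$usage
}

# Hand-built apa_usage object from a PAS x library count matrix.
# gene_ids: per PAS; fractions: per library.
make_usage <- function(counts, gene_ids, fractions,
                       categories = rep("utr3", nrow(counts))) {
  n_pas <- nrow(counts)
  libs <- sprintf("lib%02d", seq_len(ncol(counts)))
  colnames(counts) <- libs
  pas <- data.frame(
    pas_id = sprintf("chr1:%d:+:%s", 100L * seq_len(n_pas), gene_ids),
    gene_id = gene_ids, category = categories, chrom = "chr1",
    strand = "+", start = 100L * seq_len(n_pas),
    end = 100L * seq_len(n_pas) + 1L, pas_pos = 100L * seq_len(n_pas),
    stringsAsFactors = FALSE)
  rownames(counts) <- pas$pas_id
  gene_tot <- rowsum(counts, pas$gene_id)[pas$gene_id, , drop = FALSE]
  usage <- counts / gene_tot
  usage[gene_tot == 0] <- NA_real_
  samples <- data.frame(
    library_id = libs,
    individual = sprintf("ind%02d", seq_len(ncol(counts))),
    fraction = fractions, batch = "b1", stringsAsFactors = FALSE)
  out <- list(pas = pas, counts = counts, usage = usage, samples = samples)
  class(out) <- "apa_usage"
  out
}

# Genome fixture: one chromosome from explicit sequence.
make_genome <- function(seq, chrom = "chrT") setNames(seq, chrom)
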