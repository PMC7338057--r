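---
title: "Models and methods in apaqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in apaqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

apaqtl quantifies alternative polyadenylation (APA) from 3'-end
sequencing and maps cis genetic effects on polyadenylation-site (PAS)
choice. This vignette documents the statistical models, the conventions
the implementation pins down, the synthetic-study generator that the test
suite exercises the pipeline on, and the limits of what those tests show.

## Coordinates and conventions

All internal coordinates are 0-based; intervals are half-open
`[start, end)`; single positions (cleavage sites, PAS, SNPs) are 0-based
base coordinates. One-based formats (GFF3, VCF) are converted at the IO
boundary. "Downstream" and "upstream" always mean transcript sense: for a
minus-strand site the downstream window lies at lower genomic
coordinates and is reverse-complemented before inspection.

## Internal-priming filters

Oligo-dT primers anneal to genomic A-stretches as well as to polyA
tails, creating spurious cleavage sites. Two filters address this:

* **Read level** — a read is removed when the 10 bases immediately 3' of
  its cleavage site (exclusive of the site itself) contain ≥ 6
  consecutive A or ≥ 7 A in total. Stated in read-mapping orientation
  this is the familiar "6 Ts in a row or 7 of 10 Ts directly upstream of
  the mapping position"; the transcript-sense statement is equivalent and
  strand-symmetric, which is the form the tests pin. The window is
  anchored at the base adjacent to the cleavage position, exclusive of
  it; the anchoring convention is not uniquely determined by the verbal
  rule, so the exclusive reading is adopted and documented here. Reads
  within 10 bases of a chromosome end cannot be assessed and are dropped
  with a warning.
* **Site level** — a called PAS is removed when the 15 bases downstream
  contain ≥ 6 consecutive A or ≥ 11 A in total. Eleven is the smallest
  integer count at or above 70% of 15 (10/15 = 66.7% would pass a strict
  70% bound), so "70% A" is implemented as ≥ 11. Windows truncated at a
  chromosome end are evaluated with the proportional threshold
  `floor(0.7 * length) + 1` on the available bases.

Both filters are idempotent and can only shrink the read/site set.

## Peak calling

Libraries are pooled (nuclear and total together, matching a design in
which one merged catalog serves both fractions; per-fraction calling is a
matter of subsetting the input). A genomic base qualifies when

* it has a non-zero count in at least `ceiling(0.9 * L)` of the `L`
  libraries, and
* its cross-library mean count is strictly greater than 2.

Maximal runs of consecutive qualifying bases on one strand form peaks;
any non-qualifying base (or coordinate gap) splits runs — no minimum
width or inter-peak gap is imposed. The PAS coordinate of a peak is its
transcript-sense 3'-most qualifying base. Both boundary readings (≥ for
the 90% rule, strict > for the mean) are pinned by tests, and the
implementation is verified base-for-base against a brute-force per-base
scan on random coverage matrices.

## Gene assignment

Peaks are assigned among the same-strand features they overlap with the
priority **3' UTR > 5 kb downstream of the gene > exon > 5' UTR >
intron**; the downstream class is derived from gene spans at assignment
time. Ties within a class are broken by larger overlap, then
lexicographically smaller gene id, making the assignment deterministic
and independent of annotation row order.

## Usage ratios

`quantify_usage()` counts, per library, reads whose cleavage position
falls within a peak span; a read overlapping several peaks is counted in
each (mirroring feature-counting with multi-overlap assignment). Usage is
the count divided by the per-library total over all PAS of the same
gene; a zero gene total yields missing values, never zeros. Within every
gene and library with non-zero total, usage sums to 1 by construction —
an invariant the acceptance suite checks across a full synthetic run.
The low-usage filter then removes sites below 5% mean usage in **both**
fractions (inclusive boundary: exactly 5% is kept), so a
nuclear-specific site is retained on the strength of its nuclear usage
alone.

## Signal sites

The 12 polyadenylation signal hexamers (AATAAA, AATTAA, AAAAAA, AAAAAG,
AATACA, AATAGA, AATATA, ACTAAA, AGTAAA, CATAAA, GATAAA, TATAAA) are
matched exactly — no mismatches, no position-weight matrices — on the
transcript-sense 100 bases upstream of each PAS. A hit's offset is
measured from motif start to the cleavage site, the adjacent base having
offset 1; `has_signal_10_50` is true when a hit starts 10–50 bases
upstream, both ends inclusive (the histogram convention is not uniquely
determined; this one is pinned and tested against a naive sliding-window
scan). The background rate draws random 40-base intronic windows. Rates
are compared with a pooled two-proportion z-test, two-sided.

## Differential usage between fractions

For one gene with K PAS, the count vector of sample *s* is modeled as
Dirichlet-multinomial with mean proportions **p** and concentration α₀
(α = α₀·**p**), which adds the across-sample overdispersion a plain
multinomial lacks. The test compares

* null: one **p** shared by both fractions, concentration α₀;
* alternative: a separate **p** per fraction, shared α₀.

The likelihood-ratio statistic is referred to χ²(K−1). Whether the
original analysis shared the concentration across fractions cannot be
determined from its description; sharing it is adopted here and stated
as a design choice. Numerically, the likelihood is profiled: for fixed
α₀ the fractions decouple and each proportion vector is optimized by
BFGS on K−1 free logits (relative tolerance 1e-10, warm-started across
outer evaluations); the profile likelihood is then maximized over
log α₀ on [log 1e−2, log 1e8] by bounded 1-D search with tolerance
1e-8. The likelihood is nearly flat in α₀ beyond ~10⁴ (the multinomial
limit), which a joint quasi-Newton handles poorly but the profile search
traverses without difficulty. Degenerate tables (all counts on one PAS)
give a zero statistic.

ΔPAU is computed from raw usage: mean total-fraction usage minus mean
nuclear usage over samples with non-zero gene totals, so per-gene ΔPAU
values sum to zero. Positive ΔPAU means higher usage in the total
fraction. After Benjamini–Hochberg correction over genes at 10% FDR,
PAS with |ΔPAU| > 0.2 inside significant genes are labeled by direction;
`nuclear_enriched_pas()` returns the ΔPAU ≤ −0.2 set and flags sites
with mean total usage ≤ 1% as near-absent from the total pool.

Under the generator's default (multinomial) null the LRT p-values are
uniform and rejection at α = 0.05 sits at its nominal level (checked on
500 simulated null genes). Under a strongly overdispersed null
(Dirichlet-multinomial, α₀ = 60) the test with an estimated shared
concentration is mildly anticonservative at 20+20 samples; a regression
test guards against gross miscalibration, and results on strongly
overdispersed data should be read with that in mind.

## cis-apaQTL mapping

Per fraction, libraries are collapsed to individuals and each PAS row of
the usage matrix becomes a phenotype: missing entries are imputed to the
row mean (keeping one design matrix across PAS), the row is centered and
scaled, rank-based inverse-normal transformed with offset
(rank − 0.5)/n (ties by average rank), and rescaled to exactly zero mean
and unit variance. Any offset convention preserves the rank invariance
that matters; this one is pinned by tests. Rows with zero variance or
fewer than 5 observed individuals are dropped.

Covariates are the top 4 principal components of the phenotype matrix
(individuals as observations) plus one-hot batch indicators.
Associations use OLS of phenotype on dosage with covariates, computed by
Frisch–Waugh residualization of both sides on the covariates — exactly
the multiple-regression t-test, verified against a hand-coded
normal-equations solver. The cis window is ±25 kb around the PAS,
inclusive at the bound; only variants with sample MAF above 5% are
tested.

The permutation pass permutes the phenotype vector across individuals
(covariate–genotype configuration fixed), recomputes the window's
minimum nominal p each time, and reports
`(1 + #{permuted ≤ observed}) / (B + 1)` with B = 1000 by default.
The empirical scheme is the contract here; a beta approximation to the
permutation null (used by standard QTL mappers for speed) is not
implemented because at these problem sizes the empirical pass is fast
enough and exactly testable. apaQTLs are variants passing 10% BH FDR
computed over all PAS-level permutation p-values within a fraction
jointly, not per gene; a per-gene rollup is available by taking each
gene's best PAS. Raw-scale effect sizes (`slope_raw`) are
covariate-adjusted OLS slopes of the *pre-normalized* usage ratio on
dosage — interpretable as Δusage per alternate allele.

## Cross-dataset statistics

* **Storey π1** — π0(λ) = #{p > λ}/(n(1−λ)) on λ = 0.05…0.95 (step
  0.05); final π0 from a cubic smoothing spline (df = 3) evaluated at
  the largest λ, falling back to the mean of the three largest-λ
  estimates when the fit degenerates (both rules are exposed; the
  recovery and monotonicity properties hold for either). The estimator
  needs well-separated alternatives to be unbiased: with heavy-tailed
  alternative p-value distributions some alternative mass lies above
  every λ and π1 is underestimated by construction. The recovery
  simulations therefore draw alternatives as two-sided normal p-values
  with mean shift 3.5 (well-powered tests), for which the estimand
  matches the injected mixture weight.
* **Effect concordance** — Pearson r and the OLS slope of one fraction's
  lead-SNP raw slopes on the other's, for pairs matched by PAS and SNP
  (`replicate_qtls()` recomputes the same pair in the other fraction).
* **Category enrichment** — one-sided Wilcoxon rank-sum tests that a
  category's association p-values are stochastically smaller than the
  background category's (exact for small untied samples, normal
  approximation with tie correction otherwise, as `wilcox.test`
  provides).
* **External-QTL overlap** — per gene-variant pair, the most significant
  nominal APA association across the gene's PAS, Bonferroni-corrected by
  the number of PAS tested in the gene, flagged below 0.05.
* **Annotation overlap** — per annotation class, the proportion of
  variants falling in it, with percentile 95% CIs from 1000 bootstrap
  resamples of the variant set.

## The synthetic-study generator

`generate_truth()` builds a uniform-composition genome with a fixed gene
architecture (200 bp 5' UTR, 500 bp exon, 1.5 kb intron, 500 bp exon,
1 kb 3' UTR; 50 genes per chromosome, 5.8 kb apart so one gene's
5-kb-downstream zone never reaches the next gene body; all plus strand
by default, mixed strands optional). Each gene receives 2–3 PAS in
distinct structural slots (3'UTR end, intron, mid-3'UTR, exon). Choices
the generator makes, and why:

* **Baseline usage.** 3'UTR-site logits are drawn N(0.8, 0.4); intronic
  and exonic logits are drawn relative to the pooled 3'UTR mass (offset
  −1.35 plus log(K−1)) with sd 0.45, which centers intronic usage near
  17–20% regardless of how many sites the gene carries — the regime in
  which intronic sites are minor but quantifiable isoforms.
* **Signal sites.** Every true PAS gets one of the 12 hexamers planted
  15–45 bases upstream, sampled with most mass on AATAAA; peak jitter
  shifts the recovered site by a base or two, keeping the recovered
  offset inside the functional 10–50 band.
* **A-poor collars.** The 29 bases around each true cleavage site (9
  upstream through 19 downstream) are rejection-sampled to contain no
  6-A run, < 7 A per 10-base subwindow and < 11 A per 15-base subwindow,
  so genuine sites never trip the mispriming filters regardless of
  jitter — making filter specificity a designed property rather than a
  seed-dependent accident.
* **Internal-priming traps.** A configurable fraction of genes (default
  10%) carries a 20-A stretch in the second exon; artifact reads are
  emitted at the trap at 30% of the gene's depth. Both filters catch
  traps by construction (the read filter removes the reads; the site
  filter removes any peak called there when the read filter is
  bypassed).
* **Genetic effects.** A fraction of genes (default 10%) get one causal
  SNP, 0.2–8 kb from the target PAS (always inside the ±25 kb window),
  with logit-scale effect β (default 1.5, random sign) added as
  β·dosage to the target PAS's logit. Dosages are binomial in an allele
  frequency drawn from `maf_range`, resampled until the sample MAF
  clears the 5% floor the mapper applies. Eight background SNPs per gene
  provide the null tests. No linkage disequilibrium is simulated, which
  is what makes lead-SNP localization a meaningful check.
* **Decay.** In the total fraction, intronic-PAS proportions are
  multiplied by the survival factor (default 0.5) and renormalized —
  the observable consequence of rapid decay of prematurely
  polyadenylated transcripts; nuclear proportions are untouched.
* **Counts and peaks.** Per gene and library, depth is Poisson (default
  mean 300 — 3'-Seq concentrates a gene's reads onto a few bases, so
  hundreds of reads per gene per library is the realistic regime and
  keeps marginal sites above the 90%-of-libraries rule); counts are
  multinomial in the expected proportions (a Dirichlet-multinomial
  option, off by default, provides overdispersed data for stressing the
  DM test); read 3'-ends jitter by a truncated discrete Gaussian within
  ±3 bases (sd `peak_width/4`), producing multi-base peaks for the
  caller.
* **Seeds.** One master seed; every library, the genotype draw and the
  truth derive independent streams by stable hashing of (seed, role), so
  a study is byte-reproducible while libraries stay independent.

What the generator does **not** emulate: sequencing errors, polyA-tail
or priming-position heterogeneity beyond the Gaussian jitter, LD
structure, overlapping or nested genes, expression-level variation
between genes beyond Poisson depth, population structure, and batch
effects on usage itself (batch labels exist for the covariate machinery;
a planted batch shift is exercised in unit tests). Passing tests
therefore show that the algorithms implement their definitions and
recover planted structure under a faithful-but-clean model — not that
the pipeline is robust to every artifact of real libraries.

## Problem sizes

The test-suite and acceptance-script runs use desk-scale versions of the
emulated design, chosen to exercise every code path while keeping a full
run in minutes: 200-gene default studies (52 individuals), a 300-gene
QTL study at B = 200 permutations, a 250-gene no-decay study at B = 150
for cross-fraction sharing, 500 simulated null genes for DM calibration,
and 1000 random coverage matrices for the peak-caller oracle. B = 1000
remains the default for real analyses; permutation p-values at B = 200
resolve to 1/201 ≈ 0.005, which is sufficient for 10% FDR over a few
hundred tests.

## Known limitations

* The DM test's shared-α₀ choice and its mild small-sample
  anticonservativeness under strong overdispersion (above).
* Peak calling has no minimum width or merge gap; a single
  non-qualifying base splits peaks. On very deep data this can fragment
  wide cleavage regions into adjacent sites.
* Multi-overlap read counting double-counts reads where peaks overlap
  on the same strand (by design, matching multi-overlap feature
  counting); with the caller's disjoint same-strand peaks this arises
  only for user-supplied catalogs.
* `normalize_phenotypes()` expects one library per individual per
  fraction; technical replicates must be collapsed upstream.
* π1 is a biased-down estimator under weak alternatives; treat it as a
  sharing summary, not an effect-size-free replication rate.
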