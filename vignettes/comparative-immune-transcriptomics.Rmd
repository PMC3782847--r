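---
title: "Methods: comparative immune transcriptomics from single pyrosequencing libraries"
author: "pyroimmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative immune transcriptomics from single pyrosequencing libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroimmune)
library(dplyr)
```

# The analysis problem

Insect innate immunity studies often compare the transcriptome of infected
and naive larvae with exactly one sequencing library per condition — for
example, fat-body/salivary-gland 454 libraries from fungus-infected and
naive *Drosophila virilis* and *D. melanogaster* larvae, each library a pool
of twenty individuals. With no biological replicates, the standard
replicate-based differential-expression machinery does not apply; instead
the analysis proceeds through a chain of simple, auditable steps:

1. **Read triage.** Each read is queried against reference sets in a fixed
   cascade — mitochondrial genome, then ribosomal RNA, then CDS, then gene,
   then transcript databases — and the first hit stops the cascade. Reads
   hitting nothing are *unidentified* and feed the novel-gene search.
2. **Quantification.** Per-gene counts are normalized for transcript length
   and depth as *reads per site per million reads*,
   $\mathrm{RPSM} = \frac{\text{reads}/\text{total reads}}{\text{transcript length}} \times 10^6$,
   then adjusted for between-library expression shifts with a
   trimmed-mean-of-M-values (TMM) scaling factor. The **induction
   coefficient** is $\mathrm{IC} = \mathrm{TMM}_{\text{infected}} /
   \mathrm{TMM}_{\text{naive}}$, with the distinguished value `Inf` when
   expression is seen only after infection and `NA` when a gene is silent in
   both libraries.
3. **Significance.** Each gene's raw counts are compared with the pooled
   counts of two endogenous control genes (RpL32- and GAPDH-style
   housekeeping genes) in a 2×2 contingency table: Pearson's chi-square
   (1 df, no continuity correction) when every cell holds at least five
   reads, otherwise the two-sided Fisher exact test.
4. **Summaries.** Regulation categories (IC > 2, 1 < IC ≤ 2, 0.5 ≤ IC < 1,
   IC < 0.5, infected-only), immune-class tallies, cross-species effector
   panels and Venn counts of expressed genes.
5. **Novel genes.** Unidentified reads are placed on the genome, merged into
   contigs, extended by ±250 bp of flanking sequence (contigs are often
   3'-UTR-sized fragments), screened by six-frame translated homology
   against a protein database at e ≤ 1e-5, and tested for induction like
   annotated genes.
6. **AMP screening.** Species-specific gene products are screened for the
   hallmarks of antimicrobial peptides: a signal peptide, a propeptide
   ending in a dibasic motif, and a short cationic mature peptide.
7. **Phylogeny.** Mature-peptide alignments are turned into
   Poisson-corrected distances ($d = -\ln(1-p)$) and a neighbor-joining
   tree with bootstrap supports.
8. **Resistance assay.** The median lethal time (LT50) is estimated from
   daily survival counts with a binomial GLM on cumulative deaths
   (logit link), $\mathrm{LT50} = -\hat\alpha/\hat\beta$.

The package implements each step as a tibble-in/tibble-out function so the
whole pipeline composes with the pipe, and ships a synthetic-data generator
that produces every input with known truth labels.

# Key parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| TMM trim fractions | 0.30 (M), 0.05 (A) | — | canonical trimmed-mean-of-M-values settings; the method's published description names the estimator but not its parameters |
| RPSM "total reads" | reads assigned to nuclear genes | reads | organellar/ribosomal fractions differ grossly between libraries and would distort per-million scaling; configurable via `totals` |
| Chi-square/Fisher switch | min cell ≥ 5 | reads | the standard chi-square validity rule; the published wording ("minimum number of reads was five or more") is read as the minimum over all four cells |
| Significance level | 0.05 | — | the `*`/`**` star convention (p < 0.05 / p < 0.01) |
| Multiple testing | none (BH optional) | — | raw p-values are reported, as in the original analyses |
| Matcher | exact + k-mer (k = 16) seed, ≥95 % identity over ≥90 % of the read | — | deterministic, parameterized stand-in for an external aligner; the matcher argument accepts any function with the same contract |
| Novel-gene flank | 250 | bp | recovers coding sequence adjacent to UTR-sized contigs |
| Karlin–Altschul constants | λ = 0.267, K = 0.041 | — | standard gapped BLOSUM62 values; calibrated by a null simulation (no false hits at e ≤ 1e-5 across random 300-nt queries) |
| AMP verdict | secreted ∧ charge ≥ +2 ∧ 10–100 aa | — | one transparent rule replacing a consensus of external predictors that disagree with each other; propeptide presence is reported, not required |
| Survival link | logit | — | probit available; LT50 is −intercept/slope under either |

# The synthetic-data generator

The generator defines the study conditions under which every property of the
pipeline is asserted:

* **Catalog** (`sim_gene_catalog()`): multinomial immune-class labels,
  gamma-distributed CDS lengths (mean 900 bp, floored at 150 bp), clean open
  reading frames, two endogenous controls forced into the highly expressed
  range, homologue identifiers for cross-species mapping.
* **Counts** (`sim_count_experiment()`): negative-binomial counts with
  dispersion 0.1 by default (a standard over-dispersion level for RNA count
  data; the original pooled-larvae libraries publish no variance
  information, so this is a package choice, not a calibrated one). Means are
  `depth × abundance × fold change`; the reserved `Inf` fold change yields
  an exactly zero naive count. Default depths (55 000 / 62 000) mirror the
  scale of reads assigned to nuclear genes in the motivating study.
* **Reads** (`sim_read_library()`): error-free forward-strand substrings of
  a single genome string with annotated mito/rRNA/gene/unannotated segments;
  default mix 5 % mito, 25 % rRNA, 50 % gene, 20 % unannotated, matching the
  observed accounting of an infected *D. virilis* library. A uniform
  substitution rate is available; sequencing errors are off by default so
  triage correctness is testable exactly before robustness.
* **Peptides** (`sim_precursor_peptides()`): signal (charged n-region,
  hydrophobic core, small-residue cleavage context) + propeptide ending in a
  dibasic motif + cationic mature segment. Non-AMP truth peptides violate
  the verdict-relevant criteria (hydrophobic core and/or mature charge), a
  share of them additionally lacking the dibasic motif — a peptide violating
  *only* the propeptide criterion would still pass the default verdict, so
  it cannot serve as a negative example.
* **Survival** (`sim_survival_counts()`): per-fly logistic death times with
  location LT50 and scale 1/slope, counted at integer days; under this model
  the cumulative death fraction at integer days is exactly logit-linear, so
  the GLM estimator is unbiased by construction (a Weibull generator would
  not have that property and was deliberately not used).

What the generator does **not** emulate: 454 homopolymer indel errors,
quality scores, paired ends, reverse-strand reads, isoforms, and biological
replicate structure. Passing tests therefore demonstrate the correctness of
the pipeline's logic and statistics under its own assumptions, not
robustness to every artefact of real pyrosequencing data.

# Numerical and design choices

* **Coordinates** are 1-based inclusive throughout (the R/IRanges idiom).
* **Matcher tie-break**: highest score, then longest aligned span, then
  lexicographically smallest target id, then leftmost position. A read
  counts toward exactly one gene.
* **TMM factors** are scaled so their product is 1; the naive library is
  the M-value reference. Genes with a zero in either library are excluded
  before trimming; a fully trimmed set falls back to the untrimmed weighted
  mean. Weights are inverse asymptotic binomial variances.
* **Category boundaries**: IC exactly 2 → weak up; exactly 0.5 → weak down;
  exactly 1 → unchanged.
* **Fisher's exact test** uses the probability-mass two-sided rule (the R
  default), and with a single control gene the homogeneity p-value is 1 by
  convention.
* **Signal-peptide core** is a run of ≥6 consecutive residues each with
  Kyte–Doolittle hydropathy ≥1.6 (so every six-residue window of the core
  has mean ≥1.6). A windowed-mean rule alone would greedily absorb the
  cleavage context into the core.
* **Net charge** counts side chains only (#K + #R − #D − #E, His neutral);
  molecular weight uses average free amino-acid masses minus one 18.02 Da
  water per bond, matching integer charges and two-decimal kDa values
  reported for insect AMP candidates.
* **Neighbor joining** breaks Q-criterion ties toward the lowest index pair
  and clamps negative branch-length estimates to zero with a warning.
  Distances use pairwise gap deletion by default (complete deletion by
  flag). Bootstrap replicates whose resampled columns give an undefined
  Poisson distance (saturated pair) are redrawn and counted.
* **Putative genes** have no transcript length, so their induction
  coefficient uses depth-normalized read counts rather than TMM values —
  a documented divergence from the annotated-gene formula, consistent with
  reporting only read counts and IC for such genes.
* **Complete separation** in a survival series (all alive → all dead with no
  partial day) cannot be fitted by a GLM; the estimator falls back to the
  midpoint of the two days and flags the result.

# Calibration experiments in the test suite

The type-I-error property (fraction of null genes with p < 0.05 within the
99 % binomial band around 0.05, ≥2 000 genes) is asserted under Poisson
sampling (`dispersion = 0`). The control-anchored 2×2 test assumes no
extra-Poisson noise — with a single pooled library per condition there is no
information to estimate biological dispersion — so nominal calibration is a
property of the test *under its own sampling model*. Under the generator's
default dispersion of 0.1 the test is anti-conservative, which is precisely
the known limitation of unreplicated designs; the power property (≥80 % of
fold-change-4 genes with expected infected count ≥50 called significantly
up) *is* asserted at the default dispersion and holds despite it.

Problem sizes used by the tests and the acceptance script — 2 500-gene null
experiments, 5 000-read triage worlds with five planted hidden genes,
10 000-fly survival cohorts, 1 000 random contingency tables, additive trees
up to 12 taxa — were chosen as the smallest sizes at which the binomial
99 % bands and recovery thresholds are informative.

# Known limitations

* The built-in matcher is exact/near-exact and ungapped; real 454 reads
  carry homopolymer indels that require a gapped aligner (the matcher
  argument accepts one).
* Printed per-gene p-values from the motivating study depend on control
  counts published only in supplementary material, and its TMM columns on
  unknown normalization settings; both are validated here through oracle
  and calibration properties rather than value-by-value reproduction.
* Venn duplicate accounting relies on homologue-family identifiers in the
  catalog; without them duplicates are reported as zero.
* The phylogeny module consumes pre-aligned peptides; alignment itself is
  out of scope.

# A compact end-to-end example

```{r, eval = FALSE}
catalog <- sim_gene_catalog(n_genes = 40, seed = 1)
genome <- sim_genome(catalog, n_hidden = 3, seed = 2)
cds <- setNames(catalog$cds_sequence, catalog$gene_id)
seg <- function(ty) {
  s <- dplyr::filter(genome$segments, type == ty)[1, ]
  setNames(substring(genome$sequence, s$start, s$end), ty)
}
refs <- list(mito = seg("mito"), rrna = seg("rrna"),
             cds = cds, gene = cds, transcript = cds)
reads <- dplyr::bind_rows(
  sim_read_library(genome, n_reads = 2000, condition = "infected", seed = 3),
  sim_read_library(genome, n_reads = 2000, condition = "naive", seed = 4)
)

assignments <- classify_reads(reads, refs)
summarize_library(assignments, reads)

expression <- count_reads_per_gene(assignments, genes = catalog$gene_id) |>
  dplyr::left_join(catalog[, c("gene_id", "transcript_length")], by = "gene_id") |>
  quantify_expression() |>
  test_induction(control_ids = catalog$gene_id[catalog$is_control])
dplyr::count(expression, category)
```
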