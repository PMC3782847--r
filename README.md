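# pyroimmune

Comparative analysis of insect immune transcriptomes sequenced as a single
pyrosequencing (454-style) read library per condition — the design used to
compare the antifungal response of *Drosophila virilis* and
*D. melanogaster* larvae, where each of the four libraries (two species ×
infected/naive) is one pool of larvae with no biological replicates.

The package covers the full chain from raw reads to biology:

* **Read triage** — hierarchical classification of every read against
  mitochondrial, rRNA, CDS, gene and transcript references (first hit wins),
  with Table-style per-library accounting whose identities
  `mito + rRNA + other = total` and `assigned + unidentified = other` hold
  by construction.
* **Quantification** — reads per site per million reads,
  `RPSM = (reads / total reads / transcript length) × 1e6`, normalized
  between libraries by a trimmed mean of M values (TMM), and the induction
  coefficient `IC = TMM_infected / TMM_naive` (`Inf` marks expression seen
  only after infection).
* **Induction statistics** — per-gene 2×2 contingency tests anchored on
  pooled endogenous controls (RpL32/GAPDH-style): Pearson chi-square when
  every cell holds ≥5 reads, Fisher's exact test otherwise; regulation
  categories at IC boundaries 0.5, 1 and 2.
* **Immune catalog** — one-to-one homologue resolution by translated
  alignment score, immune-class annotation (recognition / signaling /
  effector), effector panels sorted by infected TMM and cross-species Venn
  counts.
* **Novel-gene discovery** — reference-guided contigs from unidentified
  reads, ±250 bp flank extension, six-frame translated homology screening
  (BLOSUM62 Smith–Waterman, Karlin–Altschul e-values, e ≤ 1e-5) and
  induction testing of the putative genes.
* **AMP screening** — signal-peptide and propeptide heuristics, molecular
  weight, net charge and residue enrichment of the mature peptide, and a
  transparent antimicrobial-peptide verdict (secreted ∧ charge ≥ +2 ∧
  10–100 aa).
* **Phylogeny** — Poisson-corrected distances `d = −ln(1 − p)`,
  neighbor joining with deterministic tie-breaking, and bootstrap supports
  over resampled alignment columns, written as Newick.
* **Resistance assay** — LT50 (median lethal time) from daily survival
  counts via a binomial GLM on cumulative deaths, `LT50 = −intercept/slope`.
* **Synthetic data** — generators for every input above (catalogs, count
  experiments, genomes with planted hidden genes, read libraries, peptide
  precursors, survival series) with truth labels for parameter-recovery
  testing.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Published library totals and per-gene TMM values ship as plain-text fixtures
under `inst/extdata/`; the package recomputes the derived quantities from
them:

```r
library(pyroimmune)
library(dplyr)

acc <- read_tsv_table(system.file("extdata", "read_accounting_454.tsv",
                                  package = "pyroimmune")) |>
  read_accounting()
acc[, c("species", "condition", "total_reads", "other_reads", "unidentified_reads")]
#>   species        condition total_reads other_reads unidentified_reads
#> 1 D_virilis      infected       109106       77558              22200
#> 2 D_virilis      naive          119533       90836              28726
#> 3 D_melanogaster infected       110578       65670               2115
#> 4 D_melanogaster naive           91947       48474               1938
```

`other_reads` are the reads left after removing mitochondrial and rRNA
matches (presumed nuclear mRNA); `unidentified_reads` hit no annotated gene
— note the ten-fold excess in *D. virilis*, the raw material of the
novel-gene search.

```r
expr <- read_tsv_table(system.file("extdata", "immune_gene_expression.tsv",
                                   package = "pyroimmune")) |>
  mutate(ic = induction_coefficient(tmm_infected, tmm_naive))
expr |> filter(gene_id %in% c("Mtk", "Drs", "GJ19916", "GJ22479")) |>
  select(species, gene_id, tmm_infected, tmm_naive, ic)
#>   species        gene_id tmm_infected tmm_naive     ic
#> 1 D_virilis      GJ22479         2.44     0     Inf
#> 2 D_virilis      GJ19916         3.81     0.138  27.6
#> 3 D_melanogaster Mtk            23.7      3.67    6.46
#> 4 D_melanogaster Drs            23.8     14.6     1.63
```

Defensin (GJ22479) is expressed only in infected *D. virilis* larvae
(`IC = Inf`) and Diptericin (GJ19916) is induced ~28-fold, whereas in
*D. melanogaster* the antifungal peptides Metchnikowin and Drosomycin
dominate — the species use different effector repertoires against the same
fungus.

```r
fit <- fit_lt50(sim_survival_counts(n_flies = 200, lt50_true = 6, seed = 1))
fit
#> LT50 fit (glm, logit link): LT50 = 6.085 days (SE 0.066), slope = 1.163
```

The methods vignette
(`vignettes/comparative-immune-transcriptomics.Rmd`) documents the model,
parameter defaults, the synthetic-data generator and the package's
numerical conventions.

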