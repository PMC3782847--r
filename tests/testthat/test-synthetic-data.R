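test_that("gene catalog generation is deterministic and respects class fractions", {
  a <- sim_gene_catalog(n_genes = 100, seed = 1)
  b <- sim_gene_catalog(n_genes = 100, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, sim_gene_catalog(n_genes = 100, seed = 2)))

  expect_false(anyDuplicated(a$gene_id) > 0)
  expect_true(all(a$transcript_length >= nchar(a$cds_sequence)))
  expect_gte(sum(a$is_control), 2)
  expect_true(all(a$immune_class[a$is_control] == "none"))

  zero <- sim_gene_catalog(
    n_genes = 50,
    class_fractions = c(recognition = 0, signaling = 0, effector = 0), seed = 3
  )
  expect_true(all(zero$immune_class == "none"))

  big <- sim_gene_catalog(
    n_genes = 1000,
    class_fractions = c(recognition = 0.02, signaling = 0.05, effector = 0.05),
    seed = 7
  )
  bounds <- binom_bounds(1000, 0.05)
  n_eff <- sum(big$immune_class == "effector")
  expect_gte(n_eff, bounds[1])
  expect_lte(n_eff, bounds[2])

  expect_error(sim_gene_catalog(n_genes = 5, seed = 1), class = "pyroimmune_parameter_error")
  expect_error(
    sim_gene_catalog(
      n_genes = 50,
      class_fractions = c(recognition = 0.8, signaling = 0.3, effector = 0.1), seed = 1
    ),
    class = "pyroimmune_parameter_error"
  )
})

test_that("count experiment honours fold changes, depths and the infected-only token", {
  cat <- sim_gene_catalog(n_genes = 40, seed = 1)

  # null case: no fold change, Poisson, equal depths -> equal in expectation
  ex <- sim_count_experiment(cat,
    dispersion = 0,
    depths = c(infected = 1e6, naive = 1e6), seed = 2
  )
  expect_true(all(ex$truth$mu_infected == ex$truth$mu_naive))
  ratio <- sum(ex$counts$reads_infected) / sum(ex$counts$reads_naive)
  expect_lt(abs(ratio - 1), 0.01)

  # infected-only token forces a zero naive count
  io <- sim_count_experiment(cat,
    fold_change = c(G00001 = Inf),
    depths = c(infected = 1e4, naive = 1e4), seed = 3
  )
  expect_identical(io$counts$reads_naive[io$counts$gene_id == "G00001"], 0)

  # Monte-Carlo oracle: fold change 4 at high depth recovered within 10%
  # (target the highest-abundance non-control gene so the ratio of means
  # across replicates is estimated precisely)
  base <- sim_count_experiment(cat, dispersion = 0, seed = 99)
  free <- base$truth[!cat$is_control, ]
  target <- free$gene_id[which.max(free$abundance)]
  draws <- vapply(seq_len(200), function(r) {
    e <- sim_count_experiment(cat,
      fold_change = stats::setNames(4, target),
      dispersion = 0.1, depths = c(infected = 1e6, naive = 1e6), seed = 100 + r
    )
    row <- e$counts[e$counts$gene_id == target, ]
    c(row$reads_infected, row$reads_naive)
  }, numeric(2))
  ratio <- mean(draws[1, ]) / mean(draws[2, ])
  expect_lt(abs(ratio - 4), 0.4)

  expect_error(
    sim_count_experiment(cat, depths = c(infected = 0, naive = 100), seed = 1),
    class = "pyroimmune_parameter_error"
  )
  ctrl <- cat$gene_id[cat$is_control][1]
  expect_error(
    sim_count_experiment(cat, fold_change = stats::setNames(2, ctrl), seed = 1),
    class = "pyroimmune_parameter_error"
  )
})

test_that("read libraries are exact substrings with the requested composition", {
  cat <- sim_gene_catalog(n_genes = 20, seed = 1)
  genome <- sim_genome(cat, n_hidden = 2, seed = 2)

  pure <- sim_read_library(genome,
    mix = c(mito = 0, rrna = 0, gene = 1, unannotated = 0),
    n_reads = 200, seed = 3
  )
  expect_true(all(grepl("^gene:", pure$truth_source)))

  lib <- sim_read_library(genome,
    mix = c(mito = 0.05, rrna = 0.25, gene = 0.50, unannotated = 0.20),
    n_reads = 10000, seed = 3
  )
  bounds <- binom_bounds(10000, 0.05)
  n_mito <- sum(lib$truth_source == "mito")
  expect_gte(n_mito, bounds[1])
  expect_lte(n_mito, bounds[2])

  # construction invariant: every read is a verbatim substring of the genome
  sample_rows <- lib[sample.int(nrow(lib), 200), ]
  expect_true(all(vapply(
    sample_rows$sequence, grepl, logical(1),
    x = genome$sequence, fixed = TRUE
  )))

  expect_error(
    sim_read_library(genome, n_reads = 100, read_length = 10000, seed = 1),
    class = "pyroimmune_parameter_error"
  )
})

test_that("precursor peptides carry the planted architecture", {
  all_amp <- sim_precursor_peptides(50, amp_fraction = 1, seed = 11)
  expect_true(all(all_amp$is_amp))
  # construction invariant: mature net charge >= +2 by the module's own
  # charge calculator
  mature <- substring(all_amp$sequence, all_amp$mature_start)
  charges <- vapply(mature, function(m) peptide_properties(m)$net_charge, integer(1))
  expect_true(all(charges >= 2))

  none <- sim_precursor_peptides(60, amp_fraction = 0, seed = 12)
  expect_false(any(none$is_amp))
  # no non-AMP satisfies all three criteria under the package's own screen
  calls <- screen_peptides(none, require_propeptide = TRUE)
  expect_false(any(calls$amp_call))

  big <- sim_precursor_peptides(200, amp_fraction = 0.3, seed = 11)
  bounds <- binom_bounds(200, 0.3)
  expect_gte(sum(big$is_amp), bounds[1])
  expect_lte(sum(big$is_amp), bounds[2])
})

test_that("survival counts follow the logistic time-mortality model", {
  # step-curve limit: infinite slope puts every death at the LT50 boundary
  step <- sim_survival_counts(n_flies = 50, lt50_true = 3, slope = Inf, horizon = 6, seed = 1)
  expect_true(all(step$alive[step$day < 3] == 50))
  expect_true(all(step$alive[step$day >= 3] == 0))

  # monotone non-increasing for every seed tried
  for (s in 1:5) {
    x <- sim_survival_counts(n_flies = 30, lt50_true = 5, seed = s)
    expect_false(is.unsorted(rev(x$alive)))
    expect_true(all(x$alive <= x$n_start))
  }

  # Monte-Carlo oracle: first day below 50% alive is LT50 +/- 1
  big <- sim_survival_counts(n_flies = 10000, lt50_true = 6, seed = 2)
  first_below <- min(big$day[big$alive < 5000])
  expect_lte(abs(first_below - 6), 1)

  expect_error(
    sim_survival_counts(n_flies = 5, lt50_true = 3, seed = 1),
    class = "pyroimmune_parameter_error"
  )
  expect_error(
    sim_survival_counts(n_flies = 20, lt50_true = 3, horizon = 0, seed = 1),
    class = "pyroimmune_parameter_error"
  )
})
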