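test_that("control pooling sums counts and reports homogeneity", {
  counts <- make_count_table(c(10, 20, 100), c(10, 20, 50))
  ctl <- pool_controls(counts, c("G001", "G002"))
  expect_identical(unname(ctl$pooled), c(30, 30))
  expect_equal(ctl$homogeneity_p, 1)

  single <- pool_controls(counts, "G003")
  expect_identical(unname(single$pooled), c(100, 50))
  expect_identical(single$homogeneity_p, 1)

  skewed <- make_count_table(c(40, 10), c(10, 40))
  p <- pool_controls(skewed, c("G001", "G002"))$homogeneity_p
  expect_equal(p, oracle_fisher_p(40, 10, 10, 40), tolerance = 1e-12)

  expect_error(pool_controls(counts, "nope"), class = "pyroimmune_configuration_error")
})

test_that("test selection follows the minimum-cell rule and p-values match oracles", {
  # perfectly proportional chi-square table
  res <- gene_induction_test(c(5, 5), c(50, 50))
  expect_identical(res$test_used, "chi-square")
  expect_equal(res$p_value, 1)

  # min cell 4 < 5 -> Fisher
  res2 <- gene_induction_test(c(4, 9), c(100, 100))
  expect_identical(res2$test_used, "fisher")

  res3 <- gene_induction_test(c(1, 9), c(10, 10))
  expect_identical(res3$test_used, "fisher")
  expect_equal(res3$p_value, oracle_fisher_p(1, 9, 10, 10), tolerance = 1e-12)

  # no-signal convention
  res4 <- gene_induction_test(c(0, 0), c(10, 10))
  expect_identical(res4$test_used, "no-signal")
  expect_identical(res4$p_value, 1)

  expect_error(gene_induction_test(c(1, 1), c(0, 5)), class = "pyroimmune_parameter_error")
})

test_that("Fisher p equals the exhaustive enumeration oracle over random tables", {
  withr::with_seed(42, {
    for (i in seq_len(400)) {
      cells <- as.vector(stats::rmultinom(1, size = sample(8:60, 1), prob = rep(1 / 4, 4)))
      res <- gene_induction_test(cells[1:2], pmax(cells[3:4], 1))
      oracle <- if (res$test_used == "fisher") {
        oracle_fisher_p(cells[1], cells[2], max(cells[3], 1), max(cells[4], 1))
      } else {
        oracle_chisq_p(cells[1], cells[2], cells[3], cells[4])
      }
      if (res$test_used != "no-signal") {
        expect_equal(res$p_value, oracle, tolerance = 1e-9)
      }
      expect_identical(
        res$test_used == "chi-square",
        min(cells[1:2], pmax(cells[3:4], 1)) >= 5
      )
    }
  })
})

test_that("regulation categories follow the IC bounds and boundary conventions", {
  calls <- classify_regulation(
    ic = c(Inf, 3.162, 2, 1.5, 1, 0.5, 0.321, 0.49, NA),
    p_value = c(0.001, 0.001, 0.2, 0.03, 1, 0.04, 0.01, 0.001, NA)
  )
  expect_identical(
    as.character(calls$category),
    c(
      "infected_only", "up_strong", "up_weak", "up_weak", "unchanged",
      "down_weak", "down_strong", "down_strong", "undefined"
    )
  )
  expect_identical(calls$significant, c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(calls$stars, c("**", "**", "", "*", "", "*", "*", "**", ""))
})

test_that("type-I error is nominal and power high on synthetic experiments", {
  # null: all fold changes 1, Poisson sampling (the test's own model)
  cat <- sim_gene_catalog(n_genes = 2000, seed = 21)
  ex <- sim_count_experiment(cat,
    dispersion = 0,
    depths = c(infected = 2e5, naive = 2e5), seed = 22
  )
  q <- quantify_expression(ex$counts, totals = ex$depths)
  res <- test_induction(q, cat$gene_id[cat$is_control])
  tested <- res[!res$is_control & res$test_used != "no-signal", ]
  n_sig <- sum(tested$p_value < 0.05)
  bounds <- binom_bounds(nrow(tested), 0.05)
  expect_gte(n_sig, bounds[1])
  expect_lte(n_sig, bounds[2])

  # power: fold change 4 with expected infected count >= 50, default dispersion
  cat2 <- sim_gene_catalog(n_genes = 400, seed = 23)
  fc_genes <- head(cat2$gene_id[!cat2$is_control], 100)
  ex4 <- sim_count_experiment(cat2,
    fold_change = stats::setNames(rep(4, length(fc_genes)), fc_genes),
    dispersion = 0.1, seed = 25
  )
  q4 <- quantify_expression(ex4$counts, totals = ex4$depths)
  res4 <- test_induction(q4, cat2$gene_id[cat2$is_control])
  eligible <- ex4$truth$gene_id[ex4$truth$true_fold_change == 4 &
    ex4$truth$mu_infected >= 50]
  hits <- res4[res4$gene_id %in% eligible, ]
  power <- mean(hits$significant & hits$ic > 1)
  expect_gte(power, 0.8)
})
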