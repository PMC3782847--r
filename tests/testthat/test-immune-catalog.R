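make_two_catalogs <- function() {
  a <- sim_gene_catalog(n_genes = 20, seed = 31)
  b <- sim_gene_catalog(n_genes = 20, seed = 31)
  b$gene_id <- sub("^G", "M", b$gene_id)
  list(a = a, b = b)
}

test_that("homologue resolution keeps one-to-one rows and scores out duplicates", {
  cats <- make_two_catalogs()
  clean <- tibble::tibble(gene_a = c("G00001", "G00002"), gene_b = c("M00001", "M00002"))
  res <- resolve_homologues(clean, cats$a, cats$b)
  expect_identical(res$map[, c("gene_a", "gene_b")], clean)
  expect_identical(unique(res$map$provenance), "table")

  # two-copy family: the identical copy must win over a diverged one
  mutate_half <- function(cds) {
    chars <- strsplit(cds, "")[[1]]
    idx <- seq(4, length(chars) - 3, by = 2)
    chars[idx] <- vapply(chars[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
    paste(chars, collapse = "")
  }
  a2 <- cats$a
  a2$gene_id[1:2] <- c("COPY1", "COPY2")
  a2$cds_sequence[1] <- cats$b$cds_sequence[1] # identical to target
  a2$cds_sequence[2] <- mutate_half(cats$b$cds_sequence[1]) # ~50% diverged
  amb <- tibble::tibble(gene_a = c("COPY1", "COPY2"), gene_b = c("M00001", "M00001"))
  res2 <- resolve_homologues(amb, a2, cats$b)
  expect_identical(nrow(res2$map), 1L)
  expect_identical(res2$map$gene_a, "COPY1")
  expect_identical(res2$map$provenance, "best_translated_hit")

  # injectivity both ways on a noisy many-to-many table
  noisy <- tibble::tibble(
    gene_a = c("G00003", "G00003", "G00004", "G00005"),
    gene_b = c("M00003", "M00004", "M00004", "M00099")
  )
  res3 <- resolve_homologues(noisy, cats$a, cats$b)
  expect_false(anyDuplicated(res3$map$gene_a) > 0)
  expect_false(anyDuplicated(res3$map$gene_b) > 0)
  expect_identical(res3$rejects$gene_b, "M00099")

  empty <- resolve_homologues(
    tibble::tibble(gene_a = character(), gene_b = character()),
    cats$a, cats$b
  )
  expect_identical(nrow(empty$map), 0L)
})

test_that("immune class assignment matches the reference list and is order-invariant", {
  cat <- sim_gene_catalog(n_genes = 150, seed = 32)
  withr::with_seed(33, {
    picked <- sample(cat$gene_id, 23 + 68 + 37)
  })
  ref <- tibble::tibble(
    gene_id = picked,
    class = rep(c("recognition", "signaling", "effector"), c(23, 68, 37)),
    subtype = ifelse(rep(c(FALSE, FALSE, TRUE), c(23, 68, 37)), "AMP", NA)
  )
  ann <- assign_immune_class(cat, ref)
  counts <- table(ann$immune_class)
  expect_identical(as.integer(counts[c("recognition", "signaling", "effector")]), c(23L, 68L, 37L))

  shuffled <- assign_immune_class(cat[sample.int(nrow(cat)), ], ref)
  expect_identical(table(shuffled$immune_class), counts)

  none <- assign_immune_class(cat, ref[0, ])
  expect_true(all(none$immune_class == "none"))

  bad <- ref
  bad$class[1] <- "mystery"
  expect_error(assign_immune_class(cat, bad), class = "pyroimmune_input_error")
})

test_that("effector summaries sort by infected TMM and preserve category tallies", {
  records <- tibble::tibble(
    species = "A",
    gene_id = c("e1", "e2", "e3", "e4", "s1"),
    immune_class = c(rep("effector", 4), "signaling"),
    effector_subtype = c("AMP", "AMP", "IM", "IM", NA),
    reads_infected = c(50, 10, 0, 30, 99),
    tmm_infected = c(5, 12, 0, 2, 50),
    reads_naive = c(5, 0, 10, 60, 99),
    tmm_naive = c(0.5, 0, 1, 4, 50),
    ic = induction_coefficient(c(5, 12, 0, 2, 50), c(0.5, 0, 1, 4, 50)),
    p_value = c(0.01, 0.001, 0.2, 0.03, 0.9)
  )
  records <- dplyr::bind_cols(
    records[, setdiff(names(records), c("ic", "p_value"))],
    classify_regulation(records$ic, records$p_value)
  )
  map <- tibble::tibble(gene_a = c("e1", "e2"), gene_b = c("m1", "m2"))
  summ <- effector_summary(records, map = map)
  expect_identical(summ$gene_id, c("e2", "e1", "e4")) # e3 unexpressed, s1 not effector
  expect_identical(as.character(summ$category[summ$gene_id == "e2"]), "infected_only")
  expect_identical(summ$homologue, c("m2", "m1", NA))
  # tallies agree with an independent classification of the same genes
  recount <- classify_regulation(summ$ic, summ$p_value)
  expect_identical(table(summ$category), table(recount$category))
})

test_that("venn counts match brute-force set algebra", {
  map <- tibble::tibble(
    gene_a = paste0("a", 1:10),
    gene_b = paste0("b", 1:10)
  )
  # disjoint with empty map
  v0 <- venn_counts(c("x1", "x2"), c("y1"), map[0, ])
  expect_identical(unlist(v0[, 1:3]), c(only_a = 2L, shared = 0L, only_b = 1L))
  # identical mapped sets
  v1 <- venn_counts(paste0("a", 1:5), paste0("b", 1:5), map)
  expect_identical(unlist(v1[, 1:3]), c(only_a = 0L, shared = 5L, only_b = 0L))

  withr::with_seed(34, {
    for (i in 1:20) {
      ea <- sample(c(paste0("a", 1:10), paste0("x", 1:5)), sample(3:12, 1))
      eb <- sample(c(paste0("b", 1:10), paste0("y", 1:5)), sample(3:12, 1))
      v <- venn_counts(ea, eb, map)
      shared_oracle <- sum(map$gene_a %in% ea & map$gene_b %in% eb)
      expect_identical(v$shared, shared_oracle)
      expect_identical(v$only_a + v$shared, length(unique(ea)) -
        sum(map$gene_a %in% ea & !map$gene_b %in% eb) +
        sum(map$gene_a %in% ea & !map$gene_b %in% eb))
      expect_identical(v$only_a, length(setdiff(
        ea, map$gene_a[map$gene_b %in% eb]
      )))
    }
  })
})
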