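world <- make_triage_world(n_genes = 15, n_reads = 600, seed = 71, n_hidden = 4)
unid_reads <- {
  a <- classify_reads(world$reads, world$references)
  world$reads[a$stage == "unidentified", ]
}

test_that("contigs merge overlapping placements and respect truth intervals", {
  genome <- world$genome
  # two overlapping reads -> one contig spanning their union
  s <- genome$segments[which(genome$segments$feature_id == "filler"), ]
  r1 <- substring(genome$sequence, s$start + 10, s$start + 109)
  r2 <- substring(genome$sequence, s$start + 60, s$start + 159)
  ctg <- build_contigs(
    tibble::tibble(read_id = c("a", "b"), sequence = c(r1, r2), condition = "infected"),
    genome
  )
  expect_identical(nrow(ctg), 1L)
  expect_identical(ctg$end - ctg$start + 1L, 150L)
  expect_identical(
    ctg$consensus,
    substring(genome$sequence, s$start + 10, s$start + 159)
  )

  # contigs from one hidden segment stay inside that segment, intervals disjoint
  hg <- genome$segments[which(genome$segments$feature_id == "HG01"), ]
  hg_reads <- unid_reads[unid_reads$truth_feature == "HG01", ]
  skip_if(nrow(hg_reads) < 3)
  ctg2 <- build_contigs(hg_reads, genome)
  expect_true(all(ctg2$start >= hg$start & ctg2$end <= hg$end))
  if (nrow(ctg2) > 1) {
    expect_true(all(ctg2$start[-1] > ctg2$end[-nrow(ctg2)]))
  }
  expect_equal(attr(ctg2, "mapped_fraction"), 1)
})

test_that("contig extension clips at genome bounds and flank 0 is the identity", {
  genome_seq <- strrep("ACGT", 2500) # 10 kb
  contig <- tibble::tibble(start = 1001L, end = 1200L)
  q <- extend_contig(contig, genome_seq, flank = 250)
  expect_identical(q$query_start, 751L)
  expect_identical(q$query_end, 1450L)
  expect_identical(nchar(q$query_sequence), 700L)

  left <- extend_contig(tibble::tibble(start = 1L, end = 100L), genome_seq, flank = 250)
  expect_identical(left$query_start, 1L)

  id <- extend_contig(contig, genome_seq, flank = 0)
  expect_identical(id$query_start, contig$start)
  expect_identical(id$query_end, contig$end)

  # a 192 bp contig yields a query of at most 692 bp
  short <- extend_contig(tibble::tibble(start = 5000L, end = 5191L), genome_seq)
  expect_lte(nchar(short$query_sequence), 692L)
})

test_that("translated homology screening finds planted ORFs in any frame", {
  withr::with_seed(72, {
    codons <- sample(setdiff(
      apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"), c("A", "C", "G", "T")),
        1, paste0,
        collapse = ""
      ),
      c("TAA", "TAG", "TGA")
    ), 60, replace = TRUE)
    orf <- paste(codons, collapse = "")
    protein <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
    decoys <- stats::setNames(
      vapply(1:20, function(i) {
        paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 150, replace = TRUE),
          collapse = ""
        )
      }, character(1)),
      paste0("decoy", 1:20)
    )
    db <- c(stats::setNames(protein, "target"), decoys)
    flank5 <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    flank3 <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  })
  query <- paste0(flank5, orf, flank3)
  hit <- screen_homology(query, db)
  expect_identical(hit$protein_id, "target")
  expect_lte(hit$evalue, 1e-5)

  # reverse-complement insertion is found in a negative frame
  rc_query <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  hit_rc <- screen_homology(rc_query, db)
  expect_identical(hit_rc$protein_id, "target")
  expect_lt(hit_rc$frame, 0)

  # threshold filtering is a pure post-condition
  hit_inf <- screen_homology(query, db, e_threshold = Inf)
  expect_identical(hit_inf$protein_id, hit$protein_id)

  expect_identical(nrow(screen_homology("AC", db)), 0L)
})

test_that("random queries never pass the e-value threshold against unrelated proteins", {
  withr::with_seed(73, {
    db <- stats::setNames(
      vapply(1:10, function(i) {
        paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 200, replace = TRUE),
          collapse = ""
        )
      }, character(1)),
      paste0("p", 1:10)
    )
    false_hits <- sum(vapply(1:60, function(i) {
      q <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
      nrow(screen_homology(q, db)) > 0
    }, logical(1)))
  })
  expect_identical(false_hits, 0L)
})

test_that("putative-gene testing mirrors the known-gene statistics", {
  putatives <- tibble::tibble(
    putative_id = c("PG1", "PG2", "PG3"),
    n_reads_infected = c(7L, 2L, 40L),
    n_reads_naive = c(0L, 10L, 38L)
  )
  res <- test_putative_genes(putatives,
    control_counts = c(infected = 500, naive = 520),
    library_sizes = c(infected = 1000, naive = 1040)
  )
  expect_identical(as.character(res$category[1]), "infected_only")
  expect_identical(res$ic[1], Inf)
  expect_equal(res$ic[2], (2 / 1000) / (10 / 1040))
  expect_identical(as.character(res$category[2]), "down_strong")
  # p-values come from the same control-anchored test as annotated genes
  expect_equal(
    res$p_value[2],
    gene_induction_test(c(2, 10), c(500, 520))$p_value
  )

  # null putatives: significant fraction near alpha
  withr::with_seed(74, {
    null_puts <- tibble::tibble(
      putative_id = sprintf("PG%04d", 1:800),
      n_reads_infected = rpois(800, 30),
      n_reads_naive = rpois(800, 30)
    )
  })
  null_res <- test_putative_genes(null_puts,
    control_counts = c(infected = 5000, naive = 5000),
    library_sizes = c(infected = 1e4, naive = 1e4)
  )
  frac <- mean(null_res$p_value < 0.05)
  bounds <- binom_bounds(800, 0.05) / 800
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("end-to-end discovery recovers planted hidden genes", {
  proteins <- stats::setNames(world$genome$hidden$protein, world$genome$hidden$hidden_id)
  pg <- discover_novel_genes(
    unid_reads, world$genome, proteins,
    control_counts = c(infected = 200, naive = 200),
    library_sizes = c(infected = 300, naive = 300)
  )
  reads_per_hidden <- table(unid_reads$truth_feature)
  eligible <- setdiff(names(reads_per_hidden[reads_per_hidden >= 20]), "filler")
  skip_if(length(eligible) == 0)
  recovered <- intersect(eligible, pg$protein_id)
  expect_gte(length(recovered) / length(eligible), 0.9)
})
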