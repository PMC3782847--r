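#' Simulate a gene catalog
#'
#' Generates a catalog of nuclear protein-coding genes with clean open reading
#' frames, immune-class labels (recognition / signaling / effector), effector
#' subtypes (AMP / IM / other), endogenous-control flags and cross-species
#' homologue identifiers. The catalog plays the role of an annotated gene set
#' (CDS plus transcript length) for one species.
#'
#' Immune classes are assigned per gene by independent multinomial draws with
#' probabilities `class_fractions` (remainder is class `"none"`). CDS lengths
#' are drawn as `3 * max(50, round(rgamma(shape = 4, scale = mean_length/12)))`
#' codons, i.e. a gamma distribution with mean `mean_length` floored at 150 bp;
#' transcript length adds a gamma-distributed untranslated region.
#' Endogenous controls (at least two, mimicking ribosomal-protein and GAPDH
#' style housekeeping genes) are drawn from the non-immune genes and always
#' carry `immune_class = "none"`.
#'
#' @param n_genes Number of genes (>= 10).
#' @param class_fractions Named numeric vector with entries `recognition`,
#'   `signaling`, `effector`; non-negative, summing to at most 1.
#' @param mean_length Mean CDS length in bp.
#' @param n_controls Number of endogenous control genes (>= 2).
#' @param homologue_fraction Fraction of genes given a homologue identifier
#'   shared with a sibling catalog generated from the same settings.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#'
#' @return A tibble with columns `gene_id`, `transcript_length`,
#'   `cds_sequence`, `immune_class`, `effector_subtype`, `is_control`,
#'   `homologue_id`.
#' @export
#' @examples
#' cat <- sim_gene_catalog(n_genes = 50, seed = 1)
#' dplyr::count(cat, immune_class)
sim_gene_catalog <- function(n_genes = 200,
                             class_fractions = c(
                               recognition = 0.02,
                               signaling = 0.05,
                               effector = 0.03
                             ),
                             mean_length = 900,
                             n_controls = 2,
                             homologue_fraction = 1,
                             seed = 1) {
  check_scalar_number(n_genes, "n_genes", min = 10, integerish = TRUE)
  check_scalar_number(mean_length, "mean_length", min = 150)
  check_scalar_number(n_controls, "n_controls", min = 2, integerish = TRUE)
  check_scalar_number(homologue_fraction, "homologue_fraction", min = 0, max = 1)
  check_seed(seed)
  wanted <- c("recognition", "signaling", "effector")
  if (!is.numeric(class_fractions) || !all(wanted %in% names(class_fractions))) {
    abort("`class_fractions` must be named with recognition/signaling/effector.",
      class = "pyroimmune_parameter_error"
    )
  }
  class_fractions <- class_fractions[wanted]
  if (any(class_fractions < 0) || sum(class_fractions) > 1) {
    abort("`class_fractions` must be non-negative and sum to at most 1.",
      class = "pyroimmune_parameter_error"
    )
  }

  withr::with_seed(seed, {
    codons <- sense_codons()
    n_codons <- pmax(50L, round(rgamma(n_genes, shape = 4, scale = mean_length / 12)))
    cds <- vapply(n_codons, function(nc) {
      paste0("ATG", paste(sample(codons, nc - 1, replace = TRUE), collapse = ""), "TAA")
    }, character(1))
    cds_length <- nchar(cds)
    utr <- round(rgamma(n_genes, shape = 2, scale = 150))
    classes <- sample(
      c(wanted, "none"), n_genes,
      replace = TRUE,
      prob = c(class_fractions, 1 - sum(class_fractions))
    )
    subtype <- rep(NA_character_, n_genes)
    eff <- which(classes == "effector")
    if (length(eff) > 0) {
      subtype[eff] <- sample(c("AMP", "IM", "other"), length(eff),
        replace = TRUE, prob = c(0.4, 0.3, 0.3)
      )
    }
    none_idx <- which(classes == "none")
    if (length(none_idx) < n_controls) {
      abort("Not enough non-immune genes to host the endogenous controls.",
        class = "pyroimmune_parameter_error"
      )
    }
    ctrl <- sample(none_idx, n_controls)
    homolog <- rep(NA_character_, n_genes)
    n_hom <- round(homologue_fraction * n_genes)
    if (n_hom > 0) {
      hom_idx <- sort(sample.int(n_genes, n_hom))
      homolog[hom_idx] <- sprintf("HOM%05d", hom_idx)
    }

    tibble(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      transcript_length = as.integer(cds_length + utr),
      cds_sequence = cds,
      immune_class = classes,
      effector_subtype = subtype,
      is_control = seq_len(n_genes) %in% ctrl,
      homologue_id = homolog
    )
  })
}
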