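# Physicochemical AMP candidate screening.

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Average masses of the free amino acids (Da); peptide mass is the residue
# sum minus one water (18.02 Da) per peptide bond.
AA_MASS <- c(
  A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.16, E = 147.13,
  Q = 146.15, G = 75.07, H = 155.16, I = 131.17, L = 131.17, K = 146.19,
  M = 149.21, F = 165.19, P = 115.13, S = 105.09, T = 119.12, W = 204.23,
  Y = 181.19, V = 117.15
)

aa_chars <- function(sequence, caller) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), names(AA_MASS))
  if (length(bad) > 0) {
    abort(
      sprintf("%s: non-standard residue(s): %s", caller, paste(bad, collapse = ", ")),
      class = "pyroimmune_input_error"
    )
  }
  chars
}

#' Predict a signal-peptide cleavage site
#'
#' Heuristic signal-peptide detector for secreted-precursor screening: within
#' the first 30 residues it looks for a hydrophobic core (a run of at least
#' six consecutive residues, each with Kyte-Doolittle hydropathy >= 1.6, so
#' every six-residue window of the core has mean hydropathy >= 1.6) preceded
#' by a positively charged n-region (at least one K/R before the core) and
#' followed within eight residues by a small-residue cleavage context
#' (A, G, S or C at the -1 position). Absence of a signal is a valid result,
#' not an error.
#'
#' @param precursor Amino-acid sequence (length >= 15).
#' @return 1-based position of the -1 residue (the last signal residue), or
#'   `NA_integer_` when no signal peptide is predicted.
#' @export
predict_signal_peptide <- function(precursor) {
  chars <- aa_chars(precursor, "predict_signal_peptide")
  if (length(chars) < 15) {
    abort("Precursor must be at least 15 residues long.",
      class = "pyroimmune_parameter_error"
    )
  }
  kd <- KD_HYDROPATHY[chars]
  window_end <- min(30, length(chars))
  hydro <- kd >= 1.6
  # first run of >= 6 hydrophobic residues starting within the first 30
  run <- rle(hydro)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  core <- which(run$values & run$lengths >= 6 & starts <= window_end)
  if (length(core) == 0) {
    return(NA_integer_)
  }
  core_start <- starts[core[1]]
  core_end <- ends[core[1]]
  if (core_start < 2 || !any(chars[seq_len(core_start - 1)] %in% c("K", "R"))) {
    return(NA_integer_)
  }
  context <- seq(core_end + 1, min(core_end + 8, length(chars)))
  hit <- context[chars[context] %in% c("A", "G", "S", "C")]
  if (length(hit) == 0) {
    return(NA_integer_)
  }
  as.integer(hit[1])
}

#' Predict propeptide cleavage after the signal peptide
#'
#' Finds the first dibasic motif (KR, RR, KK or RK) starting at position 3 or
#' later of the post-signal sequence; the mature peptide starts immediately
#' after the motif. Without a motif the whole post-signal sequence is mature.
#'
#' @param post_signal Amino-acid sequence following the signal peptide
#'   (non-empty).
#' @return 1-based start of the mature segment within `post_signal`, or
#'   `NA_integer_` when no dibasic motif is found.
#' @export
predict_propeptide_cleavage <- function(post_signal) {
  chars <- aa_chars(post_signal, "predict_propeptide_cleavage")
  if (length(chars) == 0) {
    abort("`post_signal` must be non-empty.", class = "pyroimmune_parameter_error")
  }
  basic <- chars %in% c("K", "R")
  starts <- which(basic[-length(basic)] & basic[-1]) # motif start positions
  starts <- starts[starts >= 3]
  if (length(starts) == 0) {
    return(NA_integer_)
  }
  as.integer(starts[1] + 2)
}

#' Physicochemical properties of a mature peptide
#'
#' Computes length, molecular weight (sum of average free amino-acid masses
#' minus one water of 18.02 Da per peptide bond, reported in kDa to two
#' decimals), integer net charge at neutral pH by side-chain counting
#' (#K + #R - #D - #E; histidine excluded, termini ignored) and the pair of
#' residues maximizing the combined composition fraction.
#'
#' @param mature Amino-acid sequence over the standard 20-letter alphabet.
#' @return Tibble with `length`, `molecular_weight_kda`, `net_charge`,
#'   `enriched_residues`, `enriched_fraction`.
#' @export
#' @examples
#' peptide_properties("GG") # 0.13 kDa, charge 0
peptide_properties <- function(mature) {
  chars <- aa_chars(mature, "peptide_properties")
  n <- length(chars)
  mw <- sum(AA_MASS[chars]) - (n - 1) * 18.02
  charge <- sum(chars == "K") + sum(chars == "R") - sum(chars == "D") - sum(chars == "E")
  comp <- sort(table(factor(chars, levels = names(AA_MASS))) / n, decreasing = TRUE)
  pair <- names(comp)[1:2]
  tibble(
    length = n,
    molecular_weight_kda = round(mw / 1000, 2),
    net_charge = as.integer(charge),
    enriched_residues = paste(pair, collapse = "+"),
    enriched_fraction = unname(sum(comp[1:2]))
  )
}

#' AMP candidacy verdict
#'
#' A candidate is called a putative antimicrobial peptide when it is secreted
#' (signal peptide predicted), its mature peptide carries a net charge of at
#' least `charge_min` and its mature length lies within `length_range`.
#' Propeptide presence is reported but, by default, not required (external
#' predictors disagree on it; the transparent rule keeps the screen
#' reproducible and the thresholds configurable).
#'
#' @param is_secreted Logical, signal peptide present.
#' @param net_charge Integer mature net charge.
#' @param mature_length Mature peptide length (aa).
#' @param has_propeptide Logical, dibasic propeptide present.
#' @param charge_min Minimum net charge (default +2).
#' @param length_range Allowed mature length range (default 10-100 aa).
#' @param require_propeptide Require the dibasic propeptide too?
#' @return Logical verdict, monotone in `net_charge`.
#' @export
amp_verdict <- function(is_secreted, net_charge, mature_length,
                        has_propeptide = NA,
                        charge_min = 2, length_range = c(10, 100),
                        require_propeptide = FALSE) {
  verdict <- is_secreted &
    net_charge >= charge_min &
    mature_length >= length_range[1] & mature_length <= length_range[2]
  if (require_propeptide) verdict <- verdict & !is.na(has_propeptide) & has_propeptide
  verdict & !is.na(verdict)
}

#' Screen precursor peptides for AMP candidates
#'
#' Full screening pipeline per precursor: signal-peptide prediction,
#' propeptide cleavage, mature-segment properties and the AMP verdict.
#'
#' @param peptides Tibble with `peptide_id` and `sequence` columns (e.g. from
#'   [sim_precursor_peptides()]), or a named character vector.
#' @inheritParams amp_verdict
#' @return Tibble with segmentation, properties and `amp_call` per precursor.
#' @export
screen_peptides <- function(peptides, charge_min = 2, length_range = c(10, 100),
                            require_propeptide = FALSE) {
  if (is.character(peptides)) {
    peptides <- tibble(
      peptide_id = names(peptides) %||% paste0("PEP", seq_along(peptides)),
      sequence = unname(peptides)
    )
  }
  purrr::map_dfr(seq_len(nrow(peptides)), function(i) {
    seq <- peptides$sequence[i]
    sig_end <- predict_signal_peptide(seq)
    is_secreted <- !is.na(sig_end)
    post <- if (is_secreted) substr(seq, sig_end + 1, nchar(seq)) else seq
    mat_start <- predict_propeptide_cleavage(post)
    has_propeptide <- !is.na(mat_start)
    mature <- if (has_propeptide) substr(post, mat_start, nchar(post)) else post
    props <- peptide_properties(mature)
    tibble(
      peptide_id = peptides$peptide_id[i],
      signal_end = sig_end,
      is_secreted = is_secreted,
      has_propeptide = has_propeptide,
      mature_start = if (is_secreted) {
        sig_end + (if (has_propeptide) mat_start else 1L)
      } else {
        if (has_propeptide) mat_start else 1L
      },
      mature_sequence = mature
    ) |>
      dplyr::bind_cols(props) |>
      mutate(amp_call = amp_verdict(
        .data$is_secreted, .data$net_charge, .data$length, .data$has_propeptide,
        charge_min = charge_min, length_range = length_range,
        require_propeptide = require_propeptide
      ))
  })
}
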