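#' Simulate secreted peptide precursors with truth segmentation
#'
#' Generates amino-acid precursor sequences with the tripartite architecture
#' of secreted antimicrobial peptides: an N-terminal signal peptide (charged
#' n-region, hydrophobic core, small-residue cleavage context), a short
#' propeptide ending in a dibasic motif, and a cationic mature peptide.
#' A fraction `amp_fraction` of precursors are AMP-truth and satisfy all
#' three criteria (signal present, dibasic propeptide, mature net charge
#' >= +2); the rest violate at least one criterion relevant to the default
#' verdict (missing hydrophobic core and/or anionic mature peptide), and a
#' share of them additionally lack the dibasic motif.
#'
#' @param n Number of precursors.
#' @param amp_fraction Fraction of AMP-truth precursors in `[0, 1]`.
#' @param seed Integer seed.
#'
#' @return Tibble with `peptide_id`, `sequence`, `is_amp`, `signal_end`
#'   (1-based index of the last signal residue, `NA` when no signal was
#'   planted) and `mature_start` (1-based index of the first mature residue).
#' @export
sim_precursor_peptides <- function(n, amp_fraction = 0.5, seed = 1) {
  check_scalar_number(n, "n", min = 1, integerish = TRUE)
  check_scalar_number(amp_fraction, "amp_fraction", min = 0, max = 1)
  check_seed(seed)

  hydrophobic <- c("L", "I", "V", "F", "A")
  neutral <- c("S", "T", "N", "Q", "G", "P", "A")
  polar_bulk <- c("G", "A", "S", "N", "T", "L", "I", "V", "F", "W", "P")

  withr::with_seed(seed, {
    is_amp <- runif(n) < amp_fraction

    make_signal <- function(hydrophobic_core = TRUE) {
      n_region <- paste0("M", sample(c("K", "R"), 1), sample(c("N", "S", "T"), 1))
      core_pool <- if (hydrophobic_core) hydrophobic else c("D", "E", "N", "S", "T")
      core <- paste(sample(core_pool, sample(7:9, 1), replace = TRUE), collapse = "")
      c_region <- paste0(
        paste(sample(c("T", "N", "Q", "P", "H"), 2, replace = TRUE), collapse = ""),
        sample(c("A", "G"), 1)
      )
      paste0(n_region, core, c_region)
    }
    make_propeptide <- function(dibasic = TRUE) {
      body <- paste(sample(neutral, sample(6:12, 1), replace = TRUE), collapse = "")
      if (dibasic) paste0(body, sample(c("KR", "RR", "KK", "RK"), 1)) else body
    }
    make_mature <- function(cationic = TRUE) {
      len <- sample(15:40, 1)
      if (cationic) {
        res <- sample(c("K", "R", polar_bulk), len,
          replace = TRUE,
          prob = c(0.18, 0.18, rep(0.64 / length(polar_bulk), length(polar_bulk)))
        )
        charge <- sum(res %in% c("K", "R"))
        while (charge < 2) { # guarantee the construction invariant
          i <- sample(which(!res %in% c("K", "R")), 1)
          res[i] <- sample(c("K", "R"), 1)
          charge <- charge + 1
        }
      } else {
        res <- sample(c("D", "E", polar_bulk), len,
          replace = TRUE,
          prob = c(0.15, 0.15, rep(0.70 / length(polar_bulk), length(polar_bulk)))
        )
        # force net charge <= 0
        while (sum(res %in% c("K", "R")) - sum(res %in% c("D", "E")) > 0) {
          i <- sample(which(res %in% c("K", "R")), 1)
          res[i] <- sample(c("D", "E"), 1)
        }
      }
      paste(res, collapse = "")
    }

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (is_amp[i]) {
        has_signal <- TRUE
        cationic <- TRUE
        dibasic <- TRUE
      } else {
        # violate at least one verdict-relevant criterion
        mode <- sample(c("signal", "charge", "both"), 1)
        has_signal <- mode == "charge"
        cationic <- mode == "signal"
        dibasic <- runif(1) > 0.3
      }
      signal <- make_signal(hydrophobic_core = has_signal)
      propep <- make_propeptide(dibasic = dibasic)
      mature <- make_mature(cationic = cationic)
      seq <- paste0(signal, propep, mature)
      rows[[i]] <- tibble(
        peptide_id = sprintf("PEP%04d", i),
        sequence = seq,
        is_amp = is_amp[i],
        signal_end = if (has_signal) nchar(signal) else NA_integer_,
        mature_start = nchar(signal) + nchar(propep) + 1L
      )
    }
    bind_rows(rows)
  })
}
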