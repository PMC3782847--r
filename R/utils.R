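# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# All 61 sense codons (standard code), used when simulating clean ORFs.
sense_codons <- function() {
  all <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste0, collapse = "")
  setdiff(all, c("TAA", "TAG", "TGA"))
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "pyroimmune_parameter_error")
  }
  if (integerish && x != round(x)) {
    abort(sprintf("`%s` must be a whole number.", name), class = "pyroimmune_parameter_error")
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s].", name, min, max),
      class = "pyroimmune_parameter_error"
    )
  }
  invisible(x)
}

check_seed <- function(seed) {
  check_scalar_number(seed, "seed", integerish = TRUE)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Normalise a reference set (named character vector or XStringSet) to a
# named character vector; names are taken up to the first whitespace.
as_reference_set <- function(x, name = "references") {
  if (inherits(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (!is.character(x) || length(x) == 0) {
    abort(sprintf("`%s` must be a non-empty named character vector or XStringSet.", name),
      class = "pyroimmune_configuration_error"
    )
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- paste0(name, "_", seq_along(x))
  }
  names(x) <- sub("\\s.*$", "", names(x))
  toupper(x)
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}
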