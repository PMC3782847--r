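#' Poisson-corrected amino-acid distances
#'
#' Pairwise distances from an amino-acid alignment under the Poisson
#' correction: with `p` the fraction of differing sites among sites where
#' both sequences are ungapped (pairwise deletion; `complete_deletion = TRUE`
#' drops every column containing a gap first), `d = -ln(1 - p)`. A pair with
#' no comparable sites, or with `p = 1` (infinite correction), is an error
#' naming the offending taxa.
#'
#' @param alignment Named character vector of equal-length aligned amino-acid
#'   sequences (gap symbol `-`), or an `AAStringSet`.
#' @param complete_deletion Drop all gapped columns before comparing.
#' @return Symmetric distance matrix with taxon dimnames.
#' @export
#' @examples
#' poisson_dist(c(a = "ARND", b = "ARNE")) # p = 0.25
poisson_dist <- function(alignment, complete_deletion = FALSE) {
  if (inherits(alignment, "XStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
    abort("Alignment rows must have unique names.", class = "pyroimmune_parameter_error")
  }
  if (length(unique(nchar(alignment))) != 1) {
    abort("All alignment rows must have equal length.", class = "pyroimmune_parameter_error")
  }
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  if (complete_deletion) {
    keep <- colSums(m == "-") == 0
    if (!any(keep)) {
      abort("No ungapped columns under complete deletion.",
        class = "pyroimmune_estimation_error"
      )
    }
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        abort(sprintf("No comparable sites between %s and %s.", rownames(m)[i], rownames(m)[j]),
          class = "pyroimmune_estimation_error"
        )
      }
      p <- mean(m[i, ok] != m[j, ok])
      if (p >= 1) {
        abort(sprintf(
          "Poisson distance undefined (p = 1) between %s and %s.",
          rownames(m)[i], rownames(m)[j]
        ), class = "pyroimmune_estimation_error")
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Agglomerative neighbor joining on a distance matrix: at each step the pair
#' minimizing the Q-criterion `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)` is merged,
#' with branch lengths from the standard two-point formulas. Ties in the
#' Q-minimization are broken towards the lowest index pair; negative branch
#' length estimates are clamped to zero with a warning. The result is an
#' unrooted tree.
#'
#' @param d Symmetric distance matrix with zero diagonal, n >= 3, with
#'   dimnames.
#' @param warn_negative Emit a warning when clamping negative lengths.
#' @return An object of class `pyro_nj`: list with `tree` (an
#'   [ape::read.tree] phylo), `newick`, and `splits` (list of clade label
#'   sets, one per internal edge, in merge order).
#' @export
nj_tree <- function(d, warn_negative = TRUE) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3) {
    abort("`d` must be a square matrix with n >= 3.", class = "pyroimmune_parameter_error")
  }
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12)) {
    abort("`d` must be symmetric with a zero diagonal.", class = "pyroimmune_parameter_error")
  }
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  built <- nj_build(d, labels, warn_negative = warn_negative)
  newick <- gsub("#S\\d+#", "", built$newick)
  structure(
    list(
      tree = ape::read.tree(text = newick),
      newick = newick,
      newick_template = built$newick,
      splits = built$splits,
      labels = labels
    ),
    class = "pyro_nj"
  )
}

# Core NJ agglomeration; returns a newick string carrying one placeholder
# token per internal edge (for later support annotation) plus the clade
# label sets those edges define.
nj_build <- function(d, labels, warn_negative = TRUE) {
  n_total <- length(labels)
  frag <- labels
  clades <- as.list(labels)
  splits <- list()
  clamped <- FALSE
  fmt <- function(x) sprintf("%.12g", x)
  clamp <- function(x) {
    if (x < 0) {
      clamped <<- TRUE
      0
    } else {
      x
    }
  }
  while (nrow(d) > 3) {
    n <- nrow(d)
    rs <- rowSums(d)
    q <- (n - 2) * d - outer(rs, rs, "+")
    q[lower.tri(q, diag = TRUE)] <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]
    j <- best[1, 2]
    li <- clamp(d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))))
    k <- length(splits) + 1
    new_frag <- sprintf("(%s:%s,%s:%s)#S%d#", frag[i], fmt(li), frag[j], fmt(lj), k)
    new_clade <- c(clades[[i]], clades[[j]])
    if (length(new_clade) >= 2 && length(new_clade) <= n_total - 2) {
      splits[[k]] <- new_clade
    } else {
      splits[[k]] <- NA
    }
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    clades <- c(clades[keep], list(new_clade))
    d <- d2
  }
  x <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  y <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  z <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- sprintf(
    "(%s:%s,%s:%s,%s:%s);",
    frag[1], fmt(x), frag[2], fmt(y), frag[3], fmt(z)
  )
  if (clamped && warn_negative) {
    warn("Negative neighbor-joining branch length(s) clamped to zero.")
  }
  list(newick = newick, splits = splits)
}

canonical_split <- function(members, all_labels) {
  anchor <- min(all_labels)
  side <- sort(members)
  if (!anchor %in% side) side <- sort(setdiff(all_labels, members))
  paste(side, collapse = "|")
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, recomputes Poisson distances
#' and the NJ tree per replicate, and reports for each internal edge of the
#' full-data tree the percentage of replicates whose tree contains the same
#' bipartition. Replicates whose resampled columns give an undefined distance
#' (saturated or non-comparable pairs) are redrawn and counted.
#'
#' @inheritParams poisson_dist
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed (fixed seed gives identical supports).
#' @param max_redraws Safety cap on redraws per replicate.
#' @return An object of class `pyro_nj_boot`: list with `tree` (phylo with
#'   integer support node labels), `support` (tibble `split`, `support`),
#'   `n_redrawn` and the base `pyro_nj` fit.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1,
                              complete_deletion = FALSE, max_redraws = 100) {
  check_scalar_number(n_replicates, "n_replicates", min = 1, integerish = TRUE)
  check_seed(seed)
  if (inherits(alignment, "XStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  labels <- names(alignment)
  base_d <- poisson_dist(alignment, complete_deletion = complete_deletion)
  base <- nj_tree(base_d, warn_negative = FALSE)
  keys <- vapply(base$splits, function(s) {
    if (length(s) == 1 && is.na(s[1])) NA_character_ else canonical_split(s, labels)
  }, character(1))

  chars <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(chars) <- labels
  n_sites <- ncol(chars)
  counts <- setNames(numeric(sum(!is.na(keys))), keys[!is.na(keys)])
  n_redrawn <- 0

  withr::with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      rep_splits <- NULL
      for (attempt in seq_len(max_redraws)) {
        cols <- sample.int(n_sites, n_sites, replace = TRUE)
        boot_aln <- setNames(apply(chars[, cols, drop = FALSE], 1, paste, collapse = ""), labels)
        d <- tryCatch(
          poisson_dist(boot_aln, complete_deletion = complete_deletion),
          error = function(e) NULL
        )
        if (is.null(d)) {
          n_redrawn <- n_redrawn + 1
          next
        }
        rep_splits <- suppressWarnings(nj_build(d, labels, warn_negative = FALSE)$splits)
        break
      }
      if (is.null(rep_splits)) {
        abort("Too many bootstrap redraws; alignment too saturated.",
          class = "pyroimmune_estimation_error"
        )
      }
      rep_keys <- vapply(rep_splits, function(s) {
        if (length(s) == 1 && is.na(s[1])) NA_character_ else canonical_split(s, labels)
      }, character(1))
      hit <- names(counts)[names(counts) %in% rep_keys]
      counts[hit] <- counts[hit] + 1
    }
  })

  support <- round(100 * counts / n_replicates)
  newick <- base$newick_template
  for (k in seq_along(keys)) {
    value <- if (is.na(keys[k])) "" else as.character(support[[keys[k]]])
    newick <- sub(sprintf("#S%d#", k), value, newick, fixed = TRUE)
  }
  structure(
    list(
      tree = ape::read.tree(text = newick),
      newick = newick,
      support = tibble(split = names(counts), support = unname(support)),
      n_redrawn = n_redrawn,
      base = base
    ),
    class = "pyro_nj_boot"
  )
}

#' Write a tree to a Newick file
#'
#' @param x A `pyro_nj` or `pyro_nj_boot` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, c("pyro_nj", "pyro_nj_boot")))
  writeLines(x$newick, path)
  invisible(path)
}
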