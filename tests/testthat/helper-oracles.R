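# Independent oracles, coded from first principles and kept free of the
# package's own implementation paths.

# Two-sided Fisher exact p by exhaustive enumeration of all 2x2 tables with
# the observed margins, summing the probabilities of tables no more likely
# than the observed one (probability-mass method).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p_obs <- logp[xs == a]
  sum(exp(logp[logp <= p_obs + log(1 + 1e-7)]))
}

# Pearson chi-square (1 df, no continuity correction) from the closed form.
oracle_chisq_p <- function(a, b, c, d) {
  o <- matrix(c(a, c, b, d), 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Brute-force trimmed weighted mean of M values, written with explicit
# sort-based trimming (independent of the package's rank-based path).
oracle_tmm_relative <- function(counts, totals, trim_m = 0.30, trim_a = 0.05) {
  ri <- counts$reads_infected / totals[["infected"]] / counts$transcript_length * 1e6
  rn <- counts$reads_naive / totals[["naive"]] / counts$transcript_length * 1e6
  use <- which(ri > 0 & rn > 0)
  m <- log2(ri[use] / rn[use])
  a <- 0.5 * log2(ri[use] * rn[use])
  n <- length(use)
  trim_keep <- function(x, frac) {
    cut <- floor(n * frac)
    ord <- order(x)
    keep <- rep(FALSE, n)
    if (cut * 2 >= n) return(keep)
    keep[ord[(cut + 1):(n - cut)]] <- TRUE
    keep
  }
  keep <- trim_keep(m, trim_m) & trim_keep(a, trim_a)
  yi <- counts$reads_infected[use]
  yn <- counts$reads_naive[use]
  w <- 1 / ((totals[["infected"]] - yi) / (totals[["infected"]] * pmax(yi, 1)) +
    (totals[["naive"]] - yn) / (totals[["naive"]] * pmax(yn, 1)))
  2^(sum(w[keep] * m[keep]) / sum(w[keep]))
}

# Newton-Raphson maximizer of the binomial log-likelihood for the
# cumulative-death logit model; independent of stats::glm.
oracle_logit_fit <- function(day, dead, n, tol = 1e-12, max_iter = 200) {
  beta <- c(0, 0.1)
  x <- cbind(1, day)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(t(x) %*% (dead - n * p))
    w <- n * p * (1 - p)
    hess <- -t(x) %*% (x * w)
    step <- solve(hess, grad)
    beta <- beta - step
    if (max(abs(step)) < tol) break
  }
  beta
}

# 99% central binomial interval.
binom_bounds <- function(n, p, conf = 0.99) {
  alpha <- (1 - conf) / 2
  c(qbinom(alpha, n, p), qbinom(1 - alpha, n, p))
}

# Random unrooted tree with positive branch lengths and its additive
# distance matrix (path lengths), via ape.
oracle_additive_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
    d <- ape::cophenetic.phylo(tr)
    list(tree = tr, d = d[sort(rownames(d)), sort(rownames(d))])
  })
}
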