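# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from its definition, not from the implementation
# under test.

# Friedman statistic from raw definition (within-block average ranks)
friedman_stat_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  rj <- colSums(r)
  num <- 12 * sum((rj - n * (k + 1) / 2)^2)
  # tie correction: average-rank ties reduce the rank variance
  ties <- sum(apply(m, 1, function(row) {
    tl <- table(row)
    sum(tl^3 - tl)
  }))
  den <- n * k * (k + 1) - ties / (k - 1)
  num / den
}

# Exact permutation P-value for the Friedman test: enumerate all (k!)^n
# within-subject orderings of the observed values
friedman_exact_p_oracle <- function(m) {
  k <- ncol(m)
  perms <- gtools_permutations(k)
  obs <- friedman_stat_oracle(m)
  idx <- rep(1L, nrow(m))
  np <- nrow(perms)
  total <- np^nrow(m)
  count <- 0L
  repeat {
    mm <- t(vapply(seq_len(nrow(m)), function(i) m[i, perms[idx[i], ]],
                   numeric(k)))
    if (friedman_stat_oracle(mm) >= obs - 1e-12) count <- count + 1L
    j <- 1L
    while (j <= length(idx)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > length(idx)) break
  }
  count / total
}

# all permutations of 1..k: choose the leading element, recurse on the rest
gtools_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest_perms <- gtools_permutations(k - 1L)
    rest_vals <- setdiff(seq_len(k), first)
    cbind(first, matrix(rest_vals[rest_perms], nrow(rest_perms)),
          deparse.level = 0)
  }))
}

# Exact two-sided Wilcoxon-Mann-Whitney P by enumeration over C(n1+n2, n1)
# group assignments of the pooled values
wmw_exact_p_oracle <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  u_stat <- function(ga, gb) {
    sum(vapply(ga, function(x) sum(x > gb) + 0.5 * sum(x == gb), numeric(1)))
  }
  obs <- u_stat(a, b)
  mu <- n1 * length(b) / 2
  combs <- utils::combn(length(pool), n1)
  dev <- abs(obs - mu)
  hits <- 0L
  for (j in seq_len(ncol(combs))) {
    ga <- pool[combs[, j]]; gb <- pool[-combs[, j]]
    if (abs(u_stat(ga, gb) - mu) >= dev - 1e-12) hits <- hits + 1L
  }
  hits / ncol(combs)
}

# Benjamini-Hochberg step-up from its definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# RVC on two-Gaussian attenuation with closed-form normal band probabilities,
# plus a 3*SEM Monte-Carlo tolerance for n-voxel samples
rvc_gaussian_oracle <- function(mi, si, me, se, band = c(-950, -856)) {
  rv <- function(m, s) {
    pband <- stats::pnorm(band[2], m, s) - stats::pnorm(band[1], m, s)
    pden <- 1 - stats::pnorm(band[1], m, s)
    pband / pden
  }
  rv(me, se) - rv(mi, si)
}

rvc_gaussian_sem <- function(mi, si, me, se, n, band = c(-950, -856)) {
  one <- function(m, s) {
    pb <- stats::pnorm(band[2], m, s) - stats::pnorm(band[1], m, s)
    pd <- 1 - stats::pnorm(band[1], m, s)
    (pb / pd)^2 * ((1 - pb) / (n * pb) + (1 - pd) / (n * pd))
  }
  sqrt(one(mi, si) + one(me, se))
}

# SEM of the ratio of two independent sample means (delta method)
ratio_of_means_sem <- function(me, se, mi, si, n_e, n_i) {
  sqrt(se^2 / (n_e * mi^2) + me^2 * si^2 / (n_i * mi^4))
}
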