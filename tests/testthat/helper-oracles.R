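# Independent brute-force oracles. These deliberately share no code with the
# package: textbook formulas evaluated the slow way.

# Welch's t from the closed-form textbook expressions.
oracle_welch <- function(ref, cmp) {
  ref <- ref[!is.na(ref)]
  cmp <- cmp[!is.na(cmp)]
  n1 <- length(ref); n2 <- length(cmp)
  m1 <- sum(ref) / n1; m2 <- sum(cmp) / n2
  v1 <- sum((ref - m1)^2) / (n1 - 1)
  v2 <- sum((cmp - m2)^2) / (n2 - 1)
  t <- (m2 - m1) / sqrt(v1 / n1 + v2 / n2)
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(delta = m2 - m1, t_stat = t, df = df,
       p = 2 * stats::pt(-abs(t), df))
}

# BH step-up by explicit enumeration over the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Pearson chi-square by the definition.
oracle_chisq <- function(tab) {
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# ward.D2 agglomeration by the Lance-Williams recursion on unsquared
# Euclidean distances: d(ij,k) = sqrt(((ni+nk) dik^2 + (nj+nk) djk^2
# - nk dij^2) / (ni+nj+nk)). Returns merge heights in merge order.
oracle_ward_d2_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b && d[active[a], active[b]] < best_d) {
        best_d <- d[active[a], active[b]]; best <- c(active[a], active[b])
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- best_d
    for (k in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      dn <- sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                    nk * d[i, j]^2) / (ni + nj + nk))
      d[i, k] <- d[k, i] <- dn
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}

# Linear-scan interval lookup with the probe->track coordinate rule:
# 1-based position p sits in [start, end) iff start <= p - 1 < end.
oracle_rt_lookup <- function(pos, chrom, track) {
  vapply(seq_along(pos), function(i) {
    for (r in seq_len(nrow(track))) {
      if (track$chrom[r] == chrom[i] &&
          track$start[r] <= pos[i] - 1 && pos[i] - 1 < track$end[r]) {
        return(track$value[r])
      }
    }
    NA_real_
  }, numeric(1))
}
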