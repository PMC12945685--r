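# Independent brute-force oracles. Each reimplements the target quantity
# by the most direct route available (closed form, exhaustive enumeration,
# stats-package fits) without touching the package's own code paths.

# weighted least squares through the origin, via lm()
oracle_ivw <- function(bx, by, sey) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sey^2)
  list(estimate = unname(coef(fit)[1]),
       se = sqrt(1 / sum(bx^2 / sey^2)))
}

# greedy p-ordered clumping by exhaustive scan
oracle_clump <- function(id, pos, p, r2mat, clump_r2, window_bp) {
  keep <- character()
  alive <- setNames(rep(TRUE, length(id)), id)
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[order(p[cand], pos[cand], id[cand])][1]
    keep <- c(keep, id[best])
    alive[best] <- FALSE
    for (j in which(alive)) {
      if (abs(pos[j] - pos[best]) <= window_bp / 2 &&
          r2mat[best, j] > clump_r2) alive[j] <- FALSE
    }
  }
  keep
}

# step-up BH by its textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# two-sided Fisher exact p by hypergeometric enumeration from lchoose
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); n1 <- sum(tab[, 1])
  N <- m1 + m2
  lo <- max(0, n1 - m2); hi <- min(n1, m1)
  lp <- vapply(lo:hi, function(k)
    lchoose(m1, k) + lchoose(m2, n1 - k) - lchoose(N, n1), numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  p_obs <- pr[a - lo + 1]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# coloc posterior by explicit enumeration over single-causal configurations
oracle_coloc <- function(l1, l2, p1, p2, p12) {
  m <- length(l1)
  lh <- c(0, -Inf, -Inf, -Inf, -Inf)
  lh[2] <- log(p1) + log(sum(exp(l1 - max(l1)))) + max(l1)
  lh[3] <- log(p2) + log(sum(exp(l2 - max(l2)))) + max(l2)
  # H3: double loop over distinct pairs
  terms <- numeric(m * (m - 1)); t <- 0L
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j) {
    t <- t + 1L; terms[t] <- l1[i] + l2[j]
  }
  mx <- max(terms)
  lh[4] <- log(p1) + log(p2) + log(sum(exp(terms - mx))) + mx
  b <- l1 + l2
  lh[5] <- log(p12) + log(sum(exp(b - max(b)))) + max(b)
  mx <- max(lh)
  post <- exp(lh - mx); post / sum(post)
}

# DerSimonian-Laird pooling written out step by step
oracle_dl <- function(est, se) {
  w <- 1 / se^2
  mu_fe <- sum(w * est) / sum(w)
  Q <- sum(w * (est - mu_fe)^2)
  k <- length(est)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(estimate = sum(ws * est) / sum(ws), se = 1 / sqrt(sum(ws)),
       tau2 = tau2, Q = Q)
}

# weighted quantile by cumulative standardized weight, for the median
oracle_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  approx(cw, x, xout = 0.5, rule = 2, ties = "ordered")$y
}
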