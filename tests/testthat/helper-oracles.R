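# Independent reference implementations used as oracles. Each is written
# from the textbook definition, deliberately brute-force, and must stay
# independent of the package code paths it checks.

# mean pairwise difference over an n x S 0/1 haplotype matrix, O(n^2 L)
oracle_pairwise_pi <- function(hap) {
  n <- nrow(hap)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(hap[i, ] != hap[j, ])
    }
  }
  total / choose(n, 2)
}

# classical Tajima's D from a haplotype matrix (fixed sample size n)
oracle_tajima <- function(hap) {
  n <- nrow(hap)
  cs <- colSums(hap)
  seg <- cs > 0 & cs < n
  S <- sum(seg)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  theta_w <- S / a1
  pi <- oracle_pairwise_pi(hap[, seg, drop = FALSE])
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- if (S == 0) NA_real_ else {
    (pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  list(S = S, theta_w = theta_w, pi = pi, D = D)
}

# Benjamini-Hochberg step-up, written as the explicit definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * ps[i:m] / (i:m)) # step-up minimum over j >= i
  }
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# two-sided Fisher exact p by exhaustive hypergeometric summation
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  lo <- max(0, k - nn); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, nn, k)
  p_obs <- dhyper(a, m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# fractional ranks by O(n^2) pairwise comparison counting
oracle_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# brute-force merging of sorted positions: two positions share a region
# iff a chain of gaps < max_gap connects them
oracle_merge <- function(pos, max_gap) {
  pos <- sort(pos)
  groups <- list()
  cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur[length(cur)] < max_gap) {
      cur <- c(cur, p)
    } else {
      groups <- c(groups, list(cur))
      cur <- p
    }
  }
  groups <- c(groups, list(cur))
  data.frame(start = vapply(groups, min, numeric(1)),
             end = vapply(groups, max, numeric(1)) + 1,
             n = lengths(groups))
}

# OLS by explicit normal equations
oracle_ols <- function(x, y, w = rep(1, length(x))) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  c(intercept = beta[1], slope = beta[2])
}

# explicit sums-of-squares decomposition for the balanced nested design:
# value ~ transfer + treatment + treatment:replicate + transfer:treatment
oracle_nested_ss <- function(df) {
  gm <- mean(df$value)
  ss <- function(means, n_each) sum(n_each * (means - gm)^2)
  ag <- function(...) aggregate(value ~ ..., data = df, FUN = mean)
  n <- nrow(df)
  m_tf <- tapply(df$value, df$transfer, mean)
  m_tr <- tapply(df$value, df$treatment, mean)
  ss_tf <- sum(table(df$transfer) * (m_tf - gm)^2)
  ss_tr <- sum(table(df$treatment) * (m_tr - gm)^2)
  # replicate within treatment: deviation of replicate-cell means from
  # their treatment mean
  cell_rep <- aggregate(value ~ treatment + replicate, df, mean)
  n_rep <- aggregate(value ~ treatment + replicate, df, length)$value
  ss_rep <- sum(n_rep * (cell_rep$value -
                           m_tr[as.character(cell_rep$treatment)])^2)
  # transfer x treatment interaction
  cell_ia <- aggregate(value ~ transfer + treatment, df, mean)
  n_ia <- aggregate(value ~ transfer + treatment, df, length)$value
  ss_ia <- sum(n_ia * (cell_ia$value -
                         m_tf[as.character(cell_ia$transfer)] -
                         m_tr[as.character(cell_ia$treatment)] + gm)^2)
  # residual: what the four orthogonal components leave of the total SS
  ss_total <- sum((df$value - gm)^2)
  ss_res <- ss_total - ss_tf - ss_tr - ss_rep - ss_ia
  list(transfer = ss_tf, treatment = ss_tr, replicate = ss_rep,
       interaction = ss_ia, residual = ss_res)
}

# the founding five-strain mixture used across tests
default_mix5 <- function() {
  c(S1 = 0.60, S2 = 0.25, S3 = 0.10, S4 = 0.04, S5 = 0.01)
}

# small hand-written alignment fixture used by the diagnostic-site tests
toy_panel <- function() {
  #            0123456789
  s1 <- paste0("AAACGTTGCA")
  s2 <- paste0("AAACGTTGCA")
  s3 <- paste0("ACACGTAGCA")
  s4 <- paste0("AAACGTTGCG")
  s5 <- paste0("AAATGTTGCA")
  seqs <- tibble::tibble(
    strain = paste0("S", 1:5),
    contig = "c1",
    seq = c(s1, s2, s3, s4, s5)
  )
  contigs <- tibble::tibble(contig = "c1", length = 10L,
                            role = "chromosomal")
  poolcoev::ref_panel(seqs, contigs, focal = "S1")
}

# 12-record variant fixture whose fate under the four filters was
# enumerated by hand (see test-variant_filters.R for the bookkeeping)
variant_fixture <- function() {
  tibble::tibble(
    sample = "s1",
    contig = "c1",
    pos = c(10L, 20L, 30L, 40L, 50L, 60L, 60L, 70L, 80L, 90L, 100L, 110L),
    type = c("SNP", "SNP", "SNP", "SNP", "SNP", "SNP", "indel",
             "SNP", "SNP", "SNP", "SNP", "SNP"),
    ref = "A", alt = c(rep("G", 6), "GT", rep("G", 5)),
    depth = c(5L, 300L, 80L, 90L, 95L, 100L, 100L, 105L, 100L, 100L,
              95L, 110L),
    alt_count = c(2L, 150L, 40L, 20L, 30L, 50L, 50L, 5L, 5L, 6L, 40L, 55L),
    alt_fwd = c(1L, 75L, 20L, 20L, 15L, 25L, 25L, 3L, 3L, 3L, 20L, 28L),
    alt_rev = c(1L, 75L, 20L, 0L, 15L, 25L, 25L, 2L, 2L, 3L, 20L, 27L),
    ref_fwd = c(2L, 75L, 20L, 0L, 33L, 25L, 25L, 50L, 48L, 47L, 28L, 27L),
    ref_rev = c(1L, 75L, 20L, 70L, 32L, 25L, 25L, 50L, 47L, 47L, 27L, 28L)
  )
}
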