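test_that("WLS recovers exact fits and matches the normal equations", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(1, 2, 3), w = c(2, 1, 5))
  fit <- weighted_least_squares(d, x, y, weights = w)
  td <- tidy(fit)
  expect_equal(td$estimate, c(0, 1), tolerance = 1e-12)
  expect_equal(glance(fit)$r.squared, 1)

  set.seed(20)
  d2 <- tibble::tibble(x = rnorm(30), y = rnorm(30))
  f2 <- weighted_least_squares(d2, x, y)
  want <- oracle_ols(d2$x, d2$y)
  expect_equal(tidy(f2)$estimate, unname(want), tolerance = 1e-10)

  d2$w <- runif(30, 0.5, 4)
  f3 <- weighted_least_squares(d2, x, y, weights = w)
  want_w <- oracle_ols(d2$x, d2$y, d2$w)
  expect_equal(tidy(f3)$estimate, unname(want_w), tolerance = 1e-10)

  # doubling all weights changes nothing
  f4 <- weighted_least_squares(d2, x, y, weights = 2 * w)
  expect_equal(tidy(f3), tidy(f4), tolerance = 1e-12)
  expect_equal(glance(f3)$p.value, glance(f4)$p.value, tolerance = 1e-12)

  bad <- tibble::tibble(x = c(1, 1, 1), y = 1:3)
  expect_error(weighted_least_squares(bad, x, y), "singular")
})

balanced_design <- function(n_rep = 5, effect = 0, noise = 0, seed = 1) {
  set.seed(seed)
  d <- tidyr::expand_grid(transfer = c("t12", "t20"),
                          treatment = c("coevolution", "one-sided"),
                          replicate = paste0("r", seq_len(n_rep)))
  d$value <- effect * (d$treatment == "coevolution") +
    rnorm(nrow(d), 0, noise)
  d
}

test_that("nested ANOVA handles degenerate designs analytically", {
  d <- balanced_design(noise = 0)
  d$value <- 5
  fit <- suppressWarnings(nested_anova(d, value, transfer, treatment,
                                       replicate))
  td <- tidy(fit)
  expect_true(all(td$sumsq[td$term != "Residuals"] < 1e-20))

  d2 <- balanced_design(effect = 2, noise = 0)
  fit2 <- nested_anova(d2, value, transfer, treatment, replicate)
  td2 <- tidy(fit2)
  expect_lt(td2$p.value[td2$term == "treatment"], 1e-10)
  expect_lt(td2$sumsq[td2$term == "transfer:treatment"], 1e-20)
})

test_that("nested ANOVA F values match the explicit SS decomposition", {
  d <- balanced_design(n_rep = 4, effect = 1, noise = 1, seed = 33)
  fit <- nested_anova(d, value, transfer, treatment, replicate)
  td <- tidy(fit)
  ss <- oracle_nested_ss(as.data.frame(d))
  df_res <- td$df[td$term == "Residuals"]
  ms_res <- ss$residual / df_res
  expect_equal(td$sumsq[td$term == "transfer"], ss$transfer,
               tolerance = 1e-8)
  expect_equal(td$sumsq[td$term == "treatment"], ss$treatment,
               tolerance = 1e-8)
  expect_equal(td$sumsq[td$term == "treatment:replicate"], ss$replicate,
               tolerance = 1e-8)
  expect_equal(td$sumsq[td$term == "transfer:treatment"], ss$interaction,
               tolerance = 1e-8)
  expect_equal(td$statistic[td$term == "transfer"],
               ss$transfer / 1 / ms_res, tolerance = 1e-8)
  expect_equal(td$statistic[td$term == "treatment"],
               ss$treatment / 1 / ms_res, tolerance = 1e-8)
})

test_that("nested ANOVA detects a 2-SD treatment effect with high power", {
  hits <- vapply(1:100, function(s) {
    d <- balanced_design(n_rep = 10, effect = 2, noise = 1, seed = s)
    td <- tidy(nested_anova(d, value, transfer, treatment, replicate))
    td$p.value[td$term == "treatment"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Spearman correlation is exact on monotone data", {
  expect_equal(spearman_correlation(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  expect_equal(spearman_correlation(1:6, -(1:6))$rho, -1)
  expect_error(spearman_correlation(1:5, rep(1, 5)), "constant")
})

test_that("the exact permutation p equals full 720-permutation enumeration", {
  set.seed(3)
  x <- rnorm(6); y <- rnorm(6)
  got <- spearman_correlation(x, y)
  expect_equal(got$method, "exact permutation")
  perms <- rbind(1:6)
  # independent enumeration via recursive generation
  gen <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(gen(v[-i]), function(rest) c(v[i], rest))
    }), recursive = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rhos <- vapply(gen(ry), function(p) cor(rx, p), numeric(1))
  expect_length(rhos, factorial(6))
  p_oracle <- mean(abs(rhos) >= abs(got$rho) - 1e-12)
  expect_equal(got$p.value, p_oracle, tolerance = 1e-12)
})

test_that("BH q-values equal the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) > -1e-14))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH controls the realised false-discovery proportion under the null", {
  set.seed(77)
  fdp <- vapply(1:50, function(i) {
    p <- pnorm(rnorm(100), lower.tail = FALSE)  # global null
    mean(bh_fdr(p) < 0.05) # every discovery is false
  }, numeric(1))
  expect_lte(mean(fdp), 0.05)
})

test_that("inverse-variance weighting beats unit weights under heteroscedasticity", {
  set.seed(55)
  err_w <- err_u <- numeric(100)
  for (i in 1:100) {
    x <- runif(30, 0, 2)
    sd_i <- ifelse(x > 1, 2, 0.2)
    y <- 1.5 * x + rnorm(30, 0, sd_i)
    d <- tibble::tibble(x = x, y = y, w = 1 / sd_i^2)
    err_w[i] <- tidy(weighted_least_squares(d, x, y, weights = w))$estimate[2] - 1.5
    err_u[i] <- tidy(weighted_least_squares(d, x, y))$estimate[2] - 1.5
  }
  expect_lt(sqrt(mean(err_w^2)), sqrt(mean(err_u^2)))
})

test_that("the candidate criteria flag exactly the hand-enumerated features", {
  res <- tibble::tibble(
    feature = paste0("f", 1:6),
    n_replicates_with_variation = c(3L, 6L, 6L, 6L, 5L, 5L),
    q_treatment = c(0.01, 0.01, 0.20, 0.01, 0.01, 0.01),
    q_transfer = c(0.5, 0.5, 0.5, 0.01, 0.5, 0.5),
    q_interaction = c(0.7, 0.7, 0.7, 0.7, 0.02, 0.7),
    is_hgt = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    treatment_variance = c(NA, NA, NA, NA, NA, 0.04))
  out <- candidate_region_filter(res)
  # f1 fails (i); f3 fails the treatment test; f4 has a transfer effect;
  # f5 has an interaction; f6 sits exactly on the 0.04 boundary (strict)
  expect_equal(out$candidate, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  res$treatment_variance[6] <- 0.0401
  expect_true(candidate_region_filter(res)$candidate[6])
})

test_that("the association battery runs end to end with per-family FDR", {
  set.seed(12)
  d <- balanced_design(n_rep = 4, noise = 1)
  d$feat1 <- rnorm(nrow(d))
  d$feat2 <- 2 * (d$treatment == "coevolution") + rnorm(nrow(d), 0, 0.3)
  d$pheno <- d$feat2 + rnorm(nrow(d), 0, 0.5)
  d$logcov <- runif(nrow(d), 1.8, 2.2)
  res <- associate_features(d, c("feat1", "feat2"), "pheno",
                            weight_col = "logcov")
  expect_s3_class(res, "association_results")
  expect_equal(sort(unique(res$test)),
               sort(c("wls", "anova-treatment", "anova-transfer",
                      "anova-interaction")))
  treat2 <- res[res$feature == "feat2" & res$test == "anova-treatment", ]
  expect_lt(treat2$q.value, 0.05)
  # the blacklist removes excluded populations before testing
  bl <- tibble::tibble(treatment = "coevolution", transfer = "t12",
                       replicate = "r3")
  res_bl <- associate_features(d, "feat2", "pheno", blacklist = bl)
  expect_s3_class(res_bl, "tbl_df")
})
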