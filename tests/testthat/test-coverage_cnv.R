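cov_tbl <- function(m, contig = "c1") {
  out <- tibble::tibble(contig = contig, pos = 0:(nrow(m) - 1))
  for (j in seq_len(ncol(m))) out[[paste0("s", j)]] <- m[, j]
  out
}

test_that("rank transform normalises within sample and averages ties", {
  d <- cov_tbl(matrix(c(10, 20, 30), ncol = 1))
  expect_equal(rank_transform(d)$s1, c(1, 2, 3) / 3)
  tie <- cov_tbl(matrix(rep(7, 5), ncol = 1))
  expect_equal(rank_transform(tie)$s1, rep((5 + 1) / (2 * 5), 5))
})

test_that("rank transform equals a brute-force comparison-count oracle", {
  set.seed(2)
  m <- matrix(rpois(200, 30), ncol = 4)
  r <- rank_transform(cov_tbl(m))
  for (j in 1:4) {
    expect_equal(r[[paste0("s", j)]], oracle_rank(m[, j]) / nrow(m))
  }
})

test_that("rank variance matches hand computation and ignores depth scale", {
  d <- cov_tbl(matrix(c(1, 2, 2, 1), ncol = 2))
  # identical-up-to-order samples: each position has ranks (0.5, 1) etc.
  two <- tibble::tibble(contig = "c1", pos = 0:1,
                        s1 = c(0.1, 0.5), s2 = c(0.9, 0.5))
  rv <- rank_variance(two)
  expect_equal(rv$rank_var[1], 0.32)  # var(c(0.1, 0.9)) = 0.8^2 / 2
  same <- cov_tbl(matrix(c(5, 9, 3, 5, 9, 3), ncol = 2))
  expect_equal(rank_variance(rank_transform(same))$rank_var, rep(0, 3))
  # multiplying one sample's raw depths leaves ranks unchanged
  m <- matrix(rpois(300, 50), ncol = 3)
  m2 <- m; m2[, 2] <- m2[, 2] * 10L
  expect_equal(rank_variance(rank_transform(cov_tbl(m))),
               rank_variance(rank_transform(cov_tbl(m2))))
  expect_error(rank_variance(rank_transform(cov_tbl(m[, 1, drop = FALSE]))),
               "2 samples")
})

test_that("outlier extraction recovers planted values and stays quiet on nulls", {
  expect_length(detect_outlier_positions(rep(0.3, 500)), 0)
  extra <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    x <- c(rnorm(10000, 0.01, 0.001), rep(0.05, 20))
    out <- detect_outlier_positions(x)
    expect_true(all(10001:10020 %in% out))  # every planted value flagged
    extra[s] <- length(setdiff(out, 10001:10020))
  }
  # with rho = 1, about one null draw per run is expected past the limit
  expect_lte(mean(extra), 2)
  # calibration: expected false-positive count under the fitted normal
  fps <- vapply(1:50, function(s) {
    set.seed(s + 200)
    length(detect_outlier_positions(rnorm(10000, 0.01, 0.001)))
  }, numeric(1))
  expect_lte(mean(fps), 2)
})

test_that("adjacent outliers merge under the strict 100-bp rule", {
  r1 <- merge_adjacent(tibble::tibble(contig = "c1",
                                      pos = c(1000L, 1050L, 1120L)))
  expect_equal(r1[, c("start", "end")],
               tibble::tibble(start = 1000L, end = 1121L))
  r2 <- merge_adjacent(tibble::tibble(contig = "c1", pos = c(1000L, 1100L)))
  expect_equal(nrow(r2), 2L)  # gap of exactly 100 does not merge
  set.seed(12)
  for (i in 1:5) {
    pos <- sort(sample.int(5000, 300))
    got <- merge_adjacent(tibble::tibble(contig = "cx", pos = pos),
                          max_gap = 100)
    want <- oracle_merge(pos, 100)
    expect_equal(got$start, as.integer(want$start))
    expect_equal(got$end, as.integer(want$end))
    expect_equal(got$n_positions, as.integer(want$n))
  }
})

test_that("copy number is depth relative to the chromosomal median", {
  m <- matrix(100L, nrow = 1000, ncol = 2)
  m[101:200, ] <- 200L
  d <- cov_tbl(m)
  contigs <- tibble::tibble(contig = "c1", length = 1000L,
                            role = "chromosomal")
  cn <- estimate_copy_number(
    tibble::tibble(contig = "c1", start = 100L, end = 200L), d, contigs)
  expect_equal(cn$copy_number, c(2, 2))
  null_cn <- estimate_copy_number(
    tibble::tibble(contig = "c1", start = 500L, end = 600L), d, contigs)
  expect_equal(null_cn$copy_number, c(1, 1))
})

test_that("contig copy number sees a 5x plasmid and is seed-stable", {
  set.seed(3)
  chrom <- matrix(rpois(4000, 100), ncol = 2)
  plas <- matrix(rpois(2000, 500), ncol = 2)
  d <- dplyr::bind_rows(cov_tbl(chrom, "chr"), cov_tbl(plas, "pla"))
  contigs <- tibble::tibble(contig = c("chr", "pla"),
                            length = c(2000L, 1000L),
                            role = c("chromosomal", "plasmid"))
  cc1 <- contig_copy_number(d, contigs, seed = 5)
  cc2 <- contig_copy_number(d, contigs, seed = 5)
  expect_identical(cc1, cc2)
  expect_lt(max(abs(cc1$copy_number[cc1$contig == "pla"] - 5)), 0.2)
  expect_lt(max(abs(cc1$copy_number[cc1$contig == "chr"] - 1)), 0.05)
})

test_that("the detector is invariant under per-sample monotone depth maps", {
  truth <- sim_truth(1, cnv = tibble::tibble(
    contig = "ctg1", start = 10000L, end = 11000L, copy_number = 2,
    carrier_frequency = 1, carrier_samples = list(1:3)))
  d <- simulate_coverage_matrix(truth, n_samples = 6,
                                contigs = tibble::tibble(
                                  contig = "ctg1", length = 30000L,
                                  role = "chromosomal"),
                                seed = 8)
  maps <- list(function(x) x^2, function(x) 3 * x + 7, function(x) exp(x / 50),
               function(x) x^3, function(x) sqrt(x), function(x) x)
  d2 <- d
  for (j in 1:6) d2[[paste0("s", j)]] <- maps[[j]](d[[paste0("s", j)]])
  rv1 <- rank_variance(rank_transform(d))
  rv2 <- rank_variance(rank_transform(d2))
  expect_equal(rv1, rv2)
})

test_that("a planted duplication is recovered as a merged region", {
  truth <- sim_truth(1, cnv = tibble::tibble(
    contig = "ctg1", start = 30000L, end = 31000L, copy_number = 2,
    carrier_frequency = 1, carrier_samples = list(1:5)))
  d <- simulate_coverage_matrix(truth, n_samples = 10,
                                contigs = tibble::tibble(
                                  contig = "ctg1", length = 60000L,
                                  role = "chromosomal"),
                                seed = 17)
  calls <- detect_cnv(d)
  ov <- calls[calls$start < 31000 & calls$end > 30000, ]
  expect_equal(nrow(ov), 1L)
  jaccard <- (min(ov$end, 31000) - max(ov$start, 30000)) /
    (max(ov$end, 31000) - min(ov$start, 30000))
  expect_gte(jaccard, 0.8)
  cn <- ov$copy_number[[1]]
  carriers <- cn$copy_number[cn$sample %in% paste0("s", 1:5)]
  expect_lt(max(abs(carriers - 2)), 0.15)
})
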