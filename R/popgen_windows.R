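#' Coverage-adjusted diversity statistics in sliding windows
#'
#' In pool-seq data the number of sampled chromosomes at a site is
#' unknown; read depth is used as its proxy. Watterson's theta and
#' Tajima's pi are therefore computed with per-site sample sizes: each
#' segregating site contributes `1 / a1(n_i)` to theta and
#' `n_i / (n_i - 1) * 2 p_i (1 - p_i)` to pi, where `n_i` is the site's
#' coverage. At constant coverage both reduce exactly to the classical
#' fixed-n estimators. Tajima's D uses the classical variance constants
#' evaluated at the window's rounded mean coverage.
#'
#' @name popgen_windows
NULL

#' Harmonic sums used by the Watterson and Tajima estimators
#'
#' @param n Sample size(s), each >= 2.
#' @return Tibble with columns `n`, `a1` (sum of 1/i, i < n) and `a2`
#'   (sum of 1/i^2).
#' @export
harmonic_numbers <- function(n) {
  if (any(n < 2) || any(n != round(n))) abort("`n` must be whole numbers >= 2")
  tibble(n = n,
         a1 = vapply(n, function(k) sum(1 / seq_len(k - 1)), numeric(1)),
         a2 = vapply(n, function(k) sum(1 / seq_len(k - 1)^2), numeric(1)))
}

# classical Tajima's D variance constants at sample size n
tajima_constants <- function(n) {
  h <- harmonic_numbers(n)
  a1 <- h$a1; a2 <- h$a2
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# segregating sites retained for the estimators: coverage >= 2 and
# frequency strictly between maf and 1
retained_sites <- function(sites, maf) {
  sites[!is.na(sites$freq) & sites$coverage >= 2 &
          sites$freq > maf & sites$freq < 1, , drop = FALSE]
}

#' Coverage-adjusted Watterson's theta for one window
#'
#' @param sites Tibble `pos`, `coverage`, `freq` for sites in the
#'   window (`freq` is the derived/minor allele frequency).
#' @param window_length Window length in bp (> 0).
#' @param maf Only polymorphisms with frequency strictly above this are
#'   counted (default 0.05).
#' @return Theta_W per bp.
#' @export
window_theta_w <- function(sites, window_length, maf = 0.05) {
  check_number(window_length, "window_length", lower = 1e-9)
  s <- retained_sites(sites, maf)
  if (!nrow(s)) return(0)
  sum(1 / harmonic_numbers(s$coverage)$a1) / window_length
}

#' Coverage-adjusted Tajima's pi for one window
#'
#' @inheritParams window_theta_w
#' @return Pi per bp (unbiased per-site heterozygosity,
#'   `n/(n-1) * 2p(1-p)`, summed and divided by window length).
#' @export
window_theta_pi <- function(sites, window_length, maf = 0.05) {
  check_number(window_length, "window_length", lower = 1e-9)
  s <- retained_sites(sites, maf)
  if (!nrow(s)) return(0)
  n <- s$coverage
  sum(n / (n - 1) * 2 * s$freq * (1 - s$freq)) / window_length
}

#' Tajima's D from window totals
#'
#' @param pi_total Sum of per-site heterozygosities (not divided by
#'   length).
#' @param theta_total Sum of per-site Watterson contributions (not
#'   divided by length).
#' @param S Number of segregating sites in the window.
#' @param n Sample size for the variance constants (the window's
#'   rounded mean coverage).
#' @return D, or `NA` when `S` = 0, `n` < 3, or the variance term is
#'   not positive.
#' @export
tajimas_d <- function(pi_total, theta_total, S, n) {
  if (is.na(S) || S < 1 || is.na(n) || n < 3) return(NA_real_)
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  if (!is.finite(v) || v <= 0) {
    warn("non-positive variance term; Tajima's D set to NA")
    return(NA_real_)
  }
  (pi_total - theta_total) / sqrt(v)
}

#' Sliding-window diversity scan
#'
#' Half-open windows `[k * step, k * step + window)` per contig; the
#' trailing window is emitted truncated to the contig end with its true
#' length used for the per-bp normalisation.
#'
#' @param sites Tibble `contig`, `pos`, `coverage`, `freq` over the
#'   genome.
#' @param window Window size in bp (default 10000).
#' @param step Step size in bp (default 5000); must not exceed
#'   `window`.
#' @param maf Frequency threshold, see [window_theta_w()].
#' @param contig_lengths Optional tibble `contig`, `length`; inferred
#'   from the largest site position when absent.
#' @param n_summary How the window's sample size for Tajima's D is
#'   summarised from retained-site coverages: `"mean"` (default),
#'   `"median"` or `"harmonic"`.
#' @return Tibble (class `window_stats`): `contig`, `start`, `end`,
#'   `length`, `S`, `mean_coverage`, `theta_w`, `theta_pi`, `tajimas_d`.
#' @export
sliding_windows <- function(sites, window = 10000, step = 5000, maf = 0.05,
                            contig_lengths = NULL,
                            n_summary = c("mean", "median", "harmonic")) {
  check_columns(sites, c("contig", "pos", "coverage", "freq"), "sites")
  n_summary <- match.arg(n_summary)
  window <- check_count(window, "window")
  step <- check_count(step, "step")
  if (window < step) abort("`window` must be >= `step`")
  cts <- if (is.null(contig_lengths)) {
    sites %>% group_by(.data$contig) %>%
      summarise(length = max(.data$pos) + 1L, .groups = "drop")
  } else {
    check_columns(contig_lengths, c("contig", "length"), "contig_lengths")
    contig_lengths
  }
  out <- purrr::pmap_dfr(cts[, c("contig", "length")], function(contig, length) {
    starts <- seq(0L, max(0L, length - 1L), by = step)
    starts <- starts[starts < length]
    ss <- sites[sites$contig == contig, ]
    purrr::map_dfr(starts, function(st) {
      en <- min(st + window, length)
      win <- ss[ss$pos >= st & ss$pos < en, ]
      ret <- retained_sites(win, maf)
      L <- en - st
      nbar <- if (nrow(ret)) mean(ret$coverage) else NA_real_
      n_d <- if (!nrow(ret)) NA_real_ else switch(n_summary,
        mean = round(mean(ret$coverage)),
        median = round(median(ret$coverage)),
        harmonic = round(nrow(ret) / sum(1 / ret$coverage)))
      tw <- window_theta_w(win, L, maf)
      tp <- window_theta_pi(win, L, maf)
      tibble(contig = contig, start = st, end = en, length = L,
             S = nrow(ret), mean_coverage = nbar,
             theta_w = tw, theta_pi = tp,
             tajimas_d = tajimas_d(tp * L, tw * L, nrow(ret), n_d))
    })
  })
  structure(out, class = c("window_stats", class(out)))
}
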