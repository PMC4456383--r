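#' Copy-number variation from across-sample coverage-rank variance
#'
#' Pooled samples can carry a duplication in only part of the population,
#' shifting coverage by a fractional factor that absolute-depth CNV
#' callers miss. The detector used here ranks each position's depth
#' within its sample (so samples of different sequencing depth are
#' comparable), computes the variance of those normalised ranks across
#' samples at every position, extracts right-tail outliers of that
#' variance by a normal quantile-quantile fit, merges outliers closer
#' than 100 bp into "coverage singularities", and estimates per-sample
#' copy number as depth relative to the chromosomal median.
#'
#' @name coverage_cnv
NULL

sample_cols <- function(depths) {
  setdiff(names(depths), c("contig", "pos"))
}

#' Rank-transform a coverage matrix
#'
#' Within each sample, positions are ranked by depth (ties receive the
#' average fractional rank) and divided by the number of positions, so
#' every sample maps onto (0, 1\] regardless of its sequencing depth.
#' Ranks are computed genome-wide across all contigs by default.
#'
#' @param depths Wide tibble: `contig`, `pos`, then one depth column per
#'   sample (as produced by [simulate_coverage_matrix()]).
#' @param by_contig Rank within each contig separately instead of
#'   genome-wide.
#' @return Tibble of the same shape with depths replaced by normalised
#'   ranks.
#' @export
rank_transform <- function(depths, by_contig = FALSE) {
  check_columns(depths, c("contig", "pos"), "depths")
  smp <- sample_cols(depths)
  if (!length(smp)) abort("no sample columns in `depths`")
  if (nrow(depths) < 2) abort("need at least 2 positions to rank")
  rk <- function(x) rank(x, ties.method = "average") / length(x)
  out <- depths
  if (by_contig) {
    out <- out %>%
      group_by(.data$contig) %>%
      mutate(across(all_of(smp), rk)) %>%
      ungroup()
  } else {
    out[smp] <- lapply(out[smp], rk)
  }
  out
}

#' Across-sample variance of coverage ranks
#'
#' @param ranks Output of [rank_transform()].
#' @return Tibble `contig`, `pos`, `rank_var` — the sample variance
#'   (n - 1 denominator) of each position's normalised ranks.
#' @export
rank_variance <- function(ranks) {
  check_columns(ranks, c("contig", "pos"), "ranks")
  smp <- sample_cols(ranks)
  if (length(smp) < 2) abort("need at least 2 samples to compute a variance")
  m <- as.matrix(ranks[smp])
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (length(smp) - 1)
  tibble(contig = ranks$contig, pos = ranks$pos, rank_var = v)
}

#' Right-tail outliers under a central-band normal fit
#'
#' Fits a normal distribution to the central quantile band of the sorted
#' values by least-squares regression of observed order statistics on
#' standard-normal quantiles (plotting positions i / (N + 1)), then
#' flags values in the right tail whose expected count under the fitted
#' normal, given N observations, is strictly below `rho`.
#'
#' @param x Numeric vector (e.g. per-position rank variances).
#' @param band Quantile band used for the fit (default 10 to 90 percent).
#' @param rho Expected-count threshold (default 1).
#' @return Integer indices of flagged values; the fitted mean/sd and the
#'   flagging limit are attached as attribute `"fit"`.
#' @export
detect_outlier_positions <- function(x, band = c(0.1, 0.9), rho = 1) {
  if (!is.numeric(x)) abort("`x` must be numeric")
  N <- length(x)
  if (N < 100) warn("fewer than 100 observations: normal fit may be unstable")
  s <- sort(x)
  if (s[1] == s[N]) {
    out <- integer(0)
    attr(out, "fit") <- c(mean = s[1], sd = 0, limit = Inf)
    return(out)
  }
  p <- seq_len(N) / (N + 1)
  keep <- p >= band[1] & p <= band[2]
  fit <- lm.fit(cbind(1, qnorm(p[keep])), s[keep])
  mu <- unname(fit$coefficients[1])
  sigma <- unname(fit$coefficients[2])
  if (!is.finite(sigma) || sigma <= 0) {
    out <- integer(0)
    attr(out, "fit") <- c(mean = mu, sd = sigma, limit = Inf)
    return(out)
  }
  limit <- qnorm(1 - rho / N, mu, sigma)
  out <- which(x > limit)
  attr(out, "fit") <- c(mean = mu, sd = sigma, limit = limit)
  out
}

#' Merge nearby outlier positions into regions
#'
#' Positions on the same contig separated by strictly less than
#' `max_gap` bp belong to the same coverage singularity; a gap of
#' exactly `max_gap` starts a new region.
#'
#' @param outliers Tibble `contig`, `pos` (0-based positions).
#' @param max_gap Merge distance in bp (default 100).
#' @return Tibble `contig`, `start`, `end` (0-based half-open),
#'   `n_positions`.
#' @export
merge_adjacent <- function(outliers, max_gap = 100) {
  check_columns(outliers, c("contig", "pos"), "outliers")
  if (!nrow(outliers)) {
    return(tibble(contig = character(), start = integer(),
                  end = integer(), n_positions = integer()))
  }
  outliers %>%
    arrange(.data$contig, .data$pos) %>%
    group_by(.data$contig) %>%
    mutate(.grp = cumsum(c(1, diff(.data$pos) >= max_gap))) %>%
    group_by(.data$contig, .data$.grp) %>%
    summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
              n_positions = dplyr::n(), .groups = "drop") %>%
    select(-".grp") %>%
    select("contig", "start", "end", "n_positions")
}

#' Per-sample copy number of a region
#'
#' Median depth inside the region divided by the median depth over all
#' chromosomal-role positions of the same sample.
#'
#' @param regions Tibble `contig`, `start`, `end` (0-based half-open).
#' @param depths Wide coverage tibble (see [rank_transform()]).
#' @param contigs Tibble `contig`, `role` (and usually `length`).
#' @return Long tibble `contig`, `start`, `end`, `sample`, `copy_number`.
#' @export
estimate_copy_number <- function(regions, depths, contigs) {
  check_columns(regions, c("contig", "start", "end"), "regions")
  check_columns(contigs, c("contig", "role"), "contigs")
  smp <- sample_cols(depths)
  chrom <- depths$contig %in% contigs$contig[contigs$role == "chromosomal"]
  if (!any(chrom)) abort("no chromosomal-role positions in `depths`")
  chrom_median <- vapply(depths[chrom, smp], median, numeric(1))
  if (any(chrom_median == 0)) {
    abort("undefined ratio: a sample has zero median chromosomal depth")
  }
  purrr::pmap_dfr(regions[, c("contig", "start", "end")],
    function(contig, start, end) {
      inside <- depths$contig == contig &
        depths$pos >= start & depths$pos < end
      med <- vapply(depths[inside, smp], median, numeric(1))
      tibble(contig = contig, start = start, end = end, sample = smp,
             copy_number = unname(med / chrom_median))
    })
}

#' Contig-level copy number with resampling variance
#'
#' Ratio of a contig's mean depth to the mean depth over chromosomal
#' contigs, per sample; the variance of the ratio is estimated by
#' drawing `n_draws` positions with replacement from the contig (all
#' positions when fewer are available).
#'
#' @inheritParams estimate_copy_number
#' @param n_draws Positions resampled for the variance (default 10000).
#' @param seed Integer seed for the resampling.
#' @return Tibble `contig`, `sample`, `copy_number`, `cn_variance`.
#' @export
contig_copy_number <- function(depths, contigs, n_draws = 10000, seed = 1L) {
  check_columns(contigs, c("contig", "role"), "contigs")
  smp <- sample_cols(depths)
  chrom <- depths$contig %in% contigs$contig[contigs$role == "chromosomal"]
  if (!any(chrom)) abort("no chromosomal-role positions in `depths`")
  chrom_mean <- colMeans(as.matrix(depths[chrom, smp]))
  with_seed(derive_seed(seed, "contig_cn"), {
    purrr::map_dfr(unique(depths$contig), function(ct) {
      rows <- which(depths$contig == ct)
      m <- as.matrix(depths[rows, smp])
      idx <- sample.int(length(rows), n_draws, replace = TRUE)
      ratios <- sweep(m, 2, chrom_mean, "/")
      tibble(contig = ct, sample = smp,
             copy_number = unname(colMeans(m) / chrom_mean),
             cn_variance = unname(apply(ratios[idx, , drop = FALSE], 2, var)))
    })
  })
}

#' Detect CNV regions in a multi-sample coverage matrix
#'
#' Full detector: rank transform, across-sample rank variance, outlier
#' extraction, merging, and per-sample copy-number estimation.
#'
#' @inheritParams rank_transform
#' @inheritParams detect_outlier_positions
#' @param max_gap Merge distance for adjacent outliers (bp).
#' @param contigs Contig table with roles; defaults to the `"contigs"`
#'   attribute of `depths` when present.
#' @return Tibble (class `cnv_calls`): one row per region with `contig`,
#'   `start`, `end`, `n_positions`, `peak_rank_var`, and a `copy_number`
#'   list-column of per-sample estimates. The per-position variance
#'   track is attached as attribute `"rank_var"`.
#' @export
detect_cnv <- function(depths, contigs = NULL, band = c(0.1, 0.9),
                       rho = 1, max_gap = 100, by_contig = FALSE) {
  contigs <- contigs %||% attr(depths, "contigs")
  if (is.null(contigs)) abort("supply `contigs` (contig, length, role)")
  rv <- rank_variance(rank_transform(depths, by_contig = by_contig))
  idx <- detect_outlier_positions(rv$rank_var, band = band, rho = rho)
  regions <- merge_adjacent(rv[idx, c("contig", "pos")], max_gap = max_gap)
  if (nrow(regions)) {
    regions$peak_rank_var <- purrr::pmap_dbl(
      regions[, c("contig", "start", "end")],
      function(contig, start, end) {
        max(rv$rank_var[rv$contig == contig &
                          rv$pos >= start & rv$pos < end])
      })
    cn <- estimate_copy_number(regions, depths, contigs)
    regions$copy_number <- purrr::pmap(
      regions[, c("contig", "start", "end")],
      function(contig, start, end) {
        cn[cn$contig == contig & cn$start == start & cn$end == end,
           c("sample", "copy_number")]
      })
  } else {
    regions$peak_rank_var <- numeric(0)
    regions$copy_number <- list()
  }
  structure(regions, class = c("cnv_calls", class(regions)),
            rank_var = rv)
}
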