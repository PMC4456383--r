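#' Post-calling variant filters for pooled samples
#'
#' Variant records come as one row per (sample, contig, position, allele)
#' with read-count evidence. Four filters are applied after calling:
#' (i) coverage-quantile, (ii) Fisher strand-bias, (iii) indel collision,
#' and (iv) minor-allele-frequency. [filter_variants()] chains them in
#' that order and records per-filter drop counts.
#'
#' Expected columns: `sample`, `contig`, `pos` (0-based), `type`
#' (`"SNP"` or `"indel"`), `ref`, `alt`, `depth`, `alt_count`,
#' `alt_fwd`, `alt_rev`, `ref_fwd`, `ref_rev`.
#'
#' @name variant_filters
NULL

variant_cols <- c("sample", "contig", "pos", "type", "depth", "alt_count")

#' Coverage-quantile filter
#'
#' Drops records whose depth falls below the `low` or above the `high`
#' empirical quantile of the per-sample depth distribution (linear
#' interpolation, [stats::quantile()] type 7). With fewer than
#' `min_records` records per sample the quantiles are unstable, so the
#' sample is passed through with a warning.
#'
#' @param variants Variant tibble, see [variant_filters].
#' @param low,high Quantile bounds (defaults 0.02 and 0.98).
#' @param min_records Minimum records per sample to apply the filter.
#' @return Filtered tibble.
#' @export
filter_coverage_quantile <- function(variants, low = 0.02, high = 0.98,
                                     min_records = 50) {
  check_columns(variants, variant_cols, "variants")
  if (!nrow(variants)) return(variants)
  variants %>%
    group_by(.data$sample) %>%
    group_modify(function(df, key) {
      if (nrow(df) < min_records) {
        warn(sprintf(
          "sample '%s': %d record(s) < %d; coverage quantiles not applied",
          key$sample, nrow(df), min_records))
        return(df)
      }
      q <- quantile(df$depth, c(low, high), type = 7, names = FALSE)
      df[df$depth >= q[1] & df$depth <= q[2], ]
    }) %>%
    ungroup()
}

#' Fisher strand-bias filter
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' \[\[alt_fwd, alt_rev\], \[ref_fwd, ref_rev\]\]; records with
#' p < `alpha` show significant strand bias and are dropped.
#'
#' @inheritParams filter_coverage_quantile
#' @param alpha Significance threshold (default 0.05).
#' @return Filtered tibble with a `strand_p` column added.
#' @export
filter_strand_bias <- function(variants, alpha = 0.05) {
  check_columns(variants, c(variant_cols, "alt_fwd", "alt_rev",
                            "ref_fwd", "ref_rev"), "variants")
  if (!nrow(variants)) {
    variants$strand_p <- numeric(0)
    return(variants)
  }
  cnts <- variants[, c("alt_fwd", "alt_rev", "ref_fwd", "ref_rev")]
  if (any(as.matrix(cnts) < 0, na.rm = TRUE)) {
    abort("invalid record: negative strand counts")
  }
  key <- do.call(paste, cnts)
  uniq <- !duplicated(key)
  p_uniq <- purrr::pmap_dbl(cnts[uniq, ], function(alt_fwd, alt_rev,
                                                   ref_fwd, ref_rev) {
    fisher.test(matrix(c(alt_fwd, ref_fwd, alt_rev, ref_rev), 2))$p.value
  })
  variants$strand_p <- p_uniq[match(key, key[uniq])]
  variants[variants$strand_p >= alpha, ]
}

#' Indel-collision filter
#'
#' A SNP sharing (sample, contig, position) with an indel record is
#' dropped; the indel itself is retained.
#'
#' @inheritParams filter_coverage_quantile
#' @return Filtered tibble.
#' @export
filter_indel_collision <- function(variants) {
  check_columns(variants, c(variant_cols, "type"), "variants")
  if (!nrow(variants)) return(variants)
  indel_keys <- with(variants[variants$type == "indel", ],
                     paste(sample, contig, pos))
  keys <- with(variants, paste(sample, contig, pos))
  variants[!(variants$type == "SNP" & keys %in% indel_keys), ]
}

#' Minor-allele-frequency filter
#'
#' Retains records with `alt_count / depth` strictly above `threshold`
#' ("above 5%" is read strictly: a frequency of exactly 0.05 is
#' dropped). Zero-depth records are dropped with a warning.
#'
#' @inheritParams filter_coverage_quantile
#' @param threshold MAF threshold (default 0.05).
#' @return Filtered tibble.
#' @export
filter_maf <- function(variants, threshold = 0.05) {
  check_columns(variants, variant_cols, "variants")
  if (!nrow(variants)) return(variants)
  zero <- variants$depth <= 0
  if (any(zero)) {
    warn(sprintf("%d zero-depth record(s) dropped", sum(zero)))
    variants <- variants[!zero, ]
  }
  variants[variants$alt_count / variants$depth > threshold, ]
}

#' Apply all four variant filters in order
#'
#' Chains coverage-quantile (i), strand-bias (ii), indel-collision (iii)
#' and MAF (iv). The coverage quantiles are computed on the pre-filter
#' depth distribution (filter order matters only through this step).
#'
#' @inheritParams filter_coverage_quantile
#' @param alpha Strand-bias threshold.
#' @param maf MAF threshold.
#' @return Filtered tibble; attribute `"audit"` is a tibble with one row
#'   per filter (`filter`, `n_in`, `n_dropped`).
#' @export
filter_variants <- function(variants, low = 0.02, high = 0.98,
                            alpha = 0.05, maf = 0.05, min_records = 50) {
  steps <- list(
    coverage_quantile = function(v)
      filter_coverage_quantile(v, low, high, min_records),
    strand_bias = function(v) filter_strand_bias(v, alpha),
    indel_collision = filter_indel_collision,
    maf = function(v) filter_maf(v, maf)
  )
  audit <- tibble(filter = names(steps), n_in = NA_integer_,
                  n_dropped = NA_integer_)
  v <- variants
  for (i in seq_along(steps)) {
    n_in <- nrow(v)
    v <- steps[[i]](v)
    audit$n_in[i] <- n_in
    audit$n_dropped[i] <- n_in - nrow(v)
  }
  attr(v, "audit") <- audit
  v
}
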