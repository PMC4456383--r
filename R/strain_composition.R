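#' Half-sample mode of a numeric sample
#'
#' Robust mode estimator for skewed unimodal data: repeatedly keep the
#' shortest interval spanning half of the (sorted) points until at most
#' three remain, then average. Deterministic, O(n log n), no bandwidth.
#'
#' @param x Numeric vector (non-empty, finite).
#' @return The modal value.
#' @export
half_sample_mode <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) abort("no data: cannot estimate a mode from an empty vector")
  x <- sort(x)
  while (length(x) > 3) {
    n <- length(x)
    h <- ceiling(n / 2)
    widths <- x[h:n] - x[1:(n - h + 1)]
    i <- which.min(widths)  # leftmost shortest half keeps ties deterministic
    x <- x[i:(i + h - 1)]
  }
  if (length(x) == 3) {
    # keep the closer pair; equidistant -> middle point
    if (x[2] - x[1] < x[3] - x[2]) return(mean(x[1:2]))
    if (x[3] - x[2] < x[2] - x[1]) return(mean(x[2:3]))
    return(x[2])
  }
  mean(x)
}

#' Mode of a frequency distribution
#'
#' The per-site substitution frequencies at one strain's diagnostic
#' sites form a skewed unimodal distribution; its mode is the strain
#' frequency estimate. The default is the half-sample mode; a kernel
#' density argmax is available as an alternative.
#'
#' @param x Numeric vector of proportions.
#' @param method `"hsm"` (default) or `"density"`.
#' @return Modal value, clipped to \[0, 1\].
#' @export
estimate_mode <- function(x, method = c("hsm", "density")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (!length(x)) abort("no data: cannot estimate a mode from an empty vector")
  m <- if (method == "hsm") {
    half_sample_mode(x)
  } else {
    if (length(unique(x)) == 1) x[1] else {
      d <- stats::density(x)
      d$x[which.max(d$y)]
    }
  }
  min(max(m, 0), 1)
}

#' Per-strain substitution frequencies at diagnostic sites
#'
#' For each diagnostic site, the frequency is the diagnostic-allele read
#' count divided by total depth at that site. Sites below `min_depth`
#' and sites absent from the pileup are dropped (counted, not errors).
#'
#' @param pileup Tibble `contig`, `pos`, `depth`, `A`, `C`, `G`, `T`
#'   (one pooled sample).
#' @param sites Output of [find_diagnostic_sites()].
#' @param min_depth Minimum depth for a site to be used (default 10).
#' @return Tibble `strain`, `contig`, `pos`, `depth`, `freq`, with the
#'   number of sites dropped for depth / absence in attributes
#'   `"n_low_depth"` / `"n_missing"`.
#' @export
diagnostic_allele_frequencies <- function(pileup, sites, min_depth = 10) {
  check_columns(pileup, c("contig", "pos", "depth", "A", "C", "G", "T"),
                "pileup")
  check_columns(sites, c("contig", "pos", "strain", "allele"), "sites")
  j <- match(paste(sites$contig, sites$pos), paste(pileup$contig, pileup$pos))
  missing <- is.na(j)
  if (any(missing)) {
    warn(sprintf("%d diagnostic site(s) absent from the pileup were dropped",
                 sum(missing)))
  }
  sites <- sites[!missing, ]
  j <- j[!missing]
  counts <- as.matrix(pileup[j, c("A", "C", "G", "T")])
  allele_count <- counts[cbind(seq_len(nrow(sites)),
                               match(sites$allele, c("A", "C", "G", "T")))]
  depth <- pileup$depth[j]
  low <- depth < min_depth
  out <- tibble(strain = sites$strain, contig = sites$contig,
                pos = sites$pos, depth = depth,
                freq = ifelse(depth > 0, allele_count / depth, NA_real_))
  out <- out[!low & depth > 0, ]
  attr(out, "n_low_depth") <- sum(low)
  attr(out, "n_missing") <- sum(missing)
  out
}

#' Estimate strain composition of a pooled sample
#'
#' Per strain, the point estimate of relative abundance is the mode of
#' the distribution of substitution frequencies across that strain's
#' diagnostic sites; the frequencies are treated as independent
#' estimates and are not renormalised, so `1 - sum(estimates)` is
#' reported as the unexplained residual.
#'
#' @inheritParams diagnostic_allele_frequencies
#' @param min_sites Minimum usable diagnostic sites per strain; strains
#'   below this are still estimated but flagged `low_support`.
#' @param method Mode estimator, see [estimate_mode()].
#' @return Tibble (class `strain_profile`): `strain`, `estimate`,
#'   `n_sites`, `low_support`; attribute `"residual"` holds
#'   `1 - sum(estimate)` and `"frequencies"` the per-site table.
#' @export
strain_composition <- function(pileup, sites, min_depth = 10,
                               min_sites = 20, method = c("hsm", "density")) {
  method <- match.arg(method)
  freqs <- diagnostic_allele_frequencies(pileup, sites, min_depth = min_depth)
  strains <- unique(sites$strain)
  est <- purrr::map_dfr(strains, function(s) {
    f <- freqs$freq[freqs$strain == s]
    tibble(strain = s,
           estimate = if (length(f)) estimate_mode(f, method) else NA_real_,
           n_sites = length(f),
           low_support = length(f) < min_sites)
  })
  if (any(est$low_support)) {
    warn(sprintf("strain(s) %s estimated from fewer than %d diagnostic sites",
                 paste(est$strain[est$low_support], collapse = ", "),
                 min_sites))
  }
  structure(est, class = c("strain_profile", class(est)),
            residual = 1 - sum(est$estimate, na.rm = TRUE),
            frequencies = freqs)
}
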