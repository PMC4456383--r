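#' Simulation truth record
#'
#' Bundles the ground truth behind a simulated pooled population: the
#' strain mixture, planted copy-number variants, planted horizontally
#' transferred fragments, and the per-base sequencing error rate. Every
#' generator consumes and/or returns one of these so parameter-recovery
#' tests can compare estimates with truth.
#'
#' @param mixture Named or unnamed numeric vector of strain proportions;
#'   must lie in \[0, 1\] and sum to 1 (tolerance 1e-12).
#' @param cnv Tibble of planted duplications with columns `contig`,
#'   `start`, `end` (0-based half-open), `copy_number`,
#'   `carrier_frequency`; optional list-column `carrier_samples` naming
#'   which pooled samples carry the event (default: all).
#' @param hgt Tibble of planted transfers with columns `donor`, `contig`,
#'   `start`, `end`, `frequency` (donor coordinates).
#' @param error_rate Per-base substitution probability in \[0, 0.25\].
#' @param seed Integer seed from which all sample-level seeds derive.
#' @return Object of class `sim_truth`.
#' @export
sim_truth <- function(mixture, cnv = NULL, hgt = NULL,
                      error_rate = 0.001, seed = 1L) {
  if (!is.numeric(mixture) || length(mixture) < 1) {
    abort("`mixture` must be a numeric vector of proportions")
  }
  if (any(mixture < 0 | mixture > 1)) abort("mixture proportions must be in [0, 1]")
  if (abs(sum(mixture) - 1) > 1e-12) abort("mixture proportions must sum to 1")
  check_number(error_rate, "error_rate", 0, 0.25)
  cnv <- if (is.null(cnv)) {
    tibble(contig = character(), start = integer(), end = integer(),
           copy_number = numeric(), carrier_frequency = numeric())
  } else {
    check_columns(cnv, c("contig", "start", "end", "copy_number",
                         "carrier_frequency"), "cnv")
    as_tibble(cnv)
  }
  hgt <- if (is.null(hgt)) {
    tibble(donor = character(), contig = character(), start = integer(),
           end = integer(), frequency = numeric())
  } else {
    check_columns(hgt, c("donor", "contig", "start", "end", "frequency"), "hgt")
    as_tibble(hgt)
  }
  for (iv in list(cnv, hgt)) {
    if (nrow(iv) && any(iv$start >= iv$end)) {
      abort("planted intervals must satisfy start < end (half-open)")
    }
  }
  if (nrow(cnv) && any(cnv$carrier_frequency < 0 | cnv$carrier_frequency > 1)) {
    abort("carrier_frequency must be in [0, 1]")
  }
  if (nrow(hgt) && any(hgt$frequency < 0 | hgt$frequency > 1)) {
    abort("hgt frequency must be in [0, 1]")
  }
  structure(
    list(mixture = mixture, cnv = cnv, hgt = hgt,
         error_rate = error_rate, seed = as.integer(seed)),
    class = "sim_truth"
  )
}

#' Simulate an aligned panel of diverged strain genomes
#'
#' Draws a random ancestral genome, splits it into contigs (the last
#' contig plays the plasmid role when there are at least two), and gives
#' each strain independent private substitutions at the requested
#' per-site rate. Because substitutions are independent across strains,
#' a column is strain-private exactly when a single strain mutated there;
#' those columns are the diagnostic sites downstream.
#'
#' @param n_strains Number of strains (>= 2).
#' @param genome_length Total aligned length in bp.
#' @param n_contigs Number of contigs the genome is split into.
#' @param divergence Per-site substitution probability per strain, in
#'   \[0, 0.2\].
#' @param mixture,error_rate Passed into the returned [sim_truth()]
#'   (defaults: the skewed founding mixture used throughout the package).
#' @param seed Integer seed; the panel is a pure function of it.
#' @return List with elements `panel` (a [ref_panel()]; focal strain is
#'   the first) and `truth` (a [sim_truth()] whose `private_sites`
#'   element records every strain-private substitution as
#'   `strain`, `contig`, `pos`, `ref`, `alt`).
#' @export
simulate_strain_panel <- function(n_strains = 5, genome_length = 50000,
                                  n_contigs = 3, divergence = 0.01,
                                  mixture = NULL, error_rate = 0.001,
                                  seed = 1L) {
  n_strains <- check_count(n_strains, "n_strains", lower = 2)
  genome_length <- check_count(genome_length, "genome_length", lower = 1)
  n_contigs <- check_count(n_contigs, "n_contigs", lower = 1)
  check_number(divergence, "divergence", 0, 0.2)
  if (genome_length < n_contigs) abort("genome_length must be >= n_contigs")
  if (is.null(mixture)) {
    mixture <- default_mixture(n_strains)
  }
  if (length(mixture) != n_strains) abort("mixture length must equal n_strains")

  strains <- paste0("S", seq_len(n_strains))
  bases <- c("A", "C", "G", "T")
  # contig spans: near-equal split, last contig is the plasmid analogue
  sizes <- rep(genome_length %/% n_contigs, n_contigs)
  sizes[n_contigs] <- sizes[n_contigs] + genome_length %% n_contigs
  roles <- c(rep("chromosomal", max(0, n_contigs - 1)),
             if (n_contigs >= 2) "plasmid" else "chromosomal")
  contigs <- tibble(contig = paste0("ctg", seq_len(n_contigs)),
                    length = as.integer(sizes), role = roles)

  out <- with_seed(derive_seed(seed, "panel"), {
    anc <- sample(bases, genome_length, replace = TRUE)
    seqs <- matrix(rep(anc, n_strains), nrow = n_strains, byrow = TRUE)
    mut_positions <- vector("list", n_strains)
    for (s in seq_len(n_strains)) {
      mut <- which(runif(genome_length) < divergence)
      mut_positions[[s]] <- mut
      if (length(mut)) {
        cur <- seqs[s, mut]
        # substitute with a uniformly chosen different base
        shift <- sample.int(3, length(mut), replace = TRUE)
        seqs[s, mut] <- bases[(match(cur, bases) - 1 + shift) %% 4 + 1]
      }
    }
    list(anc = anc, seqs = seqs, mut = mut_positions)
  })

  # strain-private = exactly one strain mutated the column
  hits <- integer(genome_length)
  for (m in out$mut) hits[m] <- hits[m] + 1L
  offsets <- cumsum(c(0, sizes))[seq_len(n_contigs)]
  to_local <- function(gpos) {
    ci <- findInterval(gpos - 1, cumsum(c(0, sizes)), rightmost.closed = TRUE)
    list(contig = contigs$contig[ci], pos = as.integer(gpos - 1 - offsets[ci]))
  }
  private <- purrr::map(seq_len(n_strains), function(s) {
    p <- out$mut[[s]][hits[out$mut[[s]]] == 1L]
    if (!length(p)) return(NULL)
    loc <- to_local(p)
    tibble(strain = strains[s], contig = loc$contig, pos = loc$pos,
           ref = out$anc[p], alt = out$seqs[s, p])
  })
  private <- dplyr::bind_rows(private)
  if (!nrow(private)) {
    private <- tibble(strain = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character())
  }
  private <- dplyr::arrange(private, .data$contig, .data$pos)

  seq_tbl <- tidyr::expand_grid(strain = strains, contig = contigs$contig)
  seq_tbl$seq <- purrr::map2_chr(seq_tbl$strain, seq_tbl$contig, function(s, ct) {
    i <- match(s, strains); j <- match(ct, contigs$contig)
    paste(out$seqs[i, (offsets[j] + 1):(offsets[j] + sizes[j])], collapse = "")
  })
  panel <- ref_panel(seq_tbl, contigs, focal = strains[1])
  truth <- sim_truth(setNames(mixture, strains), error_rate = error_rate,
                     seed = seed)
  truth$private_sites <- private
  list(panel = panel, truth = truth)
}

# the study's founding mixture shape: one dominant strain, steeply
# skewed minority strains
default_mixture <- function(k) {
  base <- c(0.60, 0.25, 0.10, 0.04, 0.01)
  if (k <= 5) {
    m <- base[seq_len(k)]
  } else {
    m <- c(base, rep(0.01, k - 5))
  }
  m / sum(m)
}

#' Simulate one pooled population sample
#'
#' Produces the summary-level data the pipeline actually consumes: a
#' per-position depth-of-coverage track on the focal reference, a pileup
#' (base counts) at the panel's polymorphic columns, per-read competitive
#' alignment records, and donor-strain depth tracks for planted HGT
#' fragments. Depth is Poisson around `mean_coverage`, multiplied by
#' `1 + carrier_frequency * (copy_number - 1)` inside planted CNVs.
#' Allele counts at each site are multinomial in the mixture-implied base
#' probabilities, perturbed by a symmetric per-base error.
#'
#' @param panel A [ref_panel()].
#' @param truth A [sim_truth()]; its `mixture` names must match the
#'   panel strains and planted intervals must reference panel contigs.
#' @param mean_coverage Expected reads per site (> 0).
#' @param read_length Simulated read length (bp) used for HGT reads.
#' @param n_background_reads Focal-assigned reads included in the
#'   assignment table to mimic the dominant strain's signal.
#' @param misassignment_rate Fraction of background reads that are
#'   spuriously uniquely-best to a random non-focal strain (noise model
#'   for the HGT false-positive analysis).
#' @param overdispersion Optional negative-binomial size parameter; the
#'   default `NULL` keeps pure Poisson coverage noise.
#' @param sample_id Label stored with the sample.
#' @param seed Integer seed (defaults to the truth's seed).
#' @return Object of class `pooled_sample`: list with tibbles `coverage`
#'   (contig, pos, depth), `pileup` (contig, pos, depth, A, C, G, T),
#'   `assignments` (read_id, strain, contig, pos, edit_dist), and
#'   `donor_coverage` (strain, contig, pos, depth), plus the truth.
#' @export
simulate_pooled_sample <- function(panel, truth, mean_coverage = 100,
                                   read_length = 100,
                                   n_background_reads = 200,
                                   misassignment_rate = 0,
                                   overdispersion = NULL,
                                   sample_id = "sample1",
                                   seed = NULL) {
  stopifnot(inherits(panel, "ref_panel"), inherits(truth, "sim_truth"))
  check_number(mean_coverage, "mean_coverage", lower = 1e-9)
  seed <- seed %||% truth$seed
  mix <- truth$mixture
  if (is.null(names(mix))) names(mix) <- panel$strains
  if (!setequal(names(mix), panel$strains)) {
    abort("inconsistent truth: mixture strains do not match the panel")
  }
  if (nrow(truth$cnv) && !all(truth$cnv$contig %in% panel$contigs$contig)) {
    abort("inconsistent truth: planted CNV references an unknown contig")
  }
  if (nrow(truth$hgt) &&
      (!all(truth$hgt$donor %in% panel$strains) ||
       !all(truth$hgt$contig %in% panel$contigs$contig))) {
    abort("inconsistent truth: planted HGT references unknown strain/contig")
  }
  mix <- mix[panel$strains]

  with_seed(derive_seed(seed, "sample", sample_id), {
    # ---- focal coverage track -------------------------------------------
    coverage <- purrr::map2(panel$contigs$contig, panel$contigs$length,
      function(ct, len) {
        lam <- rep(mean_coverage, len)
        cv <- truth$cnv[truth$cnv$contig == ct, ]
        if (nrow(cv)) {
          for (i in seq_len(nrow(cv))) {
            idx <- (cv$start[i] + 1):cv$end[i]
            lam[idx] <- lam[idx] *
              (1 + cv$carrier_frequency[i] * (cv$copy_number[i] - 1))
          }
        }
        depth <- if (is.null(overdispersion)) {
          rpois(len, lam)
        } else {
          stats::rnbinom(len, mu = lam, size = overdispersion)
        }
        tibble(contig = ct, pos = 0:(len - 1), depth = depth)
      }) %>% dplyr::bind_rows()

    # ---- pileup at polymorphic panel columns ----------------------------
    poly <- polymorphic_columns(panel)
    pileup <- if (nrow(poly)) {
      depth <- coverage$depth[match(paste(poly$contig, poly$pos),
                                    paste(coverage$contig, coverage$pos))]
      probs <- site_base_probs(poly, mix, truth$error_rate)
      counts <- rmultinom_rows(depth, probs)
      tibble(contig = poly$contig, pos = poly$pos, depth = depth,
             A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4])
    } else {
      tibble(contig = character(), pos = integer(), depth = integer(),
             A = integer(), C = integer(), G = integer(), T = integer())
    }

    # ---- read assignment records ----------------------------------------
    non_focal <- setdiff(panel$strains, panel$focal)
    mk_reads <- function(n, strain, contig, lo, hi, prefix) {
      if (n == 0) return(NULL)
      pos <- if (hi > lo) sample(lo:hi, n, replace = TRUE) else rep(lo, n)
      ids <- paste0(prefix, seq_len(n))
      purrr::map(panel$strains, function(s) {
        d <- if (s == strain) 0L else 1L + rpois(n, 1)
        tibble(read_id = ids, strain = s, contig = contig,
               pos = pos, edit_dist = as.integer(d))
      }) %>% dplyr::bind_rows()
    }
    focal_chrom <- panel$contigs[panel$contigs$role == "chromosomal", ]
    if (!nrow(focal_chrom)) focal_chrom <- panel$contigs
    n_noise <- rbinom(1, n_background_reads, misassignment_rate)
    n_focal <- n_background_reads - n_noise
    reads <- list(
      mk_reads(n_focal, panel$focal, focal_chrom$contig[1],
               0L, focal_chrom$length[1] - read_length, "bg"),
      if (n_noise > 0) {
        purrr::map(seq_len(n_noise), function(i) {
          s <- sample(non_focal, 1)
          ct <- sample(panel$contigs$contig, 1)
          mk_reads(1, s, ct,
                   0L, panel$contigs$length[match(ct, panel$contigs$contig)] -
                     read_length, paste0("noise", i, "_"))
        }) %>% dplyr::bind_rows()
      }
    )
    if (nrow(truth$hgt)) {
      for (i in seq_len(nrow(truth$hgt))) {
        h <- truth$hgt[i, ]
        n <- rpois(1, h$frequency * mean_coverage *
                     (h$end - h$start) / read_length)
        reads <- c(reads, list(
          mk_reads(n, h$donor, h$contig, h$start,
                   max(h$start, h$end - read_length), paste0("hgt", i, "_"))
        ))
      }
    }
    assignments <- dplyr::bind_rows(reads)
    if (!nrow(assignments)) {
      assignments <- tibble(read_id = character(), strain = character(),
                            contig = character(), pos = integer(),
                            edit_dist = integer())
    }

    # ---- donor-assigned depth tracks ------------------------------------
    assigned <- assign_reads(assignments, panel$focal)
    donor_coverage <- purrr::map(non_focal, function(s) {
      rd <- assigned[assigned$assigned_strain == s, ]
      if (!nrow(rd)) return(NULL)
      purrr::map(unique(rd$contig), function(ct) {
        len <- panel$contigs$length[match(ct, panel$contigs$contig)]
        depth <- depth_from_reads(rd$pos[rd$contig == ct], read_length, len)
        covered <- which(depth > 0)
        tibble(strain = s, contig = ct, pos = covered - 1L,
               depth = depth[covered])
      }) %>% dplyr::bind_rows()
    }) %>% dplyr::bind_rows()
    if (!nrow(donor_coverage)) {
      donor_coverage <- tibble(strain = character(), contig = character(),
                               pos = integer(), depth = integer())
    }

    structure(
      list(sample_id = sample_id, coverage = coverage, pileup = pileup,
           assignments = assignments, donor_coverage = donor_coverage,
           truth = truth, mean_coverage = mean_coverage,
           read_length = read_length),
      class = "pooled_sample"
    )
  })
}

#' @export
print.pooled_sample <- function(x, ...) {
  cat(sprintf("<pooled_sample> '%s': %d positions, %d pileup sites, %d reads\n",
              x$sample_id, nrow(x$coverage), nrow(x$pileup),
              dplyr::n_distinct(x$assignments$read_id)))
  invisible(x)
}

# alignment columns with >= 2 alleles across strains (gap/N columns kept;
# they simply never become diagnostic)
polymorphic_columns <- function(panel) {
  purrr::map(panel$contigs$contig, function(ct) {
    m <- contig_matrix(panel, ct)
    poly <- which(apply(m, 2, function(col) length(unique(col)) > 1))
    if (!length(poly)) return(NULL)
    tibble(contig = ct, pos = poly - 1L,
           bases = lapply(poly, function(j) m[, j]))
  }) %>% dplyr::bind_rows()
}

# per-site observed base probabilities: mixture-weighted truth, then a
# symmetric substitution error e (observed b = true b w.p. 1-e, else
# uniform among the other three)
site_base_probs <- function(poly, mix, error_rate) {
  bases <- c("A", "C", "G", "T")
  probs <- t(vapply(poly$bases, function(bs) {
    p <- vapply(bases, function(b) sum(mix[bs == b]), numeric(1))
    p / max(sum(p), 1e-300)
  }, numeric(4)))
  e <- error_rate
  probs * (1 - e) + (1 - probs) * e / 3
}

# one multinomial draw per row, via sequential binomials (vectorised)
rmultinom_rows <- function(size, probs) {
  n <- length(size)
  out <- matrix(0L, n, 4)
  remaining <- size
  pleft <- rowSums(probs)
  for (j in 1:3) {
    pj <- ifelse(pleft > 0, pmin(1, probs[, j] / pleft), 0)
    out[, j] <- rbinom(n, remaining, pj)
    remaining <- remaining - out[, j]
    pleft <- pleft - probs[, j]
  }
  out[, 4] <- remaining
  out
}

# depth track from read start positions (0-based) of fixed length
depth_from_reads <- function(starts, read_length, contig_length) {
  delta <- numeric(contig_length + 1)
  s <- pmin(pmax(starts, 0), contig_length - 1)
  e <- pmin(s + read_length, contig_length)
  for (i in seq_along(s)) {
    delta[s[i] + 1] <- delta[s[i] + 1] + 1
    delta[e[i] + 1] <- delta[e[i] + 1] - 1
  }
  cumsum(delta)[seq_len(contig_length)]
}

#' Simulate a multi-sample coverage matrix with planted CNVs
#'
#' Generates the across-sample depth matrix the CNV detector consumes.
#' All samples share one position-specific coverage bias (a lognormal
#' site effect with mean 1, emulating the mappability and composition
#' biases that real libraries share), and each sample adds independent
#' Poisson noise around it. Planted duplications multiply expected
#' depth by `1 + carrier_frequency * (copy_number - 1)` in their
#' carrier samples only, so an event perturbs the coverage ranks of
#' carriers relative to non-carriers while leaving non-carriers on the
#' shared bias.
#'
#' @param truth A [sim_truth()] whose `cnv` table may include a
#'   `carrier_samples` list-column of sample indices (default all).
#' @param n_samples Number of pooled samples (columns).
#' @param contigs Tibble `contig`, `length`, `role`; default one 100-kb
#'   chromosomal contig.
#' @param mean_coverage Expected depth per site.
#' @param site_sd Log-scale SD of the shared per-position bias
#'   (0 gives pure Poisson coverage; default 0.3).
#' @param seed Integer seed.
#' @return Wide tibble: `contig`, `pos`, then one integer depth column
#'   per sample (`s1`, `s2`, ...), with the contig table as attribute
#'   `"contigs"`.
#' @export
simulate_coverage_matrix <- function(truth, n_samples = 10,
                                     contigs = NULL, mean_coverage = 100,
                                     site_sd = 0.3, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  n_samples <- check_count(n_samples, "n_samples", lower = 1)
  if (is.null(contigs)) {
    contigs <- tibble(contig = "ctg1", length = 100000L, role = "chromosomal")
  }
  cnv <- truth$cnv
  if (nrow(cnv) && is.null(cnv$carrier_samples)) {
    cnv$carrier_samples <- rep(list(seq_len(n_samples)), nrow(cnv))
  }
  with_seed(derive_seed(seed, "covmat"), {
    blocks <- purrr::map2(contigs$contig, contigs$length, function(ct, len) {
      prof <- if (site_sd > 0) {
        # mean-1 lognormal site effect shared by all samples
        exp(rnorm(len, -site_sd^2 / 2, site_sd))
      } else rep(1, len)
      base_lam <- mean_coverage * prof
      cols <- purrr::map(seq_len(n_samples), function(j) {
        lam <- base_lam
        cv <- cnv[cnv$contig == ct, ]
        if (nrow(cv)) {
          for (i in seq_len(nrow(cv))) {
            if (j %in% cv$carrier_samples[[i]]) {
              idx <- (cv$start[i] + 1):cv$end[i]
              lam[idx] <- lam[idx] *
                (1 + cv$carrier_frequency[i] * (cv$copy_number[i] - 1))
            }
          }
        }
        rpois(len, lam)
      })
      names(cols) <- paste0("s", seq_len(n_samples))
      dplyr::bind_cols(tibble(contig = ct, pos = 0:(len - 1)), cols)
    })
    out <- dplyr::bind_rows(blocks)
    attr(out, "contigs") <- contigs
    out
  })
}

#' Simulate a window of haplotypes under the infinite-sites model
#'
#' Places mutations independently per site: a site segregates with
#' probability `theta_per_site * a1(n)` (so the expected number of
#' segregating sites matches Watterson's expectation), the derived-allele
#' count is drawn from the neutral site-frequency spectrum
#' (P(i) proportional to 1/i), and carriers are chosen uniformly. The
#' full haplotype matrix is returned so exact pairwise-difference oracles
#' can be computed alongside the pooled summary.
#'
#' @param n_haplotypes Number of haplotypes (>= 2).
#' @param length Window length in bp.
#' @param theta_per_site Expected diversity per site.
#' @param coverage If `NULL`, pooled counts are noise-free (depth = n,
#'   count = derived-allele count); otherwise per-site depth is
#'   Poisson(`coverage`) and counts are binomial in the true frequency.
#' @param seed Integer seed.
#' @return List: `haplotypes` (n x S 0/1 matrix), `positions` (0-based
#'   site positions), `sites` (tibble `contig`, `pos`, `coverage`,
#'   `freq`), `length`.
#' @export
simulate_haplotype_window <- function(n_haplotypes = 10, length = 5000,
                                      theta_per_site = 0.005,
                                      coverage = NULL, seed = 1L) {
  n <- check_count(n_haplotypes, "n_haplotypes", lower = 2)
  length <- check_count(length, "length", lower = 1)
  check_number(theta_per_site, "theta_per_site", 0, 1)
  with_seed(derive_seed(seed, "hapwin"), {
    a1 <- sum(1 / seq_len(n - 1))
    seg <- which(runif(length) < theta_per_site * a1)
    S <- base::length(seg)
    sfs <- (1 / seq_len(n - 1)) / a1
    counts <- if (S) sample(seq_len(n - 1), S, replace = TRUE, prob = sfs) else integer()
    hap <- matrix(0L, n, S)
    for (j in seq_len(S)) {
      hap[sample.int(n, counts[j]), j] <- 1L
    }
    if (is.null(coverage)) {
      depth <- rep(n, S)
      alt <- counts
    } else {
      depth <- rpois(S, coverage)
      alt <- rbinom(S, depth, counts / n)
    }
    sites <- tibble(contig = "win", pos = as.integer(seg - 1),
                    coverage = as.integer(depth),
                    freq = ifelse(depth > 0, alt / depth, NA_real_))
    list(haplotypes = hap, positions = as.integer(seg - 1),
         sites = sites, length = length)
  })
}
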