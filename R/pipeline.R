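#' Pipeline configuration
#'
#' A nested list mirroring the stages; unknown keys are rejected so
#' typos cannot silently fall back to defaults. All thresholds carry
#' the package defaults (MAF 0.05, window 10 kb / step 5 kb, merge gap
#' 100 bp, HGT minimum length 1 kb, treatment-variance screen 0.04,
#' FDR 0.05).
#'
#' @param path YAML file path.
#' @return Validated config list (class `poolcoev_config`).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "panel", "strainfreq", "cnv", "hgt", "popgen"),
    simulate = list(
      n_strains = 5L, genome_length = 50000L, n_contigs = 3L,
      divergence = 0.01, mixture = NULL, error_rate = 0.001,
      mean_coverage = 100, n_samples = 3L, cnv = NULL, hgt = NULL
    ),
    strainfreq = list(min_depth = 10, min_sites = 20),
    filter = list(low = 0.02, high = 0.98, alpha = 0.05, maf = 0.05),
    cnv = list(rho = 1, band = c(0.1, 0.9), max_gap = 100),
    hgt = list(min_length = 1000, max_gap = 100, min_depth = 1),
    popgen = list(window = 10000L, step = 5000L, maf = 0.05),
    associate = list(fdr = 0.05, variance_screen = 0.04, phenotypes = NULL),
    blacklist = NULL
  )
}

#' @rdname read_config
#' @param cfg A raw config list (e.g. parsed from YAML).
#' @export
validate_config <- function(cfg) {
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (k in names(cfg)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      bad <- setdiff(names(cfg[[k]]), names(def[[k]]))
      if (length(bad)) {
        abort(sprintf("unknown config key(s) under '%s': %s", k,
                      paste(bad, collapse = ", ")))
      }
      def[[k]][names(cfg[[k]])] <- cfg[[k]]
    } else {
      def[[k]] <- cfg[[k]]
    }
  }
  ranges <- list(
    c("filter", "maf", 0, 1), c("filter", "alpha", 0, 1),
    c("filter", "low", 0, 1), c("filter", "high", 0, 1),
    c("popgen", "maf", 0, 1), c("cnv", "rho", 0, Inf),
    c("hgt", "min_length", 1, Inf), c("associate", "fdr", 0, 1),
    c("associate", "variance_screen", 0, Inf)
  )
  for (r in ranges) {
    v <- def[[r[1]]][[r[2]]]
    check_number(v, paste(r[1], r[2], sep = "."),
                 as.numeric(r[3]), as.numeric(r[4]))
  }
  structure(def, class = c("poolcoev_config", "list"))
}

config_hash <- function(cfg) {
  fnv1a_hex(paste(deparse(unclass(cfg)), collapse = ""))
}

planted_tibble <- function(x, cols) {
  if (is.null(x)) return(NULL)
  rows <- purrr::map(x, function(e) {
    cs <- e$carrier_samples
    e$carrier_samples <- NULL
    tb <- as_tibble(e[cols[cols %in% names(e)]])
    tb$carrier_samples <- list(cs)
    tb
  })
  dplyr::bind_rows(rows)
}

#' Run the pooled-population genomics pipeline
#'
#' Chains simulate, panel, strain composition, CNV, HGT and
#' population-genetic windows on synthetic data, writing every artifact
#' as TSV/BED/FASTA stamped with the package version, a hash of the
#' config, and the seed. Reruns with the same config and seed reproduce
#' all outputs bit-identically (only the run log carries a timestamp).
#'
#' @param config A config list from [read_config()] /
#'   [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   run log.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "poolcoev_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  prov <- sprintf("poolcoev %s | config %s | seed %d",
                  as.character(utils::packageVersion("poolcoev")),
                  config_hash(config), seed)
  log <- list(tool = "poolcoev",
              version = as.character(utils::packageVersion("poolcoev")),
              config_hash = config_hash(config), seed = seed, stages = list())
  res <- list()
  stages <- config$stages

  # ---- simulate --------------------------------------------------------
  sim_cfg <- config$simulate
  cnv_tbl <- planted_tibble(sim_cfg$cnv,
                            c("contig", "start", "end", "copy_number",
                              "carrier_frequency"))
  hgt_tbl <- planted_tibble(sim_cfg$hgt,
                            c("donor", "contig", "start", "end", "frequency"))
  sp <- simulate_strain_panel(
    n_strains = sim_cfg$n_strains, genome_length = sim_cfg$genome_length,
    n_contigs = sim_cfg$n_contigs, divergence = sim_cfg$divergence,
    mixture = unlist(sim_cfg$mixture), error_rate = sim_cfg$error_rate,
    seed = seed)
  panel <- sp$panel
  n_samples <- sim_cfg$n_samples
  samples <- purrr::map(seq_len(n_samples), function(j) {
    pick <- function(tb) {
      if (is.null(tb)) return(NULL)
      keep <- purrr::map_lgl(tb$carrier_samples,
                             function(cs) is.null(cs) || j %in% cs)
      out <- tb[keep, setdiff(names(tb), "carrier_samples")]
      if (nrow(out)) out else NULL
    }
    truth_j <- sim_truth(sp$truth$mixture, cnv = pick(cnv_tbl),
                         hgt = pick(hgt_tbl),
                         error_rate = sim_cfg$error_rate, seed = seed)
    simulate_pooled_sample(panel, truth_j,
                           mean_coverage = sim_cfg$mean_coverage,
                           sample_id = paste0("pop", j), seed = seed)
  })
  if ("simulate" %in% stages) {
    write_panel(panel, file.path(out_dir, "panel.fasta"),
                file.path(out_dir, "contigs.tsv"))
    for (s in samples) {
      pc_write_tsv(s$pileup,
                   file.path(out_dir, paste0("pileup_", s$sample_id, ".tsv")),
                   prov)
    }
    log$stages$simulate <- list(n_samples = n_samples,
                                genome_length = sim_cfg$genome_length)
  }
  res$panel <- panel
  res$samples <- samples

  # ---- panel: metareference + diagnostic sites -------------------------
  sites <- find_diagnostic_sites(panel)
  if ("panel" %in% stages) {
    meta <- build_metareference(panel)
    write_fasta(tibble(name = paste0("meta_", meta$contig), seq = meta$seq),
                file.path(out_dir, "metareference.fasta"))
    pc_write_tsv(sites, file.path(out_dir, "diagnostic_sites.tsv"), prov)
    log$stages$panel <- list(n_diagnostic_sites = nrow(sites))
  }
  res$sites <- sites

  # ---- strain composition ---------------------------------------------
  if ("strainfreq" %in% stages) {
    profiles <- purrr::map_dfr(samples, function(s) {
      pr <- suppressWarnings(
        strain_composition(s$pileup, sites,
                           min_depth = config$strainfreq$min_depth,
                           min_sites = config$strainfreq$min_sites))
      tibble(sample = s$sample_id, strain = pr$strain,
             estimate = pr$estimate, n_sites = pr$n_sites,
             residual = attr(pr, "residual"))
    })
    pc_write_tsv(profiles, file.path(out_dir, "strain_composition.tsv"), prov)
    log$stages$strainfreq <- list(n_rows = nrow(profiles))
    res$profiles <- profiles
  }

  # ---- CNV -------------------------------------------------------------
  if ("cnv" %in% stages) {
    depths <- samples[[1]]$coverage[, c("contig", "pos")]
    for (s in samples) depths[[s$sample_id]] <- s$coverage$depth
    calls <- detect_cnv(depths, contigs = panel$contigs,
                        band = unlist(config$cnv$band), rho = config$cnv$rho,
                        max_gap = config$cnv$max_gap)
    if (nrow(calls)) {
      write_bed(calls[, c("contig", "start", "end")],
                file.path(out_dir, "cnv.bed"), prov)
      cn <- tidyr::unnest(calls[, c("contig", "start", "end", "copy_number")],
                          "copy_number")
      pc_write_tsv(cn, file.path(out_dir, "cnv_copy_number.tsv"), prov)
    } else {
      pc_write_tsv(tibble(contig = character(), start = integer(),
                          end = integer()),
                   file.path(out_dir, "cnv.bed"), prov)
    }
    log$stages$cnv <- list(n_regions = nrow(calls))
    res$cnv <- calls
  }

  # ---- HGT -------------------------------------------------------------
  if ("hgt" %in% stages) {
    frags <- purrr::map_dfr(samples, function(s) {
      assigned <- assign_reads(s$assignments, panel$focal)
      purrr::map_dfr(setdiff(panel$strains, panel$focal), function(d) {
        track <- nonfocal_coverage(assigned, d, panel$contigs,
                                   read_length = s$read_length)
        fr <- call_fragments(track, min_length = config$hgt$min_length,
                             max_gap = config$hgt$max_gap,
                             min_depth = config$hgt$min_depth, donor = d)
        if (!nrow(fr)) return(NULL)
        fr <- fragment_frequency(fr, track, s$coverage, panel$contigs)
        fr$sample <- s$sample_id
        fr
      })
    })
    pc_write_tsv(frags, file.path(out_dir, "hgt_fragments.tsv"), prov)
    log$stages$hgt <- list(n_fragments = nrow(frags))
    res$hgt <- frags
  }

  # ---- popgen ----------------------------------------------------------
  if ("popgen" %in% stages) {
    wins <- purrr::map_dfr(samples, function(s) {
      pu <- s$pileup
      if (!nrow(pu)) return(NULL)
      cnts <- as.matrix(pu[, c("A", "C", "G", "T")])
      minor <- ifelse(pu$depth > 0, 1 - apply(cnts, 1, max) / pu$depth, NA)
      st <- tibble(contig = pu$contig, pos = pu$pos,
                   coverage = pu$depth, freq = minor)
      w <- sliding_windows(st, window = config$popgen$window,
                           step = config$popgen$step,
                           maf = config$popgen$maf,
                           contig_lengths = panel$contigs)
      w$sample <- s$sample_id
      w
    })
    pc_write_tsv(wins, file.path(out_dir, "popgen_windows.tsv"), prov)
    log$stages$popgen <- list(n_windows = nrow(wins))
    res$popgen <- wins
  }

  log$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  res$log <- log
  invisible(res)
}
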