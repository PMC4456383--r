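#' Horizontal gene transfer detection by competitive mapping
#'
#' In a population dominated by the focal strain, reads that map
#' uniquely and best to a *non-focal* reference genome betray imported
#' DNA. Runs of donor-assigned coverage at least 1 kb long are called as
#' putative HGT fragments, and their within-population frequency is the
#' ratio of the fragment's median donor-assigned depth to the median
#' depth over the focal strain's chromosomal contigs.
#'
#' @name hgt_detection
NULL

#' Depth of uniquely-best donor-assigned reads
#'
#' @param assignments Tibble from [assign_reads()] (columns
#'   `read_id`, `assigned_strain`, `contig`, `pos`); ties are already
#'   `"excluded"` there and contribute to no track.
#' @param donor Donor strain label.
#' @param contigs Tibble `contig`, `length` covering the donor
#'   coordinates.
#' @param read_length Read length in bp used to extend each start
#'   position.
#' @return Tibble `contig`, `pos`, `depth` with every position of the
#'   donor contigs that has positive depth.
#' @export
nonfocal_coverage <- function(assignments, donor, contigs,
                              read_length = 100) {
  check_columns(assignments, c("read_id", "assigned_strain", "contig", "pos"),
                "assignments")
  check_columns(contigs, c("contig", "length"), "contigs")
  rd <- assignments[assignments$assigned_strain == donor &
                      !is.na(assignments$pos), ]
  out <- purrr::map(unique(rd$contig), function(ct) {
    len <- contigs$length[match(ct, contigs$contig)]
    if (is.na(len)) abort(sprintf("contig '%s' missing from `contigs`", ct))
    depth <- depth_from_reads(rd$pos[rd$contig == ct], read_length, len)
    covered <- which(depth > 0)
    if (!length(covered)) return(NULL)
    tibble(contig = ct, pos = covered - 1L, depth = depth[covered])
  }) %>% dplyr::bind_rows()
  if (!nrow(out)) {
    out <- tibble(contig = character(), pos = integer(), depth = integer())
  }
  out
}

#' Call HGT fragments from a donor depth track
#'
#' Maximal runs of positions with depth >= `min_depth`, allowing
#' internal uncovered gaps up to `max_gap` bp, retained only when the
#' run spans at least `min_length` bp. "Continuous" donor evidence is
#' thus read with the same 100-bp tolerance the CNV merge uses, since
#' read sampling at low fragment frequency leaves short gaps.
#'
#' @param track Tibble `contig`, `pos`, `depth` (positions with zero
#'   depth may be present or absent — both are treated as uncovered).
#' @param min_length Minimum fragment span in bp (default 1000).
#' @param max_gap Maximum internal uncovered gap in bp (default 100).
#' @param min_depth Minimum depth for a position to count as covered.
#' @param donor Optional donor label copied onto the output.
#' @return Tibble (class `hgt_fragments`): `donor`, `contig`, `start`,
#'   `end` (0-based half-open), `n_covered`.
#' @export
call_fragments <- function(track, min_length = 1000, max_gap = 100,
                           min_depth = 1, donor = NA_character_) {
  check_columns(track, c("contig", "pos", "depth"), "track")
  covered <- track[track$depth >= min_depth, ]
  if (!nrow(covered)) {
    return(structure(tibble(donor = character(), contig = character(),
                            start = integer(), end = integer(),
                            n_covered = integer()),
                     class = c("hgt_fragments", "tbl_df", "tbl", "data.frame")))
  }
  runs <- covered %>%
    arrange(.data$contig, .data$pos) %>%
    group_by(.data$contig) %>%
    mutate(.grp = cumsum(c(1, diff(.data$pos) > max_gap + 1))) %>%
    group_by(.data$contig, .data$.grp) %>%
    summarise(start = min(.data$pos), end = max(.data$pos) + 1L,
              n_covered = dplyr::n(), .groups = "drop") %>%
    filter(.data$end - .data$start >= min_length) %>%
    mutate(donor = donor) %>%
    select("donor", "contig", "start", "end", "n_covered")
  structure(runs, class = c("hgt_fragments", class(runs)))
}

#' Within-population frequency of an HGT fragment
#'
#' @param fragments Tibble `contig`, `start`, `end` (donor coordinates).
#' @param donor_track Donor-assigned depth track (`contig`, `pos`,
#'   `depth`); positions absent from the track count as depth 0.
#' @param focal_coverage Focal-reference depth track (`contig`, `pos`,
#'   `depth`) for the same sample.
#' @param contigs Tibble `contig`, `role` for the focal reference.
#' @return Input fragments with columns `median_depth` and `frequency`
#'   added. Frequencies above 1 are possible (multicopy transferred
#'   elements) and are not clipped.
#' @export
fragment_frequency <- function(fragments, donor_track, focal_coverage,
                               contigs) {
  check_columns(fragments, c("contig", "start", "end"), "fragments")
  check_columns(contigs, c("contig", "role"), "contigs")
  chrom <- focal_coverage$contig %in%
    contigs$contig[contigs$role == "chromosomal"]
  if (!any(chrom)) abort("no chromosomal-role positions in `focal_coverage`")
  denom <- median(focal_coverage$depth[chrom])
  if (denom == 0) abort("undefined ratio: zero median chromosomal depth")
  med <- purrr::pmap_dbl(fragments[, c("contig", "start", "end")],
    function(contig, start, end) {
      d <- numeric(end - start)  # implicit zeros for uncovered positions
      hit <- donor_track$contig == contig &
        donor_track$pos >= start & donor_track$pos < end
      d[donor_track$pos[hit] - start + 1] <- donor_track$depth[hit]
      median(d)
    })
  fragments$median_depth <- med
  fragments$frequency <- med / denom
  fragments
}

#' Treatment-variance screen for HGT fragments
#'
#' A transferred region is only a coevolution candidate when its
#' frequency differs among treatments: the variance of the
#' per-treatment mean frequencies must strictly exceed `threshold`.
#'
#' @param frequencies Tibble with columns `treatment` and `frequency`
#'   (one row per population sample).
#' @param threshold Variance threshold (default 0.04).
#' @return One-row tibble: `treatment_variance`, `flagged`.
#' @export
treatment_variance_screen <- function(frequencies, threshold = 0.04) {
  check_columns(frequencies, c("treatment", "frequency"), "frequencies")
  means <- tapply(frequencies$frequency, frequencies$treatment, mean)
  if (length(means) < 2) abort("need at least 2 treatment groups")
  v <- var(as.numeric(means))
  tibble(treatment_variance = v, flagged = v > threshold)
}
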