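#' Construct a reference strain panel
#'
#' A reference panel holds a multiple alignment of the founding strain
#' genomes, split per contig, together with contig roles (chromosomal or
#' plasmid) and the focal strain that dominates the evolved populations.
#' All downstream coordinates are 0-based half-open, per contig.
#'
#' @param sequences Tibble with columns `strain`, `contig`, `seq`: one
#'   aligned sequence (A/C/G/T/N/`-`) per strain per contig. Within a
#'   contig all strains must have equal-length sequences.
#' @param contigs Tibble with columns `contig`, `length`, `role`; `role`
#'   is `"chromosomal"` or `"plasmid"`.
#' @param focal Label of the focal strain (must appear in `sequences`).
#'
#' @return An object of class `ref_panel`: a list with elements
#'   `sequences`, `contigs`, `strains`, `focal`.
#' @export
ref_panel <- function(sequences, contigs, focal) {
  check_columns(sequences, c("strain", "contig", "seq"), "sequences")
  check_columns(contigs, c("contig", "length", "role"), "contigs")
  sequences <- as_tibble(sequences)
  contigs <- as_tibble(contigs)
  strains <- unique(sequences$strain)
  if (length(strains) < 1) abort("panel needs at least one strain")
  if (!focal %in% strains) abort("`focal` is not a strain in the panel")
  if (!all(contigs$role %in% c("chromosomal", "plasmid"))) {
    abort("contig roles must be 'chromosomal' or 'plasmid'")
  }
  if (anyDuplicated(contigs$contig)) abort("duplicated contig ids")
  bad_chars <- grepl("[^ACGTNRYSWKMBDHV-]", sequences$seq)
  if (any(bad_chars)) {
    abort("invalid alphabet: sequences may contain only IUPAC nucleotide codes and -")
  }
  # every strain must carry every contig, at the declared aligned length
  for (ct in contigs$contig) {
    rows <- sequences[sequences$contig == ct, ]
    if (!setequal(rows$strain, strains)) {
      abort(sprintf("contig '%s' is missing for some strains", ct))
    }
    len <- unique(nchar(rows$seq))
    if (length(len) != 1) {
      abort(sprintf("aligned sequences for contig '%s' differ in length", ct))
    }
    if (len != contigs$length[contigs$contig == ct]) {
      abort(sprintf("contig '%s': declared length disagrees with sequences", ct))
    }
  }
  structure(
    list(sequences = sequences, contigs = contigs,
         strains = strains, focal = focal),
    class = "ref_panel"
  )
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d strains, %d contigs, %s bp aligned (focal: %s)\n",
              length(x$strains), nrow(x$contigs),
              format(sum(x$contigs$length), big.mark = ","), x$focal))
  invisible(x)
}

# character matrix (strains x positions) for one contig, rows in panel
# strain order
contig_matrix <- function(panel, contig) {
  rows <- panel$sequences[panel$sequences$contig == contig, ]
  rows <- rows[match(panel$strains, rows$strain), ]
  do.call(rbind, strsplit(rows$seq, "", fixed = TRUE))
}

# IUPAC code for every subset of {A,C,G,T}, keyed by bitmask A=1 C=2 G=4 T=8
iupac_codes <- c(
  "", "A", "C", "M", "G", "R", "S", "V",
  "T", "W", "Y", "H", "K", "D", "B", "N"
)
# inverse map: IUPAC character -> base bitmask ('-' carries no bases)
iupac_masks <- setNames(c(seq_along(iupac_codes[-1]), 0),
                        c(iupac_codes[-1], "-"))

#' Collapse a strain panel into an IUPAC metareference
#'
#' Each alignment column is replaced by the IUPAC ambiguity code for the
#' set of bases observed across strains, so that reads from any founding
#' strain can be mapped without strain variants counting as mismatches.
#' Gaps are dropped from the union (indel columns are kept without gaps);
#' a column containing `N` in any strain emits `N`; columns that are gap
#' in every strain are removed.
#'
#' @param panel A [ref_panel()].
#' @return Tibble with columns `contig`, `seq` — one consensus sequence
#'   per contig.
#' @export
build_metareference <- function(panel) {
  stopifnot(inherits(panel, "ref_panel"))
  out <- purrr::map_chr(panel$contigs$contig, function(ct) {
    m <- contig_matrix(panel, ct)
    # bitwise union of the base sets encoded by each strain's character
    masks <- matrix(iupac_masks[m], nrow = nrow(m))
    mask <- rep(0L, ncol(m))
    for (i in seq_len(nrow(masks))) mask <- bitwOr(mask, masks[i, ])
    code <- iupac_codes[mask + 1]
    paste(code[mask > 0], collapse = "")  # all-gap columns dropped
  })
  tibble(contig = panel$contigs$contig, seq = out)
}

#' Find strain-diagnostic polymorphic sites
#'
#' A diagnostic site is an alignment column where exactly one strain
#' carries a substitution and all other strains share one background
#' allele — so the read frequency of the diagnostic allele in a pooled
#' sample directly estimates that strain's abundance. Columns containing
#' gaps or `N`, and columns with more than two alleles, are excluded.
#'
#' @param panel A [ref_panel()].
#' @return Tibble (class `diagnostic_sites`) with columns `contig`,
#'   `pos` (0-based), `strain`, `allele`, `background`, sorted by
#'   (contig, pos).
#' @export
find_diagnostic_sites <- function(panel) {
  stopifnot(inherits(panel, "ref_panel"))
  k <- length(panel$strains)
  if (k < 2) {
    return(tibble(contig = character(), pos = integer(),
                  strain = character(), allele = character(),
                  background = character()))
  }
  res <- purrr::map(panel$contigs$contig, function(ct) {
    m <- contig_matrix(panel, ct)
    cnt <- rbind(A = colSums(m == "A"), C = colSums(m == "C"),
                 G = colSums(m == "G"), T = colSums(m == "T"))
    clean <- colSums(cnt) == k            # no gap, no N anywhere
    n_alleles <- colSums(cnt > 0)
    minor_is_one <- colSums(cnt == 1) >= 1 & colSums(cnt == k - 1) >= 1
    keep <- which(clean & n_alleles == 2 & minor_is_one)
    if (!length(keep)) return(NULL)
    bases <- rownames(cnt)
    allele <- bases[apply(cnt[, keep, drop = FALSE] == 1, 2, which.max)]
    background <- bases[apply(cnt[, keep, drop = FALSE] == k - 1, 2, which.max)]
    strain <- panel$strains[
      mapply(function(j, b) which(m[, j] == b), keep, allele)
    ]
    tibble(contig = ct, pos = keep - 1L, strain = strain,
           allele = allele, background = background)
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    out <- tibble(contig = character(), pos = integer(),
                  strain = character(), allele = character(),
                  background = character())
  }
  dplyr::arrange(out, .data$contig, .data$pos)
}

#' Competitively assign reads to their best-matching strain
#'
#' Each read is aligned to every strain genome; the edit distance (the
#' SAM `NM` count of mismatches plus indels) is compared across strains
#' and the read is assigned to a strain only when that strain's distance
#' is strictly lower than every other strain's. Reads tying for the best
#' distance are `"excluded"`: they carry no strain information. Missing
#' alignments (unmapped to a given strain) are treated as infinitely
#' distant.
#'
#' @param alignments Tibble with columns `read_id`, `strain`,
#'   `edit_dist`, and optionally `contig`, `pos` (position of the read on
#'   that strain's reference).
#' @param focal Focal strain label; must occur in the panel of strains
#'   seen in `alignments`.
#' @return Tibble with one row per read: `read_id`, `assigned_strain`
#'   (a strain label or `"excluded"`), `edit_dist`, and `contig`/`pos`
#'   of the winning alignment when present in the input.
#' @export
assign_reads <- function(alignments, focal) {
  check_columns(alignments, c("read_id", "strain", "edit_dist"), "alignments")
  strains <- unique(alignments$strain)
  if (!focal %in% strains) abort(sprintf("unknown focal strain '%s'", focal))
  has_pos <- all(c("contig", "pos") %in% names(alignments))
  al <- alignments %>%
    filter(!is.na(.data$edit_dist)) %>%
    group_by(.data$read_id) %>%
    mutate(.best = min(.data$edit_dist),
           .n_best = sum(.data$edit_dist == .data$.best)) %>%
    ungroup()
  winners <- al %>%
    filter(.data$edit_dist == .data$.best) %>%
    mutate(assigned_strain = ifelse(.data$.n_best == 1L,
                                    .data$strain, "excluded")) %>%
    distinct(.data$read_id, .keep_all = TRUE)
  cols <- c("read_id", "assigned_strain", "edit_dist",
            if (has_pos) c("contig", "pos"))
  out <- winners[, cols]
  out$edit_dist[out$assigned_strain == "excluded"] <- NA_integer_
  if (has_pos) {
    out$contig[out$assigned_strain == "excluded"] <- NA_character_
    out$pos[out$assigned_strain == "excluded"] <- NA_integer_
  }
  out
}
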