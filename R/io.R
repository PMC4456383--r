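#' File formats
#'
#' Readers and writers for the plain formats the pipeline touches.
#' Coordinates are 0-based half-open internally; BED output keeps that
#' convention, VCF output converts to 1-based. Every TSV writer can
#' prepend `#`-prefixed provenance lines, which every TSV reader skips.
#'
#' @name io
NULL

pc_write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  # drop list-columns (not representable in TSV)
  df <- df[!vapply(df, is.list, logical(1))]
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(x) {
      if (is.numeric(x)) format(x, digits = 15, trim = TRUE, scientific = FALSE)
      else as.character(x)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

pc_read_tsv <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types %||%
                    readr::cols(), progress = FALSE)
}

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings: sequences come back as a tibble of
#' `name`, `seq`; wrapped and unwrapped line widths parse identically.
#'
#' @param path File path.
#' @return `read_fasta()`: tibble `name`, `seq`. `write_fasta()`: the
#'   path, invisibly.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA I/O")
  }
  x <- Biostrings::readBStringSet(path)
  tibble(name = names(x), seq = unname(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs Tibble with columns `name`, `seq`.
#' @param width Line-wrap width (default 80).
#' @export
write_fasta <- function(seqs, path, width = 80) {
  check_columns(seqs, c("name", "seq"), "seqs")
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA I/O")
  }
  x <- Biostrings::BStringSet(setNames(seqs$seq, seqs$name))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write a strain panel as aligned FASTA plus a contig table
#'
#' One FASTA record per strain (contigs concatenated in contig-table
#' order) and a TSV of contig spans in alignment coordinates.
#'
#' @param panel A [ref_panel()].
#' @param fasta_path,contigs_path Output paths.
#' @export
write_panel <- function(panel, fasta_path, contigs_path) {
  stopifnot(inherits(panel, "ref_panel"))
  seqs <- purrr::map_chr(panel$strains, function(s) {
    paste(purrr::map_chr(panel$contigs$contig, function(ct) {
      panel$sequences$seq[panel$sequences$strain == s &
                            panel$sequences$contig == ct]
    }), collapse = "")
  })
  write_fasta(tibble(name = panel$strains, seq = seqs), fasta_path)
  spans <- panel$contigs
  spans$start <- cumsum(c(0L, spans$length))[seq_len(nrow(spans))]
  spans$end <- spans$start + spans$length
  pc_write_tsv(spans[, c("contig", "start", "end", "length", "role")],
               contigs_path)
  invisible(fasta_path)
}

#' @rdname write_panel
#' @param focal Focal strain label.
#' @return `read_panel()`: a [ref_panel()].
#' @export
read_panel <- function(fasta_path, contigs_path, focal) {
  fa <- read_fasta(fasta_path)
  spans <- pc_read_tsv(contigs_path)
  check_columns(spans, c("contig", "start", "end", "role"), "contigs file")
  seq_tbl <- purrr::pmap_dfr(
    spans[, c("contig", "start", "end")],
    function(contig, start, end) {
      tibble(strain = fa$name, contig = contig,
             seq = substr(fa$seq, start + 1, end))
    })
  contigs <- tibble(contig = spans$contig,
                    length = as.integer(spans$end - spans$start),
                    role = spans$role)
  ref_panel(seq_tbl, contigs, focal = focal)
}

#' Read competitive-alignment summaries
#'
#' Per-read, per-strain edit distances, either from a TSV with columns
#' `read_id`, `strain`, `contig`, `pos`, `edit_dist`, or from one
#' SAM/BAM file per strain whose `NM` tags carry the edit distance
#' (positions are converted to 0-based). Records without an `NM` tag
#' are skipped with a counted warning.
#'
#' @param path TSV path, or a named character vector of SAM/BAM paths
#'   (names = strain labels).
#' @return Tibble `read_id`, `strain`, `contig`, `pos`, `edit_dist`.
#' @export
read_alignment_summaries <- function(path) {
  if (length(path) == 1 && grepl("\\.tsv$", path, ignore.case = TRUE)) {
    out <- pc_read_tsv(path)
    check_columns(out, c("read_id", "strain", "edit_dist"), "alignment TSV")
    return(out)
  }
  if (!all(grepl("\\.(sam|bam)$", path, ignore.case = TRUE))) {
    abort("unknown alignment format: expected .tsv, .sam or .bam")
  }
  if (is.null(names(path))) abort("SAM/BAM paths must be named by strain")
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Rsamtools is required for SAM/BAM input")
  }
  purrr::imap_dfr(path, function(p, strain) {
    if (grepl("\\.sam$", p, ignore.case = TRUE)) {
      p <- Rsamtools::asBam(p, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    }
    b <- Rsamtools::scanBam(
      p, param = Rsamtools::ScanBamParam(
        what = c("qname", "rname", "pos"),
        tag = "NM"))[[1]]
    nm <- b$tag$NM
    if (is.null(nm)) nm <- rep(NA_integer_, length(b$qname))
    n_missing <- sum(is.na(nm))
    if (n_missing) {
      warn(sprintf("%d read(s) without an NM tag were skipped", n_missing))
    }
    keep <- !is.na(nm)
    tibble(read_id = b$qname[keep], strain = strain,
           contig = as.character(b$rname[keep]),
           pos = b$pos[keep] - 1L, edit_dist = as.integer(nm[keep]))
  })
}

#' Write interval calls as BED
#'
#' BED is 0-based half-open, matching the internal convention; no
#' coordinate shift is applied. Inverted intervals are refused.
#'
#' @param regions Tibble with `contig`, `start`, `end` and optionally a
#'   `name` column.
#' @param path Output path.
#' @param provenance Optional provenance string written as a `#` header.
#' @export
write_bed <- function(regions, path, provenance = NULL) {
  check_columns(regions, c("contig", "start", "end"), "regions")
  if (any(regions$end <= regions$start)) {
    abort("refusing to write inverted or empty intervals")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  nm <- if ("name" %in% names(regions)) regions$name else
    paste0("region", seq_len(nrow(regions)))
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$contig,
                     as.integer(regions$start), as.integer(regions$end), nm),
             con)
  invisible(path)
}

#' Read and write variant tables as minimal VCF
#'
#' The VCF twin of the variant tibble: positions are written 1-based;
#' depth, alt count and strand counts travel in the INFO field
#' (`DP`, `AC`, `SB=alt_fwd,alt_rev,ref_fwd,ref_rev`), sample and type
#' in `SM` / `TY`. Reading uses vcfR.
#'
#' @param variants Variant tibble (see [variant_filters]).
#' @param path File path.
#' @export
write_vcf <- function(variants, path) {
  check_columns(variants, c("sample", "contig", "pos", "type", "ref", "alt",
                            "depth", "alt_count", "alt_fwd", "alt_rev",
                            "ref_fwd", "ref_rev"), "variants")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=poolcoev-%s",
                   as.character(utils::packageVersion("poolcoev"))),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt count\">",
           "##INFO=<ID=SB,Number=4,Type=Integer,Description=\"alt_fwd,alt_rev,ref_fwd,ref_rev\">",
           "##INFO=<ID=SM,Number=1,Type=String,Description=\"Sample\">",
           "##INFO=<ID=TY,Number=1,Type=String,Description=\"SNP or indel\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t.\tDP=%d;AC=%d;SB=%d,%d,%d,%d;SM=%s;TY=%s",
    variants$contig, as.integer(variants$pos) + 1L, variants$ref,
    variants$alt, variants$depth, variants$alt_count, variants$alt_fwd,
    variants$alt_rev, variants$ref_fwd, variants$ref_rev,
    variants$sample, variants$type)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("vcfR is required for VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"),
                                      fix$INFO))
    sub(paste0("^;?", key, "="), "", m)
  }
  sb <- do.call(rbind, strsplit(info("SB"), ","))
  tibble(sample = info("SM"), contig = fix$CHROM,
         pos = as.integer(fix$POS) - 1L, type = info("TY"),
         ref = fix$REF, alt = fix$ALT,
         depth = as.integer(info("DP")), alt_count = as.integer(info("AC")),
         alt_fwd = as.integer(sb[, 1]), alt_rev = as.integer(sb[, 2]),
         ref_fwd = as.integer(sb[, 3]), ref_rev = as.integer(sb[, 4]))
}
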