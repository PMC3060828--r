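#' Read a multiple sequence alignment
#'
#' Parses an aligned FASTA or Clustal (`.aln`) file into a simple alignment
#' object. All records must have identical gapped length; sequences are
#' uppercased on read. The alignment itself is expected to come from an
#' external MSA tool (ClustalW, MAFFT, ...): this package consumes alignments,
#' it does not compute them.
#'
#' @param source Path to an alignment file, or a character string containing
#'   the alignment text itself (detected by the presence of newlines or a
#'   leading `>`).
#' @param format `"auto"` (default; Clustal is recognised by its header),
#'   `"fasta"` or `"clustal"`.
#' @return An object of class `dna_alignment`: a list with `ids`, `seqs`
#'   (named character vector of gapped sequences) and `ncol`.
#' @examples
#' aln <- read_alignment(">a\nAC-GT\n>b\nACCGT\n")
#' aln$ncol
#' @export
read_alignment <- function(source, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  stopifnot(is.character(source), length(source) == 1L)
  is_text <- grepl("[\n>]", source) && !file.exists(source)
  path <- source
  if (is_text) {
    path <- tempfile(fileext = ".aln")
    on.exit(unlink(path), add = TRUE)
    writeLines(source, path)
  } else if (!file.exists(source)) {
    rlang::abort(paste0("alignment file not found: ", source),
                 class = "swarmprimer_input_error")
  }
  if (format == "auto") {
    head_line <- readLines(path, n = 1L)
    format <- if (grepl("^CLUSTAL", toupper(trimws(head_line)))) "clustal" else "fasta"
  }
  if (format == "clustal") {
    msa <- tryCatch(
      Biostrings::readDNAMultipleAlignment(path, format = "clustal"),
      error = function(e) rlang::abort(
        paste0("failed to parse Clustal alignment: ", conditionMessage(e)),
        class = "swarmprimer_format_error")
    )
    seqs <- toupper(as.character(msa))
  } else {
    # BStringSet tolerates gap characters and ragged records, letting us
    # report length mismatches as a format error rather than a parse crash.
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) rlang::abort(
        paste0("failed to parse FASTA alignment: ", conditionMessage(e)),
        class = "swarmprimer_format_error")
    )
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
  }
  new_alignment(seqs)
}

new_alignment <- function(seqs) {
  if (length(seqs) == 0L) {
    rlang::abort("alignment contains no records", class = "swarmprimer_input_error")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    rlang::abort(
      sprintf("alignment records differ in length (%s)",
              paste(unique(widths), collapse = ", ")),
      class = "swarmprimer_format_error")
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    rlang::abort(
      paste0("record '", names(seqs)[bad][1],
             "' contains characters outside A/C/G/T/N/-"),
      class = "swarmprimer_format_error")
  }
  structure(list(ids = names(seqs), seqs = seqs, ncol = unname(widths[1])),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> %d records x %d columns\n", length(x$ids), x$ncol))
  invisible(x)
}

#' Extract the ungapped reference template from an alignment
#'
#' Strips gaps from the chosen record; primer and amplicon coordinates
#' produced downstream are 1-based positions on this ungapped sequence.
#'
#' @param alignment A `dna_alignment` from [read_alignment()].
#' @param ref_id Identifier of the record to use as coordinate reference.
#' @param circular Is the underlying molecule circular?
#' @return A [template_sequence()].
#' @export
reference_template <- function(alignment, ref_id, circular = TRUE) {
  stopifnot(inherits(alignment, "dna_alignment"))
  if (!ref_id %in% alignment$ids) {
    rlang::abort(paste0("no alignment record named '", ref_id, "'"),
                 class = "swarmprimer_lookup_error")
  }
  ungapped <- gsub("-", "", alignment$seqs[[ref_id]], fixed = TRUE)
  template_sequence(ungapped, id = ref_id, circular = circular)
}

#' Conserved regions of an alignment, in reference coordinates
#'
#' A conserved column is one where every record carries the same unambiguous
#' base (no gaps, no N). Maximal runs of conserved columns are mapped to
#' ungapped coordinates on the chosen reference record and filtered to a
#' minimum length, since only runs at least as long as the shortest
#' admissible primer can host one. On a circular template a run touching both
#' the first and last column is reported as a single origin-spanning region.
#'
#' @inheritParams reference_template
#' @param min_len Minimum region length in nt (default 18, the shortest
#'   admissible primer).
#' @return A tibble with columns `start`, `end` (1-based inclusive reference
#'   positions), `length` and `wraps` (does the region span the origin?).
#'   Regions are disjoint and sorted by start; for a wrapped region
#'   `start > end` and `length = L - start + 1 + end`.
#' @examples
#' aln <- read_alignment(">a\nACGTACGTA\n>b\nACGAACGTA\n")
#' conserved_regions(aln, "a", min_len = 4, circular = FALSE)
#' @export
conserved_regions <- function(alignment, ref_id, min_len = 18, circular = TRUE) {
  stopifnot(inherits(alignment, "dna_alignment"), min_len >= 1)
  if (!ref_id %in% alignment$ids) {
    rlang::abort(paste0("no alignment record named '", ref_id, "'"),
                 class = "swarmprimer_lookup_error")
  }
  mat <- do.call(rbind, strsplit(unname(alignment$seqs), "", fixed = TRUE))
  ref_chars <- strsplit(alignment$seqs[[ref_id]], "", fixed = TRUE)[[1]]
  identical_col <- matrixStats_all_equal(mat)
  conserved <- identical_col & mat[1, ] %in% c("A", "C", "G", "T")
  # Reference position of each non-gap reference column.
  ref_pos <- cumsum(ref_chars != "-")
  L <- ref_pos[length(ref_pos)]

  runs <- rle(conserved)
  ends_col <- cumsum(runs$lengths)
  starts_col <- ends_col - runs$lengths + 1L
  keep <- runs$values
  regions <- tibble::tibble(
    start = ref_pos[starts_col[keep]],
    end = ref_pos[ends_col[keep]],
    wraps = FALSE
  )
  regions$length <- regions$end - regions$start + 1L

  if (circular && nrow(regions) >= 2L) {
    first_touches <- conserved[1]
    last_touches <- conserved[alignment$ncol]
    if (first_touches && last_touches) {
      n <- nrow(regions)
      merged <- tibble::tibble(
        start = regions$start[n], end = regions$end[1], wraps = TRUE,
        length = regions$length[n] + regions$length[1])
      regions <- dplyr::bind_rows(regions[-c(1L, n), ], merged)
    }
  }
  regions <- regions[regions$length >= min_len, , drop = FALSE]
  dplyr::arrange(regions[, c("start", "end", "length", "wraps")], .data$start)
}

# all rows of a character matrix equal, per column
matrixStats_all_equal <- function(mat) {
  if (nrow(mat) == 1L) return(rep(TRUE, ncol(mat)))
  colSums(mat == mat[rep(1L, nrow(mat)), , drop = FALSE]) == nrow(mat)
}

# Logical mask over reference positions 1..L marking conserved bases.
conserved_mask <- function(regions, L) {
  mask <- rep(FALSE, L)
  for (i in seq_len(nrow(regions))) {
    if (regions$wraps[i]) {
      mask[regions$start[i]:L] <- TRUE
      mask[1:regions$end[i]] <- TRUE
    } else {
      mask[regions$start[i]:regions$end[i]] <- TRUE
    }
  }
  mask
}

#' Write conserved regions as BED
#'
#' Writes a BED-like TSV. BED intervals are 0-based half-open, so a region
#' `start..end` (1-based inclusive) becomes `start-1, end`; this is the only
#' place in the package where coordinates leave the 1-based frame. A wrapped
#' region is emitted as two intervals sharing a name.
#'
#' @param regions Tibble from [conserved_regions()].
#' @param path Output file path.
#' @param template The [template_sequence()] the coordinates refer to.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(regions, path, template) {
  stopifnot(inherits(template, "template_sequence"))
  rows <- purrr::pmap_dfr(regions, function(start, end, length, wraps) {
    if (wraps) {
      tibble::tibble(chrom = template$id,
                     chromStart = c(start - 1L, 0L),
                     chromEnd = c(template$length, end),
                     name = sprintf("conserved_wrap_%d", start))
    } else {
      tibble::tibble(chrom = template$id, chromStart = start - 1L,
                     chromEnd = end, name = sprintf("conserved_%d", start))
    }
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
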