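#' Build a template sequence
#'
#' A template sequence is the ungapped reference coordinate frame in which all
#' primer and amplicon positions are expressed. Coordinates throughout the
#' package are 1-based and inclusive on this sequence; for circular templates
#' positions wrap modulo the template length, so an amplicon may legally span
#' the origin.
#'
#' @param seq A single nucleotide string (A/C/G/T/N, case-insensitive).
#' @param id Identifier carried through to output writers.
#' @param circular Is the molecule circular (e.g. a mitochondrial genome)?
#' @return An object of class `template_sequence` with fields `id`, `seq`
#'   (uppercased), `circular` and `length`.
#' @examples
#' tpl <- template_sequence("acgtACGT", id = "toy", circular = TRUE)
#' tpl$length
#' @export
template_sequence <- function(seq, id = "template", circular = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) {
    rlang::abort("template sequence must be nonempty", class = "swarmprimer_input_error")
  }
  if (grepl("-", seq, fixed = TRUE)) {
    rlang::abort("template sequence must be ungapped", class = "swarmprimer_input_error")
  }
  if (grepl("[^ACGTN]", seq)) {
    rlang::abort("template sequence may only contain A/C/G/T/N",
                 class = "swarmprimer_input_error")
  }
  structure(
    list(id = as.character(id), seq = seq, circular = isTRUE(circular),
         length = nchar(seq)),
    class = "template_sequence"
  )
}

#' @export
print.template_sequence <- function(x, ...) {
  cat(sprintf("<template_sequence> %s: %d nt, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of A/C/G/T/N sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("GAAT")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

# Circular 1-based inclusive substring. `start` in 1..L, len <= L.
subseq_circular <- function(tpl, start, len) {
  L <- tpl$length
  stopifnot(start >= 1L, start <= L, len >= 1L)
  if (start + len - 1L <= L) {
    return(substr(tpl$seq, start, start + len - 1L))
  }
  if (!tpl$circular) {
    rlang::abort("interval runs past the end of a linear template",
                 class = "swarmprimer_decode_error")
  }
  if (len > L) {
    rlang::abort("interval longer than the template", class = "swarmprimer_decode_error")
  }
  paste0(substr(tpl$seq, start, L), substr(tpl$seq, 1L, start + len - 1L - L))
}

# Map any integer position onto 1..L.
wrap_position <- function(pos, L) ((pos - 1L) %% L) + 1L

# Positions (1..L) covered by a possibly wrapping interval.
circular_positions <- function(start, len, L) wrap_position(start + seq_len(len) - 1L, L)
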