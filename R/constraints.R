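#' Primer-pair design constraints
#'
#' Bundles the bounds every candidate primer pair is checked against. The
#' defaults are the standard settings for tiling a mitochondrial genome with
#' mutually overlapping amplicons: Tm in \[54, 65\] °C with at most 3 °C
#' difference within a pair, lengths in \[18, 28\] nt differing by at most
#' 3 nt, products of 800-1100 nt, dimers flagged above 5 base pairings,
#' hairpin stems of 4+ bp, at most 3 G/C among the 5 terminal bases, and
#' junction overlaps of 90-200 nt (extendable in 50 nt steps up to 500 nt).
#'
#' @param tm_min,tm_max Melting-temperature window (°C).
#' @param tm_diff_max Maximum |Tm_fwd - Tm_rev| (°C).
#' @param len_min,len_max Primer length window (nt).
#' @param len_diff_max Maximum |len_fwd - len_rev| (nt).
#' @param product_min,product_max PCR product length window (nt).
#' @param gc_min,gc_max Acceptable GC content window (percent). This window
#'   is a soft, weighted term rather than a hard filter: published primer
#'   sets contain occasional primers outside it.
#' @param dimer_min_pairings A primer-dimer is flagged when more than this
#'   many base pairings form at some antiparallel offset.
#' @param dimer_mode Count the longest `"contiguous"` run of pairings
#'   (default) or the `"total"` pairings at the best offset.
#' @param hairpin_min_stem Minimum self-complementary stem length (bp)
#'   considered a hairpin.
#' @param hairpin_min_loop Minimum loop size (nt) between the stem halves;
#'   3 nt is the physical minimum.
#' @param terminus_window,terminus_gc_max Flag a terminus whose first/last
#'   `terminus_window` bases contain more than `terminus_gc_max` G/C.
#' @param endmatch_len 3'-end complementarity length checked between the two
#'   primers of a pair.
#' @param min_overlap,max_overlap Required overlap window (nt) between
#'   consecutive amplicons; the next forward primer is sought this far
#'   upstream of the previous reverse primer.
#' @param overlap_step,overlap_cap Automatic overlap extension step and cap
#'   (nt) used when no primer can be designed in the current window.
#' @return An object of class `design_constraints`.
#' @examples
#' design_constraints(product_min = 500, product_max = 700)
#' @export
design_constraints <- function(tm_min = 54, tm_max = 65, tm_diff_max = 3,
                               len_min = 18, len_max = 28, len_diff_max = 3,
                               product_min = 800, product_max = 1100,
                               gc_min = 40, gc_max = 60,
                               dimer_min_pairings = 5,
                               dimer_mode = c("contiguous", "total"),
                               hairpin_min_stem = 4, hairpin_min_loop = 3,
                               terminus_window = 5, terminus_gc_max = 3,
                               endmatch_len = 3,
                               min_overlap = 90, max_overlap = 200,
                               overlap_step = 50, overlap_cap = 500) {
  dimer_mode <- match.arg(dimer_mode)
  c_ <- list(tm_min = tm_min, tm_max = tm_max, tm_diff_max = tm_diff_max,
             len_min = as.integer(len_min), len_max = as.integer(len_max),
             len_diff_max = as.integer(len_diff_max),
             product_min = as.integer(product_min),
             product_max = as.integer(product_max),
             gc_min = gc_min, gc_max = gc_max,
             dimer_min_pairings = as.integer(dimer_min_pairings),
             dimer_mode = dimer_mode,
             hairpin_min_stem = as.integer(hairpin_min_stem),
             hairpin_min_loop = as.integer(hairpin_min_loop),
             terminus_window = as.integer(terminus_window),
             terminus_gc_max = as.integer(terminus_gc_max),
             endmatch_len = as.integer(endmatch_len),
             min_overlap = as.integer(min_overlap),
             max_overlap = as.integer(max_overlap),
             overlap_step = as.integer(overlap_step),
             overlap_cap = as.integer(overlap_cap))
  for (rng in list(c("tm_min", "tm_max"), c("len_min", "len_max"),
                   c("product_min", "product_max"), c("gc_min", "gc_max"),
                   c("min_overlap", "max_overlap"),
                   c("max_overlap", "overlap_cap"))) {
    if (c_[[rng[1]]] > c_[[rng[2]]]) {
      rlang::abort(sprintf("constraint bound %s > %s", rng[1], rng[2]),
                   class = "swarmprimer_config_error")
    }
  }
  structure(c_, class = "design_constraints")
}

#' Weights of the penalty terms in the fitness function
#'
#' The fitness of a candidate pair is the weighted sum of its penalty terms;
#' zero fitness means every constraint is satisfied. The exact weights only
#' shape the search: safety-critical terms (secondary structure, specificity,
#' 3'-end complementarity) default to 10, graded comfort terms to 1, and the
#' conserved-placement term — which keeps primers inside alignment-conserved
#' regions — to 50 so the swarm cannot trade it against anything else.
#'
#' @param tm_range,tm_diff,length_range,length_diff,gc_range,product_len,gc_clamp,terminus_gc
#'   Weights of the graded/comfort terms.
#' @param hairpin,dimer,specificity,endmatch Weights of the safety terms.
#' @param conserved Weight of the conserved-region placement term.
#' @return An object of class `constraint_weights` (named numeric vector).
#' @export
constraint_weights <- function(tm_range = 1, tm_diff = 1, length_range = 1,
                               length_diff = 1, gc_range = 1, product_len = 1,
                               hairpin = 10, dimer = 10, specificity = 10,
                               gc_clamp = 1, endmatch = 10, terminus_gc = 1,
                               conserved = 50) {
  w <- c(tm_range = tm_range, tm_diff = tm_diff, length_range = length_range,
         length_diff = length_diff, gc_range = gc_range,
         product_len = product_len, hairpin = hairpin, dimer = dimer,
         specificity = specificity, gc_clamp = gc_clamp, endmatch = endmatch,
         terminus_gc = terminus_gc, conserved = conserved)
  if (any(w < 0) || all(w == 0)) {
    rlang::abort("weights must be nonnegative with at least one positive",
                 class = "swarmprimer_config_error")
  }
  structure(w, class = c("constraint_weights", "numeric"))
}

#' Melting-temperature penalties of a primer pair
#'
#' @param tm_f,tm_r Forward/reverse primer melting temperatures (°C).
#' @param constraints A [design_constraints()] object.
#' @return Named numeric: `range` counts primers outside the Tm window
#'   (0, 1 or 2; bounds inclusive), `diff` is 1 when the pair's Tm difference
#'   exceeds the maximum.
#' @export
tm_penalties <- function(tm_f, tm_r, constraints = design_constraints()) {
  out_f <- tm_f < constraints$tm_min | tm_f > constraints$tm_max
  out_r <- tm_r < constraints$tm_min | tm_r > constraints$tm_max
  c(range = as.numeric(out_f) + as.numeric(out_r),
    diff = as.numeric(abs(tm_f - tm_r) > constraints$tm_diff_max))
}

#' Length penalties of a primer pair
#'
#' @param len_f,len_r Forward/reverse primer lengths (nt).
#' @inheritParams tm_penalties
#' @return Named numeric: `range` counts primers outside the length window
#'   (bounds inclusive), `diff` is 1 when the lengths differ by more than the
#'   maximum.
#' @export
length_penalties <- function(len_f, len_r, constraints = design_constraints()) {
  out_f <- len_f < constraints$len_min | len_f > constraints$len_max
  out_r <- len_r < constraints$len_min | len_r > constraints$len_max
  c(range = as.numeric(out_f) + as.numeric(out_r),
    diff = as.numeric(abs(len_f - len_r) > constraints$len_diff_max))
}

#' GC-content penalty of a primer pair
#'
#' @param gc_f,gc_r Forward/reverse GC percentages.
#' @inheritParams tm_penalties
#' @return Number of primers (0-2) with GC content outside the window.
#' @export
gc_penalty <- function(gc_f, gc_r, constraints = design_constraints()) {
  as.numeric(gc_f < constraints$gc_min | gc_f > constraints$gc_max) +
    as.numeric(gc_r < constraints$gc_min | gc_r > constraints$gc_max)
}

#' Product-length penalty
#'
#' Zero inside the product window; outside it, the distance in nt to the
#' nearest bound, so the optimizer has a gradient back toward the window.
#'
#' @param product_len Product length (nt).
#' @inheritParams tm_penalties
#' @export
product_length_penalty <- function(product_len, constraints = design_constraints()) {
  stopifnot(all(product_len >= 1))
  pmax(0, constraints$product_min - product_len,
       product_len - constraints$product_max)
}

# Maximum number of Watson-Crick pairings between p1 and p2 over all ungapped
# antiparallel offsets. mode "contiguous": longest run of consecutive
# pairings at the best offset; "total": most pairings at any single offset.
dimer_pairings <- function(p1, p2, mode = "contiguous") {
  b1 <- strsplit(toupper(p1), "", fixed = TRUE)[[1]]
  b2 <- strsplit(toupper(p2), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "x")
  n1 <- length(b1); n2 <- length(b2)
  m <- outer(unname(comp[b1]), b2, "==")  # i pairs j (antiparallel when i+j fixed)
  if (mode == "total") {
    # pairings per antiparallel offset = per antidiagonal i+j
    hits <- which(m, arr.ind = TRUE)
    if (nrow(hits) == 0L) return(0L)
    return(max(tabulate(hits[, 1] + hits[, 2])))
  }
  # longest run of consecutive pairings along any antidiagonal, by the
  # standard reset recurrence r[i,j] = m[i,j] * (r[i-1,j+1] + 1)
  r <- matrix(0L, n1, n2)
  r[1, ] <- m[1, ]
  if (n1 > 1L) {
    for (i in 2:n1) {
      if (n2 > 1L) r[i, 1:(n2 - 1L)] <- m[i, 1:(n2 - 1L)] * (r[i - 1L, 2:n2] + 1L)
      r[i, n2] <- m[i, n2]
    }
  }
  as.integer(max(r))
}

#' Primer-dimer check
#'
#' Slides one primer along the other in antiparallel orientation and counts
#' Watson-Crick pairings at each ungapped offset. The pair is flagged when
#' the best offset exceeds `dimer_min_pairings` pairings. Use `p1 == p2` for
#' a self-dimer check.
#'
#' @param p1,p2 Primer sequences (5'->3').
#' @inheritParams tm_penalties
#' @return 1 if a dimer is predicted, else 0.
#' @examples
#' dimer_check("AAAAAA", "TTTTTT")  # 6 contiguous pairings -> 1
#' dimer_check("ACGT", "ACGT")      # at most 4 pairings -> 0
#' @export
dimer_check <- function(p1, p2, constraints = design_constraints()) {
  as.numeric(dimer_pairings(p1, p2, constraints$dimer_mode) >
               constraints$dimer_min_pairings)
}

#' Hairpin check
#'
#' A primer is flagged when it can fold back on itself with a stem of at
#' least `hairpin_min_stem` Watson-Crick base pairs enclosing a loop of at
#' least `hairpin_min_loop` nt.
#'
#' @param p Primer sequence (5'->3').
#' @inheritParams tm_penalties
#' @return 1 if a hairpin is predicted, else 0.
#' @examples
#' hairpin_check("GGGGAAATTTCCCC")
#' @export
hairpin_check <- function(p, constraints = design_constraints()) {
  b <- strsplit(toupper(p), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "x")
  n <- length(b)
  k <- constraints$hairpin_min_stem
  loop <- constraints$hairpin_min_loop
  if (n < 2 * k + loop) return(0)
  cb <- unname(comp[b])
  for (i in 1:(n - 2 * k - loop + 1)) {
    stem5 <- cb[i:(i + k - 1)]
    for (j in (i + k + loop):(n - k + 1)) {
      # stem5 pairs the reversed downstream segment
      if (all(stem5 == b[(j + k - 1):j])) return(1)
    }
  }
  0
}

#' Binding-site specificity check
#'
#' Counts occurrences of the primer's binding site on the template,
#' considering both strands and — for circular templates — sites crossing the
#' origin. A specific primer binds exactly once; the penalty is the number of
#' extra occurrences.
#'
#' @param p Primer sequence (5'->3').
#' @param template A [template_sequence()].
#' @return Extra-occurrence count (0 when the primer is specific).
#' @export
specificity_check <- function(p, template) {
  stopifnot(inherits(template, "template_sequence"))
  p <- toupper(p)
  if (nchar(p) > template$length) {
    rlang::abort("primer longer than template", class = "swarmprimer_input_error")
  }
  subject <- specificity_subject(template, nchar(p))
  n <- Biostrings::countPattern(p, subject) +
    Biostrings::countPattern(revcomp(p), subject)
  max(0, n - 1)
}

# Circularized subject for substring search: template plus the first
# (overhang) bases, so matches crossing the origin are found exactly once.
specificity_subject <- function(template, overhang) {
  ext <- template$seq
  if (template$circular && overhang > 1) {
    ext <- paste0(ext, substr(ext, 1L, overhang - 1L))
  }
  Biostrings::DNAString(ext)
}

#' 3'-end GC clamp check
#'
#' @param p Primer sequence (5'->3').
#' @return 0 when the 3'-terminal base is G or C (stabilising extension
#'   initiation), else 1.
#' @export
gc_clamp_check <- function(p) {
  p <- toupper(p)
  as.numeric(!substr(p, nchar(p), nchar(p)) %in% c("G", "C"))
}

#' 3'-end complementarity (end-match) check
#'
#' Flags a pair whose 3'-terminal bases are mutually Watson-Crick
#' complementary in antiparallel orientation — such pairs prime on each other
#' and form primer-dimers during PCR.
#'
#' @param pf,pr Forward and reverse primer sequences (5'->3').
#' @inheritParams tm_penalties
#' @return 1 if the `endmatch_len` 3'-terminal bases anneal, else 0.
#' @export
endmatch_check <- function(pf, pr, constraints = design_constraints()) {
  k <- constraints$endmatch_len
  pf <- toupper(pf); pr <- toupper(pr)
  stopifnot(nchar(pf) >= k, nchar(pr) >= k)
  end_f <- substr(pf, nchar(pf) - k + 1L, nchar(pf))
  end_r <- substr(pr, nchar(pr) - k + 1L, nchar(pr))
  as.numeric(end_f == revcomp(end_r))
}

#' Terminal GC-richness check
#'
#' @param p Primer sequence (5'->3').
#' @inheritParams tm_penalties
#' @return Number of termini (0-2) whose terminal window (default 5 nt)
#'   contains more than `terminus_gc_max` G/C bases.
#' @export
terminus_gc_check <- function(p, constraints = design_constraints()) {
  p <- toupper(p)
  wn <- constraints$terminus_window
  if (nchar(p) < wn) {
    rlang::abort("primer shorter than the terminus window",
                 class = "swarmprimer_input_error")
  }
  gc_count <- function(s) nchar(gsub("[^GC]", "", s))
  head5 <- substr(p, 1L, wn)
  tail3 <- substr(p, nchar(p) - wn + 1L, nchar(p))
  as.numeric(gc_count(head5) > constraints$terminus_gc_max) +
    as.numeric(gc_count(tail3) > constraints$terminus_gc_max)
}
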