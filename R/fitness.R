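# Evaluation context: everything needed to score a candidate pair against a
# fixed template, precomputed once per optimization so the per-particle cost
# is only string slicing and the constraint checks. Scores are memoized on
# the integer coordinates, which the swarm revisits heavily as it converges.
make_eval_context <- function(template, constraints, weights, thermo,
                              regions = NULL) {
  stopifnot(inherits(template, "template_sequence"),
            inherits(constraints, "design_constraints"),
            inherits(weights, "constraint_weights"),
            inherits(thermo, "thermo_params"))
  L <- template$length
  doubled <- if (template$circular) paste0(template$seq, template$seq) else template$seq
  overhang <- if (template$circular) constraints$len_max - 1L else 0L
  list(template = template, constraints = constraints, weights = weights,
       thermo = thermo, L = L, doubled = doubled,
       subject = paste0(template$seq, substr(template$seq, 1L, overhang)),
       mask = if (!is.null(regions)) conserved_mask(regions, L),
       memo = new.env(parent = emptyenv()))
}

ctx_subseq <- function(ctx, start, len) {
  if (start + len - 1L > ctx$L && !ctx$template$circular) {
    rlang::abort("interval runs past the end of a linear template",
                 class = "swarmprimer_decode_error")
  }
  substr(ctx$doubled, start, start + len - 1L)
}

# Count occurrences of a primer on the circularized subject. Restarting one
# position past each hit makes the count include overlapping matches while
# keeping the fast fixed-string search. Matches starting past `max_start`
# are rotations already counted once (the subject carries a fixed overhang
# sized for the longest primer) and are excluded.
count_occurrences <- function(pattern, subject, max_start = Inf) {
  n <- 0L; offset <- 0L; total <- nchar(subject)
  repeat {
    i <- regexpr(pattern, substr(subject, offset + 1L, total),
                 fixed = TRUE, useBytes = TRUE)
    if (i == -1L) break
    start <- offset + i
    if (start > max_start) break
    n <- n + 1L
    offset <- start
  }
  n
}

ctx_specificity <- function(ctx, p) {
  n <- count_occurrences(p, ctx$subject, ctx$L) +
    count_occurrences(revcomp(p), ctx$subject, ctx$L)
  max(0, n - 1)
}

penalty_terms <- c("tm_range", "tm_diff", "length_range", "length_diff",
                   "gc_range", "product_len", "hairpin", "dimer",
                   "specificity", "gc_clamp", "endmatch", "terminus_gc",
                   "conserved")

# Score one integer-coded candidate {fs, fl, rl, pl}; fs in 1..L.
eval_pair_ctx <- function(fs, fl, rl, pl, ctx) {
  key <- paste(fs, fl, rl, pl, sep = "_")
  hit <- ctx$memo[[key]]
  if (!is.null(hit)) return(hit)
  cns <- ctx$constraints
  L <- ctx$L
  fwd <- ctx_subseq(ctx, fs, fl)
  rev_start <- wrap_position(fs + pl - rl, L)
  rev_site <- ctx_subseq(ctx, rev_start, rl)
  rev <- revcomp(rev_site)

  tms <- tm_calc(c(fwd, rev), ctx$thermo)
  gcs <- 100 * nchar(gsub("[AT]", "", c(fwd, rev))) / c(fl, rl)
  tmp <- tm_penalties(tms[1], tms[2], cns)
  lnp <- length_penalties(fl, rl, cns)

  terms <- c(
    tm_range = unname(tmp["range"]), tm_diff = unname(tmp["diff"]),
    length_range = unname(lnp["range"]), length_diff = unname(lnp["diff"]),
    gc_range = gc_penalty(gcs[1], gcs[2], cns),
    product_len = product_length_penalty(pl, cns),
    hairpin = hairpin_check(fwd, cns) + hairpin_check(rev, cns),
    dimer = dimer_check(fwd, fwd, cns) + dimer_check(rev, rev, cns) +
      dimer_check(fwd, rev, cns),
    specificity = ctx_specificity(ctx, fwd) + ctx_specificity(ctx, rev),
    gc_clamp = gc_clamp_check(fwd) + gc_clamp_check(rev),
    endmatch = endmatch_check(fwd, rev, cns),
    terminus_gc = terminus_gc_check(fwd, cns) + terminus_gc_check(rev, cns),
    # graded: number of primer bases outside conserved sequence, so the
    # swarm has a slope toward fully conserved placements
    conserved = if (is.null(ctx$mask)) 0 else {
      sum(!ctx$mask[circular_positions(fs, fl, L)]) +
        sum(!ctx$mask[circular_positions(rev_start, rl, L)])
    }
  )
  res <- list(
    terms = terms,
    fitness = sum(unclass(ctx$weights)[names(terms)] * terms),
    fwd_seq = fwd, rev_seq = rev, rev_start = rev_start,
    tm_f = tms[1], tm_r = tms[2], gc_f = gcs[1], gc_r = gcs[2]
  )
  ctx$memo[[key]] <- res
  res
}

#' Evaluate a primer pair against all design constraints
#'
#' Runs every constraint check on the pair encoded by
#' `{fwd_start, fwd_len, rev_len, product_len}` and aggregates the weighted
#' penalty terms into a fitness value. Zero fitness means the pair satisfies
#' every constraint.
#'
#' @param pair A list, one-row data frame, or numeric vector giving
#'   `fwd_start`, `fwd_len`, `rev_len` and `product_len` (1-based template
#'   coordinates).
#' @param template A [template_sequence()].
#' @param constraints A [design_constraints()].
#' @param weights A [constraint_weights()].
#' @param thermo A [thermo_params()].
#' @param regions Optional conserved-region tibble from
#'   [conserved_regions()]; when supplied, primers leaving conserved regions
#'   incur the `conserved` penalty term.
#' @return A one-row tibble with the decoded primers, their Tm and GC
#'   content, one column per penalty term, and `fitness`.
#' @examples
#' tpl <- template_sequence(paste(rep("ACGTTGCA", 30), collapse = ""))
#' evaluate_primer_pair(list(fwd_start = 1, fwd_len = 20,
#'                           rev_len = 20, product_len = 120),
#'                      tpl, design_constraints(product_min = 100,
#'                                              product_max = 150))
#' @export
evaluate_primer_pair <- function(pair, template,
                                 constraints = design_constraints(),
                                 weights = constraint_weights(),
                                 thermo = thermo_params(), regions = NULL) {
  pair <- as.list(pair)
  if (is.null(names(pair)) || !all(c("fwd_start", "fwd_len", "rev_len",
                                     "product_len") %in% names(pair))) {
    names(pair) <- c("fwd_start", "fwd_len", "rev_len", "product_len")
  }
  fs <- as.integer(pair$fwd_start); fl <- as.integer(pair$fwd_len)
  rl <- as.integer(pair$rev_len); pl <- as.integer(pair$product_len)
  if (fs < 1L || fs > template$length) {
    rlang::abort("fwd_start outside the template", class = "swarmprimer_decode_error")
  }
  ctx <- make_eval_context(template, constraints, weights, thermo, regions)
  res <- eval_pair_ctx(fs, fl, rl, pl, ctx)
  breakdown_row(fs, fl, rl, pl, res)
}

# Penalty-term columns carry a `pen_` prefix so e.g. the product-length
# penalty does not collide with the product_len coordinate column.
breakdown_row <- function(fs, fl, rl, pl, res) {
  terms <- res$terms
  names(terms) <- paste0("pen_", names(terms))
  dplyr::bind_cols(
    tibble::tibble(fwd_start = unname(fs), fwd_len = unname(fl),
                   rev_start = unname(res$rev_start), rev_len = unname(rl),
                   product_len = unname(pl),
                   fwd_seq = res$fwd_seq, rev_seq = res$rev_seq,
                   tm_f = unname(res$tm_f), tm_r = unname(res$tm_r),
                   gc_f = unname(res$gc_f), gc_r = unname(res$gc_r)),
    tibble::as_tibble(as.list(terms)),
    tibble::tibble(fitness = res$fitness)
  )
}

#' Decode a particle into its primer pair
#'
#' A particle `{Fs, Fl, Rl, Pl}` encodes: forward primer = template bases
#' `Fs .. Fs+Fl-1`; amplicon = `Fs .. Fs+Pl-1`; reverse primer = reverse
#' complement of the amplicon's last `Rl` bases. On circular templates the
#' amplicon may wrap through the origin; on linear templates running past the
#' end is a decode error.
#'
#' @param particle Numeric vector `c(Fs, Fl, Rl, Pl)` (or a named
#'   list/one-row data frame with those fields).
#' @param template A [template_sequence()].
#' @return A one-row tibble: `fwd_seq`, `rev_seq`, `product_seq`,
#'   `fwd_start`, `fwd_len`, `rev_start`, `rev_len`, `product_len`.
#' @examples
#' tpl <- template_sequence("ACTTAGCGAATG", circular = FALSE)
#' decode_particle(c(2, 3, 4, 10), tpl)  # fwd CTT, product CTTAGCGAAT, rev ATTC
#' @export
decode_particle <- function(particle, template) {
  p <- as.list(particle)
  if (is.null(names(p)) || !all(c("Fs", "Fl", "Rl", "Pl") %in% names(p))) {
    names(p) <- c("Fs", "Fl", "Rl", "Pl")
  }
  fs <- as.integer(p$Fs); fl <- as.integer(p$Fl)
  rl <- as.integer(p$Rl); pl <- as.integer(p$Pl)
  stopifnot(fl >= 1, rl >= 1, pl >= fl, pl >= rl)
  if (fs < 1L || fs > template$length) {
    rlang::abort("particle start outside the template",
                 class = "swarmprimer_decode_error")
  }
  product <- subseq_circular(template, fs, pl)
  rev_start <- wrap_position(fs + pl - rl, template$length)
  tibble::tibble(
    fwd_seq = substr(product, 1L, fl),
    rev_seq = revcomp(substr(product, pl - rl + 1L, pl)),
    product_seq = product,
    fwd_start = fs, fwd_len = fl, rev_start = rev_start, rev_len = rl,
    product_len = pl)
}
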