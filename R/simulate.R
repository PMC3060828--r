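#' Specification for a simulated family of closely related circular genomes
#'
#' Describes a substitution-only evolution experiment: an ancestral circular
#' sequence and independently mutated descendants, with per-block relative
#' mutation rates emulating a mitochondrial genome (slowly evolving rRNA
#' genes, protein-coding genes at the background rate, and a fast,
#' D-loop-like control region). Substitution-only evolution keeps the family
#' trivially pre-aligned, so conserved-region extraction has an exact
#' column-scan oracle.
#'
#' @param genome_len Genome length in nt (default 16500, a typical
#'   vertebrate mitogenome).
#' @param n_sequences Number of descendant sequences.
#' @param divergence Expected genome-wide substitutions per site per
#'   descendant, in \[0, 1).
#' @param blocks Tibble with `start`, `end` (1-based inclusive) and `rate`
#'   (relative mutation rate); blocks must tile the genome. Rates are
#'   rescaled so the length-weighted mean is 1, keeping `divergence` the
#'   genome-wide expectation. `NULL` builds the default mitogenome-like
#'   profile: two rRNA-like blocks at 0.2x, thirteen coding-like blocks at
#'   1x, one control-region-like block at 8x.
#' @param gc Ancestral GC fraction.
#' @param seed Optional integer seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(genome_len = 16500, n_sequences = 2, divergence = 0.02,
                     blocks = NULL, gc = 0.5, seed = NULL) {
  genome_len <- as.integer(genome_len)
  stopifnot(genome_len >= 100, n_sequences >= 1,
            divergence >= 0, divergence < 1, gc > 0, gc < 1)
  if (is.null(blocks)) blocks <- default_block_profile(genome_len)
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("start", "end", "rate") %in% names(blocks)))
  blocks <- dplyr::arrange(blocks, .data$start)
  if (blocks$start[1] != 1L || blocks$end[nrow(blocks)] != genome_len ||
      (nrow(blocks) > 1 && any(blocks$start[-1] != blocks$end[-nrow(blocks)] + 1L))) {
    rlang::abort("blocks must tile the genome without gaps",
                 class = "swarmprimer_config_error")
  }
  len <- blocks$end - blocks$start + 1L
  blocks$rate <- blocks$rate * genome_len / sum(len * blocks$rate)
  structure(list(genome_len = genome_len, n_sequences = as.integer(n_sequences),
                 divergence = divergence, blocks = blocks, gc = gc,
                 seed = seed),
            class = "sim_spec")
}

# Mitogenome-like rate profile: ~6% rRNA-like at 0.2x, 13 coding-like blocks
# at 1x filling the middle, and a 7% control-region-like tail at 3x --
# roughly the relative D-loop rate seen between congeneric fish, and
# consistent with control regions that still carry conserved anchors a few
# hundred nt apart.
default_block_profile <- function(genome_len) {
  b1 <- round(0.06 * genome_len)
  b2 <- round(0.93 * genome_len)
  coding_bounds <- round(seq(b1, b2, length.out = 14L))
  tibble::tibble(
    start = c(1L, coding_bounds[-14] + 1L, b2 + 1L),
    end = c(coding_bounds[1], coding_bounds[-1], genome_len),
    rate = c(0.2, rep(1, 13), 3))
}

#' Simulate a family of closely related circular genomes
#'
#' Draws an ancestral circular sequence and mutates each descendant
#' independently: every site substitutes with probability
#' `divergence * rate(block)`, to a base drawn uniformly from the three
#' alternatives. Because only substitutions are applied, the descendants are
#' returned both as templates and as an exact (gap-free) alignment.
#'
#' @param spec A [sim_spec()].
#' @return A list with `templates` (list of [template_sequence()]),
#'   `alignment` (a `dna_alignment`) and `spec`.
#' @examples
#' fam <- simulate_family(sim_spec(genome_len = 2000, divergence = 0, seed = 1))
#' fam$alignment
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- spec$genome_len
  base_prob <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
                 G = spec$gc / 2, T = (1 - spec$gc) / 2)
  ancestor <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)
  site_rate <- rep(spec$blocks$rate, spec$blocks$end - spec$blocks$start + 1L)
  p_mut <- pmin(spec$divergence * site_rate, 0.95)
  bases <- c("A", "C", "G", "T")

  seqs <- character(spec$n_sequences)
  for (i in seq_len(spec$n_sequences)) {
    child <- ancestor
    hit <- which(stats::runif(L) < p_mut)
    if (length(hit)) {
      # substitute to one of the three other bases, uniformly
      shift <- sample.int(3L, length(hit), replace = TRUE)
      child[hit] <- bases[(match(child[hit], bases) - 1L + shift) %% 4L + 1L]
    }
    seqs[i] <- paste(child, collapse = "")
  }
  names(seqs) <- sprintf("sim_%02d", seq_len(spec$n_sequences))
  templates <- purrr::imap(seqs, ~ template_sequence(.x, id = .y, circular = TRUE))
  list(templates = unname(templates), alignment = new_alignment(seqs),
       spec = spec)
}

#' Published conserved primer set for the parrotfish mitogenome pair
#'
#' The 22 conserved primer pairs reported for tiling the complete
#' mitochondrial genomes of *Scarus forsteni* and *S. rubroviolaceus*
#' (GenBank FJ619271.1 / FJ227899.1), shipped as a validation fixture:
#' sequences, 1-based start indices on the reference genome, lengths, the
#' reported GC% and Tm, and product lengths. The final two amplicons wrap
#' through the origin; their coordinate arithmetic implies a reference
#' template length of 16702 nt, attached as `attr(x, "template_len")`.
#'
#' @return A tibble with 22 rows and columns `set`, `fwd_seq`, `fwd_start`,
#'   `fwd_len`, `fwd_gc`, `fwd_tm`, `rev_seq`, `rev_start`, `rev_len`,
#'   `rev_gc`, `rev_tm`, `product_len`.
#' @examples
#' scarus_primer_set()[1, c("fwd_seq", "product_len")]
#' @export
scarus_primer_set <- function() {
  path <- system.file("extdata", "scarus_mtdna_primers.tsv",
                      package = "swarmprimer", mustWork = TRUE)
  tbl <- read_primer_table(path)
  attr(tbl, "template_len") <- 16702L
  tbl
}

#' Audit a primer table against the pairwise design constraints
#'
#' Re-checks an existing primer table (for example a published set, or the
#' output of [tile_genome()]) against the sequence-level constraints that
#' can be verified from the table alone: primer lengths and their pairwise
#' difference, the 3' GC clamp, terminal GC richness, and the within-pair Tm
#' difference (using the table's Tm column when present, otherwise computed).
#' When the table carries coordinates and a template length, the product
#' arithmetic identity `product_len = (rev_start + rev_len - fwd_start) mod
#' L` is verified as well.
#'
#' @param pairs Tibble with at least `fwd_seq` and `rev_seq`; optionally
#'   `fwd_tm`/`rev_tm`, coordinates and `product_len`.
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_params()], used when Tm columns are absent.
#' @param template_len Template length for the coordinate identity;
#'   defaults to `attr(pairs, "template_len")`.
#' @return A tibble, one row per pair, with logical check columns
#'   (`len_ok`, `len_diff_ok`, `gc_clamp_ok`, `terminus_gc_ok`,
#'   `tm_diff_ok`, `product_arith_ok`) and `pass` (all checks TRUE).
#' @export
validate_primer_set <- function(pairs, constraints = design_constraints(),
                                thermo = thermo_params(),
                                template_len = NULL) {
  pairs <- tibble::as_tibble(pairs)
  template_len <- template_len %||% attr(pairs, "template_len")
  stopifnot(all(c("fwd_seq", "rev_seq") %in% names(pairs)))
  fl <- nchar(pairs$fwd_seq); rl <- nchar(pairs$rev_seq)
  tm_f <- if ("fwd_tm" %in% names(pairs) && !all(is.na(pairs$fwd_tm))) {
    pairs$fwd_tm
  } else melting_temperature(pairs$fwd_seq, thermo)
  tm_r <- if ("rev_tm" %in% names(pairs) && !all(is.na(pairs$rev_tm))) {
    pairs$rev_tm
  } else melting_temperature(pairs$rev_seq, thermo)
  out <- tibble::tibble(
    set = if ("set" %in% names(pairs)) pairs$set else seq_len(nrow(pairs)),
    len_ok = fl >= constraints$len_min & fl <= constraints$len_max &
      rl >= constraints$len_min & rl <= constraints$len_max,
    len_diff_ok = abs(fl - rl) <= constraints$len_diff_max,
    gc_clamp_ok = gc_clamp_check(pairs$fwd_seq) == 0 &
      gc_clamp_check(pairs$rev_seq) == 0,
    terminus_gc_ok = vapply(pairs$fwd_seq, terminus_gc_check, numeric(1),
                            constraints = constraints) == 0 &
      vapply(pairs$rev_seq, terminus_gc_check, numeric(1),
             constraints = constraints) == 0,
    tm_diff_ok = abs(tm_f - tm_r) <= constraints$tm_diff_max)
  if (!is.null(template_len) &&
      all(c("fwd_start", "rev_start", "product_len") %in% names(pairs))) {
    out$product_arith_ok <-
      (pairs$rev_start + rl - pairs$fwd_start) %% template_len ==
      pairs$product_len %% template_len
  }
  out$pass <- apply(dplyr::select(out, -"set"), 1L, all)
  out
}
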