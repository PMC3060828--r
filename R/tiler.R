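#' Overlap between two adjacent amplicons
#'
#' The number of template positions shared by consecutive amplicons:
#' `(prev_rev_start + prev_rev_len) - next_fwd_start`, reduced modulo the
#' template length so wrapped junctions on circular genomes are handled by
#' the same arithmetic.
#'
#' @param prev_rev_start 1-based start of the previous pair's reverse-primer
#'   binding site (its 5'-most plus-strand coordinate).
#' @param prev_rev_len Length of the previous reverse primer (nt).
#' @param next_fwd_start 1-based start of the next pair's forward primer.
#' @param template_len Template length (nt).
#' @return Overlap in nt. A zero overlap (a coverage gap) is an error.
#' @examples
#' overlap_length(1058, 22, 976, 16702)  # 104
#' overlap_length(1956, 25, 1816, 16702) # 165
#' @export
overlap_length <- function(prev_rev_start, prev_rev_len, next_fwd_start,
                           template_len) {
  ov <- (prev_rev_start + prev_rev_len - next_fwd_start) %% template_len
  if (any(ov == 0)) {
    rlang::abort("adjacent amplicons do not overlap (coverage gap)",
                 class = "swarmprimer_coverage_error")
  }
  ov
}

#' Junction overlaps of a primer table
#'
#' Data-frame-first wrapper over [overlap_length()]: computes the overlap of
#' every cyclically adjacent pair (1 with 2, ..., last with 1) of an ordered
#' primer table.
#'
#' @param pairs Tibble with columns `rev_start`, `rev_len` and `fwd_start`,
#'   in tiling order.
#' @param template_len Template length (nt).
#' @return A tibble with columns `from`, `to` and `overlap`.
#' @export
tiling_overlaps <- function(pairs, template_len) {
  n <- nrow(pairs)
  nxt <- c(seq_len(n)[-1], 1L)
  tibble::tibble(
    from = seq_len(n), to = nxt,
    overlap = overlap_length(pairs$rev_start, pairs$rev_len,
                             pairs$fwd_start[nxt], template_len))
}

# Overlap-extension state of the current junction: the working overlap
# ceiling grows by `overlap_step` up to `overlap_cap` when no primer can be
# designed in the current window.
new_extension_state <- function(constraints) {
  list(max_overlap = constraints$max_overlap, extended = FALSE)
}

#' Extend the admissible overlap of the current junction
#'
#' When no suitable primer pair exists in the current sliding window, the
#' admissible overlap with the previous amplicon is enlarged stepwise, which
#' widens the window upstream; the junction is flagged as extended.
#'
#' @param state Extension state (list with `max_overlap` and `extended`),
#'   initially the constraint's `max_overlap`.
#' @param constraints A [design_constraints()].
#' @return The updated state.
#' @examples
#' st <- list(max_overlap = 200, extended = FALSE)
#' extend_overlap(st, design_constraints())$max_overlap  # 250
#' @export
extend_overlap <- function(state, constraints = design_constraints()) {
  if (state$max_overlap >= constraints$overlap_cap) {
    rlang::abort("overlap extension cap reached",
                 class = "swarmprimer_tiling_failure")
  }
  state$max_overlap <- min(state$max_overlap + constraints$overlap_step,
                           constraints$overlap_cap)
  state$extended <- TRUE
  state
}

#' Sliding window for the next amplicon
#'
#' The next forward primer must start far enough upstream of the previous
#' amplicon's end that the two amplicons share between `min_overlap` and the
#' current (possibly extended) maximum overlap. For a previous amplicon
#' ending at `prev_end`, the admissible forward starts are
#' `[prev_end - max_overlap + 1, prev_end - min_overlap + 1]`.
#'
#' @param prev_end Unwrapped end coordinate of the previous amplicon (its
#'   reverse-primer site 3' boundary on the plus strand).
#' @param constraints A [design_constraints()].
#' @param state Extension state (see [extend_overlap()]); `NULL` for the
#'   unextended default.
#' @return A [design_window()].
#' @examples
#' w <- next_window(1079)
#' c(w$fs_min, w$fs_max)  # 880 990
#' @export
next_window <- function(prev_end, constraints = design_constraints(),
                        state = NULL) {
  max_ov <- if (is.null(state)) constraints$max_overlap else state$max_overlap
  design_window(prev_end - max_ov + 1L, prev_end - constraints$min_overlap + 1L)
}

# Terms that must be exactly zero for a designed pair to be accepted into
# the tiling: conserved placement, product-length window, and the
# safety-critical secondary-structure/specificity/end-complementarity
# checks. The remaining (comfort) terms are minimized but not gating.
tiling_required_terms <- c("conserved", "product_len", "specificity",
                           "dimer", "hairpin", "endmatch")

pair_acceptable <- function(best_row) {
  all(unlist(best_row[paste0("pen_", tiling_required_terms)]) == 0)
}

#' Tile a circular genome with overlapping conserved primer pairs
#'
#' Walks the circular template designing one primer pair per amplicon: the
#' first window opens at the first conserved region; each subsequent window
#' is placed 90-200 nt (the overlap window) upstream of the previous
#' amplicon's end, intersected with the conserved regions, and optimized
#' with a particle swarm. When no acceptable pair is found the optimizer is
#' restarted, then the admissible overlap is extended stepwise up to a cap.
#' The walk stops once the running amplicon chain wraps past the first
#' forward primer with at least the minimum overlap, closing the circle.
#'
#' @param template A circular [template_sequence()].
#' @param regions Conserved-region tibble from [conserved_regions()].
#' @param constraints A [design_constraints()].
#' @param weights A [constraint_weights()].
#' @param thermo A [thermo_params()].
#' @param swarm A [swarm_config()].
#' @param seed Optional integer seed; fixes the whole design run.
#' @param restarts Fresh swarm restarts to attempt per window before
#'   extending the overlap.
#' @param quiet Suppress per-window progress messages.
#' @return An object of class `primer_tiling`: `pairs` (tibble, one row per
#'   pair with coordinates, sequences, Tm, GC and penalty breakdown),
#'   `junctions` (tibble with `from`, `to`, `overlap`, `extended`),
#'   `template_len`, `complete`, `failures`, `seed`. On an unrecoverable
#'   junction failure a partial tiling is returned with
#'   `complete = FALSE` and diagnostics in `failures`.
#' @export
tile_genome <- function(template, regions,
                        constraints = design_constraints(),
                        weights = constraint_weights(),
                        thermo = thermo_params(),
                        swarm = swarm_config(), seed = NULL, restarts = 5,
                        quiet = TRUE) {
  stopifnot(inherits(template, "template_sequence"))
  if (!template$circular) {
    rlang::abort("tile_genome() requires a circular template",
                 class = "swarmprimer_input_error")
  }
  if (nrow(regions) == 0L) {
    rlang::abort("no conserved regions to design in",
                 class = "swarmprimer_input_error")
  }
  if (!is.null(seed)) set.seed(seed)
  ctx <- make_eval_context(template, constraints, weights, thermo, regions)
  L <- template$length

  pairs <- list(); junctions <- list(); failures <- list()
  extended_flags <- logical(0)

  # First window: opens at the first conserved region's first base; its span
  # matches the width of a regular sliding window.
  first_start <- regions$start[1]
  win_width <- constraints$max_overlap - constraints$min_overlap + 1L
  window <- design_window(first_start, first_start + win_width - 1L)

  design_one <- function(window) {
    best <- NULL
    for (r in seq_len(restarts + 1L)) {
      res <- optimize_window(window, template, regions, constraints, weights,
                             thermo, swarm, .ctx = ctx)
      if (is.null(best) || res$fitness < best$fitness) best <- res
      if (pair_acceptable(res$best)) return(res)
    }
    best
  }

  state <- new_extension_state(constraints)
  anchor <- NA_integer_  # unwrapped forward start of pair 1
  prev_end <- NA_integer_
  set_no <- 0L
  repeat {
    res <- tryCatch(design_one(window), swarmprimer_infeasible = function(e) e)
    if (rlang::is_condition(res) || !pair_acceptable(res$best)) {
      st_new <- tryCatch(extend_overlap(state, constraints),
                         swarmprimer_tiling_failure = function(e) NULL)
      ok <- !is.null(st_new)
      if (ok) state <- st_new
      if (ok && set_no > 0L) {
        window <- next_window(prev_end, constraints, state)
        next
      }
      if (ok && set_no == 0L) {
        # first window: widen forwards instead (no previous junction)
        window <- design_window(window$fs_min,
                                window$fs_max + constraints$overlap_step)
        next
      }
      failures[[length(failures) + 1L]] <- list(
        after_set = set_no, window = c(window$fs_min, window$fs_max),
        reason = if (rlang::is_condition(res)) conditionMessage(res)
                 else "no acceptable pair within overlap cap")
      break
    }

    set_no <- set_no + 1L
    row <- res$best
    # recover the unwrapped start from the window interval
    fs_unwrapped <- window$fs_min +
      ((row$fwd_start - wrap_position(window$fs_min, L)) %% L)
    if (set_no == 1L) anchor <- fs_unwrapped
    end_unwrapped <- fs_unwrapped + row$product_len - 1L
    if (set_no > 1L) {
      junctions[[length(junctions) + 1L]] <- tibble::tibble(
        from = set_no - 1L, to = set_no,
        overlap = (prev_end + 1L) - fs_unwrapped,
        extended = state$extended)
    }
    pairs[[set_no]] <- dplyr::bind_cols(tibble::tibble(set = set_no), row)
    if (!quiet) {
      message(sprintf("set %d: fwd %d len %d, product %d, fitness %.2f",
                      set_no, row$fwd_start, row$fwd_len, row$product_len,
                      res$fitness))
    }
    prev_end <- end_unwrapped
    # Circular closure: stop once the chain wraps past the anchor with at
    # least the minimum overlap against pair 1.
    if (prev_end >= anchor + L + constraints$min_overlap - 1L) break
    state <- new_extension_state(constraints)
    window <- next_window(prev_end, constraints, state)
  }

  complete <- length(failures) == 0L && set_no >= 1L
  pairs_tbl <- dplyr::bind_rows(pairs)
  if (complete) {
    closing_overlap <- prev_end - (anchor + L) + 1L
    junctions[[length(junctions) + 1L]] <- tibble::tibble(
      from = set_no, to = 1L, overlap = closing_overlap,
      extended = closing_overlap > constraints$max_overlap)
  }
  structure(
    list(pairs = pairs_tbl,
         junctions = dplyr::bind_rows(junctions),
         template_len = L, template_id = template$id,
         complete = complete, failures = failures, seed = seed,
         constraints = constraints),
    class = "primer_tiling")
}

#' @export
print.primer_tiling <- function(x, ...) {
  cat(sprintf("<primer_tiling> %d pairs on %d nt circular template (%s)\n",
              nrow(x$pairs), x$template_len,
              if (x$complete) "complete" else "PARTIAL"))
  if (nrow(x$junctions)) {
    cat(sprintf("  junction overlaps: %d-%d nt, %d extended\n",
                min(x$junctions$overlap), max(x$junctions$overlap),
                sum(x$junctions$extended)))
  }
  invisible(x)
}

#' Fraction of template positions covered by the tiling's amplicons
#'
#' Exact interval arithmetic over the circle: each amplicon covers
#' `product_len` positions starting at its forward primer, wrapping through
#' the origin where needed.
#'
#' @param tiling A `primer_tiling`.
#' @return Fraction in \[0, 1\].
#' @export
tiling_coverage <- function(tiling) {
  covered <- rep(FALSE, tiling$template_len)
  for (i in seq_len(nrow(tiling$pairs))) {
    covered[circular_positions(tiling$pairs$fwd_start[i],
                               tiling$pairs$product_len[i],
                               tiling$template_len)] <- TRUE
  }
  mean(covered)
}
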