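#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a primer tiling
#'
#' @param x A `primer_tiling`.
#' @param ... Unused.
#' @return The pairs tibble, one row per designed primer pair.
#' @export
tidy.primer_tiling <- function(x, ...) x$pairs

#' One-row summary of a primer tiling
#'
#' @param x A `primer_tiling`.
#' @param ... Unused.
#' @return A one-row tibble: number of pairs, coverage fraction, overlap
#'   range, number of extended junctions, product-length range, completeness.
#' @export
glance.primer_tiling <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    coverage = tiling_coverage(x),
    min_overlap = if (nrow(x$junctions)) min(x$junctions$overlap) else NA_integer_,
    max_overlap = if (nrow(x$junctions)) max(x$junctions$overlap) else NA_integer_,
    n_extended = sum(x$junctions$extended),
    min_product = min(x$pairs$product_len),
    max_product = max(x$pairs$product_len),
    complete = x$complete)
}

#' Tidy a swarm result
#'
#' @param x A `swarm_result` from [optimize_window()].
#' @param ... Unused.
#' @return A tibble with `iteration` and `best_fitness` (the nonincreasing
#'   global-best trace).
#' @export
tidy.swarm_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history), best_fitness = x$history)
}

#' One-row summary of a swarm result
#'
#' @param x A `swarm_result`.
#' @param ... Unused.
#' @return A one-row tibble: final fitness, iterations, evaluations, and
#'   whether every constraint was satisfied (fitness 0).
#' @export
glance.swarm_result <- function(x, ...) {
  tibble::tibble(fitness = x$fitness,
                 iterations = length(x$history),
                 evaluations = x$evaluations,
                 all_satisfied = x$fitness == 0)
}
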