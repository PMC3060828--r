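primer_table_cols <- c("set", "fwd_seq", "fwd_start", "fwd_len", "fwd_gc",
                       "fwd_tm", "rev_seq", "rev_start", "rev_len", "rev_gc",
                       "rev_tm", "product_len")

#' Write a primer table as TSV
#'
#' One row per primer pair, in the conventional column order (set number,
#' forward sequence/start/length/GC/Tm, the same for the reverse primer, and
#' product length). GC% and Tm are carried in full precision internally and
#' rounded to 1 decimal place here, at write time.
#'
#' @param x A `primer_tiling` or a tibble with the primer-table columns.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_primer_table <- function(x, path) {
  tbl <- if (inherits(x, "primer_tiling")) x$pairs else tibble::as_tibble(x)
  if (nrow(tbl) == 0L) {
    writeLines(paste(primer_table_cols, collapse = "\t"), path)
    return(invisible(path))
  }
  if (!"set" %in% names(tbl)) tbl$set <- seq_len(nrow(tbl))
  # design results carry tm_f/gc_f-style names; map onto the table schema
  aliases <- c(fwd_tm = "tm_f", rev_tm = "tm_r", fwd_gc = "gc_f", rev_gc = "gc_r")
  for (col in names(aliases)) {
    if (!col %in% names(tbl) && aliases[[col]] %in% names(tbl)) {
      tbl[[col]] <- tbl[[aliases[[col]]]]
    }
  }
  for (col in c("fwd_gc", "fwd_tm", "rev_gc", "rev_tm")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
    tbl[[col]] <- round(tbl[[col]], 1)
  }
  utils::write.table(tbl[, primer_table_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer table written by [write_primer_table()]
#'
#' @param path TSV file path.
#' @return A tibble with the primer-table columns; coordinates are exact
#'   integers (only GC/Tm were rounded at write time).
#' @export
read_primer_table <- function(path) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(fwd_seq = "character",
                                          rev_seq = "character"),
                           stringsAsFactors = FALSE)
  tibble::as_tibble(tbl)
}

#' Write tiling intervals as BED
#'
#' Emits amplicons (and optionally primer binding sites) as BED intervals.
#' BED uses 0-based half-open coordinates, so position `p..q` (1-based
#' inclusive) becomes `p-1, q`; intervals wrapping the circular origin are
#' split into two lines sharing a name.
#'
#' @param tiling A `primer_tiling`.
#' @param path Output file path.
#' @param what `"amplicons"` or `"primers"`.
#' @return The path, invisibly.
#' @export
write_tiling_bed <- function(tiling, path, what = c("amplicons", "primers")) {
  what <- match.arg(what)
  L <- tiling$template_len
  chrom <- tiling$template_id
  bed_rows <- function(start, len, name) {
    end <- start + len - 1L
    if (end <= L) {
      tibble::tibble(chrom = chrom, chromStart = start - 1L, chromEnd = end,
                     name = name)
    } else {
      tibble::tibble(chrom = chrom, chromStart = c(start - 1L, 0L),
                     chromEnd = c(L, end - L), name = name)
    }
  }
  p <- tiling$pairs
  rows <- if (what == "amplicons") {
    purrr::map_dfr(seq_len(nrow(p)), function(i) {
      bed_rows(p$fwd_start[i], p$product_len[i], sprintf("amplicon_%d", p$set[i]))
    })
  } else {
    purrr::map_dfr(seq_len(nrow(p)), function(i) {
      dplyr::bind_rows(
        bed_rows(p$fwd_start[i], p$fwd_len[i], sprintf("fwd_%d", p$set[i])),
        bed_rows(p$rev_start[i], p$rev_len[i], sprintf("rev_%d", p$set[i])))
    })
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' Machine-readable record of a design run: seed, constraint configuration,
#' per-pair penalty breakdown, junction overlaps and extension flags.
#'
#' @param tiling A `primer_tiling`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_run_report <- function(tiling, path) {
  report <- list(
    template = list(id = tiling$template_id, length = tiling$template_len),
    seed = tiling$seed,
    complete = tiling$complete,
    constraints = unclass(tiling$constraints),
    pairs = tiling$pairs,
    junctions = tiling$junctions,
    failures = tiling$failures)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Assemble and validate a run configuration
#'
#' @param alignment Path to the input alignment (aligned FASTA or Clustal).
#' @param ref_id Record to use as the coordinate reference.
#' @param out_dir Output directory for the TSV/BED/JSON artifacts.
#' @param circular Is the genome circular?
#' @param min_region_len Minimum conserved-region length (defaults to the
#'   constraint's `len_min`).
#' @param constraints,weights,thermo,swarm Component configurations; lists
#'   of overrides are also accepted (e.g. from a YAML file).
#' @param seed Integer seed for the design run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(alignment, ref_id, out_dir = ".", circular = TRUE,
                       min_region_len = NULL,
                       constraints = design_constraints(),
                       weights = constraint_weights(),
                       thermo = thermo_params(), swarm = swarm_config(),
                       seed = 1L) {
  if (is.list(constraints) && !inherits(constraints, "design_constraints")) {
    constraints <- do.call(design_constraints, constraints)
  }
  if (is.list(weights) && !inherits(weights, "constraint_weights")) {
    weights <- do.call(constraint_weights, weights)
  }
  if (is.list(thermo) && !inherits(thermo, "thermo_params")) {
    thermo <- do.call(thermo_params, thermo)
  }
  if (is.list(swarm) && !inherits(swarm, "swarm_config")) {
    swarm <- do.call(swarm_config, swarm)
  }
  structure(list(alignment = alignment, ref_id = ref_id, out_dir = out_dir,
                 circular = isTRUE(circular),
                 min_region_len = min_region_len %||% constraints$len_min,
                 constraints = constraints, weights = weights,
                 thermo = thermo, swarm = swarm, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The file may contain top-level keys `alignment`, `ref_id`, `out_dir`,
#' `circular`, `min_region_len`, `seed`, and nested mappings `constraints`,
#' `weights`, `thermo`, `swarm` whose entries override the corresponding
#' defaults. Invalid bounds (e.g. `tm_min > tm_max`) are rejected here,
#' before any computation.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$alignment) || is.null(cfg$ref_id)) {
    rlang::abort("config must name 'alignment' and 'ref_id'",
                 class = "swarmprimer_config_error")
  }
  run_config(
    alignment = cfg$alignment, ref_id = cfg$ref_id,
    out_dir = cfg$out_dir %||% ".", circular = cfg$circular %||% TRUE,
    min_region_len = cfg$min_region_len,
    constraints = do.call(design_constraints, cfg$constraints %||% list()),
    weights = do.call(constraint_weights, cfg$weights %||% list()),
    thermo = do.call(thermo_params, cfg$thermo %||% list()),
    swarm = do.call(swarm_config, cfg$swarm %||% list()),
    seed = cfg$seed %||% 1L)
}

#' Run the full design pipeline
#'
#' Reads the alignment, extracts conserved regions on the chosen reference,
#' tiles the genome, and writes the primer table (TSV), amplicon/primer BED
#' files, a conserved-region BED and a JSON run report into the output
#' directory. Re-running with the same configuration and seed reproduces the
#' outputs byte for byte.
#'
#' @param config A [run_config()] (or the path to a YAML config file).
#' @return The `primer_tiling`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  aln <- read_alignment(config$alignment)
  template <- reference_template(aln, config$ref_id, circular = config$circular)
  regions <- conserved_regions(aln, config$ref_id,
                               min_len = config$min_region_len,
                               circular = config$circular)
  tiling <- tile_genome(template, regions, config$constraints,
                        config$weights, config$thermo, config$swarm,
                        seed = config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  write_primer_table(tiling, out("primers.tsv"))
  write_tiling_bed(tiling, out("amplicons.bed"), "amplicons")
  write_tiling_bed(tiling, out("primers.bed"), "primers")
  write_regions_bed(regions, out("conserved_regions.bed"), template)
  write_run_report(tiling, out("report.json"))
  invisible(tiling)
}
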