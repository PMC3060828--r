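# Nearest-neighbor thermodynamic parameter sets. Values are dinucleotide
# stacking terms for DNA/DNA duplexes: dH in kcal/mol, dS in cal/(mol K).
# Both tables are symmetric under reverse complement (value(XY) ==
# value(revcomp(XY))), which makes Tm(s) == Tm(revcomp(s)) hold exactly.

nn_tables <- list(
  # SantaLucia PNAS 1998 unified parameters, with per-end duplex-initiation
  # terms keyed on the terminal base (A/T vs G/C).
  santalucia1998 = list(
    dH = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0, TT = -7.9, TG = -8.5,
           AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0),
    dS = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9),
    end_dH = c(A = 2.3, C = 0.1, G = 0.1, T = 2.3),
    end_dS = c(A = 4.1, C = -2.8, G = -2.8, T = 4.1)
  ),
  # Breslauer PNAS 1986 parameters. The classical initiation entropy of
  # -10.8 cal/(mol K) is split evenly over the two duplex ends so that the
  # reverse-complement symmetry of the total remains explicit.
  breslauer1986 = list(
    dH = c(AA = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, GT = -6.5, CT = -7.8,
           GA = -5.6, CG = -11.9, GC = -11.1, GG = -11.0, TT = -9.1,
           TG = -5.8, AC = -6.5, AG = -7.8, TC = -5.6, CC = -11.0),
    dS = c(AA = -24.0, AT = -23.9, TA = -16.9, CA = -12.9, GT = -17.3,
           CT = -20.8, GA = -13.5, CG = -27.8, GC = -26.7, GG = -26.6,
           TT = -24.0, TG = -12.9, AC = -17.3, AG = -20.8, TC = -13.5,
           CC = -26.6),
    end_dH = c(A = 0, C = 0, G = 0, T = 0),
    end_dS = c(A = -5.4, C = -5.4, G = -5.4, T = -5.4)
  )
)

#' Thermodynamic parameters for melting-temperature calculation
#'
#' Bundles the nearest-neighbor stacking table, the duplex initiation terms,
#' the oligonucleotide concentration and the ionic conditions used by
#' [melting_temperature()]. The monovalent-equivalent salt concentration is
#' the von Ahsen combination `monovalent_mM + 120 * sqrt(mg_mM)`, the form
#' used by NetPrimer-style calculators.
#'
#' @param table Nearest-neighbor parameter set: `"santalucia1998"` (unified
#'   DNA parameters, the default) or `"breslauer1986"`.
#' @param conc_nM Total single-strand oligonucleotide concentration in nM
#'   (default 250 nM, the conventional PCR primer annealing concentration).
#' @param monovalent_mM Monovalent cation concentration in mM (default 50).
#' @param mg_mM Free Mg2+ concentration in mM (default 1.5).
#' @param R Molar gas constant in cal/(mol K).
#' @return An object of class `thermo_params`.
#' @examples
#' thermo_params()
#' thermo_params(table = "breslauer1986")
#' @export
thermo_params <- function(table = c("santalucia1998", "breslauer1986"),
                          conc_nM = 250, monovalent_mM = 50, mg_mM = 1.5,
                          R = 1.987) {
  table <- match.arg(table)
  stopifnot(conc_nM > 0, monovalent_mM > 0, mg_mM >= 0, R > 0)
  nn <- nn_tables[[table]]
  structure(
    list(table = table, nn = nn, conc_nM = conc_nM,
         monovalent_mM = monovalent_mM, mg_mM = mg_mM, R = R,
         salt_equivalent_mM = monovalent_mM + 120 * sqrt(mg_mM)),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "<thermo_params> %s, C = %g nM, [K+]eq = %.1f mM\n",
    x$table, x$conc_nM, x$salt_equivalent_mM))
  invisible(x)
}

check_acgt <- function(seq, what = "sequence") {
  if (length(seq) == 0L || any(!nzchar(seq))) {
    rlang::abort(paste(what, "must be nonempty"), class = "swarmprimer_input_error")
  }
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    rlang::abort(paste0(what, " contains characters outside A/C/G/T: ",
                        seq[bad][1]),
                 class = "swarmprimer_input_error")
  }
  invisible(seq)
}

#' GC content of primer sequences
#'
#' @param seq Character vector of A/C/G/T sequences (case-insensitive).
#' @return Numeric vector of GC percentages in \[0, 100\], computed exactly
#'   (rounding for display is left to the output writers).
#' @examples
#' gc_content(c("ATTTAGCCAATGACACCTAGCC", "GCGC", "AAAA"))
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  check_acgt(seq, "gc_content() input")
  n_gc <- nchar(gsub("[AT]", "", seq))
  100 * n_gc / nchar(seq)
}

# dH (kcal/mol) and dS (cal/(mol K)) of duplex formation for one sequence.
nn_sums <- function(seq, nn) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  di <- paste0(b[-length(b)], b[-1])
  ends <- c(b[1], b[length(b)])
  c(dH = sum(nn$dH[di]) + sum(nn$end_dH[ends]),
    dS = sum(nn$dS[di]) + sum(nn$end_dS[ends]))
}

#' Nearest-neighbor melting temperature
#'
#' Computes the duplex melting temperature of each primer against its perfect
#' complement as
#' `Tm(°C) = 1000 * dH / (dS + R * ln(C/4)) - 273.15 + 16.6 * log10([K+]eq)`,
#' where `dH` (kcal/mol) and `dS` (cal/(mol K)) accumulate nearest-neighbor
#' stacking terms plus duplex initiation terms, `C` is the oligonucleotide
#' concentration in mol/L and `[K+]eq` the monovalent-equivalent salt
#' concentration in mol/L.
#'
#' @param seq Character vector of primer sequences (length >= 2 nt each).
#' @param params A [thermo_params()] object.
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @seealso [tm_details()] for the underlying enthalpy/entropy terms.
#' @examples
#' melting_temperature("ATTTAGCCAATGACACCTAGCC")
#' @export
melting_temperature <- function(seq, params = thermo_params()) {
  seq <- toupper(seq)
  check_acgt(seq, "melting-temperature input")
  if (any(nchar(seq) < 2L)) {
    rlang::abort("melting temperature needs sequences of length >= 2",
                 class = "swarmprimer_input_error")
  }
  tm_calc(seq, params)
}

# Validation-free numeric core shared by melting_temperature()/tm_details()
# and the (hot) fitness evaluation path.
tm_calc <- function(seq, params) {
  nn <- params$nn
  C <- params$conc_nM * 1e-9
  denom_add <- params$R * log(C / 4)
  salt_term <- 16.6 * log10(params$salt_equivalent_mM / 1000)
  vapply(strsplit(seq, "", fixed = TRUE), function(b) {
    di <- paste0(b[-length(b)], b[-1])
    H <- sum(nn$dH[di]) + nn$end_dH[b[1]] + nn$end_dH[b[length(b)]]
    S <- sum(nn$dS[di]) + nn$end_dS[b[1]] + nn$end_dS[b[length(b)]]
    1000 * H / (S + denom_add) - 273.15 + salt_term
  }, numeric(1), USE.NAMES = FALSE)
}

#' Melting temperature with thermodynamic breakdown
#'
#' @inheritParams melting_temperature
#' @return A tibble with one row per sequence: `seq`, `dH` (kcal/mol), `dS`
#'   (cal/(mol K)), `salt_equivalent_mM` and `tm` (°C).
#' @export
tm_details <- function(seq, params = thermo_params()) {
  seq <- toupper(seq)
  check_acgt(seq, "melting-temperature input")
  if (any(nchar(seq) < 2L)) {
    rlang::abort("melting temperature needs sequences of length >= 2",
                 class = "swarmprimer_input_error")
  }
  hs <- vapply(seq, nn_sums, numeric(2), nn = params$nn)
  tibble::tibble(seq = seq, dH = unname(hs["dH", ]), dS = unname(hs["dS", ]),
                 salt_equivalent_mM = params$salt_equivalent_mM,
                 tm = tm_calc(seq, params))
}
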