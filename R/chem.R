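#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble
NULL

# Monoisotopic residue masses (Da), 20 canonical amino acids.
# A plain-text copy ships in inst/extdata/aa_monoisotopic_masses.tsv.
AA_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

MASS_PROTON <- 1.007276  # charge carrier; targeted-proteomics convention
MASS_WATER  <- 18.010565 # H2O, completes the peptide backbone

#' Monoisotopic amino-acid residue masses
#'
#' Residue (not free amino acid) monoisotopic masses in daltons for the 20
#' canonical amino acids, as used throughout the package's mass arithmetic.
#'
#' @return A tibble with columns `residue` and `mass`.
#' @export
#' @examples
#' aa_masses()
aa_masses <- function() {
  tibble(residue = names(AA_MONO), mass = unname(AA_MONO))
}

#' Default fixed modifications
#'
#' Carbamidomethylation of cysteine (+57.021464 Da), the fixed modification
#' introduced by chloroacetamide alkylation during standard sample
#' preparation. Supplied as the default `fixed_mods` of the mass functions.
#'
#' @return Named numeric vector of residue mass shifts in Da.
#' @export
default_fixed_mods <- function() {
  c(C = 57.021464)
}

check_sequence <- function(sequence) {
  if (length(sequence) == 0) abort("`sequence` must not be empty.")
  bad <- is.na(sequence) | !nzchar(sequence)
  if (any(bad)) abort("Peptide sequences must be non-empty strings.")
  chars <- strsplit(sequence, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    unknown <- which(!chars[[i]] %in% names(AA_MONO))
    if (length(unknown)) {
      abort(sprintf(
        "Unknown residue '%s' at position %d of sequence '%s'.",
        chars[[i]][unknown[1]], unknown[1], sequence[i]
      ))
    }
  }
  invisible(chars)
}

check_charge <- function(charge) {
  if (any(is.na(charge)) || any(charge < 1) || any(charge != as.integer(charge))) {
    abort("`charge` must be a positive integer.")
  }
  invisible(charge)
}

mod_shift <- function(chars, fixed_mods) {
  if (length(fixed_mods) == 0) return(0)
  sum(fixed_mods[match(chars, names(fixed_mods))], na.rm = TRUE)
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue monoisotopic masses plus one water, plus any fixed
#' modification shifts (by default carbamidomethyl cysteine).
#'
#' @param sequence Character vector of peptide sequences (uppercase
#'   one-letter codes, 20 canonical residues).
#' @param fixed_mods Named numeric vector mapping residue letters to mass
#'   shifts in Da. Use `numeric(0)` for none.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @export
#' @examples
#' peptide_mass("EGDLIAAQAR")
peptide_mass <- function(sequence, fixed_mods = default_fixed_mods()) {
  chars <- check_sequence(sequence)
  vapply(chars, function(ch) {
    sum(AA_MONO[ch]) + MASS_WATER + mod_shift(ch, fixed_mods)
  }, numeric(1))
}

#' Precursor m/z of a protonated peptide
#'
#' `[M + zH]z+` monoisotopic m/z: `(neutral mass + z * 1.007276) / z`.
#'
#' @inheritParams peptide_mass
#' @param charge Positive integer precursor charge(s), recycled against
#'   `sequence`.
#' @return Numeric vector of m/z values (full precision; see
#'   [round_half_up()] for 3-decimal reporting).
#' @export
#' @examples
#' precursor_mz("EGDLIAAQAR", 2)
precursor_mz <- function(sequence, charge, fixed_mods = default_fixed_mods()) {
  check_charge(charge)
  m <- peptide_mass(sequence, fixed_mods)
  (m + charge * MASS_PROTON) / charge
}

#' Fragment-ion m/z for the b and y series
#'
#' Singly- or multiply-protonated backbone fragment masses: a b ion is the
#' sum of the first `ordinal` residues; a y ion the sum of the last
#' `ordinal` residues plus water; both plus `charge` protons, divided by
#' `charge`.
#'
#' @inheritParams precursor_mz
#' @param series `"b"` or `"y"` (vectorised).
#' @param ordinal Fragment ordinal, `1 .. nchar(sequence) - 1`.
#' @param charge Fragment charge, default 1.
#' @return Numeric vector of fragment m/z values.
#' @export
#' @examples
#' fragment_mz("LADALQELR", "y", 7)   # y7+
#' fragment_mz("LADALQELR", "b", 2)   # b2+
fragment_mz <- function(sequence, series, ordinal, charge = 1L,
                        fixed_mods = default_fixed_mods()) {
  if (length(sequence) == 0) return(numeric(0))
  check_sequence(sequence)
  check_charge(charge)
  n <- max(length(sequence), length(series), length(ordinal), length(charge))
  sequence <- rep_len(sequence, n)
  series <- rep_len(series, n)
  ordinal <- rep_len(ordinal, n)
  charge <- rep_len(charge, n)
  if (!all(series %in% c("b", "y"))) abort("`series` must be \"b\" or \"y\".")
  out <- numeric(n)
  for (i in seq_len(n)) {
    len <- nchar(sequence[i])
    if (ordinal[i] < 1 || ordinal[i] > len - 1) {
      abort(sprintf(
        "Fragment ordinal %d out of range for '%s' (allowed 1..%d).",
        ordinal[i], sequence[i], len - 1
      ))
    }
    piece <- if (series[i] == "b") {
      substr(sequence[i], 1, ordinal[i])
    } else {
      substr(sequence[i], len - ordinal[i] + 1, len)
    }
    ch <- strsplit(piece, "", fixed = TRUE)[[1]]
    neutral <- sum(AA_MONO[ch]) + mod_shift(ch, fixed_mods) +
      if (series[i] == "y") MASS_WATER else 0
    out[i] <- (neutral + charge[i] * MASS_PROTON) / charge[i]
  }
  out
}

#' Round half away from zero
#'
#' Reporting helper matching the convention used for printed assay m/z
#' values: ties round up (10.0005 -> 10.001) rather than to even as in
#' base [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 3, the assay convention).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
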