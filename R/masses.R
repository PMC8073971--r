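# Monoisotopic residue masses and fragment mass arithmetic.
#
# All internal mass computation is done in exact integer units of 1e-5 Da
# (every residue mass has exactly 5 decimals), so that fragment sums are
# identical integers whatever the summation path. Floating-point sums would
# otherwise flip the discretization key of masses that sit exactly on a bin
# boundary (e.g. 1010.4115 Da at 0.001 Da precision), depending on whether a
# fragment mass is built by prefix accumulation or as "mass + delta_m".

# 1 Da = .MASS_SCALE integer units
.MASS_SCALE <- 1e5
.WATER_INT <- 1801056   # 18.01056 Da
.PROTON_INT <- 100728   # 1.00728 Da

#' Monoisotopic residue masses
#'
#' Returns the monoisotopic masses (in Daltons, 5 decimals) of the 20
#' canonical amino acid residues, i.e. the mass each residue contributes to a
#' peptide chain (free amino acid mass minus water). Isoleucine and leucine
#' are isobaric: `residue_masses()[["I"]] == residue_masses()[["L"]]`.
#'
#' @return Named numeric vector of length 20, names are one-letter residue
#'   codes.
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function() {
  c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
}

#' Physical mass constants
#'
#' Monoisotopic mass of water and of a proton, in Daltons. These are the two
#' constants needed to turn residue-mass sums into peptide masses (`+ water`)
#' and singly protonated fragment ion masses (`+ proton`).
#'
#' @return Named numeric vector with elements `water` and `proton`.
#' @export
mass_constants <- function() {
  c(water = .WATER_INT / .MASS_SCALE, proton = .PROTON_INT / .MASS_SCALE)
}

# residue masses in integer units, indexed by raw char code
.residue_lut <- local({
  lut <- rep(NA_real_, 127L)
  rm_ <- c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
  lut[utf8ToInt(paste(names(rm_), collapse = ""))] <- round(unname(rm_) * 1e5)
  lut
})

# per-residue masses of one sequence in integer units; errors on unknowns
.residue_int_vec <- function(sequence) {
  codes <- utf8ToInt(sequence)
  m <- .residue_lut[codes]
  if (anyNA(m)) {
    bad <- unique(intToUtf8(codes[is.na(m)], multiple = TRUE))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  m
}

# exact integer mass of a neutral peptide
.peptide_int <- function(sequence) {
  sum(.residue_int_vec(sequence)) + .WATER_INT
}

# round a mass in Da to exact integer units
.as_int_mass <- function(mass_da) round(mass_da * .MASS_SCALE)

#' Monoisotopic peptide mass
#'
#' Mass of the neutral peptide: sum of its residue masses plus one water.
#'
#' @param sequence Character vector of peptide sequences over the 20 canonical
#'   one-letter residue codes.
#' @return Numeric vector of masses in Daltons.
#' @export
#' @examples
#' peptide_mass("EAEDISEK") - peptide_mass("EAEISEK") # mass of D
peptide_mass <- function(sequence) {
  vapply(sequence, function(s) .peptide_int(s) / .MASS_SCALE,
         numeric(1), USE.NAMES = FALSE)
}

#' Discretize a fragment mass
#'
#' Maps a mass to an integer key, `round(mass / precision)`. Two masses are
#' considered shared between spectra iff their keys are equal. The default
#' precision of 0.001 Da keeps exact-composition coincidences together
#' (e.g. the GG dipeptide and an N residue differ by 1e-5 Da and share a key)
#' while avoiding floating-point equality tests.
#'
#' @param mass Numeric vector of masses (Da).
#' @param precision Positive bin width in Daltons (default 0.001).
#' @return Integer-valued numeric vector of keys.
#' @export
discretize <- function(mass, precision = 0.001) {
  stopifnot(is.numeric(precision), length(precision) == 1L, precision > 0)
  round(mass / precision)
}

# key from an exact integer mass; deterministic for a given integer
.key_from_int <- function(int_mass, precision) {
  round(int_mass / (precision * .MASS_SCALE))
}
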