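# Theoretical spectrum generation: annotated b/y fragment ion series.

#' Generate the annotated theoretical spectrum of a peptide
#'
#' Fragments the peptide in silico into its complete b and y ion series,
#' singly protonated and singly charged:
#' `b_i = sum(residues 1..i) + proton`, `y_i = sum(residues n-i+1..n) + water
#' + proton`, for `i = 1..n` (the full-length ions `b_n` and `y_n` are
#' included, so a peptide of length n yields exactly `2n` fragments).
#' Intensities are conceptually unit-valued and are not stored. Each fragment
#' is annotated with its generating subsequence: the length-`i` prefix for
#' `b_i`, the length-`i` suffix for `y_i`.
#'
#' @param sequence A single peptide sequence.
#' @param precision Discretization bin width in Da passed to [discretize()].
#' @return A [data.table::data.table] with columns `ion` ("b"/"y"), `index`,
#'   `mass`, `subseq` and integer `key`.
#' @export
#' @examples
#' generate_spectrum("EAEISEK") # 14 fragments
generate_spectrum <- function(sequence, precision = 0.001) {
  stopifnot(length(sequence) == 1L, nchar(sequence) >= 1L)
  m <- .residue_int_vec(sequence)
  n <- length(m)
  b <- cumsum(m) + .PROTON_INT
  y <- cumsum(rev(m)) + .WATER_INT + .PROTON_INT
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sub_b <- substring(sequence, 1L, seq_len(n))
  sub_y <- vapply(seq_len(n), function(i)
    paste(chars[(n - i + 1L):n], collapse = ""), character(1))
  out <- data.table::data.table(
    ion = rep(c("b", "y"), each = n),
    index = rep(seq_len(n), 2L),
    mass = c(b, y) / .MASS_SCALE,
    subseq = c(sub_b, sub_y)
  )
  out[, "key" := .key_from_int(c(b, y), precision)]
  out
}

# discretized key multiset of one peptide, as a sorted numeric vector
.spectrum_keys <- function(sequence, precision = 0.001) {
  m <- .residue_int_vec(sequence)
  sort(.key_from_int(c(cumsum(m) + .PROTON_INT,
                       cumsum(rev(m)) + .WATER_INT + .PROTON_INT),
                     precision))
}

#' Fragment key multisets for many peptides
#'
#' Vectorized companion of [generate_spectrum()] for the search engine: only
#' the discretized mass keys are produced, one multiset per peptide.
#'
#' @param sequences Character vector of peptide sequences.
#' @param precision Discretization bin width in Da.
#' @return List of sorted numeric key vectors, one per sequence.
#' @export
spectrum_keys <- function(sequences, precision = 0.001) {
  lapply(sequences, .spectrum_keys, precision = precision)
}

#' Dump spectra as a fragment table
#'
#' @param sequences Character vector of peptides.
#' @param precision Discretization bin width in Da.
#' @return One [data.table::data.table] with a `peptide` column followed by
#'   the [generate_spectrum()] columns.
#' @export
spectrum_table <- function(sequences, precision = 0.001) {
  data.table::rbindlist(lapply(sequences, function(s) {
    sp <- generate_spectrum(s, precision)
    sp[, "peptide" := s]
    data.table::setcolorder(sp, "peptide")
  }))
}
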