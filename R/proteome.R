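# Protein FASTA input, decoy construction and in-silico tryptic digestion.

.AA20 <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
           "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")

#' Read a protein FASTA file
#'
#' Parses a (possibly line-wrapped) amino acid FASTA file into a protein
#' table. The accession is the header token up to the first whitespace;
#' sequences are uppercased. Records with empty sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A [data.table::data.table] with columns `id`, `sequence` and
#'   `origin` (all `"target"`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no FASTA records in ", path)
  wid <- Biostrings::width(aa)
  if (any(wid == 0L)) {
    stop("empty sequence for record(s): ",
         paste(names(aa)[wid == 0L], collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(aa))
  data.table::data.table(
    id = ids,
    sequence = toupper(as.character(aa)),
    origin = "target"
  )
}

#' Write a protein table as FASTA
#'
#' @param proteins Protein table with columns `id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

.str_reverse <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Build the decoy database by protein reversal
#'
#' Each target protein yields one decoy whose full sequence is the reversal
#' of the target sequence. Reversal happens *before* digestion, so decoy
#' peptides are in general not reversed target peptides.
#'
#' @param proteins Protein table with `origin == "target"`.
#' @param decoy_tag Prefix added to each accession (default `"DECOY_"`).
#' @return Protein table with `origin == "decoy"`.
#' @export
#' @examples
#' p <- data.table::data.table(id = "P1", sequence = "MAAEISEK",
#'                             origin = "target")
#' make_decoy(p)$sequence # "KESIEAAM"
make_decoy <- function(proteins, decoy_tag = "DECOY_") {
  stopifnot(all(proteins$origin == "target"))
  data.table::data.table(
    id = paste0(decoy_tag, proteins$id),
    sequence = .str_reverse(proteins$sequence),
    origin = "decoy"
  )
}

#' Digestion parameters
#'
#' @param min_length Minimum retained peptide length (default 7).
#' @param max_length Maximum retained peptide length (default 30).
#' @param missed_cleavages Number of allowed missed cleavages. Only 0 is
#'   supported: the framework compares a fully tryptic peptide set to itself,
#'   so missed and semi-tryptic cleavage products cannot occur.
#' @return A list of class `digestion_params`.
#' @export
digestion_params <- function(min_length = 7L, max_length = 30L,
                             missed_cleavages = 0L) {
  stopifnot(min_length >= 1L, max_length >= min_length)
  if (missed_cleavages != 0L) {
    stop("only missed_cleavages = 0 is supported")
  }
  structure(list(min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 missed_cleavages = 0L),
            class = "digestion_params")
}

# tryptic cleavage of one sequence: cut after every K and R
.cleave_tryptic <- function(sequence) {
  strsplit(sequence, "(?<=[KR])", perl = TRUE)[[1]]
}

#' In-silico tryptic digestion
#'
#' Cleaves every protein after each lysine (K) and arginine (R), keeps the
#' C-terminal fragment whatever its final residue, then applies the study
#' filters: peptide length within `[min_length, max_length]` and no `X`
#' (unknown residue) anywhere in the peptide.
#'
#' @param proteins Protein table (columns `id`, `sequence`, `origin`).
#' @param params A [digestion_params()] object.
#' @return A [data.table::data.table] of peptides with columns `sequence`,
#'   `origin`, `parent` (one row per peptide occurrence) -- deduplicate with
#'   [build_peptide_sets()].
#' @export
digest <- function(proteins, params = digestion_params()) {
  stopifnot(inherits(params, "digestion_params"))
  pieces <- strsplit(proteins$sequence, "(?<=[KR])", perl = TRUE)
  n_per <- lengths(pieces)
  pep <- data.table::data.table(
    sequence = unlist(pieces, use.names = FALSE),
    origin = rep(proteins$origin, n_per),
    parent = rep(proteins$id, n_per)
  )
  len <- nchar(pep$sequence)
  keep <- len >= params$min_length & len <= params$max_length &
    !grepl("X", pep$sequence, fixed = TRUE)
  pep[keep]
}

#' Build deduplicated bait and database peptide sets
#'
#' Digests are deduplicated by exact sequence *within each origin*, merging
#' parent accessions. The bait set holds the distinct target peptides; the
#' database set is the union of distinct target and distinct decoy peptides
#' (a sequence present in both origins keeps one entry per origin). Peptide
#' monoisotopic masses are attached.
#'
#' @param target_proteins Target protein table.
#' @param decoy_proteins Decoy protein table (e.g. from [make_decoy()]).
#' @param params A [digestion_params()] object.
#' @return List with elements `bait` and `database`, each a
#'   [data.table::data.table] with columns `sequence`, `origin`, `parents`
#'   (semicolon-joined accessions) and `mass`.
#' @export
build_peptide_sets <- function(target_proteins, decoy_proteins,
                               params = digestion_params()) {
  dedup <- function(pep) {
    if (nrow(pep) == 0L) return(pep)
    sequence <- origin <- parent <- NULL # data.table NSE
    out <- pep[, .(parents = paste(sort(unique(parent)), collapse = ";")),
               by = .(sequence, origin)]
    data.table::setorder(out, sequence)
    out
  }
  tgt <- dedup(digest(target_proteins, params))
  dec <- dedup(digest(decoy_proteins, params))
  if (nrow(tgt) == 0L) {
    stop("no target peptides survive the length [", params$min_length, ",",
         params$max_length, "] and 'X' filters")
  }
  db <- rbind(tgt, dec)
  tgt[, "mass" := peptide_mass(tgt$sequence)]
  db[, "mass" := peptide_mass(db$sequence)]
  list(bait = tgt, database = db)
}
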