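# Brute-force oracles, independent of the package's search/realign code
# paths: fragment masses are built per fragment from substring residue sums
# (exact integer units of 1e-5 Da, summed residue by residue), candidate
# enumeration is an all-pairs double loop, and shifted spectra are rebuilt
# from scratch at every location.

RES_INT <- round(c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
) * 1e5)
WATER_INT <- 1801056
PROTON_INT <- 100728

oracle_sub_mass <- function(s) {
  if (nchar(s) == 0) return(0)
  sum(RES_INT[strsplit(s, "")[[1]]])
}

# every b/y fragment of a peptide with annotation, masses in integer units
oracle_fragments <- function(seq) {
  n <- nchar(seq)
  subs_b <- substring(seq, 1, seq_len(n))
  subs_y <- substring(seq, n - seq_len(n) + 1, n)
  data.frame(
    ion = rep(c("b", "y"), each = n),
    index = rep(seq_len(n), 2),
    int_mass = c(vapply(subs_b, oracle_sub_mass, 0) + PROTON_INT,
                 vapply(subs_y, oracle_sub_mass, 0) + WATER_INT + PROTON_INT),
    subseq = c(subs_b, subs_y),
    row.names = NULL
  )
}

oracle_keys <- function(seq, precision = 0.001) {
  round(oracle_fragments(seq)$int_mass / (precision * 1e5))
}

# multiset intersection size via table()
oracle_mult_intersect <- function(ka, kb) {
  ta <- table(ka)
  tb <- table(kb)
  common <- intersect(names(ta), names(tb))
  sum(pmin(ta[common], tb[common]))
}

oracle_spc <- function(a, b, precision = 0.001) {
  oracle_mult_intersect(oracle_keys(a, precision), oracle_keys(b, precision))
}

# shifted hit keys at one boundary, rebuilt from scratch
oracle_shifted_keys <- function(hit, delta_m, location, precision = 0.001) {
  fr <- oracle_fragments(hit)
  n <- nchar(hit)
  sh <- (fr$ion == "b" & fr$index >= location + 1) |
    (fr$ion == "y" & fr$index >= n - location)
  round((fr$int_mass + round(delta_m * 1e5) * sh) / (precision * 1e5))
}

oracle_best_shift <- function(bait, hit, delta_m, precision = 0.001) {
  bk <- oracle_keys(bait, precision)
  raw <- oracle_mult_intersect(bk, oracle_keys(hit, precision))
  best <- c(spc = raw, location = NA)
  for (l in 0:nchar(hit)) {
    spc <- oracle_mult_intersect(bk,
                                 oracle_shifted_keys(hit, delta_m, l, precision))
    if (spc > best[["spc"]] || (spc == best[["spc"]] && !is.na(best[["location"]]))) {
      best <- c(spc = spc, location = l)
    }
  }
  best
}

# all-pairs candidate enumeration by double loop (key count tables are
# precomputed per spectrum; the pairwise comparison is still exhaustive)
oracle_candidates <- function(bait_seqs, db_seqs, threshold, precision = 0.001) {
  tb <- lapply(bait_seqs, function(s) table(oracle_keys(s, precision)))
  td <- lapply(db_seqs, function(s) table(oracle_keys(s, precision)))
  out <- list()
  for (i in seq_along(bait_seqs)) {
    for (j in seq_along(db_seqs)) {
      if (bait_seqs[i] == db_seqs[j]) next
      common <- intersect(names(tb[[i]]), names(td[[j]]))
      spc <- sum(pmin(tb[[i]][common], td[[j]][common]))
      if (spc >= threshold) {
        out[[length(out) + 1L]] <- data.frame(bait_id = i, hit_id = j,
                                              raw_spc = spc)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(bait_id = integer(0), hit_id = integer(0), raw_spc = integer(0))
}

# LIPR on the raw (unshifted) alignment by exhaustive fragment comparison
oracle_lipr_raw <- function(bait, hit, precision = 0.001) {
  fb <- oracle_fragments(bait)
  fh <- oracle_fragments(hit)
  fb$key <- round(fb$int_mass / (precision * 1e5))
  fh$key <- round(fh$int_mass / (precision * 1e5))
  shared <- intersect(fb$key, fh$key)
  num <- 0
  den <- 0
  for (k in shared) {
    sb <- fb$subseq[fb$key == k]
    sh <- fh$subseq[fh$key == k]
    m <- min(length(sb), length(sh))
    den <- den + m
    if (!any(outer(sb, sh, "=="))) num <- num + m
  }
  num / den
}

# random tryptic-style peptides (terminal K/R, no internal K/R)
random_peptides <- function(n, seed, len_range = c(7, 14)) {
  set.seed(seed)
  inner <- setdiff(names(RES_INT)[1:20], c("K", "R"))
  unique(vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    paste0(paste(sample(inner, len - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1)))
}

# peptide table in the shape build_peptide_sets() produces
as_peptide_table <- function(seqs, origin = "target") {
  data.table::data.table(sequence = seqs, origin = origin, parents = "T",
                         mass = specshift::peptide_mass(seqs))
}

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
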