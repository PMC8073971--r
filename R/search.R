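# Candidate PSM enumeration over bait x database and Strategy1 selection.
#
# The all-vs-all comparison is driven by an inverted index on discretized
# fragment masses (key -> postings of spectrum id and multiplicity), which
# reproduces exactly the pairs an all-pairs scan would find.

#' Shared peaks count between two spectra
#'
#' Size of the multiset intersection of the discretized fragment mass keys of
#' two theoretical spectra: a key occurring `a` times in one spectrum and `b`
#' times in the other contributes `min(a, b)`.
#'
#' @param a,b Peptide sequences, or precomputed key vectors from
#'   [spectrum_keys()].
#' @param precision Discretization bin width in Da.
#' @return Integer shared peaks count.
#' @export
#' @examples
#' count_spc("EAEDISEK", "EAEISEK") # 7
count_spc <- function(a, b, precision = 0.001) {
  ka <- if (is.character(a)) .spectrum_keys(a, precision) else a
  kb <- if (is.character(b)) .spectrum_keys(b, precision) else b
  .spc_keys(ka, kb)
}

# multiset intersection size of two key vectors
.spc_keys <- function(ka, kb) {
  u <- c(ka, kb)
  lev <- unique(u)
  ia <- tabulate(match(ka, lev), nbins = length(lev))
  ib <- tabulate(match(kb, lev), nbins = length(lev))
  sum(pmin(ia, ib))
}

# long table of per-spectrum distinct keys with multiplicities
.fragment_index <- function(sequences, precision) {
  keys <- spectrum_keys(sequences, precision)
  n_per <- lengths(keys)
  dt <- data.table::data.table(
    spec = rep(seq_along(sequences), n_per),
    k = unlist(keys, use.names = FALSE)
  )
  data.table::setnames(dt, "k", "key")
  spec <- key <- NULL
  dt[, .(ct = .N), by = .(spec, key)]
}

#' Enumerate candidate PSMs
#'
#' Compares every bait spectrum against every database spectrum through the
#' fragment-mass inverted index and returns all pairs whose shared peaks
#' count reaches `threshold`. Pairs matching a peptide sequence to itself
#' (in either origin) are forbidden. For each candidate the precursor mass
#' difference `delta_m = mass(bait) - mass(hit)` is recorded.
#'
#' @param bait Bait peptide table (`sequence`, `mass`; e.g.
#'   `build_peptide_sets()$bait`).
#' @param database Database peptide table (`sequence`, `origin`, `mass`).
#' @param threshold Minimum raw SPC for a pair to become a candidate
#'   (default 7).
#' @param precision Discretization bin width in Da.
#' @return A [data.table::data.table] with columns `bait_id`, `hit_id` (row
#'   indices into `bait` and `database`), `bait_seq`, `hit_seq`,
#'   `hit_origin`, `raw_spc` and `delta_m`, ordered by `bait_id`, `hit_id`.
#' @export
enumerate_candidates <- function(bait, database, threshold = 7L,
                                 precision = 0.001) {
  stopifnot(threshold >= 1L, nrow(bait) > 0L, nrow(database) > 0L)
  bf <- .fragment_index(bait$sequence, precision)
  df <- .fragment_index(database$sequence, precision)
  data.table::setkey(df, key)
  j <- df[bf, on = "key", allow.cartesian = TRUE, nomatch = NULL]
  # j columns: spec (db id), key, ct (db mult), i.spec (bait id), i.ct
  spec <- i.spec <- ct <- i.ct <- raw_spc <- NULL
  cand <- j[, .(raw_spc = sum(pmin(ct, i.ct))), by = .(bait_id = i.spec,
                                                       hit_id = spec)]
  cand <- cand[raw_spc >= threshold]
  cand[, "bait_seq" := bait$sequence[cand$bait_id]]
  cand[, "hit_seq" := database$sequence[cand$hit_id]]
  cand <- cand[cand$bait_seq != cand$hit_seq]
  cand[, "hit_origin" := database$origin[cand$hit_id]]
  cand[, "delta_m" := bait$mass[cand$bait_id] - database$mass[cand$hit_id]]
  data.table::setorderv(cand, c("bait_id", "hit_id"))
  data.table::setcolorder(cand, c("bait_id", "hit_id", "bait_seq", "hit_seq",
                                  "hit_origin", "raw_spc", "delta_m"))
  cand[]
}

# deterministic best-per-bait selection shared by both strategies:
# max score, then smallest |delta_m|, then target before decoy, then
# lexicographically smallest hit sequence
.select_best <- function(cand, score_col) {
  ord <- order(cand$bait_id, -cand[[score_col]], abs(cand$delta_m),
               cand$hit_origin != "target", cand$hit_seq, method = "radix")
  best <- cand[ord][!duplicated(cand$bait_id[ord])]
  data.table::setorderv(best, "bait_id")
  best[]
}

#' Select best PSMs under Strategy1 (raw SPC)
#'
#' For each bait with at least one candidate, keeps the candidate with the
#' highest raw shared peaks count, ignoring `delta_m`. Ties are broken
#' deterministically: smallest `abs(delta_m)`, then target before decoy,
#' then lexicographically smallest hit sequence.
#'
#' @param candidates Output of [enumerate_candidates()].
#' @return One row per bait with a `score` column (`= raw_spc`) and
#'   `strategy = 1L`.
#' @export
select_best_strategy1 <- function(candidates) {
  best <- .select_best(candidates, "raw_spc")
  best[, "score" := best$raw_spc]
  best[, "strategy" := 1L]
  best[, "location" := NA_integer_]
  best[]
}
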