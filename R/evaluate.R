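# Quality measures over best PSMs: target/decoy FDR, delta-m grouping,
# Green/Orange/Red explainability classification, and LIPR.

# Two exact residue-mass sums only differ by float noise (~1e-12) when the
# residue multisets are identical; true compositional near-coincidences
# (e.g. GG vs N) sit at 1e-5 Da. 1e-6 separates the two regimes.
.DM_TOL <- 1e-6

#' Delta-m group of a PSM
#'
#' `G1` for `delta_m == 0`, `G2` for `delta_m > 0` (bait heavier than hit),
#' `G3` for `delta_m < 0`.
#'
#' @param delta_m Numeric vector of precursor mass differences.
#' @return Character vector of `"G1"`, `"G2"`, `"G3"`.
#' @export
delta_m_group <- function(delta_m) {
  ifelse(abs(delta_m) < .DM_TOL, "G1", ifelse(delta_m > 0, "G2", "G3"))
}

#' Target/decoy FDR at a score cutoff
#'
#' Restricts the best PSMs to `score >= min_score` and computes the false
#' discovery rate as the proportion of best PSMs whose hit is a decoy over
#' the total number of retained best PSMs: `FDR = D / (T + D)`. Counts are
#' also broken down by delta-m group and hit origin (the Table-1/2 row
#' shape).
#'
#' @param best Best-PSM table (columns `score`, `hit_origin`, `delta_m`).
#' @param min_score Score cutoff (default 0: keep everything).
#' @return One-row [data.table::data.table] with per-group counts,
#'   `total_target`, `total_decoy` and `fdr` (fraction in \[0,1\], `NA` when
#'   no PSM is retained).
#' @export
compute_fdr <- function(best, min_score = 0L) {
  kept <- best[best$score >= min_score]
  grp <- delta_m_group(kept$delta_m)
  tgt <- kept$hit_origin == "target"
  n_t <- sum(tgt)
  n_d <- sum(!tgt)
  data.table::data.table(
    min_score = min_score,
    g1_target = sum(tgt & grp == "G1"), g1_decoy = sum(!tgt & grp == "G1"),
    g2_target = sum(tgt & grp == "G2"), g2_decoy = sum(!tgt & grp == "G2"),
    g3_target = sum(tgt & grp == "G3"), g3_decoy = sum(!tgt & grp == "G3"),
    total_target = n_t, total_decoy = n_d,
    fdr = if (n_t + n_d > 0L) n_d / (n_t + n_d) else NA_real_
  )
}

#' FDR table over all observed score cutoffs
#'
#' @param best Best-PSM table.
#' @param scores Integer cutoffs; defaults to every observed score.
#' @return Stacked [compute_fdr()] rows, one per cutoff.
#' @export
fdr_table <- function(best, scores = sort(unique(best$score))) {
  data.table::rbindlist(lapply(scores, compute_fdr, best = best))
}

#' Minimum score reaching a target FDR
#'
#' Smallest score cutoff `s` such that the FDR of the best PSMs with
#' `score >= s` falls below `alpha`.
#'
#' @param best Best-PSM table.
#' @param alpha FDR level in (0,1), default 0.01.
#' @return Integer cutoff, or `NA` if no cutoff qualifies.
#' @export
threshold_at_fdr <- function(best, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  tab <- fdr_table(best)
  ok <- which(!is.na(tab$fdr) & tab$fdr < alpha)
  if (length(ok) == 0L) NA_integer_ else as.integer(tab$min_score[ok[1L]])
}

#' Minimum score reaching a target FDR from cumulative count rows
#'
#' Companion of [threshold_at_fdr()] for precomputed score distributions
#' (rows of cumulative target/decoy counts per minimum score, the shape in
#' which search engines report them).
#'
#' @param min_score Integer vector of score cutoffs.
#' @param total_target,total_decoy Cumulative counts at each cutoff.
#' @param alpha FDR level in (0,1).
#' @return Smallest `min_score` whose `D / (T + D)` is below `alpha`, or
#'   `NA`.
#' @export
threshold_from_curve <- function(min_score, total_target, total_decoy,
                                 alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  fdr <- total_decoy / (total_target + total_decoy)
  ord <- order(min_score)
  ok <- ord[!is.na(fdr[ord]) & fdr[ord] < alpha]
  if (length(ok) == 0L) NA_integer_ else as.integer(min_score[ok[1L]])
}

# ---------------------------------------------------------------------------
# sequence decomposition shared by the color classification and LIPR

# Splits bait vs hit into common prefix (length p), contested middles and
# common suffix (length s). With anchor = shift boundary l (and
# bait[1..l] == hit[1..l]), the prefix is pinned at l so that the contested
# interval sits where the spectra were realigned; otherwise the maximal
# common prefix is used, with the suffix maximal under p + s <= min(nb, nh).
.decompose <- function(bait, hit, anchor = NULL) {
  nb <- nchar(bait)
  nh <- nchar(hit)
  bc <- strsplit(bait, "", fixed = TRUE)[[1]]
  hc <- strsplit(hit, "", fixed = TRUE)[[1]]
  lim <- min(nb, nh)
  p <- 0L
  while (p < lim && bc[p + 1L] == hc[p + 1L]) p <- p + 1L
  if (!is.null(anchor) && !is.na(anchor) && anchor <= p) p <- as.integer(anchor)
  lim_s <- lim - p
  s <- 0L
  while (s < lim_s && bc[nb - s] == hc[nh - s]) s <- s + 1L
  list(p = p, s = s,
       bait_mid = substr(bait, p + 1L, nb - s),
       hit_mid = substr(hit, p + 1L, nh - s))
}

# how many distinct residue letters have a mass indistinguishable from
# `target_mass` at the given discretization (I and L always collide)
.n_residues_at_mass <- function(target_mass, precision) {
  rm_ <- residue_masses()
  sum(discretize(rm_, precision) == discretize(target_mass, precision))
}

#' Green/Orange/Red classification of a best PSM
#'
#' Measures how hard it is to reconstruct the bait sequence from the hit
#' sequence plus `delta_m` (and the shift location): the bait and hit are
#' decomposed into a common prefix, a contested interval and a common
#' suffix, and the contested interval is interpreted as the editing
#' operation explaining `delta_m`.
#'
#' * **Red**: `delta_m == 0` (different sequences of identical mass can
#'   never be realigned), or the differences require edits at two or more
#'   separated locations (the contested intervals share interior residues).
#' * **Green**: a single unambiguous edit reproduces the bait -- insertion
#'   of one residue whose mass matches `delta_m` uniquely, deletion of a
#'   contiguous hit substring of mass `-delta_m` (its content is read off
#'   the hit, so any length is unambiguous), or substitution of one residue
#'   by one residue of unambiguous mass.
#' * **Orange**: the location is known but the content is not fully
#'   determined -- insertion of two or more residues (their order cannot be
#'   deduced from `delta_m`), a single-residue insertion or substitution
#'   whose mass matches several residue letters (I/L), or a compact block
#'   replacement (consecutive edits at one location).
#'
#' @param bait_seq,hit_seq Peptide sequences.
#' @param delta_m `mass(bait) - mass(hit)`.
#' @param location Optional shift boundary of the PSM's alignment (used to
#'   anchor the decomposition; `NA` for Strategy1 or identity alignments).
#' @param precision Discretization bin width in Da (mass-ambiguity test).
#' @return `"Green"`, `"Orange"` or `"Red"`.
#' @export
#' @examples
#' classify_color("EAEDISEK", "EAEISEK", peptide_mass("D") -
#'   peptide_mass("")) # insertion of D: Green
classify_color <- function(bait_seq, hit_seq, delta_m, location = NA,
                           precision = 0.001) {
  if (abs(delta_m) < .DM_TOL) return("Red")
  d <- .decompose(bait_seq, hit_seq, anchor = location)
  bm <- d$bait_mid
  hm <- d$hit_mid
  lb <- nchar(bm)
  lh <- nchar(hm)
  # mass bookkeeping: the contested intervals must carry delta_m
  mid_dm <- (sum(.residue_int_vec(bm)) - sum(.residue_int_vec(hm))) /
    .MASS_SCALE
  if (abs(mid_dm - delta_m) > 1e-4) return("Red")
  if (lh == 0L && lb == 1L) {
    # single-residue insertion: Green iff the residue mass is unambiguous
    amb <- .n_residues_at_mass(.residue_int_vec(bm) / .MASS_SCALE, precision)
    return(if (amb == 1L) "Green" else "Orange")
  }
  if (lh == 0L && lb >= 2L) return("Orange") # multi-residue insertion
  if (lb == 0L) return("Green")              # contiguous deletion
  if (lb == 1L && lh == 1L) {
    # single-residue substitution
    amb <- .n_residues_at_mass(.residue_int_vec(bm) / .MASS_SCALE, precision)
    return(if (amb == 1L) "Green" else "Orange")
  }
  # block replacement: consecutive edits at one location are Orange; any
  # residue shared by both contested intervals is an interior anchor that
  # splits the difference into >= 2 separated edit sites -> Red
  if (length(intersect(strsplit(bm, "", fixed = TRUE)[[1]],
                       strsplit(hm, "", fixed = TRUE)[[1]])) == 0L) {
    "Orange"
  } else {
    "Red"
  }
}

# ---------------------------------------------------------------------------
# LIPR

# Is one matched fragment pair sequence-concordant?  Unshifted pairs are
# concordant iff their subsequences are identical strings.  A shifted hit
# fragment is concordant iff splicing the contested bait interval into it at
# the shift site reproduces the bait fragment's subsequence ("string
# surgery"), i.e. the unmodified residues agree.
.pair_concordant <- function(b_sub, h_sub, h_ion, h_index, h_shifted,
                             bait_seq, hit_seq, dec) {
  if (!h_shifted) return(b_sub == h_sub)
  if (is.null(dec)) return(FALSE)
  p <- dec$p
  lhm <- nchar(dec$hit_mid)
  nh <- nchar(hit_seq)
  nb <- nchar(bait_seq)
  if (h_ion == "b") {
    if (h_index < p + lhm) return(FALSE) # fragment covers the edit only partly
    surg <- paste0(substr(bait_seq, 1L, p + nchar(dec$bait_mid)),
                   substr(hit_seq, p + lhm + 1L, h_index))
  } else {
    if (h_index < nh - p) return(FALSE)
    surg <- paste0(substr(hit_seq, nh - h_index + 1L, p),
                   substr(bait_seq, p + 1L, nb))
  }
  surg == b_sub
}

#' Low Information Peaks Rate of a PSM
#'
#' Fraction of the shared masses of a PSM whose generating fragment
#' subsequences differ, i.e. mass matches that carry no sequence evidence.
#' A shared mass counts as informative when at least one pair of generating
#' fragments is sequence-concordant (identical subsequences for unshifted
#' matches; for matches created by the shift realignment, identical after
#' splicing the modification interval in or out at the shift site). LIPR is
#' 0 for a PSM whose every shared mass reflects identical local sequence,
#' and 1 when no shared mass does.
#'
#' @param bait_seq,hit_seq Peptide sequences.
#' @param delta_m `mass(bait) - mass(hit)` (default 0).
#' @param location Shift boundary of the PSM's alignment; `NA`/`NULL` scores
#'   the raw (unshifted) alignment.
#' @param precision Discretization bin width in Da.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' lipr("LESGAEEK", "LEGSAEEK") # 8/14
lipr <- function(bait_seq, hit_seq, delta_m = 0, location = NULL,
                 precision = 0.001) {
  bsp <- generate_spectrum(bait_seq, precision)
  use_shift <- !is.null(location) && !is.na(location) &&
    abs(delta_m) >= .DM_TOL
  if (use_shift) {
    hsp <- apply_shift(generate_spectrum(hit_seq, precision), delta_m,
                       location, precision)
    dec <- .decompose(bait_seq, hit_seq, anchor = location)
  } else {
    hsp <- generate_spectrum(hit_seq, precision)
    hsp[, "shifted" := FALSE]
    dec <- NULL
  }
  keys <- intersect(bsp$key, hsp$key)
  if (length(keys) == 0L) {
    stop("PSM has no shared masses; LIPR is undefined")
  }
  num <- 0L
  den <- 0L
  for (k in keys) {
    ib <- which(bsp$key == k)
    ih <- which(hsp$key == k)
    mult <- min(length(ib), length(ih))
    den <- den + mult
    conc <- FALSE
    for (i in ib) {
      for (j in ih) {
        if (.pair_concordant(bsp$subseq[i], hsp$subseq[j], hsp$ion[j],
                             hsp$index[j], hsp$shifted[j],
                             bait_seq, hit_seq, dec)) {
          conc <- TRUE
          break
        }
      }
      if (conc) break
    }
    if (!conc) num <- num + mult
  }
  num / den
}

# ---------------------------------------------------------------------------
# per-PSM evaluation and report tables

#' Evaluate best PSMs
#'
#' Attaches the delta-m group, the Green/Orange/Red color and the LIPR to
#' every best PSM of a strategy run.
#'
#' @param best Best-PSM table from [select_best_strategy1()] or
#'   [select_best_strategy2()].
#' @param precision Discretization bin width in Da.
#' @return The table with added `group`, `color` and `lipr` columns.
#' @export
evaluate_psms <- function(best, precision = 0.001) {
  out <- data.table::copy(best)
  out[, "group" := delta_m_group(out$delta_m)]
  loc <- if ("location" %in% names(out)) out$location else
    rep(NA_integer_, nrow(out))
  out[, "color" := mapply(classify_color, out$bait_seq, out$hit_seq,
                          out$delta_m, loc,
                          MoreArgs = list(precision = precision),
                          USE.NAMES = FALSE)]
  out[, "lipr" := mapply(function(b, h, dm, l)
    lipr(b, h, dm, l, precision = precision),
    out$bait_seq, out$hit_seq, out$delta_m, loc, USE.NAMES = FALSE)]
  out[]
}

#' Strategy-specific best-PSM sets
#'
#' Splits two best-PSM tables (one per strategy, keyed by bait) into the
#' PSMs specific to each: baits for which the two strategies selected
#' different hits. Both specific sets have the same size by construction.
#'
#' @param best1,best2 Best-PSM tables of Strategy1 and Strategy2.
#' @return List with elements `ss1` and `ss2`.
#' @export
strategy_specific_sets <- function(best1, best2) {
  stopifnot(identical(best1$bait_id, best2$bait_id))
  differ <- best1$hit_id != best2$hit_id
  list(ss1 = best1[differ], ss2 = best2[differ])
}

#' Color and LIPR summary of a PSM set
#'
#' Table-3-shaped one-row summary: count of PSMs per color class and the
#' average LIPR (as a percentage).
#'
#' @param evaluated An [evaluate_psms()] table.
#' @param label Optional dataset label.
#' @return One-row [data.table::data.table].
#' @export
summarize_colors <- function(evaluated, label = "") {
  data.table::data.table(
    dataset = label,
    n_green = sum(evaluated$color == "Green"),
    n_orange = sum(evaluated$color == "Orange"),
    n_red = sum(evaluated$color == "Red"),
    total = nrow(evaluated),
    mean_lipr_pct = if (nrow(evaluated)) 100 * mean(evaluated$lipr)
                    else NA_real_
  )
}

#' Color fractions by minimum score
#'
#' For each score cutoff, the fraction of retained PSMs in each color class
#' and the mean LIPR (the Figs 4/5 curve shape).
#'
#' @param evaluated An [evaluate_psms()] table.
#' @param scores Cutoffs; defaults to every observed score.
#' @return [data.table::data.table] with one row per cutoff.
#' @export
color_fraction_by_score <- function(evaluated,
                                    scores = sort(unique(evaluated$score))) {
  data.table::rbindlist(lapply(scores, function(s) {
    kept <- evaluated[evaluated$score >= s]
    data.table::data.table(
      min_score = s,
      n = nrow(kept),
      frac_green = mean(kept$color == "Green"),
      frac_orange = mean(kept$color == "Orange"),
      frac_red = mean(kept$color == "Red"),
      mean_lipr_pct = 100 * mean(kept$lipr)
    )
  }))
}
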