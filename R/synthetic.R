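# Seeded synthetic proteomes and planted-modification fixtures.

# run `code` under `seed` without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

#' Generate a random synthetic proteome
#'
#' Draws proteins over the 20 canonical residues with the combined K/R
#' frequency boosted so that tryptic digestion yields peptides mostly inside
#' the retained length range (mean inter-cleavage distance `1 / kr_prob`
#' residues). Sequence realism beyond cleavage-site density is not attempted:
#' the generator controls peptide lengths, which is what the downstream
#' pipeline is sensitive to. Deterministic given `seed`.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer range the protein lengths are drawn from
#'   uniformly (default 250--450, around the typical protein length).
#' @param kr_prob Combined probability of K or R per position (default 0.12,
#'   giving a mean tryptic peptide length around 8).
#' @param seed Integer RNG seed.
#' @param path Optional file path; when given the proteome is also written
#'   as FASTA.
#' @return Protein table (`id`, `sequence`, `origin = "target"`).
#' @export
generate_proteome <- function(n_proteins = 50L, length_range = c(250L, 450L),
                              kr_prob = 0.12, seed = 1L, path = NULL) {
  stopifnot(n_proteins >= 1L, kr_prob > 0, kr_prob < 1)
  aa <- .AA20
  probs <- rep((1 - kr_prob) / 18, 20)
  probs[aa %in% c("K", "R")] <- kr_prob / 2
  prot <- .with_seed(seed, {
    lens <- (length_range[1]:length_range[2])[sample.int(
      length_range[2] - length_range[1] + 1L, n_proteins, replace = TRUE)]
    data.table::data.table(
      id = sprintf("SYN%04d", seq_len(n_proteins)),
      sequence = vapply(lens, function(n)
        paste(sample(aa, n, replace = TRUE, prob = probs), collapse = ""),
        character(1)),
      origin = "target"
    )
  })
  if (!is.null(path)) write_fasta(prot, path)
  prot
}

# draw one element uniformly; safe for length-1 vectors (unlike sample())
.sample1 <- function(x) x[sample.int(length(x), 1L)]

# eligibility and drawing of one edit; returns NULL on an infeasible draw
.draw_edit <- function(kind, source, min_len, max_len) {
  aa <- .AA20
  n <- nchar(source)
  keys <- discretize(residue_masses(), 0.001)
  if (kind == "insert1") {
    if (n + 1L > max_len) return(NULL)
    site <- sample(0:n, 1L)
    res <- sample(aa, 1L)
    bait <- paste0(substr(source, 1, site), res, substr(source, site + 1, n))
    expected <- if (res %in% c("I", "L")) "Orange" else "Green"
    list(bait = bait, site = site, content = res,
         delta_m = unname(residue_masses()[res]), expected_color = expected)
  } else if (kind == "insertK") {
    if (n + 2L > max_len) return(NULL)
    site <- sample(0:n, 1L)
    res <- paste(sample(aa, 2L, replace = TRUE), collapse = "")
    bait <- paste0(substr(source, 1, site), res, substr(source, site + 1, n))
    list(bait = bait, site = site, content = res,
         delta_m = sum(.residue_int_vec(res)) / .MASS_SCALE,
         expected_color = "Orange")
  } else if (kind == "delete") {
    if (n - 1L < min_len) return(NULL)
    # bait length uniform over what a contiguous deletion allows
    bait_len <- .sample1(min_len:(n - 1L))
    k <- n - bait_len
    start <- .sample1(seq_len(n - k + 1L))
    content <- substr(source, start, start + k - 1L)
    bait <- paste0(substr(source, 1, start - 1L), substr(source, start + k, n))
    list(bait = bait, site = start - 1L, content = content,
         delta_m = -sum(.residue_int_vec(content)) / .MASS_SCALE,
         expected_color = "Green")
  } else if (kind == "substitute") {
    # a single substitution leaves n - 1 shared fragment masses, so sources
    # must exceed the length floor for the pair to stay above a candidate
    # threshold equal to min_len
    if (n < min_len + 1L) return(NULL)
    pos <- sample(seq_len(n), 1L)
    orig <- substr(source, pos, pos)
    # exclude the original letter and its mass-degenerate partners, which
    # would give delta_m = 0
    pool <- aa[keys != discretize(residue_masses()[orig], 0.001)]
    res <- sample(pool, 1L)
    bait <- source
    substr(bait, pos, pos) <- res
    expected <- if (res %in% c("I", "L")) "Orange" else "Green"
    list(bait = bait, site = pos, content = paste0(orig, ">", res),
         delta_m = unname(residue_masses()[res] - residue_masses()[orig]),
         expected_color = expected)
  } else if (kind == "twoSite") {
    if (n < min_len + 1L || n < 5L) return(NULL)
    # substitutions at two sites separated by >= 1 unchanged residue
    pos1 <- sample(seq_len(n - 2L), 1L)
    pos2 <- .sample1(seq(pos1 + 2L, n))
    bait <- source
    dm <- 0
    cont <- character(2)
    for (k in c(1L, 2L)) {
      pos <- c(pos1, pos2)[k]
      orig <- substr(source, pos, pos)
      pool <- aa[keys != discretize(residue_masses()[orig], 0.001)]
      res <- sample(pool, 1L)
      substr(bait, pos, pos) <- res
      dm <- dm + residue_masses()[res] - residue_masses()[orig]
      cont[k] <- paste0(orig, ">", res)
    }
    list(bait = bait, site = pos1, content = paste(cont, collapse = ","),
         delta_m = unname(dm), expected_color = "Red")
  } else {
    stop("unknown edit kind: ", kind)
  }
}

# adjacent-residue transposition of a bait usable as a database confounder:
# same mass (delta_m = 0), different sequence, raw SPC 2n-2 against the bait.
# Returns NA when no swap position yields a clean tryptic singleton.
.swap_confounder <- function(bait, avoid) {
  n <- nchar(bait)
  # internal K/R would make the confounder protein digest into pieces
  if (grepl("[KR]", substr(bait, 1L, n - 1L))) return(NA_character_)
  pos <- seq_len(n - 2L)
  pos <- pos[substr(bait, pos, pos) !=
               substr(bait, pos + 1L, pos + 1L)]
  if (length(pos) == 0L) return(NA_character_)
  for (i in pos[sample.int(length(pos))]) {
    sw <- bait
    substr(sw, i, i) <- substr(bait, i + 1L, i + 1L)
    substr(sw, i + 1L, i + 1L) <- substr(bait, i, i)
    if (!(sw %in% avoid)) return(sw)
  }
  NA_character_
}

#' Plant sequence edits into peptides
#'
#' Creates bait peptides by applying one specified editing operation to a
#' randomly drawn source peptide, and records the ground truth. Baits that
#' collide with an existing database sequence (self-matches are forbidden
#' downstream) or leave the retained length range are redrawn. The baits are
#' meant to be searched as extra "experimental" spectra against the
#' unmodified database, so the true source is always present.
#'
#' For a fraction `confound_rate` of the baits a *confounder* protein is
#' also emitted: an adjacent-residue transposition of the bait, to be
#' appended to the target database. A confounder has the same mass as its
#' bait (`delta_m = 0`) and shares all but two fragment masses with it
#' (raw SPC `2n - 2`), emulating the same-mass permuted peptide pairs that
#' are abundant in real proteomes and that dominate the `delta_m = 0` group
#' of best PSMs. They are what separates raw-SPC from shift-SPC ranking: a
#' raw-score selection prefers the confounder, while realignment restores
#' the true source (whose shift SPC is `2 * min(n_bait, n_hit)`).
#'
#' @param peptides Source peptide table (e.g. `build_peptide_sets()$bait`).
#' @param n_edits Number of baits to plant.
#' @param kinds Edit kinds to draw from: `"insert1"` (one residue),
#'   `"insertK"` (two residues), `"delete"` (contiguous block),
#'   `"substitute"` (one residue), `"twoSite"` (two separated
#'   substitutions).
#' @param seed Integer RNG seed.
#' @param forbidden Character vector of sequences baits must avoid
#'   (defaults to the source peptide sequences).
#' @param min_length,max_length Retained peptide length range.
#' @param confound_rate Fraction of baits that receive a same-mass
#'   transposed confounder in the database (default 0.2).
#' @return List with `baits` (peptide-table shape, `parents = "planted"`),
#'   `truth` (`bait`, `source`, `edit_kind`, `site`, `content`, `delta_m`,
#'   `expected_color`, `confounder`) and `confounders` (protein table to
#'   append to the target proteome; empty when none were drawn).
#' @export
plant_edits <- function(peptides, n_edits = 100L,
                        kinds = c("insert1", "delete", "substitute"),
                        seed = 1L, forbidden = peptides$sequence,
                        min_length = 7L, max_length = 30L,
                        confound_rate = 0.2) {
  stopifnot(n_edits >= 1L, nrow(peptides) >= 1L,
            confound_rate >= 0, confound_rate <= 1)
  truth <- .with_seed(seed, {
    rows <- vector("list", n_edits)
    taken <- character(0)
    for (i in seq_len(n_edits)) {
      repeat {
        kind <- .sample1(kinds)
        src <- peptides$sequence[sample.int(nrow(peptides), 1L)]
        e <- .draw_edit(kind, src, min_length, max_length)
        if (is.null(e)) next
        if (e$bait %in% forbidden || e$bait %in% taken || e$bait == src) next
        taken <- c(taken, e$bait)
        rows[[i]] <- data.table::data.table(
          bait = e$bait, source = src, edit_kind = kind, site = e$site,
          content = e$content, delta_m = e$delta_m,
          expected_color = e$expected_color
        )
        break
      }
    }
    tt <- data.table::rbindlist(rows)
    conf <- rep(NA_character_, n_edits)
    # only deletion/substitution baits are confounded: their source reaches
    # shift SPC 2 * min > 2n - 2, so realignment still separates truth from
    # confounder; for insertions the two scores tie structurally and the
    # ground truth would no longer be unique
    pick <- stats::runif(n_edits) < confound_rate &
      tt$edit_kind %in% c("delete", "substitute")
    for (i in which(pick)) {
      conf[i] <- .swap_confounder(tt$bait[i],
                                  c(forbidden, taken, conf[!is.na(conf)]))
    }
    tt[, "confounder" := conf]
    tt
  })
  baits <- data.table::data.table(
    sequence = truth$bait, origin = "target", parents = "planted",
    mass = peptide_mass(truth$bait)
  )
  confs <- truth$confounder[!is.na(truth$confounder)]
  confounders <- data.table::data.table(
    id = if (length(confs)) sprintf("CONF%03d", seq_along(confs))
         else character(0),
    sequence = confs,
    origin = rep("target", length(confs))
  )
  list(baits = baits, truth = truth, confounders = confounders)
}

#' The worked realignment example pair
#'
#' The bait/hit pair used throughout the documentation: bait `EAEDISEK`
#' against hit `EAEISEK` (one aspartate inserted after position 3). Their
#' spectra share 7 raw masses; shifting the hit by `delta_m = mass(D)` at
#' location 3 adds 8 matches and removes 1, for a shift SPC of 14.
#'
#' @return List with `bait`, `hit`, `delta_m`, `raw_spc`, `location`,
#'   `shift_spc`.
#' @export
fig2_fixture <- function() {
  list(bait = "EAEDISEK", hit = "EAEISEK",
       delta_m = unname(residue_masses()["D"]),
       raw_spc = 7L, location = 3L, shift_spc = 14L)
}

#' Planted-edit recovery experiment
#'
#' End-to-end exercise of the pipeline: generate a synthetic proteome,
#' digest it with decoys, plant `n_edits` modified baits, search them
#' against the merged target/decoy database under both strategies and score
#' how often each strategy returns the true source peptide as best PSM.
#'
#' A draw is flagged `alt_perfect` when the Strategy2 winner is a peptide
#' other than the source that is itself a perfect single-shift explanation
#' of the bait (score `>= 2 * min(length(bait), length(winner))`): for such
#' draws the database coincidentally holds a second equally valid source and
#' the ground truth is not unique. A draw is flagged `coincidence` when the
#' bait spectrum, or the source spectrum realigned at its best location,
#' contains duplicated mass keys: for those pairs the multiset SPC is
#' clipped below `2 * min(n_bait, n_hit)` even though every fragment aligns.
#'
#' @param n_proteins,n_edits,seed Generation parameters.
#' @param kinds Edit kinds passed to [plant_edits()].
#' @param confound_rate Fraction of baits with a same-mass transposed
#'   confounder in the database (see [plant_edits()]).
#' @param threshold Candidate SPC threshold.
#' @param precision Discretization bin width in Da.
#' @return List with `truth` (augmented with per-strategy outcomes),
#'   `best1`, `best2`, `sets`, and the counts `recovered1`, `recovered2`,
#'   `n_alt_perfect`, `n_coincidence`.
#' @export
recovery_experiment <- function(n_proteins = 50L, n_edits = 100L, seed = 1L,
                                kinds = c("insert1", "delete", "substitute"),
                                confound_rate = 0.2, threshold = 7L,
                                precision = 0.001) {
  prot <- generate_proteome(n_proteins, seed = seed)
  sets0 <- build_peptide_sets(prot, make_decoy(prot))
  planted <- plant_edits(sets0$bait, n_edits, kinds = kinds,
                         seed = seed + 1000003L,
                         forbidden = sets0$database$sequence,
                         confound_rate = confound_rate)
  # confounder proteins join the target proteome before decoy generation
  prot_all <- rbind(prot, planted$confounders)
  sets <- build_peptide_sets(prot_all, make_decoy(prot_all))
  cand <- enumerate_candidates(planted$baits, sets$database,
                               threshold = threshold, precision = precision)
  best1 <- select_best_strategy1(cand)
  best2 <- select_best_strategy2(cand, precision = precision)
  truth <- data.table::copy(planted$truth)
  truth[, "bait_id" := seq_len(nrow(truth))]
  m1 <- match(truth$bait_id, best1$bait_id)
  m2 <- match(truth$bait_id, best2$bait_id)
  truth[, "hit1" := best1$hit_seq[m1]]
  truth[, "hit2" := best2$hit_seq[m2]]
  truth[, "score2" := best2$score[m2]]
  truth[, "location2" := best2$location[m2]]
  truth[, "recovered1" := !is.na(truth$hit1) & truth$hit1 == truth$source]
  truth[, "recovered2" := !is.na(truth$hit2) & truth$hit2 == truth$source]
  truth[, "alt_perfect" := !truth$recovered2 & !is.na(truth$hit2) &
          truth$score2 >= 2L * pmin(nchar(truth$bait), nchar(truth$hit2))]
  truth[, "coincidence" := mapply(function(b, s, dm) {
    bk <- spectrum_keys(b, precision)[[1]]
    if (anyDuplicated(bk) > 0L) return(TRUE)
    bs <- best_shift(b, s, dm, precision)
    hk <- if (is.na(bs$location)) {
      spectrum_keys(s, precision)[[1]]
    } else {
      sp <- generate_spectrum(s, precision)
      apply_shift(sp, dm, bs$location, precision)$key
    }
    anyDuplicated(hk) > 0L
  }, truth$bait, truth$source, truth$delta_m, USE.NAMES = FALSE)]
  list(truth = truth, best1 = best1, best2 = best2, sets = sets,
       recovered1 = sum(truth$recovered1),
       recovered2 = sum(truth$recovered2),
       n_alt_perfect = sum(truth$alt_perfect),
       n_coincidence = sum(truth$coincidence))
}
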