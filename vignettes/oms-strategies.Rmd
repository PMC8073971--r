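---
title: "Comparing open-modification-search strategies on theoretical spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing open-modification-search strategies on theoretical spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specshift)
```

## The setting

Open modification search (OMS) identifies tandem mass spectra by comparing a
query spectrum against *all* peptides of a proteome, allowing the precursor
masses to differ by some Δm that is attributed to a modification. `specshift`
studies the two ranking strategies OMS engines use, in the cleanest setting
available: both sides of every comparison are *theoretical* spectra computed
from peptide sequences, so the true generating sequence of every query is
known and scoring behaviour can be evaluated exactly, without noise, missing
peaks or intensity models.

The pipeline is:

1. **Digestion** — proteins are cleaved after every K and R (trypsin),
   peptides shorter than 7 or longer than 30 residues, or containing `X`,
   are removed. A decoy database is built by reversing each protein *before*
   digestion, so decoy peptides are not simply reversed target peptides.
2. **Spectra** — a peptide of length $n$ yields the complete singly
   protonated b and y ion series ($b_i$ = prefix of length $i$ + proton;
   $y_i$ = suffix of length $i$ + water + proton), $2n$ annotated fragments
   including the full-length ions. Intensities are all unit and not stored.
3. **Search** — every *bait* (a target peptide playing the experimental
   role) is compared to every *hit* candidate in the merged target∪decoy
   database through an inverted index on discretized fragment masses. The
   similarity is the **shared peaks count** (SPC): the multiset intersection
   size of the two spectra's mass keys. Pairs with SPC ≥ 7 are candidate
   PSMs; a peptide is never matched to itself.
4. **Ranking** — *Strategy 1* keeps, per bait, the candidate with the
   highest raw SPC. *Strategy 2* first realigns every candidate with
   Δm ≠ 0: the hit's fragment masses are shifted by Δm at each possible
   location, and the best resulting SPC (the *shift SPC*) becomes the
   candidate's score.
5. **Evaluation** — target/decoy FDR = D/(T+D) over best PSMs above a score
   cutoff; a Green/Orange/Red classification of how unambiguously the bait
   sequence can be reconstructed from hit + Δm; and LIPR, the fraction of
   shared masses that carry no sequence evidence.

## Shift semantics and tie-breaking

A shift location $\ell \in \{0, \dots, n_{hit}\}$ is the boundary after hit
residue $\ell$ ($\ell = 0$: N-terminal side; $\ell = n_{hit}$: C-terminal
side). Shifting at $\ell$ adds Δm to every fragment whose residue span
crosses the boundary: $b_i$ for $i \ge \ell + 1$ and $y_i$ for
$i \ge n_{hit} - \ell$. The identity (no-shift) alignment is always kept as
a candidate, so shift SPC ≥ raw SPC holds by construction.

For the reference pair — bait `EAEDISEK`, hit `EAEISEK`, Δm = mass(D) — the
spectra share 7 raw masses; shifting at location 3 creates 8 new matches and
removes 1, for a shift SPC of 14:

```{r}
f <- fig2_fixture()
count_spc(f$bait, f$hit)
shift_match_delta(f$bait, f$hit, f$delta_m, location = 3)
best_shift(f$bait, f$hit, f$delta_m)
```

A subtlety worth recording: for a single inserted residue the optimum is
attained at *both* boundaries of the insertion (here $\ell = 2$ and
$\ell = 3$ are both 14), because fragment mass multisets commute across the
inserted residue — `mass(EAE) + D = mass(EAED)`. Ties between locations are
therefore broken towards the **largest** $\ell$, which is the boundary that
pins the maximal common prefix and is the conventional way to report the
modification site. The identity alignment wins only when no location
strictly improves the raw SPC.

## Mass arithmetic and discretization

Monoisotopic residue masses carry exactly five decimals, so all internal
mass computation uses exact integers in units of $10^{-5}$ Da. This is not a
micro-optimization: a fragment mass such as 1010.4115 Da sits exactly on a
0.001 Da bin boundary, and floating-point sums built along different paths
(prefix accumulation versus "raw mass + Δm") can round it into different
bins. With integer sums, identical masses are identical integers and the
discretization `key = round(mass / precision)` is deterministic.

The default `precision = 0.001` Da was chosen so that exact-composition
coincidences — GG vs N, GA vs Q, KE vs GVT, all equal to within
$10^{-5}$ Da — share a key, as they genuinely share a mass to any realistic
instrument, while everything farther apart stays separate. For
theoretical-vs-theoretical comparison any precision between roughly
$10^{-2}$ and $10^{-4}$ Da gives identical results except at those
coincidences; the value is a configuration key (`run_config(precision=)`).

SPC counts shared discretized mass *values* with min-multiplicity, not
annotated ion pairs: a key occurring twice in one spectrum and once in the
other contributes one. Duplicate keys inside a single theoretical spectrum
are rare composition coincidences; where they occur, a perfectly realigned
pair can score one below $2\min(n_{bait}, n_{hit})$, which the planted-edit
experiment accounts for by flagging such draws.

## The Green/Orange/Red classification

For a best PSM (bait, hit, Δm, location), the two sequences are decomposed
into a common prefix, a contested interval on each side, and a common
suffix. The prefix is anchored at the alignment's shift location when that
is consistent (`bait[1..l] == hit[1..l]`); otherwise the maximal common
prefix is used, with the suffix maximal under the no-overlap constraint.
The contested intervals are then read as the editing operation:

* Δm = 0 → **Red** (different sequences of equal mass cannot be realigned).
* Contested hit interval empty, one bait residue → single insertion:
  **Green** if the residue is the only letter with that mass at the working
  precision, **Orange** if several letters share it (I/L always do).
* Contested hit interval empty, several bait residues → **Orange**: the
  inserted composition is determined but its order is not ("AL" vs "LA").
* Contested bait interval empty → contiguous deletion: **Green** at any
  length, because the deleted content is read off the hit itself.
* One residue on each side → substitution: **Green**/**Orange** by the same
  mass-uniqueness rule as insertion.
* Both intervals non-empty and longer: a compact block replacement
  (consecutive edits at one location) is **Orange** when the two intervals
  share no residue letter; a shared letter is an interior anchor implying
  two or more separated edit sites → **Red**. A deduced edit whose interval
  masses cannot carry Δm is also **Red**.

The deduced edit always reproduces the bait by construction of the
decomposition; the interval-mass check guards the remaining degrees of
freedom. With this contract, planted single insertions/deletions/
substitutions classify Green (or Orange exactly when the inserted or
substituted residue is I/L), two-residue insertions classify Orange, and
two-site substitutions classify Red — verified against generated ground
truth in the test suite.

## LIPR

LIPR is the fraction of a PSM's shared masses for which *no* pair of
generating fragments is sequence-concordant. Unshifted matched pairs are
concordant iff their subsequences are identical strings. A matched pair
created by the realignment is concordant iff splicing the contested bait
interval into the hit fragment at the shift site reproduces the bait
fragment's subsequence (string surgery) — i.e. the unmodified residues
agree. This makes a correctly realigned single-edit PSM score LIPR = 0,
while a same-mass transposition pair like `LESGAEEK` vs `LEGSAEEK` scores
8/14: the six fragments that avoid the swapped region agree, the eight that
span it match by mass only.

```{r}
lipr("LESGAEEK", "LEGSAEEK")
lipr(f$bait, f$hit, f$delta_m, location = 3)
```

When a shared key has multiplicity above one, the key counts as informative
if *any* cross pair is concordant; the min-multiplicity then contributes to
neither side of the discordance count. This convention only matters at
composition coincidences.

## The synthetic proteome and what it does (not) emulate

`generate_proteome()` draws proteins uniformly over the 20 residues with
the combined K/R frequency raised to 0.12 (0.06 each), making the mean
tryptic fragment about 8 residues so that digestion populates the retained
7–30 range; protein lengths are uniform on 250–450. This controls the one
property the pipeline is sensitive to — peptide length distribution — and
nothing else: there is no residue-usage bias, no homology, no splice
isoforms, and no experimental-spectrum imperfection. Passing tests on this
generator therefore demonstrate the correctness of scoring, realignment and
evaluation, not performance on real proteomes, whose abundant near-duplicate
peptides make the search space much harder.

`plant_edits()` builds ground-truth baits by one editing operation on a
random database peptide. Two constraints keep the experiment about ranking
rather than about the candidate threshold: substitution sources must exceed
the length floor by one (a single substitution leaves $n - 1$ shared
masses, which must stay ≥ the threshold of 7), and deletion lengths are
drawn so the bait length is uniform over [7, n−1], populating the low-score
regime where ranking decisions are non-trivial.

Because a fully random database almost never contains a competitor close to
a planted bait, raw-SPC ranking would trivially match shift-SPC ranking on
it. Real proteomes are different: a large share of best PSMs pair peptides
of *equal* mass (Δm = 0) with high raw SPC — permuted compositions from
homologous sequences. The generator emulates exactly this population with
*confounders*: for a fraction (default 0.2) of the planted baits, an
adjacent-residue transposition of the bait is added to the target database.
A confounder has Δm = 0 and raw SPC $2n - 2$ against its bait, so raw-SPC
ranking prefers it to the true source (raw SPC ≈ n), while realignment
restores the source at shift SPC $2\min(n_{bait}, n_{hit}) > 2n - 2$. Only
deletion- and substitution-baits are confounded: for an insertion bait the
source's shift SPC is itself $2n - 2$, the two explanations tie, and the
ground truth would no longer be unique.

## Problem sizes and numerical choices

The test suite and the recovery experiment run at desk scale by design: 50
synthetic proteins (≈ 1,900 database peptides after decoys), 100 planted
edits, oracle cross-checks on 200 peptides with brute-force all-pairs and
all-locations recomputation. The full workflow scales to real FASTA inputs
through the same functions (`oms_run()`, `cmd_run()`), where runtime is
dominated by the candidate enumeration join and the per-candidate
realignment loop; a complete human-proteome run is supported but takes
hours, and exact agreement of best-PSM counts with other engines can differ
marginally through tie-breaking among equal scores.

Other choices that were genuinely open:

* **Best-PSM tie-break** (not specified by SPC alone): maximal score, then
  smallest |Δm|, then target before decoy, then lexicographically smallest
  hit sequence. Deterministic, and biased towards the least-modified,
  target-side explanation.
* **Peptide deduplication** happens within each origin separately; a
  sequence generated by both a target and a decoy protein keeps one entry
  per origin. Contaminant or extra proteins are ordinary target entries
  appended before decoy generation.
* **Δm = 0 test**: exact residue-mass sums are integers, so the test is
  exact; a tolerance of $10^{-6}$ Da on the Da-scale interface separates
  float noise from the smallest real composition difference ($10^{-5}$ Da).
* **`minimum_score = 60`** is mirrored in `run_config()` for configuration
  fidelity with the engine convention it comes from, but has no effect
  here; `single_match = TRUE` (one best PSM per bait) is the only supported
  mode, and missed or semi-tryptic cleavage is out of scope because a
  peptide set compared against itself cannot produce either.

## Known limitations

* Only b/y singly charged ions; no neutral losses, isotopes or charge
  states — deliberate, as the study design removes instrument effects.
* One shift site per PSM; Δm composed of edits at two separated locations
  is detected (Red) but not decomposed.
* The Red class conflates "nearly explainable" and "hopeless" PSMs; LIPR is
  the measure that separates them in practice.
* The classification reads its edit from one prefix/suffix decomposition;
  pathological repeats could admit an alternative edit of the same mass at
  another location, which would still be reported with the anchored
  location.
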